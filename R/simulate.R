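# Seeded synthetic-data generators. Each generator is a pure function of
# (ground truth, design, seed) and returns the peak tables the fitters
# consume together with a ground-truth sidecar for recovery tests.
# Intensity noise is multiplicative Gaussian (one fractional sigma).

.DEFAULT_R1_DELAYS <- c(0.01, 0.06, 0.12, 0.20, 0.35, 0.55, 0.85, 1.2)
.DEFAULT_R2_DELAYS <- c(0.008, 0.016, 0.03, 0.05, 0.08, 0.11, 0.15, 0.2)

#' Ground truth for a synthetic relaxation study
#'
#' Assembles the per-residue motional models and N-H orientations, the
#' global diffusion tensor, and the noise level that the generators use.
#'
#' @param residues A tibble with one row per residue: `residue` (integer id)
#'   and the motional parameters `model` ("M1".."M5"), `s2`, and optionally
#'   `tau_e` (ps), `s2f`, `rex` (1/s) and `nh_angle` (radians; required for
#'   axial tensors unless orientations are supplied as unit-vector columns
#'   `x`, `y`, `z`).
#' @param tensor The global [diffusion_tensor()].
#' @param noise Fractional Gaussian intensity noise (>= 0).
#'
#' @return An object of class `ground_truth`.
#' @examples
#' gt <- ground_truth(
#'   tibble::tibble(residue = 1:3, model = "M1", s2 = 0.9),
#'   diffusion_tensor("isotropic", tau_m = 10.8)
#' )
#' @export
ground_truth <- function(residues, tensor, noise = 0.02) {
  stopifnot(is.data.frame(residues), inherits(tensor, "diffusion_tensor"))
  if (nrow(residues) == 0) abort("`residues` must contain at least one residue.")
  if (noise < 0) abort("`noise` must be >= 0.")
  if (!all(c("residue", "model", "s2") %in% names(residues)))
    abort("`residues` needs at least columns residue, model, s2.")
  residues <- residues |>
    mutate(
      tau_e = if ("tau_e" %in% names(residues)) .data$tau_e else 0,
      s2f = if ("s2f" %in% names(residues)) .data$s2f else 1,
      rex = if ("rex" %in% names(residues)) .data$rex else 0
    ) |>
    mutate(tau_e = coalesce(.data$tau_e, 0), s2f = coalesce(.data$s2f, 1),
           rex = coalesce(.data$rex, 0))
  if (anyDuplicated(residues$residue)) abort("duplicate residue ids in truth.")
  if (tensor$kind != "isotropic") {
    if (all(c("x", "y", "z") %in% names(residues))) {
      v <- as.matrix(residues[, c("x", "y", "z")])
      v <- v / sqrt(rowSums(v^2))
      residues$nh_angle <- acos(pmin(1, abs(v %*% tensor$axis)))
      residues[, c("x", "y", "z")] <- v
    } else if (!("nh_angle" %in% names(residues))) {
      abort("axial tensor truth needs `nh_angle` or orientation columns x,y,z.")
    }
  }
  structure(list(residues = as_tibble(residues), tensor = tensor,
                 noise = noise),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d residues, %s tensor (tau_m %.3g ns), noise %.3g\n",
              nrow(x$residues), x$tensor$kind, x$tensor$tau_m, x$noise))
  invisible(x)
}

# truth rates per residue
.truth_rates <- function(truth, spin) {
  truth$residues |>
    rowwise() |>
    mutate(rates = list(relaxation_rates(
      motional_model(.data$model, s2 = .data$s2,
                     tau_e = if (.data$model %in% c("M2", "M4", "M5")) .data$tau_e else 0,
                     s2f = if (.data$model == "M5") .data$s2f else 1,
                     rex = if (.data$model %in% c("M3", "M4")) .data$rex else 0),
      truth$tensor, spin,
      nh_angle = if (truth$tensor$kind == "isotropic") NULL else .data$nh_angle
    ))) |>
    ungroup() |>
    tidyr::unnest("rates")
}

#' Simulate an R1/R2/NOE relaxation dataset
#'
#' Generates per-residue intensity decay series for R1 and R2
#' (`I(t) = I0 exp(-R t) (1 + eps)`, `eps ~ N(0, noise)`) and
#' saturated/reference NOE intensity pairs consistent with the ground-truth
#' NOE, mimicking interleaved experiments recorded with and without proton
#' pre-saturation.
#'
#' @param truth A [ground_truth()].
#' @param spin A [spin_system()].
#' @param delays_r1,delays_r2 Relaxation delay grids in s (>= 5 points each).
#' @param i0 Reference peak intensity (arbitrary units).
#' @param seed Integer seed; the output is a pure function of
#'   (truth, delays, seed).
#'
#' @return A list of class `relaxation_sim` with elements `decays` (tibble:
#'   residue, experiment, delay_s, intensity, sigma), `noe` (tibble:
#'   residue, i_sat, i_ref, sigma_sat, sigma_ref), `rates` (ground-truth
#'   R1/R2/NOE sidecar), `truth`, `spin` and `seed`.
#' @export
simulate_relaxation <- function(truth, spin,
                                delays_r1 = .DEFAULT_R1_DELAYS,
                                delays_r2 = .DEFAULT_R2_DELAYS,
                                i0 = 1e5, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spin, "spin_system"))
  if (length(delays_r1) < 5 || length(delays_r2) < 5)
    abort("at least 5 relaxation delays are required for R1 and for R2.")
  if (any(delays_r1 < 0) || any(delays_r2 < 0))
    abort("relaxation delays must be >= 0.")

  rates <- .truth_rates(truth, spin)
  noise <- truth$noise

  out <- .with_seed(seed, {
    decays <- bind_rows(
      crossing(rates["residue"], tibble(experiment = "R1", delay_s = delays_r1)) |>
        left_join(rates[, c("residue", "r1")], by = "residue") |>
        mutate(rate = .data$r1),
      crossing(rates["residue"], tibble(experiment = "R2", delay_s = delays_r2)) |>
        left_join(rates[, c("residue", "r2")], by = "residue") |>
        mutate(rate = .data$r2)
    ) |>
      mutate(
        intensity = i0 * exp(-.data$rate * .data$delay_s) *
          (1 + rnorm(n(), 0, noise)),
        sigma = noise * i0
      ) |>
      select("residue", "experiment", "delay_s", "intensity", "sigma") |>
      arrange(.data$residue, .data$experiment, .data$delay_s)

    noe <- rates |>
      transmute(
        .data$residue,
        i_sat = .data$noe * i0 * (1 + rnorm(n(), 0, noise)),
        i_ref = i0 * (1 + rnorm(n(), 0, noise)),
        sigma_sat = noise * i0,
        sigma_ref = noise * i0
      )
    list(decays = decays, noe = noe)
  })

  structure(list(decays = out$decays, noe = out$noe,
                 rates = rates[, c("residue", "model", "s2", "r1", "r2", "noe")],
                 truth = truth, spin = spin, seed = seed),
            class = "relaxation_sim")
}

#' Simulate a constant-time CPMG intensity dataset
#'
#' For each residue, field and nu_CPMG value (including the 0 Hz reference
#' and any duplicated points) generates
#' `I = i0 exp(-R2eff t_relax) (1 + eps)` with R2eff from the numerical
#' Bloch-McConnell propagator. Duplicate points receive independent noise.
#'
#' @param cluster A tibble with one row per residue: `residue`, `dw_ppm`
#'   and optionally per-field exchange-free rates as columns `r20` (single
#'   value for all fields); alternatively pass `r20` as a tibble
#'   (residue, field_mhz, r20) via the `r20` argument.
#' @param kex,pa Shared exchange rate (1/s) and major-state population.
#' @param design A [cpmg_design()].
#' @param r20 Exchange-free transverse rate specification: a single number,
#'   or a tibble (residue, field_mhz, r20). Overrides an `r20` column in
#'   `cluster`.
#' @param noise Fractional Gaussian intensity noise.
#' @param i0 Reference intensity.
#' @param seed Integer seed.
#' @param gamma_ratio gamma_H/gamma_N for the ppm to rad/s conversion.
#'
#' @return A list of class `cpmg_sim` with `intensities` (tibble: residue,
#'   field_mhz, nu_cpmg_hz, replicate, intensity), `r2eff` (noise-free
#'   ground-truth profiles), `truth` (kex, pa, per-residue dw, r20 table),
#'   `design` and `seed`.
#' @export
simulate_cpmg <- function(cluster, kex, pa, design = cpmg_design(),
                          r20 = 15, noise = 0.02, i0 = 1e6, seed = 1L,
                          gamma_ratio = -9.8655) {
  stopifnot(is.data.frame(cluster), inherits(design, "cpmg_design"))
  if (!all(c("residue", "dw_ppm") %in% names(cluster)))
    abort("`cluster` needs columns residue and dw_ppm.")
  if (!any(design$nu_cpmg == 0))
    abort("`design` must include the nu_cpmg = 0 reference plane.")
  nonzero <- design$nu_cpmg[design$nu_cpmg > 0]
  if (!anyDuplicated(nonzero))
    abort("`design` must duplicate at least one nonzero nu_cpmg value.")
  if (pa < 0.5 || pa > 1) abort("`pa` must lie in [0.5, 1].")

  r20_tbl <- if (is.data.frame(r20)) {
    as_tibble(r20)
  } else {
    crossing(residue = cluster$residue, field_mhz = design$fields) |>
      mutate(r20 = as.numeric(r20))
  }

  profiles <- crossing(cluster[, c("residue", "dw_ppm")],
                       field_mhz = design$fields) |>
    left_join(r20_tbl, by = c("residue", "field_mhz"))
  if (anyNA(profiles$r20)) abort("`r20` table does not cover every (residue, field).")

  truth_r2eff <- profiles |>
    rowwise() |>
    mutate(profile = list({
      nus <- design$nu_cpmg
      r2 <- rep(NA_real_, length(nus))
      nz <- nus > 0
      r2[nz] <- bloch_mcconnell_r2eff(nus[nz], kex, pa, .data$dw_ppm,
                                      .data$r20, .data$field_mhz,
                                      design$t_relax, gamma_ratio)
      tibble(nu_cpmg_hz = nus, r2eff = r2)
    })) |>
    ungroup() |>
    select("residue", "field_mhz", "profile") |>
    tidyr::unnest("profile") |>
    group_by(.data$residue, .data$field_mhz, .data$nu_cpmg_hz) |>
    mutate(replicate = row_number()) |>
    ungroup()

  intensities <- .with_seed(seed, {
    truth_r2eff |>
      mutate(
        decay = ifelse(is.na(.data$r2eff), 1, exp(-.data$r2eff * design$t_relax)),
        intensity = i0 * .data$decay * (1 + rnorm(n(), 0, noise))
      ) |>
      select("residue", "field_mhz", "nu_cpmg_hz", "replicate", "intensity")
  })

  structure(list(
    intensities = intensities,
    r2eff = filter(truth_r2eff, !is.na(.data$r2eff)),
    truth = list(kex = kex, pa = pa, papb = pa * (1 - pa),
                 cluster = as_tibble(cluster[, c("residue", "dw_ppm")]),
                 r20 = r20_tbl, noise = noise),
    design = design, seed = seed
  ), class = "cpmg_sim")
}

#' Simulate a pH-titration chemical-shift series
#'
#' Per-residue amide 1H/15N shifts follow a single-pKa sigmoid between an
#' acidic and a neutral endpoint, plus Gaussian shift noise. Residues can be
#' flagged unobservable above/below a given pH (emulating exchange-broadened
#' peaks that only become visible at lower pH) or emit a second, minor peak
#' inside a pH window (co-existing conformations).
#'
#' @param truth A tibble with one row per residue: `residue`, endpoint
#'   shifts `dh_high`, `dn_high` (at the high-pH end) and `dh_low`,
#'   `dn_low` (low-pH end), `pka`, and optionally `appear_below`
#'   (peak missing at pH above this), `vanish_below` (missing below this),
#'   `multi_lo`/`multi_hi` (second peak emitted for pH in this window).
#' @param ph pH series, sorted descending (e.g. 7.0 down to 1.5).
#' @param noise_h,noise_n Gaussian shift noise (ppm) for 1H and 15N.
#' @param seed Integer seed.
#'
#' @return A list of class `titration_sim` with `shifts` (tibble: residue,
#'   ph, dh_ppm, dn_ppm, status, peakset), `truth` and `seed`. Missing
#'   peaks carry `status = "missing"` and NA shifts.
#' @export
simulate_titration <- function(truth, ph = c(7, 6, 5, 4.5, 4, 3.5, 3.2, 2.8, 2.5, 2, 1.5),
                               noise_h = 0.002, noise_n = 0.01, seed = 1L) {
  stopifnot(is.data.frame(truth))
  if (length(ph) < 3) abort("at least 3 pH points are required.")
  if (is.unsorted(rev(ph), strictly = TRUE))
    abort("`ph` must be sorted strictly descending.")
  need <- c("residue", "dh_high", "dn_high", "dh_low", "dn_low", "pka")
  if (!all(need %in% names(truth)))
    abort(paste("`truth` needs columns", paste(need, collapse = ", ")))
  opt <- function(col, default) {
    if (col %in% names(truth)) coalesce(truth[[col]], default) else
      rep(default, nrow(truth))
  }
  tr <- tibble(
    residue = truth$residue,
    dh_high = truth$dh_high, dn_high = truth$dn_high,
    dh_low = truth$dh_low, dn_low = truth$dn_low, pka = truth$pka,
    appear_below = opt("appear_below", Inf),
    vanish_below = opt("vanish_below", -Inf),
    multi_lo = opt("multi_lo", NA_real_),
    multi_hi = opt("multi_hi", NA_real_)
  )

  shifts <- .with_seed(seed, {
    grid <- crossing(tr, ph = ph) |>
      mutate(
        frac = 1 / (1 + 10^(.data$pka - .data$ph)),  # -> 1 at high pH
        dh = .data$dh_low + (.data$dh_high - .data$dh_low) * .data$frac,
        dn = .data$dn_low + (.data$dn_high - .data$dn_low) * .data$frac,
        present = .data$ph <= .data$appear_below & .data$ph >= .data$vanish_below,
        multiple = .data$present & !is.na(.data$multi_lo) &
          .data$ph >= .data$multi_lo & .data$ph <= .data$multi_hi
      )
    major <- grid |>
      mutate(
        status = case_when(!.data$present ~ "missing",
                           .data$multiple ~ "multiple",
                           TRUE ~ "present"),
        peakset = "major",
        dh_ppm = ifelse(.data$present, .data$dh + rnorm(n(), 0, noise_h), NA_real_),
        dn_ppm = ifelse(.data$present, .data$dn + rnorm(n(), 0, noise_n), NA_real_)
      )
    minor <- grid |>
      filter(.data$multiple) |>
      mutate(
        status = "multiple", peakset = "minor",
        dh_ppm = .data$dh_low + rnorm(n(), 0, noise_h),
        dn_ppm = .data$dn_low + rnorm(n(), 0, noise_n)
      )
    bind_rows(major, minor) |>
      select("residue", "ph", "dh_ppm", "dn_ppm", "status", "peakset") |>
      arrange(desc(.data$ph), .data$residue, .data$peakset)
  })

  structure(list(shifts = shifts, truth = tr, seed = seed),
            class = "titration_sim")
}

# evaluate expr with a temporary, restored RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
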