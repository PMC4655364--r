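# Estimation of R1/R2 from intensity decays, NOE from saturated/reference
# pairs, and R2eff dispersion profiles from constant-time CPMG intensities.

#' Fit a mono-exponential intensity decay
#'
#' Nonlinear least-squares fit of `I(t) = I0 exp(-R t)` (Levenberg-
#' Marquardt, started from the log-linear regression). Parameter errors
#' come from the fit covariance by default, or from Monte Carlo resampling
#' of the residual scatter.
#'
#' @param delays Relaxation delays in s (>= 3 distinct values).
#' @param intensities Peak intensities (> 0 for the starting log-linear
#'   regression; individual noisy points may be <= 0 only if at least 3
#'   positive points remain).
#' @param sigma Intensity uncertainty; a single value or one per point.
#'   Used for chi-square weighting; if `NULL`, unit weights.
#' @param errors `"covariance"` or `"montecarlo"`.
#' @param n_mc Monte Carlo iterations when `errors = "montecarlo"`.
#' @param seed Seed for the Monte Carlo resampling.
#'
#' @return A one-row tibble: `rate`, `rate_sigma`, `i0`, `i0_sigma`,
#'   `chisq`, `converged`.
#' @examples
#' t <- c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8)
#' fit_monoexponential(t, 100 * exp(-12 * t))
#' @export
fit_monoexponential <- function(delays, intensities, sigma = NULL,
                                errors = c("covariance", "montecarlo"),
                                n_mc = 500, seed = 1L) {
  errors <- match.arg(errors)
  if (length(delays) != length(intensities))
    abort("`delays` and `intensities` lengths differ.")
  if (length(unique(delays)) < 3)
    abort("at least 3 distinct delays are required.")
  if (all(intensities <= 0)) abort("intensities must be positive.")
  w <- if (is.null(sigma)) rep(1, length(delays)) else {
    if (any(sigma <= 0)) abort("`sigma` must be positive.")
    1 / rep(sigma, length.out = length(delays))^2
  }

  pos <- intensities > 0
  if (sum(pos) < 3) abort("fewer than 3 positive intensities.")
  start_fit <- stats::lm(log(intensities[pos]) ~ delays[pos])
  start <- list(i0 = exp(unname(coef(start_fit)[1])),
                r = max(1e-6, -unname(coef(start_fit)[2])))

  df <- data.frame(t = delays, y = intensities, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-r * t), data = df, start = start,
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-12,
                                                           ptol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble(rate = NA_real_, rate_sigma = NA_real_, i0 = NA_real_,
                  i0_sigma = NA_real_, chisq = NA_real_, converged = FALSE))
  }
  cf <- coef(fit)
  resid <- intensities - cf["i0"] * exp(-cf["r"] * delays)
  chisq <- sum(w * resid^2)

  if (errors == "covariance") {
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
    # vcov scales by residual variance; for sigma-weighted chi-square errors
    # rescale to the supplied sigmas when they are meaningful
    if (!is.null(sigma) && length(delays) > 2) {
      s2_hat <- chisq / (length(delays) - 2)
      if (is.finite(s2_hat) && s2_hat > 0) se <- se / sqrt(s2_hat)
    }
    rate_sigma <- unname(se["r"]); i0_sigma <- unname(se["i0"])
  } else {
    sig <- if (is.null(sigma)) sqrt(mean(resid^2)) else
      rep(sigma, length.out = length(delays))
    draws <- .with_seed(seed, {
      vapply(seq_len(n_mc), function(i) {
        yy <- cf["i0"] * exp(-cf["r"] * delays) + rnorm(length(delays), 0, sig)
        f2 <- tryCatch(
          minpack.lm::nlsLM(y ~ i0 * exp(-r * t),
                            data = data.frame(t = delays, y = yy),
                            start = list(i0 = unname(cf["i0"]), r = unname(cf["r"])),
                            weights = w),
          error = function(e) NULL)
        if (is.null(f2)) c(NA_real_, NA_real_) else unname(coef(f2)[c("r", "i0")])
      }, numeric(2))
    })
    rate_sigma <- sd(draws[1, ], na.rm = TRUE)
    i0_sigma <- sd(draws[2, ], na.rm = TRUE)
  }

  tibble(rate = unname(cf["r"]), rate_sigma = rate_sigma,
         i0 = unname(cf["i0"]), i0_sigma = i0_sigma,
         chisq = chisq, converged = TRUE)
}

#' Fit all decay series in a decay table
#'
#' @param decays A decay table (columns residue, experiment, delay_s,
#'   intensity, and optionally sigma), as produced by
#'   [simulate_relaxation()] or read with [read_peak_table()].
#' @inheritParams fit_monoexponential
#' @return A tibble with one row per (residue, experiment): the
#'   [fit_monoexponential()] columns.
#' @export
fit_decays <- function(decays, errors = c("covariance", "montecarlo"),
                       n_mc = 500, seed = 1L) {
  errors <- match.arg(errors)
  stopifnot(is.data.frame(decays))
  if (!"experiment" %in% names(decays)) decays$experiment <- "R"
  decays |>
    group_by(.data$residue, .data$experiment) |>
    group_modify(~ fit_monoexponential(
      .x$delay_s, .x$intensity,
      sigma = if ("sigma" %in% names(.x) && all(is.finite(.x$sigma)) &&
                all(.x$sigma > 0)) .x$sigma else NULL,
      errors = errors, n_mc = n_mc, seed = seed
    )) |>
    ungroup()
}

#' Steady-state heteronuclear NOE from an intensity pair
#'
#' `NOE = I_sat/I_ref` with first-order error propagation
#' `sigma = |NOE| sqrt((s_sat/I_sat)^2 + (s_ref/I_ref)^2)` (and
#' `sigma = s_sat/|I_ref|` when `I_sat = 0`).
#'
#' @param i_sat,i_ref Peak intensities with and without proton
#'   pre-saturation; `i_ref` must be nonzero. Vectorised.
#' @param sigma_sat,sigma_ref Intensity uncertainties.
#' @return A tibble with columns `noe`, `noe_sigma`.
#' @examples
#' compute_noe(80, 100, 2, 2)
#' @export
compute_noe <- function(i_sat, i_ref, sigma_sat = 0, sigma_ref = 0) {
  if (any(i_ref == 0)) abort("`i_ref` must be nonzero.")
  noe <- i_sat / i_ref
  noe_sigma <- ifelse(
    i_sat == 0,
    sigma_sat / abs(i_ref),
    abs(noe) * sqrt((sigma_sat / i_sat)^2 + (sigma_ref / i_ref)^2)
  )
  tibble(noe = noe, noe_sigma = noe_sigma)
}

#' Assemble per-residue relaxation records
#'
#' Joins fitted R1, R2 and NOE values into the record format the
#' model-free machinery consumes, with the R2/R1 ratio and its first-order
#' propagated uncertainty.
#'
#' @param decay_fits Output of [fit_decays()] (experiments "R1" and "R2").
#' @param noe A NOE table (residue, i_sat, i_ref, sigma_sat, sigma_ref).
#' @param field_mhz Spectrometer 1H frequency (MHz) for bookkeeping.
#' @param ph Sample pH for bookkeeping.
#' @param peakset Peak-set label (major/minor).
#' @return A tibble with one row per residue: residue, ph, field_mhz,
#'   peakset, r1, r1_sigma, r2, r2_sigma, noe, noe_sigma, r2_r1,
#'   r2_r1_sigma.
#' @export
relaxation_records <- function(decay_fits, noe, field_mhz, ph = NA_real_,
                               peakset = "major") {
  stopifnot(is.data.frame(decay_fits), is.data.frame(noe))
  wide <- decay_fits |>
    filter(.data$experiment %in% c("R1", "R2")) |>
    select("residue", "experiment", "rate", "rate_sigma") |>
    pivot_wider(names_from = "experiment",
                values_from = c("rate", "rate_sigma")) |>
    rename(r1 = "rate_R1", r2 = "rate_R2",
           r1_sigma = "rate_sigma_R1", r2_sigma = "rate_sigma_R2")
  noe_fit <- noe |>
    mutate(compute_noe(.data$i_sat, .data$i_ref,
                       .data$sigma_sat, .data$sigma_ref)) |>
    select("residue", "noe", "noe_sigma")
  wide |>
    left_join(noe_fit, by = "residue") |>
    mutate(
      ph = ph, field_mhz = field_mhz, peakset = peakset,
      r2_r1 = .data$r2 / .data$r1,
      r2_r1_sigma = .data$r2_r1 *
        sqrt((.data$r2_sigma / .data$r2)^2 + (.data$r1_sigma / .data$r1)^2)
    ) |>
    select("residue", "ph", "field_mhz", "peakset", "r1", "r1_sigma",
           "r2", "r2_sigma", "noe", "noe_sigma", "r2_r1", "r2_r1_sigma")
}

#' Compute R2eff dispersion profiles from CPMG intensities
#'
#' Applies `R2eff = -(1/t_relax) log(I_nu/I_0)` per residue and field,
#' collapsing duplicated nu_CPMG points to their mean intensity. The
#' per-point intensity error is the fractional scatter of the duplicated
#' points, `|I_a - I_b|/sqrt(2)` pooled across residues (per field), with a
#' configurable fractional floor; whichever is larger applies.
#'
#' @param intensities CPMG intensity table (residue, field_mhz, nu_cpmg_hz,
#'   replicate, intensity) including the nu_cpmg = 0 reference.
#' @param t_relax Constant relaxation time in s.
#' @param sigma_floor Minimum fractional intensity error.
#' @return A tibble of class `dispersion_profile`: residue, field_mhz,
#'   nu_cpmg_hz, r2eff, r2eff_sigma, i0.
#' @export
r2eff_profile <- function(intensities, t_relax = 0.060, sigma_floor = 0.005) {
  stopifnot(is.data.frame(intensities))
  if (!any(intensities$nu_cpmg_hz == 0))
    abort("the nu_cpmg = 0 reference plane is missing.")
  if (any(intensities$intensity <= 0))
    abort("non-positive CPMG intensities cannot be converted to R2eff.")

  # pooled fractional duplicate error per field
  dup_sigma <- intensities |>
    filter(.data$nu_cpmg_hz > 0) |>
    group_by(.data$field_mhz, .data$residue, .data$nu_cpmg_hz) |>
    filter(n() >= 2) |>
    summarise(frac = abs(diff(.data$intensity[1:2])) / sqrt(2) /
                mean(.data$intensity), .groups = "drop") |>
    group_by(.data$field_mhz) |>
    summarise(sigma_frac = sqrt(mean(.data$frac^2)), .groups = "drop") |>
    mutate(sigma_frac = pmax(.data$sigma_frac, sigma_floor))
  if (nrow(dup_sigma) == 0)
    dup_sigma <- tibble(field_mhz = unique(intensities$field_mhz),
                        sigma_frac = sigma_floor)

  refs <- intensities |>
    filter(.data$nu_cpmg_hz == 0) |>
    group_by(.data$residue, .data$field_mhz) |>
    summarise(i0 = mean(.data$intensity), .groups = "drop")

  out <- intensities |>
    filter(.data$nu_cpmg_hz > 0) |>
    group_by(.data$residue, .data$field_mhz, .data$nu_cpmg_hz) |>
    summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    left_join(refs, by = c("residue", "field_mhz")) |>
    left_join(dup_sigma, by = "field_mhz") |>
    mutate(
      r2eff = -log(.data$intensity / .data$i0) / t_relax,
      r2eff_sigma = .data$sigma_frac / t_relax
    ) |>
    select("residue", "field_mhz", "nu_cpmg_hz", "r2eff", "r2eff_sigma", "i0") |>
    arrange(.data$residue, .data$field_mhz, .data$nu_cpmg_hz)
  class(out) <- c("dispersion_profile", class(out))
  attr(out, "t_relax") <- t_relax
  out
}
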