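# Two-state CPMG dispersion fitting: exchange detection, per-residue fits,
# clustered global fits with shared (kex, pA pB), and population algebra.
# The numerical Bloch-McConnell propagator is the forward model throughout;
# since the exchange-free rate enters R2eff additively, the per-(residue,
# field) r20 values are profiled out exactly at each objective evaluation.

.DEFAULT_KEX_GRID <- c(200, 500, 1000, 2000, 4000)
.DEFAULT_PAPB_GRID <- c(0.005, 0.02, 0.05)

# exchange contribution matrix for one residue: rows follow `rows` order
.exch_contrib <- function(kex, papb, dw_ppm, nu, field, t_relax, gamma_ratio) {
  pa <- population_from_product(papb)
  out <- numeric(length(nu))
  for (f in unique(field)) {
    idx <- field == f
    out[idx] <- .bm_contrib(nu[idx], kex, pa, .dw_rad(dw_ppm, f, gamma_ratio),
                            t_relax)
  }
  out
}

# chi-square with r20 profiled out per (residue, field) group
.disp_chisq <- function(contrib, obs, w, grp) {
  resid <- obs - contrib
  # optimal r20 per group = weighted mean of residuals
  mw <- tapply(w * resid, grp, sum) / tapply(w, grp, sum)
  sum(w * (resid - mw[grp])^2)
}

#' Major-state population from the pA pB product
#'
#' Inverts `q = pA (1 - pA)` under the two-state constraint, returning the
#' major root `pA = (1 + sqrt(1 - 4q))/2`.
#'
#' @param q Population product in \[0, 0.25\]; vectorised.
#' @return pA in \[0.5, 1\].
#' @examples
#' population_from_product(0.028)  # ~0.9712
#' @export
population_from_product <- function(q) {
  if (any(q < 0 | q > 0.25 + 1e-12))
    abort("`q` must lie in [0, 0.25].")
  (1 + sqrt(pmax(0, 1 - 4 * q))) / 2
}

# assemble the flat vectors a fit needs from a dispersion profile tibble
.disp_data <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  need <- c("residue", "field_mhz", "nu_cpmg_hz", "r2eff", "r2eff_sigma")
  if (!all(need %in% names(profiles)))
    abort(paste("profiles need columns", paste(need, collapse = ", ")))
  profiles <- arrange(profiles, .data$residue, .data$field_mhz, .data$nu_cpmg_hz)
  list(
    res = profiles$residue,
    field = profiles$field_mhz,
    nu = profiles$nu_cpmg_hz,
    obs = profiles$r2eff,
    w = 1 / profiles$r2eff_sigma^2,
    grp = interaction(profiles$residue, profiles$field_mhz, drop = TRUE)
  )
}

#' Test a residue for conformational exchange
#'
#' Compares a flat model (one constant R2eff per field) against the
#' two-state exchange fit by an F-test at level `alpha`.
#'
#' @param profiles Dispersion profile tibble for one residue (both fields;
#'   >= 6 points total), from [r2eff_profile()].
#' @param t_relax Constant relaxation time in s.
#' @param alpha Test level.
#' @param gamma_ratio gamma_H/gamma_N for ppm conversion.
#' @return A one-row tibble: `exchanging`, `f_statistic`, `p_value`,
#'   `chisq_flat`, `chisq_exchange`.
#' @export
detect_exchange <- function(profiles, t_relax = 0.060, alpha = 0.05,
                            gamma_ratio = -9.8655) {
  d <- .disp_data(profiles)
  n <- length(d$obs)
  if (n < 6) abort("at least 6 dispersion points are required.")
  n_fields <- length(unique(d$field))

  mw <- tapply(d$w * d$obs, d$grp, sum) / tapply(d$w, d$grp, sum)
  chisq_flat <- sum(d$w * (d$obs - mw[d$grp])^2)

  fit <- fit_dispersion(profiles, t_relax = t_relax, n_mc = 0,
                        gamma_ratio = gamma_ratio)
  chisq_exch <- fit$chisq
  p_flat <- n_fields
  p_exch <- 3 + n_fields
  df2 <- n - p_exch
  f_stat <- if (df2 > 0 && chisq_exch > 0)
    ((chisq_flat - chisq_exch) / (p_exch - p_flat)) / (chisq_exch / df2)
  else Inf
  p_val <- pf(f_stat, p_exch - p_flat, max(df2, 1), lower.tail = FALSE)
  tibble(exchanging = is.finite(f_stat) && f_stat > 0 && p_val < alpha,
         f_statistic = f_stat, p_value = p_val,
         chisq_flat = chisq_flat, chisq_exchange = chisq_exch)
}

# core minimisation shared by single-residue and global fits. The shared
# parameters are optimised as (log kex, log papb) so all coordinates have
# comparable scale; dw stays in ppm. Starts are given on the natural scale.
.disp_fit_core <- function(d, t_relax, gamma_ratio, starts,
                           refine_top = 3) {
  res_ids <- unique(d$res)
  n_res <- length(res_ids)
  res_idx <- match(d$res, res_ids)

  natural <- function(q) c(exp(q[1]), exp(q[2]), q[-(1:2)])
  objective <- function(q) {
    p <- natural(q)
    kex <- p[1]; papb <- p[2]; dws <- p[-(1:2)]
    contrib <- numeric(length(d$obs))
    pa <- population_from_product(papb)
    for (r in seq_len(n_res)) {
      sel <- res_idx == r
      fields <- d$field[sel]
      for (f in unique(fields)) {
        ss <- sel & d$field == f
        contrib[ss] <- .bm_contrib(d$nu[ss], kex, pa,
                                   .dw_rad(dws[r], f, gamma_ratio), t_relax)
      }
    }
    .disp_chisq(contrib, d$obs, d$w, d$grp)
  }

  lower <- c(log(10), log(1e-8), rep(0, n_res))
  upper <- c(log(1e5), log(0.2499), rep(30, n_res))
  to_q <- function(s) pmin(upper, pmax(lower, c(log(s[1]), log(s[2]), s[-(1:2)])))
  scores <- vapply(starts, function(s) objective(to_q(s)), numeric(1))
  ord <- order(scores)[seq_len(min(refine_top, length(starts)))]
  best <- NULL
  for (k in ord) {
    o <- nlminb(to_q(starts[[k]]), objective, lower = lower, upper = upper,
                control = list(rel.tol = 1e-12, iter.max = 1000,
                               eval.max = 4000))
    # one restart from the solution guards against premature stalls
    o2 <- nlminb(o$par, objective, lower = lower, upper = upper,
                 control = list(rel.tol = 1e-12, iter.max = 1000,
                                eval.max = 4000))
    if (o2$objective < o$objective) o <- o2
    if (is.null(best) || o$objective < best$objective ||
        (abs(o$objective - best$objective) < 1e-9 &&
           o$par[1] < best$par[1]))
      best <- o
  }

  # recover profiled r20 and per-residue chi-square shares
  p <- natural(best$par)
  pa <- population_from_product(p[2])
  contrib <- numeric(length(d$obs))
  for (r in seq_len(n_res)) {
    sel <- res_idx == r
    for (f in unique(d$field[sel])) {
      ss <- sel & d$field == f
      contrib[ss] <- .bm_contrib(d$nu[ss], p[1], pa,
                                 .dw_rad(p[r + 2], f, gamma_ratio), t_relax)
    }
  }
  resid <- d$obs - contrib
  r20_grp <- tapply(d$w * resid, d$grp, sum) / tapply(d$w, d$grp, sum)
  pt_chisq <- d$w * (resid - r20_grp[d$grp])^2

  # rebuild (residue, field) keys from the data rather than from the
  # mangled interaction() level names
  key <- !duplicated(d$grp)
  r20_tbl <- tibble(residue = d$res[key], field_mhz = d$field[key],
                    grp = d$grp[key]) |>
    mutate(r20 = as.numeric(r20_grp[as.character(.data$grp)])) |>
    select(-"grp")

  list(
    kex = p[1], papb = p[2], pa = pa,
    dw = tibble(residue = res_ids, dw_ppm = p[-(1:2)]),
    r20 = r20_tbl,
    chisq = best$objective,
    chisq_by_residue = tibble(residue = d$res, chisq = pt_chisq) |>
      group_by(.data$residue) |> summarise(chisq = sum(.data$chisq)),
    convergence = best$convergence,
    at_bound = p[1] <= 10 * 1.001 || p[1] >= 1e5 * 0.999 ||
      p[2] >= 0.2499 * 0.999
  )
}

# Monte Carlo errors for a dispersion fit: resample profiles around the
# fitted model and refit from the fitted parameters
.disp_mc <- function(d, fit, t_relax, gamma_ratio, n_mc, seed) {
  res_ids <- fit$dw$residue
  model_vals <- numeric(length(d$obs))
  for (r in seq_along(res_ids)) {
    for (f in unique(d$field)) {
      ss <- d$res == res_ids[r] & d$field == f
      if (!any(ss)) next
      r20 <- fit$r20$r20[fit$r20$residue == res_ids[r] &
                           fit$r20$field_mhz == f]
      model_vals[ss] <- r20 + .bm_contrib(d$nu[ss], fit$kex, fit$pa,
                                          .dw_rad(fit$dw$dw_ppm[r], f,
                                                  gamma_ratio), t_relax)
    }
  }
  sig <- 1 / sqrt(d$w)
  start <- list(c(fit$kex, fit$papb, fit$dw$dw_ppm))
  draws <- .with_seed(seed, {
    lapply(seq_len(n_mc), function(i) {
      d2 <- d
      d2$obs <- model_vals + rnorm(length(model_vals), 0, sig)
      tryCatch(.disp_fit_core(d2, t_relax, gamma_ratio, start, refine_top = 1),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  kexs <- vapply(draws[ok], `[[`, numeric(1), "kex")
  papbs <- vapply(draws[ok], `[[`, numeric(1), "papb")
  dws <- vapply(draws[ok], function(x) x$dw$dw_ppm, numeric(length(res_ids)))
  if (is.null(dim(dws))) dws <- matrix(dws, nrow = 1)
  list(kex_sigma = sd(kexs), papb_sigma = sd(papbs),
       dw_sigma = tibble(residue = res_ids, dw_sigma = apply(dws, 1, sd)),
       failures = sum(!ok))
}

# standard multi-start grid; dw start from the fast-exchange amplitude
.disp_starts <- function(d, n_res, res_idx, kex_grid, papb_grid) {
  amp <- vapply(seq_len(n_res), function(r) {
    sel <- res_idx == r
    g <- d$grp[sel]
    a <- tapply(d$obs[sel], g, function(x) max(x) - min(x))
    max(mean(a, na.rm = TRUE), 0.5)
  }, numeric(1))
  starts <- list()
  for (kex in kex_grid) for (q in papb_grid) {
    # fast-exchange scale: Rex ~ q dw^2 / kex at the reference field
    dw0 <- sqrt(pmax(amp, 0.1) * kex / q) / .dw_rad(1, 800, -9.8655)
    starts[[length(starts) + 1]] <- c(kex, q, pmin(pmax(dw0, 0.2), 10))
  }
  starts
}

#' Fit a two-state exchange model to one residue
#'
#' Minimises the sigma-weighted chi-square of the Bloch-McConnell forward
#' model over (kex, pA pB, dw) with the exchange-free rate per field
#' profiled out exactly. Multi-start over a coarse (kex, pA pB) grid with
#' best-chi-square refinement; ties resolve toward the smallest kex.
#' Errors by Monte Carlo resampling.
#'
#' @param profiles Dispersion profile tibble for one residue (ideally both
#'   fields; single-field data are accepted with a degeneracy warning).
#' @param t_relax Constant relaxation time in s.
#' @param kex_grid,papb_grid Multi-start initialisation grids.
#' @param n_mc Monte Carlo iterations for parameter errors (0 to skip).
#' @param seed Integer seed.
#' @param gamma_ratio gamma_H/gamma_N.
#' @return An object of class `dispersion_fit` (single-residue flavour).
#' @export
fit_dispersion <- function(profiles, t_relax = 0.060,
                           kex_grid = .DEFAULT_KEX_GRID,
                           papb_grid = .DEFAULT_PAPB_GRID,
                           n_mc = 100, seed = 1L, gamma_ratio = -9.8655) {
  d <- .disp_data(profiles)
  if (length(unique(d$res)) != 1)
    abort("`profiles` must contain exactly one residue; see fit_dispersion_global().")
  if (length(unique(d$field)) < 2)
    warn("single-field dispersion data: kex/pApB/dw are weakly identifiable.")
  res_idx <- rep(1L, length(d$obs))
  starts <- .disp_starts(d, 1L, res_idx, kex_grid, papb_grid)
  fit <- .disp_fit_core(d, t_relax, gamma_ratio, starts)

  # an exchange amplitude within the data uncertainty leaves kex undefined
  amp <- max(abs(.bm_contrib(
    c(50, 750), fit$kex, fit$pa,
    .dw_rad(fit$dw$dw_ppm[1], max(d$field), gamma_ratio), t_relax)))
  degenerate <- amp < 3 * median(1 / sqrt(d$w)) ||
    fit$papb * fit$dw$dw_ppm[1]^2 < 1e-6
  if (degenerate)
    warn("no measurable dispersion amplitude: exchange parameters are degenerate.")

  err <- if (n_mc > 0) .disp_mc(d, fit, t_relax, gamma_ratio, n_mc, seed)
  else list(kex_sigma = NA_real_, papb_sigma = NA_real_,
            dw_sigma = tibble(residue = fit$dw$residue, dw_sigma = NA_real_),
            failures = 0L)

  structure(c(fit, list(kex_sigma = err$kex_sigma, papb_sigma = err$papb_sigma,
                        dw_sigma = err$dw_sigma, mc_failures = err$failures,
                        degenerate = degenerate, t_relax = t_relax,
                        gamma_ratio = gamma_ratio, n_points = length(d$obs),
                        fields = unique(d$field), scope = "single")),
            class = "dispersion_fit")
}

#' Global two-state fit of a residue cluster
#'
#' Joint weighted chi-square minimisation over all residues and fields in
#' the cluster with kex and pA pB shared, one dw (ppm, field-independent)
#' per residue, and one exchange-free rate per (residue, field) profiled
#' out exactly. Cluster membership is caller-declared; see
#' [suggest_cluster()] for an automatic suggestion.
#'
#' @param profiles Dispersion profile tibble for >= 3 residues at one or
#'   two fields.
#' @inheritParams fit_dispersion
#' @param n_mc Monte Carlo iterations for shared-parameter errors.
#' @return An object of class `dispersion_fit` (global flavour) carrying
#'   shared `kex`, `papb`, `pa`, per-residue `dw`, per-(residue, field)
#'   `r20` and per-residue chi-square contributions.
#' @export
fit_dispersion_global <- function(profiles, t_relax = 0.060,
                                  kex_grid = .DEFAULT_KEX_GRID,
                                  papb_grid = .DEFAULT_PAPB_GRID,
                                  n_mc = 50, seed = 1L,
                                  gamma_ratio = -9.8655) {
  d <- .disp_data(profiles)
  res_ids <- unique(d$res)
  if (length(res_ids) < 3)
    abort("a cluster needs at least 3 residues for a global fit.")
  res_idx <- match(d$res, res_ids)
  starts <- .disp_starts(d, length(res_ids), res_idx, kex_grid, papb_grid)

  # seed the joint fit from independent per-residue fits (standard
  # workflow): shared parameters from their medians, dw per residue
  single <- lapply(res_ids, function(rid) {
    dr <- lapply(d, function(v) if (length(v) == length(d$res)) v[d$res == rid] else v)
    dr$grp <- droplevels(dr$grp)
    st <- .disp_starts(dr, 1L, rep(1L, length(dr$obs)), kex_grid, papb_grid)
    tryCatch(.disp_fit_core(dr, t_relax, gamma_ratio, st, refine_top = 2),
             error = function(e) NULL)
  })
  ok <- !vapply(single, is.null, logical(1))
  if (any(ok)) {
    kex0 <- median(vapply(single[ok], `[[`, numeric(1), "kex"))
    papb0 <- median(vapply(single[ok], `[[`, numeric(1), "papb"))
    dw0 <- vapply(seq_along(res_ids), function(r)
      if (ok[r]) single[[r]]$dw$dw_ppm[1] else 2, numeric(1))
    starts <- c(list(c(kex0, papb0, dw0)), starts)
  }

  fit <- .disp_fit_core(d, t_relax, gamma_ratio, starts)
  if (fit$at_bound)
    warn("global fit converged at a parameter bound; treat kex/pApB with caution.")

  err <- if (n_mc > 0) .disp_mc(d, fit, t_relax, gamma_ratio, n_mc, seed)
  else list(kex_sigma = NA_real_, papb_sigma = NA_real_,
            dw_sigma = tibble(residue = res_ids, dw_sigma = NA_real_),
            failures = 0L)

  structure(c(fit, list(kex_sigma = err$kex_sigma, papb_sigma = err$papb_sigma,
                        dw_sigma = err$dw_sigma, mc_failures = err$failures,
                        degenerate = FALSE, t_relax = t_relax,
                        gamma_ratio = gamma_ratio, n_points = length(d$obs),
                        fields = unique(d$field), scope = "global")),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("<dispersion_fit:%s> kex = %.0f +/- %.0f /s, pApB = %.4f +/- %.4f (pA = %.1f%%)\n",
              x$scope, x$kex, x$kex_sigma %||% NA, x$papb, x$papb_sigma %||% NA,
              100 * x$pa))
  cat(sprintf("  %d residues, %d points, chi-square %.2f\n",
              nrow(x$dw), x$n_points, x$chisq))
  invisible(x)
}

#' Suggest a cluster of residues with compatible exchange
#'
#' Runs single-residue fits and groups residues whose kex estimates agree
#' pairwise within `n_sigma` combined standard deviations with the
#' reference (median-kex) residue. The suggestion is advisory and never
#' applied automatically.
#'
#' @param profiles Dispersion profiles for several residues.
#' @inheritParams fit_dispersion
#' @param n_sigma Compatibility window in combined-sigma units.
#' @return A tibble (residue, kex, kex_sigma, compatible).
#' @export
suggest_cluster <- function(profiles, t_relax = 0.060, n_sigma = 2,
                            n_mc = 50, seed = 1L, gamma_ratio = -9.8655) {
  fits <- profiles |>
    group_by(.data$residue) |>
    group_map(function(df, key) {
      f <- fit_dispersion(mutate(df, residue = key$residue), t_relax = t_relax,
                          n_mc = n_mc, seed = seed, gamma_ratio = gamma_ratio)
      tibble(residue = key$residue, kex = f$kex, kex_sigma = f$kex_sigma)
    }) |>
    bind_rows()
  ref <- fits$kex[which.min(abs(fits$kex - median(fits$kex)))]
  ref_sig <- fits$kex_sigma[which.min(abs(fits$kex - median(fits$kex)))]
  fits |>
    mutate(compatible = abs(.data$kex - ref) <=
             n_sigma * sqrt(.data$kex_sigma^2 + ref_sig^2))
}

#' Model dispersion curves on a dense frequency grid
#'
#' Evaluates the fitted Bloch-McConnell model (the same forward model used
#' in fitting) on the grid of realisable nu_CPMG values (even 180-degree
#' pulse counts within `t_relax`) for reporting and plotting.
#'
#' @param fit A `dispersion_fit` object.
#' @param nu_range Frequency range in Hz.
#' @return A tibble (residue, field_mhz, nu_cpmg_hz, r2eff).
#' @export
dispersion_curves <- function(fit, nu_range = c(25, 800)) {
  stopifnot(inherits(fit, "dispersion_fit"))
  nus <- .cpmg_realizable(fit$t_relax, nu_range[1], nu_range[2])
  crossing(fit$dw, field_mhz = fit$fields, nu_cpmg_hz = nus) |>
    left_join(fit$r20, by = c("residue", "field_mhz")) |>
    group_by(.data$residue, .data$field_mhz) |>
    mutate(r2eff = .data$r20 + .bm_contrib(
      .data$nu_cpmg_hz, fit$kex, fit$pa,
      .dw_rad(.data$dw_ppm[1], .data$field_mhz[1], fit$gamma_ratio),
      fit$t_relax)) |>
    ungroup() |>
    select("residue", "field_mhz", "nu_cpmg_hz", "r2eff")
}
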