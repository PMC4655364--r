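# Rate estimation from intensities.

test_that("noiseless mono-exponential decays are recovered exactly", {
  t <- c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8)
  f <- fit_monoexponential(t, 100 * exp(-12 * t))
  expect_equal(f$rate, 12, tolerance = 1e-8)
  expect_equal(f$i0, 100, tolerance = 1e-8)
  expect_lt(f$chisq, 1e-12)
  expect_true(f$converged)
})

test_that("underdetermined or invalid decays are rejected", {
  expect_error(fit_monoexponential(c(0.1, 0.2), c(90, 80)), "3 distinct")
  expect_error(fit_monoexponential(c(0.1, 0.1, 0.1), c(90, 80, 70)),
               "3 distinct")
  expect_error(fit_monoexponential(c(0.1, 0.2, 0.3), c(-1, -2, -3)),
               "positive")
})

test_that("noisy rate estimates match an exhaustive grid search", {
  set.seed(11)
  t <- c(0.01, 0.06, 0.12, 0.2, 0.35, 0.55, 0.85, 1.2)
  r_true <- 1.1
  y <- 1000 * exp(-r_true * t) * (1 + rnorm(8, 0, 0.02))
  f <- fit_monoexponential(t, y, sigma = 20)

  # 1-D grid over R with I0 profiled analytically (linear in e^{-Rt})
  grid <- seq(0.8, 1.4, by = 1e-4)
  chis <- vapply(grid, function(r) {
    e <- exp(-r * t)
    i0 <- sum(y * e) / sum(e^2)
    sum((y - i0 * e)^2) / 20^2
  }, numeric(1))
  r_grid <- grid[which.min(chis)]
  expect_equal(f$rate, r_grid, tolerance = 2e-4)
  expect_lt(abs(f$rate - r_true), 3 * f$rate_sigma)
})

test_that("Monte Carlo and covariance errors agree for a well-behaved decay", {
  set.seed(12)
  t <- c(0.01, 0.06, 0.12, 0.2, 0.35, 0.55, 0.85, 1.2)
  y <- 1000 * exp(-1.1 * t) * (1 + rnorm(8, 0, 0.02))
  f_cov <- fit_monoexponential(t, y, sigma = 20)
  f_mc <- fit_monoexponential(t, y, sigma = 20, errors = "montecarlo",
                              n_mc = 400, seed = 2)
  expect_equal(f_mc$rate_sigma, f_cov$rate_sigma, tolerance = 0.25)
})

test_that("NOE ratios and their first-order errors are propagated correctly", {
  expect_equal(compute_noe(100, 100)$noe, 1)
  z <- compute_noe(0, 100, sigma_sat = 2, sigma_ref = 3)
  expect_equal(z$noe, 0)
  expect_equal(z$noe_sigma, 2 / 100)
  h <- compute_noe(80, 100, 2, 2)
  expect_equal(h$noe, 0.8)
  expect_equal(h$noe_sigma, 0.8 * sqrt((2 / 80)^2 + (2 / 100)^2),
               tolerance = 1e-12)  # 0.02561
  expect_error(compute_noe(80, 0), "nonzero")
})

test_that("R2/R1 error propagation matches Monte Carlo within 10%", {
  set.seed(4)
  r1 <- 0.75; s1 <- 0.02; r2 <- 16; s2 <- 0.4
  prop <- (r2 / r1) * sqrt((s1 / r1)^2 + (s2 / r2)^2)
  draws <- rnorm(1e4, r2, s2) / rnorm(1e4, r1, s1)
  expect_equal(prop, sd(draws), tolerance = 0.1)
})

test_that("R2eff follows the constant-time intensity-ratio formula", {
  tab <- tibble::tibble(
    residue = 1L, field_mhz = 800.2,
    nu_cpmg_hz = c(0, 100, 100, 200),
    replicate = c(1L, 1L, 2L, 1L),
    intensity = c(1000, 301.2, 301.2, 500)
  )
  prof <- r2eff_profile(tab, t_relax = 0.06, sigma_floor = 0.01)
  expect_equal(prof$r2eff[prof$nu_cpmg_hz == 100], 20.0, tolerance = 1e-3)
  expect_equal(prof$r2eff[prof$nu_cpmg_hz == 200], -log(0.5) / 0.06,
               tolerance = 1e-9)
  # identical duplicates: the duplicate-derived error collapses and the
  # configured floor applies
  expect_equal(unique(prof$r2eff_sigma), 0.01 / 0.06, tolerance = 1e-12)
  # I = I0 means no decay
  tab2 <- dplyr::mutate(tab, intensity = c(1000, 1000, 1000, 1000))
  expect_equal(r2eff_profile(tab2, 0.06)$r2eff, c(0, 0), tolerance = 1e-12)
})

test_that("duplicate-plane scatter sets the profile error when above the floor", {
  set.seed(21)
  cl <- tibble::tibble(residue = 1:6, dw_ppm = 0)
  sim <- simulate_cpmg(cl, kex = 1000, pa = 0.99, r20 = 15, noise = 0.02,
                       seed = 9)
  prof <- r2eff_profile(sim$intensities, sigma_floor = 0.001)
  # pooled fractional sigma from |Ia - Ib|/sqrt(2) across residues, per field
  pooled <- sim$intensities |>
    dplyr::filter(nu_cpmg_hz == 100) |>
    dplyr::group_by(field_mhz, residue) |>
    dplyr::summarise(fr = abs(diff(intensity)) / sqrt(2) / mean(intensity),
                     .groups = "drop") |>
    dplyr::group_by(field_mhz) |>
    dplyr::summarise(s = sqrt(mean(fr^2)))
  for (f in pooled$field_mhz) {
    expect_equal(unique(prof$r2eff_sigma[prof$field_mhz == f]),
                 pooled$s[pooled$field_mhz == f] / 0.06, tolerance = 1e-9)
  }
  expect_gt(min(prof$r2eff_sigma), 0.001 / 0.06)
})

test_that("profile computation rejects unusable tables", {
  tab <- tibble::tibble(residue = 1L, field_mhz = 800.2, nu_cpmg_hz = 100,
                        replicate = 1L, intensity = 500)
  expect_error(r2eff_profile(tab), "reference")
  tab0 <- tibble::tibble(residue = 1L, field_mhz = 800.2,
                         nu_cpmg_hz = c(0, 100), replicate = c(1L, 1L),
                         intensity = c(1000, -5))
  expect_error(r2eff_profile(tab0), "positive")
})

test_that("records assemble with a consistent R2/R1 quotient", {
  tr <- tibble::tibble(residue = 1:3, model = "M1", s2 = 0.9)
  out <- fx_pipeline_records(tr, fx_iso(10.8), fx_spin(), noise = 0.01,
                             seed = 3)
  rec <- out$records
  expect_equal(rec$r2_r1, rec$r2 / rec$r1, tolerance = 1e-12)
  expect_true(all(rec$r1 > 0 & rec$r2 > 0))
  expect_true(all(rec$r1_sigma >= 0 & rec$r2_sigma >= 0))
})
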