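# Exchange detection, per-residue and global two-state fits, population
# algebra, model curves.

make_profile <- function(dw_ppm, kex = 1822, papb = 0.026, r20 = 17,
                         noise = 0.02, seed = 1, residues = 1L) {
  cl <- tibble::tibble(residue = residues, dw_ppm = dw_ppm)
  sim <- simulate_cpmg(cl, kex = kex, pa = population_from_product(papb),
                       r20 = r20, noise = noise, seed = seed)
  r2eff_profile(sim$intensities)
}

test_that("population algebra inverts the pA pB product", {
  expect_equal(population_from_product(0), 1)
  expect_equal(population_from_product(0.25), 0.5)
  expect_equal(population_from_product(0.028), (1 + sqrt(1 - 0.112)) / 2)
  expect_gte(100 * population_from_product(0.028), 97.1)
  # identity on [0.5, 1]
  pa <- seq(0.5, 1, by = 0.01)
  expect_equal(population_from_product(pa * (1 - pa)), pa, tolerance = 1e-12)
  expect_error(population_from_product(0.3), "0.25")
})

test_that("flat and degenerate profiles are not called exchanging", {
  prof <- make_profile(0, noise = 0)
  d <- suppressWarnings(detect_exchange(prof))
  expect_false(d$exchanging)
  # papb * dw^2 = 0 through papb ~ 0
  prof2 <- make_profile(2, papb = 1e-10, noise = 0)
  d2 <- suppressWarnings(detect_exchange(prof2))
  expect_false(d2$exchanging)
  expect_error(detect_exchange(prof[1:4, ]), "6 dispersion")
})

test_that("genuine exchange is detected with high power at 2% noise", {
  hits <- vapply(1:10, function(s) {
    prof <- make_profile(2, kex = 1095, papb = 0.024, seed = 300 + s)
    detect_exchange(prof)$exchanging
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("noiseless profiles return the generating exchange parameters", {
  prof <- make_profile(2, noise = 0)
  f <- fit_dispersion(prof, n_mc = 0)
  expect_equal(f$kex, 1822, tolerance = 1e-4)
  expect_equal(f$papb, 0.026, tolerance = 1e-6)
  expect_equal(f$dw$dw_ppm, 2, tolerance = 1e-4)
  expect_equal(f$r20$r20, rep(17, 2), tolerance = 1e-6)
  expect_lt(f$chisq, 1e-8)
})

test_that("single-residue fits recover kex within 10% at 2% noise", {
  prof <- make_profile(2.5, kex = 1822, papb = 0.026, seed = 1)
  f <- fit_dispersion(prof, n_mc = 0)
  expect_lt(abs(f$kex / 1822 - 1), 0.10)
})

test_that("zero shift difference is flagged as degenerate", {
  prof <- make_profile(0, noise = 0.01, seed = 2)
  expect_warning(f <- fit_dispersion(prof, n_mc = 0), "degenerate")
  expect_true(f$degenerate)
})

test_that("global cluster fits share parameters and respect nesting", {
  set.seed(6)
  cl <- tibble::tibble(residue = 1:4, dw_ppm = c(1.5, 2.5, 3.2, 2.0))
  sim <- simulate_cpmg(cl, kex = 1822, pa = population_from_product(0.026),
                       r20 = 17, noise = 0.02, seed = 60)
  prof <- r2eff_profile(sim$intensities)
  g <- fit_dispersion_global(prof, n_mc = 0)
  expect_lt(abs(g$kex / 1822 - 1), 0.10)
  expect_lt(abs(g$papb - 0.026), 0.005)

  # nesting: the constrained global optimum cannot undercut the sum of the
  # unconstrained per-residue optima
  singles <- vapply(cl$residue, function(r) {
    fit_dispersion(dplyr::filter(prof, residue == r), n_mc = 0)$chisq
  }, numeric(1))
  expect_gte(g$chisq, sum(singles) - 1e-6)
  expect_error(fit_dispersion_global(dplyr::filter(prof, residue <= 2)),
               "3 residues")
})

test_that("a no-exchange member leaves the shared parameters intact", {
  cl <- tibble::tibble(residue = 1:4, dw_ppm = c(2, 2.5, 3, 0))
  sim <- simulate_cpmg(cl, kex = 1500, pa = population_from_product(0.025),
                       r20 = 16, noise = 0.01, seed = 61)
  prof <- r2eff_profile(sim$intensities)
  g <- fit_dispersion_global(prof, n_mc = 0)
  expect_lt(g$dw$dw_ppm[g$dw$residue == 4], 0.2)
  expect_lt(abs(g$kex / 1500 - 1), 0.10)
})

test_that("fits are invariant to row order and residue relabelling", {
  cl <- tibble::tibble(residue = 1:3, dw_ppm = c(1.8, 2.6, 3.1))
  sim <- simulate_cpmg(cl, kex = 1822, pa = population_from_product(0.026),
                       r20 = 17, noise = 0.02, seed = 62)
  prof <- r2eff_profile(sim$intensities)
  g1 <- fit_dispersion_global(prof, n_mc = 0)
  shuffled <- prof[rev(seq_len(nrow(prof))), ]
  g2 <- fit_dispersion_global(shuffled, n_mc = 0)
  expect_equal(g1$kex, g2$kex, tolerance = 1e-8)
  expect_equal(g1$papb, g2$papb, tolerance = 1e-10)
  relab <- dplyr::mutate(prof, residue = residue + 100L)
  g3 <- fit_dispersion_global(relab, n_mc = 0)
  expect_equal(g1$kex, g3$kex, tolerance = 1e-8)
})

test_that("Monte Carlo errors are reproducible and kex lands near truth", {
  prof <- make_profile(2.5, kex = 1822, papb = 0.026, seed = 1)
  f1 <- fit_dispersion(prof, n_mc = 30, seed = 9)
  f2 <- fit_dispersion(prof, n_mc = 30, seed = 9)
  expect_identical(f1$kex_sigma, f2$kex_sigma)
  expect_gt(f1$kex_sigma, 0)
  expect_lt(abs(f1$kex - 1822), 5 * max(f1$kex_sigma, 0.05 * 1822))
})

test_that("model curves are flat without exchange and grow with dw", {
  # curve amplitude rises along a dw ladder at fixed kex and papb
  amp <- vapply(c(0.5, 1, 2, 3, 4), function(dw) {
    r <- relaxfit:::.bm_contrib(c(50, 750), 1822,
                                population_from_product(0.026),
                                relaxfit:::.dw_rad(dw, 800.2), 0.06)
    r[1] - r[2]
  }, numeric(1))
  expect_true(all(diff(amp) > 0))

  prof <- make_profile(2, noise = 0)
  f <- fit_dispersion(prof, n_mc = 0)
  curves <- dispersion_curves(f)
  expect_setequal(unique(curves$field_mhz), c(800.2, 600.13))
  # the curve passes through the fitted model at the measured frequencies
  at_fit <- dplyr::semi_join(curves, prof, by = c("field_mhz", "nu_cpmg_hz"))
  cmp <- dplyr::left_join(at_fit, prof,
                          by = c("residue", "field_mhz", "nu_cpmg_hz"))
  expect_equal(cmp$r2eff.x, cmp$r2eff.y, tolerance = 1e-6)
  # flat curves for a dw = 0 fit
  proff <- make_profile(0, noise = 0)
  ff <- suppressWarnings(fit_dispersion(proff, n_mc = 0))
  cf <- dispersion_curves(ff)
  expect_lt(max(cf$r2eff) - min(cf$r2eff), 1e-6)
})

test_that("cluster suggestion ranks compatible residues", {
  cl <- tibble::tibble(residue = 1:3, dw_ppm = c(2, 2.5, 3))
  sim <- simulate_cpmg(cl, kex = 1500, pa = population_from_product(0.025),
                       r20 = 16, noise = 0.01, seed = 63)
  prof <- r2eff_profile(sim$intensities)
  sug <- suggest_cluster(prof, n_mc = 20, seed = 2)
  expect_equal(nrow(sug), 3)
  expect_true(all(c("kex", "kex_sigma", "compatible") %in% names(sug)))
})
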