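# Diffusion-tensor estimation, model fitting/selection, Monte Carlo
# errors, inertia utility.

test_that("noiseless M1 data are fitted exactly and selected deterministically", {
  sp <- fx_spin()
  tn <- fx_iso(10.8)
  rec <- fx_record(1L, motional_model("M1", s2 = 0.87), tn, sp)
  f <- fit_motional_model(rec, "M1", tn, sp)
  expect_equal(f$model$s2, 0.87, tolerance = 1e-6)
  expect_lt(f$chisq, 1e-10)
  sel <- select_model(rec, tn, sp)
  expect_equal(sel$model_id, "M1")
  # exact-fit guard: no extra-parameter model on noiseless data
  expect_equal(select_model(rec, tn, sp)$model_id, "M1")
})

test_that("exchange broadening is attributed to Rex, not absorbed by M1", {
  sp <- fx_spin()
  tn <- fx_iso(10.8)
  rec <- fx_record(1L, motional_model("M3", s2 = 0.88, rex = 3), tn, sp)
  f1 <- fit_motional_model(rec, "M1", tn, sp)
  f3 <- fit_motional_model(rec, "M3", tn, sp)
  expect_gt(f1$chisq, 10)
  expect_lt(f3$chisq, 1e-8)
  expect_equal(f3$model$rex, 3, tolerance = 1e-4)
  expect_equal(select_model(rec, tn, sp)$model_id, "M3")
})

test_that("noisy M2 fits agree with a dense two-parameter grid search", {
  sp <- fx_spin()
  tn <- fx_iso(10.8)
  rec <- fx_record(1L, motional_model("M2", s2 = 0.82, tau_e = 40), tn, sp,
                   noisy = TRUE, seed = 31)
  f <- fit_motional_model(rec, "M2", tn, sp)

  obs <- c(rec$r1, rec$r2, rec$noe)
  sig <- c(rec$r1_sigma, rec$r2_sigma, rec$noe_sigma)
  grid <- expand.grid(s2 = seq(0.70, 0.95, by = 0.0025),
                      tau_e = seq(0, 150, by = 1))
  chis <- vapply(seq_len(nrow(grid)), function(i) {
    m <- motional_model("M2", s2 = grid$s2[i], tau_e = grid$tau_e[i])
    calc <- relaxation_rates(m, tn, sp)
    sum(((obs - c(calc$r1, calc$r2, calc$noe)) / sig)^2)
  }, numeric(1))
  k <- which.min(chis)
  expect_lte(f$chisq, chis[k] + 1e-6)
  expect_equal(f$model$s2, grid$s2[k], tolerance = 0.005)
  expect_equal(f$model$tau_e, grid$tau_e[k], tolerance = 2)
  # parameters near truth at this noise level
  expect_lt(abs(f$model$s2 - 0.82), 0.05)
})

test_that("M1 truth keeps M1 and Rex truth earns an exchange model under noise", {
  sp <- fx_spin()
  tn <- fx_iso(10.8)
  set.seed(8)
  n <- 20
  m1_sel <- vapply(seq_len(n), function(i) {
    rec <- fx_record(i, motional_model("M1", s2 = 0.9), tn, sp,
                     noisy = TRUE, seed = 100 + i)
    select_model(rec, tn, sp)$model_id
  }, character(1))
  expect_gte(mean(m1_sel == "M1"), 0.9)

  rex_sel <- vapply(seq_len(10), function(i) {
    rec <- fx_record(i, motional_model("M3", s2 = 0.88, rex = 5), tn, sp,
                     noisy = TRUE, seed = 200 + i)
    select_model(rec, tn, sp)$model_id
  }, character(1))
  expect_gte(mean(rex_sel %in% c("M3", "M4")), 0.9)
})

test_that("Monte Carlo errors are seeded, vanish with the noise, and scale with it", {
  sp <- fx_spin()
  tn <- fx_iso(10.8)
  rec <- fx_record(1L, motional_model("M1", s2 = 0.9), tn, sp)
  f <- fit_motional_model(rec, "M1", tn, sp)

  e1 <- monte_carlo_errors(rec, f$model, "M1", tn, sp, n_iter = 200, seed = 5)
  e2 <- monte_carlo_errors(rec, f$model, "M1", tn, sp, n_iter = 200, seed = 5)
  expect_identical(e1, e2)

  tiny <- rec
  tiny$r1_sigma <- 1e-9; tiny$r2_sigma <- 1e-9; tiny$noe_sigma <- 1e-9
  e0 <- monte_carlo_errors(tiny, f$model, "M1", tn, sp, n_iter = 100, seed = 5)
  expect_lt(e0$s2_sigma, 1e-6)

  dbl <- rec
  dbl$r1_sigma <- 2 * rec$r1_sigma
  dbl$r2_sigma <- 2 * rec$r2_sigma
  dbl$noe_sigma <- 2 * rec$noe_sigma
  eb <- monte_carlo_errors(rec, f$model, "M1", tn, sp, n_iter = 500, seed = 6)
  ed <- monte_carlo_errors(dbl, f$model, "M1", tn, sp, n_iter = 500, seed = 6)
  expect_equal(ed$s2_sigma / eb$s2_sigma, 2, tolerance = 0.25)
  expect_error(monte_carlo_errors(rec, f$model, "M1", tn, sp, n_iter = 50),
               ">= 100")
})

test_that("isotropic synthetic data yield an isotropic tensor", {
  sp <- fx_spin()
  # noiseless: the exact-fit guard keeps the description isotropic
  tr <- tibble::tibble(residue = 1:20, model = "M1", s2 = 0.9)
  out0 <- fx_pipeline_records(tr, fx_iso(10.8), sp, noise = 0, seed = 13)
  orient <- fx_orientations(20, seed = 13)
  df0 <- estimate_diffusion(out0$records, orient, sp)
  expect_equal(df0$tensor$kind, "isotropic")
  expect_equal(df0$tensor$d_ratio, 1)
  expect_equal(df0$tensor$tau_m, 10.8, tolerance = 1e-4)
  # with noise the tumbling time is still recovered and any residual
  # anisotropy stays within the noise
  out <- fx_pipeline_records(tr, fx_iso(10.8), sp, noise = 0.02, seed = 13)
  df <- estimate_diffusion(out$records, orient, sp)
  expect_equal(df$tensor$tau_m, 10.8, tolerance = 0.03)
  expect_lt(abs(df$tensor$d_ratio - 1), 0.15)
})

test_that("diffusion estimation is invariant to uniform intensity rescaling", {
  sp <- fx_spin()
  tr <- tibble::tibble(residue = 1:15, model = "M1", s2 = 0.9)
  gt <- ground_truth(tr, fx_iso(10.8), noise = 0.01)
  sim <- simulate_relaxation(gt, sp, seed = 2)
  scaled <- dplyr::mutate(sim$decays, intensity = intensity * 7.3,
                          sigma = sigma * 7.3)
  noe_scaled <- dplyr::mutate(sim$noe, i_sat = i_sat * 7.3,
                              i_ref = i_ref * 7.3,
                              sigma_sat = sigma_sat * 7.3,
                              sigma_ref = sigma_ref * 7.3)
  rec_a <- relaxation_records(fit_decays(sim$decays), sim$noe, 800.2)
  rec_b <- relaxation_records(fit_decays(scaled), noe_scaled, 800.2)
  expect_equal(rec_a$r1, rec_b$r1, tolerance = 1e-8)
  expect_equal(rec_a$r2, rec_b$r2, tolerance = 1e-8)
  orient <- fx_orientations(15, seed = 3)
  fa <- estimate_diffusion(rec_a, orient, sp)
  fb <- estimate_diffusion(rec_b, orient, sp)
  expect_equal(fa$tensor$tau_m, fb$tensor$tau_m, tolerance = 1e-6)
  expect_equal(fa$tensor$d_ratio, fb$tensor$d_ratio, tolerance = 1e-6)
})

test_that("oblate anisotropy is recognised against the prolate alternative", {
  sp <- fx_spin()
  wins <- vapply(1:3, function(rep) {
    orient <- fx_orientations(30, seed = 40 + rep)
    tr <- dplyr::mutate(orient, model = "M1", s2 = 0.9)
    tens <- fx_oblate(10.8, d_ratio = 0.83)
    out <- fx_pipeline_records(tr, tens, sp, noise = 0.02, seed = 50 + rep)
    df <- estimate_diffusion(out$records, orient, sp)
    df$fits$axial_oblate$chisq < df$fits$axial_prolate$chisq
  }, logical(1))
  expect_true(all(wins))
})

test_that("diffusion estimation demands enough rigid residues and orientations", {
  sp <- fx_spin()
  tr <- tibble::tibble(residue = 1:5, model = "M1", s2 = 0.9)
  out <- fx_pipeline_records(tr, fx_iso(10.8), sp, noise = 0.01, seed = 4)
  expect_error(estimate_diffusion(out$records, NULL, sp), "rigid")
  tr2 <- tibble::tibble(residue = 1:12, model = "M1", s2 = 0.9)
  out2 <- fx_pipeline_records(tr2, fx_iso(10.8), sp, noise = 0.01, seed = 4)
  expect_warning(df <- estimate_diffusion(out2$records, NULL, sp),
                 "isotropic")
  expect_equal(df$tensor$kind, "isotropic")
})

test_that("records with missing observables are passed through as skipped", {
  sp <- fx_spin()
  tn <- fx_iso(10.8)
  rec <- fx_record(1L, motional_model("M1", s2 = 0.9), tn, sp)
  rec2 <- rec; rec2$residue <- 2L; rec2$noe <- NA_real_
  mf <- model_free_analysis(dplyr::bind_rows(rec, rec2), tn, sp, n_mc = 0)
  res <- tidy(mf)
  expect_equal(res$status, c("fitted", "skipped"))
  expect_equal(glance(mf)$n_skipped, 1L)
})

test_that("principal inertia moments match direct eigenanalysis", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(unlist(inertia_ratio(cube)), c(ix = 1, iy = 1, iz = 1),
               tolerance = 1e-12)

  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 2, 0), c(0, -2, 0))
  got <- inertia_ratio(pts)
  # oracle: hand-built tensor, direct eigendecomposition
  it <- matrix(0, 3, 3)
  r2 <- rowSums(pts^2)
  for (i in 1:3) for (j in 1:3)
    it[i, j] <- sum((i == j) * r2 - pts[, i] * pts[, j])
  ev <- sort(eigen(it, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(unlist(got), c(ix = 1, iy = ev[2] / ev[1], iz = ev[3] / ev[1]),
               tolerance = 1e-12)
  expect_true(got$iy >= got$iz && got$iz > 0 && got$iy <= 1)

  expect_error(inertia_ratio(matrix(c(0, 0, 0), 1)), "3 atoms")
  line <- cbind(seq(0, 5, by = 1), 0, 0)
  expect_error(inertia_ratio(line), "collinear")
})

test_that("N-H orientations are read from PDB records, rebuilding H when absent", {
  pdb <- fx_write_mini_pdb(tempfile(fileext = ".pdb"))
  orient <- nh_orientations(pdb)
  expect_equal(nrow(orient), 2)
  expect_equal(sqrt(orient$x^2 + orient$y^2 + orient$z^2), c(1, 1),
               tolerance = 1e-9)
  # residue 1 has an explicit H: the vector points from N to H
  expect_equal(unlist(orient[1, c("x", "y", "z")]),
               c(x = -0.5, y = 0.866, z = 0), tolerance = 1e-3)
  # residue 2 has no H: the reconstructed vector points away from both the
  # preceding carbonyl C and its own CA
  v2 <- unlist(orient[2, c("x", "y", "z")])
  to_ca <- c(3.989, 2.831, 0) - c(3.332, 1.536, 0)
  to_c <- c(2.009, 1.420, 0) - c(3.332, 1.536, 0)
  expect_lt(sum(v2 * to_ca), 0)
  expect_lt(sum(v2 * to_c), 0)
})
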