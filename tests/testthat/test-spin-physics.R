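# Spectral densities and relaxation-rate expressions.

test_that("rigid-rotor and zero-frequency limits of the spectral density are exact", {
  sp <- fx_spin()
  tn <- fx_iso(10.7)
  tau <- 10.7e-9
  w <- c(0, sp$omega_n, sp$omega_h)

  # S2 = 1: single Lorentzian regardless of tau_e
  m1 <- motional_model("M1", s2 = 1)
  expect_equal(lipari_szabo_J(w, m1, tn), 0.4 * tau / (1 + (w * tau)^2),
               tolerance = 1e-12)

  # omega = 0, tau_e = 0: J(0) = (2/5) S2 tau_m
  m <- motional_model("M1", s2 = 0.8)
  expect_equal(lipari_szabo_J(0, m, tn), 0.4 * 0.8 * tau, tolerance = 1e-12)
})

test_that("model-free J matches a numerical cosine transform of the correlation function", {
  sp <- fx_spin()
  tn <- fx_iso(10.7)
  m <- motional_model("M2", s2 = 0.85, tau_e = 50)
  w <- sp$omega_n
  corr <- function(t) {
    0.4 * (0.85 + 0.15 * exp(-t / 50e-12)) * exp(-t / 10.7e-9)
  }
  j_num <- 2 * stats::integrate(function(t) corr(t) * cos(w * t), 0, Inf,
                                rel.tol = 1e-12)$value
  expect_equal(lipari_szabo_J(w, m, tn), j_num, tolerance = 1e-3)
})

test_that("extended model with s2f = 1 reduces to the simple two-parameter form", {
  sp <- fx_spin()
  tn <- fx_iso(9.5)
  w <- c(0, sp$omega_n, sp$omega_h - sp$omega_n, sp$omega_h,
         sp$omega_h + sp$omega_n)
  m5 <- motional_model("M5", s2 = 0.8, tau_e = 120, s2f = 1)
  m2 <- motional_model("M2", s2 = 0.8, tau_e = 120)
  expect_equal(lipari_szabo_J(w, m5, tn), lipari_szabo_J(w, m2, tn),
               tolerance = 1e-14)
})

test_that("axial spectral density collapses to the isotropic form as the anisotropy vanishes", {
  sp <- fx_spin()
  m <- motional_model("M2", s2 = 0.85, tau_e = 40)
  iso <- fx_iso(10.8)
  near_iso <- diffusion_tensor("axial_oblate", tau_m = 10.8,
                               d_ratio = 1 - 1e-13)
  angles <- seq(0, pi / 2, length.out = 20)
  freqs <- c(0, sp$omega_n, sp$omega_h - sp$omega_n, sp$omega_h,
             sp$omega_h + sp$omega_n)
  for (a in angles) {
    expect_equal(lipari_szabo_J(freqs, m, near_iso, nh_angle = a),
                 lipari_szabo_J(freqs, m, iso),
                 tolerance = 1e-10)
  }
  expect_error(lipari_szabo_J(0, m, near_iso), "nh_angle")
})

test_that("relaxation rates match an independent term-by-term re-derivation", {
  sp <- fx_spin(800.2)
  tn <- fx_iso(10.8)
  m <- motional_model("M1", s2 = 0.91)
  got <- relaxation_rates(m, tn, sp)

  # independent derivation with its own constants
  gamma_h <- 2.6752218744e8
  gamma_n <- gamma_h / -9.8655
  hbar <- 1.054571817e-34
  r <- 1.02e-10
  wh <- 2 * pi * 800.2e6
  wn <- wh / 9.8655
  jj <- function(w) 0.4 * 0.91 * 10.8e-9 / (1 + (w * 10.8e-9)^2)
  d <- 1e-7 * hbar * gamma_h * abs(gamma_n) / r^3
  cc <- wn * 160e-6 / sqrt(3)
  r1 <- d^2 / 4 * (jj(wh - wn) + 3 * jj(wn) + 6 * jj(wh + wn)) + cc^2 * jj(wn)
  r2 <- d^2 / 8 * (4 * jj(0) + jj(wh - wn) + 3 * jj(wn) + 6 * jj(wh) +
                     6 * jj(wh + wn)) + cc^2 / 6 * (4 * jj(0) + 3 * jj(wn))
  noe <- 1 + (gamma_h / gamma_n) *
    (d^2 / 4 * (6 * jj(wh + wn) - jj(wh - wn))) / r1
  expect_equal(got$r1, r1, tolerance = 1e-10)
  expect_equal(got$r2, r2, tolerance = 1e-10)
  expect_equal(got$noe, noe, tolerance = 1e-10)
})

test_that("extreme-narrowing NOE approaches 1 + gamma_H/(2 gamma_N)", {
  sp <- spin_system(800.2, csa_ppm = 0)
  tn <- diffusion_tensor("isotropic", tau_m = 1e-5)  # ns; deep extreme narrowing
  m <- motional_model("M1", s2 = 1)
  noe <- relaxation_rates(m, tn, sp)$noe
  expect_equal(noe, 1 - 9.8655 / 2, tolerance = 1e-4)
})

test_that("NOE and R2/R1 are independent of S2 under model M1", {
  sp <- fx_spin()
  tn <- fx_iso(10.8)
  a <- relaxation_rates(motional_model("M1", s2 = 0.5), tn, sp)
  b <- relaxation_rates(motional_model("M1", s2 = 0.95), tn, sp)
  expect_equal(a$noe, b$noe, tolerance = 1e-12)
  expect_equal(a$r2 / a$r1, b$r2 / b$r1, tolerance = 1e-12)
})

test_that("R2/R1 increases strictly with the tumbling time", {
  sp <- fx_spin()
  m <- motional_model("M1", s2 = 0.9)
  ratios <- vapply(seq(5, 15, by = 1), function(tm) {
    r <- relaxation_rates(m, fx_iso(tm), sp)
    r$r2 / r$r1
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("constructors enforce the physical invariants", {
  expect_error(spin_system(-600), "positive")
  expect_error(spin_system(800, gamma_ratio = -8), "1%")
  expect_error(motional_model("M1", s2 = 1.2), "0, 1")
  expect_error(motional_model("M1", s2 = 0.8, rex = 2), "not a parameter")
  expect_error(motional_model("M5", s2 = 0.9, tau_e = 50, s2f = 0.8), "exceed")
  expect_error(diffusion_tensor("axial_oblate", tau_m = 10, d_ratio = 1.1),
               "inconsistent")
  expect_error(diffusion_tensor("isotropic", tau_m = -1), "positive")
  expect_error(two_state_exchange(kex = 100, pa = 0.4, dw_ppm = 1), "0.5")
  ex <- two_state_exchange(kex = 100, pa = 0.97, dw_ppm = 1)
  expect_lte(ex$pa * ex$pb, 0.25)
  # unit axis normalisation
  tn <- diffusion_tensor("axial_prolate", tau_m = 10, d_ratio = 1.3,
                         axis = c(0, 0, 2))
  expect_equal(sum(tn$axis^2), 1)
  # omega_N / omega_H equals the gamma ratio to machine precision
  sp <- fx_spin()
  expect_equal(sp$omega_n / sp$omega_h, 1 / 9.8655, tolerance = 1e-15)
})
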