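# Two-state CPMG dispersion forward models: the numerical Bloch-McConnell
# propagator (authoritative for fitting) and the Carver-Richards closed
# form (independent oracle and fast initialisation).

# ppm -> rad/s for 15N at a given 1H field
.dw_rad <- function(dw_ppm, field_mhz, gamma_ratio = -9.8655) {
  dw_ppm * 1e-6 * 2 * pi * field_mhz * 1e6 / abs(gamma_ratio)
}

#' Carver-Richards effective transverse relaxation rate
#'
#' Closed-form R2eff for two-state exchange during an ideal CPMG train,
#' valid in all exchange regimes. Reduces to `r20` when `dw_ppm = 0` or
#' `pa = 1`.
#'
#' @param nu_cpmg Refocusing frequency in Hz (> 0); vectorised.
#' @param kex Exchange rate k_AB + k_BA in 1/s.
#' @param pa Major-state population in \[0.5, 1\].
#' @param dw_ppm 15N chemical-shift difference between the states in ppm.
#' @param r20 Exchange-free transverse rate in 1/s (shared by both states).
#' @param field_mhz Spectrometer 1H frequency in MHz.
#' @param gamma_ratio gamma_H/gamma_N, used to convert ppm to rad/s.
#'
#' @return R2eff in 1/s, same length as `nu_cpmg`.
#' @examples
#' carver_richards_r2eff(c(50, 750), kex = 1822, pa = 0.9866,
#'                       dw_ppm = 2, r20 = 12, field_mhz = 800.2)
#' @export
carver_richards_r2eff <- function(nu_cpmg, kex, pa, dw_ppm, r20,
                                  field_mhz, gamma_ratio = -9.8655) {
  if (any(nu_cpmg <= 0))
    abort("`nu_cpmg` must be > 0; the reference plane has no closed form.")
  pb <- 1 - pa
  dw <- .dw_rad(dw_ppm, field_mhz, gamma_ratio)
  if (dw == 0 || pb == 0) return(rep(r20, length(nu_cpmg)))

  psi <- kex^2 - dw^2
  zeta <- -2 * dw * kex * (pa - pb)
  root <- sqrt(psi^2 + zeta^2)
  d_plus <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  d_minus <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  eta_plus <- sqrt(pmax(psi + root, 0) / 2) / (2 * nu_cpmg)
  eta_minus <- sqrt(pmax(-psi + root, 0) / 2) / (2 * nu_cpmg)

  big <- eta_plus > 300
  ac <- numeric(length(nu_cpmg))
  arg <- d_plus * cosh(eta_plus[!big]) - d_minus * cos(eta_minus[!big])
  ac[!big] <- acosh(pmax(arg, 1))
  # cosh overflow guard: acosh(D+ cosh x - ...) ~ x + log(D+) for large x
  ac[big] <- eta_plus[big] + log(d_plus)
  r20 + kex / 2 - nu_cpmg * ac
}

#' Bloch-McConnell effective transverse relaxation rate
#'
#' Numerically propagates two-state transverse magnetisation through the
#' constant-time CPMG echo train (tau_cp - 180 - 2 tau_cp - 180 - tau_cp
#' blocks) and returns `R2eff = -(1/t_relax) log(|M_A(t_relax)|/p_A)`, with
#' magnetisation started at the equilibrium populations. Off-resonance
#' effects, finite pulse widths and longitudinal relaxation during the
#' train are neglected (pure transverse two-spin-state evolution), matching
#' the idealised constant-time analysis regime. The exchange-free rate
#' `r20` enters additively and exactly.
#'
#' @inheritParams carver_richards_r2eff
#' @param t_relax Constant transverse relaxation time in s; each `nu_cpmg`
#'   must realise an even 180-degree pulse count within 1% (see
#'   [cpmg_design()]).
#'
#' @return R2eff in 1/s, same length as `nu_cpmg`.
#' @examples
#' bloch_mcconnell_r2eff(c(50, 750), kex = 1822, pa = 0.9866,
#'                       dw_ppm = 2, r20 = 12, field_mhz = 800.2)
#' @export
bloch_mcconnell_r2eff <- function(nu_cpmg, kex, pa, dw_ppm, r20,
                                  field_mhz, t_relax = 0.060,
                                  gamma_ratio = -9.8655) {
  if (any(nu_cpmg <= 0)) abort("`nu_cpmg` must be > 0.")
  for (nu in unique(nu_cpmg)) .cpmg_pulses(nu, t_relax)
  dw <- .dw_rad(dw_ppm, field_mhz, gamma_ratio)
  r20 + .bm_contrib(nu_cpmg, kex, pa, dw, t_relax)
}

# exchange contribution to R2eff (value with r20 = 0), vectorised over
# nu_cpmg. The block propagator over tau-180-2tau-180-tau collapses to the
# fixed complex matrix G = E1 Conj(E2) E1 because a 180 pulse conjugates
# the transverse magnetisation; G is raised to the block count by 2x2
# spectral decomposition, all componentwise across nu_cpmg.
.bm_contrib <- function(nu_cpmg, kex, pa, dw_rad, t_relax) {
  pb <- 1 - pa
  if (dw_rad == 0 || pb == 0 || kex * pa * pb == 0)
    return(numeric(length(nu_cpmg)))

  n_p <- vapply(nu_cpmg, .cpmg_pulses, integer(1), t_relax = t_relax)
  n_blocks <- n_p / 2L
  delta <- t_relax / (2 * n_p)

  kab <- kex * pb
  kba <- kex * pa
  l11 <- complex(real = -kab)
  l12 <- complex(real = kba)
  l21 <- complex(real = kab)
  l22 <- complex(real = -kba, imaginary = -dw_rad)

  ee <- .expm22_vec(l11, l12, l21, l22, delta)       # E1 at delta
  e2 <- .expm22_vec(l11, l12, l21, l22, 2 * delta)   # E2 at 2 delta
  c11 <- Conj(e2$m11); c12 <- Conj(e2$m12)
  c21 <- Conj(e2$m21); c22 <- Conj(e2$m22)

  # H = Conj(E2) %*% E1
  h11 <- c11 * ee$m11 + c12 * ee$m21
  h12 <- c11 * ee$m12 + c12 * ee$m22
  h21 <- c21 * ee$m11 + c22 * ee$m21
  h22 <- c21 * ee$m12 + c22 * ee$m22
  # G = E1 %*% H
  g11 <- ee$m11 * h11 + ee$m12 * h21
  g12 <- ee$m11 * h12 + ee$m12 * h22
  g21 <- ee$m21 * h11 + ee$m22 * h21
  g22 <- ee$m21 * h12 + ee$m22 * h22

  gn <- .matpow22_vec(g11, g12, g21, g22, n_blocks)
  ma <- gn$m11 * pa + gn$m12 * pb
  -log(Mod(ma) / pa) / t_relax
}

# componentwise expm of the 2x2 complex matrix L scaled by t (t vectorised)
.expm22_vec <- function(l11, l12, l21, l22, t) {
  tr <- l11 + l22
  disc <- sqrt(tr^2 - 4 * (l11 * l22 - l12 * l21))
  lam1 <- (tr + disc) / 2
  lam2 <- (tr - disc) / 2
  e1 <- exp(lam1 * t)
  e2 <- exp(lam2 * t)
  dl <- lam1 - lam2
  if (Mod(dl) < 1e-12 * max(Mod(lam1), 1)) {
    # degenerate pair: expm(Lt) = e^{lam t} (I + t (L - lam I))
    list(m11 = e1 * (1 + t * (l11 - lam1)), m12 = e1 * t * l12,
         m21 = e1 * t * l21, m22 = e1 * (1 + t * (l22 - lam1)))
  } else {
    f1 <- e1 / dl; f2 <- e2 / dl
    list(m11 = f1 * (l11 - lam2) - f2 * (l11 - lam1),
         m12 = (f1 - f2) * l12,
         m21 = (f1 - f2) * l21,
         m22 = f1 * (l22 - lam2) - f2 * (l22 - lam1))
  }
}

# componentwise N-th power of 2x2 complex matrices (N vectorised)
.matpow22_vec <- function(g11, g12, g21, g22, n) {
  tr <- g11 + g22
  disc <- sqrt(tr^2 - 4 * (g11 * g22 - g12 * g21))
  mu1 <- (tr + disc) / 2
  mu2 <- (tr - disc) / 2
  dl <- mu1 - mu2
  degen <- Mod(dl) < 1e-13 * pmax(Mod(mu1), 1e-300)
  p1 <- mu1^n
  p2 <- mu2^n
  f1 <- ifelse(degen, 0, p1 / dl)
  f2 <- ifelse(degen, 0, p2 / dl)
  out <- list(
    m11 = f1 * (g11 - mu2) - f2 * (g11 - mu1),
    m12 = (f1 - f2) * g12,
    m21 = (f1 - f2) * g21,
    m22 = f1 * (g22 - mu2) - f2 * (g22 - mu1)
  )
  if (any(degen)) {
    # (mu I + X)^n with X nilpotent: mu^n I + n mu^(n-1) X
    b <- n * mu1^(n - 1)
    out$m11[degen] <- (p1 + b * (g11 - mu1))[degen]
    out$m12[degen] <- (b * g12)[degen]
    out$m21[degen] <- (b * g21)[degen]
    out$m22[degen] <- (p1 + b * (g22 - mu1))[degen]
  }
  out
}
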