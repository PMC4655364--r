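# Lipari-Szabo spectral densities and the standard 15N dipolar + CSA
# relaxation-rate expressions built on them.

#' Lipari-Szabo spectral density
#'
#' Evaluates the (extended) model-free spectral density J(omega) for a
#' motional model under isotropic or axially symmetric overall tumbling.
#' For an axial tensor the standard three-term form is used, with
#' correlation times `1/(6 D_perp)`, `1/(5 D_perp + D_par)` and
#' `1/(2 D_perp + 4 D_par)` and amplitudes determined by the angle between
#' the N-H bond and the symmetry axis. Internal motion enters through
#' `s2`, `tau_e` and (extended form) `s2f`; each overall correlation time
#' `tau_i` is combined with `tau_e` as `tau_i tau_e/(tau_i + tau_e)`.
#'
#' @param omega Angular frequency (rad/s); vectorised.
#' @param model A [motional_model()].
#' @param tensor A [diffusion_tensor()].
#' @param nh_angle Angle (radians) between the N-H bond vector and the
#'   tensor symmetry axis; required for axial tensors, ignored for
#'   isotropic ones.
#'
#' @return J(omega) in s/rad, same length as `omega`.
#' @examples
#' sp <- spin_system(800.2)
#' m <- motional_model("M2", s2 = 0.85, tau_e = 50)
#' tn <- diffusion_tensor("isotropic", tau_m = 10.7)
#' lipari_szabo_J(c(0, sp$omega_n), m, tn)
#' @export
lipari_szabo_J <- function(omega, model, tensor, nh_angle = NULL) {
  stopifnot(inherits(model, "motional_model"),
            inherits(tensor, "diffusion_tensor"))
  if (any(omega < 0)) abort("`omega` must be >= 0.")
  if (tensor$kind == "isotropic") {
    taus <- tensor$tau_m * 1e-9
    amps <- matrix(1, 1, 1)
  } else {
    if (is.null(nh_angle))
      abort("`nh_angle` is required for an axially symmetric tensor.")
    taus <- .axial_taus(tensor$tau_m, tensor$d_ratio)
    amps <- .axial_amplitudes(cos(nh_angle))
  }
  .mf_J(omega, model$s2, model$tau_e * 1e-12, model$s2f, taus, drop(amps))
}

# core spectral density: taus in s (length 1 or 3), amps same length,
# tau_e in s. Returns vector over omega.
.mf_J <- function(omega, s2, tau_e_s, s2f, taus, amps) {
  out <- numeric(length(omega))
  for (k in seq_along(taus)) {
    tk <- taus[k]
    slow <- s2 * tk / (1 + (omega * tk)^2)
    if (tau_e_s > 0 && s2f > s2) {
      tp <- tk * tau_e_s / (tk + tau_e_s)
      fast <- (s2f - s2) * tp / (1 + (omega * tp)^2)
    } else fast <- 0
    out <- out + amps[k] * (slow + fast)
  }
  0.4 * out
}

#' 15N relaxation rates from a motional model
#'
#' Computes R1, R2 and the steady-state heteronuclear NOE from the standard
#' 15N dipolar + CSA expressions, evaluating the spectral density at
#' 0, omega_N, omega_H - omega_N, omega_H and omega_H + omega_N. An `rex`
#' term in the model is added to R2 only, as an additive constant at the
#' measurement field.
#'
#' @inheritParams lipari_szabo_J
#' @param spin A [spin_system()].
#'
#' @return A one-row tibble with columns `r1`, `r2` (1/s) and `noe`.
#' @examples
#' relaxation_rates(motional_model("M1", s2 = 0.91),
#'                  diffusion_tensor("isotropic", tau_m = 10.8),
#'                  spin_system(800.2))
#' @export
relaxation_rates <- function(model, tensor, spin, nh_angle = NULL) {
  stopifnot(inherits(spin, "spin_system"))
  j <- lipari_szabo_J(.spin_frequencies(spin), model, tensor, nh_angle)
  .rates_from_J(j, spin, model$rex)
}

# j: J at {0, wN, wH-wN, wH, wH+wN}
.rates_from_J <- function(j, spin, rex = 0) {
  d2 <- spin$d2; c2 <- spin$c2
  r1 <- d2 / 4 * (j[3] + 3 * j[2] + 6 * j[5]) + c2 * j[2]
  r2 <- d2 / 8 * (4 * j[1] + j[3] + 3 * j[2] + 6 * j[4] + 6 * j[5]) +
    c2 / 6 * (4 * j[1] + 3 * j[2]) + rex
  sigma_nh <- d2 / 4 * (6 * j[5] - j[3])
  noe <- 1 + spin$gamma_ratio * sigma_nh / r1
  tibble(r1 = r1, r2 = r2, noe = noe)
}

# fast path for diffusion fitting: R2/R1 ratio for a rigid (M1) residue as a
# function of the tensor, vectorised over residues via cos_theta. S2 cancels.
.rigid_ratio <- function(tau_m_ns, d_ratio, cos_theta, spin) {
  w <- .spin_frequencies(spin)
  if (d_ratio == 1) {
    n <- if (is.null(cos_theta)) 1L else length(cos_theta)
    taus <- tau_m_ns * 1e-9
    jw <- 0.4 * taus / (1 + (w * taus)^2)
    j <- matrix(jw, nrow = n, ncol = 5, byrow = TRUE)
  } else {
    taus <- .axial_taus(tau_m_ns, d_ratio)
    amps <- .axial_amplitudes(cos_theta)          # n x 3
    lor <- outer(taus, w, function(tk, om) tk / (1 + (om * tk)^2)) # 3 x 5
    j <- 0.4 * (amps %*% lor)                     # n x 5
  }
  d2 <- spin$d2; c2 <- spin$c2
  r1 <- d2 / 4 * (j[, 3] + 3 * j[, 2] + 6 * j[, 5]) + c2 * j[, 2]
  r2 <- d2 / 8 * (4 * j[, 1] + j[, 3] + 3 * j[, 2] + 6 * j[, 4] + 6 * j[, 5]) +
    c2 / 6 * (4 * j[, 1] + 3 * j[, 2])
  r2 / r1
}
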