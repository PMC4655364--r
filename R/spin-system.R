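# Constructors and validators for the physical objects the forward models
# consume: the spin system (field and interaction constants), the local
# motional model (M1-M5), the rotational diffusion tensor, the two-state
# exchange parameters, and the constant-time CPMG design.

# gyromagnetic ratio of 1H in rad s^-1 T^-1; only the 1H frequency and the
# gamma ratio are user-facing, gamma_N is derived.
.GAMMA_H <- 2.6752218744e8
.HBAR <- 1.054571817e-34
.MU0_4PI <- 1e-7

#' Define a 15N-1H spin system
#'
#' Collects the spectrometer field and the interaction constants needed by
#' the dipolar/CSA relaxation-rate expressions. Defaults are the community
#' standard values for backbone amide model-free analysis; all are
#' overridable.
#'
#' @param field_mhz Spectrometer 1H frequency in MHz (e.g. 800.2).
#' @param gamma_ratio Ratio of gyromagnetic ratios, gamma_H/gamma_N
#'   (dimensionless, negative for 15N).
#' @param r_nh N-H bond length in Angstrom.
#' @param csa_ppm 15N chemical shift anisotropy in ppm.
#'
#' @return An object of class `spin_system`: a list with the inputs plus the
#'   derived angular frequencies `omega_h`, `omega_n` (magnitudes, rad/s) and
#'   the squared dipolar (`d2`) and CSA (`c2`) interaction constants.
#'
#' @examples
#' spin_system(800.2)
#' @export
spin_system <- function(field_mhz = 800.2, gamma_ratio = -9.8655,
                        r_nh = 1.02, csa_ppm = -160) {
  if (!is.numeric(field_mhz) || length(field_mhz) != 1L || field_mhz <= 0)
    abort("`field_mhz` must be a single positive number.")
  if (abs(abs(gamma_ratio) - 9.87) > 0.01 * 9.87)
    abort("|gamma_ratio| must be within 1% of 9.87.")
  if (r_nh <= 0) abort("`r_nh` must be positive.")

  omega_h <- 2 * pi * field_mhz * 1e6            # rad/s, magnitude
  omega_n <- omega_h / abs(gamma_ratio)          # rad/s, magnitude
  gamma_n <- .GAMMA_H / gamma_ratio              # signed
  d <- .MU0_4PI * .HBAR * .GAMMA_H * abs(gamma_n) / (r_nh * 1e-10)^3
  cc <- omega_n * abs(csa_ppm) * 1e-6 / sqrt(3)

  structure(
    list(field_mhz = field_mhz, gamma_ratio = gamma_ratio, r_nh = r_nh,
         csa_ppm = csa_ppm, omega_h = omega_h, omega_n = omega_n,
         d2 = d^2, c2 = cc^2),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> 1H %.2f MHz (15N %.2f MHz), rNH %.3f A, CSA %.0f ppm\n",
              x$field_mhz, x$omega_n / (2 * pi * 1e6), x$r_nh, x$csa_ppm))
  invisible(x)
}

# frequencies (rad/s magnitudes) at which J must be evaluated
.spin_frequencies <- function(spin) {
  c(0, spin$omega_n, spin$omega_h - spin$omega_n,
    spin$omega_h, spin$omega_h + spin$omega_n)
}

.MODEL_PARAMS <- list(
  M1 = "s2", M2 = c("s2", "tau_e"), M3 = c("s2", "rex"),
  M4 = c("s2", "tau_e", "rex"), M5 = c("s2", "tau_e", "s2f")
)

#' Define a Lipari-Szabo motional model
#'
#' One of the five standard model-free parameterisations of internal N-H
#' bond motion: M1 (`s2`), M2 (`s2`, `tau_e`), M3 (`s2`, `rex`),
#' M4 (`s2`, `tau_e`, `rex`), M5 (`s2`, `tau_e`, `s2f`). Parameters not
#' belonging to the chosen model must be left at their defaults.
#'
#' @param model Model identifier, `"M1"` to `"M5"`.
#' @param s2 Generalised squared order parameter (0-1).
#' @param tau_e Effective internal correlation time in ps (M2/M4/M5).
#' @param s2f Squared order parameter of the fast internal motion (M5 only);
#'   the slow component is `s2/s2f`.
#' @param rex Chemical/conformational exchange contribution to R2 in 1/s
#'   (M3/M4), treated as an additive constant at the measurement field.
#'
#' @return An object of class `motional_model`.
#' @examples
#' motional_model("M2", s2 = 0.82, tau_e = 40)
#' @export
motional_model <- function(model = c("M1", "M2", "M3", "M4", "M5"),
                           s2, tau_e = 0, s2f = 1, rex = 0) {
  model <- match.arg(model)
  free <- .MODEL_PARAMS[[model]]
  if (!("tau_e" %in% free) && tau_e != 0)
    abort(sprintf("`tau_e` is not a parameter of %s.", model))
  if (!("s2f" %in% free) && s2f != 1)
    abort(sprintf("`s2f` is not a parameter of %s.", model))
  if (!("rex" %in% free) && rex != 0)
    abort(sprintf("`rex` is not a parameter of %s.", model))
  if (s2 < 0 || s2 > 1) abort("`s2` must lie in [0, 1].")
  if (s2f < 0 || s2f > 1) abort("`s2f` must lie in [0, 1].")
  if (s2 > s2f + 1e-12) abort("`s2` must not exceed `s2f`.")
  if (tau_e < 0) abort("`tau_e` must be >= 0.")
  if (rex < 0) abort("`rex` must be >= 0.")
  structure(list(model = model, s2 = s2, tau_e = tau_e, s2f = s2f, rex = rex),
            class = "motional_model")
}

#' @export
print.motional_model <- function(x, ...) {
  free <- .MODEL_PARAMS[[x$model]]
  vals <- vapply(free, function(p) x[[p]], numeric(1))
  cat(sprintf("<motional_model> %s: %s\n", x$model,
              paste(sprintf("%s=%.4g", free, vals), collapse = ", ")))
  invisible(x)
}

#' Define a rotational diffusion tensor
#'
#' Isotropic or axially symmetric overall tumbling. The overall correlation
#' time is `tau_m = 1/(6 D_iso)` with `D_iso = (D_par + 2 D_perp)/3`; the
#' anisotropy is `d_ratio = D_par/D_perp` (< 1 oblate, > 1 prolate).
#'
#' @param kind `"isotropic"`, `"axial_oblate"` or `"axial_prolate"`.
#' @param tau_m Overall rotational correlation time in ns.
#' @param d_ratio Diffusion anisotropy D_par/D_perp; must be 1 for
#'   isotropic, < 1 for oblate, > 1 for prolate.
#' @param axis Unit vector of the symmetry axis in the molecular frame
#'   (axial kinds only; normalised internally).
#'
#' @return An object of class `diffusion_tensor`.
#' @examples
#' diffusion_tensor("axial_oblate", tau_m = 10.8, d_ratio = 0.89)
#' @export
diffusion_tensor <- function(kind = c("isotropic", "axial_oblate", "axial_prolate"),
                             tau_m, d_ratio = 1, axis = c(0, 0, 1)) {
  kind <- match.arg(kind)
  if (tau_m <= 0) abort("`tau_m` must be positive (ns).")
  ok <- switch(kind,
    isotropic = d_ratio == 1,
    axial_oblate = d_ratio < 1,
    axial_prolate = d_ratio > 1
  )
  if (!ok) abort(sprintf("`d_ratio` = %g is inconsistent with kind '%s'.",
                         d_ratio, kind))
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0) abort("`axis` must be a nonzero 3-vector.")
  structure(list(kind = kind, tau_m = tau_m, d_ratio = d_ratio,
                 axis = axis / nrm),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat(sprintf("<diffusion_tensor> %s: tau_m %.3g ns, D_par/D_perp %.3g\n",
              x$kind, x$tau_m, x$d_ratio))
  invisible(x)
}

# the three correlation times (s) of an axially symmetric rotor, longest first
.axial_taus <- function(tau_m_ns, d_ratio) {
  d_iso <- 1 / (6 * tau_m_ns * 1e-9)
  d_par <- 3 * d_iso * d_ratio / (d_ratio + 2)
  d_perp <- 3 * d_iso / (d_ratio + 2)
  c(1 / (6 * d_perp), 1 / (5 * d_perp + d_par), 1 / (2 * d_perp + 4 * d_par))
}

# amplitude coefficients for the axial three-term spectral density;
# theta is the N-H vs symmetry-axis angle. Rows sum to 1.
.axial_amplitudes <- function(cos_theta) {
  c2 <- cos_theta^2
  s2 <- 1 - c2
  cbind(((3 * c2 - 1) / 2)^2, 3 * s2 * c2, 0.75 * s2^2)
}

#' Define two-state chemical exchange parameters
#'
#' Parameters of the A <-> B exchange process probed by CPMG relaxation
#' dispersion: total exchange rate `kex = k_AB + k_BA`, major-state
#' population `pa` (so `pb = 1 - pa`), and the 15N chemical-shift difference
#' between the states in ppm (stored as a magnitude; its rad/s value scales
#' linearly with the static field).
#'
#' @param kex Exchange rate in 1/s.
#' @param pa Major-state population, in (0.5, 1].
#' @param dw_ppm |omega_A - omega_B| in ppm (>= 0).
#' @param r20 Exchange-free transverse relaxation rate(s) in 1/s; a named
#'   vector keyed by field (MHz) or a single value.
#'
#' @return An object of class `two_state_exchange`.
#' @examples
#' two_state_exchange(kex = 1822, pa = 0.9866, dw_ppm = 2, r20 = 12)
#' @export
two_state_exchange <- function(kex, pa, dw_ppm, r20 = numeric()) {
  if (kex <= 0) abort("`kex` must be positive.")
  if (pa < 0.5 || pa > 1) abort("`pa` must lie in [0.5, 1].")
  if (dw_ppm < 0) abort("`dw_ppm` must be >= 0.")
  structure(list(kex = kex, pa = pa, pb = 1 - pa, dw_ppm = dw_ppm, r20 = r20),
            class = "two_state_exchange")
}

#' @export
print.two_state_exchange <- function(x, ...) {
  cat(sprintf("<two_state_exchange> kex %.4g /s, pA %.4f (pApB %.4g), dw %.3g ppm\n",
              x$kex, x$pa, x$pa * x$pb, x$dw_ppm))
  invisible(x)
}

#' Define a constant-time CPMG experiment design
#'
#' The default reproduces the published design: a 60 ms constant transverse
#' relaxation period and nu_CPMG values of 0, 50, 100 (duplicated), 150,
#' 200, 250, 300, 350, 400, 450, 500, 600 and 750 Hz at 1H fields of 800.2
#' and 600.13 MHz, where `nu_cpmg = 1/(4 tau_cp)` and `tau_cp` is the delay
#' flanking each 180-degree pulse. Every nonzero nu_cpmg must correspond to
#' an even number of 180-degree pulses within `t_relax` after rounding
#' (realised frequency within 1% of the requested one).
#'
#' @param t_relax Constant transverse relaxation time in s.
#' @param nu_cpmg Refocusing frequencies in Hz; may contain 0 (the
#'   reference plane) and duplicates.
#' @param fields Spectrometer 1H frequencies in MHz.
#'
#' @return An object of class `cpmg_design`.
#' @examples
#' cpmg_design()
#' @export
cpmg_design <- function(t_relax = 0.060,
                        nu_cpmg = c(0, 50, 100, 100, 150, 200, 250, 300,
                                    350, 400, 450, 500, 600, 750),
                        fields = c(800.2, 600.13)) {
  if (t_relax <= 0) abort("`t_relax` must be positive.")
  if (any(nu_cpmg < 0)) abort("`nu_cpmg` values must be >= 0.")
  for (nu in unique(nu_cpmg[nu_cpmg > 0])) .cpmg_pulses(nu, t_relax)
  structure(list(t_relax = t_relax, nu_cpmg = nu_cpmg, fields = fields),
            class = "cpmg_design")
}

#' @export
print.cpmg_design <- function(x, ...) {
  cat(sprintf("<cpmg_design> t_relax %.3g s; %d nu_cpmg points (%s Hz); fields %s MHz\n",
              x$t_relax, length(x$nu_cpmg),
              paste(x$nu_cpmg, collapse = ", "),
              paste(x$fields, collapse = ", ")))
  invisible(x)
}

# number of 180-degree pulses fitting in t_relax at nu_cpmg: rounded to the
# nearest even integer; > 1% mismatch between requested and realised
# frequency is an error.
.cpmg_pulses <- function(nu_cpmg, t_relax) {
  n <- 2L * as.integer(round(nu_cpmg * t_relax))
  if (n < 2L) n <- 2L
  realized <- n / (2 * t_relax)
  if (abs(realized - nu_cpmg) > 0.01 * nu_cpmg)
    abort(sprintf(
      "nu_cpmg = %g Hz is incompatible with t_relax = %g s (realised %g Hz, > 1%% off).",
      nu_cpmg, t_relax, realized))
  n
}

# realisable nu_cpmg values (even pulse count) within a range, for dense
# model curves
.cpmg_realizable <- function(t_relax, nu_min, nu_max) {
  k <- seq.int(max(1L, floor(nu_min * t_relax)), ceiling(nu_max * t_relax))
  k / t_relax
}
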