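# Shared fixtures, all generated in code.

fx_spin <- function(field = 800.2) spin_system(field)

fx_iso <- function(tau_m = 10.8) diffusion_tensor("isotropic", tau_m = tau_m)

fx_oblate <- function(tau_m = 10.8, d_ratio = 0.89, axis = c(0, 0, 1)) {
  diffusion_tensor("axial_oblate", tau_m = tau_m, d_ratio = d_ratio,
                   axis = axis)
}

# random unit vectors (seeded)
fx_orientations <- function(n, seed = 7) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  tibble::tibble(residue = seq_len(n), x = v[, 1], y = v[, 2], z = v[, 3])
}

# a relaxation record straight from the forward model (no decay fitting).
# The stated sigmas (2% on rates, 0.02 absolute on NOE) are also the noise
# scale when `noisy`, so the chi-square calibration is exact.
fx_record <- function(residue, model, tensor, spin, nh_angle = NULL,
                      frac_sigma = c(r1 = 0.02, r2 = 0.02, noe = 0.02),
                      noisy = FALSE, seed = NULL) {
  rt <- relaxation_rates(model, tensor, spin, nh_angle)
  sig <- c(frac_sigma[["r1"]] * rt$r1, frac_sigma[["r2"]] * rt$r2,
           abs(frac_sigma[["noe"]]))
  obs <- c(rt$r1, rt$r2, rt$noe)
  if (noisy) {
    if (!is.null(seed)) set.seed(seed)
    obs <- obs + rnorm(3, 0, sig)
  }
  tibble::tibble(residue = residue, ph = 7, field_mhz = spin$field_mhz,
                 peakset = "major",
                 r1 = obs[1], r1_sigma = sig[1],
                 r2 = obs[2], r2_sigma = sig[2],
                 noe = obs[3], noe_sigma = sig[3],
                 r2_r1 = obs[2] / obs[1],
                 r2_r1_sigma = obs[2] / obs[1] *
                   sqrt((sig[1] / obs[1])^2 + (sig[2] / obs[2])^2))
}

# full synthetic pipeline: truth table -> records (decay + NOE fitting)
fx_pipeline_records <- function(truth_tbl, tensor, spin, noise = 0.02,
                                seed = 1) {
  gt <- ground_truth(truth_tbl, tensor, noise = noise)
  sim <- simulate_relaxation(gt, spin, seed = seed)
  fits <- fit_decays(sim$decays)
  list(records = relaxation_records(fits, sim$noe,
                                    field_mhz = spin$field_mhz, ph = 7),
       sim = sim)
}

# minimal synthetic PDB text (two alanine-like residues + one glycine-like;
# fabricated coordinates, not a deposited structure)
fx_write_mini_pdb <- function(path) {
  lines <- c(
    "REMARK synthetic test structure",
    sprintf("ATOM  %5d  N   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N", 1, 1, 0.000, 0.000, 0.000),
    sprintf("ATOM  %5d  H   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           H", 2, 1, -0.500, 0.866, 0.000),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C", 3, 1, 1.458, 0.000, 0.000),
    sprintf("ATOM  %5d  C   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C", 4, 1, 2.009, 1.420, 0.000),
    sprintf("ATOM  %5d  O   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O", 5, 1, 1.251, 2.390, 0.000),
    sprintf("ATOM  %5d  N   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N", 6, 2, 3.332, 1.536, 0.000),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C", 7, 2, 3.989, 2.831, 0.000),
    sprintf("ATOM  %5d  C   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C", 8, 2, 5.504, 2.705, 0.000),
    sprintf("ATOM  %5d  O   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O", 9, 2, 6.092, 1.625, 0.000),
    "END")
  writeLines(lines, path)
  path
}
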