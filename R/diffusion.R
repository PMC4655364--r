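# Rotational diffusion tensor estimation from R2/R1 ratios, N-H bond
# orientations from coordinates, and the inertia-tensor utility.

# axis unit vector from polar angles
.axis_from_angles <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# chi-square of observed ratios against a tensor parameterisation
.ratio_chisq <- function(tau_m, d_ratio, axis, obs, sig, vecs, spin) {
  cth <- if (is.null(vecs)) NULL else pmin(1, abs(drop(vecs %*% axis)))
  calc <- .rigid_ratio(tau_m, d_ratio, cth, spin)
  sum(((obs - calc) / sig)^2)
}

#' Select the rigid residue subset for diffusion fitting
#'
#' Standard practice filter: residues with NOE at or above a cutoff and
#' R2/R1 within a multiple of the interquartile range of the median,
#' excluding residues with fast internal motion or exchange broadening.
#'
#' @param records A relaxation record table (see [relaxation_records()]).
#' @param noe_min Minimum heteronuclear NOE (default 0.65).
#' @param iqr_mult R2/R1 window half-width in IQR units (default 1.5).
#' @return The filtered record tibble.
#' @export
rigid_subset <- function(records, noe_min = 0.65, iqr_mult = 1.5) {
  stopifnot(is.data.frame(records))
  ok <- records |> filter(.data$noe >= noe_min)
  med <- median(ok$r2_r1)
  iqr <- IQR(ok$r2_r1)
  filter(ok, abs(.data$r2_r1 - med) <= iqr_mult * iqr)
}

#' Estimate the rotational diffusion tensor from R2/R1 ratios
#'
#' Fits isotropic, axially symmetric oblate and prolate diffusion tensors
#' to the R2/R1 ratios of a rigid residue subset (under rigid local motion
#' the ratio is independent of S2). The axial models require per-residue
#' N-H bond orientations; model choice is by F-test of the chi-square
#' reduction of the better axial model over the isotropic one, with the
#' oblate/prolate branch decided by the lower chi-square.
#'
#' @param records A relaxation record table (one field, one pH).
#' @param orientations A tibble (residue, x, y, z) of N-H unit vectors in
#'   the molecular frame (see [nh_orientations()]), or `NULL` for an
#'   isotropic-only fit (a warning is emitted).
#' @param spin A [spin_system()].
#' @param noe_min,iqr_mult Rigid-subset selection, see [rigid_subset()].
#' @param alpha F-test level for preferring the axial model.
#' @param tau_limits Search range for tau_m in ns.
#' @return An object of class `diffusion_fit`: the selected
#'   [diffusion_tensor()], per-model chi-squares, the F-test, the rigid
#'   subset used, and per-residue angles to the symmetry axis.
#' @export
estimate_diffusion <- function(records, orientations = NULL, spin,
                               noe_min = 0.65, iqr_mult = 1.5, alpha = 0.05,
                               tau_limits = c(2, 30)) {
  stopifnot(inherits(spin, "spin_system"))
  rigid <- rigid_subset(records, noe_min, iqr_mult)
  if (nrow(rigid) < 10)
    abort(sprintf("only %d rigid residues (>= 10 required).", nrow(rigid)))
  obs <- rigid$r2_r1
  sig <- rigid$r2_r1_sigma
  if (any(!is.finite(sig) | sig <= 0)) sig <- rep(0.05 * median(obs), length(obs))
  n <- length(obs)

  iso_opt <- optimize(function(tm)
    .ratio_chisq(tm, 1, NULL, obs, sig, NULL, spin),
    interval = tau_limits)
  chisq_iso <- iso_opt$objective
  tau_iso <- iso_opt$minimum

  fits <- list(isotropic = list(tau_m = tau_iso, d_ratio = 1, axis = c(0, 0, 1),
                                chisq = chisq_iso))

  if (is.null(orientations)) {
    warn("no N-H orientations supplied: falling back to an isotropic fit.")
    tensor <- diffusion_tensor("isotropic", tau_m = tau_iso)
    return(structure(list(tensor = tensor, fits = fits, f_test = NULL,
                          rigid = rigid, angles = NULL, spin = spin),
                     class = "diffusion_fit"))
  }

  vecs <- rigid |>
    left_join(orientations, by = "residue")
  if (anyNA(vecs$x)) abort("orientations missing for some rigid residues.")
  vmat <- as.matrix(vecs[, c("x", "y", "z")])
  vmat <- vmat / sqrt(rowSums(vmat^2))

  axial_fit <- function(d_lo, d_hi) {
    starts <- crossing(
      theta = c(0.3, 1.0, 1.5), phi = c(0.5, 2.0, 4.0),
      d0 = (d_lo + d_hi) / 2
    )
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      st <- starts[k, ]
      o <- nlminb(
        c(tau_iso, st$d0, st$theta, st$phi),
        function(p) .ratio_chisq(p[1], p[2], .axis_from_angles(p[3], p[4]),
                                 obs, sig, vmat, spin),
        lower = c(tau_limits[1], d_lo, 0, -2 * pi),
        upper = c(tau_limits[2], d_hi, pi, 2 * pi)
      )
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    list(tau_m = best$par[1], d_ratio = best$par[2],
         axis = .axis_from_angles(best$par[3], best$par[4]),
         chisq = best$objective)
  }

  fits$axial_oblate <- axial_fit(0.40, 0.999)
  fits$axial_prolate <- axial_fit(1.001, 2.5)

  ax_kind <- if (fits$axial_oblate$chisq <= fits$axial_prolate$chisq)
    "axial_oblate" else "axial_prolate"
  ax <- fits[[ax_kind]]
  f_stat <- ((chisq_iso - ax$chisq) / 3) / (ax$chisq / (n - 4))
  p_val <- pf(f_stat, 3, n - 4, lower.tail = FALSE)

  # an isotropic fit at the numerical floor (noise-free data) cannot be
  # improved upon meaningfully; the F ratio is then 0/0 noise
  exact_iso <- chisq_iso < 1e-8 * n
  if (!exact_iso && is.finite(f_stat) && f_stat > 0 && p_val < alpha) {
    tensor <- diffusion_tensor(ax_kind, tau_m = ax$tau_m,
                               d_ratio = ax$d_ratio, axis = ax$axis)
  } else {
    tensor <- diffusion_tensor("isotropic", tau_m = tau_iso)
  }

  angles <- tibble(
    residue = vecs$residue,
    nh_angle = acos(pmin(1, abs(drop(vmat %*% tensor$axis))))
  )
  structure(list(tensor = tensor, fits = fits,
                 f_test = list(statistic = f_stat, p_value = p_val,
                               df = c(3, n - 4), alpha = alpha,
                               axial_kind = ax_kind),
                 rigid = rigid, angles = angles, spin = spin),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> selected %s: tau_m = %.3f ns, D_par/D_perp = %.3f\n",
              x$tensor$kind, x$tensor$tau_m, x$tensor$d_ratio))
  cat(sprintf("  chi-square: iso %.2f", x$fits$isotropic$chisq))
  if (!is.null(x$fits$axial_oblate))
    cat(sprintf(", oblate %.2f, prolate %.2f", x$fits$axial_oblate$chisq,
                x$fits$axial_prolate$chisq))
  cat(sprintf("  (n = %d rigid residues)\n", nrow(x$rigid)))
  invisible(x)
}

#' N-H bond orientations from a PDB structure
#'
#' Extracts amide N to H unit vectors per residue from the first model of a
#' PDB file (via the bio3d reader). When the amide proton is absent the
#' H position is reconstructed from backbone geometry: along the bisector
#' of the C(i-1)->N and CA->N directions.
#'
#' @param pdb Path to a PDB file or a `bio3d` pdb object.
#' @return A tibble (residue, x, y, z) of unit vectors.
#' @export
nh_orientations <- function(pdb) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort("the bio3d package is required to read PDB coordinates.")
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, multi = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", ]
  # first chain/model only for orientation purposes
  at <- at[at$chain == at$chain[1], ]
  res_ids <- sort(unique(at$resno))
  rows <- lapply(res_ids, function(r) {
    nn <- at[at$resno == r & at$elety == "N", ][1, ]
    if (!nrow(nn) || is.na(nn$x)) return(NULL)
    hh <- at[at$resno == r & at$elety %in% c("H", "HN"), ]
    if (nrow(hh) >= 1 && !is.na(hh$x[1])) {
      v <- c(hh$x[1] - nn$x, hh$y[1] - nn$y, hh$z[1] - nn$z)
    } else {
      ca <- at[at$resno == r & at$elety == "CA", ][1, ]
      cp <- at[at$resno == r - 1 & at$elety == "C", ][1, ]
      if (!nrow(ca) || !nrow(cp) || is.na(ca$x) || is.na(cp$x)) return(NULL)
      u1 <- c(nn$x - cp$x, nn$y - cp$y, nn$z - cp$z)
      u2 <- c(nn$x - ca$x, nn$y - ca$y, nn$z - ca$z)
      u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
      v <- u1 + u2
    }
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NULL)
    tibble(residue = r, x = v[1] / nv, y = v[2] / nv, z = v[3] / nv)
  })
  bind_rows(rows)
}

#' Principal moments of inertia, normalised
#'
#' Computes the mass-weighted inertia tensor about the centre of mass and
#' returns the principal moments sorted descending, normalised to the
#' largest (Ix = 1).
#'
#' @param coordinates An n x 3 matrix/data frame of coordinates, or a PDB
#'   path / bio3d pdb object (all ATOM records of the first model).
#' @param masses Atomic masses; defaults to unit masses for matrix input
#'   and element masses for PDB input.
#' @return A tibble with one row: `ix`, `iy`, `iz` (normalised, descending).
#' @examples
#' cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
#' inertia_ratio(cube)
#' @export
inertia_ratio <- function(coordinates, masses = NULL) {
  if (is.character(coordinates) || inherits(coordinates, "pdb")) {
    if (!requireNamespace("bio3d", quietly = TRUE))
      abort("the bio3d package is required to read PDB coordinates.")
    pdb <- if (is.character(coordinates))
      bio3d::read.pdb(coordinates, multi = FALSE) else coordinates
    at <- pdb$atom[pdb$atom$type == "ATOM", ]
    coordinates <- as.matrix(at[, c("x", "y", "z")])
    if (is.null(masses)) {
      mass_map <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
      elem <- toupper(substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1))
      masses <- unname(mass_map[elem])
      masses[is.na(masses)] <- 12.011
    }
  }
  xyz <- as.matrix(coordinates)
  if (ncol(xyz) != 3) abort("coordinates must have three columns.")
  n <- nrow(xyz)
  if (n < 3) abort("at least 3 atoms are required.")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n) abort("`masses` length must match the atom count.")

  com <- colSums(xyz * masses) / sum(masses)
  rc <- sweep(xyz, 2, com)
  r2 <- rowSums(rc^2)
  it <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    it[i, j] <- sum(masses * ((i == j) * r2 - rc[, i] * rc[, j]))
  }
  ev <- sort(eigen(it, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[3] <= 1e-10 * ev[1])
    abort("degenerate (collinear) geometry: smallest principal moment is ~0.")
  tibble(ix = 1, iy = ev[2] / ev[1], iz = ev[3] / ev[1])
}
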