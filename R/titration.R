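# Composite chemical-shift-perturbation computation and peak-status
# bookkeeping across a pH titration series.

#' Composite amide chemical-shift change
#'
#' `sqrt(dH^2 + (w dN)^2)` with the conventional nitrogen weight of 0.2,
#' reflecting the narrower 1H shift dispersion.
#'
#' @param dh,dn 1H and 15N shift changes in ppm; vectorised.
#' @param weight Nitrogen scaling weight (> 0).
#' @return Composite shift change in ppm (>= 0).
#' @examples
#' composite_shift(0.03, 0.5)  # 0.1044
#' @export
composite_shift <- function(dh, dn, weight = 0.2) {
  if (weight <= 0) abort("`weight` must be > 0.")
  sqrt(dh^2 + (weight * dn)^2)
}

#' Composite shift changes between two pH points
#'
#' Computes the per-residue composite shift change between two pH values of
#' a titration series. Residues missing at either endpoint are flagged
#' (`missing_a`/`missing_b`) and carry no numeric value; they are never
#' zero-filled. Only major peaks are compared.
#'
#' @param shifts A shift table (residue, ph, dh_ppm, dn_ppm, status,
#'   peakset), e.g. from [simulate_titration()] or [read_peak_table()].
#' @param ph_a,ph_b The two pH values; both must occur in the series.
#' @param weight Nitrogen weight for [composite_shift()].
#' @return A tibble (residue, d_comp, missing_a, missing_b).
#' @export
csp_between <- function(shifts, ph_a, ph_b, weight = 0.2) {
  stopifnot(is.data.frame(shifts))
  if (!"peakset" %in% names(shifts)) shifts$peakset <- "major"
  for (p in c(ph_a, ph_b)) {
    if (!any(abs(shifts$ph - p) < 1e-9))
      abort(sprintf("pH %.2f is not part of the series.", p))
  }
  one <- function(p, tag) {
    shifts |>
      filter(abs(.data$ph - p) < 1e-9, .data$peakset == "major") |>
      transmute(.data$residue,
                "{tag}_dh" := .data$dh_ppm, "{tag}_dn" := .data$dn_ppm,
                "missing_{tag}" := .data$status == "missing")
  }
  full_join(one(ph_a, "a"), one(ph_b, "b"), by = "residue") |>
    mutate(
      missing_a = coalesce(.data$missing_a, TRUE),
      missing_b = coalesce(.data$missing_b, TRUE),
      d_comp = ifelse(.data$missing_a | .data$missing_b, NA_real_,
                      composite_shift(.data$a_dh - .data$b_dh,
                                      .data$a_dn - .data$b_dn, weight))
    ) |>
    select("residue", "d_comp", "missing_a", "missing_b") |>
    arrange(.data$residue)
}

#' Summarise peak status across a pH series
#'
#' Tabulates present/missing/multiple counts per pH, the first-appearance
#' pH of every residue as the titration proceeds from high to low pH (the
#' highest pH at which its major peak is observed), and the pH window in
#' which each residue shows multiple peak sets. Input row order is
#' irrelevant.
#'
#' @param shifts A shift table (residue, ph, dh_ppm, dn_ppm, status,
#'   peakset).
#' @return A list of class `peak_status_summary` with `counts`
#'   (ph, present, missing, multiple), `first_appearance`
#'   (residue, ph_first; NA if never observed) and `multiple_window`
#'   (residue, ph_from, ph_to).
#' @export
peak_status_summary <- function(shifts) {
  stopifnot(is.data.frame(shifts))
  if (nrow(shifts) == 0) abort("empty shift table.")
  if (!"peakset" %in% names(shifts)) shifts$peakset <- "major"
  major <- filter(shifts, .data$peakset == "major")

  counts <- major |>
    group_by(.data$ph) |>
    summarise(present = sum(.data$status == "present"),
              missing = sum(.data$status == "missing"),
              multiple = sum(.data$status == "multiple"),
              .groups = "drop") |>
    arrange(desc(.data$ph))

  first_appearance <- major |>
    group_by(.data$residue) |>
    summarise(ph_first = if (any(.data$status != "missing"))
      max(.data$ph[.data$status != "missing"]) else NA_real_,
      .groups = "drop") |>
    arrange(.data$residue)

  multi <- filter(major, .data$status == "multiple")
  multiple_window <- if (nrow(multi) == 0) {
    tibble(residue = multi$residue, ph_from = numeric(), ph_to = numeric())
  } else {
    multi |>
      group_by(.data$residue) |>
      summarise(ph_from = max(.data$ph), ph_to = min(.data$ph),
                .groups = "drop") |>
      arrange(.data$residue)
  }

  structure(list(counts = counts, first_appearance = first_appearance,
                 multiple_window = multiple_window),
            class = "peak_status_summary")
}

#' @export
print.peak_status_summary <- function(x, ...) {
  cat("<peak_status_summary>\n")
  print(x$counts)
  late <- filter(x$first_appearance,
                 !is.na(.data$ph_first) &
                   .data$ph_first < max(x$counts$ph))
  if (nrow(late))
    cat(sprintf("  %d residues first observed below pH %.1f\n",
                nrow(late), max(x$counts$ph)))
  invisible(x)
}

#' Compare forward and reverse titrations
#'
#' Reversibility check: per-residue composite shift difference between two
#' series at matched pH points (major peaks only), reporting the maximum
#' discrepancy per residue.
#'
#' @param forward,reverse Two shift tables covering common pH points.
#' @param weight Nitrogen weight for [composite_shift()].
#' @return A tibble (residue, max_d_comp, n_ph).
#' @export
titration_reversibility <- function(forward, reverse, weight = 0.2) {
  f <- filter(forward, .data$peakset == "major", .data$status != "missing")
  r <- filter(reverse, .data$peakset == "major", .data$status != "missing")
  inner_join(f, r, by = c("residue", "ph"), suffix = c("_f", "_r")) |>
    mutate(d_comp = composite_shift(.data$dh_ppm_f - .data$dh_ppm_r,
                                    .data$dn_ppm_f - .data$dn_ppm_r, weight)) |>
    group_by(.data$residue) |>
    summarise(max_d_comp = max(.data$d_comp), n_ph = n(), .groups = "drop")
}
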