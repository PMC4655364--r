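# ggplot2 graphics for the result types.

#' Plot dispersion profiles with fitted curves
#'
#' @param object A `dispersion_fit`.
#' @param profiles Optional dispersion profile tibble to overlay as points
#'   with error bars.
#' @param ... Unused.
#' @return A ggplot object: R2eff vs nu_CPMG, faceted by residue, coloured
#'   by field.
#' @exportS3Method ggplot2::autoplot
autoplot.dispersion_fit <- function(object, profiles = NULL, ...) {
  curves <- dispersion_curves(object)
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$nu_cpmg_hz, y = .data$r2eff,
                                    colour = factor(.data$field_mhz))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~residue, scales = "free_y") +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2]^eff ~ (s^-1)),
                  colour = "1H field (MHz)") +
    ggplot2::theme_bw()
  if (!is.null(profiles)) {
    p <- p +
      ggplot2::geom_pointrange(
        data = profiles,
        ggplot2::aes(x = .data$nu_cpmg_hz, y = .data$r2eff,
                     ymin = .data$r2eff - .data$r2eff_sigma,
                     ymax = .data$r2eff + .data$r2eff_sigma,
                     colour = factor(.data$field_mhz)),
        size = 0.2)
  }
  p
}

#' Plot model-free results along the sequence
#'
#' @param object A `model_free_fit`.
#' @param ... Unused.
#' @return A ggplot object: S2 (with Monte Carlo error bars) per residue,
#'   coloured by selected model.
#' @exportS3Method ggplot2::autoplot
autoplot.model_free_fit <- function(object, ...) {
  res <- filter(object$results, .data$status == "fitted")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$residue, y = .data$s2,
                                    fill = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$s2 - .data$s2_sigma,
                                        ymax = .data$s2 + .data$s2_sigma),
                           width = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::labs(x = "residue", y = expression(S^2), fill = "model") +
    ggplot2::theme_bw()
}

#' Plot the R2/R1 ratios behind a diffusion-tensor fit
#'
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed R2/R1 of the rigid subset vs residue,
#'   with the isotropic-fit level.
#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_fit <- function(object, ...) {
  iso_ratio <- .rigid_ratio(object$fits$isotropic$tau_m, 1, NULL, object$spin)
  ggplot2::ggplot(object$rigid,
                  ggplot2::aes(x = .data$residue, y = .data$r2_r1)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$r2_r1 - .data$r2_r1_sigma,
      ymax = .data$r2_r1 + .data$r2_r1_sigma)) +
    ggplot2::geom_hline(yintercept = iso_ratio, linetype = 2) +
    ggplot2::labs(x = "residue", y = expression(R[2] / R[1])) +
    ggplot2::theme_bw()
}

#' Bar plot of composite shift changes
#'
#' Residues missing at either endpoint are drawn as grey marker bars
#' rather than omitted.
#'
#' @param csp Output of [csp_between()].
#' @param missing_height Bar height used to mark missing residues.
#' @return A ggplot object.
#' @export
plot_csp <- function(csp, missing_height = NULL) {
  stopifnot(is.data.frame(csp))
  h <- missing_height %||% (0.5 * max(csp$d_comp, na.rm = TRUE))
  df <- csp |>
    mutate(missing = .data$missing_a | .data$missing_b,
           height = ifelse(.data$missing, h, .data$d_comp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$height,
                                   fill = .data$missing)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "grey70"),
                               labels = c("observed", "missing"),
                               name = NULL) +
    ggplot2::labs(x = "residue",
                  y = expression(Delta * delta[comp] ~ "(ppm)")) +
    ggplot2::theme_bw()
}
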