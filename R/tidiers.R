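# broom-style tidy()/glance() methods for the fitted objects.

#' @rdname model_free_analysis
#' @param x A `model_free_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.model_free_fit <- function(x, ...) x$results

#' @rdname model_free_analysis
#' @exportS3Method generics::glance
glance.model_free_fit <- function(x, ...) {
  res <- filter(x$results, .data$status == "fitted")
  tibble(
    n_residues = nrow(x$results),
    n_fitted = nrow(res),
    n_skipped = sum(x$results$status == "skipped"),
    mean_s2 = mean(res$s2),
    tensor_kind = x$tensor$kind,
    tau_m = x$tensor$tau_m,
    d_ratio = x$tensor$d_ratio,
    criterion = x$criterion,
    alpha = x$alpha
  )
}

#' @rdname fit_dispersion
#' @param x A `dispersion_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dispersion_fit <- function(x, ...) {
  x$dw |>
    left_join(x$dw_sigma, by = "residue") |>
    left_join(x$chisq_by_residue, by = "residue") |>
    left_join(pivot_wider(x$r20, names_from = "field_mhz",
                          values_from = "r20", names_prefix = "r20_"),
              by = "residue")
}

#' @rdname fit_dispersion
#' @exportS3Method generics::glance
glance.dispersion_fit <- function(x, ...) {
  tibble(
    kex = x$kex, kex_sigma = x$kex_sigma,
    papb = x$papb, papb_sigma = x$papb_sigma,
    pa = x$pa, pa_percent = 100 * x$pa,
    chisq = x$chisq, n_points = x$n_points,
    n_residues = nrow(x$dw), scope = x$scope,
    degenerate = x$degenerate
  )
}

#' @rdname estimate_diffusion
#' @param x A `diffusion_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.diffusion_fit <- function(x, ...) {
  kinds <- names(x$fits)
  tibble(
    kind = kinds,
    tau_m = vapply(x$fits, `[[`, numeric(1), "tau_m"),
    d_ratio = vapply(x$fits, `[[`, numeric(1), "d_ratio"),
    chisq = vapply(x$fits, `[[`, numeric(1), "chisq"),
    selected = kinds == x$tensor$kind
  )
}

#' @rdname estimate_diffusion
#' @exportS3Method generics::glance
glance.diffusion_fit <- function(x, ...) {
  tibble(
    kind = x$tensor$kind,
    tau_m = x$tensor$tau_m,
    d_ratio = x$tensor$d_ratio,
    n_rigid = nrow(x$rigid),
    chisq = x$fits[[x$tensor$kind]]$chisq,
    f_statistic = if (is.null(x$f_test)) NA_real_ else x$f_test$statistic,
    p_value = if (is.null(x$f_test)) NA_real_ else x$f_test$p_value
  )
}
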