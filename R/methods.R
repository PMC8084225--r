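#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname eaaforest-tidiers
tidy.eaa_result <- function(x, pooled = FALSE, ...) {
  if (pooled) pooled_results(x) else tibble::as_tibble(x)
}

#' Tidiers for EAA results and smooth fits
#'
#' `tidy()` on an `eaa_result` returns the per-replicate long table (or the
#' pooled table with `pooled = TRUE`); `glance()` summarizes each test and
#' interval: cell counts, the fraction of per-replicate |z| > 1.96, the
#' number of BH-significant cells and the mean z.  On an `eaa_smooth`,
#' `tidy()` returns the evaluation grid and `glance()` the fit summary.
#'
#' @param x An `eaa_result` or `eaa_smooth`.
#' @param pooled Return the pooled-null table instead (results only).
#' @param ... Unused.
#' @name eaaforest-tidiers
#' @export
glance.eaa_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$test, .data$interval) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_defined = sum(!is.na(.data$z)),
      frac_sig_z = mean(abs(.data$z) > 1.96, na.rm = TRUE),
      n_bh_significant = sum(.data$bh_significant, na.rm = TRUE),
      mean_z = mean(.data$z, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @export
#' @rdname eaaforest-tidiers
tidy.eaa_smooth <- function(x, ...) x$grid

#' @export
#' @rdname eaaforest-tidiers
glance.eaa_smooth <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, k_used = paste(x$k_used, collapse = "x"),
    edf = x$edf, method = x$method, n = nrow(x$data),
    r_squared = summary(x$model)$r.sq
  )
}
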