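#' Species-removal (subset) analysis
#'
#' Re-runs EAA tests with the focal and/or annular tree sets restricted by
#' species, the protocol used to attribute phylogenetic-distance anomalies
#' to individual species: a species kept as focal still appears as an
#' annular neighbor unless also dropped from the annular side, and vice
#' versa.  All quantile schemes are recomputed on the subset.
#'
#' @param plot,D,tests,config,intervals As in [run_eaa_test()].
#' @param focal_keep,annular_keep Character vectors of species codes to
#'   keep on each side (`NULL` = keep all).
#' @param focal_drop,annular_drop Alternatively, species to drop.
#' @return An `eaa_result`.
#' @export
subset_run <- function(plot, D, focal_keep = NULL, annular_keep = NULL,
                       focal_drop = NULL, annular_drop = NULL,
                       tests = 1:6, config = eaa_config(), intervals = NULL) {
  if (!is.null(focal_drop)) focal_keep <- setdiff(plot$species, focal_drop)
  if (!is.null(annular_drop)) annular_keep <- setdiff(plot$species, annular_drop)
  if (!is.null(focal_keep) && !any(plot$species %in% focal_keep)) {
    stop("focal set would be empty")
  }
  if (!is.null(annular_keep) && !any(plot$species %in% annular_keep)) {
    stop("annular set would be empty")
  }
  config$focal_keep <- focal_keep
  config$annular_keep <- annular_keep
  run_eaa_test(plot, D, tests = tests, config = config, intervals = intervals)
}

#' Compare two fitted curves (before/after an intervention)
#'
#' Pointwise difference of two curve fits on a common grid, with the
#' propagated 95% band, the grid regions where the band excludes zero,
#' and the extrema gained or lost between the fits.  Used after the
#' distance-manipulation and species-removal protocols.
#'
#' @param fit_before,fit_after `eaa_smooth` curve fits on the same grid.
#' @return A list of class `eaa_curve_comparison`: `grid` (x, diff, se,
#'   lower, upper, significant), `regions` (start/end x of runs where the
#'   difference band excludes 0), `extrema_before`, `extrema_after`.
#' @export
compare_curves <- function(fit_before, fit_after) {
  stopifnot(inherits(fit_before, "eaa_smooth"), inherits(fit_after, "eaa_smooth"),
            fit_before$kind == "curve", fit_after$kind == "curve")
  gb <- fit_before$grid; ga <- fit_after$grid
  if (nrow(gb) != nrow(ga) || max(abs(gb$x - ga$x)) > 1e-8) {
    stop("curve grids do not match")
  }
  d <- ga$fit - gb$fit
  se <- sqrt(ga$se^2 + gb$se^2)
  lower <- d - 1.96 * se
  upper <- d + 1.96 * se
  sig <- lower > 0 | upper < 0
  grid <- tibble::tibble(x = gb$x, diff = d, se = se,
                         lower = lower, upper = upper, significant = sig)
  ## contiguous significant runs
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  regions <- tibble::tibble(
    x_start = gb$x[starts[keep]], x_end = gb$x[ends[keep]],
    sign = vapply(keep, function(k) {
      if (mean(d[starts[k]:ends[k]]) > 0) "positive" else "negative"
    }, "")
  )
  structure(
    list(grid = grid, regions = regions,
         extrema_before = locate_extrema(fit_before),
         extrema_after = locate_extrema(fit_after)),
    class = "eaa_curve_comparison"
  )
}

#' @export
print.eaa_curve_comparison <- function(x, ...) {
  cat(sprintf("<eaa_curve_comparison> %d grid points, %d significant region(s)\n",
              nrow(x$grid), nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}
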