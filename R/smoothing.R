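#' Penalized-spline smooth of z-values along phylogenetic distance
#'
#' Fits `y ~ s(x, k)` with a cubic regression spline (penalized, smoothing
#' parameter by REML by default) and evaluates the fit with a pointwise 95%
#' band on a regular grid.  Grid points whose fitted value lies inside the
#' null z band `[-1.96, 1.96]` are masked as non-significant (gray in the
#' plots); values outside it are colored.
#'
#' @param x Predictor (phylogenetic distance, Ma).
#' @param y Response (z-values).
#' @param k Basis dimension; chosen by [choose_k()] when `NULL`.
#' @param method Smoothing-parameter criterion, `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @param n_grid Number of grid points (default 100).
#' @return An object of class `eaa_smooth`: list with `grid` (tibble of
#'   `x`, `fit`, `se`, `lower`, `upper`, `significant`), `k_used`, `edf`,
#'   `model` (the `mgcv::gam` fit) and the data points.
#' @export
fit_curve <- function(x, y, k = NULL, method = "REML", n_grid = 100) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(k)) k <- choose_k(x, y)
  if (k < 3) stop("k must be >= 3")
  if (length(x) < k + 2) stop("need at least k + 2 points")
  dat <- data.frame(x = x, y = y)
  fit <- gam_safe(y ~ s(x, k = k, bs = "cr"), dat, method)
  gx <- seq(min(x), max(x), length.out = n_grid)
  pr <- mgcv::predict.gam(fit, newdata = data.frame(x = gx), se.fit = TRUE)
  grid <- tibble::tibble(
    x = gx, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
    lower = .data$fit - 1.96 * .data$se, upper = .data$fit + 1.96 * .data$se,
    significant = abs(.data$fit) > 1.96
  )
  structure(
    list(grid = grid, k_used = k, edf = sum(fit$edf), method = method,
         model = fit, data = dat, kind = "curve"),
    class = "eaa_smooth"
  )
}

## REML can fail on degenerate (noise-free) responses; fall back to GCV and
## then to an unpenalized fit
gam_safe <- function(formula, dat, method) {
  fit <- try(mgcv::gam(formula, data = dat, method = method), silent = TRUE)
  if (inherits(fit, "try-error")) {
    fit <- try(mgcv::gam(formula, data = dat, method = "GCV.Cp"), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    fit <- mgcv::gam(formula, data = dat, sp = 0)
  }
  fit
}

#' Basis-dimension selection for the smooths
#'
#' Chooses the smallest candidate `k` whose basis passes the usual
#' adequacy diagnostics: effective degrees of freedom comfortably below
#' the basis dimension (`edf < 0.9 (k - 1)`) and no residual pattern
#' against the predictor (the randomization test of `mgcv::k.check` with
#' p > 0.05).  If no candidate passes, the largest is returned with a
#' warning.  The randomization inside the diagnostic runs under a fixed
#' local seed, so the choice is deterministic for given data.
#'
#' @param x,y Data.
#' @param k_grid Candidate basis dimensions (default `4:min(20, n - 2)`).
#' @return The selected `k`.
#' @export
choose_k <- function(x, y, k_grid = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n_ux <- length(unique(x))
  k_grid <- k_grid %||% seq(4L, max(4L, min(20L, n_ux - 1L, length(x) - 2L)))
  dat <- data.frame(x = x, y = y)
  old <- local_seed(271828L)
  on.exit(restore_seed(old))
  for (k in k_grid) {
    if (length(x) < k + 2 || n_ux <= k) next
    fit <- try(mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat, method = "REML"),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    edf <- sum(fit$edf) - 1
    kc <- try(mgcv::k.check(fit, subsample = 5000, n.rep = 200), silent = TRUE)
    pval <- if (inherits(kc, "try-error") || is.null(dim(kc))) 1 else kc[1, "p-value"]
    if (edf < 0.9 * (k - 1) && (is.na(pval) || pval > 0.05)) return(k)
  }
  warning("no candidate k passed the basis diagnostics; using the largest")
  max(k_grid)
}

#' Tensor-product smooth of z over physical and phylogenetic distance
#'
#' Fits `z ~ te(physical, phylo)` with cubic regression spline marginals to
#' the per-cell z-values of all annuli and phylogenetic bins, evaluated on
#' a full factorial grid.  The physical coordinate of an annulus is its
#' area-weighted mean radius.  Same band and significance-mask semantics
#' as [fit_curve()].
#'
#' @param physical Physical distance (m) per point (annulus mean radius).
#' @param phylo Phylogenetic distance (Ma) per point.
#' @param z z-values.
#' @param k Length-2 basis dimensions for the marginals (default `c(5, 8)`,
#'   capped by the number of distinct values).
#' @param method Smoothing-parameter criterion.
#' @param n_grid Grid resolution per axis (physical axis uses the annulus
#'   midpoints themselves).
#' @return An `eaa_smooth` with `kind = "surface"`; `grid` has columns
#'   `physical`, `phylo`, `fit`, `se`, `lower`, `upper`, `significant`.
#' @export
fit_surface <- function(physical, phylo, z, k = c(5, 8), method = "REML",
                        n_grid = 60) {
  ok <- is.finite(physical) & is.finite(phylo) & is.finite(z)
  physical <- physical[ok]; phylo <- phylo[ok]; z <- z[ok]
  if (length(unique(physical)) < 2) stop("need at least 2 annuli")
  if (length(unique(phylo)) < 3) stop("need at least 3 phylogenetic bins")
  k <- c(min(k[1], length(unique(physical))), min(k[2], length(unique(phylo))))
  if (any(k < 2)) stop("not enough distinct values for a surface")
  dat <- data.frame(px = physical, py = phylo, z = z)
  fit <- gam_safe(z ~ te(px, py, k = k, bs = "cr"), dat, method)
  gpx <- sort(unique(physical))
  gpy <- seq(min(phylo), max(phylo), length.out = n_grid)
  grid <- expand.grid(px = gpx, py = gpy)
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE)
  grid <- tibble::tibble(
    physical = grid$px, phylo = grid$py,
    fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
    lower = .data$fit - 1.96 * .data$se, upper = .data$fit + 1.96 * .data$se,
    significant = abs(.data$fit) > 1.96
  )
  structure(
    list(grid = grid, k_used = k, edf = sum(fit$edf), method = method,
         model = fit, data = dat, kind = "surface"),
    class = "eaa_smooth"
  )
}

#' @export
print.eaa_smooth <- function(x, ...) {
  cat(sprintf("<eaa_smooth> %s, k = %s, edf = %.2f, %d grid points\n",
              x$kind, paste(x$k_used, collapse = "x"), x$edf, nrow(x$grid)))
  invisible(x)
}

#' Peaks and valleys of a fitted curve
#'
#' Local extrema of the fitted function whose 95% band excludes the fitted
#' values at the neighboring shoulders (the nearest local extremum of the
#' opposite sense, or the curve end, on each side); these are the localized
#' exceptions to a smooth phylogenetic-distance decline.  Ranked by
#' absolute depth/height.
#'
#' @param curve An `eaa_smooth` curve fit.
#' @return A tibble with `type` (`"peak"`/`"valley"`), `x`, `value`,
#'   `depth` (signed offset from the higher/lower shoulder).
#' @export
locate_extrema <- function(curve) {
  stopifnot(inherits(curve, "eaa_smooth"), curve$kind == "curve")
  g <- curve$grid
  n <- nrow(g)
  f <- g$fit
  d <- sign(diff(f))
  ## indices of interior local maxima / minima of the fitted grid
  turn <- which(d[-1] != d[-(n - 1)] & d[-(n - 1)] != 0) + 1L
  out <- list()
  for (i in turn) {
    is_peak <- f[i] > f[i - 1]
    ## shoulders: nearest turning point (or end) on each side
    left <- c(1L, turn[turn < i])
    right <- c(turn[turn > i], n)
    l <- max(left); r <- min(right)
    if (is_peak) {
      shoulder <- max(f[l], f[r])
      keep <- g$lower[i] > shoulder
      depth <- f[i] - shoulder
    } else {
      shoulder <- min(f[l], f[r])
      keep <- g$upper[i] < shoulder
      depth <- f[i] - shoulder
    }
    if (keep) {
      out[[length(out) + 1L]] <- tibble::tibble(
        type = if (is_peak) "peak" else "valley",
        x = g$x[i], value = f[i], depth = depth
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(type = character(), x = numeric(),
                          value = numeric(), depth = numeric()))
  }
  res <- dplyr::bind_rows(out)
  res[order(-abs(res$depth)), ]
}

#' Fit the standard 2D curve or 3D surface to an EAA result
#'
#' Convenience wrappers pooling the per-replicate z points of one test (and
#' optionally one group/variant/interval) and fitting [fit_curve()] along
#' phylogenetic distance for a single annulus, or [fit_surface()] over
#' (annulus mean radius x phylogenetic distance).
#'
#' @param result An `eaa_result`.
#' @param test Test id.
#' @param annulus Annulus for the 2D curve (default 1).
#' @param group,variant,interval Optional filters (defaults: all groups of
#'   the test's first variant, all intervals).
#' @param ... Passed to the fitting function.
#' @return An `eaa_smooth`.
#' @export
fit_result_curve <- function(result, test, annulus = 1, group = NULL,
                             variant = NULL, interval = NULL, ...) {
  df <- filter_result(result, test, group, variant, interval)
  df <- df[df$annulus == annulus, ]
  fit_curve(df$phylo_ma, df$z, ...)
}

#' @rdname fit_result_curve
#' @export
fit_result_surface <- function(result, test, group = NULL, variant = NULL,
                               interval = NULL, ...) {
  df <- filter_result(result, test, group, variant, interval)
  cfg <- attr(result, "config")
  mids <- annulus_midpoints(build_annulus_system(cfg$total_area, cfg$n_annuli))
  fit_surface(mids[df$annulus], df$phylo_ma, df$z, ...)
}

filter_result <- function(result, test, group, variant, interval) {
  df <- tibble::as_tibble(result)
  df <- df[df$test == test & !is.na(df$z), ]
  if (!is.null(variant)) df <- df[df$variant %in% variant, ]
  if (!is.null(group)) df <- df[df$group %in% group, ]
  if (!is.null(interval)) df <- df[df$interval %in% interval, ]
  if (nrow(df) == 0) stop("no usable z-values after filtering")
  df
}
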