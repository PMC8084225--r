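#' Equal-area annulus systems
#'
#' Constructs `n_annuli` concentric rings around a focal point such that
#' every ring has exactly the same area `total_area / n_annuli`.  The closed
#' form for the ring boundaries is `r_k = sqrt(k * total_area / (n_annuli * pi))`,
#' so each distance band carries the same expected number of neighbors under
#' spatial randomness and therefore the same statistical power.
#'
#' @param total_area Total area covered by all annuli, m^2 (default 500, the
#'   standard neighborhood size used across forest dynamics plots).
#' @param n_annuli Number of annuli (typically 5-20 depending on stem
#'   density).
#' @return An object of class `annulus_system`: list with `radii`
#'   (length `n_annuli + 1`, starting at 0), `n_annuli`, `total_area`,
#'   `ring_area`.
#' @examples
#' sys <- build_annulus_system(500, 10)
#' sys$radii[11]^2 * pi # 500
#' @export
build_annulus_system <- function(total_area = 500, n_annuli = 10) {
  if (!is.numeric(total_area) || total_area <= 0) stop("total_area must be > 0")
  if (!is.numeric(n_annuli) || n_annuli < 1 || n_annuli != round(n_annuli)) {
    stop("n_annuli must be a positive integer")
  }
  n_annuli <- as.integer(n_annuli)
  radii <- sqrt(seq(0L, n_annuli) * total_area / (n_annuli * pi))
  structure(
    list(
      radii = radii, n_annuli = n_annuli,
      total_area = as.numeric(total_area),
      ring_area = total_area / n_annuli
    ),
    class = "annulus_system"
  )
}

#' @export
print.annulus_system <- function(x, ...) {
  cat(sprintf("<annulus_system> %d rings of %.6g m2 each, outer radius %.4f m\n",
              x$n_annuli, x$ring_area, max(x$radii)))
  invisible(x)
}

#' Mean radius of each annulus (area-weighted)
#'
#' The continuous physical-distance coordinate assigned to an annulus for
#' surface fitting: the area-weighted mean radius
#' `(2/3) (r_k^3 - r_{k-1}^3) / (r_k^2 - r_{k-1}^2)`.
#'
#' @param system An [build_annulus_system()] object.
#' @return Numeric vector of length `n_annuli`, in m.
#' @export
annulus_midpoints <- function(system) {
  r0 <- system$radii[-length(system$radii)]
  r1 <- system$radii[-1]
  (2 / 3) * (r1^3 - r0^3) / (r1^2 - r0^2)
}

#' Annulus membership of a neighbor
#'
#' Returns the 1-based index `k` of the annulus with `r_{k-1} <= d < r_k`
#' for the Euclidean distance `d` between focal and neighbor; distance 0
#' (a co-located stem of a different tree) falls in annulus 1, and any
#' `d >= r_n` returns `NA` (outside the neighborhood).
#'
#' @param focal_xy,neighbor_xy Length-2 numeric vectors (m), or two-column
#'   matrices of points.
#' @param system An [build_annulus_system()] object.
#' @return Integer annulus index (vector), `NA` for outside.
#' @export
annulus_index <- function(focal_xy, neighbor_xy, system) {
  f <- matrix(focal_xy, ncol = 2)
  nb <- matrix(neighbor_xy, ncol = 2)
  d <- sqrt((f[, 1] - nb[, 1])^2 + (f[, 2] - nb[, 2])^2)
  annulus_of_distance(d, system)
}

annulus_of_distance <- function(d, system) {
  k <- findInterval(d, system$radii)
  k[k > system$n_annuli] <- NA_integer_
  as.integer(k)
}

#' Fraction of a ring lying inside the plot
#'
#' Exact area of the intersection of an annulus (centered on a focal tree)
#' with the plot rectangle, as a fraction of the ring area.  Computed by
#' piecewise adaptive quadrature of the circle-rectangle chord length with
#' breakpoints at the tangency abscissae, which is exact to well below the
#' 1e-3 tolerance used throughout.
#'
#' @param focal_xy Length-2 numeric (m); must lie inside the plot.
#' @param ring Length-2 numeric `c(r_inner, r_outer)` in m, or an annulus
#'   index together with `system`.
#' @param plot_rect Length-2 numeric `c(width, height)` of the plot (m).
#' @param system Optional [build_annulus_system()] used when `ring` is an
#'   index.
#' @return Fraction in (0, 1].
#' @export
edge_fraction <- function(focal_xy, ring, plot_rect, system = NULL) {
  W <- plot_rect[1]; H <- plot_rect[2]
  cx <- focal_xy[1]; cy <- focal_xy[2]
  if (cx < 0 || cx >= W || cy < 0 || cy >= H) stop("focal point outside plot")
  if (length(ring) == 1) {
    stopifnot(!is.null(system))
    ring <- system$radii[c(ring, ring + 1)]
  }
  r0 <- ring[1]; r1 <- ring[2]
  stopifnot(r1 > r0, r0 >= 0)
  a1 <- disc_rect_area(cx, cy, r1, W, H)
  a0 <- if (r0 > 0) disc_rect_area(cx, cy, r0, W, H) else 0
  (a1 - a0) / (pi * (r1^2 - r0^2))
}

## exact area of disc(center (cx,cy), radius r) intersected with [0,W]x[0,H]
disc_rect_area <- function(cx, cy, r, W, H) {
  if (r <= 0) return(0)
  ## fast path: disc entirely inside
  if (cx - r >= 0 && cx + r <= W && cy - r >= 0 && cy + r <= H) return(pi * r^2)
  xlo <- max(0, cx - r); xhi <- min(W, cx + r)
  if (xhi <= xlo) return(0)
  ## breakpoints where the chord endpoints cross y = 0 or y = H
  br <- c(xlo, xhi)
  for (y0 in c(0, H)) {
    dy <- y0 - cy
    if (abs(dy) < r) {
      s <- sqrt(r^2 - dy^2)
      br <- c(br, cx - s, cx + s)
    }
  }
  br <- sort(unique(pmin(pmax(br, xlo), xhi)))
  chord <- function(x) {
    s <- sqrt(pmax(0, r^2 - (x - cx)^2))
    pmax(0, pmin(H, cy + s) - pmax(0, cy - s))
  }
  total <- 0
  for (i in seq_len(length(br) - 1)) {
    if (br[i + 1] - br[i] < 1e-12) next
    total <- total + stats::integrate(chord, br[i], br[i + 1],
                                      rel.tol = 1e-10, abs.tol = 1e-10,
                                      subdivisions = 200L)$value
  }
  total
}

## fraction-inside matrix for many focal points x all annuli of a system;
## interior trees short-circuit to 1
edge_fraction_matrix <- function(x, y, system, W, H) {
  n <- length(x)
  k <- system$n_annuli
  rmax <- max(system$radii)
  out <- matrix(1, n, k)
  near <- which(x < rmax | x > W - rmax | y < rmax | y > H - rmax)
  for (i in near) {
    areas <- vapply(system$radii, function(r) disc_rect_area(x[i], y[i], r, W, H), 0)
    fr <- diff(areas) / (pi * diff(system$radii^2))
    out[i, ] <- fr
  }
  out
}

#' Edge-correction weights
#'
#' Inverse-area weights `1 / fraction_inside` for every focal tree and
#' annulus; counts and summed basal areas of neighbors are multiplied by
#' the weight of their annulus so that trees near the plot boundary are
#' not biased low.  With `mode = "drop"`, focal trees whose outermost ring
#' has `fraction_inside < drop_threshold` get weight `NA` (excluded).
#'
#' @param x,y Focal coordinates (m).
#' @param system An [build_annulus_system()].
#' @param width,height Plot dimensions (m).
#' @param mode `"weight"` (default) or `"drop"`.
#' @param drop_threshold Minimum outermost-ring fraction kept under
#'   `"drop"` (default 0.5).
#' @return Numeric matrix, trees x annuli.
#' @export
edge_weights <- function(x, y, system, width, height,
                         mode = c("weight", "drop"), drop_threshold = 0.5) {
  mode <- match.arg(mode)
  fr <- edge_fraction_matrix(x, y, system, width, height)
  w <- 1 / fr
  if (mode == "drop") {
    dropped <- fr[, system$n_annuli] < drop_threshold
    w[] <- 1
    w[dropped, ] <- NA_real_
  }
  w
}
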