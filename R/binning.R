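#' Basal area of a tree
#'
#' Sum of the cross-sectional stem areas at breast height (1.3 m):
#' `sum(pi * (d/2)^2)` over all stems, in cm^2.  Multi-stemmed trees are
#' summed; an empty stem list gives 0.
#'
#' @param stem_dbhs Numeric vector of stem diameters (cm).
#' @return Basal area in cm^2.
#' @examples
#' basal_area(2)      # pi
#' basal_area(c(1, 1)) # pi / 2
#' @export
basal_area <- function(stem_dbhs) {
  if (any(stem_dbhs < 0)) stop("negative dbh")
  sum(pi * (stem_dbhs / 2)^2)
}

## Equal-count bin assignment within a single vector.
## ties = "stable": ties broken by input order (deterministic);
## ties = "random": ties permuted by the current RNG stream, so tied values
## can land in adjacent bins differently across replicates.
## Values are assigned by sorted position: bin sizes differ by at most 1.
quantile_bins <- function(values, n_bins, ties = c("stable", "random")) {
  ties <- match.arg(ties)
  n <- length(values)
  if (n == 0) return(integer(0))
  if (n < n_bins) {
    ## rank-based fallback: ties share the lower bin
    r <- match(values, sort(unique(values)))
    return(as.integer(r))
  }
  tb <- if (ties == "random") stats::runif(n) else seq_len(n)
  ord <- order(values, tb)
  bin <- integer(n)
  bin[ord] <- as.integer(ceiling(seq_len(n) * n_bins / n))
  bin
}

#' Focal-tree size quantiles
#'
#' Divides the diameters of the focal trees of each species, at the start
#' of a census period, into `n_bins` equal-count classes (quartiles by
#' default).  Quantiles are always computed within species, never pooled
#' across them; species with fewer trees than bins are assigned by rank
#' with ties sharing the lower bin.
#'
#' @param plot An [fdp_census()] object.
#' @param census Census index at which sizes are taken (interval start).
#' @param n_bins Number of size classes (default 4).
#' @param focal Optional logical/integer vector selecting the focal rows
#'   (defaults to all trees measurable at `census`).
#' @return A tibble with `.idx`, `tree_id`, `species`, `dbh`, `size_bin`.
#' @export
focal_size_quartiles <- function(plot, census, n_bins = 4, focal = NULL) {
  st <- census_state(plot, census)
  if (is.null(focal)) focal <- st$status %in% c("recruit", "alive")
  st <- st[focal, , drop = FALSE]
  st |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(size_bin = quantile_bins(.data$dbh, n_bins)) |>
    dplyr::ungroup() |>
    dplyr::select(".idx", "tree_id", "species", "dbh", "size_bin")
}

#' Annular-biomass quintiles
#'
#' Divides focal-tree-level summed annular basal areas into `n_bins`
#' equal-count classes (quintiles by default).  Ties are broken by the
#' current RNG stream, so a set of identical sums is spread uniformly
#' across bins under the replicate seed.
#'
#' @param sums Numeric vector of summed annular basal areas (cm^2).
#' @param n_bins Number of classes (default 5).
#' @return Integer vector of bin indices.
#' @export
annular_biomass_quintiles <- function(sums, n_bins = 5) {
  quantile_bins(sums, n_bins, ties = "random")
}

#' Phylogenetic-distance quantiles over species pairs
#'
#' Orders all unordered species pairs (conspecific pairs included at 0 Ma)
#' by divergence time and cuts them into `q` equal-count bins.  Pairs that
#' share the same distance are permuted by the current RNG stream before
#' cutting, so tied pairs spanning a bin boundary land in adjacent bins in
#' different replicates -- rerunning with fresh tie shuffles is how the
#' analysis averages over this arbitrary choice.  Conspecific (0 Ma) pairs
#' are anchored in bin 1 and never shuffled across the first boundary.
#'
#' @param D Symmetric species distance matrix (Ma), zero diagonal.
#' @param q Number of quantile bins (>= 2; at most the number of pairs).
#' @return A tibble with `sp_a`, `sp_b` (sorted within pair), `distance`
#'   (Ma) and `bin`.
#' @export
phylo_quantiles <- function(D, q) {
  check_phylo_distances(D)
  sp <- rownames(D)
  S <- length(sp)
  idx <- which(upper.tri(D, diag = TRUE), arr.ind = TRUE)
  pairs <- tibble::tibble(
    sp_a = sp[pmin(idx[, 1], idx[, 2])],
    sp_b = sp[pmax(idx[, 1], idx[, 2])],
    distance = D[idx]
  )
  P <- nrow(pairs)
  if (q < 2) stop("q must be >= 2")
  if (q > P) stop("q exceeds the number of species pairs")
  bin <- quantile_bins(pairs$distance, q, ties = "random")
  bin[pairs$distance == 0] <- 1L
  pairs$bin <- bin
  pairs
}

## bin -> representative Ma (mean pair distance per bin), used as the
## phylogenetic plotting coordinate
phylo_bin_midpoints <- function(pairs, q) {
  out <- rep(NA_real_, q)
  agg <- tapply(pairs$distance, pairs$bin, mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Normalized focal-tree growth rates
#'
#' Raw growth is the dbh change (cm) of focal survivors -- trees present at
#' both ends of a census interval -- over that interval.  Rates are then
#' standardized to mean 0, SD 1 within strata of species x census x
#' start-diameter decile, removing the confounding of tree size, species
#' and secular trends.  Strata of size 1 or zero spread normalize to 0.
#' The number of diameter classes per species is reduced below 10 when a
#' species has fewer than 10 trees per class.
#'
#' @param plot An [fdp_census()] object.
#' @param interval Census interval index (interval `j` spans censuses `j`
#'   to `j + 1`).
#' @param n_deciles Nominal number of diameter classes (default 10).
#' @return A tibble with `.idx`, `tree_id`, `species`, `dbh_start`, `raw`,
#'   `normalized`, `stratum`.
#' @export
normalized_growth <- function(plot, interval, n_deciles = 10) {
  stopifnot(interval >= 1, interval + 1 <= plot$n_censuses)
  s0 <- census_state(plot, interval)
  s1 <- census_state(plot, interval + 1)
  surv <- s0$status %in% c("recruit", "alive") & s1$status == "alive"
  out <- tibble::tibble(
    .idx = s0$.idx[surv],
    tree_id = s0$tree_id[surv],
    species = s0$species[surv],
    dbh_start = s0$dbh[surv],
    raw = s1$dbh[surv] - s0$dbh[surv]
  )
  out |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(
      stratum = quantile_bins(.data$dbh_start,
                              max(1L, min(n_deciles, dplyr::n() %/% 10L)))
    ) |>
    dplyr::group_by(.data$species, .data$stratum) |>
    dplyr::mutate(
      normalized = {
        m <- mean(.data$raw); s <- stats::sd(.data$raw)
        if (dplyr::n() < 2 || !is.finite(s) || s < 1e-12) {
          rep(0, dplyr::n())
        } else {
          (.data$raw - m) / s
        }
      }
    ) |>
    dplyr::ungroup()
}

#' Small/large split of trees that died
#'
#' Annular trees of each species that died during an interval are divided
#' into two equal-sized groups, small and large, by a per-species median
#' split on their last recorded dbh; with an odd count the median tree
#' goes to the small group.
#'
#' @param plot An [fdp_census()] object.
#' @param interval Census interval index.
#' @return A tibble with `.idx`, `tree_id`, `species`, `dbh`, `size_class`
#'   (`"small"`/`"large"`).
#' @export
split_dead_small_large <- function(plot, interval) {
  stopifnot(interval >= 1, interval + 1 <= plot$n_censuses)
  s0 <- census_state(plot, interval)
  s1 <- census_state(plot, interval + 1)
  died <- s0$status %in% c("recruit", "alive") & s1$status == "dead"
  out <- tibble::tibble(
    .idx = s0$.idx[died],
    tree_id = s0$tree_id[died],
    species = s0$species[died],
    dbh = s0$dbh[died]
  )
  out |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(size_class = {
      n <- dplyr::n()
      cls <- character(n)
      ord <- order(.data$dbh, seq_len(n))
      n_small <- ceiling(n / 2)
      cls[ord] <- rep(c("small", "large"), c(n_small, n - n_small))
      cls
    }) |>
    dplyr::ungroup()
}
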