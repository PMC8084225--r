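#' Analysis configuration
#'
#' Collects the tunable parameters of an EAA run.  Defaults follow the
#' standard design: 500 m^2 of neighborhood split into 10 equal-area
#' annuli, focal sizes in quartiles, annular biomass in quintiles, and
#' ten tie-shuffle replicates of 100 null iterations each (1,000 null
#' iterations in total).
#'
#' @param n_annuli Number of equal-area annuli (5-20 typical).
#' @param total_area Total annulus area per focal tree, m^2.
#' @param n_phylo_bins Number of phylogenetic-distance quantiles (5-20).
#' @param n_size_bins Focal-size quantiles for Tests 1-3 (default 4).
#' @param n_biomass_bins Annular-biomass quantiles for Test 4 (default 5).
#' @param replicates Tie-shuffle replicates (default 10).
#' @param iterations Null-model iterations per replicate (default 100).
#' @param alpha Benjamini-Hochberg level (default 0.05).
#' @param edge_mode `"weight"` (inverse-area weighting, default) or
#'   `"drop"` (exclude focal trees whose outermost ring fraction is below
#'   `drop_threshold`).
#' @param drop_threshold See `edge_mode`.
#' @param seed Seed for the null-model permutation stream.
#' @param tie_seed Seed for the tie-shuffle stream (quantile tie breaks and
#'   phylo-bin shuffles); defaults to `seed`.  Changing only `tie_seed`
#'   perturbs results within Monte Carlo error.
#' @param focal_keep,annular_keep Optional character vectors of species
#'   codes: restrict the focal and/or annular tree sets (species-removal
#'   protocol).  A species removed as focal still counts as an annular
#'   neighbor unless also removed from `annular_keep`, and vice versa.
#' @return A list of class `eaa_config`.
#' @export
eaa_config <- function(n_annuli = 10, total_area = 500, n_phylo_bins = 8,
                       n_size_bins = 4, n_biomass_bins = 5,
                       replicates = 10, iterations = 100, alpha = 0.05,
                       edge_mode = c("weight", "drop"), drop_threshold = 0.5,
                       seed = 1L, tie_seed = NULL,
                       focal_keep = NULL, annular_keep = NULL) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(replicates >= 1, iterations >= 2, alpha > 0, alpha < 1)
  structure(
    list(
      n_annuli = as.integer(n_annuli), total_area = total_area,
      n_phylo_bins = as.integer(n_phylo_bins),
      n_size_bins = as.integer(n_size_bins),
      n_biomass_bins = as.integer(n_biomass_bins),
      replicates = as.integer(replicates), iterations = as.integer(iterations),
      alpha = alpha, edge_mode = edge_mode, drop_threshold = drop_threshold,
      seed = as.integer(seed),
      tie_seed = as.integer(tie_seed %||% seed),
      focal_keep = focal_keep, annular_keep = annular_keep
    ),
    class = "eaa_config"
  )
}

## all neighbor pairs within rmax via a uniform grid (cell size rmax);
## returns i (focal), j (neighbor), d
neighbor_pairs <- function(x, y, rmax) {
  n <- length(x)
  cx <- floor(x / rmax); cy <- floor(y / rmax)
  key <- function(a, b) paste(a, b)
  pts <- tibble::tibble(j = seq_len(n), xx = x, yy = y, cx = cx, cy = cy)
  acc <- vector("list", 9)
  m <- 0
  for (dx in -1:1) {
    for (dy in -1:1) {
      m <- m + 1
      lhs <- tibble::tibble(i = pts$j, fx = pts$xx, fy = pts$yy,
                            k = key(pts$cx + dx, pts$cy + dy))
      rhs <- tibble::tibble(j = pts$j, xx = pts$xx, yy = pts$yy,
                            k = key(pts$cx, pts$cy))
      acc[[m]] <- dplyr::inner_join(lhs, rhs, by = "k", relationship = "many-to-many")
    }
  }
  cand <- dplyr::bind_rows(acc)
  d2 <- (cand$fx - cand$xx)^2 + (cand$fy - cand$yy)^2
  keep <- d2 < rmax^2 & cand$i != cand$j
  tibble::tibble(i = cand$i[keep], j = cand$j[keep], d = sqrt(d2[keep]))
}

## Heavy per-interval preparation shared by all replicates: the focal
## universe (every tree present at interval start or end, with survival /
## recruitment / death flags, size bins, normalized growth), the neighbor
## pair list with annulus indices and edge weights, and species codes.
prepare_interval <- function(plot, D, interval, config) {
  system <- build_annulus_system(config$total_area, config$n_annuli)
  static <- plot$n_censuses == 1
  j0 <- if (static) 1L else interval
  j1 <- if (static) 1L else interval + 1L
  stopifnot(j1 <= plot$n_censuses)
  if (!all(plot$species %in% rownames(D))) {
    stop("phylogenetic distances missing for species: ",
         paste(setdiff(plot$species, rownames(D)), collapse = ", "))
  }
  s0 <- census_state(plot, j0)
  s1 <- census_state(plot, j1)
  alive0 <- s0$status %in% c("recruit", "alive")
  alive1 <- s1$status %in% c("recruit", "alive")
  present <- alive0 | alive1
  f <- tibble::tibble(
    .idx = s0$.idx[present],
    tree_id = s0$tree_id[present],
    species = s0$species[present],
    x = s0$x[present], y = s0$y[present],
    dbh0 = s0$dbh[present], ba0 = s0$ba[present],
    alive0 = alive0[present], alive1 = alive1[present]
  )
  f$surv <- f$alive0 & f$alive1
  f$recruit <- !static & s1$status[present] == "recruit"
  f$dead <- f$alive0 & !f$alive1

  if (!is.null(config$focal_keep)) {
    keep_f <- f$species %in% config$focal_keep
    if (!any(keep_f)) stop("focal_keep empties the focal set")
  } else {
    keep_f <- rep(TRUE, nrow(f))
  }

  ## small/large split of the dead (per species, median on last dbh)
  f$dead_class <- NA_character_
  if (any(f$dead)) {
    dd <- f[f$dead, ]
    dd <- dd |>
      dplyr::group_by(.data$species) |>
      dplyr::mutate(size_class = {
        n <- dplyr::n()
        cls <- character(n)
        ord <- order(.data$dbh0, seq_len(n))
        ns <- ceiling(n / 2)
        cls[ord] <- rep(c("small", "large"), c(ns, n - ns))
        cls
      }) |>
      dplyr::ungroup()
    f$dead_class[f$dead] <- dd$size_class
  }

  ## size quartiles / quintiles among focal survivors, within species
  f$size_bin <- NA_integer_
  f$size_q5 <- NA_integer_
  sv <- which(f$surv & keep_f)
  if (length(sv)) {
    sp_sv <- f$species[sv]
    f$size_bin[sv] <- assign_within(f$dbh0[sv], sp_sv,
                                    function(v) quantile_bins(v, config$n_size_bins))
    f$size_q5[sv] <- assign_within(f$dbh0[sv], sp_sv, function(v) quantile_bins(v, 5))
  }

  ## normalized growth for survivors
  f$growth <- NA_real_
  if (!static && length(sv)) {
    g <- normalized_growth(plot, interval)
    m <- match(f$.idx, g$.idx)
    f$growth <- g$normalized[m]
  }

  ## neighbor pairs (focal x annular) within the outermost radius
  rmax <- max(system$radii)
  pr <- neighbor_pairs(f$x, f$y, rmax)
  pr$annulus <- annulus_of_distance(pr$d, system)
  pr <- pr[!is.na(pr$annulus), ]
  ## focal side restricted to kept focal species; annular side optionally
  pr <- pr[keep_f[pr$i], ]
  if (!is.null(config$annular_keep)) {
    keep_a <- f$species %in% config$annular_keep
    if (!any(keep_a)) stop("annular_keep empties the annular set")
    pr <- pr[keep_a[pr$j], ]
  }

  w <- edge_weights(f$x, f$y, system, plot$width, plot$height,
                    mode = config$edge_mode,
                    drop_threshold = config$drop_threshold)
  if (config$edge_mode == "drop") {
    dropped <- is.na(w[, 1])
    keep_f <- keep_f & !dropped
    pr <- pr[!dropped[pr$i], ]
    w[is.na(w)] <- 1
  }
  pr$w <- w[cbind(pr$i, pr$annulus)]

  sp_codes <- sort(unique(f$species))
  list(
    system = system, static = static, interval = interval,
    focal = f, keep_f = keep_f, pairs = pr,
    f_sp = match(f$species, sp_codes), sp_codes = sp_codes,
    surv_rows = sv
  )
}

assign_within <- function(values, block, fn) {
  out <- integer(length(values))
  for (ii in split(seq_along(values), block)) out[ii] <- fn(values[ii])
  out
}

#' Build the focal-annular neighborhood table
#'
#' For every focal tree, annulus and phylogenetic-distance quantile, the
#' edge-weighted summed basal area of annular survivors and the (weighted
#' and unweighted) counts of annular trees by fate: total present, recruits,
#' deaths (small/large), survivors.  The quantile assignment of species
#' pairs can be supplied (one tie-shuffle replicate) or is computed with
#' the current RNG stream.
#'
#' @param plot An [fdp_census()] object.
#' @param D Species distance matrix (Ma).
#' @param interval Census interval index.
#' @param config An [eaa_config()].
#' @param pair_bins Optional result of [phylo_quantiles()] for this `D`.
#' @return A list of class `eaa_neighborhood` carrying the focal table,
#'   the per-cell measure matrices, the annulus system and the bin map.
#' @export
build_neighborhood <- function(plot, D, interval = 1, config = eaa_config(),
                               pair_bins = NULL) {
  prep <- prepare_interval(plot, D, interval, config)
  if (is.null(pair_bins)) pair_bins <- phylo_quantiles(D, config$n_phylo_bins)
  nb <- bin_neighborhood(prep, D, pair_bins, config)
  structure(nb, class = "eaa_neighborhood")
}

## Turn the prepared interval + a pair->bin assignment into dense
## focal x cell measure matrices (cell = annulus x phylo bin).
bin_neighborhood <- function(prep, D, pair_bins, config) {
  f <- prep$focal
  pr <- prep$pairs
  Q <- config$n_phylo_bins
  K <- config$n_annuli
  C <- K * Q
  S <- length(prep$sp_codes)
  bm <- matrix(NA_integer_, S, S, dimnames = list(prep$sp_codes, prep$sp_codes))
  pb <- pair_bins[pair_bins$sp_a %in% prep$sp_codes & pair_bins$sp_b %in% prep$sp_codes, ]
  bm[cbind(pb$sp_a, pb$sp_b)] <- pb$bin
  bm[cbind(pb$sp_b, pb$sp_a)] <- pb$bin
  bin <- bm[cbind(prep$f_sp[pr$i], prep$f_sp[pr$j])]
  if (anyNA(bin)) stop("species pair missing from pair_bins")
  cell <- (pr$annulus - 1L) * Q + bin

  Fn <- nrow(f)
  lin <- pr$i + (cell - 1L) * Fn
  vals <- cbind(
    ba   = pr$w * ifelse(f$surv[pr$j], f$ba0[pr$j], 0),
    end  = pr$w * as.numeric(f$alive1[pr$j]),
    rec  = pr$w * as.numeric(f$recruit[pr$j]),
    a0   = pr$w * as.numeric(f$alive0[pr$j]),
    ds   = pr$w * as.numeric(f$dead[pr$j] & f$dead_class[pr$j] == "small"),
    dl   = pr$w * as.numeric(f$dead[pr$j] & f$dead_class[pr$j] == "large"),
    n    = as.numeric(f$alive0[pr$j] | f$alive1[pr$j]),
    nrec = as.numeric(f$recruit[pr$j]),
    nds  = as.numeric(f$dead[pr$j] & f$dead_class[pr$j] == "small"),
    ndl  = as.numeric(f$dead[pr$j] & f$dead_class[pr$j] == "large"),
    nsur = as.numeric(f$surv[pr$j])
  )
  vals[is.na(vals)] <- 0
  sums <- rowsum(vals, lin)
  pos <- as.integer(rownames(sums))
  M <- lapply(colnames(vals), function(cc) {
    m <- matrix(0, Fn, C)
    m[pos] <- sums[, cc]
    m
  })
  names(M) <- colnames(vals)
  list(
    focal = f, keep_f = prep$keep_f, surv_rows = prep$surv_rows,
    f_sp = prep$f_sp, sp_codes = prep$sp_codes,
    system = prep$system, static = prep$static, interval = prep$interval,
    n_phylo_bins = Q, n_annuli = K, n_cells = C,
    M = M, pair_bins = pair_bins,
    pr = tibble::tibble(i = pr$i, j = pr$j, cell = cell, w = pr$w),
    bin_ma = phylo_bin_midpoints(pair_bins, Q)
  )
}

#' Long-format view of a neighborhood table
#'
#' One row per non-empty (focal tree, annulus, phylogenetic bin) cell with
#' unweighted counts by annular fate and the edge-weighted summed survivor
#' basal area.  The counts partition: `n_recruits + n_dead_small +
#' n_dead_large + n_survivors = n_annular_total`.
#'
#' @param nb A [build_neighborhood()] object.
#' @return A tibble.
#' @export
neighborhood_table <- function(nb) {
  stopifnot(inherits(nb, "eaa_neighborhood"))
  Q <- nb$n_phylo_bins
  nz <- which(nb$M$n > 0)
  Fn <- nrow(nb$focal)
  fi <- (nz - 1L) %% Fn + 1L
  cell <- (nz - 1L) %/% Fn + 1L
  tibble::tibble(
    tree_id = nb$focal$tree_id[fi],
    species = nb$focal$species[fi],
    annulus = (cell - 1L) %/% Q + 1L,
    phylo_bin = (cell - 1L) %% Q + 1L,
    ba_weighted = nb$M$ba[nz],
    n_annular_total = nb$M$n[nz],
    n_recruits = nb$M$nrec[nz],
    n_dead_small = nb$M$nds[nz],
    n_dead_large = nb$M$ndl[nz],
    n_survivors = nb$M$nsur[nz]
  )
}

#' @export
print.eaa_neighborhood <- function(x, ...) {
  cat(sprintf(
    "<eaa_neighborhood> interval %d: %d focal trees, %d annuli x %d phylo bins\n",
    x$interval, sum(x$keep_f), x$n_annuli, x$n_phylo_bins
  ))
  invisible(x)
}
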