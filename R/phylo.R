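#' Pairwise phylogenetic distances from a Newick tree
#'
#' Converts a time-calibrated phylogeny into the symmetric species-by-species
#' matrix of divergence times: millions of years (Ma) back to the last common
#' ancestor of each species pair, zero on the diagonal (conspecifics).
#'
#' In `"strict_ultrametric"` mode the tree must be ultrametric (all leaf
#' depths equal to within a relative 1e-6); the distance is the depth of the
#' most recent common ancestor below the present.  In `"half_patristic"`
#' mode half the patristic (sum-of-branch-lengths) distance is used, which
#' coincides with the MRCA depth on ultrametric trees but is also defined
#' for non-ultrametric input.
#'
#' @param tree_text A Newick string, or an `ape::phylo` object.
#' @param mode `"strict_ultrametric"` (default) or `"half_patristic"`.
#' @return A symmetric numeric matrix in Ma with species dimnames.
#' @examples
#' D <- distances_from_newick("((A:10,B:10):90,C:100);")
#' D["A", "B"] # 10
#' D["A", "C"] # 100
#' @export
distances_from_newick <- function(tree_text, mode = c("strict_ultrametric", "half_patristic")) {
  mode <- match.arg(mode)
  tree <- if (inherits(tree_text, "phylo")) tree_text else ape::read.tree(text = tree_text)
  if (is.null(tree)) stop("could not parse Newick tree")
  n <- length(tree$tip.label)
  if (n == 1) {
    D <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(D)
  }
  if (mode == "strict_ultrametric") {
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    if (diff(range(depths)) > 1e-6 * max(depths)) {
      stop("tree is not ultrametric (leaf depths differ); use mode = \"half_patristic\"")
    }
  }
  D <- ape::cophenetic.phylo(tree) / 2
  D <- D[sort(rownames(D)), sort(colnames(D))]
  diag(D) <- 0
  D
}

check_phylo_distances <- function(D) {
  stopifnot(is.matrix(D), !is.null(rownames(D)), identical(rownames(D), colnames(D)))
  if (any(D < 0)) stop("negative phylogenetic distances")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("nonzero diagonal in distance matrix")
  invisible(D)
}

#' Genus-level distance sampling for unresolved species
#'
#' For species placed only to genus, a species-pair divergence within the
#' genus is not known; following the genus-level placement convention, the
#' within-genus distance for each such pair is drawn uniformly from the
#' interval from the present back to the genus' last common ancestor.
#' Cross-genus distances are taken from the genus-level matrix unchanged.
#'
#' @param D_genus Symmetric genus-by-genus matrix of LCA depths (Ma); the
#'   diagonal entry of a genus is its own crown (LCA) depth used as the
#'   sampling upper bound for within-genus pairs.
#' @param species_to_genus Named character vector mapping species code to
#'   genus; every species must be assigned.
#' @param resolved Character vector of species whose pairwise distances are
#'   fully resolved; pairs of resolved congeners keep the genus diagonal
#'   value instead of being sampled.  Default none.
#' @param seed Integer seed making the draws reproducible.
#' @return Symmetric species-by-species distance matrix (Ma).
#' @export
sample_genus_level_distances <- function(D_genus, species_to_genus, resolved = character(), seed = 1L) {
  stopifnot(is.matrix(D_genus), identical(rownames(D_genus), colnames(D_genus)))
  sp <- names(species_to_genus)
  if (is.null(sp) || anyNA(species_to_genus) || !all(species_to_genus %in% rownames(D_genus))) {
    stop("every species must be assigned to a genus present in D_genus")
  }
  withr_seed <- local_seed(seed)
  S <- length(sp)
  D <- matrix(0, S, S, dimnames = list(sp, sp))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j <= i) next
      gi <- species_to_genus[[i]]; gj <- species_to_genus[[j]]
      if (gi != gj) {
        D[i, j] <- D[j, i] <- D_genus[gi, gj]
      } else {
        depth <- D_genus[gi, gi]
        d <- if (all(c(sp[i], sp[j]) %in% resolved)) depth else stats::runif(1, 0, depth)
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  restore_seed(withr_seed)
  D
}

#' Set selected species-pair distances (sensitivity protocol)
#'
#' Overwrites the phylogenetic distance of the listed species pairs with a
#' chosen value (both triangle mirrors), leaving every other entry
#' untouched.  Ultrametricity is deliberately not enforced: the point of
#' the manipulation is to move pairs into a different distance quantile
#' and check that the analysis responds where, and only where, it should.
#'
#' @param D Symmetric species distance matrix (Ma).
#' @param pairs Two-column matrix / data frame of species codes, one pair
#'   per row (or a length-2 character vector for a single pair).
#' @param new_ma New distance in Ma (>= 0).
#' @return The modified matrix.
#' @export
manipulate_distances <- function(D, pairs, new_ma) {
  check_phylo_distances(D)
  if (new_ma < 0) stop("new_ma must be >= 0")
  if (is.null(pairs) || length(pairs) == 0) return(D)
  if (is.vector(pairs) && length(pairs) == 2) pairs <- matrix(pairs, 1)
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (!a %in% rownames(D) || !b %in% rownames(D)) {
      stop("unknown species in pair: ", a, " / ", b)
    }
    D[a, b] <- D[b, a] <- new_ma
  }
  D
}

## seed scoping helpers: run a block under a given seed and restore the
## caller's RNG state afterwards
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
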