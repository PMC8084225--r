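#' The six focal-annular EAA tests
#'
#' @description
#' Each test compares an observed focal-annular statistic, per annulus and
#' phylogenetic-distance quantile, against a Monte Carlo null model in which
#' one focal-tree attribute is repeatedly shuffled within species while
#' every other property of the plot (positions, species identities, annular
#' properties) is left intact:
#'
#' * **Test 1** -- mean edge-weighted summed basal area of annular survivors
#'   per focal-size quartile; null shuffles focal survivor sizes.
#'   NDD expectation: negative relationship with focal size.
#' * **Test 2** -- fraction of annular trees that recruit, per focal-size
#'   quartile; null shuffles focal survivor sizes.  NDD: negative.
#' * **Test 3** -- fraction of annular trees that die (small and large dead
#'   annular trees separately), per focal-size quartile; null shuffles focal
#'   survivor sizes.  NDD: positive for large dead annular trees.
#' * **Test 4** -- difference in mean normalized growth of the smallest
#'   focal-size quintile between each annular-biomass quintile and the
#'   comparison group of focal trees with no qualifying annular trees in
#'   the cell; null shuffles normalized growth within species.  NDD:
#'   negative.
#' * **Test 5** -- fraction of annular recruits around focal recruits vs
#'   other focal trees; null shuffles focal fates within species.  NDD:
#'   higher around focal recruits.
#' * **Test 6** -- fraction of annular deaths around focal trees that died
#'   (small/large) vs others; null shuffles focal fates.  NDD: higher
#'   around focal deaths.
#'
#' `run_eaa_test()` repeats each analysis over `config$replicates`
#' tie-shuffle replicates of the phylogenetic quantiles, runs
#' `config$iterations` null iterations per replicate, and reports per-cell
#' z-scores `(observed - null mean) / null SD` both per replicate (against
#' that replicate's own null) and pooled over all replicates' iterations.
#' Two-sided normal p-values are Benjamini-Hochberg adjusted within each
#' (test x census interval) family.
#'
#' @param plot An [fdp_census()] object (>= 2 censuses for Tests 2-6).
#' @param D Species distance matrix (Ma), covering all plot species.
#' @param tests Integer subset of 1:6.
#' @param config An [eaa_config()].
#' @param intervals Census intervals to analyze (default all).
#' @return An `eaa_result`: a tibble with one row per (test, interval,
#'   replicate, variant, focal group, annulus, phylo bin) carrying
#'   `observed`, `null_mean`, `null_sd`, `z`, `p`, `bh_significant`, plus
#'   attributes `pooled` (the pooled-null version, without the replicate
#'   index) and `config`.
#' @export
run_eaa_test <- function(plot, D, tests = 1:6, config = eaa_config(),
                         intervals = NULL) {
  stopifnot(inherits(plot, "fdp"), all(tests %in% 1:6))
  tests <- as.integer(tests)
  check_phylo_distances(D)
  if (plot$n_censuses < 2 && any(tests != 1L)) {
    stop("Tests 2-6 need at least two censuses (a census interval)")
  }
  intervals <- intervals %||% seq_len(max(1L, plot$n_censuses - 1L))
  ni <- length(intervals)
  R <- config$replicates

  old_seed <- local_seed(config$seed)
  null_seeds <- array(sample.int(.Machine$integer.max - 1L, ni * R * 6L),
                      dim = c(ni, R, 6L))
  set.seed(config$tie_seed)
  tie_seeds <- matrix(sample.int(.Machine$integer.max - 1L, ni * R), ni, R)

  rep_rows <- list()
  pooled_rows <- list()
  for (ii in seq_len(ni)) {
    prep <- prepare_interval(plot, D, intervals[ii], config)
    pool <- list()
    metas <- list()
    ma_sum <- 0
    for (r in seq_len(R)) {
      set.seed(tie_seeds[ii, r])
      pair_bins <- phylo_quantiles(D, config$n_phylo_bins)
      nb <- bin_neighborhood(prep, D, pair_bins, config)
      ma_sum <- ma_sum + nb$bin_ma
      machines <- lapply(tests, function(tt) test_machine(tt, nb, config))
      for (ti in seq_along(tests)) {
        tt <- tests[ti]
        set.seed(null_seeds[ii, r, tt])
        res <- run_machine(machines[[ti]], config$iterations)
        rep_rows[[length(rep_rows) + 1L]] <- cell_rows(
          tt, intervals[ii], r, machines[[ti]]$meta, nb, res
        )
        key <- as.character(tt)
        metas[[key]] <- machines[[ti]]$meta
        pool[[key]] <- pool_accumulate(pool[[key]], res)
      }
    }
    nb$bin_ma <- ma_sum / R # label-level midpoint, averaged over tie shuffles
    for (key in names(pool)) {
      tt <- as.integer(key)
      pooled_rows[[length(pooled_rows) + 1L]] <- cell_rows(
        tt, intervals[ii], NA_integer_, metas[[key]], nb, pool_finish(pool[[key]])
      )
    }
  }
  restore_seed(old_seed)

  out <- dplyr::bind_rows(rep_rows)
  out <- add_significance(out, config$alpha)
  pooled <- add_significance(dplyr::bind_rows(pooled_rows), config$alpha)
  pooled$replicate <- NULL
  structure(out,
    pooled = pooled, config = config,
    class = c("eaa_result", class(tibble::tibble()))
  )
}

#' @export
print.eaa_result <- function(x, ...) {
  cat(sprintf("<eaa_result> tests %s, %d rows; pooled table in attr(x, \"pooled\")\n",
              paste(sort(unique(x$test)), collapse = ","), nrow(x)))
  NextMethod()
}

#' Pooled-null results of an EAA run
#'
#' The headline table: per-cell z-scores against the null distribution
#' pooled over all tie-shuffle replicates (e.g. 10 x 100 = 1,000
#' iterations), with BH-adjusted significance flags.
#'
#' @param x An `eaa_result`.
#' @return A tibble.
#' @export
pooled_results <- function(x) attr(x, "pooled")

add_significance <- function(df, alpha) {
  if (nrow(df) == 0) return(df)
  df$p <- 2 * stats::pnorm(-abs(df$z))
  df |>
    dplyr::group_by(.data$test, .data$interval) |>
    dplyr::mutate(bh_significant = bh_adjust(.data$p, alpha)) |>
    dplyr::ungroup()
}

## ---- statistic machines ---------------------------------------------------

rowsum_g <- function(M, g, G) {
  rs <- rowsum(M, g)
  out <- matrix(0, G, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

perm_within <- function(v, split_idx) {
  for (jj in split_idx) {
    if (length(jj) > 1L) v[jj] <- v[jj][sample.int(length(jj))]
  }
  v
}

## A machine bundles: meta (variant/group labels per output row), state0
## (the observed attribute assignment), perm() (one within-species shuffle
## of state0) and stat() (output-rows x cells statistic matrix).
test_machine <- function(test, nb, config) {
  f <- nb$focal
  C <- nb$n_cells
  sv <- nb$surv_rows
  if (test %in% 1:3 && length(sv) == 0) stop("no focal survivors in interval")
  if (test %in% c(1:3)) {
    G <- config$n_size_bins
    g0 <- f$size_bin[sv]
    split_idx <- split(seq_along(sv), f$species[sv])
    counts <- tabulate(g0, G)
    Mba <- nb$M$ba[sv, , drop = FALSE]
    Mend <- nb$M$end[sv, , drop = FALSE]
    Mrec <- nb$M$rec[sv, , drop = FALSE]
    Ma0 <- nb$M$a0[sv, , drop = FALSE]
    Mds <- nb$M$ds[sv, , drop = FALSE]
    Mdl <- nb$M$dl[sv, , drop = FALSE]
    stat <- switch(as.character(test),
      "1" = function(g) rowsum_g(Mba, g, G) / counts,
      "2" = function(g) {
        den <- rowsum_g(Mend, g, G)
        out <- rowsum_g(Mrec, g, G) / den
        out[den == 0] <- NA_real_
        out
      },
      "3" = function(g) {
        den <- rowsum_g(Ma0, g, G)
        small <- rowsum_g(Mds, g, G) / den
        large <- rowsum_g(Mdl, g, G) / den
        small[den == 0] <- NA_real_
        large[den == 0] <- NA_real_
        rbind(small, large)
      }
    )
    meta <- if (test == 3) {
      tibble::tibble(variant = rep(c("small_dead", "large_dead"), each = G),
                     group = rep(paste0("Q", seq_len(G)), 2))
    } else {
      tibble::tibble(variant = "all", group = paste0("Q", seq_len(G)))
    }
    list(meta = meta, state0 = g0, stat = stat,
         perm = function(g) perm_within(g, split_idx))
  } else if (test == 4) {
    if (nb$static) stop("Test 4 needs a census interval")
    G <- config$n_biomass_bins
    growth0 <- f$growth[sv]
    split_idx <- split(seq_along(sv), f$species[sv])
    cand <- which(f$size_q5[sv] == 1L)
    Mba <- nb$M$ba[sv, , drop = FALSE]
    ## per cell: qualifying candidates split into biomass quantiles; the
    ## rest of the candidates form the comparison group
    rf <- integer(0); rg <- integer(0)
    for (cc in seq_len(C)) {
      v <- Mba[cand, cc]
      qual <- v > 0
      if (any(qual)) {
        bins <- quantile_bins(v[qual], G, ties = "random")
        rf <- c(rf, cand[qual]); rg <- c(rg, (cc - 1L) * (G + 1L) + bins)
      }
      if (any(!qual)) {
        rf <- c(rf, cand[!qual])
        rg <- c(rg, rep((cc - 1L) * (G + 1L) + G + 1L, sum(!qual)))
      }
    }
    counts <- tabulate(rg, C * (G + 1L))
    stat <- function(growth) {
      sums <- numeric(C * (G + 1L))
      rs <- rowsum(growth[rf], rg)
      sums[as.integer(rownames(rs))] <- rs
      means <- sums / counts # NaN where empty
      mm <- matrix(means, G + 1L, C)
      out <- mm[seq_len(G), , drop = FALSE] -
        matrix(mm[G + 1L, ], G, C, byrow = TRUE)
      out
    }
    list(meta = tibble::tibble(variant = "all", group = paste0("B", seq_len(G))),
         state0 = growth0, stat = stat,
         perm = function(gr) perm_within(gr, split_idx))
  } else {
    ## Tests 5-6: the fate (recruit / died / survivor) is shuffled within
    ## species as a property of the tree, so it moves with the tree in both
    ## its focal and its annular role -- statistics are recomputed from the
    ## pair list each iteration.
    if (nb$static) stop("Tests 5-6 need a census interval")
    lab0 <- ifelse(f$recruit, 1L, ifelse(f$dead, 2L, 3L)) # recruit/died/survivor
    split_idx <- split(seq_len(nrow(f)), f$species)
    pr <- nb$pr
    if (test == 5) {
      G <- 2L
      grp_base <- (pr$cell - 1L) * G
      stat <- function(lab) {
        g <- ifelse(lab[pr$i] == 1L, 1L, 2L)
        rec_j <- pr$w * (lab[pr$j] == 1L)
        end_j <- pr$w * (lab[pr$j] != 2L)
        rs <- rowsum(cbind(rec_j, end_j), grp_base + g)
        num <- den <- numeric(G * C)
        pos <- as.integer(rownames(rs))
        num[pos] <- rs[, 1]; den[pos] <- rs[, 2]
        out <- matrix(num / den, G, C)
        out[den == 0] <- NA_real_
        out
      }
      meta <- tibble::tibble(variant = "all", group = c("recruit", "other"))
    } else {
      G <- 3L
      grp_base <- (pr$cell - 1L) * G
      dbh0 <- f$dbh0
      species <- f$species
      ## small/large split of whichever trees carry the died label
      dead_split <- function(lab) {
        cls <- integer(length(lab)) # 1 small, 2 large, 0 not dead
        died <- which(lab == 2L)
        for (ii in split(died, species[died])) {
          n <- length(ii)
          ord <- order(dbh0[ii], seq_len(n))
          ns <- ceiling(n / 2)
          cls[ii[ord]] <- rep(c(1L, 2L), c(ns, n - ns))
        }
        cls
      }
      stat <- function(lab) {
        cls <- dead_split(lab)
        g <- ifelse(lab[pr$i] == 2L, cls[pr$i], 3L)
        dead_j <- pr$w * (lab[pr$j] == 2L)
        a0_j <- pr$w * (lab[pr$j] != 1L)
        rs <- rowsum(cbind(dead_j, a0_j), grp_base + g)
        num <- den <- numeric(G * C)
        pos <- as.integer(rownames(rs))
        num[pos] <- rs[, 1]; den[pos] <- rs[, 2]
        out <- matrix(num / den, G, C)
        out[den == 0] <- NA_real_
        out
      }
      meta <- tibble::tibble(variant = "all",
                             group = c("died_small", "died_large", "other"))
    }
    list(meta = meta, state0 = lab0, stat = stat,
         perm = function(lab) perm_within(lab, split_idx))
  }
}

run_machine <- function(m, iterations) {
  obs <- m$stat(m$state0)
  s <- matrix(0, nrow(obs), ncol(obs))
  s2 <- s
  nfin <- s
  for (it in seq_len(iterations)) {
    v <- m$stat(m$perm(m$state0))
    fin <- is.finite(v)
    v[!fin] <- 0
    s <- s + v
    s2 <- s2 + v^2
    nfin <- nfin + fin
  }
  list(obs = obs, s = s, s2 = s2, n = nfin)
}

pool_accumulate <- function(acc, res) {
  if (is.null(acc)) {
    fin <- is.finite(res$obs)
    o <- res$obs; o[!fin] <- 0
    return(list(obs_s = o, obs_n = fin * 1, s = res$s, s2 = res$s2, n = res$n))
  }
  fin <- is.finite(res$obs)
  o <- res$obs; o[!fin] <- 0
  acc$obs_s <- acc$obs_s + o
  acc$obs_n <- acc$obs_n + fin
  acc$s <- acc$s + res$s
  acc$s2 <- acc$s2 + res$s2
  acc$n <- acc$n + res$n
  acc
}

pool_finish <- function(acc) {
  obs <- acc$obs_s / acc$obs_n
  obs[acc$obs_n == 0] <- NA_real_
  list(obs = obs, s = acc$s, s2 = acc$s2, n = acc$n)
}

## flatten a (rows x cells) result into tidy rows with z-scores
cell_rows <- function(test, interval, replicate, meta, nb, res) {
  n <- res$n
  null_mean <- res$s / n
  null_var <- (res$s2 - res$s^2 / n) / pmax(n - 1, 1)
  null_sd <- sqrt(pmax(null_var, 0))
  null_mean[n < 2] <- NA_real_
  null_sd[n < 2] <- NA_real_
  z <- (res$obs - null_mean) / null_sd
  z[!is.finite(res$obs) | !is.finite(null_sd) | null_sd < 1e-12] <- NA_real_
  G <- nrow(meta)
  Q <- nb$n_phylo_bins
  C <- nb$n_cells
  cellk <- rep(seq_len(C), each = G)
  tibble::tibble(
    test = test, interval = interval, replicate = replicate,
    variant = rep(meta$variant, C), group = rep(meta$group, C),
    annulus = (cellk - 1L) %/% Q + 1L,
    phylo_bin = (cellk - 1L) %% Q + 1L,
    phylo_ma = nb$bin_ma[(cellk - 1L) %% Q + 1L],
    observed = as.vector(res$obs),
    null_mean = as.vector(null_mean),
    null_sd = as.vector(null_sd),
    z = as.vector(z)
  )
}

#' Observed statistic of one test on a neighborhood
#'
#' The per-cell observed values (no null model): one row per focal group,
#' annulus and phylogenetic bin.  Useful for checking the statistics
#' against direct recomputation.
#'
#' @param test Test id (1-6).
#' @param nb A [build_neighborhood()] object.
#' @param config The [eaa_config()] used to build `nb`.
#' @return A tibble with `variant`, `group`, `annulus`, `phylo_bin`,
#'   `observed`.
#' @export
observed_statistic <- function(test, nb, config = eaa_config()) {
  m <- test_machine(test, nb, config)
  obs <- m$stat(m$state0)
  out <- cell_rows(test, nb$interval, NA_integer_, m$meta, nb,
                   list(obs = obs, s = obs * 0, s2 = obs * 0, n = obs * 0 + 2))
  out[, c("variant", "group", "annulus", "phylo_bin", "observed")]
}

#' One within-species null shuffle of a plot
#'
#' Returns a copy of the plot in which the focal attribute of the requested
#' null model has been permuted within species (and within the census
#' interval), leaving positions, species identities and all annular
#' properties intact: `"size"` permutes interval-start diameters among
#' survivors (the Test 1-3 null), `"growth"` permutes diameter increments
#' among survivors (Test 4), `"fate"` permutes whole per-census records --
#' which trees recruited, survived or died -- among the trees of a species
#' present in the interval (Tests 5-6).
#'
#' @param plot An [fdp_census()] object.
#' @param interval Census interval index.
#' @param what `"size"`, `"growth"` or `"fate"`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A shuffled [fdp_census()] object.
#' @export
null_shuffle <- function(plot, interval = 1, what = c("size", "growth", "fate"),
                         seed = NULL) {
  what <- match.arg(what)
  stopifnot(inherits(plot, "fdp"))
  if (!is.null(seed)) old <- local_seed(seed)
  j0 <- interval
  j1 <- min(interval + 1L, plot$n_censuses)
  alive0 <- plot$status[, j0] %in% c("recruit", "alive")
  alive1 <- plot$status[, j1] %in% c("recruit", "alive")
  trees <- plot$trees
  if (what == "size") {
    surv <- which(alive0 & alive1)
    for (ii in split(surv, trees$species[surv])) {
      if (length(ii) < 2) next
      p <- ii[sample.int(length(ii))]
      trees[[paste0("dbh_", j0)]][ii] <- trees[[paste0("dbh_", j0)]][p]
    }
  } else if (what == "growth") {
    surv <- which(alive0 & alive1)
    d0 <- plot$dbh[, j0]
    d1 <- plot$dbh[, j1]
    for (ii in split(surv, trees$species[surv])) {
      if (length(ii) < 2) next
      p <- ii[sample.int(length(ii))]
      trees[[paste0("dbh_", j1)]][ii] <- format_dbh(d0[ii] + (d1[p] - d0[p]))
    }
  } else {
    pres <- which(alive0 | alive1)
    cols <- c(paste0("dbh_", seq_len(plot$n_censuses)),
              paste0("status_", seq_len(plot$n_censuses)))
    for (ii in split(pres, trees$species[pres])) {
      if (length(ii) < 2) next
      p <- ii[sample.int(length(ii))]
      trees[ii, cols] <- trees[p, cols]
    }
  }
  if (!is.null(seed)) restore_seed(old)
  fdp_census(trees, plot$width, plot$height, plot$interval_years)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `alpha` over one family of
#' two-sided p-values.  `NA` p-values (undefined cells) are excluded from
#' the family and flagged `NA`.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha FDR level in (0, 1).
#' @return Logical vector of rejection flags.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  out <- rep(NA, length(p_values))
  ok <- !is.na(p_values)
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH") <= alpha
  out
}

## ---- results io -----------------------------------------------------------

#' Write and read long-format results
#'
#' One CSV row per (test, interval, replicate, variant, group, annulus,
#' phylo bin) with the observed statistic, null mean/SD, z, p and the
#' BH-adjusted significance flag; written at full precision so a read-back
#' reproduces z exactly.
#'
#' @param result An `eaa_result` (or any tibble of its shape).
#' @param path File path.
#' @return `write_results()` the path, invisibly; `read_results()` a tibble.
#' @export
write_results <- function(result, path) {
  df <- tibble::as_tibble(result)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    variant = "c", group = "c", .default = readr::col_guess()
                  ))
}
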