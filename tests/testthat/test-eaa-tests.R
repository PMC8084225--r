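cfg_small <- eaa_config(n_annuli = 5, total_area = 200, n_phylo_bins = 2,
                        replicates = 2, iterations = 30, seed = 17)

test_that("neighbors land in the annulus given by the closed-form radii", {
  tr <- tibble::tibble(
    tree_id = c("f", "n1", "n2"), species = c("oak", "oak", "fir"),
    x = c(15, 18, 15 + 4.2), y = c(15, 15, 15),
    dbh_1 = c(10, 5, 5), status_1 = "alive",
    dbh_2 = c(10.5, 5.5, 5.5), status_2 = "alive"
  )
  plt <- fdp_census(tr, 30, 30)
  nb <- build_neighborhood(plt, toy_distances(), 1,
                           eaa_config(n_annuli = 10, total_area = 500,
                                      n_phylo_bins = 2, seed = 1))
  tab <- neighborhood_table(nb)
  # r_1 = sqrt(50/pi) = 3.989: the 3 m neighbor is in annulus 1, the
  # 4.2 m neighbor in annulus 2
  f <- tab[tab$tree_id == "f", ]
  expect_equal(sort(f$annulus[f$n_annular_total > 0]), c(1L, 2L))
})

test_that("neighborhood counts partition by fate and match a brute-force scan", {
  plt <- toy_plot()
  D <- toy_distances()
  cfg <- eaa_config(n_annuli = 4, total_area = 300, n_phylo_bins = 2, seed = 2)
  nb <- build_neighborhood(plt, D, 1, cfg)
  tab <- neighborhood_table(nb)
  expect_true(all(tab$n_recruits + tab$n_dead_small + tab$n_dead_large +
                    tab$n_survivors == tab$n_annular_total))

  # total neighbor count within r_n equals a direct O(n^2) scan
  s1 <- census_state(plt, 1); s2 <- census_state(plt, 2)
  present <- s1$status %in% c("recruit", "alive") | s2$status %in% c("recruit", "alive")
  xs <- s1$x[present]; ys <- s1$y[present]
  rn <- sqrt(300 / pi)
  brute <- 0
  for (i in seq_along(xs)) {
    d <- sqrt((xs - xs[i])^2 + (ys - ys[i])^2)
    brute <- brute + sum(d < rn) - 1
  }
  expect_equal(sum(tab$n_annular_total), brute)
})

test_that("test statistics match spec arithmetic and a brute-force oracle", {
  plt <- toy_plot()
  D <- toy_distances()
  cfg <- eaa_config(n_annuli = 4, total_area = 300, n_phylo_bins = 2, seed = 4)
  set.seed(4)
  pb <- phylo_quantiles(D, 2)
  nb <- build_neighborhood(plt, D, 1, cfg, pair_bins = pb)

  obs1 <- observed_statistic(1, nb, cfg)
  # independent brute force from raw records: per focal survivor loop over
  # all trees, assign annuli from pairwise distances, phylo bins from the
  # pair table, weights from edge_fraction; group means include zeros
  s1 <- census_state(plt, 1); s2 <- census_state(plt, 2)
  alive1 <- s1$status %in% c("recruit", "alive")
  alive2 <- s2$status %in% c("recruit", "alive")
  surv <- alive1 & alive2
  sys <- build_annulus_system(cfg$total_area, cfg$n_annuli)
  binmap <- function(a, b) {
    hit <- (pb$sp_a == a & pb$sp_b == b) | (pb$sp_a == b & pb$sp_b == a)
    pb$bin[hit]
  }
  Q <- cfg$n_phylo_bins
  qs <- focal_size_quartiles(plt, 1, focal = surv)
  acc <- array(0, c(4, cfg$n_annuli, Q))
  nfoc <- integer(4)
  for (fi in which(surv)) {
    g <- qs$size_bin[qs$.idx == fi]
    nfoc[g] <- nfoc[g] + 1
    for (j in which(alive1 | alive2)) {
      if (j == fi) next
      k <- annulus_index(c(s1$x[fi], s1$y[fi]), c(s1$x[j], s1$y[j]), sys)
      if (is.na(k)) next
      if (!(alive1[j] && alive2[j])) next # annular survivors only
      w <- 1 / edge_fraction(c(s1$x[fi], s1$y[fi]), k, c(plt$width, plt$height), sys)
      b <- binmap(s1$species[fi], s1$species[j])
      acc[g, k, b] <- acc[g, k, b] + w * s1$ba[j]
    }
  }
  for (g in 1:4) {
    got <- obs1[obs1$group == paste0("Q", g), ]
    for (r in seq_len(nrow(got))) {
      expect_equal(got$observed[r], acc[g, got$annulus[r], got$phylo_bin[r]] / nfoc[g],
                   tolerance = 1e-9)
    }
  }

  # Test 2 fraction arithmetic: recruits / present-at-end, pooled per group
  f <- nb$focal; sv <- nb$surv_rows
  obs2 <- observed_statistic(2, nb, cfg)
  g1 <- sv[f$size_bin[sv] == 1]
  manual2 <- colSums(nb$M$rec[g1, , drop = FALSE]) /
    colSums(nb$M$end[g1, , drop = FALSE])
  got2 <- obs2[obs2$group == "Q1", ]
  got2 <- got2[order((got2$annulus - 1) * cfg$n_phylo_bins + got2$phylo_bin), ]
  expect_equal(got2$observed, manual2, tolerance = 1e-12)
})

test_that("null shuffles conserve within-species multisets and pooled totals", {
  plt <- toy_plot()
  shuf <- null_shuffle(plt, 1, "size", seed = 9)
  # multiset of census-1 diameters per species conserved
  for (sp in plt$species) {
    expect_equal(sort(plt$dbh[plt$trees$species == sp, 1]),
                 sort(shuf$dbh[shuf$trees$species == sp, 1]))
  }
  # positions and annular properties untouched
  expect_equal(shuf$trees$x, plt$trees$x)
  expect_equal(shuf$status, plt$status)

  # conservation oracle: the shuffle permutes focal group labels within
  # species, so the all-focal pooled statistic total per cell is unchanged
  D <- toy_distances()
  cfg <- eaa_config(n_annuli = 4, total_area = 300, n_phylo_bins = 2, seed = 4)
  set.seed(4); pb <- phylo_quantiles(D, 2)
  nb0 <- build_neighborhood(plt, D, 1, cfg, pair_bins = pb)
  m <- eaaforest:::test_machine(1, nb0, cfg)
  counts <- tabulate(m$state0, 4)
  set.seed(77)
  obs <- m$stat(m$state0)
  per <- m$stat(m$perm(m$state0))
  expect_equal(colSums(obs * counts), colSums(per * counts), tolerance = 1e-9)

  # a single-tree species is unchanged under any shuffle
  one <- which(table(plt$trees$species) == 1)
  if (length(one)) {
    sp1 <- names(one)[1]
    expect_equal(shuf$trees$dbh_1[shuf$trees$species == sp1],
                 plt$trees$dbh_1[plt$trees$species == sp1])
  }
})

test_that("identical seeds reproduce results bit for bit", {
  sim <- small_null_sim()
  r1 <- run_eaa_test(sim$plot, sim$D, tests = c(1, 5), config = cfg_small)
  r2 <- run_eaa_test(sim$plot, sim$D, tests = c(1, 5), config = cfg_small)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_identical(pooled_results(r1), pooled_results(r2))
})

test_that("single-test runs reproduce the same numbers as joint runs", {
  sim <- small_null_sim()
  joint <- run_eaa_test(sim$plot, sim$D, tests = c(1, 2), config = cfg_small)
  solo <- run_eaa_test(sim$plot, sim$D, tests = 2, config = cfg_small)
  cols <- c("replicate", "variant", "group", "annulus", "phylo_bin",
            "observed", "null_mean", "null_sd", "z")
  j2 <- tibble::as_tibble(joint)
  j2 <- j2[j2$test == 2, ]
  for (cc in cols) expect_equal(j2[[cc]], solo[[cc]], tolerance = 1e-12)
})

test_that("quartile z-scores balance for the size-shuffle tests", {
  sim <- small_null_sim()
  res <- run_eaa_test(sim$plot, sim$D, tests = 1:3,
                      config = eaa_config(n_annuli = 6, n_phylo_bins = 3,
                                          replicates = 3, iterations = 100, seed = 23))
  df <- tibble::as_tibble(res)
  bal <- df[!is.na(df$z), ] |>
    dplyr::group_by(test, replicate, variant, annulus, phylo_bin) |>
    dplyr::filter(dplyr::n() == 4) |>
    dplyr::summarise(m = mean(z), .groups = "drop")
  expect_lt(mean(abs(bal$m)), 0.2)
})

test_that("tests needing an interval refuse single-census plots", {
  sim <- small_null_sim()
  tr <- sim$plot$trees
  tr <- tr[, c("tree_id", "species", "x", "y", "dbh_1", "status_1")]
  tr <- tr[tr$status_1 %in% c("alive", "recruit"), ]
  plt1 <- fdp_census(tr, sim$plot$width, sim$plot$height)
  expect_error(run_eaa_test(plt1, sim$D, tests = 2, config = cfg_small),
               "at least two censuses")
  # clustering alone works on a single census
  r <- run_eaa_test(plt1, sim$D, tests = 1, config = cfg_small)
  expect_true(all(is.finite(r$observed)))
})

test_that("BH step-up matches a hand oracle and controls FDR", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_adjust(c(0.9, 0.95), 0.05), rep(FALSE, 2))
  expect_error(bh_adjust(0.5, 1.5), "alpha")

  # independent step-up oracle on random families
  step_up <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= seq_len(m) * alpha / m)
    out <- rep(FALSE, m)
    if (length(k)) out[o[seq_len(max(k))]] <- TRUE
    out
  }
  set.seed(12)
  for (i in 1:200) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_identical(bh_adjust(p, 0.05), step_up(p, 0.05))
  }

  # all-null families: mean false-discovery proportion ~ alpha
  set.seed(13)
  fdp <- vapply(1:1000, function(i) {
    p <- 2 * pnorm(-abs(rnorm(20)))
    mean(bh_adjust(p, 0.05))
    # under the global null every discovery is false: FDP is 0 or 1
  }, 0)
  fdp <- as.numeric(fdp > 0)
  expect_lt(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})
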