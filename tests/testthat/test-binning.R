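test_that("basal area sums stem cross-sections", {
  expect_equal(basal_area(2), pi)
  expect_equal(basal_area(numeric(0)), 0)
  expect_equal(basal_area(c(1, 1)), pi / 2, tolerance = 1e-12)
  expect_error(basal_area(-2), "negative")
})

test_that("focal size quartiles are equal-count within species", {
  tr <- tibble::tibble(
    tree_id = sprintf("t%02d", 1:12),
    species = rep(c("a", "b"), c(4, 8)),
    x = seq(1, 12), y = rep(1, 12),
    dbh_1 = c(1, 2, 3, 4, 8:1), status_1 = "alive"
  )
  plt <- fdp_census(tr, 20, 5)
  q <- focal_size_quartiles(plt, 1)
  expect_equal(q$size_bin[q$species == "a"], 1:4)
  expect_equal(as.integer(table(q$size_bin[q$species == "b"])), rep(2L, 4))

  # within species, never pooled: matches a per-species rank oracle
  oracle <- unsplit(lapply(split(q$dbh, q$species), function(v) {
    ceiling(rank(v, ties.method = "first") * 4 / length(v))
  }), q$species)
  expect_equal(q$size_bin, as.integer(oracle))
})

test_that("small species fall back to rank bins with ties shared low", {
  tr <- tibble::tibble(
    tree_id = c("u", "v", "w"), species = "a", x = 1:3, y = rep(1, 3),
    dbh_1 = c(5, 2, 5), status_1 = "alive"
  )
  q <- focal_size_quartiles(fdp_census(tr, 10, 5), 1)
  expect_equal(q$size_bin, c(2L, 1L, 2L))
})

test_that("biomass quintiles are equal-count with random tie spread", {
  b <- annular_biomass_quintiles(c(10, 3, 8, 1, 7, 2, 9, 5, 4, 6))
  expect_equal(as.integer(table(b)), rep(2L, 5))
  # bin means monotone nondecreasing (sort oracle)
  v <- runif(40)
  bb <- annular_biomass_quintiles(v)
  expect_true(all(diff(tapply(v, bb, mean)) >= 0))
  # all-tied values spread across bins under the RNG stream
  set.seed(1)
  tied <- annular_biomass_quintiles(rep(3, 25))
  expect_equal(as.integer(table(tied)), rep(5L, 5))
  set.seed(2)
  tied2 <- annular_biomass_quintiles(rep(3, 25))
  expect_false(identical(tied, tied2))
})

test_that("phylo quantiles order pairs with conspecifics anchored in bin 1", {
  D <- matrix(c(0, 10, 20, 10, 0, 30, 20, 30, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # pairs: three conspecific at 0 plus 10, 20, 30 -> Q = 6 one per bin
  pb <- phylo_quantiles(D, 6)
  expect_equal(sort(pb$bin[pb$distance == 0]), c(1L, 1L, 1L))
  expect_equal(pb$bin[order(pb$distance)][4:6], c(4L, 5L, 6L))
  expect_error(phylo_quantiles(D, 20), "number of species pairs")
  expect_error(phylo_quantiles(D, 1), ">= 2")
})

test_that("tied pairs are shuffled across adjacent bins over replicates", {
  # 8 species, all heterospecific pairs at 111 Ma: 28 tied pairs over 2 bins
  S <- 8
  D <- matrix(111, S, S); diag(D) <- 0
  dimnames(D) <- list(letters[1:S], letters[1:S])
  # Q = 4: bin 1 anchors the 8 conspecific pairs; the 28 tied pairs span
  # the remaining bins, so each pair should visit several bins
  hits <- matrix(0, 28, 2)
  for (r in 1:40) {
    set.seed(100 + r)
    pb <- phylo_quantiles(D, 4)
    het <- pb[pb$distance > 0, ]
    het <- het[order(het$sp_a, het$sp_b), ]
    hits[, 1] <- hits[, 1] + (het$bin == 2)
    hits[, 2] <- hits[, 2] + (het$bin == 4)
  }
  freq2 <- hits[, 1] / 40
  # each tied pair lands in bin 2 with frequency ~ 9/28, and varies
  expect_true(all(freq2 > 0.05 & freq2 < 0.75))
  # determinism: same seed, same assignment
  set.seed(5); a <- phylo_quantiles(D, 4)
  set.seed(5); b <- phylo_quantiles(D, 4)
  expect_identical(a, b)
})

test_that("normalized growth standardizes within strata", {
  # two-tree stratum {1, 3} -> normalized {-1, +1}
  tr <- tibble::tibble(
    tree_id = c("a", "b", "c"), species = c("s", "s", "t"),
    x = 1:3, y = rep(1, 3),
    dbh_1 = c(5, 5, 4), status_1 = "alive",
    dbh_2 = c(6, 8, 4.5), status_2 = "alive"
  )
  g <- normalized_growth(fdp_census(tr, 10, 5), 1)
  # sample-SD standardization: {1, 3} -> +/- 1/sqrt(2), so the stratum has
  # mean 0 and (sample) SD exactly 1
  expect_equal(sort(g$normalized[g$species == "s"]), c(-1, 1) / sqrt(2))
  expect_equal(sd(g$normalized[g$species == "s"]), 1)
  expect_equal(g$normalized[g$species == "t"], 0) # singleton stratum

  # per-stratum mean 0 / SD 1 on a simulated plot
  sim <- small_null_sim()
  gg <- normalized_growth(sim$plot, 1)
  chk <- gg |>
    dplyr::group_by(species, stratum) |>
    dplyr::filter(dplyr::n() >= 2, sd(raw) > 1e-12) |>
    dplyr::summarise(m = mean(normalized), s = sd(normalized), .groups = "drop")
  expect_true(all(abs(chk$m) < 1e-9))
  expect_true(all(abs(chk$s - 1) < 1e-9))
})

test_that("normalized growth is invariant to per-species affine rescaling", {
  sim <- small_null_sim()
  g1 <- normalized_growth(sim$plot, 1)
  # rescale raw growth: dbh_2' = dbh_1 + a * (dbh_2 - dbh_1) + b per species
  plt <- sim$plot
  ab <- list(a = 2.5, b = 4)
  d1 <- plt$dbh[, 1]; d2 <- plt$dbh[, 2]
  surv <- plt$status[, 1] %in% c("recruit", "alive") & plt$status[, 2] == "alive"
  newd2 <- d2
  newd2[surv] <- d1[surv] + ab$a * (d2[surv] - d1[surv]) + ab$b
  plt$trees$dbh_2[surv] <- eaaforest:::format_dbh(newd2[surv])
  plt2 <- fdp_census(plt$trees, plt$width, plt$height)
  g2 <- normalized_growth(plt2, 1)
  expect_equal(g2$normalized, g1$normalized, tolerance = 1e-8)
})

test_that("dead trees split into equal small/large groups per species", {
  tr <- tibble::tibble(
    tree_id = sprintf("t%d", 1:7),
    species = c(rep("a", 4), rep("b", 3)),
    x = 1:7, y = rep(1, 7),
    dbh_1 = c(1, 2, 3, 4, 1, 2, 3), status_1 = "alive",
    dbh_2 = NA_real_, status_2 = "dead"
  )
  s <- split_dead_small_large(fdp_census(tr, 10, 5), 1)
  expect_equal(s$size_class[s$species == "a"], c("small", "small", "large", "large"))
  expect_equal(s$size_class[s$species == "b"], c("small", "small", "large"))
  # counting property on a simulated plot
  sim <- small_null_sim()
  ss <- split_dead_small_large(sim$plot, 1)
  tab <- table(ss$species, ss$size_class)
  if (nrow(tab) > 0 && ncol(tab) == 2) {
    expect_true(all(abs(tab[, "small"] - tab[, "large"]) <= 1))
  }
})

test_that("quantile schemes partition their units with equal counts", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    nb <- sample(2:6, 1)
    b <- eaaforest:::quantile_bins(runif(n), nb)
    expect_equal(length(b), n)
    tab <- tabulate(b, nb)
    expect_lte(max(tab) - min(tab), 1)
    expect_equal(sum(tab), n)
  }
})
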