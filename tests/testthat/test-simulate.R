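test_that("simulation is a deterministic function of the configuration", {
  cfg <- sim_config(seed = 5, n_trees = 400, n_species = 6, width = 50,
                    height = 50, n_censuses = 2)
  s1 <- simulate_fdp(cfg)
  s2 <- simulate_fdp(cfg)
  expect_identical(s1$plot$trees, s2$plot$trees)
  expect_identical(s1$D, s2$D)
})

test_that("zero-strength effects leave the simulation exactly unchanged", {
  base <- sim_config(seed = 8, n_trees = 400, n_species = 6, width = 50,
                     height = 50, n_censuses = 2)
  with0 <- base
  with0$effects <- list(interaction_effect("ndd", "recruitment", strength = 0))
  expect_identical(simulate_fdp(base)$plot$trees, simulate_fdp(with0)$plot$trees)
})

test_that("defaults sit inside the observed stem-density envelope", {
  sim <- simulate_fdp(sim_config(seed = 2))
  dens <- sum(sim$plot$status[, 1] %in% c("alive", "recruit")) /
    (sim$plot$width * sim$plot$height)
  expect_gte(dens, 0.035)
  expect_lte(dens, 0.829)
  # recruits respect the census threshold
  expect_true(all(sim$plot$dbh[!is.na(sim$plot$dbh)] >= 1))
})

test_that("different seeds give indistinguishable summary distributions", {
  sims <- lapply(1:10, function(s) {
    simulate_fdp(sim_config(seed = s, n_trees = 500, n_species = 8,
                            width = 60, height = 60, n_censuses = 2))
  })
  dbh_of <- function(sim) {
    d <- sim$plot$dbh[, 1]
    d[!is.na(d)]
  }
  ab_of <- function(sim) as.numeric(sort(table(sim$plot$trees$species)))
  pvals <- vapply(1:9, function(i) {
    suppressWarnings(ks.test(dbh_of(sims[[i]]), dbh_of(sims[[i + 1]]))$p.value)
  }, 0)
  expect_gte(sum(pvals > 0.01), 8)
  pvals2 <- vapply(1:9, function(i) {
    suppressWarnings(ks.test(ab_of(sims[[i]]), ab_of(sims[[i + 1]]))$p.value)
  }, 0)
  expect_gte(sum(pvals2 > 0.01), 8)
})

test_that("planting helpers validate their arguments", {
  cfg <- sim_config(seed = 1)
  expect_error(plant_allelopathy(cfg, donor = "sp01", susceptible = c("sp01", "sp02")),
               "donor")
  expect_error(interaction_effect("allelopathy"), "donor")
  expect_identical(plant_pair_null(cfg, NULL), cfg)
  cfg2 <- plant_pair_null(cfg, rbind(c("sp01", "sp02")))
  expect_equal(nrow(cfg2$null_pairs), 1)
})

test_that("statuses follow the recruit/alive/dead life cycle", {
  sim <- simulate_fdp(sim_config(seed = 12, n_trees = 600, n_species = 6,
                                 width = 60, height = 60, n_censuses = 4))
  st <- sim$plot$status
  ord <- c(prior = 1, recruit = 2, alive = 3, dead = 4)
  num <- matrix(ord[st], nrow(st))
  expect_true(all(apply(num, 1, function(s) !is.unsorted(s))))
  # there are recruits and deaths over the censuses
  expect_gt(sum(st == "recruit"), 0)
  expect_gt(sum(st == "dead"), 0)
})

test_that("co-clustered species groups share spatial structure", {
  groups <- list(c("sp01", "sp02"))
  cfg <- sim_config(seed = 4, n_species = 4, n_trees = 1200, width = 100,
                    height = 100, cluster_groups = groups, cluster_size = 40,
                    cluster_sigma = 4, n_censuses = 1, logseries_x = 1)
  sim <- simulate_fdp(cfg)
  tr <- sim$plot$trees
  nn_dist <- function(sa, sb) {
    a <- tr[tr$species == sa, ]; b <- tr[tr$species == sb, ]
    m <- vapply(seq_len(nrow(a)), function(i) {
      min(sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2))
    }, 0)
    median(m)
  }
  # co-clustered partner is much nearer on median than an unrelated species
  expect_lt(nn_dist("sp01", "sp02"), nn_dist("sp01", "sp03"))
})
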