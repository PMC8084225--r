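# Shared fixtures, built in code.

# A deterministic 3-tree toy census (two censuses, statuses inferred).
toy_trees <- function() {
  tibble::tibble(
    tree_id = c("a", "b", "c"),
    species = c("sp1", "sp1", "sp2"),
    x = c(1, 2, 3), y = c(1, 1, 2),
    dbh_1 = c(NA, 2.0, 5.0),
    dbh_2 = c(1.2, 2.5, NA)
  )
}

# A small deterministic plot with enough structure for the neighborhood
# oracles: 2 species, known positions, 2 censuses with explicit statuses.
toy_plot <- function(n = 50, width = 30, height = 30, seed = 7) {
  old <- eaaforest:::local_seed(seed)
  on.exit(eaaforest:::restore_seed(old))
  sp <- sample(c("oak", "fir"), n, replace = TRUE)
  d1 <- round(1 + rexp(n, 1 / 4), 3)
  grow <- round(runif(n, 0, 1), 3)
  dies <- runif(n) < 0.2
  recruit <- runif(n) < 0.15 & !dies
  d1[recruit] <- NA
  trees <- tibble::tibble(
    tree_id = sprintf("t%03d", seq_len(n)),
    species = sp,
    x = runif(n, 0, width), y = runif(n, 0, height),
    dbh_1 = ifelse(is.na(d1), NA_character_, format(d1, trim = TRUE)),
    status_1 = ifelse(is.na(d1), "prior", "alive"),
    dbh_2 = ifelse(dies, NA_character_,
                   format(round(ifelse(is.na(d1), 1 + grow, d1 + grow), 3), trim = TRUE)),
    status_2 = ifelse(dies, "dead", ifelse(recruit, "recruit", "alive"))
  )
  fdp_census(trees, width, height)
}

toy_distances <- function() {
  matrix(c(0, 80, 80, 0), 2, 2, dimnames = list(c("fir", "oak"), c("fir", "oak")))
}

# Small null simulation shared by several test files.
small_null_sim <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      cfg <- sim_config(seed = 99, width = 60, height = 60, n_species = 8,
                        n_trees = 700, n_censuses = 2, cluster_size = 1,
                        dispersal = "uniform")
      value <<- simulate_fdp(cfg)
    }
    value
  }
})
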