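#' Ready-made study conditions for the worked examples
#'
#' @description
#' These constructors return [sim_config()] objects (plus protocol metadata
#' where relevant) for the standard demonstration scenarios used in the
#' examples, the test suite and the acceptance script:
#'
#' * `demo_null_config()` -- a no-effect plot in which every attribute is
#'   independent of the neighborhood (uniform initial pattern, uniform
#'   propagule rain, no planted effects): the null-calibration condition.
#' * `demo_ndd_config()` -- conspecific negative density dependence planted
#'   on growth, recruitment and mortality, the direction-recovery
#'   condition: clustering and recruitment should drop, and large-tree
#'   mortality rise, around large conspecific focal trees.
#' * `demo_decay_config()` -- conspecific recruitment NDD with a 5 m
#'   exponential kernel: significance should decay smoothly across annuli.
#' * `demo_valley_config()` -- co-occurring species groups interacting
#'   through an explicit pair-weight matrix, with the three pairs at
#'   111 Ma silenced: a planted "valley" of lowered significance at
#'   intermediate phylogenetic distance, plus the pair set whose distances
#'   the sensitivity protocol moves to 50 Ma.
#' * `demo_allelopathy_config()` -- one distantly related donor species
#'   (split from all others at 200 Ma) suppresses recruitment and growth
#'   of all species except one immune species, emulating the
#'   hemlock-style allelopathy removal analysis.
#'
#' @param seed Integer seed for the simulation.
#' @return A `sim_config`, or for the valley and allelopathy demos a list
#'   with the config and protocol metadata (`null_pairs`, `manip_pairs`,
#'   `valley_bin`/`donor_bin` helpers).
#' @name eaa-demos
NULL

#' @rdname eaa-demos
#' @export
demo_null_config <- function(seed = 1L) {
  sim_config(
    seed = seed, width = 100, height = 100, n_species = 20, n_trees = 2000,
    n_censuses = 2, burn_in = 1,
    cluster_size = 1, dispersal = "uniform"
  )
}

#' @rdname eaa-demos
#' @export
demo_ndd_config <- function(seed = 1L) {
  sim_config(
    seed = seed, width = 150, height = 150, n_species = 20, n_trees = 4500,
    n_censuses = 2, burn_in = 3,
    base_recruitment = 0.45, establishment = 0.6,
    effects = list(
      interaction_effect("ndd", "growth", strength = 3.0,
                         spatial_scale = 3, lambda = 0),
      interaction_effect("ndd", "recruitment", strength = 3.5,
                         spatial_scale = 3, lambda = 0),
      interaction_effect("ndd", "mortality", strength = 0.5,
                         spatial_scale = 3, lambda = 0)
    )
  )
}

#' @rdname eaa-demos
#' @export
demo_decay_config <- function(seed = 1L) {
  sim_config(
    seed = seed, width = 150, height = 150, n_species = 20, n_trees = 4500,
    n_censuses = 3, burn_in = 3,
    base_recruitment = 0.45, establishment = 0.6,
    effects = list(
      interaction_effect("ndd", "recruitment", strength = 3,
                         spatial_scale = 6, lambda = 0)
    )
  )
}

## 16-species ultrametric tree holding three species pairs at 111 Ma and a
## rich spread of shallow divergences, crown depth 200 Ma
valley_demo_tree <- function() {
  AB <- "((sp01:111,(sp02:72,sp03:72):39):14,(sp04:111,sp05:111):14)"
  C <- "(((sp06:20,sp07:20):25,sp08:45):20,sp09:65)"
  Dd <- "(((sp10:30,sp11:30):28,sp12:58):32,sp13:90)"
  E <- "(sp14:75,sp15:75)"
  CD <- sprintf("(%s:95,%s:70)", C, Dd)
  CDE <- sprintf("(%s:15,%s:100)", CD, E)
  ABCDE <- sprintf("(%s:65,%s:15)", AB, CDE)
  sprintf("(%s:10,sp16:200);", ABCDE)
}

#' @rdname eaa-demos
#' @param planted Plant the 111-Ma interaction valley (default `TRUE`);
#'   `FALSE` gives the matching baseline with all pair interactions live.
#' @export
demo_valley_config <- function(seed = 1L, planted = TRUE) {
  sp <- sprintf("sp%02d", 1:16)
  groups <- list(c("sp06", "sp07", "sp08", "sp09"),
                 c("sp10", "sp11", "sp12", "sp13"),
                 c("sp01", "sp02", "sp03"), c("sp04", "sp05"),
                 c("sp14", "sp15"))
  W <- matrix(0, 16, 16, dimnames = list(sp, sp))
  for (g in groups) for (a in g) for (b in g) if (a != b) W[a, b] <- 1
  null_pairs <- rbind(c("sp01", "sp02"), c("sp01", "sp03"), c("sp04", "sp05"))
  config <- sim_config(
    seed = seed, width = 150, height = 150, n_species = 16, n_trees = 4500,
    n_censuses = 3, burn_in = 2,
    base_recruitment = 0.45, establishment = 0.6,
    cluster_groups = groups, tree = valley_demo_tree(), logseries_x = 1.0,
    effects = list(
      interaction_effect("ndd", "recruitment", strength = 3.5,
                         spatial_scale = 5, pair_weights = W)
    ),
    null_pairs = if (planted) null_pairs else NULL
  )
  list(
    config = config,
    null_pairs = null_pairs,
    manip_pairs = rbind(c("sp01", "sp02"), c("sp01", "sp03"), c("sp02", "sp03")),
    manip_ma = 50
  )
}

#' @rdname eaa-demos
#' @export
demo_allelopathy_config <- function(seed = 1L) {
  ## donor sp02 splits at the root (200 Ma); the other 15 species form a
  ## pectinate clade with divergences from 15 to 158 Ma
  tips <- sprintf("sp%02d", c(1, 3:16))
  build <- "(sp01:15,sp03:15)"
  d <- 15
  for (i in seq_along(tips[-(1:2)])) {
    d2 <- 15 + 11 * i
    build <- sprintf("(%s:%d,%s:%d)", build, d2 - d, tips[i + 2], d2)
    d <- d2
  }
  nwk <- sprintf("(%s:%d,sp02:200);", build, 200 - d)
  config <- sim_config(
    seed = seed, width = 150, height = 150, n_species = 16, n_trees = 4500,
    n_censuses = 3, burn_in = 1, cluster_size = 1,
    tree = nwk, logseries_x = 1.0,
    base_recruitment = 0.45, establishment = 0.6
  )
  config <- plant_allelopathy(config, donor = "sp02", immune = "sp01",
                              strength = 3.5, spatial_scale = 3,
                              donor_min_dbh = 4)
  list(config = config, donor = "sp02", immune = "sp01")
}
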