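#' Simulation configuration for a synthetic forest dynamics plot
#'
#' Defines the study conditions of a simulated plot: a rectangular window,
#' log-series-like species abundances, Thomas-cluster conspecific spatial
#' pattern, an ultrametric Yule phylogeny, and multi-census demography
#' (recruitment at the 1 cm dbh threshold, growth, mortality) optionally
#' modulated by planted neighbor-interaction effects with known ground
#' truth.
#'
#' Defaults emulate a mid-density plot: 100 x 100 m, 20 species, ~2,000
#' stems (0.2 trees/m^2, inside the range observed across real plots),
#' 5-year census intervals, ~12% mortality and a compensating recruitment
#' flux per interval, and mean growth of 0.6 cm per interval.
#'
#' @param width,height Plot dimensions (m).
#' @param n_species,n_trees Species count and target initial stem count.
#' @param logseries_x Abundance decay: species of rank s has expected share
#'   proportional to `x^s / s`.
#' @param cluster_size,cluster_sigma Thomas process: mean trees per parent
#'   cluster and Gaussian offspring spread (m).
#' @param cluster_groups Optional list of character vectors of species codes;
#'   species in a group share the same Thomas cluster parents, so their
#'   stems are spatially intermingled (co-occurring species groups).
#'   Species not listed cluster on their own.
#' @param yule_root_depth,yule_birth Phylogeny: crown depth (Ma) the Yule
#'   tree is scaled to, and its birth rate.
#' @param tree Optional Newick string or `phylo` used instead of a random
#'   Yule tree (tips must be `sp01 ... spNN`).
#' @param n_censuses,interval_years,burn_in Number of recorded censuses,
#'   interval length (years), and unrecorded spin-up intervals before the
#'   first census.
#' @param base_mortality Per-interval death probability baseline.
#' @param base_recruitment Expected propagules per alive conspecific adult
#'   per interval.
#' @param establishment Baseline propagule establishment probability.
#' @param recruit_sigma Propagule dispersal spread around the parent (m).
#' @param dispersal `"clustered"` (default): propagules land near a random
#'   alive conspecific adult, the storage-effect mechanism that produces
#'   genuine recruit-recruit clustering; `"uniform"`: propagule rain across
#'   the plot, making recruitment positions independent of the
#'   neighborhood (the pure null condition).
#' @param growth_mean,growth_sd Diameter increment (cm per interval).
#' @param dbh_init_mean Mean initial dbh (cm; gamma-distributed above the
#'   1 cm threshold).
#' @param effects List of [interaction_effect()] specifications.
#' @param null_pairs Two-column matrix of species pairs whose interaction
#'   weight is forced to zero in every effect (see [plant_pair_null()]).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(width = 100, height = 100,
                       n_species = 20, n_trees = 2000, logseries_x = 0.95,
                       cluster_size = 20, cluster_sigma = 5,
                       cluster_groups = NULL,
                       yule_root_depth = 200, yule_birth = 0.1, tree = NULL,
                       n_censuses = 2, interval_years = 5, burn_in = 0,
                       base_mortality = 0.12, base_recruitment = 0.25,
                       establishment = 0.5, recruit_sigma = 4,
                       dispersal = c("clustered", "uniform"),
                       growth_mean = 0.6, growth_sd = 0.4,
                       dbh_init_mean = 4,
                       effects = list(), null_pairs = NULL, seed = 1L) {
  stopifnot(
    width > 0, height > 0, n_species >= 1, n_trees >= 1,
    base_mortality >= 0, base_mortality <= 1,
    establishment >= 0, establishment <= 1,
    cluster_sigma > 0, growth_sd > 0, n_censuses >= 1
  )
  dispersal <- match.arg(dispersal)
  structure(as.list(environment()), class = "sim_config")
}

#' Planted neighbor-interaction effect
#'
#' Describes one interaction planted into the simulation.  The pressure a
#' target tree (or propagule site) experiences is the sum over neighbors
#' within the kernel range of `basal area x exp(-d / spatial_scale) x
#' phylogenetic weight`, standardized by the mean positive pressure across
#' targets; `strength` is the resulting shift, per unit of standardized
#' pressure, on the log-odds of the targeted demographic rate (or on mean
#' growth, in SD units).  `strength = 0` is exactly null (the term is
#' skipped).
#'
#' @param kind `"ndd"` (suppression increasing with relatedness),
#'   `"pdd"` (facilitation), or `"allelopathy"` (suppression by large
#'   trees of one donor species, independent of phylogenetic distance).
#' @param target `"recruitment"`, `"mortality"`, `"growth"` or `"all"`.
#' @param strength Log-odds (or growth-SD) shift per unit pressure.
#' @param spatial_scale Exponential kernel scale (m).
#' @param lambda Phylogenetic kernel scale (Ma): weight `exp(-Ma/lambda)`;
#'   `Inf` ignores phylogeny, `0` restricts to conspecifics.
#' @param pair_weights Optional explicit species-pair weight matrix
#'   overriding the exponential kernel.
#' @param donor,susceptible,immune Allelopathy: donor species code, the
#'   species suppressed (default: all others), and species explicitly
#'   unaffected.
#' @param donor_min_dbh Minimum donor dbh (cm) for allelopathic pressure.
#' @return A list of class `interaction_effect`.
#' @export
interaction_effect <- function(kind = c("ndd", "pdd", "allelopathy"),
                               target = c("all", "recruitment", "mortality", "growth"),
                               strength = 1, spatial_scale = 5, lambda = 50,
                               pair_weights = NULL,
                               donor = NULL, susceptible = NULL, immune = NULL,
                               donor_min_dbh = 10) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  if (kind == "allelopathy") {
    if (is.null(donor)) stop("allelopathy needs a donor species")
    if (!is.null(susceptible) && donor %in% susceptible) {
      stop("donor cannot be in the susceptible set")
    }
  }
  structure(
    list(kind = kind, target = target, strength = strength,
         spatial_scale = spatial_scale, lambda = lambda,
         pair_weights = pair_weights,
         donor = donor, susceptible = susceptible, immune = immune,
         donor_min_dbh = donor_min_dbh),
    class = "interaction_effect"
  )
}

#' Plant an allelopathic donor into a configuration
#'
#' Recruitment and growth of the susceptible species are suppressed near
#' large trees of the donor species regardless of phylogenetic distance;
#' `immune` species are unaffected.  With `strength = 0` the configuration
#' is unchanged in effect.
#'
#' @param config A [sim_config()].
#' @param donor Donor species code.
#' @param susceptible Species suppressed (default: all except donor and
#'   immune).
#' @param immune Species explicitly unaffected.
#' @param strength,spatial_scale,donor_min_dbh See [interaction_effect()].
#' @return The augmented configuration.
#' @export
plant_allelopathy <- function(config, donor, susceptible = NULL, immune = NULL,
                              strength = 2, spatial_scale = 5, donor_min_dbh = 10) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(susceptible) && donor %in% susceptible) {
    stop("donor cannot be in the susceptible set")
  }
  for (tg in c("recruitment", "growth")) {
    config$effects <- c(config$effects, list(interaction_effect(
      kind = "allelopathy", target = tg, strength = strength,
      spatial_scale = spatial_scale, donor = donor,
      susceptible = susceptible, immune = immune, donor_min_dbh = donor_min_dbh
    )))
  }
  config
}

#' Silence the interaction of selected species pairs
#'
#' Sets the interaction weight of the listed focal-annular species pairs to
#' zero in every planted effect, creating a "valley" of lowered
#' significance at the phylogenetic distance those pairs share.  An empty
#' pair list is a no-op.
#'
#' @param config A [sim_config()].
#' @param species_pairs Two-column matrix/data frame of species codes.
#' @return The augmented configuration.
#' @export
plant_pair_null <- function(config, species_pairs) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(species_pairs) || NROW(species_pairs) == 0) return(config)
  species_pairs <- as.matrix(species_pairs)
  stopifnot(ncol(species_pairs) == 2)
  config$null_pairs <- rbind(config$null_pairs, species_pairs)
  config
}

## reflect coordinates into [0, L)
reflect_into <- function(v, L) {
  v <- abs(v)
  v <- ifelse(v >= 2 * L, v %% (2 * L), v)
  ifelse(v >= L, 2 * L - v - 1e-9, v)
}

## neighbor pairs between a target point set and a source point set
cross_pairs <- function(tx, ty, sx, sy, rmax) {
  key <- function(a, b) paste(a, b)
  src <- tibble::tibble(j = seq_along(sx), xx = sx, yy = sy,
                        k = key(floor(sx / rmax), floor(sy / rmax)))
  acc <- list(); m <- 0
  tcx <- floor(tx / rmax); tcy <- floor(ty / rmax)
  for (dx in -1:1) {
    for (dy in -1:1) {
      m <- m + 1
      lhs <- tibble::tibble(i = seq_along(tx), fx = tx, fy = ty,
                            k = key(tcx + dx, tcy + dy))
      acc[[m]] <- dplyr::inner_join(lhs, src, by = "k", relationship = "many-to-many")
    }
  }
  cand <- dplyr::bind_rows(acc)
  d2 <- (cand$fx - cand$xx)^2 + (cand$fy - cand$yy)^2
  keep <- d2 < rmax^2
  tibble::tibble(i = cand$i[keep], j = cand$j[keep], d = sqrt(d2[keep]))
}

## standardized interaction pressure of one effect on a set of targets
## t_self: index of each target in the source frame (NA for propagules)
effect_pressure <- function(effect, tx, ty, t_species, t_self,
                            src, D, null_pairs) {
  cutoff <- min(15, 4 * effect$spatial_scale)
  pp <- cross_pairs(tx, ty, src$x, src$y, cutoff)
  if (!is.na(t_self[1]) || any(!is.na(t_self))) {
    pp <- pp[is.na(t_self[pp$i]) | t_self[pp$i] != pp$j, ]
  }
  if (nrow(pp) == 0) return(numeric(length(tx)))
  tsp <- t_species[pp$i]
  ssp <- src$species[pp$j]
  if (effect$kind == "allelopathy") {
    sus <- effect$susceptible %||% setdiff(unique(c(t_species, src$species)),
                                           c(effect$donor, effect$immune))
    sus <- setdiff(sus, effect$immune)
    w <- as.numeric(ssp == effect$donor &
                      src$dbh[pp$j] >= effect$donor_min_dbh &
                      tsp %in% sus)
  } else if (!is.null(effect$pair_weights)) {
    w <- effect$pair_weights[cbind(tsp, ssp)]
  } else if (effect$lambda <= 0) {
    w <- as.numeric(tsp == ssp)
  } else if (is.infinite(effect$lambda)) {
    w <- 1
  } else {
    w <- exp(-D[cbind(tsp, ssp)] / effect$lambda)
  }
  if (!is.null(null_pairs) && nrow(null_pairs) > 0) {
    keyset <- c(paste(null_pairs[, 1], null_pairs[, 2]),
                paste(null_pairs[, 2], null_pairs[, 1]))
    w[paste(tsp, ssp) %in% keyset] <- 0
  }
  val <- (src$ba[pp$j] / 100) * exp(-pp$d / effect$spatial_scale) * w
  P <- numeric(length(tx))
  agg <- rowsum(val, pp$i)
  P[as.integer(rownames(agg))] <- agg
  pos <- P[P > 0]
  if (length(pos)) P <- P / mean(pos)
  P
}

## summed log-odds (or growth) shift over effects hitting a target class
total_shift <- function(effects, target_class, tx, ty, t_species, t_self,
                        src, D, null_pairs) {
  shift <- numeric(length(tx))
  for (e in effects) {
    if (e$strength == 0) next
    if (!(e$target == "all" || e$target == target_class)) next
    s <- if (e$kind == "pdd") -e$strength else e$strength
    shift <- shift + s * effect_pressure(e, tx, ty, t_species, t_self,
                                         src, D, null_pairs)
  }
  shift
}

#' Simulate a censused forest plot with known ground truth
#'
#' Generates the initial spatial pattern (Thomas clusters per species with
#' log-series-like abundances), an ultrametric Yule phylogeny, and then
#' runs per-interval demography -- mortality, growth, and spatially
#' explicit recruitment (propagules dispersed around conspecific adults
#' with an establishment probability) -- each modulated on the log-odds
#' scale by the planted interaction effects.  Probabilities pushed outside
#' `[1e-6, 1 - 1e-6]` are clamped and counted.
#'
#' @param config A [sim_config()].
#' @return A list of class `fdp_sim`: `plot` (an [fdp_census()]), `D`
#'   (species distance matrix, Ma), `tree` (the `phylo`), `config`,
#'   `clamp_count`, and `ground_truth` (the planted effects and null
#'   pairs).
#' @export
simulate_fdp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  S <- config$n_species
  sp_codes <- sprintf("sp%02d", seq_len(S))

  ## phylogeny
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(S, birth = config$yule_birth, death = 0)
    tree$tip.label <- sp_codes
  } else if (!inherits(tree, "phylo")) {
    tree <- ape::read.tree(text = tree)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * config$yule_root_depth / depth
  D <- distances_from_newick(tree)
  if (!all(sp_codes %in% rownames(D))) stop("tree tips must match species codes")

  ## abundances and initial Thomas-cluster pattern
  share <- config$logseries_x^seq_len(S) / seq_len(S)
  counts <- as.vector(stats::rmultinom(1, config$n_trees, share / sum(share)))
  ## each species (or declared co-occurring species group) gets its own
  ## Thomas cluster parents
  group_of <- stats::setNames(sp_codes, sp_codes)
  for (g in seq_along(config$cluster_groups)) {
    group_of[config$cluster_groups[[g]]] <- paste0("grp", g)
  }
  xs <- ys <- numeric(0); spv <- character(0)
  for (grp in unique(group_of)) {
    members <- which(group_of == grp)
    n_grp <- sum(counts[members])
    if (n_grp == 0) next
    npar <- max(1L, round(n_grp / config$cluster_size))
    px <- stats::runif(npar, 0, config$width)
    py <- stats::runif(npar, 0, config$height)
    for (s in members) {
      n <- counts[s]
      if (n == 0) next
      pa <- sample.int(npar, n, replace = TRUE)
      xs <- c(xs, reflect_into(px[pa] + stats::rnorm(n, 0, config$cluster_sigma), config$width))
      ys <- c(ys, reflect_into(py[pa] + stats::rnorm(n, 0, config$cluster_sigma), config$height))
      spv <- c(spv, rep(sp_codes[s], n))
    }
  }
  n0 <- length(xs)
  live <- tibble::tibble(
    id = seq_len(n0), species = spv, x = xs, y = ys,
    dbh = 1 + stats::rgamma(n0, shape = 1.2,
                            scale = (config$dbh_init_mean - 1) / 1.2)
  )
  live$ba <- pi * (live$dbh / 2)^2
  next_id <- n0 + 1L
  clamp_count <- 0L

  n_steps <- config$burn_in + config$n_censuses - 1L
  ## history: per recorded census, a snapshot tibble(id, species, x, y, dbh, new)
  history <- vector("list", config$n_censuses)
  recruits_at <- integer(0) # census index at which each id recruited (0 = initial)
  record <- function(census, new_ids) {
    history[[census]] <<- live[, c("id", "species", "x", "y", "dbh")]
    recruits_at[as.character(new_ids)] <<- census
  }
  if (config$burn_in == 0L) record(1L, integer(0))

  step_no <- 0L
  for (step in seq_len(n_steps)) {
    step_no <- step_no + 1L
    recorded <- step_no > config$burn_in
    src <- live # interval-start state drives all pressures
    ## mortality
    mshift <- total_shift(config$effects, "mortality",
                          live$x, live$y, live$species, seq_len(nrow(live)),
                          src, D, config$null_pairs)
    pm <- stats::plogis(stats::qlogis(min(max(config$base_mortality, 1e-6), 1 - 1e-6)) + mshift)
    clamp_count <- clamp_count + sum(pm < 1e-6 | pm > 1 - 1e-6)
    pm <- pmin(pmax(pm, 1e-6), 1 - 1e-6)
    dies <- stats::runif(nrow(live)) < pm
    ## growth of survivors
    gshift <- total_shift(config$effects, "growth",
                          live$x, live$y, live$species, seq_len(nrow(live)),
                          src, D, config$null_pairs)
    inc <- pmax(stats::rnorm(nrow(live), config$growth_mean, config$growth_sd) -
                  gshift * config$growth_sd, 0)
    ## recruitment: propagules dispersed around conspecific adults
    new_rows <- NULL
    n_alive <- table(factor(src$species, levels = sp_codes))
    nprop <- stats::rpois(S, config$base_recruitment * as.numeric(n_alive))
    if (sum(nprop) > 0) {
      prop <- dplyr::bind_rows(lapply(which(nprop > 0), function(s) {
        if (config$dispersal == "uniform") {
          return(tibble::tibble(
            species = sp_codes[s],
            x = stats::runif(nprop[s], 0, config$width),
            y = stats::runif(nprop[s], 0, config$height)
          ))
        }
        par_idx <- which(src$species == sp_codes[s])
        pick <- par_idx[sample.int(length(par_idx), nprop[s], replace = TRUE)]
        tibble::tibble(
          species = sp_codes[s],
          x = reflect_into(src$x[pick] + stats::rnorm(nprop[s], 0, config$recruit_sigma),
                           config$width),
          y = reflect_into(src$y[pick] + stats::rnorm(nprop[s], 0, config$recruit_sigma),
                           config$height)
        )
      }))
      rshift <- total_shift(config$effects, "recruitment",
                            prop$x, prop$y, prop$species, rep(NA_integer_, nrow(prop)),
                            src, D, config$null_pairs)
      pe <- stats::plogis(stats::qlogis(min(max(config$establishment, 1e-6), 1 - 1e-6)) - rshift)
      clamp_count <- clamp_count + sum(pe < 1e-6 | pe > 1 - 1e-6)
      pe <- pmin(pmax(pe, 1e-6), 1 - 1e-6)
      est <- stats::runif(nrow(prop)) < pe
      if (any(est)) {
        prop <- prop[est, ]
        new_rows <- tibble::tibble(
          id = seq.int(next_id, length.out = nrow(prop)),
          species = prop$species, x = prop$x, y = prop$y,
          dbh = 1 + stats::rexp(nrow(prop), rate = 2)
        )
        next_id <- next_id + nrow(prop)
      }
    }
    live <- live[!dies, ]
    live$dbh <- live$dbh + inc[!dies]
    if (!is.null(new_rows)) live <- dplyr::bind_rows(live, new_rows)
    live$ba <- pi * (live$dbh / 2)^2
    new_ids <- if (is.null(new_rows)) integer(0) else new_rows$id
    if (recorded) {
      record(step_no - config$burn_in + 1L, new_ids)
    } else if (step_no == config$burn_in) {
      record(1L, new_ids) # census 1 is the state at the end of the spin-up
    }
  }

  ## assemble the wide census table
  all_ids <- sort(unique(unlist(lapply(history, function(h) h$id))))
  k <- config$n_censuses
  meta <- dplyr::bind_rows(history)[, c("id", "species", "x", "y")]
  meta <- meta[!duplicated(meta$id), ]
  meta <- meta[match(all_ids, meta$id), ]
  trees <- tibble::tibble(
    tree_id = sprintf("t%06d", all_ids),
    species = meta$species, x = meta$x, y = meta$y
  )
  dbh_mat <- matrix(NA_real_, length(all_ids), k)
  for (j in seq_len(k)) {
    m <- match(all_ids, history[[j]]$id)
    dbh_mat[, j] <- history[[j]]$dbh[m]
  }
  first_seen <- apply(!is.na(dbh_mat), 1, function(p) match(TRUE, p))
  last_seen <- apply(!is.na(dbh_mat), 1, function(p) max(which(p)))
  status <- matrix("prior", length(all_ids), k)
  for (i in seq_along(all_ids)) {
    f0 <- first_seen[i]; l0 <- last_seen[i]
    status[i, f0:l0] <- "alive"
    rc <- recruits_at[as.character(all_ids[i])]
    if (!is.na(rc) && rc >= 1) status[i, f0] <- "recruit"
    if (l0 < k) status[i, (l0 + 1):k] <- "dead"
  }
  for (j in seq_len(k)) {
    trees[[paste0("dbh_", j)]] <- ifelse(is.na(dbh_mat[, j]), NA_character_,
                                         format_dbh(dbh_mat[, j]))
    trees[[paste0("status_", j)]] <- status[, j]
  }
  plot <- fdp_census(trees, config$width, config$height, config$interval_years)
  structure(
    list(plot = plot, D = D, tree = tree, config = config,
         clamp_count = clamp_count,
         ground_truth = list(effects = config$effects,
                             null_pairs = config$null_pairs)),
    class = "fdp_sim"
  )
}

#' @export
print.fdp_sim <- function(x, ...) {
  cat("<fdp_sim> seed", x$config$seed, "with",
      length(x$ground_truth$effects), "planted effect(s)\n")
  print(x$plot)
  invisible(x)
}
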