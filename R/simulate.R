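#' Scenario definition for the synthetic community generators
#'
#' Bundles every knob of the synthetic-community generators: the sampling
#' design (stations x habitat groups), the metacommunity, and the assembly
#' regime parameters. Defaults emulate an estuarine survey: 21 stations in a
#' one-degree box (125-126 E, 30-31 N), four habitat groups per station
#' (surface / middle / bottom water plus sediment), a few hundred taxa with a
#' heavy-tailed (lognormal, sigma = 1.5) rank-abundance distribution, and
#' 1000 reads per sample.
#'
#' @param n_stations Number of stations.
#' @param groups Character vector of habitat group labels sampled at each
#'   station.
#' @param n_taxa Number of taxa in the metacommunity.
#' @param reads_per_sample Sequencing depth N per sample.
#' @param metacommunity Optional simplex vector of metacommunity relative
#'   abundances; if `NULL`, a lognormal rank-abundance vector is drawn from
#'   the scenario seed.
#' @param lognormal_sigma Standard deviation (log scale) of the lognormal
#'   rank-abundance draw used when `metacommunity` is `NULL`.
#' @param migration_rate Sloan migration rate m in (0, 1].
#' @param selection_strength Inverse-niche-width w (>= 0) of the Gaussian
#'   selection kernel.
#' @param niche_conservatism_sigma Brownian rate of trait evolution on the
#'   tree; larger values give less phylogenetically conserved niches.
#' @param decay_rate Exponential distance-decay rate of metacommunity mixing
#'   weights, per meter.
#' @param bbox Named numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed Integer seed; every generator is a pure function of
#'   (scenario, seed).
#' @return A list of class `"assembly_scenario"`.
#' @export
assembly_scenario <- function(n_stations = 21,
                              groups = c("surface", "middle", "bottom", "sediment"),
                              n_taxa = 300,
                              reads_per_sample = 1000,
                              metacommunity = NULL,
                              lognormal_sigma = 1.5,
                              migration_rate = 0.1,
                              selection_strength = 0,
                              niche_conservatism_sigma = 1,
                              decay_rate = 0,
                              bbox = c(lon_min = 125, lon_max = 126,
                                       lat_min = 30, lat_max = 31),
                              seed = 1) {
  stopifnot(n_stations >= 1, n_taxa >= 2, reads_per_sample >= 1,
            migration_rate > 0, migration_rate <= 1,
            selection_strength >= 0, niche_conservatism_sigma >= 0,
            decay_rate >= 0)
  if (!is.null(metacommunity)) {
    if (abs(sum(metacommunity) - 1) > 1e-12) stop("metacommunity must sum to 1")
    if (length(metacommunity) != n_taxa) stop("metacommunity length != n_taxa")
  }
  structure(list(n_stations = n_stations, groups = groups, n_taxa = n_taxa,
                 reads_per_sample = reads_per_sample,
                 metacommunity = metacommunity,
                 lognormal_sigma = lognormal_sigma,
                 migration_rate = migration_rate,
                 selection_strength = selection_strength,
                 niche_conservatism_sigma = niche_conservatism_sigma,
                 decay_rate = decay_rate, bbox = bbox, seed = seed),
            class = "assembly_scenario")
}

# Run code under a given seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

scenario_metacommunity <- function(scenario) {
  if (!is.null(scenario$metacommunity)) return(scenario$metacommunity)
  local_seed(scenario$seed * 7 + 1, {
    x <- rlnorm(scenario$n_taxa, meanlog = 0, sdlog = scenario$lognormal_sigma)
    x / sum(x)
  })
}

n_samples_of <- function(scenario) scenario$n_stations * length(scenario$groups)

sample_ids_of <- function(scenario) {
  grid <- expand.grid(group = scenario$groups,
                      station = seq_len(scenario$n_stations),
                      stringsAsFactors = FALSE)
  sprintf("%s_ST%02d", grid$group, grid$station)
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule tree with `n_taxa` leaves labelled `t1..tn`, rescaled to unit
#' root-to-tip depth.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric [ape::phylo] tree of depth 1.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  local_seed(seed * 11 + 2, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- paste0("t", seq_len(n_taxa))
    tree
  })
}

counts_from_weights <- function(weights, n_reads, sample_ids, taxon_ids) {
  counts <- t(apply(weights, 1, function(wr) {
    rmultinom(1, n_reads, wr / sum(wr))[, 1]
  }))
  dimnames(counts) <- list(sample_ids, taxon_ids)
  as_community(counts)
}

#' Simulate communities under Sloan neutral assembly
#'
#' Each sample's relative abundances are drawn from the stationary Sloan
#' distribution Beta(N m p_i, N m (1 - p_i)), renormalized, and counts drawn
#' multinomially with total N. `N m` is the quantity the neutral community
#' model fit later reports as `Nm`.
#'
#' @param scenario An [assembly_scenario()].
#' @param n_samples Number of samples; defaults to stations x groups.
#' @return Community tibble of counts.
#' @export
simulate_neutral <- function(scenario, n_samples = NULL) {
  p <- scenario_metacommunity(scenario)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  n_samples <- n_samples %||% n_samples_of(scenario)
  ids <- if (is.null(scenario$.sample_ids)) {
    sprintf("S%03d", seq_len(n_samples))
  } else scenario$.sample_ids
  nm <- scenario$reads_per_sample * scenario$migration_rate
  local_seed(scenario$seed * 13 + 3, {
    weights <- t(vapply(seq_len(n_samples), function(s) {
      x <- rbeta(length(p), nm * p, nm * (1 - p))
      x[!is.finite(x) | x < 0] <- 0
      if (sum(x) == 0) x <- p
      x / sum(x)
    }, numeric(length(p))))
    counts_from_weights(weights, scenario$reads_per_sample, ids,
                        paste0("t", seq_along(p)))
  })
}

#' Simulate communities under environmental selection
#'
#' Taxon niche optima evolve on the tree by Brownian motion (rate
#' `niche_conservatism_sigma`), so optima carry phylogenetic signal; the
#' sampling weight of taxon i in sample j is
#' `p_i * exp(-w * (env_j - opt_i)^2)` and counts are multinomial with the
#' scenario's read depth. `w = 0` collapses to multinomial sampling from the
#' metacommunity.
#'
#' @param scenario An [assembly_scenario()]; `selection_strength` is w.
#' @param tree Tree whose tips cover the scenario's taxa (`t1..tn`).
#' @param env_values Numeric vector, one environmental value per sample.
#' @return Community tibble of counts.
#' @export
simulate_selection <- function(scenario, tree, env_values) {
  p <- scenario_metacommunity(scenario)
  n_taxa <- length(p)
  if (!all(paste0("t", seq_len(n_taxa)) %in% tree$tip.label)) {
    stop("tree tips must cover taxa t1..tn")
  }
  w <- scenario$selection_strength
  if (w < 0) stop("selection_strength must be >= 0")
  local_seed(scenario$seed * 17 + 4, {
    opt <- if (scenario$niche_conservatism_sigma == 0) {
      setNames(rep(0, n_taxa), paste0("t", seq_len(n_taxa)))
    } else {
      ape::rTraitCont(tree, model = "BM",
                      sigma = scenario$niche_conservatism_sigma, root.value = 0)
    }
    opt <- opt[paste0("t", seq_len(n_taxa))]
    weights <- t(vapply(env_values, function(e) {
      wt <- p * exp(-w * (e - opt)^2)
      if (sum(wt) == 0) wt <- p
      wt
    }, numeric(n_taxa)))
    ids <- sprintf("S%03d", seq_along(env_values))
    counts_from_weights(weights, scenario$reads_per_sample, ids,
                        paste0("t", seq_len(n_taxa)))
  })
}

#' Simulate communities with distance-dependent turnover
#'
#' Each taxon is anchored at a random location in the scenario's bounding
#' box; its local metacommunity weight at a sample decays exponentially with
#' great-circle distance from the anchor at rate `decay_rate` (per meter), so
#' expected compositional similarity of two samples declines with their
#' geographic distance. `decay_rate = 0` yields exchangeable samples.
#'
#' @param scenario An [assembly_scenario()].
#' @param coords Data frame with columns `longitude`, `latitude`, one row per
#'   sample (and optionally `sample_id`).
#' @return Community tibble of counts.
#' @export
simulate_distance_decay <- function(scenario, coords) {
  p <- scenario_metacommunity(scenario)
  bb <- scenario$bbox
  if (any(coords$longitude < bb["lon_min"] | coords$longitude > bb["lon_max"] |
          coords$latitude < bb["lat_min"] | coords$latitude > bb["lat_max"])) {
    warning("some coordinates fall outside the scenario bounding box")
  }
  ids <- if ("sample_id" %in% names(coords)) {
    coords$sample_id
  } else {
    sprintf("S%03d", seq_len(nrow(coords)))
  }
  local_seed(scenario$seed * 19 + 5, {
    anchors <- cbind(runif(length(p), bb["lon_min"], bb["lon_max"]),
                     runif(length(p), bb["lat_min"], bb["lat_max"]))
    d <- geosphere::distm(cbind(coords$longitude, coords$latitude), anchors,
                          fun = function(x, y) {
                            geosphere::distHaversine(x, y, r = 6371000)
                          })
    weights <- sweep(exp(-scenario$decay_rate * d), 2, p, `*`)
    counts_from_weights(weights, scenario$reads_per_sample, ids,
                        paste0("t", seq_along(p)))
  })
}

# Sloan stationary sampling with an extra per-sample lognormal factor shared
# by members of the same guild (NA = no guild); collapses to simulate_neutral
# when guild_sd = 0 or no taxon has a guild.
simulate_neutral_guilds <- function(scenario, guild, guild_sd) {
  p <- scenario_metacommunity(scenario)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  n_samples <- n_samples_of(scenario)
  ids <- if (is.null(scenario$.sample_ids)) {
    sprintf("S%03d", seq_len(n_samples))
  } else scenario$.sample_ids
  nm <- scenario$reads_per_sample * scenario$migration_rate
  n_guilds <- max(guild, na.rm = TRUE)
  local_seed(scenario$seed * 13 + 3, {
    weights <- t(vapply(seq_len(n_samples), function(s) {
      x <- rbeta(length(p), nm * p, nm * (1 - p))
      x[!is.finite(x) | x < 0] <- 0
      if (sum(x) == 0) x <- p
      fac <- exp(rnorm(n_guilds, 0, guild_sd))
      mult <- ifelse(is.na(guild), 1, fac[ifelse(is.na(guild), 1, guild)])
      w <- x * mult
      w / sum(w)
    }, numeric(length(p))))
    counts_from_weights(weights, scenario$reads_per_sample, ids,
                        paste0("t", seq_along(p)))
  })
}

#' Generate the full synthetic estuary survey fixture
#'
#' Emulates a one-degree estuarine survey: 21 stations on a grid in
#' 125-126 E / 30-31 N, each sampled in three water layers plus sediment.
#' Water-layer communities are generated under drift-dominated neutral
#' assembly (low migration), sediment under homogenizing-dispersal-leaning
#' assembly (high migration). Environmental variables are generated so that
#' NH4-N correlates positively with PO4-P and NO2-N and negatively with
#' NO3-N and pH.
#'
#' A minority of taxa (default 30%) belong to cooperative guilds whose
#' members share a per-sample lognormal abundance factor in the sediment
#' habitat, planting the positive co-occurrence structure that correlation
#' networks detect (and making the sediment network denser than the
#' water-layer networks); guild effects are independent of the phylogeny
#' and of space, and the water layers stay purely neutral.
#'
#' @param seed Integer seed.
#' @param n_taxa Number of taxa in the shared metacommunity.
#' @param reads_per_sample Read depth per sample.
#' @param water_m Migration rate for the water-layer groups.
#' @param sediment_m Migration rate for the sediment group.
#' @param n_guilds Number of cooperative guilds.
#' @param guild_sd Lognormal standard deviation of the shared guild factor.
#' @param guild_fraction Fraction of taxa assigned to a guild.
#' @param guild_groups Habitat groups whose samples express the guild
#'   factors (default sediment only, keeping the water-layer groups purely
#'   neutral).
#' @return List with `community`, `tree`, `metadata`, and the per-group
#'   `scenarios` used.
#' @export
simulate_estuary_survey <- function(seed = 1, n_taxa = 300,
                                    reads_per_sample = 1000,
                                    water_m = 0.1, sediment_m = 0.8,
                                    n_guilds = 6, guild_sd = 1.5,
                                    guild_fraction = 0.3,
                                    guild_groups = "sediment") {
  n_stations <- 21
  groups <- c("surface", "middle", "bottom", "sediment")
  tree <- simulate_tree(n_taxa, seed = seed)
  base <- assembly_scenario(n_stations = n_stations, groups = groups,
                            n_taxa = n_taxa,
                            reads_per_sample = reads_per_sample, seed = seed)
  p <- scenario_metacommunity(base)

  # 5x5 grid clipped to 21 stations
  gx <- seq(125.1, 125.9, length.out = 5)
  gy <- seq(30.1, 30.9, length.out = 5)
  grid <- expand.grid(longitude = gx, latitude = gy)[seq_len(n_stations), ]

  meta <- local_seed(seed * 23 + 6, {
    s <- scale(grid$longitude + grid$latitude)[, 1] + rnorm(n_stations, 0, 0.4)
    station <- tibble::tibble(
      station = sprintf("ST%02d", seq_len(n_stations)),
      longitude = grid$longitude, latitude = grid$latitude,
      `NH4-N` = round(pmax(0.15 + 0.08 * s + rnorm(n_stations, 0, 0.015), 0.01), 4),
      `PO4-P` = round(pmax(0.030 + 0.012 * s + rnorm(n_stations, 0, 0.004), 0.001), 4),
      `NO2-N` = round(pmax(0.012 + 0.006 * s + rnorm(n_stations, 0, 0.002), 0.001), 4),
      `NO3-N` = round(pmax(0.60 - 0.15 * s + rnorm(n_stations, 0, 0.04), 0.05), 4),
      pH = round(8.10 - 0.12 * s + rnorm(n_stations, 0, 0.03), 3))
    tidyr::crossing(group = groups, station = station$station) |>
      dplyr::left_join(station, by = "station") |>
      dplyr::mutate(sample_id = paste0(.data$group, "_", .data$station)) |>
      dplyr::relocate("sample_id") |>
      dplyr::arrange(.data$sample_id)
  })

  group_m <- c(surface = water_m, middle = water_m, bottom = water_m,
               sediment = sediment_m)
  guild <- local_seed(seed * 29 + 7, {
    g <- sample.int(n_guilds, n_taxa, replace = TRUE)
    g[runif(n_taxa) >= guild_fraction] <- NA_integer_
    g
  })
  scenarios <- lapply(groups, function(g) {
    sc <- assembly_scenario(n_stations = n_stations, groups = g,
                            n_taxa = n_taxa, metacommunity = p,
                            reads_per_sample = reads_per_sample,
                            migration_rate = group_m[[g]],
                            seed = seed * 100 + match(g, groups))
    sc$.sample_ids <- paste0(g, "_", sprintf("ST%02d", seq_len(n_stations)))
    sc
  })
  names(scenarios) <- groups
  parts <- lapply(groups, function(g) {
    if (g %in% guild_groups) {
      simulate_neutral_guilds(scenarios[[g]], guild = guild,
                              guild_sd = guild_sd)
    } else {
      simulate_neutral(scenarios[[g]])
    }
  })
  m <- do.call(rbind, lapply(parts, comm_matrix))
  m <- m[sort(rownames(m)), , drop = FALSE]
  list(community = as_community(m), tree = tree,
       metadata = meta[match(rownames(m), meta$sample_id), ],
       scenarios = scenarios)
}
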