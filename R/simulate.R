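# Synthetic reservoir survey generator. Sites sit on a 1-D river axis
# ordered by distance to the dam; species occupancy combines a Gaussian
# niche window along the axis (turnover knob) with an ordered retention
# threshold (nestedness knob), and counts/biomass follow log-normal x
# Poisson structure. Defaults emulate a 9-site, 23-species reservoir survey
# with roughly 11 species, 135 individuals and 8 kg per site.

#' Scenario specification for the synthetic survey generator
#'
#' @param n_sites Number of sites along the river axis (>= 3).
#' @param n_species Species-pool size.
#' @param gradient_strength >= 0; shrinks each species' occupancy window
#'   along the axis, dialing species replacement (turnover). 0 = every
#'   species' window covers the whole axis.
#' @param nestedness_strength >= 0; spreads species' retention thresholds
#'   so richness erodes in a fixed species order with distance from the
#'   dam, dialing nestedness. 0 = no ordered loss.
#' @param abundance_sigma Log-normal sigma of the per-species abundance
#'   scale.
#' @param invader_fraction Proportion of the pool forced present at every
#'   site (invasive species caught everywhere).
#' @param phylo_signal >= 0; Brownian-motion weight tying niche optima to
#'   the phylogeny, so phylogenetic beta tracks taxonomic beta when > 0.
#' @param mean_count Expected individuals per occupied cell at a fully
#'   suitable site.
#' @param mean_mass_kg Median individual mass (kg) across species.
#' @param env_noise Observation-noise multiplier for environmental trends
#'   (1 = calibrated default, 0 = noise-free).
#' @param river_length_km Length of the sampled river axis.
#' @param seed Integer seed used by the `simulate_*` functions.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(n_sites = 9, n_species = 23,
                          gradient_strength = 2, nestedness_strength = 0.3,
                          abundance_sigma = 1, invader_fraction = 2 / 23,
                          phylo_signal = 0, mean_count = 8,
                          mean_mass_kg = 0.038, env_noise = 1,
                          river_length_km = 40, seed = 1) {
  if (n_sites < 3) abort("n_sites must be at least 3")
  if (n_species < 2) abort("n_species must be at least 2")
  if (gradient_strength < 0 || nestedness_strength < 0) {
    abort("strengths must be non-negative")
  }
  if (invader_fraction < 0 || invader_fraction > 1) {
    abort("invader_fraction must be in [0, 1]")
  }
  structure(
    list(n_sites = n_sites, n_species = n_species,
         gradient_strength = gradient_strength,
         nestedness_strength = nestedness_strength,
         abundance_sigma = abundance_sigma,
         invader_fraction = invader_fraction, phylo_signal = phylo_signal,
         mean_count = mean_count, mean_mass_kg = mean_mass_kg,
         env_noise = env_noise, river_length_km = river_length_km,
         seed = seed),
    class = "scenario_spec"
  )
}

#' Simulate an ultrametric species-pool phylogeny
#'
#' Pure-birth (Yule) tree rescaled to height 1, tips `sp001..spN`.
#' Deterministic given the seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric `ape::phylo` tree of height 1.
#' @export
simulate_phylogeny <- function(n_species, seed = 1) {
  if (n_species < 2) abort("n_species must be at least 2")
  set.seed(seed)
  tree <- if (n_species == 2) {
    ape::read.tree(text = "(sp001:1,sp002:1);")
  } else {
    ape::rphylo(n_species, birth = 1, death = 0)
  }
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate river geometry
#'
#' Sites are ordered along the river with increasing distance to the dam;
#' pairwise river distance is the absolute difference of axis positions.
#' An optional tributary puts some sites on a branch joining the mainstem
#' at `branch_at_km`, making distances non-Euclidean in one dimension:
#' the distance between a mainstem and a tributary site runs through the
#' junction.
#'
#' @param n_sites Number of sites (>= 2).
#' @param river_length_km Axis length (dam at 0).
#' @param seed Integer seed (placement jitter).
#' @param branch_sites Integer indices of sites moved onto the tributary
#'   (empty = single channel).
#' @param branch_at_km Junction position of the tributary on the mainstem.
#' @return A `river_layout` (see [read_layout()]).
#' @export
simulate_layout <- function(n_sites, river_length_km = 40, seed = 1,
                            branch_sites = integer(0), branch_at_km = NULL) {
  if (n_sites < 2) abort("n_sites must be at least 2")
  set.seed(seed)
  gap <- river_length_km / n_sites
  pos <- seq(gap, river_length_km, length.out = n_sites)
  if (n_sites > 2) {
    pos <- sort(pos + runif(n_sites, -0.2 * gap, 0.2 * gap))
  }
  sites <- sprintf("S%d", seq_len(n_sites))
  on_branch <- seq_len(n_sites) %in% branch_sites
  if (any(on_branch)) {
    branch_at_km <- branch_at_km %||% (river_length_km / 2)
    # branch offset of a tributary site = how far past the junction it sits
    offset <- ifelse(on_branch, pmax(pos - branch_at_km, 0.1 * gap), 0)
    main_pos <- ifelse(on_branch, branch_at_km, pos)
    dam_km <- main_pos + offset
    pd <- matrix(0, n_sites, n_sites, dimnames = list(sites, sites))
    for (i in seq_len(n_sites)) {
      for (j in seq_len(n_sites)) {
        if (on_branch[i] == on_branch[j]) {
          pd[i, j] <- abs((main_pos[i] + offset[i]) - (main_pos[j] + offset[j]))
        } else {
          pd[i, j] <- abs(main_pos[i] - branch_at_km) + offset[i] +
            abs(main_pos[j] - branch_at_km) + offset[j]
        }
      }
    }
    diag(pd) <- 0
  } else {
    dam_km <- pos
    pd <- abs(outer(pos, pos, "-"))
    dimnames(pd) <- list(sites, sites)
  }
  new_layout(tibble(site = sites, dam_km = dam_km), pd)
}

# Default trend set: four variables increase away from the dam (one
# saturating), two decrease (one saturating), five are pure noise.
# base/amplitude are in each variable's natural units; noise_sd is the
# Gaussian observation noise at env_noise = 1.
default_env_trends <- function() {
  tibble(
    variable = c("WT", "pH", "WD", "NTU", "CODMn", "COD", "TP", "TN",
                 "SO4", "NN", "CHL.a"),
    trend = c("none", "none", "decrease", "increase", "increase",
              "increase", "none", "increase", "decrease", "none", "none"),
    shape = c("linear", "linear", "linear", "linear", "saturating", "linear",
              "linear", "linear", "saturating", "linear", "linear"),
    base = c(16, 8, 60, 2, 2, 10, 0.05, 1, 20, 0.02, 5),
    amplitude = c(0, 0, -40, 6, 3, 8, 0, 1.5, -15, 0, 0),
    noise_sd = c(0.5, 0.2, 1.5, 0.4, 0.2, 0.6, 0.01, 0.1, 0.8, 0.005, 1)
  )
}

#' Simulate the environmental table along the dam-distance gradient
#'
#' Eleven water-quality variables: four increase with distance from the dam
#' (permanganate index saturating), two decrease (sulfate saturating, water
#' depth linear), and five are pure noise; Gaussian observation noise is
#' scaled by `spec$env_noise`.
#'
#' @param spec A [scenario_spec()].
#' @param layout A `river_layout` giving each site's dam distance.
#' @param trends Optional trend table overriding `default_env_trends()`.
#' @return Environment tibble (`site` + 11 variables).
#' @export
simulate_environment <- function(spec, layout, trends = NULL) {
  trends <- trends %||% default_env_trends()
  set.seed(spec$seed + 211)
  d <- layout$dam_distance$dam_km
  dn <- d / max(d)
  env <- tibble(site = layout$dam_distance$site)
  for (k in seq_len(nrow(trends))) {
    tr <- trends[k, ]
    signal <- if (tr$trend == "none") {
      rep(0, length(dn))
    } else if (tr$shape == "saturating") {
      tr$amplitude * (1 - exp(-3 * dn)) / (1 - exp(-3))
    } else {
      tr$amplitude * dn
    }
    noise <- rnorm(length(dn), 0, tr$noise_sd * spec$env_noise)
    env[[tr$variable]] <- tr$base + signal + noise
  }
  env
}

#' Simulate a survey table from a scenario
#'
#' Species occupancy is deterministic given the draws of the niche optima
#' and retention ranks: a species occupies the sites inside its Gaussian
#' niche window (half-width 0.5/(1 + gradient_strength) on the unit axis)
#' that also fall below its retention threshold
#' (exp(-nestedness_strength * rank)); invaders are present everywhere.
#' Counts are Poisson around a log-normal species abundance scale times the
#' suitability at the site (minimum 1 where present); biomass is count
#' times a log-normal species mean mass. Every species is guaranteed at
#' least one occurrence (its best site) and every site at least two
#' species, so generated tables pass [validate_survey()] silently.
#'
#' @param spec A [scenario_spec()].
#' @param tree Species-pool tree with `spec$n_species` tips (used when
#'   `phylo_signal > 0` to give niche optima Brownian structure).
#' @param layout Optional `river_layout`; generated from the spec when
#'   `NULL`.
#' @return A validated survey tibble.
#' @export
simulate_survey <- function(spec, tree, layout = NULL) {
  if (length(tree$tip.label) != spec$n_species) {
    abort("tree tip count must equal spec$n_species")
  }
  layout <- layout %||% simulate_layout(spec$n_sites, spec$river_length_km,
                                        seed = spec$seed)
  set.seed(spec$seed + 101)
  sites <- layout$dam_distance$site
  x <- layout$dam_distance$dam_km / max(layout$dam_distance$dam_km)
  nsp <- spec$n_species
  species <- tree$tip.label

  # niche optima on the unit axis, optionally with Brownian signal
  if (spec$phylo_signal > 0) {
    bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    u_raw <- (1 - spec$phylo_signal) * stats::rnorm(nsp) +
      spec$phylo_signal * as.numeric(scale(bm[species]))
    u <- (rank(u_raw) - 0.5) / nsp
  } else {
    u <- runif(nsp)
  }
  # half-width 1 at gradient 0 covers the whole unit axis (x, u in [0, 1])
  half_width <- 1 / (1 + spec$gradient_strength)
  # stretch optima a little past both ends of the axis so species slide in
  # and out in both directions (replacement) rather than piling richness
  # mid-axis (which would read as nestedness)
  u <- -0.5 * half_width + u * (1 + half_width)
  retention_rank <- runif(nsp)
  threshold <- exp(-spec$nestedness_strength * retention_rank)
  n_invaders <- ceiling(spec$invader_fraction * nsp)
  invaders <- if (n_invaders > 0) sample.int(nsp, n_invaders) else integer(0)

  suit <- matrix(0, length(sites), nsp, dimnames = list(sites, species))
  present <- matrix(FALSE, length(sites), nsp, dimnames = list(sites, species))
  for (k in seq_len(nsp)) {
    g <- exp(-((x - u[k]) / (2 * half_width))^2)
    window <- abs(x - u[k]) <= half_width
    retained <- x <= threshold[k]
    present[, k] <- (window & retained) | (k %in% invaders)
    suit[, k] <- pmax(g, 0.05)
  }
  # Guarantee every species somewhere: place it where its suitability is
  # highest among sites close to (or below) its retention threshold, which
  # keeps forced occurrences consistent with the nested richness gradient.
  for (k in seq_len(nsp)) {
    if (!any(present[, k])) {
      score <- suit[, k] * exp(-5 * pmax(0, x - threshold[k]))
      present[which.max(score), k] <- TRUE
    }
  }
  for (s in seq_along(sites)) {
    if (sum(present[s, ]) < 2) {
      need <- 2 - sum(present[s, ])
      candidates <- order(suit[s, ], decreasing = TRUE)
      candidates <- candidates[!present[s, candidates]]
      present[s, candidates[seq_len(need)]] <- TRUE
    }
  }

  abundance_scale <- rlnorm(nsp, log(spec$mean_count), spec$abundance_sigma)
  mean_mass <- rlnorm(nsp, log(spec$mean_mass_kg), 0.8)
  rows <- list()
  for (s in seq_along(sites)) {
    for (k in seq_len(nsp)) {
      if (!present[s, k]) next
      cnt <- 1 + rpois(1, abundance_scale[k] * suit[s, k])
      rows[[length(rows) + 1]] <- tibble(
        site = sites[s], species = species[k], count = cnt,
        biomass = cnt * mean_mass[k]
      )
    }
  }
  validate_survey(list_rbind(rows))
}

#' Simulate a full scenario: tree, layout, environment and survey
#'
#' @param spec A [scenario_spec()].
#' @return List with `spec`, `tree`, `layout`, `env`, `survey` — mutually
#'   consistent inputs for [run_pipeline()].
#' @export
simulate_scenario <- function(spec = scenario_spec()) {
  tree <- simulate_phylogeny(spec$n_species, seed = spec$seed)
  layout <- simulate_layout(spec$n_sites, spec$river_length_km,
                            seed = spec$seed)
  env <- simulate_environment(spec, layout)
  survey <- simulate_survey(spec, tree, layout)
  list(spec = spec, tree = tree, layout = layout, env = env, survey = survey)
}
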