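# Shared fixtures and independent oracles. Oracles deliberately take a
# different computational route from the package implementation.

tree_abc <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# small survey with every site non-empty and every species somewhere
make_random_survey <- function(n_sites = 6, n_species = 10, seed = 1,
                               p_occ = 0.5) {
  set.seed(seed)
  sites <- paste0("S", seq_len(n_sites))
  species <- paste0("t", seq_len(n_species))
  pres <- matrix(runif(n_sites * n_species) < p_occ, n_sites, n_species)
  for (k in seq_len(n_species)) if (!any(pres[, k])) {
    pres[sample.int(n_sites, 1), k] <- TRUE
  }
  for (s in seq_len(n_sites)) if (sum(pres[s, ]) < 2) {
    pres[s, sample.int(n_species, 2)] <- TRUE
  }
  rows <- which(pres, arr.ind = TRUE)
  tibble::tibble(
    site = sites[rows[, 1]], species = species[rows[, 2]],
    count = sample(1:20, nrow(rows), replace = TRUE),
    biomass = round(runif(nrow(rows), 0.05, 3), 3)
  ) |> dplyr::mutate(biomass = .data$biomass * .data$count)
}

# Brute-force Faith PD: for every edge, find the tips below it via
# extract.clade and test intersection with the community.
pd_edge_union_oracle <- function(community, tree, include_root = TRUE) {
  ntip <- length(tree$tip.label)
  total <- 0
  n_comm <- length(unique(community))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- if (child <= ntip) tree$tip.label[child]
             else ape::extract.clade(tree, child)$tip.label
    hit <- length(intersect(below, community))
    on <- hit > 0 && (include_root || hit < n_comm)
    if (on) total <- total + tree$edge.length[e]
  }
  total
}

# Unweighted mean pairwise distance by explicit double loop.
mpd_double_loop_oracle <- function(species, tree) {
  D <- ape::cophenetic.phylo(tree)
  tot <- 0; npairs <- 0
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (j <= i) next
      tot <- tot + D[species[i], species[j]]
      npairs <- npairs + 1
    }
  }
  tot / npairs
}

# Benjamini-Hochberg step-up by the explicit min-over-tail definition:
# for the i-th smallest p, adjusted = min over j >= i of min(1, p_(j) n / j).
bh_brute_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (pos in seq_len(n)) {
    tail_vals <- vapply(pos:n, function(j) p[ord[j]] * n / j, numeric(1))
    adj[ord[pos]] <- min(1, tail_vals)
  }
  adj
}

# Closed-form simple linear regression.
ols_closed_form <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- cor(x, y)^2
  list(slope = b, intercept = a, r2 = r2)
}

expect_no_warning <- function(expr) {
  expect_warning(expr, regexp = NA)
}
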