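# Pairwise Sorensen beta-diversity partitioned into turnover and nestedness
# at the taxonomic (species sets) and phylogenetic (shared/unique branch
# length) levels, plus the beta-deviation contrast between levels.

#' Shared/unique species counts for a site pair
#'
#' @param community_i,community_j Character vectors of species present.
#' @return Named vector `c(a, b, c)`: shared, unique to i, unique to j.
#' @export
abc_taxonomic <- function(community_i, community_j) {
  community_i <- unique(community_i)
  community_j <- unique(community_j)
  if (length(community_i) == 0 || length(community_j) == 0) {
    abort("beta-diversity is undefined for an empty community")
  }
  c(a = length(intersect(community_i, community_j)),
    b = length(setdiff(community_i, community_j)),
    c = length(setdiff(community_j, community_i)))
}

#' Shared/unique branch lengths for a site pair
#'
#' Components of phylogenetic Sorensen dissimilarity: `a` is the total
#' length of branches on both communities' spanning subtrees, `b` the
#' length found only on community i's subtree, `c` only on j's. Subtrees
#' include the root path by default, mirroring [faith_pd()], so that
#' a + b = PD(i) and a + c = PD(j).
#'
#' @param community_i,community_j Character vectors of species present.
#' @param tree Tree covering both communities.
#' @param include_root Include root paths (default `TRUE`).
#' @return Named vector `c(a, b, c)` in branch-length units.
#' @export
abc_phylogenetic <- function(community_i, community_j, tree,
                             include_root = TRUE) {
  machine <- pd_machine(tree)
  abc_phylo_machine(unique(community_i), unique(community_j), tree$tip.label,
                    machine, include_root)
}

abc_phylo_machine <- function(community_i, community_j, tips, machine,
                              include_root) {
  if (length(community_i) == 0 || length(community_j) == 0) {
    abort("beta-diversity is undefined for an empty community")
  }
  idx_i <- match(community_i, tips)
  idx_j <- match(community_j, tips)
  if (anyNA(idx_i) || anyNA(idx_j)) abort("species not in tree")
  edge_set <- function(idx) {
    counts <- colSums(machine$inc[idx, , drop = FALSE])
    on <- counts > 0L
    if (!include_root) on <- on & counts < length(idx)
    on
  }
  ei <- edge_set(idx_i)
  ej <- edge_set(idx_j)
  c(a = sum(machine$len[ei & ej]),
    b = sum(machine$len[ei & !ej]),
    c = sum(machine$len[!ei & ej]))
}

#' Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' Baselga's pairwise decomposition from shared (`a`) and unique (`b`, `c`)
#' components: beta_sor = (b + c) / (2a + b + c); turnover
#' beta_sim = min(b, c) / (a + min(b, c)); nestedness
#' beta_sne = beta_sor - beta_sim. The additive identity holds exactly and
#' all three lie in \[0, 1\]. Works equally on species counts and on branch
#' lengths.
#'
#' @param a,b,c Non-negative shared/unique components (vectorized).
#' @return Tibble `beta_sor`, `beta_turn`, `beta_nes`.
#' @examples
#' sorensen_partition(2, 1, 3)  # 0.5 = 1/3 + 1/6
#' @export
sorensen_partition <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0)) abort("a, b, c must be non-negative")
  if (any(a + b <= 0 | a + c <= 0)) {
    abort("each community must have a positive component (a+b > 0 and a+c > 0)")
  }
  bmin <- pmin(b, c)
  beta_sor <- (b + c) / (2 * a + b + c)
  beta_turn <- ifelse(bmin == 0, 0, bmin / (a + bmin))
  tibble(beta_sor = beta_sor, beta_turn = beta_turn,
         beta_nes = beta_sor - beta_turn)
}

#' Pairwise beta-diversity at taxonomic and phylogenetic levels
#'
#' Counts are collapsed to presence/absence; every unordered site pair gets
#' a (total, turnover, nestedness) Sorensen triple at the taxonomic level
#' and, when a tree is supplied, at the phylogenetic level.
#'
#' @param survey Survey tibble with at least 2 sites.
#' @param tree Optional tree covering all surveyed species; `NULL` for
#'   taxonomic-only output.
#' @param include_root Passed to the phylogenetic components.
#' @return Long tibble: `site_i`, `site_j`, `level`, `beta_sor`,
#'   `beta_turn`, `beta_nes`. Pairs involving a site with no species are
#'   `NA` with a warning.
#' @export
beta_pairs <- function(survey, tree = NULL, include_root = TRUE) {
  m <- survey_matrix(survey, "presence")
  if (nrow(m) < 2) abort("beta-diversity needs at least 2 sites")
  if (ncol(m) < 2) abort("beta-diversity needs at least 2 species")
  sites <- rownames(m)
  comm <- lapply(sites, function(s) colnames(m)[m[s, ] > 0])
  names(comm) <- sites
  empty <- sites[lengths(comm) == 0]
  if (length(empty) > 0) {
    warn(paste0("site(s) with no species; their pairs are NA: ",
                paste(empty, collapse = ", ")))
  }
  if (!is.null(tree)) {
    missing_sp <- setdiff(colnames(m), tree$tip.label)
    if (length(missing_sp) > 0) {
      abort(paste0("species not in tree: ", paste(missing_sp, collapse = ", ")))
    }
    machine <- pd_machine(tree)
  }
  prs <- combn(sites, 2)
  one_level <- function(level) {
    triples <- map(seq_len(ncol(prs)), function(k) {
      si <- prs[1, k]; sj <- prs[2, k]
      if (length(comm[[si]]) == 0 || length(comm[[sj]]) == 0) {
        return(tibble(site_i = si, site_j = sj, level = level,
                      beta_sor = NA_real_, beta_turn = NA_real_,
                      beta_nes = NA_real_))
      }
      abc <- if (level == "taxonomic") {
        abc_taxonomic(comm[[si]], comm[[sj]])
      } else {
        abc_phylo_machine(comm[[si]], comm[[sj]], tree$tip.label, machine,
                          include_root)
      }
      part <- sorensen_partition(abc[["a"]], abc[["b"]], abc[["c"]])
      bind_cols(tibble(site_i = si, site_j = sj, level = level), part)
    })
    list_rbind(triples)
  }
  out <- one_level("taxonomic")
  if (!is.null(tree)) out <- bind_rows(out, one_level("phylogenetic"))
  out
}

#' Summaries of pairwise beta-diversity per level
#'
#' Mean total, turnover and nestedness over all pairs, and the turnover
#' share computed as a ratio of means (100 * mean turnover / mean total),
#' the convention under which turnover and nestedness shares add to 100%.
#'
#' @param pairs Output of [beta_pairs()].
#' @return Tibble with one row per level: `level`, `n_pairs`, `mean_sor`,
#'   `mean_turn`, `mean_nes`, `turnover_share`, `nestedness_share`.
#' @export
beta_summary <- function(pairs) {
  pairs |>
    group_by(.data$level) |>
    summarise(
      n_pairs = sum(!is.na(.data$beta_sor)),
      mean_sor = mean(.data$beta_sor, na.rm = TRUE),
      mean_turn = mean(.data$beta_turn, na.rm = TRUE),
      mean_nes = mean(.data$beta_nes, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      turnover_share = ifelse(.data$mean_sor > 0,
                              100 * .data$mean_turn / .data$mean_sor, NA_real_),
      nestedness_share = ifelse(.data$mean_sor > 0,
                                100 * .data$mean_nes / .data$mean_sor, NA_real_)
    )
}

#' Beta-deviation between taxonomic and phylogenetic dissimilarity
#'
#' (beta_tax - beta_phy) / beta_tax, evaluated on the mean pairwise values.
#' Positive values indicate communities holding many endemics that are
#' phylogenetically close (taxonomic dissimilarity exceeds phylogenetic);
#' negative values indicate sharing of distantly related species.
#'
#' @param mean_beta_tax Mean taxonomic Sorensen dissimilarity (> 0).
#' @param mean_beta_phy Mean phylogenetic Sorensen dissimilarity.
#' @return The deviation (<= 1); `NA` when `mean_beta_tax` is 0.
#' @examples
#' beta_deviation(0.33, 0.26)  # 0.2121
#' @export
beta_deviation <- function(mean_beta_tax, mean_beta_phy) {
  if (is.na(mean_beta_tax) || mean_beta_tax == 0) return(NA_real_)
  (mean_beta_tax - mean_beta_phy) / mean_beta_tax
}

#' Effect size of the taxonomic vs phylogenetic contrast
#'
#' Cohen's d on the chosen beta component across site pairs, signed
#' phylogenetic minus taxonomic so that d is negative when taxonomic
#' dissimilarity is the larger (the reservoir-survey convention); 95% CI by
#' the normal approximation of d's standard error; p from Welch's
#' two-sample t test.
#'
#' @param pairs Output of [beta_pairs()] containing both levels.
#' @param component `"sor"`, `"turn"`, or `"nes"`.
#' @return One-row tibble: `component`, `mean_tax`, `mean_phy`, `cohens_d`,
#'   `ci_low`, `ci_high`, `p`, `n_pairs`.
#' @export
compare_levels <- function(pairs, component = c("sor", "turn", "nes")) {
  component <- match.arg(component)
  col <- paste0("beta_", ifelse(component == "sor", "sor", component))
  x_tax <- pairs[[col]][pairs$level == "taxonomic"]
  x_phy <- pairs[[col]][pairs$level == "phylogenetic"]
  x_tax <- x_tax[!is.na(x_tax)]
  x_phy <- x_phy[!is.na(x_phy)]
  if (length(x_tax) != length(x_phy)) abort("unequal pair counts across levels")
  if (length(x_tax) < 2) {
    return(tibble(component = component, mean_tax = NA_real_,
                  mean_phy = NA_real_, cohens_d = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, p = NA_real_, n_pairs = length(x_tax)))
  }
  d <- cohens_d(x_phy, x_tax)
  n1 <- length(x_phy); n2 <- length(x_tax)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  p <- t.test(x_phy, x_tax)$p.value
  tibble(component = component, mean_tax = mean(x_tax), mean_phy = mean(x_phy),
         cohens_d = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
         p = p, n_pairs = n1)
}

# Pooled-SD Cohen's d of x relative to y.
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y)))
  (mean(x) - mean(y)) / sp
}
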