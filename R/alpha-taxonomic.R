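# Taxonomic alpha-diversity, dominance (IRI), and sampling completeness.

#' Margalef richness index
#'
#' (S - 1) / ln N. Zero for a single species; `NA` when no individuals.
#'
#' @param S Number of species.
#' @param N Number of individuals.
#' @return Numeric (vectorized).
#' @export
margalef <- function(S, N) {
  out <- ifelse(N < 1, NA_real_, ifelse(S <= 1, 0, (S - 1) / log(N)))
  as.numeric(out)
}

#' Shannon diversity (natural log)
#'
#' @param abundances Non-negative vector; zeros are dropped.
#' @return H' in nats.
#' @export
shannon <- function(abundances) {
  x <- abundances[abundances > 0]
  if (length(x) == 0) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' H' / ln S with H' in nats, so a perfectly even community scores 1.
#' Undefined (`NA`) for fewer than two species with positive abundance.
#'
#' @param abundances Non-negative vector; zeros are dropped.
#' @return Evenness in (0, 1], or `NA`.
#' @examples
#' pielou(c(10, 10, 10))  # 1
#' @export
pielou <- function(abundances) {
  x <- abundances[abundances > 0]
  if (length(x) < 2) return(NA_real_)
  shannon(x) / log(length(x))
}

#' Per-site divergence from the community centroid (Hellinger space)
#'
#' Each site's counts are Hellinger-transformed (square root of within-site
#' relative abundance); the divergence is the Euclidean distance from the
#' site's transformed profile to the centroid (arithmetic mean of the
#' transformed rows). Zero everywhere iff all sites share the same relative
#' composition; invariant to rescaling any one site's counts.
#'
#' @param survey Survey tibble with at least 2 sites.
#' @return Tibble `site`, `hellinger_div`. A site with zero total count gets
#'   `NA` with a warning.
#' @export
hellinger_divergence <- function(survey) {
  m <- survey_matrix(survey, "count")
  if (nrow(m) < 2) abort("hellinger_divergence needs at least 2 sites")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warn(paste0("site(s) with zero total count: ",
                paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  H <- vegan::decostand(m[tot > 0, , drop = FALSE], method = "hellinger")
  centroid <- colMeans(H)
  d <- sqrt(rowSums(sweep(H, 2, centroid)^2))
  tibble(site = rownames(m),
         hellinger_div = unname(d[match(rownames(m), names(d))]))
}

#' Taxonomic alpha-diversity table
#'
#' One row per site: richness `S`, individuals `N`, Margalef richness,
#' Shannon H' (nats), Pielou evenness, and the Hellinger divergence from
#' the community centroid.
#'
#' @param survey Survey tibble.
#' @return A tibble with one row per site.
#' @export
alpha_taxonomic <- function(survey) {
  m <- survey_matrix(survey, "count")
  hel <- hellinger_divergence(survey)
  base <- tibble(
    site = rownames(m),
    S = apply(m, 1, function(x) sum(x > 0)),
    N = rowSums(m),
    margalef = margalef(apply(m, 1, function(x) sum(x > 0)), rowSums(m)),
    shannon = apply(m, 1, shannon),
    pielou = apply(m, 1, pielou)
  )
  left_join(base, hel, by = "site")
}

#' IRI from occurrence, abundance and biomass proportions
#'
#' IRI = 10000 * Fi * (Ni + Wi), with all three inputs as proportions in
#' \[0, 1\] (not percentages), bounding the index by 20000.
#'
#' @param fi Occurrence frequency (proportion of sites occupied).
#' @param ni Proportion of all individuals belonging to the species.
#' @param wi Proportion of all biomass.
#' @return Numeric IRI (vectorized).
#' @export
iri_score <- function(fi, ni, wi) {
  if (any(fi < 0 | fi > 1 | ni < 0 | ni > 1 | wi < 0 | wi > 1, na.rm = TRUE)) {
    abort("fi, ni, wi must be proportions in [0, 1]")
  }
  10000 * fi * (ni + wi)
}

#' Classify IRI values into dominance classes
#'
#' Above the dominant threshold (strict) is "dominant"; between the two
#' thresholds (inclusive) is "common"; below the common threshold is "rare".
#'
#' @param iri Numeric IRI values.
#' @param thresholds `c(dominant, common)`, strictly ordered; default
#'   `c(500, 100)`.
#' @return Character vector of classes.
#' @export
iri_classify <- function(iri, thresholds = c(500, 100)) {
  if (length(thresholds) != 2 || !(thresholds[1] > thresholds[2])) {
    abort("thresholds must be c(dominant, common) with dominant > common")
  }
  ifelse(iri > thresholds[1], "dominant",
         ifelse(iri >= thresholds[2], "common", "rare"))
}

#' Index of relative importance per species
#'
#' Fi = occupied sites / total sites; Ni and Wi are pool-wide proportions of
#' individuals and biomass. Species are classified by [iri_classify()].
#'
#' @param survey Survey tibble.
#' @param thresholds Dominance thresholds, see [iri_classify()].
#' @return Tibble sorted by decreasing IRI: `species`, `fi`, `ni`, `wi`,
#'   `iri`, `class`.
#' @export
iri_table <- function(survey, thresholds = c(500, 100)) {
  cm <- survey_matrix(survey, "count")
  bm <- survey_matrix(survey, "biomass")
  n_sites <- nrow(cm)
  fi <- colSums(cm > 0) / n_sites
  ni <- colSums(cm) / sum(cm)
  tot_b <- sum(bm)
  if (tot_b == 0 && sum(cm) > 0) {
    warn("total biomass is zero; Wi term set to 0")
    wi <- rep(0, ncol(bm))
  } else {
    wi <- colSums(bm) / tot_b
  }
  out <- tibble(
    species = colnames(cm), fi = unname(fi), ni = unname(ni), wi = unname(wi),
    iri = iri_score(unname(fi), unname(ni), unname(wi))
  )
  out$class <- iri_classify(out$iri, thresholds)
  arrange(out, desc(.data$iri))
}

#' Abundance-based sample coverage
#'
#' The coverage estimator from singleton/doubleton counts:
#' C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2)), where f1 and f2 are the
#' numbers of species observed exactly once and twice and n the total count.
#' Equals 1 when there are no singletons.
#'
#' @param abundances Pooled per-species counts.
#' @return Coverage in \[0, 1\]; `NA` for an empty sample.
#' @export
sample_coverage <- function(abundances) {
  x <- abundances[abundances > 0]
  n <- sum(x)
  if (n < 1) return(NA_real_)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  a <- (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  1 - (f1 / n) * a
}

#' Rarefaction curve (hypergeometric expectation)
#'
#' Expected species count at each subsample depth m:
#' E\[S_m\] = sum_k (1 - choose(n - n_k, m) / choose(n, m)). Exact, not
#' extrapolating: depths beyond the sample size are an error.
#'
#' @param abundances Per-species counts for one assemblage.
#' @param depths Integer subsample sizes, each <= sum(abundances).
#' @return Tibble `depth`, `expected_s`; non-decreasing in depth and equal
#'   to the observed richness at full depth.
#' @export
rarefaction_curve <- function(abundances, depths) {
  x <- abundances[abundances > 0]
  n <- sum(x)
  if (any(depths > n)) abort("rarefaction depth exceeds sample size (no extrapolation)")
  if (any(depths < 1)) abort("depths must be positive")
  es <- vapply(depths, function(m) {
    unname(vegan::rarefy(matrix(x, nrow = 1), sample = m)[1])
  }, numeric(1))
  tibble(depth = as.integer(depths), expected_s = es)
}

#' Per-site and pooled sampling completeness
#'
#' @param survey Survey tibble.
#' @return Tibble with one row per site plus a `"pooled"` row: `site`, `n`,
#'   `coverage`.
#' @export
sampling_completeness <- function(survey) {
  m <- survey_matrix(survey, "count")
  per_site <- tibble(
    site = rownames(m),
    n = rowSums(m),
    coverage = apply(m, 1, sample_coverage)
  )
  pooled <- tibble(site = "pooled", n = sum(m),
                   coverage = sample_coverage(colSums(m)))
  bind_rows(per_site, pooled)
}
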