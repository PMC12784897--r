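# fishdiv

Multidimensional diversity analysis for freshwater fish surveys in
dammed rivers. Reservoir impoundment homogenizes habitats and fish
communities; quantifying that signal takes more than species counts.
fishdiv implements the full analysis a reservoir survey calls for:

* **Taxonomic α-diversity** — Margalef richness ((S−1)/ln N), Pielou
  evenness (H′/ln S), and per-site divergence from the community
  centroid in Hellinger space; abundance-based sample coverage and exact
  rarefaction for sampling completeness.
* **Phylogenetic α-diversity** — Faith's PD, abundance-weighted MPD and
  VPD over distinct species pairs, and their standardized effect sizes,
  SES = (obs − null mean)/null SD, under a seeded taxa-labels null that
  shuffles tree tip labels over the sampled species pool.
* **β-diversity partitioning** — pairwise Sørensen dissimilarity
  β_sor = (b+c)/(2a+b+c) split into turnover
  β_sim = min(b,c)/(a+min(b,c)) and nestedness β_sne = β_sor − β_sim
  (Baselga), computed on species sets and, in parallel, on shared/unique
  branch lengths; the beta-deviation (β_tax − β_phy)/β_tax and a
  Cohen's-d contrast between the two levels.
* **Dominance** — the index of relative importance,
  IRI = 10000 · F_i · (N_i + W_i) on proportions, with
  dominant (> 500) / common (100–500) / rare (< 100) classes.
* **Driver attribution** — environmental heterogeneity as distance to
  the standardized centroid, Spearman + Benjamini–Hochberg screening of
  α-diversity against water chemistry and dam distance, distance-decay
  OLS of β components on environmental and river distance (with a Mantel
  permutation p as a robustness column), two-predictor hierarchical
  partitioning (Chevan–Sutherland "average shared variance"), and
  GCV-selected GAM trends along the dam-distance gradient.
* **A synthetic-data generator** whose turnover and nestedness knobs map
  onto the Baselga components by construction, for testing and power
  exploration without field data.

Everything takes tidy data frames first and returns tibbles, so stages
chain with the pipe; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(fishdiv)

sc <- simulate_scenario(scenario_spec(seed = 42))  # 9 sites x 23 species
head(alpha_taxonomic(sc$survey), 3)
#>   site      S     N margalef shannon pielou hellinger_div
#> 1 S1       12    93     2.43    2.24  0.900         0.695
#> 2 S2       11    84     2.26    2.09  0.870         0.647
#> 3 S3       13   121     2.50    2.29  0.892         0.458

pairs <- beta_pairs(sc$survey, sc$tree)
beta_summary(pairs)
#>   level        n_pairs mean_sor mean_turn mean_nes turnover_share nestedness_share
#> 1 phylogenetic      36    0.227    0.0988    0.128           43.5             56.5
#> 2 taxonomic         36    0.489    0.291     0.199           59.4             40.6
```

Per-site richness sits near 11 species and ~100 individuals, the scale a
single-reservoir gillnet survey produces. Mean taxonomic dissimilarity
(0.489) exceeds phylogenetic (0.227): `beta_deviation(0.489, 0.227)`
returns `0.536` — the simulated communities hold endemics that are
phylogenetically close, so composition differs more than evolutionary
history. `compare_levels(pairs, "sor")` quantifies the same contrast as
Cohen's d = −1.36 (95% CI [−1.88, −0.85], Welch p ≈ 3e-7); negative d
means the taxonomic level is the more dissimilar one.

```r
fit <- distance_decay(pairs, sc$layout$pair_distance,
                      component = "sor", level = "taxonomic",
                      predictor_name = "spatial")
glance(fit)
#>   level     component predictor  slope intercept    r2 adj_r2       p
#> 1 taxonomic sor       spatial   0.0208     0.188 0.619  0.608 1.27e-8
```

Dissimilarity rises by ~0.02 per river km (adj R² = 0.61): sites far
apart along the axis share fewer species. Hierarchical partitioning then
splits the two-predictor R²; in this scenario river distance carries the
larger independent share (0.44 vs 0.19 of a full R² = 0.63).

The dominance index reproduces a published reservoir composition table
shipped with the package:

```r
comp <- dongfeng_composition()
iri <- iri_score(comp$occurrence_pct / 100, comp$abundance_pct / 100,
                 comp$biomass_pct / 100)
head(dplyr::tibble(species = comp$species, iri = round(iri, 1),
                   class = iri_classify(iri))[order(-iri), ], 6)
#>   species                          iri class
#> 1 Lepomis cyanellus             6006   dominant
#> 2 Carassius auratus             3724   dominant
#> 3 Coptodon zillii               3711   dominant
#> 4 Hemiculter leucisculus         864   dominant
#> 5 Pseudogyrinocheilus prochilus  721.7 dominant
#> 6 Opsariichthys bidens           464.9 common
```

Five species classify as dominant — two of them (the green sunfish and
redbelly tilapia) invasives caught at every site, the fingerprint of
impoundment-driven homogenization.

`run_pipeline(run_config(seed = 1, out_dir = "out"))` chains every stage
and writes one CSV per table plus a run log; a thin command-line wrapper
with `simulate`/`alpha`/`beta`/`drivers`/`all` verbs lives at
`inst/scripts/fishdiv-cli.R`.

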