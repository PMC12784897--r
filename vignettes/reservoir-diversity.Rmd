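---
title: "Multidimensional diversity of reservoir fish assemblages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional diversity of reservoir fish assemblages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishdiv)
```

fishdiv analyses a fish survey — per-site counts and biomass for a species
pool, a rooted phylogeny over that pool, a site-by-variable water-chemistry
table, and river distances — the way reservoir impoundment studies do:
within-site (α) diversity at the taxonomic and phylogenetic levels,
between-site (β) dissimilarity partitioned into turnover and nestedness at
both levels, dominance scoring, and attribution of the β patterns to
environmental heterogeneity versus river distance. This vignette records
the models, the parameter choices, and the places where the design was
genuinely open.

## The data model

A survey is a long tibble with one row per (site, species) occurrence and
paired `count` (individuals) and `biomass` (kg) columns. Zero-count rows
with positive biomass are rejected: biomass without individuals cannot
arise from a catch. Phylogenies are `ape::phylo` trees with branch
lengths; ultrametricity is checked and reported but not required, since
all quantities below are well defined on any rooted tree with
non-negative branch lengths. `align_inputs()` forces the site sets of all
tables to agree and, under its default strict policy, errors on any
survey/tree species mismatch — silently pruning tips would change every
phylogenetic quantity downstream without the user noticing.

## Within-site diversity

Taxonomic α-diversity uses the Margalef index $(S-1)/\ln N$ for richness,
Pielou's $J = H'/\ln S$ (Shannon in natural logarithms, so that $J \le 1$)
for evenness, and a divergence measure: each site's counts are
Hellinger-transformed (square roots of within-site relative abundances)
and the site's score is the Euclidean distance from its transformed
profile to the centroid of all transformed profiles. The divergence is
therefore invariant to total catch size per site and is zero exactly when
all sites share one relative composition.

Phylogenetic α-diversity comprises Faith's PD — the branch length of the
minimal subtree spanning the community, including the root path by
default so that the full pool recovers the total tree length and a single
species has nonzero PD (the `include_root` flag is exposed because both
conventions circulate) — and abundance-weighted MPD and VPD. The latter
average the patristic distances over distinct between-species pairs
$i<j$ with weights $f_i f_j$ (products of relative abundances),
excluding self-pairs; including self-pairs (a convention used by some
toolchains) deflates MPD by the factor $1-\sum_i f_i^2$, and the test
suite pins down that exact relationship against an independent
implementation.

Standardized effect sizes use the taxa-labels null: the community matrix
is untouched while the tree's tip labels are shuffled uniformly — over
the *pooled species set actually observed in the survey*, not the
possibly larger tree, so the null reflects the sampled pool. With
`n_perm` permutations (999 by default; at least 99),
$\mathrm{SES} = (\mathrm{obs} - \bar{x}_{\mathrm{null}})/s_{\mathrm{null}}$
and the rank p-value uses the add-one rule
$(\#\{x_{\mathrm{null}} \le \mathrm{obs}\}+1)/(n_{\mathrm{perm}}+1)$,
which cannot produce zero at finite replication. When a metric is
invariant under relabeling (a star tree, or PD of a community holding the
entire pool) the null SD is zero and SES is reported as missing rather
than as an arbitrary number.

Sampling completeness is reported two ways, because "accumulation curve"
analyses in the field may mean either: the abundance-based coverage
estimator $\hat C = 1 - (f_1/n)\,[(n-1)f_1/((n-1)f_1+2f_2)]$ from
singleton/doubleton counts, and the exact hypergeometric rarefaction
expectation $E[S_m]$. Neither extrapolates beyond the sample.

## Between-site diversity

Pairwise β-diversity works on presence/absence. For a site pair,
$a$ is the shared richness and $b, c$ the unique richness on either side;
the Sørensen dissimilarity $\beta_{sor} = (b+c)/(2a+b+c)$ splits into
turnover $\beta_{sim} = \min(b,c)/(a+\min(b,c))$ and nestedness
$\beta_{sne} = \beta_{sor} - \beta_{sim}$ (Baselga's pairwise
decomposition). The identity $\beta_{sor} = \beta_{sim} + \beta_{sne}$ is
exact in the implementation, and all three lie in $[0,1]$.

The phylogenetic version replaces richness with branch length: $a$ is the
length shared by both communities' spanning subtrees, $b$ and $c$ the
lengths unique to each. Subtrees include the root path by the same flag
as `faith_pd()`, preserving the additivity $a+b = PD_i$, $a+c = PD_j$
under either convention. On a star tree with unit branches the
phylogenetic triple collapses to the taxonomic one, a property the tests
exercise directly.

Summaries use the ratio of means: the turnover share is
$100 \cdot \overline{\beta_{sim}}/\overline{\beta_{sor}}$ over pairs, the
convention that keeps turnover and nestedness shares additive to 100%.
The beta-deviation, $(\beta_{tax}-\beta_{phy})/\beta_{tax}$, is likewise
evaluated on the mean pairwise values: positive when assemblages hold
many phylogenetically close endemics, negative when they share distantly
related species. The level contrast reports Cohen's d signed
phylogenetic-minus-taxonomic — negative d when taxonomic dissimilarity is
larger, matching how impoundment studies report this comparison — with a
normal-approximation 95% CI and a Welch two-sample p. (A two-group
"Tukey HSD" reduces to a pairwise comparison; Welch + effect size is that
comparison stated plainly.)

## Driver attribution

Environmental heterogeneity gets two explicit definitions, because the
analysis needs both: per site, the Euclidean distance from the site's
z-scored (mean 0, SD 1, $n-1$ denominator) environmental profile to the
group centroid, whose mean is the overall heterogeneity; and pairwise,
the Euclidean distance between two sites' z-scored profiles, which is the
predictor the distance-decay design requires. Constant variables are
dropped with a warning before standardization.

α-diversity screening is Spearman rank correlation (average ranks for
ties, two-sided p) of each index against each driver, with
Benjamini–Hochberg adjustment applied within one family per index across
its full driver set — the family structure is not canonical, and this
choice keeps each index's error rate interpretable on its own.

Distance decay is ordinary least squares of a β component on a pairwise
distance, reporting slope, intercept, adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-2)$ and the parametric slope p. β responses here
sit well inside $(0,1)$, so the Gaussian identity link is the default; a
logit variant was considered and rejected as an undocumented
complication. Pairwise dissimilarities are not independent observations,
so a seeded Mantel-style permutation p (site-label permutations of the
predictor matrix) is emitted alongside as a clearly labelled robustness
column; the parametric p remains the primary output.

Hierarchical partitioning for the two predictors uses the
Chevan–Sutherland all-subsets form: the independent contribution of
$X_1$ is $R^2(X_1)/2 + (R^2(X_1,X_2)-R^2(X_2))/2$, symmetrically for
$X_2$. The two contributions sum to the full-model $R^2$ identically, and
equal the marginal $R^2$ when the predictors are orthogonal — both
properties are enforced at $10^{-10}$ in the tests. Near-collinear
predictors ($|r|>0.999$) are computed but flagged.

Trends along the dam-distance axis are univariate Gaussian GAMs with
GCV-selected smoothness (`mgcv`), preceded by a Shapiro–Wilk normality
check at 0.05; failing responses are log-transformed, shifted first when
non-positive values are present. The reported deviance explained is
(null − residual)/null deviance, guarded to 0 for a constant response.
The smooth basis is capped at $k = \min(7, n-2)$, which at the nine-site
scale of a single-reservoir survey leaves the smoother free without
exhausting the degrees of freedom; below seven observations the fit
falls back to a straight line with a warning.

## What the synthetic generator emulates — and what it does not

`simulate_scenario()` builds a survey whose shape matches a dammed
reservoir: sites ordered along a one-dimensional river axis by distance
to the dam, an ultrametric pure-birth species tree (height 1), eleven
water-chemistry variables of which four increase away from the dam (the
permanganate index saturating), two decrease (sulfate saturating, water
depth linear) and five are noise, and a community assembled from two
independent knobs:

* `gradient_strength` shrinks each species' occupancy window
  (half-width $1/(1+g)$ on the unit axis) around a niche optimum —
  species replacement, which reads as turnover;
* `nestedness_strength` spreads species-specific retention thresholds
  $e^{-ns \cdot r_k}$, eroding richness in a fixed species order with
  distance from the dam — ordered loss, which reads as nestedness.

Occupancy is deterministic given the niche/threshold draws; stochasticity
enters through those draws and through log-normal × Poisson counts and
log-normal species masses. Optima are stretched slightly past both axis
ends so species slide in and out in both directions instead of piling
richness mid-axis. A configurable fraction of the pool (default 2 of 23,
the invader slot) is forced present everywhere, and `phylo_signal`
optionally ties optima to Brownian motion on the tree so phylogenetic β
can track or decouple from taxonomic β.

The defaults (`gradient_strength = 2`, `nestedness_strength = 0.3`,
`mean_count = 8`, `mean_mass_kg = 0.038`, 9 sites × 23 species on a
40 km axis) were calibrated once, loosely (±30%), to the magnitudes a
single-reservoir gillnet survey produces — about 11 species, 135
individuals and 8 kg per site — and are not revisited per analysis.
The generator does *not* emulate gear selectivity, seasonal dynamics, or
observation error in species identification; passing tests on synthetic
data therefore demonstrate correctness of the computations and the
qualitative recoverability of turnover- versus nestedness-dominated
structure, not field realism.

## Numerical conventions and degenerate inputs

* Proportions, not percentages, enter the dominance index
  IRI $= 10000 \, F_i (N_i + W_i)$, bounding it by 20000; classes are
  dominant (strictly above 500), common (100–500 inclusive), rare
  (below 100). Published tables printing $F_i, N_i, W_i$ at two decimals
  limit how precisely a printed IRI can be re-derived; the worked-example
  tests honour exactly that rounding envelope.
* Pielou is missing below two species; MPD/VPD below two species;
  β-diversity errors on empty communities rather than imputing.
* The additive β identity is enforced to $10^{-12}$, hierarchical
  partitioning identities to $10^{-10}$; PD equalities are exact.
* All pipeline randomness derives from one master seed via per-stage
  hashes, so `run_pipeline()` output tables are byte-identical across
  repeated runs and individual stages can be replayed in isolation.

## Problem sizes used in the checks

The shipped verification suite works at the scale the method targets:
9 × 23 synthetic surveys (50 replicates for the partition identity, 40
paired replicates for the turnover/nestedness scenario contrast), 200
random tree/community instances for the PD additivity oracle, 400
randomly assembled communities at 999 permutations for the null-model
calibration, and 500–1000 random datasets for the partitioning and
Benjamini–Hochberg oracles. These sizes were chosen to make the
stochastic checks statistically decisive (e.g. the SES mean over 400
communities has standard error ≈ 0.05 against the ±0.15 band the
calibration check allows).

## Known limitations

Pairwise (not multiple-site) decomposition only; no Jaccard-family or
basal-weighted phylogenetic β; no extrapolated richness; decay fits treat
pairs as independent in the parametric p (the Mantel column is the
honest alternative); the two-predictor hierarchical partition does not
generalize here to more predictors because the drivers of interest are
exactly environmental heterogeneity and river distance. The local
contribution (LCBD/SCBD) family is deliberately out of scope.
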