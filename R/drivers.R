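# Driver attribution: environmental heterogeneity, correlation screening of
# alpha-diversity, distance-decay regressions for beta-diversity, two-predictor
# hierarchical partitioning, and GAM trends along the dam-distance gradient.

# z-score columns (mean 0, SD 1, n-1 denominator); constant columns dropped
# with a warning.
standardize_env <- function(env) {
  vars <- env[setdiff(names(env), "site")]
  sds <- vapply(vars, sd, numeric(1))
  constant <- names(vars)[sds == 0 | is.na(sds)]
  if (length(constant) > 0) {
    warn(paste0("dropping constant environmental variable(s): ",
                paste(constant, collapse = ", ")))
    vars <- vars[setdiff(names(vars), constant)]
  }
  if (ncol(vars) == 0) abort("no environmental variable with positive variance")
  z <- scale(as.matrix(vars))
  rownames(z) <- env$site
  z
}

#' Environmental heterogeneity (distance to the group centroid)
#'
#' Each variable is z-scored across sites; a site's heterogeneity is the
#' Euclidean distance from its standardized profile to the group centroid
#' (the origin after centering), and the overall heterogeneity is the mean
#' across sites. Invariant to affine rescaling of any input variable and to
#' site or variable order.
#'
#' @param env Environment tibble (`site` column + numeric variables).
#' @return An `env_het` object: list with `per_site` (tibble `site`,
#'   `distance`) and `overall` (mean distance).
#' @export
env_heterogeneity <- function(env) {
  if (nrow(env) < 2) abort("need at least 2 sites")
  z <- standardize_env(env)
  d <- sqrt(rowSums(z^2))
  structure(
    list(per_site = tibble(site = env$site, distance = unname(d)),
         overall = mean(d)),
    class = "env_het"
  )
}

#' @export
print.env_het <- function(x, ...) {
  cat("Environmental heterogeneity (mean distance to centroid):",
      round(x$overall, 4), "over", nrow(x$per_site), "sites\n")
  invisible(x)
}

#' @rdname tidy.decay_fit
#' @export
tidy.env_het <- function(x, ...) x$per_site

#' Pairwise environmental distance matrix
#'
#' Euclidean distance between sites' z-scored environmental profiles — the
#' pairwise predictor used by the distance-decay analysis.
#'
#' @param env Environment tibble.
#' @return Symmetric named matrix with zero diagonal.
#' @export
env_distance_matrix <- function(env) {
  z <- standardize_env(env)
  as.matrix(dist(z))
}

#' Spearman screening of alpha-diversity against drivers, BH-adjusted
#'
#' Spearman rank correlation (average ranks for ties, two-sided p) of each
#' diversity index against each driver; Benjamini-Hochberg adjustment is
#' applied within one family per diversity index (one index against its
#' whole driver set).
#'
#' @param alpha_table Tibble with `site` plus numeric index columns.
#' @param drivers Tibble with `site` plus numeric driver columns
#'   (environmental variables, dam distance, ...).
#' @return Tibble `index`, `driver`, `rho`, `p`, `p_adj`. Constant columns
#'   yield `NA` rho.
#' @export
spearman_bh_screen <- function(alpha_table, drivers) {
  if (nrow(alpha_table) < 4) abort("need at least 4 sites for screening")
  merged <- inner_join(alpha_table, drivers, by = "site",
                       suffix = c("", ".driver"))
  idx_cols <- setdiff(names(alpha_table), "site")
  drv_cols <- setdiff(names(drivers), "site")
  drv_cols <- ifelse(drv_cols %in% idx_cols, paste0(drv_cols, ".driver"),
                     drv_cols)
  rows <- crossing(index = idx_cols, driver = drv_cols)
  res <- pmap(rows, function(index, driver) {
    x <- merged[[index]]
    y <- merged[[driver]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(index = index, driver = driver,
                    rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    tibble(index = index, driver = driver,
           rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- list_rbind(res)
  out |>
    group_by(.data$index) |>
    mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(driver = sub("\\.driver$", "", .data$driver))
}

# Align a pairwise predictor matrix with a beta-pairs tibble subset.
pair_predictor <- function(pairs_one, predictor) {
  if (is.null(dimnames(predictor))) abort("predictor matrix must be named")
  miss <- setdiff(unique(c(pairs_one$site_i, pairs_one$site_j)),
                  rownames(predictor))
  if (length(miss) > 0) {
    abort(paste0("predictor matrix lacks site(s): ", paste(miss, collapse = ", ")))
  }
  predictor[cbind(pairs_one$site_i, pairs_one$site_j)]
}

#' Distance-decay regression of beta-diversity on a pairwise distance
#'
#' Ordinary least-squares (Gaussian, identity link) fit of one beta
#' component on a pairwise predictor (environmental or river distance),
#' reporting slope, intercept, adjusted R-squared
#' (1 - (1 - R^2)(n - 1)/(n - 2)) and the parametric p of the slope.
#' Because pairwise dissimilarities are not independent, an optional
#' Mantel-style permutation p (seeded site-label permutations of the
#' predictor) is offered as a robustness output.
#'
#' @param pairs Output of [beta_pairs()] (one or both levels).
#' @param predictor Named symmetric site-by-site distance matrix.
#' @param component `"sor"`, `"turn"`, or `"nes"`.
#' @param level `"taxonomic"` or `"phylogenetic"`.
#' @param predictor_name Label stored with the fit.
#' @param n_perm Mantel permutations (0 = skip).
#' @param seed Optional seed for the permutation stream.
#' @return A `decay_fit` object (see [tidy.decay_fit()], [glance.decay_fit()],
#'   [autoplot.decay_fit()]).
#' @export
distance_decay <- function(pairs, predictor, component = c("sor", "turn", "nes"),
                           level = c("taxonomic", "phylogenetic"),
                           predictor_name = "distance", n_perm = 0,
                           seed = NULL) {
  component <- match.arg(component)
  level <- match.arg(level)
  col <- paste0("beta_", ifelse(component == "sor", "sor", component))
  sub <- pairs[pairs$level == level, ]
  if (nrow(sub) == 0) abort(paste0("no pairs at level ", level))
  y <- sub[[col]]
  x <- pair_predictor(sub, predictor)
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) abort("need at least 3 site pairs (n - 2 degrees of freedom)")
  if (sd(x) == 0) {
    warn("zero-variance predictor; decay fit refused")
    return(structure(list(component = component, level = level,
                          predictor = predictor_name, model = NULL,
                          data = tibble(distance = x, beta = y),
                          slope = NA_real_, intercept = NA_real_,
                          r2 = NA_real_, adj_r2 = NA_real_, p = NA_real_,
                          mantel_p = NA_real_, n_pairs = n),
                     class = "decay_fit"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  p <- sm$coefficients["x", "Pr(>|t|)"]
  mantel_p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    sites <- rownames(predictor)
    r2_perm <- vapply(seq_len(n_perm), function(b) {
      perm <- setNames(sample(sites), sites)
      xp <- predictor[cbind(perm[sub$site_i[ok]], perm[sub$site_j[ok]])]
      if (sd(xp) == 0) return(0)
      cor(xp, y)^2
    }, numeric(1))
    mantel_p <- (sum(r2_perm >= r2) + 1) / (n_perm + 1)
  }
  structure(
    list(component = component, level = level, predictor = predictor_name,
         model = fit, data = tibble(distance = x, beta = y),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2, adj_r2 = adj, p = p, mantel_p = mantel_p, n_pairs = n),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Distance decay:", x$level, paste0("beta_", x$component), "~",
      x$predictor, "\n  slope =", signif(x$slope, 4),
      " adj R2 =", signif(x$adj_r2, 3), " p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' Tidiers for fitted driver objects
#'
#' `tidy()` returns per-term (or per-site/per-predictor) rows; `glance()`
#' returns a one-row model summary, in the broom convention.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.decay_fit
NULL

#' @rdname tidy.decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(level = x$level, component = x$component, predictor = x$predictor,
         slope = x$slope, intercept = x$intercept, r2 = x$r2,
         adj_r2 = x$adj_r2, p = x$p, mantel_p = x$mantel_p,
         n_pairs = x$n_pairs)
}

# All-subsets R2 for a simple OLS on a subset of predictors.
subset_r2 <- function(y, X) {
  if (ncol(X) == 0) return(0)
  summary(lm(y ~ X))$r.squared
}

#' Two-predictor hierarchical partitioning of explained variance
#'
#' All-subsets decomposition of the two-predictor model R^2 into
#' independent ("average shared variance") contributions: the independent
#' contribution of X1 is R2(X1)/2 + (R2(X1, X2) - R2(X2))/2, and
#' symmetrically for X2; the two contributions sum to the full-model R^2
#' exactly, and each equals its marginal R^2 when the predictors are
#' orthogonal. The joint (shared) component of each predictor is its
#' marginal R^2 minus its independent contribution.
#'
#' @param y Response vector (e.g. one beta component over site pairs).
#' @param x1,x2 Predictor vectors (e.g. environmental and river distance).
#' @param labels Length-2 predictor names.
#' @return An `hp_fit` object with per-predictor contributions, the full
#'   model R^2 and the residual share.
#' @export
hierarchical_partition <- function(y, x1, x2,
                                   labels = c("environment", "spatial")) {
  ok <- !is.na(y) & !is.na(x1) & !is.na(x2)
  y <- y[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  if (sd(x1) == 0 || sd(x2) == 0) abort("both predictors must be non-constant")
  if (abs(cor(x1, x2)) > 0.999) {
    warn("predictors are nearly collinear (|r| > 0.999); partition is unstable")
  }
  r1 <- subset_r2(y, cbind(x1))
  r2_ <- subset_r2(y, cbind(x2))
  r12 <- subset_r2(y, cbind(x1, x2))
  i1 <- r1 / 2 + (r12 - r2_) / 2
  i2 <- r2_ / 2 + (r12 - r1) / 2
  structure(
    list(
      contributions = tibble(
        predictor = labels,
        independent = c(i1, i2),
        marginal_r2 = c(r1, r2_),
        joint = c(r1 - i1, r2_ - i2)
      ),
      full_r2 = r12,
      residual_share = 1 - r12,
      n = length(y)
    ),
    class = "hp_fit"
  )
}

#' @export
print.hp_fit <- function(x, ...) {
  cat("Hierarchical partitioning (full R2 =", round(x$full_r2, 4), "):\n")
  print(x$contributions)
  invisible(x)
}

#' @rdname tidy.decay_fit
#' @export
tidy.hp_fit <- function(x, ...) x$contributions

#' @rdname tidy.decay_fit
#' @export
glance.hp_fit <- function(x, ...) {
  tibble(full_r2 = x$full_r2, residual_share = x$residual_share, n = x$n)
}

#' Smooth trend of a variable along the dam-distance gradient
#'
#' Fits a univariate Gaussian GAM (thin-plate smooth, smoothness chosen by
#' GCV via `mgcv`) of `y` on `x`, after a Shapiro-Wilk normality pre-check
#' at the 0.05 level: a non-normal response is log-transformed (shifted
#' first when any value is <= 0, with a warning). Reports the adjusted
#' R-squared, the smooth-term p and the deviance explained
#' ((null - residual deviance)/null deviance). With fewer than 7
#' observations the fit falls back to a straight line with a warning.
#'
#' @param x Predictor, e.g. river distance to the dam (km).
#' @param y Response (environmental variable or per-site heterogeneity).
#' @param k Smooth basis dimension; default adapts to the sample size.
#' @return A `trend_fit` object (see [tidy.decay_fit()] family and
#'   [autoplot.trend_fit()]).
#' @export
smooth_trend <- function(x, y, k = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3) abort("need at least 3 observations")
  transformed <- FALSE
  if (sd(y) > 0 && n >= 3) {
    sw <- shapiro.test(y)
    if (sw$p.value < 0.05) {
      if (any(y <= 0)) {
        warn("non-normal response with non-positive values; shifting before log transform")
        y <- y - min(y) + 1
      }
      y <- log(y)
      transformed <- TRUE
    }
  }
  null_dev <- sum((y - mean(y))^2)
  if (n < 7) {
    warn("fewer than 7 observations; falling back to a linear fit")
    fit <- lm(y ~ x)
    sm <- summary(fit)
    res_dev <- sum(stats::residuals(fit)^2)
    de <- if (null_dev <= 1e-300) 0 else (null_dev - res_dev) / null_dev
    out <- list(model = fit, smooth = FALSE, transformed = transformed,
                adj_r2 = sm$adj.r.squared,
                p = sm$coefficients["x", "Pr(>|t|)"],
                deviance_explained = de,
                fitted = tibble(x = x, y = y, fitted = stats::fitted(fit)),
                n = n)
    return(structure(out, class = "trend_fit"))
  }
  k <- k %||% max(3, min(7, n - 2))
  fit <- mgcv::gam(y ~ s(x, k = k), method = "GCV.Cp",
                   family = stats::gaussian())
  sm <- summary(fit)
  de <- if (null_dev <= 1e-300) 0 else unname(sm$dev.expl)
  structure(
    list(model = fit, smooth = TRUE, transformed = transformed,
         adj_r2 = unname(sm$r.sq), p = unname(sm$s.table[1, "p-value"]),
         deviance_explained = de,
         fitted = tibble(x = x, y = y, fitted = unname(stats::fitted(fit))),
         n = n),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(if (x$smooth) "GAM trend" else "Linear trend (fallback)",
      ": adj R2 =", signif(x$adj_r2, 3),
      " p =", signif(x$p, 3),
      " deviance explained =", signif(x$deviance_explained, 3), "\n")
  invisible(x)
}

#' @rdname tidy.decay_fit
#' @export
tidy.trend_fit <- function(x, ...) x$fitted

#' @rdname tidy.decay_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(adj_r2 = x$adj_r2, p = x$p,
         deviance_explained = x$deviance_explained,
         smooth = x$smooth, log_transformed = x$transformed, n = x$n)
}
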