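test_that("environmental heterogeneity matches the hand example", {
  env <- tibble::tibble(site = c("S1", "S2"), v = c(0, 2))
  het <- env_heterogeneity(env)
  expect_equal(het$per_site$distance, c(sqrt(0.5), sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(het$overall, sqrt(0.5), tolerance = 1e-12)

  env_mixed <- tibble::tibble(site = paste0("S", 1:3), v1 = c(1, 1, 1),
                              v2 = c(1, 2, 3))
  expect_warning(het0 <- env_heterogeneity(env_mixed), "constant")
  expect_equal(nrow(het0$per_site), 3)
  # all variables constant leaves nothing to standardize
  expect_error(suppressWarnings(
    env_heterogeneity(tibble::tibble(site = c("a", "b"), v = c(1, 1)))
  ), "positive variance")
})

test_that("heterogeneity is invariant to rescaling, site and variable order", {
  set.seed(3)
  env <- tibble::tibble(site = paste0("S", 1:8),
                        a = rnorm(8), b = runif(8) * 100, c = rnorm(8, 5))
  h1 <- env_heterogeneity(env)$overall
  scaled <- dplyr::mutate(env, b = 3 * b - 7)
  expect_equal(env_heterogeneity(scaled)$overall, h1, tolerance = 1e-12)
  reordered <- env[sample(8), c("site", "c", "a", "b")]
  expect_equal(env_heterogeneity(reordered)$overall, h1, tolerance = 1e-12)
})

test_that("environmental distances are Euclidean on z-scores", {
  env <- tibble::tibble(site = c("S1", "S2"), v = c(0, 2))
  d <- env_distance_matrix(env)
  expect_equal(d["S1", "S2"], sqrt(2), tolerance = 1e-12)
  set.seed(4)
  env8 <- tibble::tibble(site = paste0("S", 1:8), a = rnorm(8), b = rnorm(8))
  d8 <- env_distance_matrix(env8)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(d8[i, j], d8[i, k] + d8[k, j] + 1e-12)
  }
})

test_that("spearman screening handles monotone signals and BH families", {
  tab <- tibble::tibble(site = paste0("S", 1:6), idx = 1:6)
  drv <- tibble::tibble(site = paste0("S", 1:6), up = c(2, 4, 5, 7, 9, 12),
                        flat = rep(1, 6))
  out <- spearman_bh_screen(tab, drv)
  expect_equal(out$rho[out$driver == "up"], 1)
  expect_true(is.na(out$rho[out$driver == "flat"]))
  expect_true(all(out$p_adj >= out$p, na.rm = TRUE))
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(23)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_brute_oracle(p),
                 tolerance = 1e-14)
  }
})

test_that("distance decay recovers exact linear relationships", {
  sites <- paste0("S", 1:5)
  D <- abs(outer(1:5, 1:5, "-")) * 3
  dimnames(D) <- list(sites, sites)
  prs <- t(combn(sites, 2))
  beta <- 0.1 + 0.02 * D[prs]
  pairs <- tibble::tibble(site_i = prs[, 1], site_j = prs[, 2],
                          level = "taxonomic", beta_sor = beta,
                          beta_turn = beta / 2, beta_nes = beta / 2)
  fit <- suppressWarnings(
    distance_decay(pairs, D, component = "sor", level = "taxonomic")
  )
  expect_equal(fit$slope, 0.02, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  cf <- ols_closed_form(D[prs], beta)
  expect_equal(fit$slope, cf$slope, tolerance = 1e-10)
  expect_equal(fit$r2, cf$r2, tolerance = 1e-10)
})

test_that("distance decay agrees with closed-form OLS on noisy data", {
  set.seed(15)
  sites <- paste0("S", 1:9)
  D <- as.matrix(dist(runif(9) * 40))
  dimnames(D) <- list(sites, sites)
  prs <- t(combn(sites, 2))
  x <- D[prs]
  y <- 0.2 + 0.01 * x + rnorm(length(x), 0, 0.05)
  pairs <- tibble::tibble(site_i = prs[, 1], site_j = prs[, 2],
                          level = "taxonomic", beta_sor = y,
                          beta_turn = y, beta_nes = 0)
  fit <- distance_decay(pairs, D, "sor", "taxonomic", n_perm = 199, seed = 1)
  cf <- ols_closed_form(x, y)
  expect_equal(fit$slope, cf$slope, tolerance = 1e-10)
  expect_equal(fit$r2, cf$r2, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1 - (1 - cf$r2) * (36 - 1) / (36 - 2),
               tolerance = 1e-10)
  expect_true(fit$mantel_p > 0 && fit$mantel_p <= 1)
  # with a real signal the permutation p should be small
  expect_lt(fit$mantel_p, 0.05)
})

test_that("distance decay refuses degenerate designs", {
  sites <- paste0("S", 1:3)
  D <- matrix(0, 3, 3, dimnames = list(sites, sites))
  pairs <- tibble::tibble(site_i = c("S1", "S1", "S2"),
                          site_j = c("S2", "S3", "S3"),
                          level = "taxonomic", beta_sor = c(.1, .2, .3),
                          beta_turn = 0, beta_nes = 0)
  expect_warning(fit <- distance_decay(pairs, D, "sor", "taxonomic"),
                 "zero-variance")
  expect_true(is.na(fit$slope))
  expect_error(distance_decay(pairs[1:2, ], D, "sor", "taxonomic"),
               "at least 3")
})

test_that("hierarchical partitioning sums to the full R2 and recovers orthogonal designs", {
  set.seed(8)
  for (i in 1:100) {
    y <- rnorm(30); x1 <- rnorm(30); x2 <- rnorm(30)
    hp <- hierarchical_partition(y, x1, x2)
    expect_equal(sum(hp$contributions$independent), hp$full_r2,
                 tolerance = 1e-10)
    expect_equal(hp$residual_share, 1 - hp$full_r2, tolerance = 1e-12)
  }
  # orthogonal design: independent contributions equal marginal R2
  x1 <- c(scale(rnorm(40)))
  x2 <- stats::resid(lm(rnorm(40) ~ x1))
  y <- x1 + 0.5 * x2 + rnorm(40, 0, 0.3)
  hp <- hierarchical_partition(y, x1, x2)
  expect_equal(hp$contributions$independent, hp$contributions$marginal_r2,
               tolerance = 1e-10)
  # response driven by x1 alone gives x2 a zero share
  y1 <- 2 * x1
  hp1 <- suppressWarnings(hierarchical_partition(y1, x1, x2))
  expect_equal(hp1$contributions$independent[2], 0, tolerance = 1e-10)
  expect_equal(hp1$contributions$independent[1], 1, tolerance = 1e-10)
  expect_error(hierarchical_partition(y, x1, rep(1, 40)), "non-constant")
})

test_that("smooth trends saturate on exact signals and degrade gracefully", {
  x <- seq(2, 40, length.out = 9)
  fit_lin <- smooth_trend(x, 3 + 0.5 * x)
  expect_equal(fit_lin$deviance_explained, 1, tolerance = 1e-6)
  fit_const <- smooth_trend(x, rep(2, 9))
  expect_equal(fit_const$deviance_explained, 0)
  suppressWarnings(
    expect_warning(fit_small <- smooth_trend(x[1:5], (3 + 0.5 * x)[1:5]),
                   "linear fit")
  )
  expect_false(fit_small$smooth)
  expect_equal(fit_small$deviance_explained, 1, tolerance = 1e-9)
})

test_that("quadratic signals are captured by the GAM at survey size", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    x <- seq(0, 1, length.out = 9)
    y <- 4 * (x - 0.5)^2 + rnorm(9, 0, 0.05)
    fit <- suppressWarnings(smooth_trend(x, y))
    if (fit$deviance_explained > 0.8) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("non-normal responses get log-transformed with shifting", {
  set.seed(2)
  x <- seq_len(20)
  y <- c(rexp(19, 0.2), 60) - 0.5  # skewed, includes values <= 0 region
  y[1] <- -0.1
  expect_warning(fit <- smooth_trend(x, y), "shifting")
  expect_true(glance(fit)$log_transformed)
})
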