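test_that("taxonomic abc components are plain set algebra", {
  expect_equal(abc_taxonomic(c("A", "B", "C"), c("B", "C", "D")),
               c(a = 2, b = 1, c = 1))
  expect_equal(abc_taxonomic(c("A", "B"), c("A", "B")), c(a = 2, b = 0, c = 0))
  expect_equal(abc_taxonomic(c("A", "B"), c("C", "D", "E")),
               c(a = 0, b = 2, c = 3))
  expect_error(abc_taxonomic(character(0), "A"), "empty")
})

test_that("phylogenetic abc components match hand-traced branch sharing", {
  tr <- tree_abc()
  expect_equal(abc_phylogenetic(c("A", "B", "C"), c("A", "B", "C"), tr),
               c(a = 5, b = 0, c = 0))
  expect_equal(abc_phylogenetic("A", "C", tr), c(a = 0, b = 2, c = 2))
  # star tree with unit branches: branch components equal species counts
  star <- star_tree(6)
  ci <- c("t1", "t2", "t3"); cj <- c("t2", "t3", "t4", "t5")
  expect_equal(abc_phylogenetic(ci, cj, star),
               c(a = 2, b = 1, c = 2))
})

test_that("sorensen_partition follows Baselga's formulas", {
  p <- sorensen_partition(2, 1, 3)
  expect_equal(p$beta_sor, 0.5)
  expect_equal(p$beta_turn, 1 / 3, tolerance = 1e-12)
  expect_equal(p$beta_nes, 1 / 6, tolerance = 1e-12)
  nested <- sorensen_partition(3, 0, 2)
  expect_equal(nested$beta_turn, 0)
  expect_equal(nested$beta_sor, 0.25)
  expect_equal(nested$beta_nes, 0.25)
  disjoint <- sorensen_partition(0, 2, 3)
  expect_equal(disjoint$beta_sor, 1)
  expect_equal(disjoint$beta_turn, 1)
  expect_equal(disjoint$beta_nes, 0)
  expect_error(sorensen_partition(0, 0, 1), "positive component")
})

test_that("the additive identity and bounds hold on random triples", {
  set.seed(13)
  a <- runif(1000, 0, 10)
  b <- runif(1000, 0, 10)
  c_ <- runif(1000, 0, 10)
  p <- sorensen_partition(a, b, c_)
  expect_true(all(abs(p$beta_sor - (p$beta_turn + p$beta_nes)) < 1e-12))
  expect_true(all(p$beta_sor >= 0 & p$beta_sor <= 1))
  expect_true(all(p$beta_turn >= 0 & p$beta_turn <= 1))
  expect_true(all(p$beta_nes >= 0 & p$beta_nes <= 1))
})

test_that("taxonomic beta_sor agrees with vegan's binary Bray-Curtis", {
  sv <- make_random_survey(7, 12, seed = 4)
  m <- survey_matrix(sv, "presence")
  ours <- beta_pairs(sv)
  vd <- as.matrix(vegan::vegdist(m, method = "bray", binary = TRUE))
  tax <- ours[ours$level == "taxonomic", ]
  expect_equal(tax$beta_sor,
               vd[cbind(tax$site_i, tax$site_j)], tolerance = 1e-12)
})

test_that("PD additivity: a+b and a+c recover each community's PD exactly", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:14, 1)
    tr <- ape::rtree(n)
    ci <- sample(tr$tip.label, sample(2:n, 1))
    cj <- sample(tr$tip.label, sample(2:n, 1))
    abc <- abc_phylogenetic(ci, cj, tr)
    expect_equal(abc[["a"]] + abc[["b"]], faith_pd(ci, tr), tolerance = 1e-12)
    expect_equal(abc[["a"]] + abc[["c"]], faith_pd(cj, tr), tolerance = 1e-12)
  }
})

test_that("phylogenetic equals taxonomic beta on unit-branch star trees", {
  star <- star_tree(10)
  for (s in 1:10) {
    sv <- make_random_survey(5, 10, seed = 100 + s)
    bp <- beta_pairs(sv, star)
    tax <- bp[bp$level == "taxonomic", c("beta_sor", "beta_turn", "beta_nes")]
    phy <- bp[bp$level == "phylogenetic", c("beta_sor", "beta_turn", "beta_nes")]
    expect_equal(tax, phy, tolerance = 1e-12)
  }
})

test_that("beta_pairs covers all unordered pairs and degenerate sites", {
  sv <- make_random_survey(9, 8, seed = 5)
  bp <- beta_pairs(sv)
  expect_equal(nrow(bp), 36)
  sv_same <- tidyr::crossing(site = paste0("S", 1:4),
                             species = c("A", "B", "C")) |>
    dplyr::mutate(count = 1, biomass = 0.1)
  bp_same <- beta_pairs(sv_same)
  expect_true(all(bp_same$beta_sor == 0))
})

test_that("adding a species unique to one site never decreases beta_sor", {
  set.seed(6)
  for (i in 1:20) {
    sv <- make_random_survey(4, 8, seed = 200 + i)
    pres <- survey_matrix(sv, "presence")
    absent <- colnames(pres)[pres["S1", ] == 0 & pres["S2", ] == 0]
    if (length(absent) == 0) next
    before <- beta_pairs(sv)
    sv2 <- dplyr::bind_rows(sv, tibble::tibble(
      site = "S1", species = absent[1], count = 1, biomass = 0.1
    ))
    after <- beta_pairs(sv2)
    pick <- function(x) x$beta_sor[x$level == "taxonomic" &
                                   ((x$site_i == "S1" & x$site_j == "S2") |
                                    (x$site_i == "S2" & x$site_j == "S1"))]
    expect_gte(pick(after), pick(before))
  }
})

test_that("beta summaries keep shares additive and beta_dev consistent", {
  sv <- make_random_survey(6, 12, seed = 9)
  tr <- ape::rtree(12); tr$tip.label <- paste0("t", 1:12)
  bs <- beta_summary(beta_pairs(sv, tr))
  expect_equal(bs$turnover_share + bs$nestedness_share, c(100, 100),
               tolerance = 1e-9)
  expect_equal(beta_deviation(0.33, 0.26), 0.07 / 0.33, tolerance = 1e-12)
  expect_equal(round(beta_deviation(0.33, 0.26), 2), 0.21)
  expect_equal(beta_deviation(0.4, 0.4), 0)
  expect_equal(beta_deviation(0.2, 0.4), -1)
  expect_true(is.na(beta_deviation(0, 0.1)))
})

test_that("level contrast reproduces the pooled-SD Cohen's d by hand", {
  x_tax <- c(0.42, 0.35, 0.51, 0.47, 0.39, 0.44, 0.36, 0.52, 0.41, 0.48)
  x_phy <- c(0.31, 0.28, 0.40, 0.33, 0.30, 0.37, 0.29, 0.41, 0.32, 0.36)
  pairs <- dplyr::bind_rows(
    tibble::tibble(site_i = "a", site_j = letters[2:11], level = "taxonomic",
                   beta_sor = x_tax, beta_turn = x_tax, beta_nes = 0),
    tibble::tibble(site_i = "a", site_j = letters[2:11],
                   level = "phylogenetic",
                   beta_sor = x_phy, beta_turn = x_phy, beta_nes = 0)
  )
  out <- compare_levels(pairs, "sor")
  sp <- sqrt((9 * var(x_phy) + 9 * var(x_tax)) / 18)
  d_hand <- (mean(x_phy) - mean(x_tax)) / sp
  expect_equal(out$cohens_d, d_hand, tolerance = 1e-12)
  expect_lt(out$cohens_d, 0)  # taxonomic larger -> negative d
  expect_lt(out$ci_low, out$cohens_d)
  expect_gt(out$ci_high, out$cohens_d)

  same <- pairs
  same$beta_sor[same$level == "phylogenetic"] <- x_tax
  expect_equal(compare_levels(same, "sor")$cohens_d, 0)
})
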