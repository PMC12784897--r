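test_that("faith_pd matches hand-traced subtrees", {
  tr <- tree_abc()
  expect_equal(faith_pd(c("A", "B", "C"), tr), 5)
  expect_equal(faith_pd(c("A", "B"), tr), 3)
  expect_equal(faith_pd("C", tr), 2)
  expect_equal(faith_pd("C", tr, include_root = FALSE), 0)
  expect_equal(faith_pd(c("A", "B"), tr, include_root = FALSE), 2)
  expect_true(is.na(faith_pd(character(0), tr)))
})

test_that("faith_pd equals the edge-union oracle and picante on random instances", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(5:14, 1)
    tr <- ape::rtree(n)
    comm <- sample(tr$tip.label, sample(1:n, 1))
    expect_equal(faith_pd(comm, tr), pd_edge_union_oracle(comm, tr),
                 tolerance = 1e-12)
    expect_equal(faith_pd(comm, tr, include_root = FALSE),
                 pd_edge_union_oracle(comm, tr, include_root = FALSE),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("picante")
  tr <- ape::rtree(12)
  m <- matrix(0, 3, 12, dimnames = list(paste0("S", 1:3), tr$tip.label))
  set.seed(8)
  for (s in 1:3) m[s, sample(12, sample(2:10, 1))] <- 1
  ours <- vapply(rownames(m), function(s)
    faith_pd(colnames(m)[m[s, ] > 0], tr), numeric(1))
  theirs <- picante::pd(m, tr, include.root = TRUE)$PD
  expect_equal(unname(ours), theirs, tolerance = 1e-10)
})

test_that("PD is monotone under species addition", {
  set.seed(21)
  tr <- ape::rtree(10)
  comm <- sample(tr$tip.label, 4)
  extra <- setdiff(tr$tip.label, comm)
  for (sp in extra) {
    expect_gte(faith_pd(c(comm, sp), tr), faith_pd(comm, tr))
  }
})

test_that("abundance-weighted MPD and VPD match hand values", {
  tr <- tree_abc()
  # one pair: mpd is the distance, vpd 0, regardless of weights
  expect_equal(mpd_vpd_abu(c(A = 1, B = 1), tr), c(mpd_abu = 2, vpd_abu = 0))
  expect_equal(mpd_vpd_abu(c(A = 100, B = 1), tr),
               c(mpd_abu = 2, vpd_abu = 0))
  mv <- mpd_vpd_abu(c(A = 1, B = 1, C = 1), tr)
  expect_equal(mv[["mpd_abu"]], 10 / 3, tolerance = 1e-12)
  expect_equal(mv[["vpd_abu"]], 8 / 9, tolerance = 1e-12)
  expect_true(all(is.na(mpd_vpd_abu(c(A = 3), tr))))
})

test_that("equal-abundance MPD equals the unweighted double-loop oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    comm <- sample(tr$tip.label, sample(3:n, 1))
    ab <- setNames(rep(2, length(comm)), comm)
    expect_equal(mpd_vpd_abu(ab, tr)[["mpd_abu"]],
                 mpd_double_loop_oracle(comm, tr), tolerance = 1e-12)
  }
  skip_if_not_installed("picante")
  tr <- ape::rtree(10)
  ab <- setNames(sample(1:9, 6), sample(tr$tip.label, 6))
  m <- matrix(0, 1, 10, dimnames = list("S1", tr$tip.label))
  m[1, names(ab)] <- ab
  # picante averages over ordered pairs INCLUDING self-pairs (diagonal
  # zeros); ours excludes them, so the two differ by the factor
  # 1 / (1 - sum(f^2)) exactly
  f <- ab / sum(ab)
  expect_equal(
    mpd_vpd_abu(ab, tr)[["mpd_abu"]] * (1 - sum(f^2)),
    picante::mpd(m, ape::cophenetic.phylo(tr), abundance.weighted = TRUE),
    tolerance = 1e-10
  )
  # and with the self-pair weight removed the unweighted case agrees directly
  meq <- m; meq[meq > 0] <- 1
  expect_equal(
    mpd_vpd_abu(setNames(rep(1, 6), names(ab)), tr)[["mpd_abu"]],
    picante::mpd(meq, ape::cophenetic.phylo(tr), abundance.weighted = FALSE),
    tolerance = 1e-10
  )
})

test_that("phylo_alpha returns one row per site with PD bounded by tree length", {
  sv <- make_random_survey(5, 9, seed = 12)
  tr <- ape::rtree(9)
  tr$tip.label <- paste0("t", 1:9)
  pa <- phylo_alpha(sv, tr)
  expect_equal(nrow(pa), 5)
  expect_true(all(pa$pd <= sum(tr$edge.length) + 1e-12))
  expect_true(all(pa$vpd_abu >= 0, na.rm = TRUE))
})

test_that("SES is NA when the metric is invariant under tip relabeling", {
  star <- star_tree(6)
  sv <- make_random_survey(4, 6, seed = 3)
  sv$species <- paste0("t", match(sv$species, paste0("t", 1:6)))
  expect_warning(
    out <- ses_null(sv, star, metric = "mpd_abu", n_perm = 99, seed = 1),
    "invariant"
  )
  expect_true(all(is.na(out$ses[!is.na(out$obs)])))

  # a community holding the whole pool has label-invariant PD
  tr <- ape::rtree(5)
  tr$tip.label <- paste0("t", 1:5)
  full <- tibble::tibble(site = "S1", species = paste0("t", 1:5),
                         count = 1:5, biomass = (1:5) / 10)
  expect_warning(
    out2 <- ses_null(full, tr, metric = "pd", n_perm = 99, seed = 1),
    "invariant"
  )
  expect_true(is.na(out2$ses))
  expect_equal(out2$null_sd, 0)
})

test_that("SES runs are deterministic given a seed and sane in shape", {
  sv <- make_random_survey(5, 8, seed = 17)
  tr <- ape::rtree(8)
  tr$tip.label <- paste0("t", 1:8)
  a <- ses_null(sv, tr, metric = c("pd", "mpd_abu"), n_perm = 99, seed = 42)
  b <- ses_null(sv, tr, metric = c("pd", "mpd_abu"), n_perm = 99, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 5 * 2)
  expect_true(all(a$rank_p > 0 & a$rank_p < 1))
  expect_equal(a$ses, (a$obs - a$null_mean) / a$null_sd, tolerance = 1e-12)
  expect_error(ses_null(sv, tr, n_perm = 50), "at least 99")
})
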