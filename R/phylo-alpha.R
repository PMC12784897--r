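# Phylogenetic alpha-diversity: Faith PD, abundance-weighted MPD/VPD, and
# standardized effect sizes under a tip-label-shuffling (taxa-labels) null.

#' Read a rooted phylogeny from a newick file
#'
#' Requires branch lengths. Ultrametricity (all root-to-tip distances equal
#' within 1e-6 of tree height) is checked and reported via a message, not
#' required. An unrooted tree (basal polytomy) is kept with its basal node
#' treated as the root, with a warning.
#'
#' @param path Newick file path.
#' @return An `ape::phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort("could not parse newick file")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree lacks branch lengths")
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  if (!ape::is.rooted(tree)) {
    warn("tree is unrooted; treating its basal node as the root")
  }
  if (is_ultrametric_tol(tree)) {
    inform("tree is ultrametric (within 1e-6 of tree height)")
  } else {
    inform("tree is NOT ultrametric")
  }
  tree
}

is_ultrametric_tol <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depth)
  if (h == 0) return(TRUE)
  (max(depth) - min(depth)) <= tol * h
}

# Tip-by-edge incidence of root paths, the workhorse behind PD and the
# phylogenetic Sorensen components. Row t marks the edges on the path from
# tip t to the root.
pd_machine <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  nmax <- max(tree$edge)
  edge_above <- integer(nmax)
  parent <- integer(nmax)
  edge_above[tree$edge[, 2]] <- seq_len(nedge)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  inc <- matrix(FALSE, ntip, nedge)
  for (tip in seq_len(ntip)) {
    node <- tip
    while (node != root) {
      e <- edge_above[node]
      inc[tip, e] <- TRUE
      node <- parent[node]
    }
  }
  list(inc = inc, len = tree$edge.length, tips = tree$tip.label)
}

pd_from_counts <- function(counts, n, machine, include_root) {
  on_subtree <- counts > 0L
  if (!include_root) on_subtree <- on_subtree & counts < n
  sum(machine$len[on_subtree])
}

#' Faith's phylogenetic diversity of one community
#'
#' Sum of branch lengths of the minimal subtree spanning the community's
#' tips. With `include_root = TRUE` (default) the path up to the root is
#' included, so the full species pool has PD equal to the total tree length
#' and a single species has a nonzero PD.
#'
#' @param community Character vector of species (tree tip labels) present.
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param include_root Include the root path? Default `TRUE`.
#' @return PD in branch-length units; `NA` for an empty community.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(c("A", "B"), tr)  # 3
#' @export
faith_pd <- function(community, tree, include_root = TRUE) {
  community <- unique(community)
  if (length(community) == 0) return(NA_real_)
  idx <- match(community, tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0("species not in tree: ",
                 paste(community[is.na(idx)], collapse = ", ")))
  }
  machine <- pd_machine(tree)
  counts <- colSums(machine$inc[idx, , drop = FALSE])
  pd_from_counts(counts, length(idx), machine, include_root)
}

# MPD/VPD over distinct unordered between-species pairs, weighted by the
# product of relative abundances.
mpd_vpd_from_dist <- function(D, f) {
  f <- f / sum(f)
  den <- 1 - sum(f^2)
  if (den <= .Machine$double.eps) {
    return(c(mpd_abu = NA_real_, vpd_abu = NA_real_))
  }
  m <- as.numeric(crossprod(f, D %*% f)) / den
  v <- as.numeric(crossprod(f, (D * D) %*% f)) / den - m^2
  c(mpd_abu = m, vpd_abu = max(v, 0))
}

#' Abundance-weighted mean and variance of pairwise phylogenetic distances
#'
#' Patristic distances among the community's species, averaged over distinct
#' between-species pairs (i < j) with weights proportional to the product of
#' the two species' relative abundances; VPD is the matching weighted
#' variance around MPD. Self-pairs are excluded.
#'
#' @param abundances Named non-negative vector (names = tree tip labels);
#'   species with zero abundance are ignored.
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Named vector `c(mpd_abu, vpd_abu)`; both `NA` when fewer than
#'   two species have positive abundance.
#' @export
mpd_vpd_abu <- function(abundances, tree) {
  abundances <- abundances[abundances > 0]
  if (length(abundances) < 2) {
    return(c(mpd_abu = NA_real_, vpd_abu = NA_real_))
  }
  sp <- names(abundances)
  if (is.null(sp) || anyNA(match(sp, tree$tip.label))) {
    abort("abundances must be named by tree tip labels")
  }
  D <- ape::cophenetic.phylo(tree)[sp, sp]
  mpd_vpd_from_dist(D, abundances)
}

#' Per-site phylogenetic alpha-diversity table
#'
#' @param survey Survey tibble (see [validate_survey()]).
#' @param tree Tree covering all surveyed species.
#' @param include_root Passed to [faith_pd()].
#' @return A tibble with one row per site: `site`, `pd`, `mpd_abu`,
#'   `vpd_abu`.
#' @export
phylo_alpha <- function(survey, tree, include_root = TRUE) {
  m <- survey_matrix(survey, "count")
  sp <- colnames(m)
  missing_sp <- setdiff(sp, tree$tip.label)
  if (length(missing_sp) > 0) {
    abort(paste0("species not in tree: ", paste(missing_sp, collapse = ", ")))
  }
  D <- ape::cophenetic.phylo(tree)[sp, sp, drop = FALSE]
  machine <- pd_machine(tree)
  tip_idx <- match(sp, tree$tip.label)
  rows <- map(rownames(m), function(s) {
    x <- m[s, ]
    present <- which(x > 0)
    pd <- if (length(present) == 0) NA_real_ else {
      counts <- colSums(machine$inc[tip_idx[present], , drop = FALSE])
      pd_from_counts(counts, length(present), machine, include_root)
    }
    mv <- if (length(present) < 2) c(NA_real_, NA_real_) else {
      mpd_vpd_from_dist(D[present, present, drop = FALSE], x[present])
    }
    tibble(site = s, pd = pd, mpd_abu = mv[[1]], vpd_abu = mv[[2]])
  })
  list_rbind(rows)
}

#' Standardized effect sizes of phylogenetic alpha-diversity
#'
#' Taxa-labels null model: the community matrix is untouched while the tip
#' labels of the phylogeny are shuffled uniformly over the pooled species
#' set (species observed anywhere in the survey), `n_perm` times. For each
#' site and metric, SES = (obs - null mean) / null SD, and the rank p-value
#' uses the add-one rule: p = (#\{null <= obs\} + 1) / (n_perm + 1).
#'
#' @param survey Survey tibble.
#' @param tree Tree covering the surveyed species; tips outside the survey
#'   pool are pruned (with a warning) before permutation so the null
#'   reflects the sampled pool.
#' @param metric Any of `"pd"`, `"mpd_abu"`, `"vpd_abu"` (several allowed;
#'   they share the same permutation stream).
#' @param n_perm Number of permutations (>= 99; 999 recommended).
#' @param seed Optional integer seed for the permutation stream.
#' @param include_root Passed to the PD computation.
#' @return A tibble with columns `site`, `metric`, `obs`, `null_mean`,
#'   `null_sd`, `ses`, `rank_p`, `n_perm`. When a metric is invariant under
#'   relabeling (null SD = 0), `ses` is `NA` with a warning.
#' @export
ses_null <- function(survey, tree, metric = c("pd", "mpd_abu", "vpd_abu"),
                     n_perm = 999, seed = NULL, include_root = TRUE) {
  metric <- match.arg(metric, several.ok = TRUE)
  if (n_perm < 99) abort("n_perm must be at least 99")
  m <- survey_matrix(survey, "count")
  pool <- colnames(m)
  if (length(setdiff(pool, tree$tip.label)) > 0) {
    abort(paste0("species not in tree: ",
                 paste(setdiff(pool, tree$tip.label), collapse = ", ")))
  }
  extra <- setdiff(tree$tip.label, pool)
  if (length(extra) > 0) {
    warn(paste0("pruning ", length(extra),
                " tree tip(s) outside the surveyed pool before permutation"))
    tree <- ape::keep.tip(tree, pool)
  }
  machine <- pd_machine(tree)
  D <- ape::cophenetic.phylo(tree)
  ord <- match(pool, tree$tip.label)  # pool index -> tip index
  D <- D[tree$tip.label, tree$tip.label]
  npool <- length(pool)
  sites <- rownames(m)
  present_idx <- lapply(sites, function(s) ord[which(m[s, ] > 0)])
  abund <- lapply(sites, function(s) m[s, m[s, ] > 0])

  eval_metrics <- function(perm) {
    # perm maps tip index -> permuted tip index
    vapply(seq_along(sites), function(i) {
      idx <- perm[present_idx[[i]]]
      out <- c(pd = NA_real_, mpd_abu = NA_real_, vpd_abu = NA_real_)
      if (length(idx) >= 1 && "pd" %in% metric) {
        counts <- colSums(machine$inc[idx, , drop = FALSE])
        out["pd"] <- pd_from_counts(counts, length(idx), machine, include_root)
      }
      if (length(idx) >= 2 && any(c("mpd_abu", "vpd_abu") %in% metric)) {
        mv <- mpd_vpd_from_dist(D[idx, idx, drop = FALSE], abund[[i]])
        out["mpd_abu"] <- mv[[1]]
        out["vpd_abu"] <- mv[[2]]
      }
      out[metric]
    }, numeric(length(metric)))
  }

  if (!is.null(seed)) set.seed(seed)
  obs <- eval_metrics(seq_len(npool))
  null_vals <- array(NA_real_, c(length(metric), length(sites), n_perm))
  for (b in seq_len(n_perm)) {
    null_vals[, , b] <- eval_metrics(sample.int(npool))
  }
  rows <- list()
  for (k in seq_along(metric)) {
    for (i in seq_along(sites)) {
      nv <- null_vals[k, i, ]
      o <- if (is.matrix(obs)) obs[k, i] else obs[i]
      mu <- mean(nv)
      sdv <- sd(nv)
      ses <- if (is.na(sdv) || sdv < 1e-12) NA_real_ else (o - mu) / sdv
      rank_p <- if (is.na(o) || all(is.na(nv))) NA_real_ else
        (sum(nv <= o, na.rm = TRUE) + 1) / (n_perm + 1)
      rows[[length(rows) + 1]] <- tibble(
        site = sites[i], metric = metric[k], obs = o,
        null_mean = mu, null_sd = sdv, ses = ses,
        rank_p = rank_p, n_perm = n_perm
      )
    }
  }
  out <- list_rbind(rows)
  if (any(!is.na(out$obs) & is.na(out$ses))) {
    warn("null SD is zero for some site/metric: metric invariant under tip relabeling; SES reported as NA")
  }
  out
}
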