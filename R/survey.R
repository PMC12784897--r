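# Survey tables: long tibbles with one row per (site, species) occurrence and
# paired count/biomass columns. All diversity functions accept this shape.

#' Validate a fish survey table
#'
#' Checks the structural invariants of a long survey table: columns
#' `site`, `species`, `count`, `biomass`; no duplicated (site, species)
#' rows; non-negative counts and biomass; and no biomass recorded for a
#' species with zero individuals.
#'
#' @param survey A data frame with columns `site`, `species`, `count`
#'   (non-negative integers) and `biomass` (non-negative, kg).
#' @return The validated survey as a tibble (invisibly usable in pipes).
#' @examples
#' validate_survey(tibble::tibble(
#'   site = c("S1", "S1", "S2"), species = c("A", "B", "A"),
#'   count = c(3, 1, 2), biomass = c(0.5, 0.2, 0.4)
#' ))
#' @export
validate_survey <- function(survey) {
  required <- c("site", "species", "count", "biomass")
  missing_cols <- setdiff(required, names(survey))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "survey table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  survey <- as_tibble(survey)
  survey$site <- as.character(survey$site)
  survey$species <- as.character(survey$species)
  dup <- duplicated(survey[c("site", "species")])
  if (any(dup)) {
    offenders <- unique(paste0(
      "(", survey$site[dup], ", ", survey$species[dup], ")"
    ))
    abort(paste0(
      "duplicate (site, species) rows: ",
      paste(head(offenders, 5), collapse = " ")
    ))
  }
  if (any(!is.finite(survey$count)) || any(!is.finite(survey$biomass))) {
    abort("count and biomass must be finite")
  }
  if (any(survey$count < 0) || any(survey$biomass < 0)) {
    abort("negative count or biomass")
  }
  if (any(abs(survey$count - round(survey$count)) > 1e-8)) {
    abort("count must be whole numbers of individuals")
  }
  bad <- survey$biomass > 0 & survey$count == 0
  if (any(bad)) {
    abort(paste0(
      "biomass without individuals at: ",
      paste(head(paste0("(", survey$site[bad], ", ", survey$species[bad], ")"), 5),
            collapse = " ")
    ))
  }
  survey
}

#' Read a survey table from CSV
#'
#' The canonical layout is long (one row per site-species occurrence,
#' columns `site,species,count,biomass`). A wide layout — two site-by-species
#' matrices, one of counts and one of biomass — is accepted for convenience.
#' Species whose total count is zero are dropped with a warning.
#'
#' @param path Path to the (count, for `layout = "wide"`) CSV file.
#' @param layout `"long"` (default) or `"wide"`.
#' @param biomass_path For `layout = "wide"`, path to the biomass matrix CSV
#'   (same sites and species as the count matrix); if `NULL`, biomass is 0.
#' @return A validated survey tibble.
#' @seealso [write_survey()], [validate_survey()]
#' @export
read_survey <- function(path, layout = c("long", "wide"), biomass_path = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (layout == "long") {
    survey <- readr::read_csv(path, show_col_types = FALSE)
  } else {
    counts <- readr::read_csv(path, show_col_types = FALSE)
    site_col <- names(counts)[1]
    long_counts <- pivot_longer(counts, -1, names_to = "species",
                                values_to = "count")
    names(long_counts)[1] <- "site"
    if (!is.null(biomass_path)) {
      bm <- readr::read_csv(biomass_path, show_col_types = FALSE)
      long_bm <- pivot_longer(bm, -1, names_to = "species",
                              values_to = "biomass")
      names(long_bm)[1] <- "site"
      survey <- left_join(long_counts, long_bm, by = c("site", "species"))
      if (any(is.na(survey$biomass))) {
        abort("wide biomass matrix does not cover all count cells")
      }
    } else {
      survey <- mutate(long_counts, biomass = 0)
    }
    survey <- filter(survey, .data$count > 0 | .data$biomass > 0)
  }
  survey <- validate_survey(survey)
  totals <- tapply(survey$count, survey$species, sum)
  absent <- names(totals)[totals == 0]
  if (length(absent) > 0) {
    warn(paste0(
      "dropping species with zero total count: ",
      paste(absent, collapse = ", ")
    ))
    survey <- filter(survey, !(.data$species %in% absent))
  }
  survey
}

#' Write a survey table to CSV (long layout)
#'
#' @param survey A validated survey tibble.
#' @param path Output CSV path.
#' @return `survey`, invisibly.
#' @export
write_survey <- function(survey, path) {
  survey <- validate_survey(survey)
  readr::write_csv(survey, path)
  invisible(survey)
}

#' Site-by-species matrix from a long survey table
#'
#' @param survey A survey tibble.
#' @param value `"count"`, `"biomass"`, or `"presence"` (0/1).
#' @return A numeric matrix, sites in rows (first-appearance order),
#'   species in columns; absent cells are 0.
#' @export
survey_matrix <- function(survey, value = c("count", "biomass", "presence")) {
  value <- match.arg(value)
  survey <- validate_survey(survey)
  sites <- unique(survey$site)
  species <- unique(survey$species)
  m <- matrix(0, length(sites), length(species),
              dimnames = list(sites, species))
  v <- if (value == "presence") as.numeric(survey$count > 0)
       else survey[[value]]
  m[cbind(survey$site, survey$species)] <- v
  m
}

#' Read a site-by-variable environment table
#'
#' First column is the site label; remaining columns are environmental
#' variables. Variables with zero variance across sites are retained here
#' and excluded (with a warning) where standardization requires variance.
#'
#' @param path CSV path.
#' @return A tibble with a `site` column and one column per variable.
#' @export
read_environment <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  env <- readr::read_csv(path, show_col_types = FALSE)
  names(env)[1] <- "site"
  env$site <- as.character(env$site)
  if (anyDuplicated(env$site)) abort("duplicate site rows in environment table")
  if (any(!vapply(env[-1], is.numeric, logical(1)))) {
    abort("environmental variables must be numeric")
  }
  env
}

#' Read river geometry: distances to the dam and between sites
#'
#' @param dam_path CSV with columns `site,dam_km` (river distance to dam).
#' @param pair_path CSV holding a square site-by-site river-distance matrix
#'   (first column = site labels). If `NULL`, pairwise distances are derived
#'   as absolute differences of dam distances (single-channel geometry).
#' @return A `river_layout` list with elements `dam_distance` (tibble) and
#'   `pair_distance` (named symmetric matrix, km).
#' @export
read_layout <- function(dam_path, pair_path = NULL) {
  if (!file.exists(dam_path)) abort(paste0("no such file: ", dam_path))
  dam <- readr::read_csv(dam_path, show_col_types = FALSE)
  names(dam)[1:2] <- c("site", "dam_km")
  dam$site <- as.character(dam$site)
  if (is.null(pair_path)) {
    pd <- abs(outer(dam$dam_km, dam$dam_km, "-"))
    dimnames(pd) <- list(dam$site, dam$site)
  } else {
    raw <- readr::read_csv(pair_path, show_col_types = FALSE)
    pd <- as.matrix(raw[-1])
    rownames(pd) <- as.character(raw[[1]])
    pd <- pd[, rownames(pd), drop = FALSE]
  }
  new_layout(dam, pd)
}

new_layout <- function(dam_distance, pair_distance) {
  if (!isTRUE(all.equal(pair_distance, t(pair_distance), tolerance = 1e-8))) {
    abort("pair_distance matrix must be symmetric")
  }
  if (any(pair_distance < 0)) abort("river distances must be non-negative")
  if (any(abs(diag(pair_distance)) > 1e-12)) {
    abort("pair_distance diagonal must be zero")
  }
  structure(
    list(dam_distance = as_tibble(dam_distance), pair_distance = pair_distance),
    class = "river_layout"
  )
}

#' @export
print.river_layout <- function(x, ...) {
  cat("River layout:", nrow(x$dam_distance), "sites,",
      "dam distance", round(min(x$dam_distance$dam_km), 2), "-",
      round(max(x$dam_distance$dam_km), 2), "km\n")
  invisible(x)
}

#' Align survey, tree, environment and layout to a common site/species set
#'
#' Ensures all tables refer to identical sites and that every surveyed
#' species is a tree tip. Under `policy = "strict"` (default) any mismatch
#' is an error naming the offending labels — silent dropping would change
#' every downstream phylogenetic quantity. Under `policy = "prune"`, tree
#' tips not in the survey are pruned and surveyed species missing from the
#' tree are dropped with a warning.
#'
#' @param survey Survey tibble.
#' @param tree An `ape::phylo` tree.
#' @param env Optional environment tibble (`NULL` to skip).
#' @param layout Optional `river_layout` (`NULL` to skip).
#' @param policy `"strict"` or `"prune"`.
#' @return A list with elements `survey`, `tree`, `env`, `layout`, all
#'   mutually consistent. Idempotent: aligning twice equals aligning once.
#' @export
align_inputs <- function(survey, tree, env = NULL, layout = NULL,
                         policy = c("strict", "prune")) {
  policy <- match.arg(policy)
  survey <- validate_survey(survey)
  sp_survey <- unique(survey$species)
  sp_tree <- tree$tip.label
  missing_from_tree <- setdiff(sp_survey, sp_tree)
  extra_tips <- setdiff(sp_tree, sp_survey)
  if (policy == "strict") {
    if (length(missing_from_tree) > 0 || length(extra_tips) > 0) {
      abort(paste0(
        "survey and tree species differ. ",
        if (length(missing_from_tree) > 0)
          paste0("Not in tree: ", paste(missing_from_tree, collapse = ", "), ". "),
        if (length(extra_tips) > 0)
          paste0("Tree-only tips: ", paste(extra_tips, collapse = ", "), ".")
      ))
    }
  } else {
    if (length(missing_from_tree) > 0) {
      warn(paste0(
        "dropping surveyed species absent from tree: ",
        paste(missing_from_tree, collapse = ", ")
      ))
      survey <- filter(survey, !(.data$species %in% missing_from_tree))
    }
    if (length(extra_tips) > 0) {
      tree <- ape::keep.tip(tree, setdiff(sp_tree, extra_tips))
    }
  }
  sites <- unique(survey$site)
  check_sites <- function(got, what) {
    if (!setequal(got, sites)) {
      miss <- setdiff(sites, got)
      extra <- setdiff(got, sites)
      abort(paste0(
        what, " sites do not match survey sites. ",
        if (length(miss) > 0) paste0("Missing: ", paste(miss, collapse = ", "), ". "),
        if (length(extra) > 0) paste0("Extra: ", paste(extra, collapse = ", "), ".")
      ))
    }
  }
  if (!is.null(env)) {
    check_sites(env$site, "environment")
    env <- env[match(sites, env$site), , drop = FALSE]
  }
  if (!is.null(layout)) {
    check_sites(layout$dam_distance$site, "layout")
    dam <- layout$dam_distance[match(sites, layout$dam_distance$site), ]
    pd <- layout$pair_distance[sites, sites, drop = FALSE]
    layout <- new_layout(dam, pd)
  }
  list(survey = survey, tree = tree, env = env, layout = layout)
}
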