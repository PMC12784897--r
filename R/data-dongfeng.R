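# Published composition summary of the Dongfeng Reservoir fish assemblage
# (karst upper Wujiang, southwest China): 23 species surveyed at 9 sites,
# with occurrence frequency, relative abundance, relative biomass (all as
# printed percentages, 2 dp) and the reported IRI. Serves as the worked
# example for the dominance index.

#' Dongfeng Reservoir fish composition summary
#'
#' Per-species occurrence frequency (`occurrence_pct`, percent of the 9
#' sites occupied), relative abundance and relative biomass
#' (`abundance_pct`, `biomass_pct`, pool-wide percentages) and the
#' dominance index as reported (`iri_reported`), with order and family.
#' The percentage columns are printed at 2 decimal places, which bounds
#' how precisely `iri_reported` can be re-derived from them.
#'
#' @return A 23-row tibble.
#' @examples
#' comp <- dongfeng_composition()
#' iri_score(comp$occurrence_pct / 100, comp$abundance_pct / 100,
#'           comp$biomass_pct / 100)
#' @export
dongfeng_composition <- function() {
  path <- system.file("extdata", "dongfeng_composition.csv",
                      package = "fishdiv", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Taxonomic breadth of a composition table
#'
#' @param composition A tibble with `species`, `family`, `order` columns,
#'   e.g. [dongfeng_composition()].
#' @return One-row tibble: `n_species`, `n_families`, `n_orders`.
#' @export
composition_summary <- function(composition) {
  tibble(
    n_species = length(unique(composition$species)),
    n_families = length(unique(composition$family)),
    n_orders = length(unique(composition$order))
  )
}
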