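# Packaged case-study fixtures: the UK lowland candidate lists.
#
# The fixtures encode raw trait values, not scores, so loading them
# exercises the full rubric path. Raw values are rubric-consistent with
# every published per-trait component; the exact value chosen within a bin
# is arbitrary (e.g. a floral-display component of 1 is encoded as 12 mm,
# of 0 as 8 mm; a grass leaf-area class of 4 as 27 mm^2). "?" cells are
# preserved as missing values. Flowering months and the two species
# recorded as not commercially sourceable (Galium verum, Prunella vulgaris)
# follow the case-study narrative; heavy-clay and sandy-loam suitability
# were not published and are shipped as missing.

#' Load a packaged case-study fixture
#'
#' @param which `"table4_grasses"` (7 assessed grasses) or
#'   `"table5_forbs"` (24 assessed forbs).
#' @return A species table (tibble).
#' @export
case_study_fixture <- function(which = c("table4_grasses", "table5_forbs")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "seedmix",
                      mustWork = TRUE)
  read_species_table(path)
}
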