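# In-code fixtures: a fully populated valid record with per-field overrides.

make_record <- function(botanical_name = "Testula plantula",
                        growth_form = "forb", ...) {
  row <- tibble::tibble(
    botanical_name = botanical_name,
    growth_form = growth_form,
    life_history = "perennial",
    native_status = "native",
    regional_distribution = TRUE,
    floral_display_mm = 12,
    trichome_density = "numerous",
    leaf_area_mm2 = 30,
    root_system = if (growth_form == "grass") "adventitious" else "tap-root",
    leaf_phenology = "evergreen",
    soil_most_soils = TRUE,
    soil_heavy_clay = NA,
    soil_sandy_loam = NA,
    established_strategy = "CSR",
    max_height_mm = 600,
    associated_floristic_diversity = 16,
    pollinator_support = TRUE,
    commercially_available = TRUE)
  row$flowering_months <- list(5:8)
  row <- row[, species_columns()]
  overrides <- list(...)
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    row[[nm]] <- if (nm == "flowering_months") list(v) else v
  }
  row
}

make_table <- function(...) {
  do.call(rbind, list(...))
}

table5_totals <- c(
  "Trifolium pratense" = 9, "Trifolium repens" = 9, "Centaurea nigra" = 8,
  "Taraxacum officinale agg." = 8, "Stachys sylvatica" = 8,
  "Leucanthemum vulgare" = 8, "Prunella vulgaris" = 8,
  "Lotus corniculatus" = 7, "Daucus carota" = 7, "Achillea millefolium" = 7,
  "Galium verum" = 7, "Ranunculus acris" = 6, "Silene dioica" = 6,
  "Veronica chamaedrys" = 5, "Hypochaeris radicata" = 4,
  "Primula vulgaris" = 4, "Heracleum sphondylium" = 2, "Vicia cracca" = 2,
  "Potentilla erecta" = 2, "Scrophularia nodosa" = 1, "Knautia arvensis" = 1,
  "Malva moschata" = 1, "Potentilla anserina" = 1, "Geranium pratense" = 1)

table4_totals <- c(
  "Agrostis capillaris" = 11, "Festuca pratensis" = 11, "Phleum pratense" = 9,
  "Dactylis glomerata" = 9, "Alopecurus pratensis" = 9,
  "Festuca rubra agg." = 8, "Festuca arundinacea" = 6)
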