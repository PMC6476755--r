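# Species trait table: schema, CSV I/O and validation.
#
# One row per candidate species. Missing trait data is NA in R and the
# literal token "?" on disk; the two representations round-trip exactly.

.base_columns_pre_soil <- c(
  "botanical_name", "growth_form", "life_history", "native_status",
  "regional_distribution", "floral_display_mm", "trichome_density",
  "leaf_area_mm2", "root_system", "leaf_phenology"
)
.base_columns_post_soil <- c(
  "established_strategy", "max_height_mm", "associated_floristic_diversity",
  "flowering_months", "pollinator_support", "commercially_available"
)
.default_soil_profiles <- c("most_soils", "heavy_clay", "sandy_loam")

.growth_forms <- c("forb", "grass")
.life_histories <- c("annual", "biennial", "perennial")
.native_statuses <- c("native", "non-native")
.trichome_levels <- c("sparse", "numerous")
.root_levels <- c("tap-root", "adventitious")
.phenology_levels <- c("estival", "evergreen")
.csr_codes <- c("C", "R", "S", "CR", "SC", "SR", "CSR")

#' Canonical species-table column order
#'
#' The documented CSV schema: fixed trait and factor columns with one logical
#' `soil_<profile>` column per declared soil profile, inserted between
#' `leaf_phenology` and `established_strategy`.
#'
#' @param soil_profiles Character vector of soil profile names.
#' @return Character vector of column names in canonical order.
#' @export
species_columns <- function(soil_profiles = .default_soil_profiles) {
  c(.base_columns_pre_soil, paste0("soil_", soil_profiles),
    .base_columns_post_soil)
}

soil_column_names <- function(records) {
  grep("^soil_", names(records), value = TRUE)
}

#' Soil profiles declared in a species table
#'
#' @param records A species table (tibble).
#' @return Character vector of profile names (the `soil_` columns without
#'   their prefix).
#' @export
soil_profiles <- function(records) {
  sub("^soil_", "", soil_column_names(records))
}

# label normalization: categories are matched case-insensitively, stored
# lower-case with hyphenated compounds ("Tap root" -> "tap-root"); CSR codes
# are stored upper-case.
normalize_category <- function(x) {
  out <- gsub("[ _]+", "-", tolower(trimws(x)))
  out[!nzchar(out) | out == "?"] <- NA_character_
  out
}

normalize_csr <- function(x) {
  out <- toupper(trimws(x))
  out[!nzchar(out) | out == "?"] <- NA_character_
  out
}

parse_months <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s)) || trimws(s) == "?") return(integer(0))
    v <- suppressWarnings(as.integer(strsplit(trimws(s), ";", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop("unparseable flowering_months entry: '", s, "'",
                       call. = FALSE)
    sort(unique(v))
  })
}

format_months <- function(m) {
  vapply(m, function(v) paste(sort(unique(as.integer(v))), collapse = ";"),
         character(1))
}

.parse_numeric_col <- function(x, field, species) {
  x <- trimws(x)
  miss <- is.na(x) | x == "?" | x == ""
  out <- rep(NA_real_, length(x))
  v <- suppressWarnings(as.numeric(x[!miss]))
  if (anyNA(v)) {
    bad <- species[!miss][is.na(v)][1]
    stop("species '", bad, "': field '", field, "' is not numeric",
         call. = FALSE)
  }
  out[!miss] <- v
  out
}

.parse_logical_col <- function(x, field, species) {
  x <- tolower(trimws(x))
  miss <- is.na(x) | x == "?" | x == ""
  out <- rep(NA, length(x))
  truthy <- x %in% c("true", "t", "1", "yes")
  falsy <- x %in% c("false", "f", "0", "no")
  bad <- !miss & !truthy & !falsy
  if (any(bad)) {
    stop("species '", species[bad][1], "': field '", field,
         "' is not a true/false value", call. = FALSE)
  }
  out[truthy] <- TRUE
  out[falsy] <- FALSE
  out
}

#' Read a species trait table from CSV
#'
#' Parses the documented schema: "?" cells become missing values (`NA`),
#' category labels are case-normalized, CSR codes upper-cased, flowering
#' months split on ";" into integer sets, and row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param schema_version Schema version string; only `"1"` is defined.
#' @return A tibble with one row per species; `flowering_months` is a
#'   list-column of integer vectors.
#' @export
read_species_table <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown schema_version '", schema_version, "'", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), fileEncoding = "UTF-8")
  fixed <- c(.base_columns_pre_soil, .base_columns_post_soil)
  unknown <- setdiff(names(raw), fixed)
  unknown <- unknown[!grepl("^soil_", unknown)]
  if (length(unknown) > 0) {
    stop("schema error: unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(fixed, names(raw))
  if (length(absent) > 0) {
    stop("schema error: missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  soil_cols <- grep("^soil_", names(raw), value = TRUE)
  if (length(soil_cols) == 0) {
    stop("schema error: no soil_<profile> column declared", call. = FALSE)
  }
  species <- trimws(raw$botanical_name)
  if (anyDuplicated(species) > 0) {
    dup <- species[duplicated(species)][1]
    stop("validation error: duplicate botanical_name '", dup, "'",
         call. = FALSE)
  }
  out <- tibble::tibble(
    botanical_name = species,
    growth_form = normalize_category(raw$growth_form),
    life_history = normalize_category(raw$life_history),
    native_status = normalize_category(raw$native_status),
    regional_distribution = .parse_logical_col(raw$regional_distribution,
                                               "regional_distribution", species),
    floral_display_mm = .parse_numeric_col(raw$floral_display_mm,
                                           "floral_display_mm", species),
    trichome_density = normalize_category(raw$trichome_density),
    leaf_area_mm2 = .parse_numeric_col(raw$leaf_area_mm2, "leaf_area_mm2",
                                       species),
    root_system = normalize_category(raw$root_system),
    leaf_phenology = normalize_category(raw$leaf_phenology)
  )
  for (sc in soil_cols) out[[sc]] <- .parse_logical_col(raw[[sc]], sc, species)
  out$established_strategy <- normalize_csr(raw$established_strategy)
  out$max_height_mm <- .parse_numeric_col(raw$max_height_mm, "max_height_mm",
                                          species)
  out$associated_floristic_diversity <- .parse_numeric_col(
    raw$associated_floristic_diversity, "associated_floristic_diversity",
    species)
  out$flowering_months <- parse_months(raw$flowering_months)
  out$pollinator_support <- .parse_logical_col(raw$pollinator_support,
                                               "pollinator_support", species)
  out$commercially_available <- .parse_logical_col(raw$commercially_available,
                                                   "commercially_available",
                                                   species)
  out[, species_columns(sub("^soil_", "", soil_cols))]
}

format_cell <- function(x) {
  if (is.logical(x)) {
    out <- ifelse(is.na(x), "?", ifelse(x, "true", "false"))
  } else if (is.numeric(x)) {
    out <- ifelse(is.na(x), "?", vapply(x, function(v) {
      if (is.na(v)) "?" else format(v, scientific = FALSE, trim = TRUE)
    }, character(1)))
  } else {
    out <- ifelse(is.na(x), "?", as.character(x))
  }
  out
}

#' Write a species trait table to CSV
#'
#' Deterministic column order (see [species_columns()]), missing values
#' rendered as `"?"`, booleans as `true`/`false`, flowering months as
#' semicolon-separated integers, UTF-8 encoding. Re-reading the file
#' recovers the input records exactly.
#'
#' @param records Species table (tibble) as returned by
#'   [read_species_table()] or [generate_species_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(records, path) {
  cols <- species_columns(soil_profiles(records))
  absent <- setdiff(cols, names(records))
  if (length(absent) > 0) {
    stop("records are missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- records[, cols]
  chr <- lapply(names(out), function(nm) {
    if (nm == "flowering_months") format_months(out[[nm]]) else
      format_cell(out[[nm]])
  })
  df <- as.data.frame(setNames(chr, names(out)), check.names = FALSE,
                      stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Export species records as JSON
#'
#' Same field names as the CSV schema; flowering months as integer arrays,
#' missing values as `null`.
#'
#' @inheritParams write_species_table
#' @return `path`, invisibly.
#' @export
export_species_json <- function(records, path) {
  jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

new_finding <- function(species, field, severity, rule, message) {
  tibble::tibble(botanical_name = species, field = field, severity = severity,
                 rule = rule, message = message)
}

empty_findings <- function() {
  new_finding(character(0), character(0), character(0), character(0),
              character(0))
}

#' Validate a species trait table
#'
#' Checks the type and domain invariants of the schema and returns findings
#' rather than raising: each finding names the species, field, severity and
#' rule violated. An empty result means all invariants hold. The input is
#' never modified.
#'
#' Rules checked include: non-empty unique botanical names; recognized
#' category labels; grasses with a recorded root system must be adventitious
#' (a required water-quality trait for the grass component); flowering
#' months within 1..12 and non-empty for forbs; non-negative sizes and
#' positive heights; associated floristic diversity at one-decimal
#' resolution (warning).
#'
#' @param records Species table (tibble); a single row validates one record.
#' @return A tibble of findings (zero rows when valid).
#' @export
validate_species <- function(records) {
  findings <- list(empty_findings())
  nm <- records$botanical_name
  add <- function(idx, field, severity, rule, message) {
    if (length(idx) > 0 && any(idx)) {
      findings[[length(findings) + 1]] <<-
        new_finding(nm[idx], field, severity, rule, message)
    }
  }
  if (nrow(records) == 0) return(empty_findings())

  add(is.na(nm) | !nzchar(trimws(nm)), "botanical_name", "error",
      "name_nonempty", "botanical_name must be non-empty")
  add(duplicated(nm), "botanical_name", "error", "name_unique",
      "botanical_name must be unique within a table")
  add(!(records$growth_form %in% .growth_forms), "growth_form", "error",
      "growth_form_domain", "growth_form must be 'forb' or 'grass'")
  add(!is.na(records$life_history) &
        !(records$life_history %in% .life_histories),
      "life_history", "error", "life_history_domain",
      "life_history must be annual, biennial or perennial")
  add(!is.na(records$native_status) &
        !(records$native_status %in% .native_statuses),
      "native_status", "error", "native_status_domain",
      "native_status must be native or non-native")
  add(!is.na(records$trichome_density) &
        !(records$trichome_density %in% .trichome_levels),
      "trichome_density", "error", "trichome_domain",
      "trichome_density must be sparse or numerous")
  add(!is.na(records$root_system) & !(records$root_system %in% .root_levels),
      "root_system", "error", "root_system_domain",
      "root_system must be tap-root or adventitious")
  add(!is.na(records$leaf_phenology) &
        !(records$leaf_phenology %in% .phenology_levels),
      "leaf_phenology", "error", "phenology_domain",
      "leaf_phenology must be estival or evergreen")
  add(!is.na(records$established_strategy) &
        !(records$established_strategy %in% .csr_codes),
      "established_strategy", "error", "csr_domain",
      "established_strategy must be a CSR code (C,R,S,CR,SC,SR,CSR)")
  add(records$growth_form == "grass" & !is.na(records$root_system) &
        records$root_system != "adventitious",
      "root_system", "error", "grass_adventitious_root",
      "grasses must have an adventitious root system")
  bad_months <- vapply(records$flowering_months,
                       function(m) length(m) > 0 && any(m < 1 | m > 12),
                       logical(1))
  add(bad_months, "flowering_months", "error", "month_range",
      "flowering months must lie in 1..12")
  empty_months <- lengths(records$flowering_months) == 0
  add(empty_months & records$growth_form == "forb", "flowering_months",
      "error", "forb_flowering_required",
      "forbs must have at least one flowering month")
  add(!is.na(records$floral_display_mm) & records$floral_display_mm < 0,
      "floral_display_mm", "error", "nonnegative",
      "floral display size cannot be negative")
  add(!is.na(records$leaf_area_mm2) & records$leaf_area_mm2 < 0,
      "leaf_area_mm2", "error", "nonnegative",
      "leaf area cannot be negative")
  add(!is.na(records$max_height_mm) & records$max_height_mm <= 0,
      "max_height_mm", "error", "positive",
      "maximum height must be positive")
  afd <- records$associated_floristic_diversity
  add(!is.na(afd) & afd < 0, "associated_floristic_diversity", "error",
      "nonnegative", "associated floristic diversity cannot be negative")
  add(!is.na(afd) & abs(afd * 10 - round(afd * 10)) > 1e-8,
      "associated_floristic_diversity", "warning", "one_decimal",
      "associated floristic diversity is binned at one-decimal resolution")
  do.call(rbind, findings)
}

#' @rdname validate_species
#' @param record A one-row species table.
#' @export
validate_record <- function(record) {
  stopifnot(nrow(record) == 1)
  validate_species(record)
}
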