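# Seeded synthetic trait-table generator.
#
# Emulates the structure of a compiled national trait database: schema-valid
# records with trait values distributed over the rubric bin domains, a
# configurable per-trait missing-data rate, optionally planted "winner"
# species with strictly dominant traits and planted establishment-gate
# failures. The generator carries its own independently written rule tables
# (plain if/else transcriptions of the published ranking system, sharing no
# code with the rubric engine) and reports every species' expected component
# scores and gate failures in a ground-truth manifest, so it doubles as a
# scoring oracle.

# --- independent oracle rule tables (do not refactor onto rubric.R) --------

oracle_forb_components <- function(row) {
  c(floral_display = if (is.na(row$floral_display_mm)) 0L else
      if (row$floral_display_mm >= 10) 1L else 0L,
    trichome_density = if (is.na(row$trichome_density)) 0L else
      if (row$trichome_density == "numerous") 1L else 0L,
    leaf_area = if (is.na(row$leaf_area_mm2)) 0L else
      if (row$leaf_area_mm2 >= 25) 1L else 0L,
    root_system = if (is.na(row$root_system)) 0L else
      if (row$root_system == "adventitious") 1L else 0L,
    leaf_phenology = if (is.na(row$leaf_phenology)) 0L else
      if (row$leaf_phenology == "evergreen") 1L else 0L,
    soil = if (is.na(row$soil_most_soils)) 0L else
      if (row$soil_most_soils) 5L else 0L)
}

oracle_grass_components <- function(row) {
  la <- row$leaf_area_mm2
  leaf_class <- if (is.na(la)) 1L else if (la < 15) 1L else if (la < 20) 2L
    else if (la < 25) 3L else if (la < 30) 4L else 5L
  st <- row$established_strategy
  strat <- if (is.na(st)) 0L else if (st %in% c("C", "SC", "CR")) 0L else 1L
  h <- row$max_height_mm
  height <- if (is.na(h)) 0L else if (h <= 750) 3L else if (h < 1500) 2L
    else if (h < 2000) 1L else 0L
  a <- row$associated_floristic_diversity
  afd <- if (is.na(a)) 1L else if (a <= 10) 1L else if (a <= 14) 2L
    else if (a <= 18) 3L else if (a <= 22) 4L else 5L
  c(leaf_area_class = leaf_class, established_strategy = strat,
    height = height, associated_floristic_diversity = afd)
}

oracle_total <- function(row) {
  if (row$growth_form == "forb") sum(oracle_forb_components(row))
  else sum(oracle_grass_components(row))
}

# ---------------------------------------------------------------------------

.sample_months <- function(n) {
  start <- sample(3:8, n, replace = TRUE)
  len <- sample(0:4, n, replace = TRUE)
  lapply(seq_len(n), function(i) start[i]:min(start[i] + len[i], 10L))
}

empty_species_table <- function(soil = .default_soil_profiles) {
  out <- tibble::tibble(
    botanical_name = character(0), growth_form = character(0),
    life_history = character(0), native_status = character(0),
    regional_distribution = logical(0), floral_display_mm = numeric(0),
    trichome_density = character(0), leaf_area_mm2 = numeric(0),
    root_system = character(0), leaf_phenology = character(0))
  for (p in soil) out[[paste0("soil_", p)]] <- logical(0)
  out$established_strategy <- character(0)
  out$max_height_mm <- numeric(0)
  out$associated_floristic_diversity <- numeric(0)
  out$flowering_months <- list()
  out$pollinator_support <- logical(0)
  out$commercially_available <- logical(0)
  out
}

.gen_many <- function(names, gf) {
  n <- length(names)
  rows <- tibble::tibble(
    botanical_name = names,
    growth_form = gf,
    life_history = "perennial",
    native_status = "native",
    regional_distribution = TRUE,
    floral_display_mm = round(runif(n, 2, 30), 1),
    trichome_density = sample(.trichome_levels, n, replace = TRUE),
    leaf_area_mm2 = round(runif(n, 5, 45), 1),
    root_system = if (gf == "grass") "adventitious" else
      sample(.root_levels, n, replace = TRUE),
    leaf_phenology = sample(.phenology_levels, n, replace = TRUE),
    soil_most_soils = runif(n) < 0.6,
    soil_heavy_clay = runif(n) < 0.5,
    soil_sandy_loam = runif(n) < 0.5,
    established_strategy = sample(.csr_codes, n, replace = TRUE),
    max_height_mm = round(runif(n, 100, 2500)),
    associated_floristic_diversity = round(runif(n, 4, 28), 1),
    pollinator_support = if (gf == "forb") TRUE else runif(n) < 0.2,
    commercially_available = runif(n) < 0.9)
  rows$flowering_months <- .sample_months(n)
  rows[, species_columns()]
}

.forb_rubric_fields <- c("floral_display_mm", "trichome_density",
                         "leaf_area_mm2", "root_system", "leaf_phenology",
                         "soil_most_soils")
.grass_rubric_fields <- c("leaf_area_mm2", "established_strategy",
                          "max_height_mm", "associated_floristic_diversity")

#' Generate a synthetic species trait table
#'
#' Produces a schema-valid table with trait values sampled over the rubric
#' bin domains, together with a ground-truth manifest computed by the
#' generator's own independent rule tables (an oracle sharing no code with
#' the scoring engine). Identical seed and configuration give identical
#' output, byte-for-byte after serialization.
#'
#' Planted winners (forbs) receive maximal trait values on every rubric
#' trait and no missing data; all other forbs are capped strictly below the
#' maximum total, so winners occupy the top ranks by construction. Planted
#' gate failures set the offending establishment field on otherwise-passing
#' species (disjointly, one criterion per planted species).
#'
#' @param n_forbs,n_grasses Species counts.
#' @param missing_rate Per-trait probability, in `[0, 1]`, that a rubric
#'   trait value is missing (applied to non-planted species only).
#' @param planted_winners Number of dominant forbs to plant
#'   (`<= n_forbs`).
#' @param planted_gate_failures Named list mapping a criterion
#'   (`life_history`, `native_status`, `regional_distribution`,
#'   `pollinator_support`) to the count of species planted to fail it.
#' @param seed Integer seed; every source of randomness flows from it.
#' @return A list with `records` (species table) and `manifest` (tibble:
#'   `botanical_name`, `growth_form`, `is_winner`, `planted_failure`,
#'   `expected_total`, `expected_missing` count).
#' @export
generate_species_table <- function(n_forbs = 20, n_grasses = 10,
                                   missing_rate = 0.05, planted_winners = 0,
                                   planted_gate_failures = list(),
                                   seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1) {
    stop("config error: missing_rate must lie in [0, 1]", call. = FALSE)
  }
  if (planted_winners > n_forbs) {
    stop("config error: planted_winners exceeds n_forbs", call. = FALSE)
  }
  valid_gates <- c("life_history", "native_status", "regional_distribution",
                   "pollinator_support")
  if (length(planted_gate_failures) > 0 &&
      !all(names(planted_gate_failures) %in% valid_gates)) {
    stop("config error: unknown gate criterion in planted_gate_failures",
         call. = FALSE)
  }
  n_failures <- sum(unlist(planted_gate_failures))
  if (planted_winners + n_failures > n_forbs + n_grasses) {
    stop("config error: more planted species than generated species",
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  if (n_forbs + n_grasses == 0) {
    return(list(records = empty_species_table(),
                manifest = tibble::tibble(
                  botanical_name = character(0), growth_form = character(0),
                  is_winner = logical(0), planted_failure = character(0),
                  expected_total = integer(0), expected_missing = integer(0))))
  }

  parts <- list()
  if (n_forbs > 0) {
    parts <- c(parts, list(.gen_many(
      sprintf("Forbus synthetica %03d", seq_len(n_forbs)), "forb")))
  }
  if (n_grasses > 0) {
    parts <- c(parts, list(.gen_many(
      sprintf("Gramen syntheticum %03d", seq_len(n_grasses)), "grass")))
  }
  records <- do.call(rbind, parts)
  n <- nrow(records)

  winner_idx <- if (planted_winners > 0) seq_len(planted_winners) else
    integer(0)
  if (length(winner_idx) > 0) {
    records$floral_display_mm[winner_idx] <- 30
    records$trichome_density[winner_idx] <- "numerous"
    records$leaf_area_mm2[winner_idx] <- 45
    records$root_system[winner_idx] <- "adventitious"
    records$leaf_phenology[winner_idx] <- "evergreen"
    records$soil_most_soils[winner_idx] <- TRUE
    records$pollinator_support[winner_idx] <- TRUE
    records$commercially_available[winner_idx] <- TRUE
    records$flowering_months[winner_idx] <- list(3:10)
  }

  # plant gate failures on distinct non-winner species
  pool <- setdiff(seq_len(n), winner_idx)
  planted_failure <- rep(NA_character_, n)
  for (crit in names(planted_gate_failures)) {
    k <- planted_gate_failures[[crit]]
    if (k == 0) next
    take_pool <- if (crit == "pollinator_support")
      intersect(pool, which(records$growth_form == "forb")) else pool
    if (k > length(take_pool)) {
      stop("config error: not enough species to plant ", crit, " failures",
           call. = FALSE)
    }
    take <- take_pool[seq_len(k)]
    pool <- setdiff(pool, take)
    planted_failure[take] <- crit
    switch(crit,
           life_history = {records$life_history[take] <- "annual"},
           native_status = {records$native_status[take] <- "non-native"},
           regional_distribution = {
             records$regional_distribution[take] <- FALSE},
           pollinator_support = {records$pollinator_support[take] <- FALSE})
  }

  # missing data on non-winner rubric traits
  if (missing_rate > 0) {
    for (i in setdiff(seq_len(n), winner_idx)) {
      fields <- if (records$growth_form[i] == "forb") .forb_rubric_fields
        else .grass_rubric_fields
      for (f in fields) {
        if (runif(1) < missing_rate) records[[f]][i] <- NA
      }
    }
  }

  # cap non-winner totals strictly below the maximum so planted winners
  # dominate
  if (length(winner_idx) > 0) {
    for (i in setdiff(seq_len(n), winner_idx)) {
      if (records$growth_form[i] == "forb" &&
          oracle_total(records[i, ]) >= 10) {
        records$floral_display_mm[i] <- 8
      }
    }
  }

  manifest <- tibble::tibble(
    botanical_name = records$botanical_name,
    growth_form = records$growth_form,
    is_winner = seq_len(n) %in% winner_idx,
    planted_failure = planted_failure,
    expected_total = vapply(seq_len(n), function(i)
      as.integer(oracle_total(records[i, ])), integer(1)),
    expected_missing = vapply(seq_len(n), function(i) {
      fields <- if (records$growth_form[i] == "forb") .forb_rubric_fields
        else .grass_rubric_fields
      sum(vapply(fields, function(f) is.na(records[[f]][i]), logical(1)))
    }, integer(1)))

  list(records = records, manifest = manifest)
}
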