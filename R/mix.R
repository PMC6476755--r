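# Seed mix assembly: combine selected forbs and grasses under a growth-form
# composition ratio, substitute commercially unavailable species with the
# best-ranked available species covering a similar flowering period, and
# report pollen/nectar coverage over the beneficial-invertebrate activity
# season (default March-October).

months_of <- function(records, name) {
  i <- match(name, records$botanical_name)
  if (is.na(i)) integer(0) else records$flowering_months[[i]]
}

is_available <- function(records, name) {
  i <- match(name, records$botanical_name)
  if (is.na(i)) return(TRUE)
  av <- records$commercially_available[i]
  is.na(av) || isTRUE(av)  # unknown availability is not grounds to drop
}

#' Substitute commercially unavailable species
#'
#' Each unavailable selected species is replaced by the available,
#' not-yet-used species from the ranked pool whose flowering months share the
#' most months with the lost species (ties broken by rank). If no candidate
#' overlaps, the highest-ranked available candidate covering the largest
#' remaining seasonal gap is taken and flagged; if the pool is exhausted the
#' species is dropped with a warning entry.
#'
#' @param selected Scorecards of the selected species (rank order).
#' @param ranked_pool Full ranked list ([rank_species()]) the selection was
#'   drawn from; must contain every selected species.
#' @param records Species table carrying `commercially_available` and
#'   `flowering_months`.
#' @param season Integer months of the activity season (for the coverage-gap
#'   fallback).
#' @return A list with `final` (scorecards) and `substitutions` (tibble
#'   `unavailable`, `substitute`, `shared_months`, `note`).
#' @export
substitute_unavailable <- function(selected, ranked_pool, records,
                                   season = 3:10) {
  stopifnot(all(selected$botanical_name %in% ranked_pool$botanical_name))
  final <- selected
  subs <- tibble::tibble(unavailable = character(0), substitute = character(0),
                         shared_months = character(0), note = character(0))
  unavailable <- selected$botanical_name[
    !vapply(selected$botanical_name, is_available, logical(1),
            records = records)]
  # process in rank order so the outcome is independent of input order
  unavailable <- unavailable[order(match(unavailable,
                                         ranked_pool$botanical_name))]
  for (lost in unavailable) {
    final <- final[final$botanical_name != lost, , drop = FALSE]
    cand <- ranked_pool[!(ranked_pool$botanical_name %in%
                            final$botanical_name) &
                          ranked_pool$botanical_name != lost, , drop = FALSE]
    cand <- cand[vapply(cand$botanical_name, is_available, logical(1),
                        records = records), , drop = FALSE]
    if (nrow(cand) == 0) {
      subs <- rbind(subs, tibble::tibble(
        unavailable = lost, substitute = NA_character_, shared_months = "",
        note = "pool exhausted; species dropped"))
      warning("no available substitute for '", lost, "'; dropped",
              call. = FALSE)
      next
    }
    lost_months <- months_of(records, lost)
    overlap <- vapply(cand$botanical_name, function(sp) {
      length(intersect(months_of(records, sp), lost_months))
    }, integer(1))
    if (any(overlap > 0)) {
      best <- cand[overlap == max(overlap), , drop = FALSE][1, ]
      shared <- intersect(months_of(records, best$botanical_name), lost_months)
      note <- "flowering-period match"
    } else {
      covered <- sort(unique(unlist(lapply(final$botanical_name, months_of,
                                           records = records))))
      gap <- setdiff(season, covered)
      gap_fill <- vapply(cand$botanical_name, function(sp) {
        length(intersect(months_of(records, sp), gap))
      }, integer(1))
      best <- cand[gap_fill == max(gap_fill), , drop = FALSE][1, ]
      shared <- integer(0)
      note <- "no flowering overlap; best coverage-gap fill taken"
    }
    final <- rbind(final, best)
    subs <- rbind(subs, tibble::tibble(
      unavailable = lost, substitute = best$botanical_name,
      shared_months = paste(shared, collapse = ";"), note = note))
  }
  final <- final[order(-final$total, lengths(final$missing_traits),
                       final$botanical_name), , drop = FALSE]
  list(final = final, substitutions = subs)
}

coverage_table <- function(species_tbl, season) {
  forbs <- species_tbl[species_tbl$growth_form == "forb", , drop = FALSE]
  rows <- lapply(season, function(m) {
    flowering <- forbs$botanical_name[
      vapply(forbs$flowering_months, function(v) m %in% v, logical(1))]
    tibble::tibble(month = m, n_forbs = length(flowering),
                   covered = length(flowering) > 0,
                   species = paste(sort(flowering), collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Assemble a seed mix
#'
#' Combines selected forb and grass scorecards into a named mix with a
#' growth-form composition ratio, handles commercial availability through
#' [substitute_unavailable()], and computes the flowering coverage of the
#' included forbs over the activity season. Output does not depend on the
#' order of the input lists.
#'
#' @param forbs,grasses Selected scorecards per growth form (grasses must be
#'   non-empty; forbs too unless `require_coverage = FALSE`).
#' @param records Species table the scorecards came from.
#' @param forb_fraction Proportion of forbs in the mix by seed weight,
#'   strictly between 0 and 1 (standard practice 0.2; alternative 0.5).
#' @param season Integer months of the beneficial-invertebrate activity
#'   season (default March-October).
#' @param ranked_forb_pool,ranked_grass_pool Ranked lists used as the
#'   substitution pool for unavailable species; default to the selections
#'   themselves (so an unavailable species with no stand-in is dropped with
#'   a warning).
#' @param name Mix label.
#' @param soil_profile Soil profile the scoring targeted (metadata).
#' @param require_coverage Error on an empty forb list? (Coverage is
#'   meaningless without forbs.)
#' @return A `seed_mix` object: list with `name`, `soil_profile`,
#'   `forb_fraction`, `grass_fraction`, `species` (tibble with
#'   `botanical_name`, `growth_form`, `total`, `include_reason`,
#'   `flowering_months`), `coverage` (per-month tibble),
#'   `coverage_fraction`, `substitutions` and `warnings` (one per uncovered
#'   month, plus substitution drops).
#' @export
assemble_mix <- function(forbs, grasses, records, forb_fraction = 0.2,
                         season = 3:10, ranked_forb_pool = NULL,
                         ranked_grass_pool = NULL, name = "seed_mix",
                         soil_profile = "most_soils",
                         require_coverage = TRUE) {
  if (nrow(grasses) == 0) stop("assembly error: no grasses selected",
                               call. = FALSE)
  if (!(forb_fraction > 0 && forb_fraction < 1)) {
    stop("forb_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (nrow(forbs) == 0 && require_coverage) {
    stop("assembly error: no forbs selected but flowering coverage required",
         call. = FALSE)
  }
  fsub <- substitute_unavailable(forbs,
                                 ranked_forb_pool %||% rank_species(forbs),
                                 records, season)
  gsub_ <- substitute_unavailable(grasses,
                                  ranked_grass_pool %||% rank_species(grasses),
                                  records, season)
  substitutions <- rbind(fsub$substitutions, gsub_$substitutions)

  mk_species <- function(cards, sub_log) {
    if (nrow(cards) == 0) {
      return(tibble::tibble(botanical_name = character(0),
                            growth_form = character(0), total = integer(0),
                            include_reason = character(0),
                            flowering_months = list()))
    }
    reason <- ifelse(cards$botanical_name %in% sub_log$substitute,
                     paste0("substitute for ", sub_log$unavailable[
                       match(cards$botanical_name, sub_log$substitute)]),
                     "selected by rank")
    tibble::tibble(
      botanical_name = cards$botanical_name,
      growth_form = cards$growth_form,
      total = cards$total,
      include_reason = reason,
      flowering_months = lapply(cards$botanical_name, months_of,
                                records = records))
  }
  species <- rbind(mk_species(fsub$final, fsub$substitutions),
                   mk_species(gsub_$final, gsub_$substitutions))
  species <- species[order(species$growth_form, -species$total,
                           species$botanical_name), , drop = FALSE]

  coverage <- coverage_table(species, season)
  warnings <- character(0)
  if (any(!coverage$covered)) {
    warnings <- paste0("no flowering forb in month ",
                       coverage$month[!coverage$covered])
  }
  dropped <- substitutions$unavailable[is.na(substitutions$substitute)]
  if (length(dropped) > 0) {
    warnings <- c(warnings, paste0("dropped without substitute: ", dropped))
  }
  structure(
    list(name = name, soil_profile = soil_profile,
         forb_fraction = forb_fraction, grass_fraction = 1 - forb_fraction,
         season = season, species = species, coverage = coverage,
         coverage_fraction = mean(coverage$covered),
         substitutions = substitutions, warnings = warnings),
    class = "seed_mix")
}

#' Flowering coverage report for a seed mix
#'
#' @param mix A `seed_mix` object.
#' @param season Months to report over; defaults to the mix's own season.
#' @return A list with `months` (tibble: month, flowering forb count,
#'   covered flag, species) and `fraction_covered`.
#' @export
coverage_report <- function(mix, season = NULL) {
  stopifnot(inherits(mix, "seed_mix"))
  season <- season %||% mix$season
  tab <- coverage_table(mix$species, season)
  list(months = tab, fraction_covered = mean(tab$covered))
}

#' @export
print.seed_mix <- function(x, ...) {
  cat("Seed mix:", x$name, "\n")
  cat(sprintf("  composition: %d%% forbs / %d%% grasses (soil profile: %s)\n",
              round(100 * x$forb_fraction), round(100 * x$grass_fraction),
              x$soil_profile))
  cat(sprintf("  species: %d forbs, %d grasses\n",
              sum(x$species$growth_form == "forb"),
              sum(x$species$growth_form == "grass")))
  for (i in seq_len(nrow(x$species))) {
    s <- x$species[i, ]
    cat(sprintf("    %-28s %-5s total %2d  %s\n", s$botanical_name,
                s$growth_form, s$total, s$include_reason))
  }
  cat(sprintf("  flowering coverage: %d%% of season (months %d-%d)\n",
              round(100 * x$coverage_fraction), min(x$season), max(x$season)))
  if (nrow(x$substitutions) > 0) {
    cat("  substitutions:\n")
    for (i in seq_len(nrow(x$substitutions))) {
      s <- x$substitutions[i, ]
      cat(sprintf("    %s -> %s (shared months: %s; %s)\n", s$unavailable,
                  ifelse(is.na(s$substitute), "<dropped>", s$substitute),
                  ifelse(nzchar(s$shared_months), s$shared_months, "none"),
                  s$note))
    }
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Export a seed mix as JSON
#'
#' @param mix A `seed_mix` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
seed_mix_to_json <- function(mix, path) {
  jsonlite::write_json(unclass(mix), path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Built-in mix configurations
#'
#' The four case-study variants: the general-purpose mix at the standard
#' 20:80 forb:grass seed-weight ratio, its 50:50 alternative, and two
#' soil-targeted mixes (heavy clay and sandy loam) that differ only in which
#' soil profile the forb rubric's soil rule targets.
#'
#' @return Named list of config fragments usable as `run_pipeline()` input
#'   (each has `rubric`, `mix` and `name` entries).
#' @export
builtin_mix_configs <- function() {
  list(
    general_20_80 = list(name = "general_20_80",
                         rubric = list(soil_profile = "most_soils"),
                         mix = list(forb_fraction = 0.2)),
    general_50_50 = list(name = "general_50_50",
                         rubric = list(soil_profile = "most_soils"),
                         mix = list(forb_fraction = 0.5)),
    heavy_clay = list(name = "heavy_clay",
                      rubric = list(soil_profile = "heavy_clay"),
                      mix = list(forb_fraction = 0.2)),
    sandy_loam = list(name = "sandy_loam",
                      rubric = list(soil_profile = "sandy_loam"),
                      mix = list(forb_fraction = 0.2))
  )
}
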