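# Scoring engine: apply a rubric to species records, producing scorecards
# with per-trait components, missing-trait flags and the rank total.
# Missing trait data contributes the rule's minimum score and is flagged —
# the policy under which the published totals for species with unavailable
# trait data are exactly the sum of their known components.

#' Score one species against a rubric
#'
#' @param record A one-row species table.
#' @param rubric A `rubric` object matching the record's growth form.
#' @return A one-row scorecard tibble: `botanical_name`, `growth_form`, one
#'   integer column per rubric trait (in rubric order), `missing_traits`
#'   (list-column of flagged trait names) and `total` (the overall rank,
#'   always the sum of the components).
#' @export
score_species <- function(record, rubric) {
  stopifnot(nrow(record) == 1, inherits(rubric, "rubric"))
  if (!identical(record$growth_form, rubric$growth_form)) {
    stop("species '", record$botanical_name, "' is a ", record$growth_form,
         " but the rubric targets ", rubric$growth_form, call. = FALSE)
  }
  components <- integer(length(rubric$rules))
  missing_traits <- character(0)
  for (i in seq_along(rubric$rules)) {
    rule <- rubric$rules[[i]]
    if (!(rule$field %in% names(record))) {
      if (rule$kind == "soil") {
        stop("config error: soil profile '", rule$params$profile,
             "' is not declared in the species table", call. = FALSE)
      }
      stop("record has no field '", rule$field, "'", call. = FALSE)
    }
    value <- record[[rule$field]][[1]]
    if (is.na(value)) {
      components[i] <- rule$missing_score
      missing_traits <- c(missing_traits, rule$trait)
    } else {
      components[i] <- tryCatch(
        apply_rule_value(rule, value),
        error = function(e) {
          stop("species '", record$botanical_name, "', trait '", rule$trait,
               "': ", conditionMessage(e), call. = FALSE)
        })
    }
  }
  card <- tibble::tibble(botanical_name = record$botanical_name,
                         growth_form = record$growth_form)
  for (i in seq_along(rubric$rules)) {
    card[[rubric$rules[[i]]$trait]] <- components[i]
  }
  card$missing_traits <- list(missing_traits)
  card$total <- sum(components)
  card
}

#' Score a species table against a rubric
#'
#' @param records Species table; every row must match the rubric's growth
#'   form.
#' @param rubric A `rubric` object.
#' @return A scorecard tibble, one row per species in input order (see
#'   [score_species()]).
#' @export
score_table <- function(records, rubric) {
  if (nrow(records) == 0) {
    card <- tibble::tibble(botanical_name = character(0),
                           growth_form = character(0))
    for (tn in rule_trait_names(rubric)) card[[tn]] <- integer(0)
    card$missing_traits <- list()
    card$total <- integer(0)
    return(card)
  }
  do.call(rbind, lapply(seq_len(nrow(records)),
                        function(i) score_species(records[i, ], rubric)))
}

# single-trait scorers -------------------------------------------------------
# Thin, vectorized wrappers over the default rubric rules. NA applies the
# missing policy (the rule's minimum score); callers needing the flag use
# score_species()/score_table().

.rule_by_trait <- function(growth_form, trait, ...) {
  rubric <- default_rubric(growth_form, ...)
  rubric$rules[[match(trait, rule_trait_names(rubric))]]
}

.apply_scalar <- function(rule, v) {
  unname(vapply(v, function(x) {
    if (is.na(x)) rule$missing_score else apply_rule_value(rule, x)
  }, numeric(1)))
}

#' Single-trait rubric scorers
#'
#' Each function applies one rule of the built-in rubrics to raw trait
#' values (vectorized); `NA` yields the rule's missing score. See
#' [default_rubric()] for the scales and boundary conventions.
#'
#' @param v Raw trait values: mm for display size and height, mm^2 for leaf
#'   area, category labels for trichomes/roots/phenology, CSR codes for
#'   strategy, mean co-occurring species count for associated floristic
#'   diversity.
#' @return Integer scores.
#' @name trait_scorers
NULL

#' @rdname trait_scorers
#' @export
score_floral_display <- function(v) {
  .apply_scalar(.rule_by_trait("forb", "floral_display"), v)
}

#' @rdname trait_scorers
#' @export
score_trichome_density <- function(v) {
  .apply_scalar(.rule_by_trait("forb", "trichome_density"),
                ifelse(is.na(v), NA, normalize_category(v)))
}

#' @rdname trait_scorers
#' @export
score_leaf_area_forb <- function(v) {
  .apply_scalar(.rule_by_trait("forb", "leaf_area"), v)
}

#' @rdname trait_scorers
#' @export
score_root_system <- function(v) {
  .apply_scalar(.rule_by_trait("forb", "root_system"),
                ifelse(is.na(v), NA, normalize_category(v)))
}

#' @rdname trait_scorers
#' @export
score_leaf_phenology <- function(v) {
  .apply_scalar(.rule_by_trait("forb", "leaf_phenology"),
                ifelse(is.na(v), NA, normalize_category(v)))
}

#' Score soil suitability for a named profile
#'
#' The heavily weighted soil rule: a species suitable for the target soil
#' profile scores `weight` (default 5), otherwise 0; an unrecorded
#' suitability scores 0 (missing policy).
#'
#' @param record A one-row species table.
#' @param soil_profile Profile name; column `soil_<profile>` must exist.
#' @param weight Score for a suitable species.
#' @return Integer score.
#' @export
score_soil <- function(record, soil_profile = "most_soils", weight = 5L) {
  col <- paste0("soil_", soil_profile)
  if (!(col %in% names(record))) {
    stop("config error: soil profile '", soil_profile,
         "' is not declared in the species table", call. = FALSE)
  }
  rule <- rubric_rule("soil", col, "soil", list(profile = soil_profile),
                      weight = weight)
  .apply_scalar(rule, record[[col]])
}

#' @rdname trait_scorers
#' @export
score_leaf_area_class_grass <- function(v) {
  .apply_scalar(.rule_by_trait("grass", "leaf_area_class"), v)
}

#' @rdname trait_scorers
#' @export
score_established_strategy <- function(v) {
  .apply_scalar(.rule_by_trait("grass", "established_strategy"),
                ifelse(is.na(v), NA, normalize_csr(v)))
}

#' @rdname trait_scorers
#' @export
score_height_grass <- function(v) {
  .apply_scalar(.rule_by_trait("grass", "height"), v)
}

#' @rdname trait_scorers
#' @export
score_afd_grass <- function(v) {
  .apply_scalar(.rule_by_trait("grass", "associated_floristic_diversity"), v)
}

#' Write scorecards to CSV
#'
#' Mirrors the published table layout: species name, one column per trait
#' component in rubric order, then the total; missing-trait flags are kept
#' in a `missing_traits` column (semicolon-separated).
#'
#' @param cards Scorecard tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorecards <- function(cards, path) {
  out <- cards
  out$missing_traits <- vapply(cards$missing_traits, paste, character(1),
                               collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
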