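# Declarative scoring rubrics.
#
# A rubric is data, not code: an ordered list of rules, each mapping one raw
# trait value to a non-negative integer score. Three rule kinds cover the
# published ranking system:
#   binary_threshold — 0 below a cut point, 1 at or above it
#   category_map     — label -> score lookup
#   binned_range     — ordered bins with per-edge boundary direction
# plus a weighted boolean `soil` rule (suitability for a named soil profile,
# heavily weighted so that establishment across variable farm soils
# dominates the ranking). Rubrics can be re-targeted to a specific soil
# profile (e.g. sandy loam) and loaded from a YAML config without code
# changes.

rubric_rule <- function(trait, field, kind, params, missing_score = 0L,
                        weight = 1L) {
  structure(list(trait = trait, field = field, kind = kind, params = params,
                 missing_score = as.integer(missing_score),
                 weight = as.integer(weight)),
            class = "rubric_rule")
}

#' Built-in rubrics
#'
#' `default_rubric()` returns the published UK lowland ranking system
#' (profile name `"uk_lowland_2019"`).
#'
#' Forbs (six rules, total range 0–10): floral display size (0: <10 mm,
#' 1: >=10 mm), trichome density (0: sparse, 1: numerous), leaf area
#' (0: <25 mm^2, 1: >=25 mm^2), root system (0: tap-root, 1: adventitious),
#' leaf phenology (0: estival, 1: evergreen), and soil suitability
#' (0: not suitable, 5: suitable for the target profile — heavily weighted).
#'
#' Grasses (four rules, total range 2–14): leaf area class (1: <15,
#' 2: 15–20, 3: 20–25, 4: 25–30, 5: >30 mm^2; shared endpoints resolved
#' lower-closed, so 15 scores 2 and 30 scores 5), established CSR strategy
#' (0: C, SC or CR; 1: CSR, R, S or SR), maximum height (0: >=2000,
#' 1: 1500–2000, 2: 750–1500, 3: <=750 mm) and associated floristic
#' diversity (1: <=10.0, 2: 10.1–14.0, 3: 14.1–18.0, 4: 18.1–22.0,
#' 5: >22.0 species).
#'
#' A missing trait contributes the rule's minimum score (0, or the lowest
#' bin for the graded grass rules) and is flagged on the scorecard.
#'
#' @param growth_form `"forb"` or `"grass"`.
#' @param soil_profile Soil profile the soil rule targets (a `soil_<profile>`
#'   column must exist in the scored records). Forb rubric only.
#' @param soil_weight Score awarded for soil suitability (default 5).
#' @return A `rubric` object.
#' @export
default_rubric <- function(growth_form = c("forb", "grass"),
                           soil_profile = "most_soils", soil_weight = 5L) {
  growth_form <- match.arg(growth_form)
  if (growth_form == "forb") {
    rules <- list(
      rubric_rule("floral_display", "floral_display_mm", "binary_threshold",
                  list(threshold = 10, min_valid = 0)),
      rubric_rule("trichome_density", "trichome_density", "category_map",
                  list(map = c(sparse = 0L, numerous = 1L))),
      rubric_rule("leaf_area", "leaf_area_mm2", "binary_threshold",
                  list(threshold = 25, min_valid = 0)),
      rubric_rule("root_system", "root_system", "category_map",
                  list(map = c("tap-root" = 0L, adventitious = 1L))),
      rubric_rule("leaf_phenology", "leaf_phenology", "category_map",
                  list(map = c(estival = 0L, evergreen = 1L))),
      rubric_rule("soil", paste0("soil_", soil_profile), "soil",
                  list(profile = soil_profile), weight = soil_weight)
    )
  } else {
    rules <- list(
      rubric_rule("leaf_area_class", "leaf_area_mm2", "binned_range",
                  list(breaks = c(15, 20, 25, 30), scores = 1:5,
                       boundary_up = c(TRUE, TRUE, TRUE, TRUE),
                       min_valid = 0),
                  missing_score = 1L),
      rubric_rule("established_strategy", "established_strategy",
                  "category_map",
                  list(map = c(C = 0L, SC = 0L, CR = 0L,
                               CSR = 1L, R = 1L, S = 1L, SR = 1L))),
      rubric_rule("height", "max_height_mm", "binned_range",
                  list(breaks = c(750, 1500, 2000), scores = c(3L, 2L, 1L, 0L),
                       boundary_up = c(FALSE, TRUE, TRUE),
                       min_valid = 0, exclusive_min = TRUE)),
      rubric_rule("associated_floristic_diversity",
                  "associated_floristic_diversity", "binned_range",
                  list(breaks = c(10, 14, 18, 22), scores = 1:5,
                       boundary_up = c(FALSE, FALSE, FALSE, FALSE),
                       min_valid = 0),
                  missing_score = 1L)
    )
  }
  structure(list(name = "uk_lowland_2019", growth_form = growth_form,
                 soil_profile = if (growth_form == "forb") soil_profile else NA,
                 rules = rules),
            class = "rubric")
}

rule_trait_names <- function(rubric) {
  vapply(rubric$rules, function(r) r$trait, character(1))
}

# score one raw value under one rule; NA handled by the caller.
apply_rule_value <- function(rule, value) {
  p <- rule$params
  if (rule$kind == "binary_threshold") {
    if (!is.numeric(value)) stop("expected a numeric value", call. = FALSE)
    if (!is.null(p$min_valid) && value < p$min_valid) {
      stop("value ", value, " below valid minimum", call. = FALSE)
    }
    return(as.integer(value >= p$threshold) * rule$weight)
  }
  if (rule$kind == "category_map") {
    key <- as.character(value)
    if (!(key %in% names(p$map))) {
      stop("unrecognized label '", key, "' (expected one of: ",
           paste(names(p$map), collapse = ", "), ")", call. = FALSE)
    }
    return(as.integer(p$map[[key]]) * rule$weight)
  }
  if (rule$kind == "binned_range") {
    if (!is.numeric(value)) stop("expected a numeric value", call. = FALSE)
    if (!is.null(p$min_valid)) {
      low <- if (isTRUE(p$exclusive_min)) value <= p$min_valid else
        value < p$min_valid
      if (low) stop("value ", value, " outside the valid domain",
                    call. = FALSE)
    }
    idx <- 1L + sum(ifelse(p$boundary_up, value >= p$breaks,
                           value > p$breaks))
    return(as.integer(p$scores[idx]) * rule$weight)
  }
  if (rule$kind == "soil") {
    if (!is.logical(value)) stop("soil suitability must be logical",
                                 call. = FALSE)
    return(as.integer(value) * rule$weight)
  }
  stop("unknown rule kind '", rule$kind, "'", call. = FALSE)
}

#' Tabulate a rubric's rules and boundary conventions
#'
#' Emits one row per rule with its kind, scale and the exact boundary
#' handling, so the scoring system can be audited without reading code.
#'
#' @param rubric A `rubric` object.
#' @return A tibble with columns `trait`, `field`, `kind`, `scale`,
#'   `missing_score` and `weight`.
#' @export
show_rubric <- function(rubric) {
  rows <- lapply(rubric$rules, function(r) {
    p <- r$params
    scale <- switch(
      r$kind,
      binary_threshold = paste0("0: <", p$threshold, ", ", r$weight, ": >=",
                                p$threshold),
      category_map = paste(paste0(names(p$map), "=",
                                  as.integer(p$map) * r$weight),
                           collapse = ", "),
      soil = paste0("0: not suitable for ", p$profile, ", ", r$weight,
                    ": suitable"),
      binned_range = {
        edges <- p$breaks
        k <- length(edges)
        pieces <- character(k + 1)
        pieces[1] <- paste0(p$scores[1], ": ",
                            if (p$boundary_up[1]) "<" else "<=", edges[1])
        for (i in seq_len(k - 1)) {
          lo <- paste0(if (p$boundary_up[i]) "[" else "(", edges[i])
          hi <- paste0(edges[i + 1], if (p$boundary_up[i + 1]) ")" else "]")
          pieces[i + 1] <- paste0(p$scores[i + 1], ": ", lo, ", ", hi)
        }
        pieces[k + 1] <- paste0(p$scores[k + 1], ": ",
                                if (p$boundary_up[k]) ">=" else ">", edges[k])
        paste(pieces, collapse = "; ")
      })
    tibble::tibble(trait = r$trait, field = r$field, kind = r$kind,
                   scale = scale, missing_score = r$missing_score,
                   weight = r$weight)
  })
  do.call(rbind, rows)
}

#' Build a rubric pair from a configuration list
#'
#' Accepts the `rubric:` section of a run config: `profile` (currently
#' `"uk_lowland_2019"`), `soil_profile` and `soil_weight` overrides.
#'
#' @param config A named list (e.g. from [yaml::read_yaml()]).
#' @return A list with elements `forb` and `grass`, each a `rubric`.
#' @export
rubrics_from_config <- function(config = list()) {
  profile <- config$profile %||% "uk_lowland_2019"
  if (!identical(profile, "uk_lowland_2019")) {
    stop("unknown rubric profile '", profile, "'", call. = FALSE)
  }
  soil_profile <- config$soil_profile %||% "most_soils"
  soil_weight <- as.integer(config$soil_weight %||% 5L)
  list(forb = default_rubric("forb", soil_profile = soil_profile,
                             soil_weight = soil_weight),
       grass = default_rubric("grass"))
}
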