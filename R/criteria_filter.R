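# Establishment gate: the initial criteria every candidate must pass before
# any trait scoring. Perennial life history, native status and good regional
# distribution are binary requirements; forbs are additionally required to
# show support for bees. Unknown (missing) gate fields exclude a species
# conservatively, with an "unknown" verdict distinct from a definite fail.

#' Establishment filter criteria
#'
#' Constructor for the gate applied before scoring. Defaults encode the
#' case-study requirements: perennial, native, regionally distributed, and
#' (for forbs) evidence of pollinator support. Set a field to `NULL`
#' (or `FALSE` for the logical requirements) to disable that criterion.
#'
#' @param required_life_history Life history a species must have, or `NULL`.
#' @param required_status Native status a species must have, or `NULL`.
#' @param require_regional_distribution Require good regional distribution?
#' @param require_pollinator_support_for_forbs Require forbs to support
#'   pollinators? Never applied to grasses.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(required_life_history = "perennial",
                            required_status = "native",
                            require_regional_distribution = TRUE,
                            require_pollinator_support_for_forbs = TRUE) {
  structure(
    list(
      required_life_history =
        if (is.null(required_life_history)) NULL else
          normalize_category(required_life_history),
      required_status =
        if (is.null(required_status)) NULL else
          normalize_category(required_status),
      require_regional_distribution = isTRUE(require_regional_distribution),
      require_pollinator_support_for_forbs =
        isTRUE(require_pollinator_support_for_forbs)
    ),
    class = "filter_criteria"
  )
}

.verdict <- function(criterion, status, reason) {
  tibble::tibble(criterion = criterion, status = status, reason = reason)
}

gate_verdicts <- function(record, criteria) {
  v <- list()
  eq_gate <- function(criterion, value, required) {
    if (is.na(value)) {
      .verdict(criterion, "unknown", paste0(criterion, " unknown"))
    } else if (value == required) {
      .verdict(criterion, "pass", paste0(criterion, " is ", required))
    } else {
      .verdict(criterion, "fail",
               paste0(criterion, " is ", value, ", required ", required))
    }
  }
  if (!is.null(criteria$required_life_history)) {
    v[[length(v) + 1]] <- eq_gate("life_history", record$life_history,
                                  criteria$required_life_history)
  }
  if (!is.null(criteria$required_status)) {
    v[[length(v) + 1]] <- eq_gate("native_status", record$native_status,
                                  criteria$required_status)
  }
  if (criteria$require_regional_distribution) {
    d <- record$regional_distribution
    v[[length(v) + 1]] <- if (is.na(d)) {
      .verdict("regional_distribution", "unknown", "distribution unknown")
    } else if (d) {
      .verdict("regional_distribution", "pass", "good regional distribution")
    } else {
      .verdict("regional_distribution", "fail",
               "not well distributed regionally")
    }
  }
  if (criteria$require_pollinator_support_for_forbs) {
    if (identical(record$growth_form, "grass")) {
      v[[length(v) + 1]] <- .verdict("pollinator_support", "pass",
                                     "gate applies to forbs only")
    } else {
      p <- record$pollinator_support
      v[[length(v) + 1]] <- if (is.na(p)) {
        .verdict("pollinator_support", "unknown", "pollinator support unknown")
      } else if (p) {
        .verdict("pollinator_support", "pass", "supports pollinators")
      } else {
        .verdict("pollinator_support", "fail",
                 "no indication of pollinator support")
      }
    }
  }
  if (length(v) == 0) return(.verdict(character(0), character(0), character(0)))
  do.call(rbind, v)
}

#' Test one species against the establishment gate
#'
#' @param record A one-row species table.
#' @param criteria A [filter_criteria()] object.
#' @return A list with `pass` (logical; `TRUE` only if every enabled
#'   criterion holds) and `verdicts`, a tibble with one row per enabled
#'   criterion (`status` is `pass`, `fail` or `unknown`) — reporting never
#'   short-circuits.
#' @export
passes_initial_criteria <- function(record, criteria = filter_criteria()) {
  stopifnot(nrow(record) == 1, inherits(criteria, "filter_criteria"))
  verdicts <- gate_verdicts(record, criteria)
  list(pass = nrow(verdicts) == 0 || all(verdicts$status == "pass"),
       verdicts = verdicts)
}

#' Partition candidates on the establishment gate
#'
#' @param records Species table.
#' @param criteria A [filter_criteria()] object.
#' @return A list with `passed` (species table), `rejected` (species table
#'   with an extra `reasons` character column; every rejected species carries
#'   at least one reason), and `verdicts` (long tibble of every per-species,
#'   per-criterion verdict, suitable for a rejection report). Both partitions
#'   preserve input order and jointly cover the input.
#' @export
filter_candidates <- function(records, criteria = filter_criteria()) {
  n <- nrow(records)
  pass <- logical(n)
  reasons <- character(n)
  all_verdicts <- vector("list", n)
  for (i in seq_len(n)) {
    res <- passes_initial_criteria(records[i, ], criteria)
    pass[i] <- res$pass
    bad <- res$verdicts[res$verdicts$status != "pass", , drop = FALSE]
    reasons[i] <- paste(bad$reason, collapse = "; ")
    if (nrow(res$verdicts) > 0) {
      all_verdicts[[i]] <- cbind(
        tibble::tibble(botanical_name = records$botanical_name[i]),
        res$verdicts)
    }
  }
  rejected <- records[!pass, , drop = FALSE]
  rejected$reasons <- reasons[!pass]
  verdicts <- if (n == 0 || all(vapply(all_verdicts, is.null, logical(1)))) {
    tibble::tibble(botanical_name = character(0), criterion = character(0),
                   status = character(0), reason = character(0))
  } else {
    tibble::as_tibble(do.call(rbind, all_verdicts[!vapply(all_verdicts,
                                                          is.null,
                                                          logical(1))]))
  }
  list(passed = records[pass, , drop = FALSE], rejected = rejected,
       verdicts = verdicts)
}
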