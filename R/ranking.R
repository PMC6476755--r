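# Ranking and cutoff selection. Species are ordered by total rank
# (descending); ties are broken by fewer missing traits, then alphabetically
# by botanical name, so output is a deterministic permutation of the input
# regardless of input order.

#' Rank scorecards within a growth form
#'
#' @param cards Scorecard tibble ([score_table()]); all rows must share one
#'   growth form.
#' @return The cards reordered by total (descending), ties broken by fewer
#'   missing traits then botanical name, with a leading `rank` column.
#' @export
rank_species <- function(cards) {
  if (nrow(cards) > 0 && length(unique(cards$growth_form)) != 1) {
    stop("cannot rank mixed growth forms; rank forbs and grasses separately",
         call. = FALSE)
  }
  n_missing <- lengths(cards$missing_traits)
  ord <- order(-cards$total, n_missing, cards$botanical_name)
  ranked <- cards[ord, , drop = FALSE]
  out <- tibble::tibble(rank = seq_len(nrow(ranked)))
  out <- cbind(out, ranked)
  attr(out, "ordering_key") <-
    "total desc, fewer missing traits, botanical_name"
  tibble::as_tibble(out)
}

#' Select candidates from a ranked list
#'
#' Applies a score threshold and/or a top-n cutoff, then explicit overrides:
#' `include` adds named species regardless of the threshold, `exclude`
#' removes them; every override is logged with a reason so the expert
#' judgement the final cut encodes stays auditable.
#'
#' @param ranked Output of [rank_species()].
#' @param min_total Minimum total rank to keep, or `NULL` for no threshold.
#' @param top_n Keep at most this many top-ranked species, or `NULL`. If
#'   larger than the list a warning is raised and all are returned.
#' @param include Botanical names to force-include (must be in `ranked`).
#' @param exclude Botanical names to force-exclude.
#' @return A list with `selected` (scorecards in rank order) and `log`
#'   (tibble `botanical_name`, `action`, `reason`).
#' @export
select_candidates <- function(ranked, min_total = NULL, top_n = NULL,
                              include = character(0), exclude = character(0)) {
  log <- tibble::tibble(botanical_name = character(0), action = character(0),
                        reason = character(0))
  keep <- rep(TRUE, nrow(ranked))
  if (!is.null(min_total)) keep <- keep & ranked$total >= min_total
  if (!is.null(top_n)) {
    if (top_n > nrow(ranked)) {
      warning("top_n (", top_n, ") exceeds the ranked list (", nrow(ranked),
              "); returning all", call. = FALSE)
      top_n <- nrow(ranked)
    }
    keep <- keep & seq_len(nrow(ranked)) <= top_n
  }
  for (sp in include) {
    i <- match(sp, ranked$botanical_name)
    if (is.na(i)) {
      stop("include override names unknown species '", sp, "'", call. = FALSE)
    }
    if (!keep[i]) {
      keep[i] <- TRUE
      log <- rbind(log, tibble::tibble(
        botanical_name = sp, action = "include",
        reason = "explicit include override (below selection cutoff)"))
    }
  }
  for (sp in exclude) {
    i <- match(sp, ranked$botanical_name)
    if (!is.na(i) && keep[i]) {
      keep[i] <- FALSE
      log <- rbind(log, tibble::tibble(
        botanical_name = sp, action = "exclude",
        reason = "explicit exclude override"))
    }
  }
  list(selected = ranked[keep, , drop = FALSE], log = log)
}

#' Write a ranked list to CSV
#'
#' @param ranked Output of [rank_species()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked <- function(ranked, path) {
  out <- ranked
  out$missing_traits <- vapply(ranked$missing_traits, paste, character(1),
                               collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
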