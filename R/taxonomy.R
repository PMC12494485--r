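# Multi-classifier viral taxonomy: per-classifier score filtering and
# rank-wise all-agree consensus.

#' Taxonomic ranks used for viral lineages
#'
#' @return Character vector of ranks from realm down to species.
#' @export
viral_ranks <- function() {
  c("realm", "kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Filter classifier taxonomy calls by score
#'
#' Each classifier's calls are filtered at its own threshold, keyed by
#' `score_kind`: bit-score calls are kept at score >= 50, percent-identity
#' calls at identity > 90, and composite virus-score calls at score > 0.7.
#'
#' @param calls Data frame with columns `votu_id`, `classifier`, `score`,
#'   `score_kind` (one of `"bitscore"`, `"pct_identity"`, `"virus_score"`)
#'   plus rank columns (see [viral_ranks()]).
#' @return The retained rows as a tibble.
#' @export
filter_calls <- function(calls) {
  check_columns(calls, c("votu_id", "classifier", "score", "score_kind"), "calls")
  known <- c("bitscore", "pct_identity", "virus_score")
  bad <- setdiff(unique(calls$score_kind), known)
  if (length(bad) > 0) {
    abort_crustvir(sprintf("Unknown score_kind: %s.", paste(bad, collapse = ", ")),
                   "invalid_record")
  }
  keep <- (calls$score_kind == "bitscore" & calls$score >= 50) |
    (calls$score_kind == "pct_identity" & calls$score > 90) |
    (calls$score_kind == "virus_score" & calls$score > 0.7)
  tibble::as_tibble(calls[keep, , drop = FALSE])
}

#' Rank-wise all-agree consensus taxonomy
#'
#' For every vOTU and rank, the rank is named only if at least one classifier
#' assigns a name there and every classifier that assigns one agrees;
#' otherwise the rank is `"unclassified"`. Classifiers that leave a rank
#' absent (NA) abstain rather than veto. Ranks are evaluated independently;
#' with `truncate_below_conflict = TRUE`, all ranks below the first rank at
#' which classifiers disagree are also set to `"unclassified"`, enforcing
#' lineage consistency.
#'
#' @param calls Filtered calls (see [filter_calls()]): at most one call per
#'   classifier per vOTU; rank columns named as in `ranks`.
#' @param ranks Rank columns to evaluate (default [viral_ranks()], restricted
#'   to those present in `calls`).
#' @param truncate_below_conflict Enforce prefix consistency (default FALSE).
#' @return A tibble with `votu_id` and one column per rank.
#' @export
consensus_taxonomy <- function(calls, ranks = viral_ranks(),
                               truncate_below_conflict = FALSE) {
  check_columns(calls, c("votu_id", "classifier"), "calls")
  ranks <- intersect(ranks, names(calls))
  if (length(ranks) == 0) {
    abort_crustvir("No rank columns found in `calls`.", "invalid_input")
  }
  dup <- calls |>
    dplyr::count(.data$votu_id, .data$classifier) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_crustvir(
      sprintf("Multiple calls from one classifier for vOTU(s): %s.",
              paste(utils::head(unique(dup$votu_id), 3), collapse = ", ")),
      "ambiguity_error"
    )
  }
  long <- calls |>
    dplyr::select("votu_id", dplyr::all_of(ranks)) |>
    tidyr::pivot_longer(dplyr::all_of(ranks), names_to = "rank", values_to = "name") |>
    dplyr::group_by(.data$votu_id, .data$rank) |>
    dplyr::summarise(
      n_names = dplyr::n_distinct(.data$name[!is.na(.data$name)]),
      name = {
        v <- unique(.data$name[!is.na(.data$name)])
        if (length(v) == 1) v else "unclassified"
      },
      .groups = "drop"
    )
  wide <- long |>
    dplyr::select(-"n_names") |>
    tidyr::pivot_wider(names_from = "rank", values_from = "name") |>
    dplyr::select("votu_id", dplyr::all_of(ranks)) |>
    dplyr::arrange(.data$votu_id)
  if (truncate_below_conflict && length(ranks) > 1) {
    conflict <- long |>
      dplyr::mutate(conflict = .data$n_names > 1) |>
      dplyr::select("votu_id", "rank", "conflict") |>
      tidyr::pivot_wider(names_from = "rank", values_from = "conflict")
    conflict <- conflict[match(wide$votu_id, conflict$votu_id), ]
    m <- as.matrix(wide[ranks])
    cm <- as.matrix(conflict[ranks])
    for (i in seq_len(nrow(m))) {
      firstc <- match(TRUE, cm[i, ])
      if (!is.na(firstc)) {
        m[i, firstc:length(ranks)] <- "unclassified"
      }
    }
    wide[ranks] <- as.data.frame(m, stringsAsFactors = FALSE)
  }
  wide
}

#' Per-rank classification rates
#'
#' Fraction of vOTUs with a named (non-`"unclassified"`) consensus value at
#' each rank.
#'
#' @param consensus Consensus tibble from [consensus_taxonomy()].
#' @param ranks Rank columns to report (defaults to those present).
#' @return A tibble `rank`, `n_classified`, `percent`.
#' @export
classification_rates <- function(consensus, ranks = viral_ranks()) {
  check_columns(consensus, "votu_id", "consensus")
  ranks <- intersect(ranks, names(consensus))
  if (nrow(consensus) == 0 || length(ranks) == 0) {
    return(tibble::tibble(rank = character(), n_classified = integer(),
                          percent = numeric()))
  }
  n_total <- nrow(consensus)
  purrr::map_dfr(ranks, function(r) {
    named <- !is.na(consensus[[r]]) & consensus[[r]] != "unclassified"
    tibble::tibble(rank = r, n_classified = sum(named),
                   percent = 100 * sum(named) / n_total)
  })
}
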