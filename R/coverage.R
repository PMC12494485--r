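# Read-recruitment coverage after mismatch filtering.
#
# Coordinates are 0-based, half-open throughout the package; conversion to
# 1-based happens only at the IRanges boundary and at GFF3 ingestion.

#' Filter recruited alignments by mismatch count
#'
#' Removes alignments carrying more than `max_mismatches` mismatches (an
#' NM-style per-alignment edit count; indels count as provided upstream) and
#' any non-primary alignments. With the default `max_mismatches = 1`,
#' alignments with two or more mismatches are removed, the stringency used
#' for island detection so that only reads from near-identical population
#' members contribute to coverage.
#'
#' @param alignments A data frame with columns `query_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `mismatches`, and optionally
#'   `is_primary` (missing column means all alignments are primary).
#' @param max_mismatches Maximum number of mismatches retained (default 1).
#' @return A tibble with the retained rows, original order preserved.
#' @examples
#' aln <- tibble::tibble(
#'   query_id = paste0("r", 1:4), contig_id = "c1",
#'   start = 0L, end = 100L, mismatches = 0:3
#' )
#' filter_alignments(aln)
#' @export
filter_alignments <- function(alignments, max_mismatches = 1) {
  check_alignments(alignments)
  if (!is.numeric(max_mismatches) || length(max_mismatches) != 1 || max_mismatches < 0) {
    abort_crustvir("`max_mismatches` must be a single non-negative number.", "invalid_input")
  }
  primary <- if ("is_primary" %in% names(alignments)) alignments$is_primary else TRUE
  tibble::as_tibble(alignments[primary & alignments$mismatches <= max_mismatches, ,
                               drop = FALSE])
}

#' Compute per-base coverage tracks
#'
#' Counts, for every base of every contig in `genomes`, the number of
#' alignment intervals containing it (the equivalent of a `genomecov`-style
#' per-base depth). The result is run-length encoded in bedGraph form:
#' adjacent bases with equal depth share one row, zero-depth runs included,
#' so every contig is covered end to end (unrecruited contigs appear as a
#' single zero-depth run).
#'
#' @param alignments A data frame of alignments (see [filter_alignments()]);
#'   typically already mismatch-filtered.
#' @param genomes A data frame with columns `genome_id`, `contig_id`,
#'   `length` (one row per contig).
#' @return A tibble with columns `genome_id`, `contig_id`, `start`, `end`
#'   (0-based half-open) and `depth`.
#' @export
compute_coverage <- function(alignments, genomes) {
  check_genomes(genomes)
  check_alignments(alignments)
  unknown <- setdiff(unique(alignments$contig_id), genomes$contig_id)
  if (length(unknown) > 0) {
    abort_crustvir(
      sprintf("Alignments reference unknown contig(s): %s.",
              paste(utils::head(unknown, 3), collapse = ", ")),
      "coordinate_error"
    )
  }
  len_of <- stats::setNames(genomes$length, genomes$contig_id)
  if (any(alignments$end > len_of[alignments$contig_id])) {
    abort_crustvir("Alignment extends beyond contig end.", "coordinate_error")
  }

  by_contig <- split(alignments, alignments$contig_id)
  tracks <- purrr::map2_dfr(
    genomes$contig_id, genomes$length,
    function(ctg, len) {
      aln <- by_contig[[ctg]]
      if (is.null(aln) || nrow(aln) == 0) {
        return(tibble::tibble(contig_id = ctg, start = 0L, end = as.integer(len),
                              depth = 0L))
      }
      cov <- IRanges::coverage(IRanges::IRanges(aln$start + 1L, aln$end),
                               width = len)
      ends <- cumsum(S4Vectors::runLength(cov))
      tibble::tibble(
        contig_id = ctg,
        start = c(0L, ends[-length(ends)]),
        end = as.integer(ends),
        depth = as.integer(S4Vectors::runValue(cov))
      )
    }
  )
  dplyr::left_join(tracks,
                   dplyr::select(genomes, "genome_id", "contig_id"),
                   by = "contig_id") |>
    dplyr::select("genome_id", "contig_id", "start", "end", "depth") |>
    dplyr::arrange(.data$contig_id, .data$start) |>
    tibble::as_tibble()
}

#' Length-weighted genome mean coverage
#'
#' The mean depth of a genome is the total number of aligned bases over all
#' member contigs divided by the genome length (sum of contig lengths), i.e.
#' a length-weighted mean -- the quantity island regimes are keyed on.
#'
#' @param coverage A coverage tibble from [compute_coverage()].
#' @param genomes Genome membership table (`genome_id`, `contig_id`, `length`).
#' @return A tibble with columns `genome_id`, `genome_length`, `mean_coverage`.
#' @export
genome_mean_coverage <- function(coverage, genomes) {
  check_genomes(genomes)
  check_columns(coverage, c("contig_id", "start", "end", "depth"), "coverage")
  glen <- genomes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(genome_length = sum(.data$length), .groups = "drop")
  if (any(glen$genome_length == 0)) {
    abort_crustvir("Genome with zero length.", "degenerate_genome")
  }
  totals <- coverage |>
    dplyr::select(dplyr::any_of(c("contig_id", "start", "end", "depth"))) |>
    dplyr::left_join(dplyr::select(genomes, "genome_id", "contig_id"),
                     by = "contig_id") |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(aligned_bases = sum(as.numeric(.data$end - .data$start) * .data$depth),
                     .groups = "drop")
  glen |>
    dplyr::left_join(totals, by = "genome_id") |>
    dplyr::mutate(
      aligned_bases = dplyr::coalesce(.data$aligned_bases, 0),
      mean_coverage = .data$aligned_bases / .data$genome_length
    ) |>
    dplyr::select("genome_id", "genome_length", "mean_coverage") |>
    dplyr::arrange(.data$genome_id)
}
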