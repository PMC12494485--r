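# TPM abundance: read counts normalised by feature length and sequencing
# depth, so that every sample's values sum to one million.

#' Tags-per-million (TPM) normalisation
#'
#' Per sample, each feature's count is divided by its length to give a rate,
#' and rates are scaled so they sum to 10^6. Samples with no mapped reads
#' stay all-zero.
#'
#' @param counts Long data frame with columns `length` (bases), `sample_id`,
#'   `count` (mapped reads), plus an identifier column (`contig_id` or
#'   `genome_id`); extra columns pass through.
#' @return The input tibble with a `tpm` column.
#' @export
tpm <- function(counts) {
  check_columns(counts, c("length", "sample_id", "count"), "counts")
  if (any(counts$length <= 0)) {
    abort_crustvir("Feature lengths must be positive.", "invalid_record")
  }
  if (any(counts$count < 0)) {
    abort_crustvir("Counts must be non-negative.", "invalid_record")
  }
  counts |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      rate = .data$count / .data$length,
      tpm = if (sum(.data$rate) > 0) .data$rate / sum(.data$rate) * 1e6
            else rep(0, dplyr::n())
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"rate")
}

#' Pool contig counts to genome level
#'
#' Genome-level abundance uses pooled member-contig counts over the summed
#' genome length (not the mean of contig TPMs).
#'
#' @param counts Long count table with `contig_id`, `sample_id`, `count`.
#' @param genomes Genome membership table (`genome_id`, `contig_id`, `length`).
#' @return A genome-level count table (`genome_id`, `length`, `sample_id`,
#'   `count`) ready for [tpm()]; `length` is the full genome length.
#' @export
pool_counts_by_genome <- function(counts, genomes) {
  check_genomes(genomes)
  check_columns(counts, c("contig_id", "sample_id", "count"), "counts")
  glen <- genomes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(length = sum(.data$length), .groups = "drop")
  counts |>
    dplyr::inner_join(dplyr::select(genomes, "genome_id", "contig_id"),
                      by = "contig_id") |>
    dplyr::group_by(.data$genome_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(glen, by = "genome_id") |>
    dplyr::select("genome_id", "length", "sample_id", "count")
}

#' log10(TPM + 1) transform
#'
#' @param x A numeric vector/matrix of TPM values, or a data frame with a
#'   `tpm` column (a `log10_tpm` column is added).
#' @return Transformed values in the same shape as the input.
#' @export
log_tpm <- function(x) {
  if (is.data.frame(x)) {
    check_columns(x, "tpm", "x")
    if (any(x$tpm < 0, na.rm = TRUE)) {
      abort_crustvir("TPM values must be non-negative.", "invalid_value")
    }
    return(dplyr::mutate(tibble::as_tibble(x), log10_tpm = log10(.data$tpm + 1)))
  }
  if (any(x < 0, na.rm = TRUE)) {
    abort_crustvir("TPM values must be non-negative.", "invalid_value")
  }
  log10(x + 1)
}

#' Aggregate TPM by taxon
#'
#' Sums member-contig TPM per taxon and sample; contigs without a lineage
#' entry (or with NA at the chosen rank) are pooled under `"unclassified"`.
#' Taxa are ordered by decreasing mean TPM across samples, the ordering used
#' for abundance profiles.
#'
#' @param tpm_tbl Output of [tpm()].
#' @param taxonomy Data frame with `contig_id` plus rank columns.
#' @param rank Name of the rank column to aggregate at (e.g. `"phylum"`).
#' @return A tibble `taxon`, `sample_id`, `tpm`, with `taxon` a factor
#'   ordered by decreasing mean abundance.
#' @export
aggregate_by_taxon <- function(tpm_tbl, taxonomy, rank) {
  check_columns(tpm_tbl, c("contig_id", "sample_id", "tpm"), "tpm_tbl")
  if (nrow(taxonomy) > 0) check_columns(taxonomy, c("contig_id", rank), "taxonomy")
  tax <- if (nrow(taxonomy) == 0) {
    tibble::tibble(contig_id = character(), taxon = character())
  } else {
    tibble::tibble(contig_id = taxonomy$contig_id, taxon = taxonomy[[rank]])
  }
  agg <- tpm_tbl |>
    dplyr::left_join(tax, by = "contig_id") |>
    dplyr::mutate(taxon = dplyr::coalesce(.data$taxon, "unclassified")) |>
    dplyr::group_by(.data$taxon, .data$sample_id) |>
    dplyr::summarise(tpm = sum(.data$tpm), .groups = "drop")
  ord <- agg |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_tpm))
  agg |>
    dplyr::mutate(taxon = factor(.data$taxon, levels = ord$taxon)) |>
    dplyr::arrange(.data$taxon, .data$sample_id)
}
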