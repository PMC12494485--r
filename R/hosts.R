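# Virus-host linkage: sequence-match filtering, association specificity
# typing, and auxiliary metabolic gene (AMG) curation.

#' Filter sequence-match evidence
#'
#' Protein matches are kept at >= 80% identity and >= 80% query coverage;
#' gene and tRNA matches at >= 90% identity and >= 90% query coverage.
#'
#' @param records Data frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `query_coverage`, `kind` (`"protein"`, `"gene"` or
#'   `"trna"`).
#' @return The retained rows as a tibble.
#' @export
filter_matches <- function(records) {
  check_columns(records, c("query_id", "subject_id", "pct_identity",
                           "query_coverage", "kind"), "records")
  bad <- setdiff(unique(records$kind), c("protein", "gene", "trna"))
  if (length(bad) > 0) {
    abort_crustvir(sprintf("Unknown match kind: %s.", paste(bad, collapse = ", ")),
                   "invalid_record")
  }
  keep <- ifelse(records$kind == "protein",
                 records$pct_identity >= 80 & records$query_coverage >= 80,
                 records$pct_identity >= 90 & records$query_coverage >= 90)
  tibble::as_tibble(records[keep, , drop = FALSE])
}

#' Type the specificity of vOTU-MAG associations
#'
#' Classifies each vOTU with at least one host link as `"unique"` (exactly
#' one distinct MAG), `"multiple_family_consensus"` (two or more MAGs that
#' all share one named family), or `"multiple_class_or_higher"` (MAGs whose
#' consensus only holds at class level or above).
#'
#' @param associations Data frame with columns `votu_id`, `mag_id`, `family`
#'   (MAG family; NA counts as no family consensus).
#' @return A tibble `votu_id`, `n_mags`, `type`.
#' @export
classify_association <- function(associations) {
  check_columns(associations, c("votu_id", "mag_id", "family"), "associations")
  if (nrow(associations) == 0) {
    abort_crustvir("No associations supplied.", "no_association")
  }
  associations |>
    dplyr::distinct(.data$votu_id, .data$mag_id, .data$family) |>
    dplyr::group_by(.data$votu_id) |>
    dplyr::summarise(
      n_mags = dplyr::n_distinct(.data$mag_id),
      type = {
        fams <- unique(.data$family)
        if (dplyr::n_distinct(.data$mag_id) == 1) "unique"
        else if (length(fams) == 1 && !anyNA(fams)) "multiple_family_consensus"
        else "multiple_class_or_higher"
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$votu_id)
}

#' Association-type spectrum
#'
#' Counts vOTUs per association type (over vOTUs with at least one host
#' link) and their percentages; all three types always appear in the output.
#'
#' @param associations As for [classify_association()].
#' @return A tibble `type`, `n_votus`, `percent`.
#' @export
association_spectrum <- function(associations) {
  types <- c("unique", "multiple_family_consensus", "multiple_class_or_higher")
  if (nrow(associations) == 0) {
    return(tibble::tibble(type = types, n_votus = 0L, percent = NA_real_))
  }
  cls <- classify_association(associations)
  tab <- cls |> dplyr::count(.data$type, name = "n_votus")
  tibble::tibble(type = types) |>
    dplyr::left_join(tab, by = "type") |>
    dplyr::mutate(
      n_votus = dplyr::coalesce(.data$n_votus, 0L),
      percent = 100 * .data$n_votus / nrow(cls)
    )
}

#' Curate auxiliary metabolic gene calls
#'
#' Combines AMG calls from the two callers (union by default, intersection
#' optionally), de-duplicating by (`votu_id`, `gene_index`, `cog_id`) with
#' the contributing callers merged, and then removes calls located at the
#' vOTU ends -- by default the first or last CDS of the contig
#' (`edge_mode = "first_last_gene"`), alternatively any gene within
#' `bp_buffer` bases of a contig terminus (`edge_mode = "bp_buffer"`, which
#' requires `gene_start`, `gene_end` and `contig_length` columns).
#'
#' @param calls Data frame with columns `votu_id`, `gene_index`,
#'   `total_genes`, `cog_id`, `caller`, and optionally `categories`,
#'   `gene_start`, `gene_end`, `contig_length`.
#' @param edge_mode `"first_last_gene"` (default) or `"bp_buffer"`.
#' @param combine `"union"` (default) or `"intersection"` of the two callers.
#' @param bp_buffer Buffer in bases for `edge_mode = "bp_buffer"`
#'   (default 500).
#' @return A tibble of curated AMG calls with a `callers` column
#'   (comma-separated, sorted).
#' @export
curate_amgs <- function(calls, edge_mode = c("first_last_gene", "bp_buffer"),
                        combine = c("union", "intersection"), bp_buffer = 500) {
  edge_mode <- match.arg(edge_mode)
  combine <- match.arg(combine)
  check_columns(calls, c("votu_id", "gene_index", "total_genes", "cog_id",
                         "caller"), "calls")
  if (nrow(calls) > 0 &&
      any(calls$gene_index < 1 | calls$gene_index > calls$total_genes)) {
    abort_crustvir("`gene_index` must lie in [1, total_genes].", "invalid_record")
  }
  if (edge_mode == "bp_buffer") {
    check_columns(calls, c("gene_start", "gene_end", "contig_length"), "calls")
  }
  extra <- setdiff(names(calls), c("votu_id", "gene_index", "cog_id", "caller"))
  merged <- calls |>
    dplyr::group_by(.data$votu_id, .data$gene_index, .data$cog_id) |>
    dplyr::summarise(
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      n_callers = dplyr::n_distinct(.data$caller),
      dplyr::across(dplyr::all_of(extra), dplyr::first),
      .groups = "drop"
    )
  if (combine == "intersection") {
    merged <- dplyr::filter(merged, .data$n_callers >= 2)
  }
  merged <- dplyr::select(merged, -"n_callers")
  out <- if (edge_mode == "first_last_gene") {
    dplyr::filter(merged, .data$gene_index != 1,
                  .data$gene_index != .data$total_genes)
  } else {
    dplyr::filter(merged, .data$gene_start >= bp_buffer,
                  .data$gene_end <= .data$contig_length - bp_buffer)
  }
  dplyr::arrange(out, .data$votu_id, .data$gene_index, .data$cog_id)
}
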