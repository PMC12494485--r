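# Island-gene overlap and eggNOG/COG functional category profiling.

#' Intersect islands with CDS features
#'
#' A gene belongs to an island if it is fully or partially contained in it,
#' implemented as an overlap of at least one base on the same contig. Every
#' overlapping (island, CDS) pair is reported once.
#'
#' @param islands Island tibble from [detect_islands()] (needs `contig_id`,
#'   `start`, `end`; other island columns are carried through with an
#'   `island_` prefix for `start`/`end`).
#' @param features CDS tibble with columns `contig_id`, `start`, `end`
#'   (0-based half-open), `protein_id`, and optionally `strand`, `cog_ids`,
#'   `categories`.
#' @return A tibble with one row per overlapping pair, island coordinates as
#'   `island_start`/`island_end` and CDS coordinates as `cds_start`/`cds_end`.
#' @export
overlap_islands_with_cds <- function(islands, features) {
  check_columns(islands, c("contig_id", "start", "end"), "islands")
  check_columns(features, c("contig_id", "start", "end", "protein_id"), "features")
  if (nrow(islands) == 0 || nrow(features) == 0) {
    return(tibble::tibble())
  }
  seqs <- union(islands$contig_id, features$contig_id)
  gr_isl <- GenomicRanges::GRanges(
    factor(islands$contig_id, levels = seqs),
    IRanges::IRanges(islands$start + 1L, islands$end)
  )
  gr_cds <- GenomicRanges::GRanges(
    factor(features$contig_id, levels = seqs),
    IRanges::IRanges(features$start + 1L, features$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_isl, gr_cds, minoverlap = 1L)
  isl <- islands |>
    dplyr::rename(island_start = "start", island_end = "end")
  cds <- features |>
    dplyr::rename(cds_start = "start", cds_end = "end") |>
    dplyr::select(-"contig_id")
  dplyr::bind_cols(
    isl[S4Vectors::queryHits(hits), , drop = FALSE],
    cds[S4Vectors::subjectHits(hits), , drop = FALSE]
  ) |> tibble::as_tibble()
}

#' Summarise eggNOG functional categories
#'
#' A protein annotated with a multi-letter category string (e.g. `"EGP"`)
#' contributes one hit to each of its letters. Proteins are de-duplicated by
#' `protein_id` first, so a gene overlapping several islands is counted once.
#' Letters whose relative share falls below `others_threshold` percent are
#' collapsed into a single `"Others"` row (the letters collapsed are recorded
#' in the `others_bucket` attribute). Category S (function unknown) can be
#' excluded from both counts and denominator with `exclude_S`.
#'
#' @param x A data frame with columns `protein_id` and `categories`
#'   (a string of one-letter eggNOG categories), e.g. the output of
#'   [overlap_islands_with_cds()].
#' @param others_threshold Percent share below which a category is folded
#'   into `"Others"` (default 2).
#' @param exclude_S Drop category S before computing shares (default FALSE).
#' @return A tibble with `category`, `count`, `percent`, sorted by decreasing
#'   count with `"Others"` last; attribute `others_bucket` lists the
#'   collapsed letters.
#' @export
summarize_categories <- function(x, others_threshold = 2, exclude_S = FALSE) {
  check_columns(x, c("protein_id", "categories"), "x")
  prof_empty <- structure(
    tibble::tibble(category = character(), count = integer(), percent = numeric()),
    others_bucket = character()
  )
  if (nrow(x) == 0) return(prof_empty)
  ann <- dplyr::distinct(x, .data$protein_id, .data$categories)
  letters_all <- strsplit(ann$categories, "", fixed = TRUE) |> unlist(use.names = FALSE)
  letters_all <- letters_all[!is.na(letters_all) & letters_all != ""]
  if (length(letters_all) == 0) return(prof_empty)
  bad <- !(letters_all %in% cog_alphabet())
  if (any(bad)) {
    rlang::warn(sprintf("%d annotation letter(s) outside the COG alphabet; bucketed as 'unknown'.",
                        sum(bad)))
    letters_all[bad] <- "unknown"
  }
  if (exclude_S) letters_all <- letters_all[letters_all != "S"]
  if (length(letters_all) == 0) return(prof_empty)
  counts <- sort(table(letters_all), decreasing = TRUE)
  prof <- tibble::tibble(
    category = names(counts),
    count = as.integer(counts),
    percent = 100 * as.integer(counts) / sum(counts)
  )
  small <- prof$percent < others_threshold
  others_bucket <- prof$category[small]
  if (any(small)) {
    prof <- dplyr::bind_rows(
      prof[!small, ],
      tibble::tibble(category = "Others",
                     count = sum(prof$count[small]),
                     percent = sum(prof$percent[small]))
    )
  }
  prof <- dplyr::arrange(prof, .data$category == "Others", dplyr::desc(.data$count),
                         .data$category)
  structure(prof, others_bucket = others_bucket)
}

#' Rank the most abundant COGs
#'
#' Counts predicted protein-encoding genes per COG identifier (a protein
#' annotated with several COGs contributes to each; duplicate
#' (protein, COG) pairs count once) and returns the `n` most abundant,
#' ranked by decreasing count with ties broken lexicographically by COG id.
#'
#' @param x A data frame with columns `protein_id`, `cog_id`, and optionally
#'   `category` and `function_label` (first value per COG is carried along).
#' @param n Number of COGs to return (default 20).
#' @return A tibble `cog_id`, `category`, `function_label`, `count`.
#' @export
top_cogs <- function(x, n = 20) {
  check_columns(x, c("protein_id", "cog_id"), "x")
  if (n < 1) abort_crustvir("`n` must be at least 1.", "invalid_input")
  if (nrow(x) == 0) {
    return(tibble::tibble(cog_id = character(), category = character(),
                          function_label = character(), count = integer()))
  }
  meta <- x |>
    dplyr::group_by(.data$cog_id) |>
    dplyr::summarise(
      category = if ("category" %in% names(x)) dplyr::first(.data$category) else NA_character_,
      function_label = if ("function_label" %in% names(x)) dplyr::first(.data$function_label) else NA_character_,
      .groups = "drop"
    )
  x |>
    dplyr::distinct(.data$protein_id, .data$cog_id) |>
    dplyr::count(.data$cog_id, name = "count") |>
    dplyr::left_join(meta, by = "cog_id") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$cog_id) |>
    dplyr::slice_head(n = n) |>
    dplyr::select("cog_id", "category", "function_label", "count")
}
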