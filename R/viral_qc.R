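# Decision rules for viral-candidate screening, vOTU retention, MAG quality
# tiering and lifestyle assignment. Threshold boundary semantics are literal;
# absent tool scores (NA) mean "tool did not run" and never count as zero.

na_false <- function(x) !is.na(x) & x

#' Screen viral candidate contigs
#'
#' A contig passes if it is at least `min_length` bases long and at least one
#' discovery tool supports it: VirSorter2 score >= 0.7, DeepVirFinder score
#' >= 0.9 with P <= 0.05, Seeker score >= 0.9, or a positive VIBRANT call.
#'
#' @param records Data frame with columns `contig_id`, `length`, and any of
#'   `vs2_score`, `dvf_score`, `dvf_p`, `seeker_score`, `vibrant_call`
#'   (missing columns / NA values mean the tool did not run).
#' @param min_length Minimum contig length in bases (default 5000).
#' @return The input tibble with a logical `pass` column.
#' @export
screen_candidates <- function(records, min_length = 5000) {
  check_columns(records, c("contig_id", "length"), "records")
  get <- function(col, default = NA_real_) {
    if (col %in% names(records)) records[[col]] else rep(default, nrow(records))
  }
  vs2 <- get("vs2_score"); dvf <- get("dvf_score"); dvfp <- get("dvf_p")
  seeker <- get("seeker_score")
  vib <- if ("vibrant_call" %in% names(records)) records$vibrant_call else rep(NA, nrow(records))
  tool_pass <- na_false(vs2 >= 0.7) |
    (na_false(dvf >= 0.9) & na_false(dvfp <= 0.05)) |
    na_false(seeker >= 0.9) |
    na_false(vib)
  dplyr::mutate(tibble::as_tibble(records),
                pass = .data$length >= min_length & tool_pass)
}

#' Apply vOTU retention criteria
#'
#' A vOTU is retained if it is at least `min_length` bases long and meets at
#' least one of: it contains a viral gene; it contains no viral gene and no
#' host gene; or it contains no viral gene but has a VirSorter2 score >= 0.95
#' or more than two hallmark viral genes.
#'
#' @param records Data frame with columns `votu_id`, `length`, `viral_genes`,
#'   `host_genes`, and optionally `vs2_score`, `hallmark_genes`.
#' @param min_length Minimum vOTU length in bases (default 5000).
#' @return The input tibble with a logical `retained` column.
#' @export
retain_votus <- function(records, min_length = 5000) {
  check_columns(records, c("votu_id", "length", "viral_genes", "host_genes"),
                "records")
  if (any(records$viral_genes < 0 | records$host_genes < 0)) {
    abort_crustvir("Gene counts must be non-negative.", "invalid_record")
  }
  vs2 <- if ("vs2_score" %in% names(records)) records$vs2_score else rep(NA_real_, nrow(records))
  hall <- if ("hallmark_genes" %in% names(records)) records$hallmark_genes else rep(NA_real_, nrow(records))
  crit <- records$viral_genes >= 1 |
    (records$viral_genes == 0 & records$host_genes == 0) |
    (records$viral_genes == 0 & (na_false(vs2 >= 0.95) | na_false(hall > 2)))
  dplyr::mutate(tibble::as_tibble(records),
                retained = .data$length >= min_length & crit)
}

#' Tier MAGs by completeness and contamination
#'
#' High quality: completeness > 90% and contamination < 5%. Medium quality:
#' not high, with completeness >= 50% and contamination < 10%. Everything
#' else is rejected. The three tiers partition the input.
#'
#' @param records Data frame with columns `mag_id`, `completeness` (percent,
#'   0-100) and `contamination` (percent, >= 0).
#' @return The input tibble with a `tier` column
#'   (`"high"`/`"medium"`/`"rejected"`).
#' @export
tier_mags <- function(records) {
  check_columns(records, c("mag_id", "completeness", "contamination"), "records")
  if (any(records$completeness < 0 | records$completeness > 100)) {
    abort_crustvir("Completeness must lie in [0, 100].", "invalid_record")
  }
  if (any(records$contamination < 0)) {
    abort_crustvir("Contamination must be non-negative.", "invalid_record")
  }
  dplyr::mutate(
    tibble::as_tibble(records),
    tier = dplyr::case_when(
      .data$completeness > 90 & .data$contamination < 5 ~ "high",
      .data$completeness >= 50 & .data$contamination < 10 ~ "medium",
      TRUE ~ "rejected"
    )
  )
}

#' Assign virulent/temperate lifestyle from classifier scores
#'
#' The lifestyle with the larger score is called when that score reaches
#' `min_score` (default 0.80, the validity threshold for lifestyle
#' annotations); below it, or on an exact tie, the vOTU stays unassigned.
#'
#' @param scores Data frame with columns `votu_id`, `virulent_score`,
#'   `temperate_score` (each in [0, 1]).
#' @param min_score Minimum valid score (default 0.80).
#' @return The input tibble with a `call` column
#'   (`"virulent"`/`"temperate"`/`"unassigned"`).
#' @export
call_lifestyle <- function(scores, min_score = 0.80) {
  check_columns(scores, c("votu_id", "virulent_score", "temperate_score"), "scores")
  s <- c(scores$virulent_score, scores$temperate_score)
  if (any(!is.na(s) & (s < 0 | s > 1))) {
    abort_crustvir("Lifestyle scores must lie in [0, 1].", "invalid_record")
  }
  dplyr::mutate(
    tibble::as_tibble(scores),
    call = dplyr::case_when(
      na_false(.data$virulent_score >= min_score) &
        na_false(.data$virulent_score > .data$temperate_score) ~ "virulent",
      na_false(.data$temperate_score >= min_score) &
        na_false(.data$temperate_score > .data$virulent_score) ~ "temperate",
      TRUE ~ "unassigned"
    )
  )
}
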