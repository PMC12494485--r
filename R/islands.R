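# Two-regime detection of metagenomic/metaviromic islands (MGIs/MVIs):
# maximal under-recruited stretches relative to the genome mean coverage.

#' Island-calling parameters
#'
#' Bundles the thresholds of the two-regime island definition. For genomes
#' with mean coverage at or above `high_cov_threshold` (default 5x), an
#' island is a maximal stretch of at least `min_len_drop` bases (default 100)
#' in which every base's depth has dropped by at least `drop_fraction`
#' (default 0.25, i.e. depth <= 0.75 x genome mean). For genomes with mean
#' coverage in `[low_cov_threshold, high_cov_threshold)` (default [2, 5)),
#' an island is a maximal zero-coverage stretch of at least `min_len_zero`
#' bases (default 200). Genomes below `low_cov_threshold` yield no calls.
#'
#' @param drop_fraction Required fractional coverage drop, in (0, 1).
#' @param min_len_drop Minimum island length (bases) in the drop regime.
#' @param min_len_zero Minimum island length (bases) in the zero regime.
#' @param high_cov_threshold Genome mean coverage at/above which the drop
#'   regime applies.
#' @param low_cov_threshold Genome mean coverage below which no islands are
#'   called; between the two thresholds the zero regime applies.
#' @param merge_gap Merge qualifying runs separated by at most this many
#'   non-qualifying bases before applying the length filter (default 0: no
#'   merging).
#' @return A list of class `island_params`.
#' @export
island_params <- function(drop_fraction = 0.25,
                          min_len_drop = 100,
                          min_len_zero = 200,
                          high_cov_threshold = 5,
                          low_cov_threshold = 2,
                          merge_gap = 0) {
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    abort_crustvir("`drop_fraction` must be in (0, 1).", "invalid_input")
  }
  if (min_len_drop <= 0 || min_len_zero <= 0) {
    abort_crustvir("Minimum island lengths must be positive.", "invalid_input")
  }
  if (low_cov_threshold >= high_cov_threshold) {
    abort_crustvir("`low_cov_threshold` must be below `high_cov_threshold`.",
                   "invalid_input")
  }
  structure(
    list(drop_fraction = drop_fraction, min_len_drop = min_len_drop,
         min_len_zero = min_len_zero, high_cov_threshold = high_cov_threshold,
         low_cov_threshold = low_cov_threshold, merge_gap = merge_gap),
    class = "island_params"
  )
}

# Collapse a run-length coverage track of one contig into maximal qualifying
# runs (depth <= threshold), optionally bridging gaps of <= merge_gap bases.
qualifying_runs <- function(track, threshold, merge_gap = 0) {
  qual <- track$depth <= threshold
  n <- length(qual)
  if (!any(qual)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  run_first <- which(c(TRUE, qual[-1] != qual[-n]))
  run_last <- c(run_first[-1] - 1L, n)
  keep <- qual[run_first]
  runs <- tibble::tibble(start = track$start[run_first[keep]],
                         end = track$end[run_last[keep]])
  if (merge_gap > 0 && nrow(runs) > 1) {
    gap <- runs$start[-1] - runs$end[-nrow(runs)]
    brk <- which(gap > merge_gap)
    runs <- tibble::tibble(start = runs$start[c(1L, brk + 1L)],
                           end = runs$end[c(brk, nrow(runs))])
  }
  runs
}

#' Detect metagenomic/metaviromic islands
#'
#' Scans per-base coverage for maximal under-recruited stretches under the
#' two-regime rule (see [island_params()]): a coverage drop of at least
#' `drop_fraction` over at least `min_len_drop` bases for well-covered
#' genomes (mean >= 5x), or a zero-coverage stretch of at least
#' `min_len_zero` bases for genomes with mean coverage between 2x and 5x.
#' The qualifying predicate is evaluated per base (every base of an island
#' must satisfy it) and islands never span contig boundaries; stretches
#' touching a contig end are reported with `at_contig_edge = TRUE`.
#'
#' @param coverage Coverage tibble from [compute_coverage()] (columns
#'   `contig_id`, `start`, `end`, `depth`; `genome_id` optional if supplied
#'   via `genomes`).
#' @param genomes Genome membership table (`genome_id`, `contig_id`,
#'   `length`).
#' @param params An [island_params()] object.
#' @return A tibble of islands: `genome_id`, `contig_id`, `start`, `end`
#'   (0-based half-open), `regime` (`"drop"` or `"zero"`), `genome_mean`,
#'   `island_mean`, `at_contig_edge`, sorted by (`genome_id`, `contig_id`,
#'   `start`).
#' @export
detect_islands <- function(coverage, genomes, params = island_params()) {
  check_genomes(genomes)
  check_columns(coverage, c("contig_id", "start", "end", "depth"), "coverage")
  if (!inherits(params, "island_params")) {
    abort_crustvir("`params` must be created by island_params().", "invalid_input")
  }
  means <- genome_mean_coverage(coverage, genomes)
  if (any(means$mean_coverage < 0)) {
    abort_crustvir("Negative genome mean coverage.", "invalid_input")
  }
  cov <- coverage |>
    dplyr::select(dplyr::any_of(c("contig_id", "start", "end", "depth"))) |>
    dplyr::left_join(dplyr::select(genomes, "genome_id", "contig_id"),
                     by = "contig_id")

  one_genome <- function(gdat, gmean, glen_tbl) {
    if (gmean < params$low_cov_threshold) {
      return(empty_islands())
    }
    if (gmean >= params$high_cov_threshold) {
      threshold <- (1 - params$drop_fraction) * gmean
      min_len <- params$min_len_drop
      regime <- "drop"
    } else {
      threshold <- 0
      min_len <- params$min_len_zero
      regime <- "zero"
    }
    purrr::map_dfr(split(gdat, gdat$contig_id), function(track) {
      track <- track[order(track$start), ]
      runs <- qualifying_runs(track, threshold, params$merge_gap)
      runs <- runs[runs$end - runs$start >= min_len, , drop = FALSE]
      if (nrow(runs) == 0) return(empty_islands())
      ctg_len <- glen_tbl$length[glen_tbl$contig_id == track$contig_id[1]]
      island_mean <- vapply(seq_len(nrow(runs)), function(i) {
        seg <- track[track$end > runs$start[i] & track$start < runs$end[i], ]
        ov <- pmin(seg$end, runs$end[i]) - pmax(seg$start, runs$start[i])
        sum(ov * seg$depth) / (runs$end[i] - runs$start[i])
      }, numeric(1))
      tibble::tibble(
        genome_id = track$genome_id[1], contig_id = track$contig_id[1],
        start = runs$start, end = runs$end, regime = regime,
        genome_mean = gmean, island_mean = island_mean,
        at_contig_edge = runs$start == 0L | runs$end == ctg_len
      )
    })
  }

  out <- purrr::map_dfr(split(cov, cov$genome_id), function(gdat) {
    gid <- gdat$genome_id[1]
    one_genome(gdat, means$mean_coverage[means$genome_id == gid],
               genomes[genomes$genome_id == gid, ])
  })
  if (nrow(out) == 0) return(empty_islands())
  dplyr::arrange(out, .data$genome_id, .data$contig_id, .data$start)
}

empty_islands <- function() {
  tibble::tibble(
    genome_id = character(), contig_id = character(),
    start = integer(), end = integer(), regime = character(),
    genome_mean = numeric(), island_mean = numeric(),
    at_contig_edge = logical()
  )
}

#' Per-genome island summary
#'
#' Counts islands and island bases per genome; genomes with no islands are
#' reported with zero counts so the table always covers the full genome set.
#'
#' @param islands Island tibble from [detect_islands()].
#' @param genomes Genome membership table.
#' @return A tibble with `genome_id`, `n_islands`, `total_island_bases`,
#'   `fraction_of_genome`.
#' @export
island_summary <- function(islands, genomes) {
  check_genomes(genomes)
  check_columns(islands, c("genome_id", "start", "end"), "islands")
  unknown <- setdiff(unique(islands$genome_id), genomes$genome_id)
  if (length(unknown) > 0) {
    abort_crustvir(sprintf("Islands reference unknown genome(s): %s.",
                           paste(unknown, collapse = ", ")),
                   "consistency_error")
  }
  glen <- genomes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(genome_length = sum(.data$length), .groups = "drop")
  per_g <- islands |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(n_islands = dplyr::n(),
                     total_island_bases = sum(.data$end - .data$start),
                     .groups = "drop")
  glen |>
    dplyr::left_join(per_g, by = "genome_id") |>
    dplyr::mutate(
      n_islands = dplyr::coalesce(.data$n_islands, 0L),
      total_island_bases = dplyr::coalesce(.data$total_island_bases, 0L),
      fraction_of_genome = .data$total_island_bases / .data$genome_length
    ) |>
    dplyr::select("genome_id", "n_islands", "total_island_bases",
                  "fraction_of_genome") |>
    dplyr::arrange(.data$genome_id)
}
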