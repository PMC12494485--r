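# Independent brute-force oracles. These deliberately avoid the package's
# run-length representations and interval machinery: coverage is counted
# base by base, islands are found by scanning a per-base predicate, and
# overlaps are tested on all pairs.

# Per-base depth by naive counting loop.
oracle_depth <- function(alignments, contig, len) {
  depth <- integer(len)
  aln <- alignments[alignments$contig_id == contig, , drop = FALSE]
  for (i in seq_len(nrow(aln))) {
    idx <- (aln$start[i] + 1):aln$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# Expand a bedGraph-style coverage tibble (one contig) to a per-base vector.
depth_vector <- function(track) {
  rep(track$depth, track$end - track$start)
}

# Exhaustive maximal-run island scanner on a per-base depth vector.
# Returns a data frame of 0-based half-open [start, end) intervals.
oracle_islands <- function(depth, genome_mean, drop_fraction = 0.25,
                           min_len_drop = 100, min_len_zero = 200,
                           high_cov = 5, low_cov = 2) {
  if (genome_mean < low_cov) {
    return(data.frame(start = integer(), end = integer()))
  }
  if (genome_mean >= high_cov) {
    qual <- depth <= (1 - drop_fraction) * genome_mean
    min_len <- min_len_drop
  } else {
    qual <- depth == 0
    min_len <- min_len_zero
  }
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# Quadratic all-pairs interval overlap test.
oracle_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$contig_id[i] == b$contig_id[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

# Random alignment set on a genome table.
random_alignments <- function(genomes, n, max_span = 200) {
  idx <- sample.int(nrow(genomes), n, replace = TRUE)
  len <- genomes$length[idx]
  span <- pmin(sample.int(max_span, n, replace = TRUE), len)
  start <- vapply(seq_len(n), function(i) {
    sample.int(len[i] - span[i] + 1L, 1L) - 1L
  }, integer(1))
  tibble::tibble(
    query_id = sprintf("r%05d", seq_len(n)),
    contig_id = genomes$contig_id[idx],
    start = start,
    end = start + span,
    mismatches = sample(0:5, n, replace = TRUE),
    is_primary = TRUE
  )
}

# A single-contig coverage tibble from a per-base depth vector.
track_from_depth <- function(depth, contig = "c1", genome = "g1") {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    genome_id = genome, contig_id = contig,
    start = as.integer(c(0L, ends[-length(ends)])),
    end = as.integer(ends), depth = as.integer(r$values)
  )
}

genomes1 <- function(len, contig = "c1", genome = "g1") {
  tibble::tibble(genome_id = genome, contig_id = contig, length = len)
}
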