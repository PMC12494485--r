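make_island <- function(contig, start, end) {
  tibble::tibble(genome_id = "g1", contig_id = contig, start = start, end = end,
                 regime = "drop", genome_mean = 10, island_mean = 2,
                 at_contig_edge = FALSE)
}

test_that("island-CDS overlap reports partial containment and skips disjoint pairs", {
  cds <- tibble::tibble(contig_id = "c1", start = c(200L, 600L), end = c(500L, 700L),
                        protein_id = c("p1", "p2"), categories = c("L", "M"))
  # island [450, 600) overlaps CDS [200, 500) partially; not CDS [600, 700)
  pairs <- overlap_islands_with_cds(make_island("c1", 450L, 600L), cds)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$protein_id, "p1")

  none <- overlap_islands_with_cds(make_island("c1", 100L, 200L),
                                   cds[cds$start == 600L, ])
  expect_equal(nrow(none), 0L)

  # empty inputs give empty output
  expect_equal(nrow(overlap_islands_with_cds(make_island("c1", 1L, 2L)[0, ], cds)), 0L)
})

test_that("overlap pairs equal the quadratic all-pairs oracle and ignore input order", {
  set.seed(808)
  contigs <- c("c1", "c2", "c3")
  isl <- tibble::tibble(
    genome_id = "g1",
    contig_id = sample(contigs, 40, replace = TRUE),
    start = sample(0:5000, 40)
  ) |> dplyr::mutate(end = start + sample(50:500, 40, replace = TRUE))
  cds <- tibble::tibble(
    contig_id = sample(contigs, 25, replace = TRUE),
    start = sample(0:5000, 25)
  ) |> dplyr::mutate(end = start + sample(100:1500, 25, replace = TRUE),
                     protein_id = sprintf("p%02d", 1:25))
  pairs <- overlap_islands_with_cds(isl, cds)
  oracle <- oracle_overlap_pairs(isl, cds)
  expect_equal(nrow(pairs), nrow(oracle))
  got <- sort(paste(pairs$contig_id, pairs$island_start, pairs$protein_id))
  want <- sort(paste(isl$contig_id[oracle[, 1]], isl$start[oracle[, 1]],
                     cds$protein_id[oracle[, 2]]))
  expect_equal(got, want)

  # shuffling input order changes nothing
  pairs2 <- overlap_islands_with_cds(isl[sample.int(40), ], cds[sample.int(25), ])
  expect_equal(sort(paste(pairs2$contig_id, pairs2$island_start, pairs2$protein_id)),
               want)
})

test_that("multi-letter categories contribute one hit per letter", {
  x <- tibble::tibble(protein_id = "p1", categories = "EGP")
  prof <- summarize_categories(x, others_threshold = 0.0001)
  expect_equal(sort(prof$category), c("E", "G", "P"))
  expect_equal(prof$count, rep(1L, 3))
  expect_equal(sum(prof$percent), 100)

  # empty input -> empty profile
  prof0 <- summarize_categories(x[0, ])
  expect_equal(nrow(prof0), 0L)
})

test_that("category totals equal brute-force expansion; duplicates deduplicated by protein", {
  set.seed(909)
  letters_pool <- c("L", "M", "E", "K", "S", "G", "P", "T")
  ids <- sprintf("p%03d", 1:150)
  cats <- vapply(seq_along(ids), function(i) {
    paste(sample(letters_pool, sample(1:3, 1)), collapse = "")
  }, character(1))
  # a protein appearing in several islands counts once
  x <- tibble::tibble(protein_id = c(ids, ids[1:30]),
                      categories = c(cats, cats[1:30]))
  prof <- summarize_categories(x, others_threshold = 0.0001)
  expanded <- unlist(strsplit(cats, ""))
  tab <- table(expanded)
  expect_equal(sum(prof$count), length(expanded))
  for (k in seq_len(nrow(prof))) {
    expect_equal(prof$count[k], as.integer(tab[[prof$category[k]]]))
  }
})

test_that("rare categories collapse into Others below the 2% threshold", {
  x <- tibble::tibble(
    protein_id = sprintf("p%03d", 1:100),
    categories = c(rep("L", 60), rep("M", 30), rep("E", 9), "Q")
  )
  prof <- summarize_categories(x, others_threshold = 2)
  expect_true("Others" %in% prof$category)
  expect_equal(attr(prof, "others_bucket"), "Q")
  expect_equal(prof$count[prof$category == "Others"], 1L)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-4)
  expect_equal(prof$category[nrow(prof)], "Others")
})

test_that("category S can be excluded from counts and denominator", {
  x <- tibble::tibble(protein_id = sprintf("p%d", 1:4),
                      categories = c("S", "S", "L", "M"))
  with_s <- summarize_categories(x, others_threshold = 0.0001)
  expect_equal(with_s$count[with_s$category == "S"], 2L)
  no_s <- summarize_categories(x, others_threshold = 0.0001, exclude_S = TRUE)
  expect_false("S" %in% no_s$category)
  expect_equal(sum(no_s$percent), 100)
})

test_that("letters outside the COG alphabet are bucketed with a warning", {
  x <- tibble::tibble(protein_id = c("p1", "p2"), categories = c("L", "l9"))
  expect_warning(prof <- summarize_categories(x, others_threshold = 0.0001),
                 "COG alphabet")
  expect_true("unknown" %in% prof$category)
})

test_that("top COGs rank by count with lexicographic ties, as in an island gene table", {
  x <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:18),
    cog_id = c(rep("COG0582", 7), rep("COG1961", 6), rep("COG5410", 5)),
    category = c(rep("L", 13), rep("K", 5)),
    function_label = "x"
  )
  top2 <- top_cogs(x, n = 2)
  expect_equal(top2$cog_id, c("COG0582", "COG1961"))
  expect_equal(top2$count, c(7L, 6L))

  # n beyond the number of distinct COGs returns all
  expect_equal(nrow(top_cogs(x, n = 50)), 3L)

  # ranking equals a full sort oracle on random counts; ties lexicographic
  set.seed(111)
  cogs <- sprintf("COG%04d", sample(1:60))
  counts <- sample(1:8, length(cogs), replace = TRUE)
  xr <- tibble::tibble(
    protein_id = sprintf("q%04d", seq_len(sum(counts))),
    cog_id = rep(cogs, counts)
  )
  ranked <- top_cogs(xr, n = length(cogs))
  oracle <- data.frame(cog_id = cogs, count = counts)
  oracle <- oracle[order(-oracle$count, oracle$cog_id), ]
  expect_equal(ranked$cog_id, oracle$cog_id)
  expect_equal(ranked$count, oracle$count)
})
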