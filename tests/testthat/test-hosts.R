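test_that("match filtering applies 80/80 for proteins and 90/90 for genes/tRNAs", {
  recs <- tibble::tibble(
    query_id = sprintf("q%d", 1:6), subject_id = "s",
    pct_identity = c(85, 85, 91, 89, 95, 90),
    query_coverage = c(82, 70, 95, 95, 89, 90),
    kind = c("protein", "protein", "gene", "gene", "trna", "trna")
  )
  kept <- filter_matches(recs)
  expect_equal(kept$query_id, c("q1", "q3", "q6"))
  expect_error(filter_matches(dplyr::mutate(recs, kind = "rna")),
               class = "crustvir_invalid_record")

  # random records against the literal threshold oracle
  set.seed(1313)
  rr <- tibble::tibble(
    query_id = sprintf("r%03d", 1:300), subject_id = "s",
    pct_identity = runif(300, 60, 100),
    query_coverage = runif(300, 60, 100),
    kind = sample(c("protein", "gene", "trna"), 300, replace = TRUE)
  )
  got <- filter_matches(rr)$query_id
  want <- rr$query_id[ifelse(rr$kind == "protein",
                             rr$pct_identity >= 80 & rr$query_coverage >= 80,
                             rr$pct_identity >= 90 & rr$query_coverage >= 90)]
  expect_equal(got, want)
})

assoc <- function(votu, mags, fams, classes = NULL) {
  if (is.null(classes)) classes <- fams
  tibble::tibble(votu_id = votu, mag_id = mags, family = fams, class = classes)
}

test_that("association typing distinguishes unique, family-consensus, and higher", {
  expect_equal(classify_association(assoc("v1", "Ice1", "Hymenobacteraceae"))$type,
               "unique")
  expect_equal(classify_association(
    assoc("v2", c("Ice1", "Ice2", "Ice3"), rep("Hymenobacteraceae", 3)))$type,
    "multiple_family_consensus")
  expect_equal(classify_association(
    assoc("v3", c("Ice1", "Ice2"), c("FamA", "FamB"), c("ClsA", "ClsB")))$type,
    "multiple_class_or_higher")
  # one MAG hit repeated is still unique
  expect_equal(classify_association(
    assoc("v4", c("Ice1", "Ice1"), rep("FamA", 2)))$type, "unique")
  # NA family blocks family consensus
  expect_equal(classify_association(
    assoc("v5", c("Ice1", "Ice2"), c(NA, NA)))$type, "multiple_class_or_higher")
  expect_error(classify_association(assoc("v", character(), character())),
               class = "crustvir_no_association")
  # permutation invariance
  a <- assoc("v6", c("Ice1", "Ice2", "Ice3"), rep("F", 3))
  expect_equal(classify_association(a), classify_association(a[3:1, ]))
})

test_that("association spectrum percentages recount correctly", {
  links <- dplyr::bind_rows(
    assoc("v1", "Ice1", "F1"), assoc("v2", "Ice2", "F1"),
    assoc("v3", c("Ice1", "Ice2"), rep("F1", 2)),
    assoc("v4", c("Ice1", "Ice3"), c("F1", "F2"), c("C1", "C2"))
  )
  spec <- association_spectrum(links)
  expect_equal(spec$n_votus, c(2L, 1L, 1L))
  expect_equal(spec$percent, c(50, 25, 25))
  all_unique <- dplyr::bind_rows(assoc("v1", "Ice1", "F1"), assoc("v2", "Ice2", "F2"))
  expect_equal(association_spectrum(all_unique)$percent, c(100, 0, 0))

  # random association sets against a recount oracle
  set.seed(1414)
  rl <- purrr::map_dfr(sprintf("v%02d", 1:30), function(v) {
    n <- sample(1:3, 1)
    assoc(v, sprintf("Ice%d", sample(1:10, n)),
          sprintf("F%d", sample(1:4, n, replace = TRUE)),
          sprintf("C%d", sample(1:2, n, replace = TRUE)))
  })
  spec2 <- association_spectrum(rl)
  cls <- classify_association(rl)
  expect_equal(sum(spec2$n_votus), nrow(cls))
  expect_equal(spec2$n_votus[spec2$type == "unique"], sum(cls$type == "unique"))
  expect_equal(sum(spec2$percent), 100)
})

amg <- function(votu, idx, total, cog, caller) {
  tibble::tibble(votu_id = votu, gene_index = idx, total_genes = total,
                 cog_id = cog, caller = caller)
}

test_that("AMG curation unions callers and removes end-located genes", {
  calls <- dplyr::bind_rows(
    amg("v1", 1L, 10L, "COG0270", "caller_a"),     # first gene: removed
    amg("v1", 10L, 10L, "COG0209", "caller_b"),    # last gene: removed
    amg("v1", 4L, 10L, "COG0270", "caller_a"),
    amg("v1", 4L, 10L, "COG0270", "caller_b"),     # duplicate -> one record
    amg("v2", 2L, 8L, "COG2189", "caller_b")
  )
  cur <- curate_amgs(calls)
  expect_equal(nrow(cur), 2L)
  expect_equal(cur$callers[cur$votu_id == "v1"], "caller_a,caller_b")
  expect_equal(cur$callers[cur$votu_id == "v2"], "caller_b")
  expect_true(all(cur$gene_index > 1 & cur$gene_index < cur$total_genes))

  # intersection mode keeps only two-caller calls
  inter <- curate_amgs(calls, combine = "intersection")
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$gene_index, 4L)

  # union is idempotent
  again <- curate_amgs(dplyr::bind_rows(calls, calls))
  expect_equal(cur, again)

  expect_error(curate_amgs(amg("v", 0L, 5L, "COG1", "caller_a")),
               class = "crustvir_invalid_record")
})

test_that("AMG curation matches a brute-force union + edge-filter oracle", {
  set.seed(1515)
  totals <- sample(5:20, 10, replace = TRUE)   # total genes is per-vOTU
  calls <- purrr::map_dfr(1:120, function(i) {
    v <- sample(1:10, 1)
    amg(sprintf("v%02d", v), sample(1:totals[v], 1), totals[v],
        sprintf("COG%04d", sample(1:6, 1)),
        sample(c("caller_a", "caller_b"), 1))
  })
  cur <- curate_amgs(calls)
  key <- unique(calls[, c("votu_id", "gene_index", "total_genes", "cog_id")])
  key <- key[key$gene_index != 1 & key$gene_index != key$total_genes, ]
  expect_equal(nrow(cur), nrow(dplyr::distinct(key, votu_id, gene_index, cog_id)))
  expect_true(all(cur$gene_index != 1))
  expect_true(all(cur$gene_index != cur$total_genes))
  for (i in seq_len(nrow(cur))) {
    sub <- calls[calls$votu_id == cur$votu_id[i] &
                   calls$gene_index == cur$gene_index[i] &
                   calls$cog_id == cur$cog_id[i], ]
    expect_equal(cur$callers[i], paste(sort(unique(sub$caller)), collapse = ","))
  }
})

test_that("bp-buffer edge mode removes genes near contig termini", {
  calls <- dplyr::bind_rows(
    amg("v1", 2L, 10L, "COG1", "caller_a"),
    amg("v1", 3L, 10L, "COG2", "caller_a")
  )
  calls$gene_start <- c(100L, 2000L)
  calls$gene_end <- c(700L, 2600L)
  calls$contig_length <- 10000L
  cur <- curate_amgs(calls, edge_mode = "bp_buffer", bp_buffer = 500)
  expect_equal(cur$cog_id, "COG2")
})
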