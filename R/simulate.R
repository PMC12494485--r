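# Seeded synthetic-data generator. Emits the inputs every pipeline stage
# consumes -- alignments with planted low-coverage islands, classifier
# taxonomy tables with controlled agreement, host predictions, AMG calls,
# QC tables and CDS annotations -- together with the ground truth, so island
# recovery, consensus taxonomy and curation rules can be verified without
# raw reads.

#' Simulation configuration
#'
#' Defaults reproduce the package's reference study conditions: 20 genomes
#' with 3 planted islands each at a 20x baseline, islands of 300-1000 bases
#' at depth fraction 0.2, 100-base reads (2x100 bp short-read recruitment),
#' four samples, and four taxonomy classifiers agreeing at rate 0.9.
#' `mismatch_rate` is the per-read probability mass over 0-3 mismatches;
#' with the default c(0.80, 0.15, 0.04, 0.01), the <=1-mismatch filter keeps
#' 95% of reads. Fractions of vOTUs with host links (0.085), with AMGs
#' (0.044) and with a temperate lifestyle (0.065) mirror proportions typical
#' of a glacier-ice metavirome.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param n_genomes,contigs_per_genome Genome set shape.
#' @param contig_length_range Contig length range in bases.
#' @param mean_depth_range Baseline depth range (one draw per genome).
#' @param n_islands_per_genome Planted islands per genome.
#' @param island_length_range Island length range in bases.
#' @param island_depth_fraction Island depth as a fraction of baseline.
#' @param read_length Read length in bases.
#' @param mismatch_rate Probability mass over 0..3 mismatches per read.
#' @param n_samples Number of pooled samples.
#' @param mode `"poisson"` (stochastic read starts) or `"tiling"`
#'   (deterministic, noiseless: exact depths, zero mismatches).
#' @param secondary_rate Fraction of reads duplicated as secondary
#'   alignments (excluded from coverage by the primary-only rule).
#' @param classifier_agreement Per-rank probability that a classifier call
#'   matches the true lineage.
#' @param classifier_assign_rate Per-rank geometric assignment rate: a
#'   classifier assigns ranks down to the first failure of a Bernoulli
#'   (`classifier_assign_rate`) trial, so with 1 every rank is assigned.
#' @param n_decoy_lineages Decoy lineages per vOTU (wrong at every rank).
#' @param n_mags,host_fraction,host_decoys Host-side shape: size of the MAG
#'   pool, fraction of vOTUs with at least one host link, and decoy hosts
#'   appended per linked vOTU.
#' @param assoc_props Mix of association types (unique / family-consensus /
#'   class-or-higher) among linked vOTUs.
#' @param amg_votu_fraction Fraction of vOTUs carrying AMGs.
#' @param temperate_fraction Fraction of vOTUs with temperate lifestyle.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 20,
                       contigs_per_genome = 1,
                       contig_length_range = c(10000, 30000),
                       mean_depth_range = c(20, 20),
                       n_islands_per_genome = 3,
                       island_length_range = c(300, 1000),
                       island_depth_fraction = 0.2,
                       read_length = 100,
                       mismatch_rate = c(`0` = 0.80, `1` = 0.15, `2` = 0.04, `3` = 0.01),
                       n_samples = 4,
                       mode = c("poisson", "tiling"),
                       secondary_rate = 0.02,
                       classifier_agreement = 0.9,
                       classifier_assign_rate = 1,
                       n_decoy_lineages = 2,
                       n_mags = 20,
                       host_fraction = 0.085,
                       host_decoys = 0,
                       assoc_props = c(unique = 0.678, family = 0.297, higher = 0.025),
                       amg_votu_fraction = 0.044,
                       temperate_fraction = 0.065) {
  mode <- match.arg(mode)
  if (abs(sum(mismatch_rate) - 1) > 1e-8) {
    abort_crustvir("`mismatch_rate` must sum to 1.", "config_error")
  }
  if (island_depth_fraction < 0 || island_depth_fraction > 1) {
    abort_crustvir("`island_depth_fraction` must lie in [0, 1].", "config_error")
  }
  if (max(island_length_range) + 400 > min(contig_length_range)) {
    abort_crustvir("Islands too long for the configured contigs.", "config_error")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# Uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample()).
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Non-overlapping island placement with >= `sep` bases between islands and
# from contig ends, so planted truth is unambiguous under maximal-run calls.
place_islands <- function(contig_len, n, len_range, sep = 200L) {
  if (n == 0) return(tibble::tibble(start = integer(), end = integer()))
  for (attempt in 1:200) {
    lens <- sample_range(len_range[1], len_range[2], n)
    starts <- sort(sample_range(sep, contig_len - sep - max(lens), n))
    ends <- starts + lens
    if (n == 1 || all(starts[-1] - ends[-n] >= sep)) {
      return(tibble::tibble(start = as.integer(starts), end = as.integer(ends)))
    }
  }
  abort_crustvir("Could not place non-overlapping islands; contigs too short.",
                 "config_error")
}

# Decompose a per-base target depth vector into alignment intervals: layer k
# covers the maximal runs where target >= k. Exact and deterministic.
tile_alignments <- function(target, contig_id) {
  max_d <- max(target)
  if (max_d == 0) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer()))
  }
  purrr::map_dfr(seq_len(max_d), function(k) {
    r <- rle(target >= k)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    tibble::tibble(contig_id = contig_id,
                   start = as.integer(starts[r$values]),
                   end = as.integer(ends[r$values]))
  })
}

#' Simulate pooled read recruitment with planted islands
#'
#' Builds a genome set, plants non-overlapping low-coverage islands, and
#' draws alignment records whose expected per-base depth equals the genome
#' baseline outside islands and baseline x `island_depth_fraction` inside.
#' In `"poisson"` mode read starts follow a position-dependent Poisson
#' process (starts may overhang contig ends and are clipped, keeping
#' expected depth uniform at the edges); in `"tiling"` mode alignments are
#' constructed deterministically so planted depths are exact and mismatch
#' counts are zero. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `genomes` (membership table), `alignments`
#'   (query_id, contig_id, start, end, mismatches, is_primary, sample_id)
#'   and `truth` (planted islands with baseline and depth fraction).
#' @export
simulate_recruitment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genomes <- purrr::map_dfr(seq_len(config$n_genomes), function(g) {
      tibble::tibble(
        genome_id = sprintf("g%03d", g),
        contig_id = sprintf("g%03d_c%02d", g, seq_len(config$contigs_per_genome)),
        length = sample_range(config$contig_length_range[1],
                              config$contig_length_range[2],
                              config$contigs_per_genome)
      )
    })
    baselines <- tibble::tibble(
      genome_id = unique(genomes$genome_id),
      baseline = round(stats::runif(config$n_genomes,
                                    config$mean_depth_range[1],
                                    config$mean_depth_range[2]))
    )

    # Assign each genome's islands to random member contigs.
    truth <- purrr::map_dfr(unique(genomes$genome_id), function(gid) {
      ctg <- genomes[genomes$genome_id == gid, ]
      n_isl <- config$n_islands_per_genome
      if (n_isl == 0) return(tibble::tibble())
      pick <- sort(sample(seq_len(nrow(ctg)), n_isl, replace = TRUE))
      purrr::map_dfr(unique(pick), function(j) {
        placed <- place_islands(ctg$length[j], sum(pick == j),
                                config$island_length_range)
        tibble::tibble(genome_id = gid, contig_id = ctg$contig_id[j],
                       start = placed$start, end = placed$end,
                       depth_fraction = config$island_depth_fraction)
      })
    })
    truth <- dplyr::left_join(truth, baselines, by = "genome_id")

    target_depth <- function(ctg_row) {
      gid <- ctg_row$genome_id
      b <- baselines$baseline[baselines$genome_id == gid]
      tgt <- rep(b, ctg_row$length)
      isl <- truth[truth$contig_id == ctg_row$contig_id, ]
      for (i in seq_len(nrow(isl))) {
        tgt[(isl$start[i] + 1):isl$end[i]] <- round(b * isl$depth_fraction[i])
      }
      tgt
    }

    aln <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
      ctg <- genomes[i, ]
      tgt <- target_depth(ctg)
      if (config$mode == "tiling") {
        out <- tile_alignments(tgt, ctg$contig_id)
        if (nrow(out) == 0) return(out)
        out$mismatches <- 0L
        return(out)
      }
      r_len <- config$read_length
      # start positions -(R-1) .. L-1, clipped; rate keyed on the read
      # midpoint so depth transitions are centred on planted island edges
      starts_all <- seq(-(r_len - 1L), ctg$length - 1L)
      mid <- pmin(pmax(starts_all + r_len %/% 2L, 0L), ctg$length - 1L)
      lambda <- tgt[mid + 1L] / r_len
      n_reads <- stats::rpois(1, sum(lambda))
      if (n_reads == 0) {
        return(tibble::tibble(contig_id = character(), start = integer(),
                              end = integer(), mismatches = integer()))
      }
      starts <- sample(starts_all, n_reads, replace = TRUE, prob = lambda)
      tibble::tibble(
        contig_id = ctg$contig_id,
        start = as.integer(pmax(starts, 0L)),
        end = as.integer(pmin(starts + r_len, ctg$length)),
        mismatches = as.integer(sample(as.integer(names(config$mismatch_rate)),
                                       n_reads, replace = TRUE,
                                       prob = config$mismatch_rate))
      )
    })
    aln <- aln |>
      dplyr::mutate(
        query_id = sprintf("read_%07d", dplyr::row_number()),
        is_primary = TRUE,
        sample_id = sprintf("S%d", sample.int(config$n_samples, dplyr::n(),
                                              replace = TRUE))
      ) |>
      dplyr::select("query_id", "contig_id", "start", "end", "mismatches",
                    "is_primary", "sample_id")
    if (config$mode == "poisson" && config$secondary_rate > 0 && nrow(aln) > 0) {
      n_sec <- stats::rbinom(1, nrow(aln), config$secondary_rate)
      if (n_sec > 0) {
        sec <- aln[sample.int(nrow(aln), n_sec), ]
        sec$is_primary <- FALSE
        sec$query_id <- paste0(sec$query_id, "_sec")
        aln <- dplyr::bind_rows(aln, sec)
      }
    }
    list(genomes = genomes, alignments = aln, truth = truth)
  })
}

ranks_ <- function() viral_ranks()

#' Simulate downstream analysis tables with ground truth
#'
#' Generates, for the vOTUs of a recruitment simulation (or a standalone set
#' of `n_votus`), the tabular inputs of the downstream stages: per-classifier
#' taxonomy calls with controlled agreement, host predictions with typed
#' vOTU-MAG association structure, AMG calls from two callers with planted
#' end-located decoys, QC tables (candidate scores, vOTU retention metrics,
#' MAG quality, lifestyle scores) and tiled CDS annotations with eggNOG/COG
#' categories. Each classifier follows the true lineage with probability
#' `classifier_agreement`, otherwise one of `n_decoy_lineages` decoy lineages
#' that differ from the truth at every rank; classifiers are independent.
#'
#' @param config A [sim_config()].
#' @param recruitment Optional output of [simulate_recruitment()]; when
#'   given, vOTU ids and contig coordinates reuse its genome set.
#' @param n_votus Number of vOTUs when `recruitment` is NULL (default 50).
#' @return A list with `tables` (classifier_calls, host_predictions,
#'   amg_calls, candidate_scores, votu_qc, mag_quality, lifestyle_scores,
#'   cds, mag_lineages, counts) and `truth` (lineages, hosts, amgs,
#'   association types).
#' @export
simulate_tables <- function(config, recruitment = NULL, n_votus = 50) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    if (!is.null(recruitment)) {
      genomes <- recruitment$genomes
      votus <- unique(genomes$genome_id)
    } else {
      votus <- sprintf("vOTU%04d", seq_len(n_votus))
      genomes <- tibble::tibble(
        genome_id = votus, contig_id = paste0(votus, "_c01"),
        length = sample_range(config$contig_length_range[1],
                              config$contig_length_range[2], length(votus))
      )
    }
    rks <- ranks_()

    ## --- true and decoy lineages -------------------------------------
    true_lineage <- purrr::map_dfr(votus, function(v) {
      tibble::as_tibble(c(
        list(votu_id = v),
        stats::setNames(as.list(paste0(rks, "_", v, "_t")), rks)
      ))
    })
    classifiers <- c("aln_protein", "aln_gene", "profile_search", "composite_scorer")
    kind_of <- c(aln_protein = "bitscore", aln_gene = "pct_identity",
                 profile_search = "bitscore", composite_scorer = "virus_score")
    draw_score <- function(kind, n) {
      switch(kind,
             bitscore = stats::runif(n, 55, 400),
             pct_identity = stats::runif(n, 91, 100),
             virus_score = stats::runif(n, 0.75, 1))
    }
    classifier_calls <- purrr::map_dfr(classifiers, function(cl) {
      # depth of the assigned rank prefix: geometric in assign_rate
      depth <- vapply(votus, function(v) {
        ok <- stats::runif(length(rks)) <= config$classifier_assign_rate
        d <- which(!ok)
        if (length(d) == 0) length(rks) else d[1] - 1L
      }, integer(1))
      follow_true <- stats::runif(length(votus)) <= config$classifier_agreement
      decoy_pick <- sample.int(config$n_decoy_lineages, length(votus), replace = TRUE)
      rows <- purrr::map_dfr(seq_along(votus), function(i) {
        v <- votus[i]
        names_full <- if (follow_true[i]) paste0(rks, "_", v, "_t")
                      else paste0(rks, "_", v, "_d", decoy_pick[i])
        names_full[seq_along(rks) > depth[i]] <- NA_character_
        tibble::as_tibble(c(list(votu_id = v),
                            stats::setNames(as.list(names_full), rks)))
      })
      rows$classifier <- cl
      rows$score_kind <- unname(kind_of[cl])
      rows$score <- draw_score(kind_of[cl], nrow(rows))
      rows
    }) |>
      dplyr::select("votu_id", "classifier", "score", "score_kind",
                    dplyr::all_of(rks))

    ## --- MAG pool with nested lineages -------------------------------
    n_mags <- config$n_mags
    classes <- sprintf("c__Class%02d", 1:4)
    fams <- tibble::tibble(
      family = sprintf("f__Family%02d", 1:8),
      class = rep(classes, each = 2)
    )
    mag_lineages <- tibble::tibble(
      mag_id = sprintf("Ice%d", seq_len(n_mags)),
      domain = "Bacteria",
      phylum = "p__Phylum01",
      class = fams$class[((seq_len(n_mags) - 1) %% nrow(fams)) + 1],
      family = fams$family[((seq_len(n_mags) - 1) %% nrow(fams)) + 1],
      genus = sprintf("g__Genus%02d", seq_len(n_mags))
    )

    ## --- host associations -------------------------------------------
    n_linked <- max(1L, round(config$host_fraction * length(votus)))
    linked <- sample(votus, n_linked)
    types <- sample(names(config$assoc_props), n_linked, replace = TRUE,
                    prob = config$assoc_props)
    host_truth <- purrr::map_dfr(seq_len(n_linked), function(i) {
      v <- linked[i]
      if (types[i] == "unique") {
        mags <- sample(mag_lineages$mag_id, 1)
      } else if (types[i] == "family") {
        fam <- sample(fams$family[fams$family %in%
          mag_lineages$family[duplicated(mag_lineages$family)]], 1)
        pool <- mag_lineages$mag_id[mag_lineages$family == fam]
        mags <- sample(pool, min(length(pool), sample(2:3, 1)))
      } else {
        cls_pick <- sample(classes, 2)
        mags <- vapply(cls_pick, function(cc) {
          sample(mag_lineages$mag_id[mag_lineages$class == cc], 1)
        }, character(1))
      }
      tibble::tibble(votu_id = v, mag_id = mags, true_type = types[i])
    })
    host_predictions <- host_truth |>
      dplyr::left_join(mag_lineages, by = "mag_id") |>
      dplyr::select("votu_id", "mag_id", "domain", "phylum", "class",
                    "family", "genus") |>
      dplyr::mutate(source = "host_predictor")
    if (config$host_decoys > 0) {
      decoys <- purrr::map_dfr(unique(host_truth$votu_id), function(v) {
        mags <- sample(mag_lineages$mag_id, config$host_decoys)
        tibble::tibble(votu_id = v, mag_id = mags)
      }) |>
        dplyr::left_join(mag_lineages, by = "mag_id") |>
        dplyr::mutate(source = "decoy")
      host_predictions <- dplyr::bind_rows(host_predictions, decoys)
    }

    ## --- AMG calls with end-located decoys ----------------------------
    n_amg_votus <- max(1L, round(config$amg_votu_fraction * length(votus)))
    amg_votus <- sample(votus, n_amg_votus)
    amg_cogs <- c("COG0270", "COG0209", "COG0208", "COG2189", "COG1351")
    amg_cats <- c(COG0270 = "L", COG0209 = "F", COG0208 = "F",
                  COG2189 = "L", COG1351 = "F")
    amg_rows <- purrr::map_dfr(amg_votus, function(v) {
      total <- 8L + stats::rpois(1, 20)
      n_true <- 1L + stats::rpois(1, 0.5)
      idx <- sample(2:(total - 1L), min(n_true, total - 2L))
      true_rows <- tibble::tibble(
        votu_id = v, gene_index = as.integer(idx), total_genes = total,
        cog_id = sample(amg_cogs, length(idx), replace = TRUE), is_decoy = FALSE
      )
      decoy_rows <- tibble::tibble(
        votu_id = v, gene_index = c(1L, total), total_genes = total,
        cog_id = sample(amg_cogs, 2, replace = TRUE), is_decoy = TRUE
      )
      dplyr::bind_rows(true_rows, decoy_rows)
    }) |>
      dplyr::mutate(categories = unname(amg_cats[.data$cog_id]))
    caller_draw <- sample(c("both", "caller_a", "caller_b"), nrow(amg_rows),
                          replace = TRUE, prob = c(0.5, 0.25, 0.25))
    amg_calls <- purrr::map_dfr(seq_len(nrow(amg_rows)), function(i) {
      callers <- if (caller_draw[i] == "both") c("caller_a", "caller_b")
                 else caller_draw[i]
      dplyr::bind_cols(amg_rows[rep(i, length(callers)), ],
                       tibble::tibble(caller = callers))
    })
    amg_truth <- amg_rows |> dplyr::filter(!.data$is_decoy) |>
      dplyr::select(-"is_decoy")

    ## --- QC tables -----------------------------------------------------
    lens <- stats::setNames(
      genomes |> dplyr::group_by(.data$genome_id) |>
        dplyr::summarise(len = sum(.data$length), .groups = "drop") |>
        dplyr::pull("len"),
      unique(genomes$genome_id)
    )
    candidate_scores <- tibble::tibble(
      contig_id = votus,
      length = as.integer(lens[votus]),
      vs2_score = stats::runif(length(votus), 0.7, 1),
      dvf_score = NA_real_, dvf_p = NA_real_,
      seeker_score = NA_real_,
      vibrant_call = stats::runif(length(votus)) < 0.5
    )
    decoy_cand <- tibble::tibble(
      contig_id = sprintf("decoy%03d", 1:10),
      length = sample(c(3000L, 6000L), 10, replace = TRUE),
      vs2_score = stats::runif(10, 0, 0.6),
      dvf_score = stats::runif(10, 0, 0.85), dvf_p = stats::runif(10, 0.1, 1),
      seeker_score = stats::runif(10, 0, 0.85),
      vibrant_call = FALSE
    )
    candidate_scores <- dplyr::bind_rows(candidate_scores, decoy_cand)
    votu_qc <- tibble::tibble(
      votu_id = votus,
      length = as.integer(lens[votus]),
      viral_genes = stats::rpois(length(votus), 3),
      host_genes = stats::rpois(length(votus), 1),
      vs2_score = stats::runif(length(votus), 0.5, 1),
      hallmark_genes = stats::rpois(length(votus), 1)
    )
    mag_quality <- tibble::tibble(
      mag_id = mag_lineages$mag_id,
      completeness = stats::runif(n_mags, 40, 100),
      contamination = stats::runif(n_mags, 0, 12)
    )
    true_temperate <- stats::runif(length(votus)) < config$temperate_fraction
    conf <- stats::runif(length(votus), 0.82, 1)
    weak <- stats::runif(length(votus)) < 0.10   # below-threshold annotations
    conf[weak] <- stats::runif(sum(weak), 0.5, 0.79)
    lifestyle_scores <- tibble::tibble(
      votu_id = votus,
      virulent_score = ifelse(true_temperate, 1 - conf, conf),
      temperate_score = ifelse(true_temperate, conf, 1 - conf)
    )

    ## --- CDS annotations ----------------------------------------------
    island_truth <- if (!is.null(recruitment)) recruitment$truth else NULL
    cog_pool <- sim_cog_pool()
    cds <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
      ctg <- genomes[i, ]
      starts <- seq(0L, ctg$length - 1200L, by = 1000L)
      if (length(starts) == 0) return(tibble::tibble())
      g_start <- as.integer(starts + sample(0:100, length(starts), replace = TRUE))
      g_end <- as.integer(g_start + sample(seq(600, 900, by = 3), length(starts),
                                           replace = TRUE))
      in_island <- rep(FALSE, length(starts))
      if (!is.null(island_truth)) {
        isl <- island_truth[island_truth$contig_id == ctg$contig_id, ]
        for (j in seq_len(nrow(isl))) {
          in_island <- in_island | (g_start < isl$end[j] & g_end > isl$start[j])
        }
      }
      # genes inside islands draw from an integrase/transposase-heavy pool
      pick <- ifelse(in_island,
                     sample(seq_len(nrow(cog_pool)), length(starts), replace = TRUE,
                            prob = cog_pool$island_weight),
                     sample(seq_len(nrow(cog_pool)), length(starts), replace = TRUE,
                            prob = cog_pool$background_weight))
      tibble::tibble(
        contig_id = ctg$contig_id,
        start = g_start, end = pmin(g_end, ctg$length),
        strand = sample(c("+", "-"), length(starts), replace = TRUE),
        protein_id = sprintf("%s_p%03d", ctg$contig_id, seq_along(starts)),
        cog_id = cog_pool$cog_id[pick],
        cog_ids = cog_pool$cog_id[pick],
        categories = cog_pool$category[pick],
        function_label = cog_pool$function_label[pick]
      )
    })

    ## --- per-sample counts (idxstats-like) ----------------------------
    counts <- if (!is.null(recruitment) && nrow(recruitment$alignments) > 0) {
      recruitment$alignments |>
        dplyr::filter(.data$is_primary) |>
        dplyr::count(.data$contig_id, .data$sample_id, name = "count") |>
        tidyr::complete(contig_id = genomes$contig_id,
                        sample_id = sprintf("S%d", seq_len(config$n_samples)),
                        fill = list(count = 0L)) |>
        dplyr::left_join(dplyr::select(genomes, "contig_id", "length"),
                         by = "contig_id") |>
        dplyr::select("contig_id", "length", "sample_id", "count")
    } else {
      tidyr::expand_grid(contig_id = genomes$contig_id,
                         sample_id = sprintf("S%d", seq_len(config$n_samples))) |>
        dplyr::left_join(dplyr::select(genomes, "contig_id", "length"),
                         by = "contig_id") |>
        dplyr::mutate(count = stats::rpois(dplyr::n(), .data$length / 50)) |>
        dplyr::select("contig_id", "length", "sample_id", "count")
    }

    list(
      tables = list(
        classifier_calls = classifier_calls,
        host_predictions = host_predictions,
        amg_calls = dplyr::select(amg_calls, -"is_decoy"),
        candidate_scores = candidate_scores,
        votu_qc = votu_qc,
        mag_quality = mag_quality,
        lifestyle_scores = lifestyle_scores,
        cds = cds,
        mag_lineages = mag_lineages,
        counts = counts
      ),
      truth = list(
        lineages = true_lineage,
        hosts = host_truth,
        amgs = amg_truth,
        temperate = tibble::tibble(votu_id = votus, temperate = true_temperate)
      )
    )
  })
}

# Small in-package pool of real COG identifiers with their standard category
# letters and functional labels; island_weight biases island genes toward
# integration/recombination/transposition functions.
sim_cog_pool <- function() {
  tibble::tribble(
    ~cog_id,   ~category, ~function_label,                                  ~island_weight, ~background_weight,
    "COG0582", "L", "Integrase",                                            8, 1,
    "COG4974", "L", "Site-specific tyrosine recombinase XerD",              6, 1,
    "COG1961", "L", "Site-specific recombinase, DNA invertase Pin",         6, 1,
    "COG2801", "L", "Transposase and inactivated derivatives",              6, 1,
    "COG3385", "L", "IS4 family transposase",                               5, 1,
    "COG3335", "L", "DDE superfamily endonuclease",                         4, 1,
    "COG0270", "L", "DNA (cytosine-5-)-methyltransferase",                  3, 1,
    "COG0553", "L", "Superfamily II DNA or RNA helicase",                   2, 1,
    "COG0438", "M", "Glycosyltransferase",                                  3, 2,
    "COG1215", "M", "Glycosyltransferase, catalytic subunit",               2, 2,
    "COG3209", "M", "Rhs family protein",                                   2, 1,
    "COG1629", "P", "Outer membrane receptor (TonB-dependent)",             2, 2,
    "COG4771", "P", "Outer membrane receptor for ferrienterochelin",        1, 2,
    "COG0642", "T", "Signal transduction histidine kinase",                 1, 3,
    "COG2205", "T", "Osmosensitive K+ channel histidine kinase",            1, 2,
    "COG0477", "EGP", "Major facilitator superfamily permease",             1, 4,
    "COG1028", "IQ", "NAD(P)-dependent dehydrogenase",                      1, 4,
    "COG0451", "GM", "Nucleoside-diphosphate-sugar epimerase",              1, 3,
    "COG0286", "V", "Type I restriction-modification methylase",            2, 1,
    "COG1192", "D", "ATPase involved in chromosome partitioning",           1, 2,
    "COG0457", "S", "Tetratricopeptide repeat protein",                     2, 6,
    "COG1132", "V", "ABC-type multidrug transport system",                  1, 2,
    "COG0745", "K", "DNA-binding response regulator",                       1, 3,
    "COG1595", "K", "RNA polymerase sigma factor",                          1, 2,
    "COG0463", "M", "Glycosyltransferase involved in cell wall biogenesis", 1, 2
  )
}
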