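# End-to-end orchestration over the package stages, with a reproducible
# manifest (per-stage record counts, parameters, md5 checksums of outputs).

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param params An [island_params()] object.
#' @param outdir Output directory (created if missing).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "coverage", "islands", "annotation", "qc", "taxonomy",
#'   "hosts", "amgs", "abundance")`.
#' @param max_mismatches Mismatch filter threshold for coverage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            params = island_params(),
                            outdir = tempfile("crustvir_run_"),
                            stages = c("simulate", "coverage", "islands",
                                       "annotation", "qc", "taxonomy", "hosts",
                                       "amgs", "abundance"),
                            max_mismatches = 1) {
  known <- c("simulate", "coverage", "islands", "annotation", "qc", "taxonomy",
             "hosts", "amgs", "abundance")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort_crustvir(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")),
                   "config_error")
  }
  structure(list(sim = sim, params = params, outdir = outdir,
                 stages = stages, max_mismatches = max_mismatches),
            class = "pipeline_config")
}

require_stage <- function(done, needed, stage) {
  missing <- setdiff(needed, done)
  if (length(missing) > 0) {
    abort_crustvir(
      sprintf("Stage '%s' requires upstream stage(s): %s.",
              stage, paste(missing, collapse = ", ")),
      "dependency_error"
    )
  }
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate -> coverage ->
#' islands -> annotation; simulate -> qc / taxonomy / hosts / amgs;
#' simulate -> abundance), writes each stage's tables under `config$outdir`,
#' and returns a manifest recording record counts and md5 checksums of every
#' output file. Reruns with an identical configuration produce identical
#' outputs and checksums.
#'
#' @param config A [pipeline_config()].
#' @return A list with `manifest` (tibble: stage, n_in, n_out, outputs, md5)
#'   and `results` (the in-memory stage outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  done <- character()
  manifest <- list()
  results <- list()

  emit <- function(stage, n_in, n_out, files) {
    sums <- tools::md5sum(files)
    manifest[[stage]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out,
      outputs = paste(basename(files), collapse = ";"),
      md5 = paste(unname(sums), collapse = ";")
    )
    done <<- c(done, stage)
  }
  out_path <- function(name) file.path(config$outdir, name)
  write_out <- function(df, name) {
    p <- out_path(name)
    readr::write_tsv(df, p)
    p
  }

  if ("simulate" %in% stages) {
    rec <- simulate_recruitment(config$sim)
    tabs <- simulate_tables(config$sim, recruitment = rec)
    results$recruitment <- rec
    results$tables <- tabs$tables
    results$truth <- c(list(islands = rec$truth), tabs$truth)
    files <- c(
      write_out(rec$genomes, "genomes.tsv"),
      write_out(rec$alignments, "alignments.tsv"),
      write_out(rec$truth, "truth_islands.tsv")
    )
    emit("simulate", 0L, nrow(rec$alignments), files)
  }

  if ("coverage" %in% stages) {
    require_stage(done, "simulate", "coverage")
    rec <- results$recruitment
    kept <- filter_alignments(rec$alignments, config$max_mismatches)
    cov <- compute_coverage(kept, rec$genomes)
    means <- genome_mean_coverage(cov, rec$genomes)
    results$coverage <- cov
    results$genome_means <- means
    files <- c(write_bedgraph(cov, out_path("coverage.bedgraph")),
               write_out(means, "genome_means.tsv"))
    emit("coverage", nrow(rec$alignments), nrow(cov), files)
  }

  if ("islands" %in% stages) {
    require_stage(done, "coverage", "islands")
    isl <- detect_islands(results$coverage, results$recruitment$genomes,
                          config$params)
    summ <- island_summary(isl, results$recruitment$genomes)
    results$islands <- isl
    results$island_summary <- summ
    files <- c(write_islands_bed(isl, out_path("islands.bed")),
               write_out(summ, "island_summary.tsv"))
    emit("islands", nrow(results$coverage), nrow(isl), files)
  }

  if ("annotation" %in% stages) {
    require_stage(done, c("islands", "simulate"), "annotation")
    pairs <- overlap_islands_with_cds(results$islands, results$tables$cds)
    profile <- if (nrow(pairs) > 0) summarize_categories(pairs)
               else summarize_categories(tibble::tibble(protein_id = character(),
                                                        categories = character()))
    cogs <- if (nrow(pairs) > 0) top_cogs(pairs) else
      top_cogs(tibble::tibble(protein_id = character(), cog_id = character()))
    results$island_cds_pairs <- pairs
    results$category_profile <- profile
    results$top_cogs <- cogs
    files <- c(write_out(profile, "island_category_profile.tsv"),
               write_out(cogs, "island_top_cogs.tsv"))
    emit("annotation", nrow(results$islands), nrow(pairs), files)
  }

  if ("qc" %in% stages) {
    require_stage(done, "simulate", "qc")
    tb <- results$tables
    results$candidates <- screen_candidates(tb$candidate_scores)
    results$votus <- retain_votus(tb$votu_qc)
    results$mag_tiers <- tier_mags(tb$mag_quality)
    results$lifestyle <- call_lifestyle(tb$lifestyle_scores)
    files <- c(write_out(results$candidates, "candidates.tsv"),
               write_out(results$votus, "votu_retention.tsv"),
               write_out(results$mag_tiers, "mag_tiers.tsv"),
               write_out(results$lifestyle, "lifestyle.tsv"))
    emit("qc", nrow(tb$candidate_scores),
         sum(results$candidates$pass) + sum(results$votus$retained), files)
  }

  if ("taxonomy" %in% stages) {
    require_stage(done, "simulate", "taxonomy")
    calls <- filter_calls(results$tables$classifier_calls)
    cons <- consensus_taxonomy(calls)
    rates <- classification_rates(cons)
    results$consensus <- cons
    results$classification_rates <- rates
    files <- c(write_out(cons, "consensus_taxonomy.tsv"),
               write_out(rates, "classification_rates.tsv"))
    emit("taxonomy", nrow(results$tables$classifier_calls), nrow(cons), files)
  }

  if ("hosts" %in% stages) {
    require_stage(done, "simulate", "hosts")
    assoc <- results$tables$host_predictions
    spectrum <- association_spectrum(assoc)
    typed <- classify_association(assoc)
    results$association_types <- typed
    results$association_spectrum <- spectrum
    files <- c(write_out(typed, "association_types.tsv"),
               write_out(spectrum, "association_spectrum.tsv"))
    emit("hosts", nrow(assoc), nrow(typed), files)
  }

  if ("amgs" %in% stages) {
    require_stage(done, "simulate", "amgs")
    curated <- curate_amgs(results$tables$amg_calls)
    results$amgs <- curated
    files <- write_out(curated, "amgs_curated.tsv")
    emit("amgs", nrow(results$tables$amg_calls), nrow(curated), files)
  }

  if ("abundance" %in% stages) {
    require_stage(done, "simulate", "abundance")
    ab <- tpm(results$tables$counts) |> log_tpm()
    results$tpm <- ab
    files <- write_out(ab, "tpm.tsv")
    emit("abundance", nrow(results$tables$counts), nrow(ab), files)
  }

  manifest <- dplyr::bind_rows(manifest)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  list(manifest = manifest, results = results)
}
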