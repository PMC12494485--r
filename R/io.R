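# Readers/writers for the plain-text dialects the pipeline speaks:
# alignment/genome TSVs, bedGraph, BED6 islands, GFF3 + emapper-style
# annotation tables.

#' Read an alignment table
#'
#' TSV with columns `query_id`, `contig_id`, `start`, `end` (0-based,
#' half-open), `mismatches` and optionally `is_primary` -- the tabular
#' equivalent of SAM records carrying an NM tag.
#'
#' @param path File path.
#' @return A tibble of alignment records.
#' @export
read_alignments <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_alignments(out)
  out
}

#' Read a genome membership table
#'
#' TSV with columns `genome_id`, `contig_id`, `length`; one row per contig.
#' MAGs have several rows, vOTUs exactly one.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_genomes <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_genomes(out)
  out
}

#' Write coverage as bedGraph
#'
#' @param coverage Coverage tibble from [compute_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  check_columns(coverage, c("contig_id", "start", "end", "depth"), "coverage")
  readr::write_tsv(
    dplyr::select(coverage, "contig_id", "start", "end", "depth"),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Write islands as BED6
#'
#' Name encodes `genome_id:regime`; score is the island mean coverage as a
#' rounded percentage of the genome mean.
#'
#' @param islands Island tibble from [detect_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  check_columns(islands, c("genome_id", "contig_id", "start", "end", "regime",
                           "genome_mean", "island_mean"), "islands")
  bed <- tibble::tibble(
    chrom = islands$contig_id,
    start = islands$start,
    end = islands$end,
    name = paste0(islands$genome_id, ":", islands$regime),
    score = ifelse(islands$genome_mean > 0,
                   round(100 * islands$island_mean / islands$genome_mean), 0),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read CDS features from GFF3 (with optional emapper-style annotations)
#'
#' Imports CDS features, converts to the package's 0-based half-open
#' coordinates, and (optionally) joins eggNOG annotations by `protein_id`
#' from an emapper-style TSV with columns `protein_id`, `cog_ids`,
#' `categories`.
#'
#' @param gff_path Path to a GFF3 file; features of type `CDS` are kept and
#'   `protein_id` is taken from the `ID` attribute.
#' @param emapper_path Optional annotation TSV path.
#' @return A tibble of CDS features.
#' @export
read_cds_gff3 <- function(gff_path, emapper_path = NULL) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  out <- tibble::tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = as.character(gr$ID)
  )
  if (!is.null(emapper_path)) {
    ann <- readr::read_tsv(emapper_path, show_col_types = FALSE)
    check_columns(ann, c("protein_id", "categories"), "emapper table")
    out <- dplyr::left_join(out, ann, by = "protein_id")
  }
  out
}

#' Write CDS features as GFF3
#'
#' @param cds CDS tibble (`contig_id`, `start`, `end`, `strand`,
#'   `protein_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_gff3 <- function(cds, path) {
  check_columns(cds, c("contig_id", "start", "end", "strand", "protein_id"), "cds")
  gr <- GenomicRanges::GRanges(
    cds$contig_id,
    IRanges::IRanges(cds$start + 1L, cds$end),
    strand = cds$strand
  )
  gr$type <- "CDS"
  gr$ID <- cds$protein_id
  gr$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
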