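# Internal validation helpers. Errors carry classed conditions so callers
# (and tests) can distinguish bad records from bad coordinates etc.

abort_crustvir <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("crustvir_", class), "crustvir_error"), ...)
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort_crustvir(sprintf("`%s` must be a data frame.", what), "invalid_input")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_crustvir(
      sprintf("`%s` is missing required column(s): %s.",
              what, paste(missing, collapse = ", ")),
      "invalid_input"
    )
  }
  invisible(df)
}

check_genomes <- function(genomes) {
  check_columns(genomes, c("genome_id", "contig_id", "length"), "genomes")
  if (any(genomes$length <= 0)) {
    abort_crustvir("Contig lengths must be positive.", "invalid_record")
  }
  if (anyDuplicated(genomes$contig_id) > 0) {
    abort_crustvir("Contig ids must be unique across the genome set.", "invalid_record")
  }
  invisible(genomes)
}

check_alignments <- function(alignments) {
  check_columns(alignments, c("query_id", "contig_id", "start", "end", "mismatches"),
                "alignments")
  if (any(alignments$mismatches < 0)) {
    abort_crustvir("Mismatch counts must be non-negative.", "invalid_record")
  }
  if (any(alignments$start < 0) || any(alignments$start >= alignments$end)) {
    abort_crustvir("Alignment intervals must satisfy 0 <= start < end.", "coordinate_error")
  }
  invisible(alignments)
}

# Standard one-letter eggNOG/COG functional category alphabet.
cog_alphabet <- function() LETTERS
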