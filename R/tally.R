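#' Condense reads into a unique-sequence tally table
#'
#' The "extract and count" step: millions of reads collapse to one row per
#' unique sequence with its occurrence count. Rows are ordered by descending
#' count, ties broken lexicographically by sequence, so serialized tallies
#' are reproducible.
#'
#' @param reads data frame with a `sequence` column (QC-filtered reads), or a
#'   character vector of sequences.
#' @param sample_id sample identifier stored on the table.
#' @return data frame of class `TallyTable` with columns `sequence`, `count`.
#' @export
build_tally <- function(reads, sample_id) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  if (length(seqs) == 0) {
    tab <- data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    counts <- table(seqs)
    tab <- data.frame(sequence = names(counts),
                      count = as.integer(counts),
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$count, tab$sequence), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, sample_id = sample_id,
            class = c("TallyTable", "data.frame"))
}

#' Write a tally table as sequence/count TSV
#'
#' @param tally `TallyTable`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_tally <- function(tally, path) {
  write_tsv(data.frame(sequence = tally$sequence, count = tally$count), path)
}

#' Read a tally table written by [write_tally()]
#'
#' @param path TSV file.
#' @param sample_id sample identifier (defaults to the file name stem).
#' @return `TallyTable`.
#' @export
read_tally <- function(path, sample_id = sub("\\..*$", "", basename(path))) {
  df <- read_tsv(path, colClasses = c("character", "integer"))
  structure(df, sample_id = sample_id,
            class = c("TallyTable", "data.frame"))
}
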