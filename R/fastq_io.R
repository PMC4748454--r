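#' Read a FASTQ file into a read table
#'
#' Reads plain or gzipped FASTQ (Phred+33) into a data frame with one row per
#' read. The quality string is kept in its ASCII encoding; use
#' [phred_to_int()] to decode.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  reads <- data.frame(id = names(x),
                      sequence = as.character(x),
                      quality = as.character(S4Vectors::mcols(x)$qualities),
                      stringsAsFactors = FALSE, row.names = NULL)
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad)) {
    stop(sprintf("malformed FASTQ record '%s' in %s: %d bases, %d quality values",
                 reads$id[which(bad)[1]], path,
                 nchar(reads$sequence[which(bad)[1]]),
                 nchar(reads$quality[which(bad)[1]])))
  }
  reads
}

#' Write a read table as FASTQ
#'
#' @param reads data frame with `id`, `sequence`, `quality` (Phred+33 strings).
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence/quality length mismatch in reads to be written")
  }
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a mature miRNA reference from FASTA
#'
#' Entry names must be unique; sequences are uppercased and validated against
#' the DNA alphabet and the 15-35 nt mature-miRNA length window.
#'
#' @param path FASTA file.
#' @param version optional version label attached to the reference.
#' @return named character vector of class `MatureReference`.
#' @export
read_reference <- function(path, version = basename(path)) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ref <- toupper(as.character(x))
  names(ref) <- sub("\\s.*$", "", names(x))
  as_mature_reference(ref, version = version)
}

#' Build a mature miRNA reference object
#'
#' @param sequences named character vector of mature sequences (DNA alphabet).
#' @param version version label.
#' @return named character vector of class `MatureReference`.
#' @export
as_mature_reference <- function(sequences, version = "custom") {
  if (length(sequences) == 0) stop("reference is empty")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("reference entry names must be present and unique")
  }
  sequences <- toupper(sequences)
  assert_dna(sequences, "reference sequence")
  len <- nchar(sequences)
  if (any(len < 15 | len > 35)) {
    stop("reference sequences must be 15-35 nt (mature miRNA length window)")
  }
  structure(sequences, version = version, class = "MatureReference")
}

#' Write a reference to FASTA
#'
#' @param reference `MatureReference` (or named character vector).
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  dna <- Biostrings::DNAStringSet(unclass(reference))
  names(dna) <- names(reference)
  Biostrings::writeXStringSet(dna, path, format = "fasta")
  invisible(path)
}

#' @export
print.MatureReference <- function(x, ...) {
  cat(sprintf("MatureReference [%s]: %d entries, lengths %d-%d nt\n",
              attr(x, "version") %||% "?", length(x),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quality character vector of quality strings.
#' @return list of integer vectors (one per string), or a single integer
#'   vector when `length(quality) == 1`.
#' @export
phred_to_int <- function(quality) {
  out <- lapply(quality, function(q) utf8ToInt(q) - 33L)
  if (length(out) == 1L) out[[1]] else out
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores integer vector of per-base scores.
#' @return single quality string.
#' @export
int_to_phred <- function(scores) {
  intToUtf8(as.integer(scores) + 33L)
}
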