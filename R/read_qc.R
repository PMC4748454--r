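#' Median Phred quality of a read
#'
#' For even-length reads the lower-middle order statistic is returned, keeping
#' the >= Q30 retention test integer-exact.
#'
#' @param qualities integer Phred scores, or a single Phred+33 quality string.
#' @return integer median quality.
#' @export
median_quality <- function(qualities) {
  if (is.character(qualities)) {
    if (length(qualities) != 1L) {
      stop("pass one quality string (or an integer score vector)")
    }
    qualities <- utf8ToInt(qualities) - 33L
  }
  n <- length(qualities)
  if (n == 0L) stop("empty quality vector")
  sort(as.integer(qualities))[(n + 1L) %/% 2L]
}

#' Trim the 3' sequencing adapter from reads
#'
#' The sequence is truncated at the leftmost position where the remainder of
#' the read matches the adapter exactly: either the full adapter (internal
#' occurrence) or, at the 3' end, an adapter prefix of at least `min_overlap`
#' bases. Qualities are truncated in lockstep. Reads without a match are
#' returned untouched. Matching is exact (synthetic adapters are planted
#' error-free; error-tolerant trimming is out of scope).
#'
#' @param reads data frame with `sequence` and optionally `quality` columns
#'   (a bare character vector of sequences is also accepted).
#' @param adapter adapter sequence, DNA alphabet.
#' @param min_overlap minimum adapter prefix length at the read 3' end.
#' @return `reads` with trimmed `sequence`/`quality` and a logical
#'   `adapter_trimmed` column.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  assert_dna(adapter, "adapter")
  if (is.character(reads)) reads <- data.frame(sequence = reads,
                                               stringsAsFactors = FALSE)
  pos <- cpp_adapter_pos(reads$sequence, adapter, as.integer(min_overlap))
  hit <- pos > 0L
  keep_len <- ifelse(hit, pos - 1L, nchar(reads$sequence))
  reads$sequence <- substr(reads$sequence, 1L, keep_len)
  if (!is.null(reads$quality)) {
    reads$quality <- substr(reads$quality, 1L, keep_len)
  }
  reads$adapter_trimmed <- hit
  reads
}

#' Quality-screen, adapter-trim and length-filter small-RNA reads
#'
#' The screening order is: (1) whole-read retention by median Phred quality
#' (reads with median < `min_median_q` are dropped), (2) exact 3' adapter
#' trimming, repeated until no adapter signal remains so that the filter is
#' idempotent, (3) post-trim length filter keeping reads of
#' `min_len`-`max_len` nt inclusive — lengths are only meaningful after
#' trimming. The returned report partitions the input exactly:
#' `reads_in = reads_out + failed_median_q + length_filtered`.
#'
#' @param reads data frame with `id`, `sequence`, `quality` (see
#'   [read_fastq()]).
#' @param adapter 3' adapter sequence; `NULL` skips trimming.
#' @param min_median_q median Phred threshold (reads kept at >= this value).
#' @param min_len,max_len inclusive post-trim length window in nt.
#' @param min_overlap minimum adapter overlap at the read 3' end.
#' @return list with `reads` (surviving reads, input order preserved) and
#'   `report` (a `QCReport`: counts per rejection reason plus the post-trim
#'   length histogram of surviving reads).
#' @export
qc_filter <- function(reads, adapter, min_median_q = 30L, min_len = 15L,
                      max_len = 35L, min_overlap = 5L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  stopifnot(all(c("sequence", "quality") %in% names(reads)))
  bad_rec <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_rec)) {
    stop(sprintf("malformed read record '%s': sequence and quality lengths differ",
                 (reads$id %||% as.character(which(bad_rec)))[which(bad_rec)[1]]))
  }
  n_in <- nrow(reads)
  med <- if (n_in) cpp_median_phred(reads$quality) else integer(0)
  pass_q <- med >= min_median_q
  kept <- reads[pass_q, , drop = FALSE]
  n_trimmed <- 0L
  if (!is.null(adapter) && nrow(kept)) {
    # trim to a fixpoint: a trimmed read whose new 3' end happens to match an
    # adapter prefix is trimmed again, so re-filtering the output is a no-op
    hit_any <- rep(FALSE, nrow(kept))
    repeat {
      trimmed <- trim_adapter(kept, adapter, min_overlap)
      hit <- trimmed$adapter_trimmed
      trimmed$adapter_trimmed <- NULL
      kept <- trimmed
      hit_any <- hit_any | hit
      if (!any(hit)) break
    }
    n_trimmed <- sum(hit_any)
  }
  len <- nchar(kept$sequence)
  in_window <- len >= min_len & len <= max_len
  out <- kept[in_window, , drop = FALSE]
  rownames(out) <- NULL
  hist_tab <- table(factor(nchar(out$sequence), levels = min_len:max_len))
  report <- structure(list(
    reads_in = n_in,
    failed_median_q = sum(!pass_q),
    adapter_trimmed = n_trimmed,
    length_filtered = sum(!in_window),
    reads_out = nrow(out),
    length_histogram = setNames(as.integer(hist_tab), names(hist_tab)),
    settings = list(min_median_q = min_median_q, min_len = min_len,
                    max_len = max_len, adapter = adapter,
                    min_overlap = min_overlap)), class = "QCReport")
  list(reads = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(paste0("QCReport: %d reads in; %d failed median Q%d; ",
                     "%d adapter-trimmed; %d outside [%d,%d] nt; %d out\n"),
              x$reads_in, x$failed_median_q, x$settings$min_median_q,
              x$adapter_trimmed, x$length_filtered,
              x$settings$min_len, x$settings$max_len, x$reads_out))
  invisible(x)
}

#' Write a QC report as a two-column TSV
#'
#' Scalar counts first, then the surviving-read length histogram as
#' `length_<n>` rows.
#'
#' @param report `QCReport`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("reads_in", "failed_median_q", "adapter_trimmed",
               "length_filtered", "reads_out",
               paste0("length_", names(report$length_histogram))),
    value = c(report$reads_in, report$failed_median_q, report$adapter_trimmed,
              report$length_filtered, report$reads_out,
              unname(report$length_histogram)))
  write_tsv(df, path)
}
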