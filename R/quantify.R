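#' Normalize counts to relative expression
#'
#' Each cell becomes the percent of its sample's mapped miRNA reads:
#' `100 * count / mapped_total`. Columns of an unfiltered matrix therefore
#' sum to 100. When normalising a detection-filtered `CountMatrix` the
#' original mapping totals are used unless `renormalize = TRUE`, so abundant
#' miRNA fractions stay interpretable as fractions of the whole miRNA load.
#'
#' @param cm `CountMatrix`.
#' @param renormalize divide by the column sums of the (possibly filtered)
#'   count table instead of the original per-sample mapping totals.
#' @return miRNA x sample numeric matrix of class `ExpressionMatrix` (percent
#'   scale).
#' @export
normalize_expression <- function(cm, renormalize = FALSE) {
  stopifnot(inherits(cm, "CountMatrix"))
  totals <- if (renormalize) colSums(cm$counts) else cm$mapped_total
  zero <- totals <= 0
  if (any(zero)) {
    stop(sprintf("sample(s) with no mapped miRNA reads: %s",
                 paste(names(totals)[zero], collapse = ", ")))
  }
  expr <- sweep(cm$counts, 2, totals, "/") * 100
  structure(expr, class = c("ExpressionMatrix", class(expr)),
            settings = cm$settings, renormalized = renormalize)
}

#' Exclude weakly evidenced miRNAs
#'
#' A miRNA is retained iff its cohort-wide read total is at least `min_reads`
#' AND it is present (count > 0) in at least `min_subjects` samples. The
#' cohort-wide reading of the read threshold (rather than per-sample) is the
#' one compatible with single-individual miRNAs at low counts;
#' `per_sample_reads = TRUE` switches to requiring `min_reads` within at
#' least one sample.
#'
#' @param cm `CountMatrix`.
#' @param min_reads minimum supporting read count (cohort-wide by default).
#' @param min_subjects minimum number of samples with a nonzero count.
#' @param per_sample_reads apply `min_reads` within single samples instead of
#'   cohort-wide.
#' @return list with `counts` (filtered `CountMatrix`; mapping totals are
#'   kept) and `removed` (audit data frame: miRNA, total reads, subjects,
#'   reason).
#' @export
detection_filter <- function(cm, min_reads = 10L, min_subjects = 3L,
                             per_sample_reads = FALSE) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (min_reads < 1L || min_subjects < 1L) stop("thresholds must be >= 1")
  m <- cm$counts
  total_reads <- rowSums(m)
  reads_ok <- if (per_sample_reads) {
    apply(m, 1, max) >= min_reads
  } else {
    total_reads >= min_reads
  }
  n_subj <- rowSums(m > 0)
  subj_ok <- n_subj >= min_subjects
  keep <- reads_ok & subj_ok
  reason <- character(sum(!keep))
  drop_ix <- which(!keep)
  reason <- ifelse(!reads_ok[drop_ix] & !subj_ok[drop_ix], "reads;subjects",
                   ifelse(!reads_ok[drop_ix], "reads", "subjects"))
  removed <- data.frame(mirna = rownames(m)[drop_ix],
                        total_reads = total_reads[drop_ix],
                        n_subjects = n_subj[drop_ix],
                        reason = reason,
                        stringsAsFactors = FALSE, row.names = NULL)
  out <- cm
  out$counts <- m[keep, , drop = FALSE]
  out$settings$detection_filter <- list(min_reads = min_reads,
                                        min_subjects = min_subjects,
                                        per_sample_reads = per_sample_reads)
  list(counts = out, removed = removed)
}

#' Per-miRNA penetrance
#'
#' Penetrance is the number of cohort samples in which a miRNA is detected
#' (count, or expression, > 0). Also returns the ubiquitous set: miRNAs
#' present in every sample.
#'
#' @param x `CountMatrix`, `ExpressionMatrix` or plain miRNA x sample matrix.
#' @return list with `penetrance` (named integer vector), `n_samples` and
#'   `ubiquitous` (character vector of miRNAs present in all samples).
#' @export
penetrance <- function(x) {
  m <- if (inherits(x, "CountMatrix")) x$counts else unclass(x)
  pen <- rowSums(m > 0)
  list(penetrance = setNames(as.integer(pen), rownames(m)),
       n_samples = ncol(m),
       ubiquitous = rownames(m)[pen == ncol(m)])
}

#' Write an expression matrix as TSV
#'
#' @param expr `ExpressionMatrix`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(mirna = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param path TSV file.
#' @return `ExpressionMatrix`.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("ExpressionMatrix", class(m)))
}
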