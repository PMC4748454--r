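# Shared in-code fixtures.

# Minimal CountMatrix wrapper around a plain counts matrix.
as_count_matrix <- function(m, mapped_total = colSums(m)) {
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("mir", seq_len(nrow(m)))
  structure(list(counts = m, mapped_total = mapped_total,
                 unmapped = setNames(numeric(ncol(m)), colnames(m)),
                 ambiguous_reads = setNames(numeric(ncol(m)), colnames(m)),
                 total_reads = colSums(m),
                 settings = list(max_mismatch = 1L, mode = "containment",
                                 ambiguous = "discard")),
            class = "CountMatrix")
}

# Expression matrix straight from numbers (percent scale assumed).
as_expr <- function(m) {
  if (ncol(m) > 0 && is.null(colnames(m))) {
    colnames(m) <- paste0("S", seq_len(ncol(m)))
  }
  if (nrow(m) > 0 && is.null(rownames(m))) {
    rownames(m) <- paste0("mir", seq_len(nrow(m)))
  }
  structure(m, class = c("ExpressionMatrix", "matrix", "array"))
}

# Small simulated cohort on disk; returns the simulate_cohort() result.
mini_cohort <- function(dir, n_subjects = 6, reads = 4000, n_mirnas = 20,
                        seed = 11, ...) {
  cfg <- cohort_config(n_subjects = n_subjects, reads_per_subject = reads,
                       n_mirnas = n_mirnas, rng_seed = seed, ...)
  simulate_cohort(cfg, dir, overwrite = TRUE)
}
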