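#' Assign sequences to mature miRNAs allowing at most one mismatch
#'
#' Ungapped assignment of each query to the reference entry (or entries) it
#' matches with the fewest substitutions, up to `max_mismatch`. In the default
#' `"containment"` mode a query hits an entry when the shorter of the two
#' matches inside the longer at some offset with Hamming distance
#' `<= max_mismatch` over the full overlap (the overlap is the shorter
#' length), which tolerates the 3' length jitter of real small-RNA reads;
#' `"end_to_end"` restricts hits to equal-length alignment. `N` bases count as
#' mismatches. A query is *ambiguous* when two or more entries tie at the
#' minimal mismatch count.
#'
#' @param sequences character vector of query sequences (15-35 nt).
#' @param reference `MatureReference` (or named character vector).
#' @param max_mismatch maximum substitutions allowed (0 or 1 in practice).
#' @param mode `"containment"` or `"end_to_end"`.
#' @return data frame with one row per query: `sequence`, `mirna` (`NA` when
#'   unmapped), `mismatches`, `ambiguous`, and `candidates` (all tied entry
#'   names, `;`-separated).
#' @export
map_sequences <- function(sequences, reference, max_mismatch = 1L,
                          mode = c("containment", "end_to_end")) {
  mode <- match.arg(mode)
  if (length(reference) == 0) stop("reference is empty")
  if (length(sequences) == 0) {
    return(data.frame(sequence = character(0), mirna = character(0),
                      mismatches = integer(0), ambiguous = logical(0),
                      candidates = character(0), stringsAsFactors = FALSE))
  }
  seqs <- toupper(sequences)
  len <- nchar(seqs)
  if (any(len < 15L | len > 35L)) {
    stop("query sequences must be 15-35 nt (apply the QC length filter first)")
  }
  hit <- cpp_assign(seqs, toupper(unclass(reference)),
                    as.integer(max_mismatch), mode == "containment")
  nm <- names(reference)
  cand <- vapply(hit$candidates, function(ix) paste(sort(nm[ix]), collapse = ";"), "")
  data.frame(sequence = sequences,
             mirna = ifelse(is.na(hit$best_idx), NA_character_, nm[hit$best_idx]),
             mismatches = hit$mismatches,
             ambiguous = hit$n_best >= 2L,
             candidates = cand,
             stringsAsFactors = FALSE)
}

#' Assign a single sequence
#'
#' @inheritParams map_sequences
#' @param sequence one query sequence.
#' @return list with `mirna` (or `NA` when unmapped), `mismatches`,
#'   `ambiguous` and the `candidates` character vector.
#' @export
map_sequence <- function(sequence, reference, max_mismatch = 1L,
                         mode = c("containment", "end_to_end")) {
  stopifnot(length(sequence) == 1L)
  df <- map_sequences(sequence, reference, max_mismatch, mode)
  list(mirna = df$mirna, mismatches = df$mismatches,
       ambiguous = df$ambiguous,
       candidates = if (nzchar(df$candidates)) strsplit(df$candidates, ";")[[1]]
                    else character(0))
}

#' Build a miRNA x sample count matrix from tally tables
#'
#' Maps every unique tally sequence once (pooled across samples) and sums the
#' tally counts per assigned miRNA. Ambiguous sequences (two or more entries
#' at the minimal mismatch count) are handled by `ambiguous` policy:
#' `"discard"` sends their counts to the unmapped total (conservative,
#' integral counts), `"split"` divides each count equally among the tied
#' entries, `"first"` assigns the lexicographically first tied entry.
#'
#' @param tallies list of `TallyTable` objects with unique sample ids.
#' @param reference `MatureReference`.
#' @param max_mismatch maximum substitutions per assignment.
#' @param mode alignment mode, see [map_sequences()].
#' @param ambiguous ambiguity policy: `"discard"`, `"split"` or `"first"`.
#' @return object of class `CountMatrix`: a list with `counts` (miRNA x
#'   sample matrix over all reference entries), `mapped_total`, `unmapped`,
#'   `ambiguous_reads` per sample, and the mapping settings.
#' @export
count_matrix <- function(tallies, reference, max_mismatch = 1L,
                         mode = c("containment", "end_to_end"),
                         ambiguous = c("discard", "split", "first")) {
  mode <- match.arg(mode)
  ambiguous <- match.arg(ambiguous)
  if (inherits(tallies, "TallyTable")) tallies <- list(tallies)
  sample_ids <- vapply(tallies, function(t) attr(t, "sample_id") %||% NA_character_, "")
  if (anyNA(sample_ids)) stop("every tally table needs a sample_id attribute")
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicate sample id: %s",
                 sample_ids[duplicated(sample_ids)][1]))
  }
  uniq <- unique(unlist(lapply(tallies, `[[`, "sequence"), use.names = FALSE))
  asn <- map_sequences(uniq, reference, max_mismatch, mode)
  nm <- names(reference)
  n_mir <- length(nm)
  counts <- matrix(0, nrow = n_mir, ncol = length(tallies),
                   dimnames = list(nm, sample_ids))
  unmapped <- ambig_reads <- total <- setNames(numeric(length(tallies)), sample_ids)
  # per-sequence weight rows: target index (0 = unmapped) and weight
  for (s in seq_along(tallies)) {
    tl <- tallies[[s]]
    ix <- match(tl$sequence, asn$sequence)
    a <- asn[ix, ]
    cnt <- tl$count
    total[s] <- sum(cnt)
    mapped_sel <- !is.na(a$mirna)
    amb_sel <- a$ambiguous & mapped_sel
    ambig_reads[s] <- sum(cnt[amb_sel])
    if (ambiguous == "discard") {
      use <- mapped_sel & !a$ambiguous
      add <- tapply(cnt[use], a$mirna[use], sum)
      counts[names(add), s] <- counts[names(add), s] + as.numeric(add)
    } else if (ambiguous == "first") {
      first_nm <- vapply(strsplit(a$candidates, ";"), function(v)
        if (length(v)) v[1] else NA_character_, "")
      use <- mapped_sel
      add <- tapply(cnt[use], first_nm[use], sum)
      counts[names(add), s] <- counts[names(add), s] + as.numeric(add)
    } else { # split
      use <- which(mapped_sel)
      cands <- strsplit(a$candidates[use], ";")
      w <- cnt[use] / lengths(cands)
      add <- tapply(rep(w, lengths(cands)), unlist(cands), sum)
      counts[names(add), s] <- counts[names(add), s] + as.numeric(add)
    }
    unmapped[s] <- total[s] - sum(counts[, s])
  }
  structure(list(counts = counts,
                 mapped_total = colSums(counts),
                 unmapped = unmapped,
                 ambiguous_reads = ambig_reads,
                 total_reads = total,
                 settings = list(max_mismatch = max_mismatch, mode = mode,
                                 ambiguous = ambiguous,
                                 reference_version = attr(reference, "version"))),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf(paste0("CountMatrix: %d miRNAs x %d samples; ",
                     "%.0f reads mapped, %.0f unmapped (policy: %s, ",
                     "max mismatch %d, %s mode)\n"),
              nrow(x$counts), ncol(x$counts), sum(x$mapped_total),
              sum(x$unmapped), x$settings$ambiguous,
              x$settings$max_mismatch, x$settings$mode))
  invisible(x)
}

#' Write a count matrix and its per-sample mapping summary
#'
#' @param cm `CountMatrix`.
#' @param counts_path TSV for the miRNA x sample count table.
#' @param summary_path optional TSV for per-sample totals (mapped, unmapped,
#'   ambiguous, total).
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, summary_path = NULL) {
  df <- data.frame(mirna = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  if (!is.null(summary_path)) {
    write_tsv(data.frame(sample = names(cm$mapped_total),
                         total_reads = cm$total_reads,
                         mapped = cm$mapped_total,
                         unmapped = cm$unmapped,
                         ambiguous = cm$ambiguous_reads), summary_path)
  }
  invisible(counts_path)
}
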