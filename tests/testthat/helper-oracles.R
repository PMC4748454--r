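# Independent reference implementations ("oracles") used to pin the
# contracts of the fast paths. These deliberately share no code with the
# package internals: plain R, exhaustive enumeration.

# Exhaustive all-entries, all-offsets Hamming assignment.
oracle_assign <- function(sequences, reference, max_mismatch = 1L,
                          mode = "containment") {
  refs <- toupper(unclass(reference))
  nm <- names(reference)
  ri <- lapply(refs, utf8ToInt)
  rl <- nchar(refs)
  rows <- lapply(toupper(sequences), function(q) {
    qi <- utf8ToInt(q)
    L <- length(qi)
    best <- Inf
    cands <- integer(0)
    for (j in seq_along(ri)) {
      M <- rl[j]
      if (mode == "end_to_end" && L != M) next
      if (L <= M) { inner <- qi; outer <- ri[[j]] }
      else { inner <- ri[[j]]; outer <- qi }
      ov <- min(L, M)
      eb <- Inf
      for (off in 0:abs(L - M)) {
        eb <- min(eb, sum(inner != outer[(off + 1):(off + ov)]))
      }
      if (eb > max_mismatch) next
      if (eb < best) { best <- eb; cands <- j }
      else if (eb == best) cands <- c(cands, j)
    }
    if (!length(cands)) {
      data.frame(mirna = NA_character_, mismatches = NA_integer_,
                 ambiguous = FALSE, candidates = "", stringsAsFactors = FALSE)
    } else {
      data.frame(mirna = nm[cands[1]], mismatches = as.integer(best),
                 ambiguous = length(cands) >= 2,
                 candidates = paste(sort(nm[cands]), collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$sequence <- sequences
  out
}

# Leftmost adapter-prefix trim position by direct enumeration.
oracle_trim_pos <- function(seq, adapter, min_overlap) {
  L <- nchar(seq)
  A <- nchar(adapter)
  for (p in seq_len(L)) {
    ov <- min(L - p + 1L, A)
    if (ov < min_overlap) break
    if (substr(seq, p, p + ov - 1L) == substr(adapter, 1L, ov)) return(p)
  }
  0L
}

# Double-loop detection filter.
oracle_detection_filter <- function(m, min_reads, min_subjects) {
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    total <- 0
    present <- 0L
    for (j in seq_len(ncol(m))) {
      total <- total + m[i, j]
      if (m[i, j] > 0) present <- present + 1L
    }
    keep[i] <- total >= min_reads && present >= min_subjects
  }
  rownames(m)[keep]
}

# Two-pass SEM: explicit mean, then explicit squared deviations.
oracle_sem <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / (length(x) - 1)) / sqrt(length(x))
}

# Quartile by explicit linear interpolation between order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Random reads derived from a reference: exact copies, 1-2 substitutions,
# 3' length jitter (trimmed or extended ends), and unrelated junk.
mutated_reads <- function(reference, n, seed, junk_frac = 0.1) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      if (runif(1) < junk_frac) {
        return(paste(sample(bases, sample(15:30, 1), TRUE), collapse = ""))
      }
      s <- strsplit(unname(sample(unclass(reference), 1)), "")[[1]]
      nmut <- sample(0:2, 1, prob = c(0.5, 0.35, 0.15))
      if (nmut > 0) {
        for (p in sample(length(s), nmut)) s[p] <- sample(setdiff(bases, s[p]), 1)
      }
      jitter <- sample(c("none", "trim", "extend"), 1,
                       prob = c(0.6, 0.25, 0.15))
      if (jitter == "trim" && length(s) > 16) {
        k <- sample(1:2, 1)
        s <- if (runif(1) < 0.5) s[-seq_len(k)] else s[seq_len(length(s) - k)]
      } else if (jitter == "extend" && length(s) < 33) {
        s <- c(s, sample(bases, sample(1:2, 1), TRUE))
      }
      paste(s, collapse = "")
    }, "")
  })
}
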