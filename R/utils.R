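#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded generator functions never perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive k reproducible child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Round half away from zero at `digits` decimals (printed-table convention).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: e.g. '%s'",
                 what, if (allow_n) ",N" else "", x[which(bad)[1]]))
  }
  invisible(TRUE)
}

# Deterministic TSV writer used for all pipeline artifacts.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
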