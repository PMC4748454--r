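#' Fraction of the miRNA load carried by the top-k species
#'
#' Ranks miRNAs by their cohort-mean expression and returns the share of
#' total mean expression contributed by the `k` most abundant. On an
#' unfiltered expression matrix this is the fraction of all mapped miRNA
#' reads attributable to the top-k species.
#'
#' @param expr `ExpressionMatrix` (or miRNA x sample matrix).
#' @param k number of top species (`k <= nrow(expr)`).
#' @return fraction in `[0, 1]`.
#' @export
load_fraction <- function(expr, k) {
  m <- unclass(expr)
  if (length(m) == 0 || nrow(m) == 0) stop("empty expression matrix")
  if (k < 1 || k > nrow(m)) stop("k must be in 1..nrow(expr)")
  means <- rowMeans(m)
  sum(sort(means, decreasing = TRUE)[seq_len(k)]) / sum(means)
}

#' Rank miRNAs by expression stability
#'
#' For each miRNA the cohort mean and standard error of the mean (SEM) of its
#' normalized expression are computed; stability is scored by default as the
#' relative SEM (`SEM / mean`), so that stably expressed miRNAs can span
#' several orders of expression magnitude (a raw-SEM score would simply pick
#' the lowest expressed; it remains available via `score = "sem"`). Lower
#' dispersion ranks higher; ties break by higher mean, then name. miRNAs with
#' zero mean have undefined dispersion and are ranked last and flagged. The
#' top decile (ceiling of 10 % of miRNAs) is flagged as the stable set.
#'
#' @param expr `ExpressionMatrix` with >= 2 samples.
#' @param score `"relative_sem"` (default) or `"sem"`.
#' @return data frame of class `StabilityReport`: `mirna`, `mean`, `sem`,
#'   `dispersion`, `rank`, `top_decile`, `undefined`.
#' @export
stability_rank <- function(expr, score = c("relative_sem", "sem")) {
  score <- match.arg(score)
  m <- unclass(expr)
  if (ncol(m) < 2) stop("need >= 2 samples to estimate SEM")
  mu <- rowMeans(m)
  sem <- apply(m, 1, sd) / sqrt(ncol(m))
  disp <- if (score == "relative_sem") ifelse(mu > 0, sem / mu, NA_real_) else sem
  undef <- is.na(disp)
  ord <- order(undef, disp, -mu, rownames(m))
  rk <- integer(nrow(m))
  rk[ord] <- seq_len(nrow(m))
  n_top <- ceiling(0.10 * nrow(m))
  out <- data.frame(mirna = rownames(m), mean = mu, sem = sem,
                    dispersion = disp, rank = rk,
                    top_decile = rk <= n_top & !undef,
                    undefined = undef,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, score = score, class = c("StabilityReport", "data.frame"))
}

#' Compare expression variability between two miRNA sets
#'
#' The haemolysis sentinel check: in the absence of haemolysis, blood-cell
#' associated miRNAs should vary between subjects no more than the rest.
#' Each set's coefficient of variation (CV, percent) is computed either as
#' the mean of per-miRNA CVs across subjects (default, a set-level summary of
#' between-subject variation) or from the pooled values of the whole set
#' (`method = "pooled"`).
#'
#' @param expr `ExpressionMatrix`.
#' @param set_a,set_b disjoint, non-empty character vectors of miRNA names
#'   present in `expr`.
#' @param method `"per_mirna"` or `"pooled"`.
#' @return named numeric `c(cv_a=, cv_b=)`, in percent.
#' @export
cv_compare <- function(expr, set_a, set_b, method = c("per_mirna", "pooled")) {
  method <- match.arg(method)
  m <- unclass(expr)
  if (length(set_a) == 0 || length(set_b) == 0) stop("both sets must be non-empty")
  if (length(intersect(set_a, set_b))) stop("sets must be disjoint")
  missing <- setdiff(c(set_a, set_b), rownames(m))
  if (length(missing)) {
    stop(sprintf("miRNA name(s) not in the expression matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  set_cv <- function(set) {
    sub <- m[set, , drop = FALSE]
    if (method == "per_mirna") {
      cvs <- apply(sub, 1, function(x) if (mean(x) > 0) 100 * sd(x) / mean(x) else NA_real_)
      mean(cvs, na.rm = TRUE)
    } else {
      v <- as.vector(sub)
      100 * sd(v) / mean(v)
    }
  }
  c(cv_a = set_cv(set_a), cv_b = set_cv(set_b))
}

#' Normal ranges of expression
#'
#' Five-number summary (min, lower quartile, median, upper quartile, max) of
#' each miRNA's normalized expression across subjects. Quartiles use linear
#' interpolation between order statistics (R quantile type 7); the convention
#' is recorded on the result.
#'
#' @param expr `ExpressionMatrix`.
#' @return data frame of class `RangeTable`: `mirna`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
range_table <- function(expr) {
  m <- unclass(expr)
  if (length(m) == 0 || nrow(m) == 0) stop("empty expression matrix")
  qs <- t(apply(m, 1, quantile, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                names = FALSE))
  out <- data.frame(mirna = rownames(m), min = qs[, 1], q1 = qs[, 2],
                    median = qs[, 3], q3 = qs[, 4], max = qs[, 5],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, quartile_convention = "linear interpolation (R type 7)",
            class = c("RangeTable", "data.frame"))
}
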