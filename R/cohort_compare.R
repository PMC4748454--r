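#' Remove nuisance covariate contributions from expression
#'
#' Fits, per miRNA, an additive least-squares linear model of expression on
#' the covariates to be *eliminated* (every factor except `factor_to_keep` by
#' default: of sex, smoking and obesity, encoded 0/1) and returns the
#' residuals plus each miRNA's grand mean, so downstream group tests on the
#' kept factor are free of the eliminated factors' linear contributions.
#'
#' @param expr `ExpressionMatrix` (columns = subjects).
#' @param metadata data frame with `subject_id` covering all columns of
#'   `expr`, and covariate columns.
#' @param factor_to_keep the factor whose effect must be preserved
#'   (`"sex"`, `"smoking"` or `"obese"`).
#' @param eliminate covariates to regress out; defaults to the other two
#'   binary factors.
#' @return `ExpressionMatrix` of residualized expression (same dimensions).
#' @export
residualize <- function(expr, metadata,
                        factor_to_keep = c("sex", "smoking", "obese"),
                        eliminate = NULL) {
  factor_to_keep <- match.arg(factor_to_keep)
  m <- unclass(expr)
  ix <- match(colnames(m), metadata$subject_id)
  if (anyNA(ix)) {
    stop(sprintf("metadata missing subject(s): %s",
                 paste(colnames(m)[is.na(ix)], collapse = ", ")))
  }
  meta <- metadata[ix, , drop = FALSE]
  if (is.null(eliminate)) {
    eliminate <- setdiff(c("sex", "smoking", "obese"), factor_to_keep)
    eliminate <- intersect(eliminate, names(meta))
  }
  if (length(eliminate) == 0) return(expr)
  X <- cbind(`(Intercept)` = 1,
             vapply(eliminate, function(v) encode_binary(meta[[v]], v),
                    numeric(nrow(meta))))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop(sprintf("confounded design: collinear covariate(s) %s",
                 paste(dropped, collapse = ", ")))
  }
  res <- t(qr.resid(qx, t(m)))
  out <- res + rowMeans(m)
  dimnames(out) <- dimnames(m)
  structure(out, class = c("ExpressionMatrix", "matrix", "array"),
            residualized = eliminate)
}

# 0/1 encoding of a binary covariate (F/M, no/yes, FALSE/TRUE, or any
# two-level factor by sorted level order).
encode_binary <- function(x, name = "covariate") {
  if (is.logical(x)) return(as.numeric(x))
  u <- sort(unique(as.character(x)))
  if (length(u) > 2) {
    stop(sprintf("covariate '%s' has more than two levels", name))
  }
  as.numeric(as.character(x) == u[length(u)])
}

#' Two-group differential expression by per-miRNA t-tests
#'
#' Runs a two-sided two-sample t-test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance form) for every miRNA between
#' the two groups. Fold changes are computed on a pseudocount-stabilized
#' scale (pseudocount = half the smallest nonzero expression value, keeping
#' ratios finite at zero means) and reported both as a `>= 1` magnitude with
#' its direction (`higher_in`) and as a signed `log2_fc`
#' (group B over group A). Significant rows (raw, or BH-adjusted when
#' requested, P below `alpha`) are ordered first, by descending fold change.
#' miRNAs with zero variance in both groups have no defined test; they are
#' flagged and excluded from the significant set.
#'
#' @param expr `ExpressionMatrix`.
#' @param groups two-level factor/character/logical vector along the columns
#'   of `expr` (or the name of a metadata column when `metadata` is given).
#' @param alpha significance level.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param adjust `"none"` (raw P, the default) or `"BH"`
#'   (Benjamini-Hochberg); adjusted P is always reported alongside.
#' @param metadata optional metadata table used to resolve `groups` by name.
#' @return data frame of class `DifferentialResult`: per miRNA the group
#'   means, `higher_in`, `fold_change`, `log2_fc`, `t`, `p`, `p_adj`,
#'   `zero_variance` and `significant`.
#' @export
t_test_de <- function(expr, groups, alpha = 0.05, var_equal = FALSE,
                      adjust = c("none", "BH"), metadata = NULL) {
  adjust <- match.arg(adjust)
  m <- unclass(expr)
  if (is.character(groups) && length(groups) == 1L && !is.null(metadata)) {
    ix <- match(colnames(m), metadata$subject_id)
    groups <- metadata[[groups]][ix]
  }
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("groups must have exactly two levels")
  if (any(table(g) < 2)) stop("both groups need >= 2 subjects")
  la <- levels(g)[1]; lb <- levels(g)[2]
  a <- m[, g == la, drop = FALSE]
  b <- m[, g == lb, drop = FALSE]
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  var_a <- apply(a, 1, var); var_b <- apply(b, 1, var)
  zerovar <- var_a == 0 & var_b == 0
  tt <- vapply(seq_len(nrow(m)), function(i) {
    if (zerovar[i]) return(c(NA_real_, NA_real_))
    ht <- t.test(a[i, ], b[i, ], var.equal = var_equal)
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  nz <- m[m > 0]
  pc <- if (length(nz)) min(nz) / 2 else 0.5
  ratio <- (mean_b + pc) / (mean_a + pc)
  out <- data.frame(mirna = rownames(m),
                    mean_a = mean_a, mean_b = mean_b,
                    higher_in = ifelse(ratio >= 1, lb, la),
                    fold_change = pmax(ratio, 1 / ratio),
                    log2_fc = log2(ratio),
                    t = tt[1, ], p = tt[2, ],
                    p_adj = p.adjust(tt[2, ], method = "BH"),
                    zero_variance = zerovar,
                    stringsAsFactors = FALSE, row.names = NULL)
  p_use <- if (adjust == "BH") out$p_adj else out$p
  out$significant <- !is.na(p_use) & p_use < alpha
  out <- out[order(-out$significant, ifelse(out$significant, -out$fold_change,
                                            out$p)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, groups = c(a = la, b = lb), alpha = alpha,
            var_equal = var_equal, adjust = adjust, pseudocount = pc,
            class = c("DifferentialResult", "data.frame"))
}

#' Correlate miRNA expression with BMI
#'
#' Pearson correlation of each miRNA's normalized expression with the
#' subjects' body mass index, optionally stratified by sex. miRNAs with zero
#' expression variance have undefined correlation and are flagged.
#'
#' @param expr `ExpressionMatrix`.
#' @param metadata data frame with `subject_id`, `bmi` and (for
#'   stratification) `sex`.
#' @param mirnas miRNA names to test (default: all rows).
#' @param by_sex also report per-sex correlations.
#' @return data frame: `mirna`, `r`, `p`, `n`, plus `r_F`/`r_M` when
#'   stratified.
#' @export
bmi_correlation <- function(expr, metadata, mirnas = NULL, by_sex = FALSE) {
  m <- unclass(expr)
  mirnas <- mirnas %||% rownames(m)
  missing <- setdiff(mirnas, rownames(m))
  if (length(missing)) {
    stop(sprintf("unknown miRNA(s): %s", paste(missing, collapse = ", ")))
  }
  ix <- match(colnames(m), metadata$subject_id)
  if (anyNA(ix)) stop("metadata does not cover all expression columns")
  bmi <- metadata$bmi[ix]
  if (length(bmi) < 3) stop("need >= 3 subjects for correlation")
  corr_one <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- cor.test(x, y, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }
  rp <- vapply(mirnas, function(mi) corr_one(m[mi, ], bmi), numeric(2))
  out <- data.frame(mirna = mirnas, r = rp[1, ], p = rp[2, ],
                    n = length(bmi), stringsAsFactors = FALSE,
                    row.names = NULL)
  if (by_sex) {
    sex <- metadata$sex[ix]
    for (sx in sort(unique(sex))) {
      sel <- sex == sx
      out[[paste0("r_", sx)]] <- if (sum(sel) >= 3) {
        vapply(mirnas, function(mi) corr_one(m[mi, sel], bmi[sel])[1], 0)
      } else NA_real_
    }
  }
  out
}

#' Heat-map-ready standardized expression
#'
#' Rows are standardized to mean 0 and unit SD, then clipped to
#' `[-clip, clip]` — the display scale used for differential-expression heat
#' maps. Zero-variance rows become all zero.
#'
#' @param expr `ExpressionMatrix` (typically subset to significant miRNAs).
#' @param clip symmetric clipping bound.
#' @return plain numeric matrix.
#' @export
heatmap_matrix <- function(expr, clip = 2) {
  m <- unclass(expr)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  pmin(pmax(z, -clip), clip)
}
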