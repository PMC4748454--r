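meta18 <- function(seed = 1) {
  withr::with_seed(seed, {
    data.frame(subject_id = sprintf("S%02d", 1:18),
               sex = rep(c("F", "M"), each = 9),
               smoking = sample(rep(c("yes", "no"), c(8, 10))),
               bmi = round(runif(18, 19, 42), 1),
               stringsAsFactors = FALSE)
  }) -> md
  md$obese <- md$bmi >= 30
  md
}

test_that("residualization removes eliminated factors and nothing else", {
  md <- meta18(2)
  withr::with_seed(3, {
    base <- matrix(rlnorm(10 * 18, 1, 0.2), nrow = 10,
                   dimnames = list(paste0("m", 1:10), md$subject_id))
  })
  # expression that is purely a smoking effect; eliminating smoking leaves
  # an exactly flat residual, hence zero sex difference
  eff <- base
  eff[3, ] <- ifelse(md$smoking == "yes", 6, 2)
  res <- residualize(as_expr(eff), md, factor_to_keep = "sex",
                     eliminate = "smoking")
  f <- md$sex == "F"
  expect_equal(mean(res[3, f]) - mean(res[3, !f]), 0, tolerance = 1e-10)
  # residuals orthogonal to every eliminated covariate
  res2 <- residualize(as_expr(eff), md, factor_to_keep = "sex")
  for (cov in c("smoking", "obese")) {
    x <- as.numeric(md[[cov]] == sort(unique(as.character(md[[cov]])))[2])
    centred <- res2 - rowMeans(res2)
    expect_true(all(abs(centred %*% (x - mean(x))) < 1e-8))
  }
  # nothing eliminated: identity
  expect_equal(residualize(as_expr(base), md, "sex", eliminate = character(0)),
               as_expr(base))
})

test_that("a confounded design fails naming the collinear factor", {
  md <- meta18(4)
  md$smoking <- ifelse(md$sex == "F", "yes", "no")  # smoking == sex
  withr::with_seed(5, {
    m <- matrix(rlnorm(5 * 18), nrow = 5,
                dimnames = list(paste0("m", 1:5), md$subject_id))
  })
  md$obese <- md$smoking == "yes"                   # obese == smoking too
  expect_error(residualize(as_expr(m), md, factor_to_keep = "sex"),
               "collinear")
})

test_that("t-tests find no signal between identical groups", {
  withr::with_seed(7, {
    half <- matrix(rlnorm(20 * 9, 2, 0.3), nrow = 20)
  })
  m <- cbind(half, half)
  colnames(m) <- sprintf("S%02d", 1:18)
  rownames(m) <- paste0("m", 1:20)
  de <- t_test_de(as_expr(m), rep(c("a", "b"), each = 9))
  expect_equal(sum(de$significant), 0)
  expect_true(all(de$p > 0.999))
  expect_true(all(de$fold_change >= 1))
})

test_that("planted fold changes are recovered with correct direction and ordering", {
  withr::with_seed(11, {
    md <- meta18(11)
    m <- matrix(rlnorm(30 * 18, 0, sqrt(log(1 + 0.3^2))), nrow = 30,
                dimnames = list(paste0("m", 1:30), md$subject_id))
    up_in_f <- paste0("m", 1:5)
    m[up_in_f, md$sex == "F"] <- m[up_in_f, md$sex == "F"] * 4
  })
  de <- t_test_de(as_expr(m), md$sex, metadata = md)
  sig <- de[de$significant, ]
  expect_true(all(up_in_f %in% sig$mirna))
  expect_true(all(sig$higher_in[sig$mirna %in% up_in_f] == "F"))
  # significant block first, ordered by descending fold change
  expect_true(all(which(de$significant) == seq_len(sum(de$significant))))
  expect_true(all(diff(de$fold_change[de$significant]) <= 1e-12))
  # groups resolvable by metadata column name
  de2 <- t_test_de(as_expr(m), "sex", metadata = md)
  expect_equal(de2$p, de$p)
})

test_that("zero-variance miRNAs are flagged and never called significant", {
  m <- rbind(flat = rep(5, 12),
             ok = c(rep(1, 6), rep(4, 6)) + seq(0, 1.1, by = 0.1))
  colnames(m) <- paste0("S", 1:12)
  de <- t_test_de(as_expr(m), rep(c("x", "y"), each = 6))
  expect_true(de$zero_variance[de$mirna == "flat"])
  expect_true(is.na(de$p[de$mirna == "flat"]))
  expect_false(de$significant[de$mirna == "flat"])
})

test_that("the false-positive rate of the t-test matches alpha on null data", {
  withr::with_seed(19, {
    m <- matrix(rlnorm(800 * 18, 0, sqrt(log(1 + 0.3^2))), nrow = 800)
    colnames(m) <- sprintf("S%02d", 1:18)
    rownames(m) <- paste0("m", 1:800)
    de <- t_test_de(as_expr(m), rep(c("a", "b"), each = 9))
    fp <- mean(de$significant)
    expect_lt(abs(fp - 0.05), 3 * sqrt(0.05 * 0.95 / 800))
  })
})

test_that("BH adjustment shrinks the significant set", {
  withr::with_seed(23, {
    md <- meta18(23)
    m <- matrix(rlnorm(100 * 18, 0, 0.3), nrow = 100,
                dimnames = list(paste0("m", 1:100), md$subject_id))
    m[1:3, md$smoking == "yes"] <- m[1:3, md$smoking == "yes"] * 5
  })
  raw <- t_test_de(as_expr(m), md$smoking)
  adj <- t_test_de(as_expr(m), md$smoking, adjust = "BH")
  expect_lte(sum(adj$significant), sum(raw$significant))
  expect_true(all(paste0("m", 1:3) %in% adj$mirna[adj$significant]))
})

test_that("BMI correlation is exact on linear data and honest on null data", {
  md <- meta18(29)
  m <- matrix(0, nrow = 2, ncol = 18,
              dimnames = list(c("linear", "noise"), md$subject_id))
  m["linear", ] <- 2 * md$bmi + 1
  withr::with_seed(31, m["noise", ] <- rlnorm(18))
  bc <- bmi_correlation(as_expr(m), md)
  expect_equal(bc$r[bc$mirna == "linear"], 1)
  # null ensemble: mean r near zero
  withr::with_seed(37, {
    rs <- replicate(40, {
      mm <- matrix(rlnorm(18), nrow = 1,
                   dimnames = list("m", md$subject_id))
      bmi_correlation(as_expr(mm), md)$r
    })
  })
  # r has SD ~ 1/sqrt(n-1) per draw; 3 SE of the 40-seed mean
  expect_lt(abs(mean(rs)), 3 * (1 / sqrt(17)) / sqrt(40))
  flat <- matrix(1, 1, 18, dimnames = list("flat", md$subject_id))
  expect_true(is.na(bmi_correlation(as_expr(flat), md)$r))
})

test_that("a slope calibrated to r = 0.65 is recovered across seeds", {
  md <- meta18(41)
  b <- md$bmi
  r_target <- 0.65
  slope <- 1
  noise_sd <- slope * sd(b) * sqrt(1 / r_target^2 - 1)
  rs <- vapply(1:30, function(s) {
    withr::with_seed(400 + s, {
      e <- matrix(slope * b + rnorm(18, 0, noise_sd), nrow = 1,
                  dimnames = list("m", md$subject_id))
      bmi_correlation(as_expr(e), md)$r
    })
  }, 0)
  expect_lt(abs(mean(rs) - r_target), 0.15)
})

test_that("sex-stratified correlations are reported when requested", {
  md <- meta18(43)
  withr::with_seed(44, {
    m <- matrix(rlnorm(2 * 18), nrow = 2,
                dimnames = list(c("a", "b"), md$subject_id))
  })
  bc <- bmi_correlation(as_expr(m), md, by_sex = TRUE)
  expect_true(all(c("r_F", "r_M") %in% names(bc)))
  f <- md$sex == "F"
  expect_equal(bc$r_F[1], cor(m[1, f], md$bmi[f]))
})

test_that("heat-map export standardizes rows and clips to [-2, 2]", {
  withr::with_seed(47, {
    m <- matrix(rlnorm(5 * 18, 2, 1), nrow = 5,
                dimnames = list(paste0("m", 1:5), paste0("S", 1:18)))
  })
  hm <- heatmap_matrix(as_expr(m))
  expect_true(all(hm >= -2 & hm <= 2))
  unclipped <- (m - rowMeans(m)) / apply(m, 1, sd)
  inside <- abs(unclipped) <= 2
  expect_equal(hm[inside], unclipped[inside])
})
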