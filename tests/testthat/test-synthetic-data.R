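test_that("generated references honour size, alphabet and pairwise distance", {
  one <- make_reference(1, c(22, 22), rng_seed = 7)
  expect_length(one, 1)
  expect_equal(nchar(one[[1]]), 22)

  ref <- make_reference(200, c(18, 25), rng_seed = 1)
  expect_length(ref, 200)
  expect_false(anyDuplicated(names(ref)) > 0)
  expect_true(all(grepl("^[ACGT]+$", ref)))
  # all-pairs Hamming scan at equal length
  lens <- nchar(ref)
  for (L in unique(lens)) {
    grp <- ref[lens == L]
    if (length(grp) < 2) next
    chars <- do.call(rbind, strsplit(unname(grp), ""))
    for (i in seq_len(nrow(chars) - 1)) {
      d <- rowSums(chars[rep(i, nrow(chars) - i), , drop = FALSE] !=
                     chars[(i + 1):nrow(chars), , drop = FALSE])
      expect_true(all(d >= 3))
    }
  }
})

test_that("reference generation is deterministic and fails on impossible requests", {
  a <- make_reference(50, c(20, 24), rng_seed = 42)
  b <- make_reference(50, c(20, 24), rng_seed = 42)
  fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
  write_reference(a, fa); write_reference(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_error(make_reference(10, c(10, 12)), "15")
  # 4^15 sequences exist but distance >= 25 at length 15 is impossible
  expect_error(make_reference(5, c(15, 15), min_distance = 25, max_tries = 50),
               "infeasible")
})

test_that("abundance profiles hit the top-1 and top-10 targets exactly", {
  ref <- make_reference(200, c(20, 24), rng_seed = 3)
  p <- sample_profile(ref, 0.60, 0.90, rng_seed = 5)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_equal(max(p), 0.60, tolerance = 1e-6)
  expect_equal(sum(sort(p, decreasing = TRUE)[1:10]), 0.90, tolerance = 1e-6)
  # tail fractions non-increasing in rank order
  rn <- attr(p, "rank_names")
  expect_true(all(diff(p[rn]) <= 1e-12))

  # top1 == top10 forces ranks 2-10 to zero
  q <- sample_profile(make_reference(20, c(20, 24), rng_seed = 1), 0.5, 0.5,
                      rng_seed = 2)
  expect_equal(unname(q[attr(q, "rank_names")[2:10]]), rep(0, 9))
  expect_equal(max(q), 0.5, tolerance = 1e-9)
})

test_that("infeasible profile targets fail explicitly", {
  ref11 <- make_reference(11, c(20, 24), rng_seed = 1)
  expect_error(sample_profile(ref11, 0.6, 0.9), "infeasible")
  ref <- make_reference(20, c(20, 24), rng_seed = 1)
  expect_error(sample_profile(ref, 0.9, 0.6), "top1")
  expect_error(sample_profile(make_reference(10, c(20, 24), rng_seed = 1),
                              0.6, 0.9), "more than 10")
})

test_that("noise-free single-miRNA reads reproduce the reference sequence", {
  ref <- as_mature_reference(c(m1 = "ACGTACGTACGTACGTACGTAC"))
  prof <- setNames(1, "m1")
  cfg <- cohort_config(n_subjects = 2, reads_per_subject = 100,
                       seq_error_rate = 0, noise_read_fraction = 0,
                       low_quality_fraction = 0, biological_cv = 0)
  res <- simulate_subject(ref, prof, cfg, list(subject_id = "S1"), rng_seed = 4)
  inserts <- substr(res$reads$sequence, 1, nchar(ref[[1]]))
  expect_true(all(inserts == ref[[1]]))
  # adapter starts right after the insert
  after <- substr(res$reads$sequence, nchar(ref[[1]]) + 1,
                  nchar(ref[[1]]) + 5)
  expect_true(all(after == substr(cfg$adapter, 1, 5)))
})

test_that("planted covariate effects scale true abundance by the fold change", {
  ref <- make_reference(16, c(20, 22), rng_seed = 9)
  prof <- sample_profile(ref, 0.5, 0.8, rng_seed = 9)
  target <- names(ref)[3]
  cfg <- cohort_config(n_subjects = 2, reads_per_subject = 50,
                       biological_cv = 0, seq_error_rate = 0,
                       noise_read_fraction = 0,
                       planted_effects = list(list(mirna = target,
                                                   covariate = "smoking",
                                                   value = "yes", fold = 4)))
  smoker <- simulate_subject(ref, prof, cfg,
                             list(subject_id = "A", smoking = "yes"), 1)
  nonsmoker <- simulate_subject(ref, prof, cfg,
                                list(subject_id = "B", smoking = "no"), 1)
  expect_equal(nonsmoker$truth$abundance, setNames(as.numeric(prof), names(prof)))
  boosted <- as.numeric(prof)
  names(boosted) <- names(prof)
  boosted[target] <- boosted[target] * 4  # 4 x baseline before renormalisation
  expect_equal(smoker$truth$abundance, boosted / sum(boosted), tolerance = 1e-12)
})

test_that("substitution errors occur at the configured per-base rate", {
  L <- 22
  ref <- as_mature_reference(c(m1 = substr(strrep("ACGT", 6), 1, L)))
  prof <- setNames(1, "m1")
  n <- 1e4
  err <- 0.01
  cfg <- cohort_config(n_subjects = 2, reads_per_subject = n,
                       seq_error_rate = err, noise_read_fraction = 0,
                       low_quality_fraction = 0, biological_cv = 0)
  res <- simulate_subject(ref, prof, cfg, list(subject_id = "S"), rng_seed = 8)
  inserts <- substr(res$reads$sequence, 1, L)
  p_hit <- mean(inserts != ref[[1]])
  p_exp <- 1 - (1 - err)^L
  expect_lt(abs(p_hit - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("read composition matches the subject's true abundances", {
  ref <- make_reference(20, c(20, 24), rng_seed = 2)
  prof <- sample_profile(ref, 0.6, 0.9, rng_seed = 2)
  n <- 2e4
  cfg <- cohort_config(n_subjects = 2, reads_per_subject = n,
                       seq_error_rate = 0, noise_read_fraction = 0,
                       low_quality_fraction = 0, biological_cv = 0.2)
  res <- simulate_subject(ref, prof, cfg, list(subject_id = "S"), rng_seed = 3)
  a <- res$truth$abundance
  frac <- res$truth$mirna_reads / n
  tol <- 3 * sqrt(a * (1 - a) / n)
  expect_true(all(abs(frac - a) <= pmax(tol, 1e-12)))
  # and the FASTQ itself carries those inserts
  tab <- table(substr(res$reads$sequence, 1, 20))
  top_mirna <- names(a)[which.max(a)]
  expect_equal(unname(tab[substr(ref[[top_mirna]], 1, 20)]) / n,
               unname(res$truth$mirna_reads[top_mirna]) / n)
})

test_that("cohorts are bit-reproducible and match the configured covariate balance", {
  cfg <- cohort_config(n_subjects = 18, reads_per_subject = 300,
                       n_mirnas = 15, rng_seed = 21, compress = FALSE)
  d1 <- file.path(tempdir(), "coh_det1")
  d2 <- file.path(tempdir(), "coh_det2")
  c1 <- simulate_cohort(cfg, d1, overwrite = TRUE)
  c2 <- simulate_cohort(cfg, d2, overwrite = TRUE)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  md <- c1$metadata
  expect_equal(as.integer(table(md$sex)[c("F", "M")]), c(9L, 9L))
  expect_equal(sum(md$smoking == "yes" & md$sex == "F"), 4)
  expect_equal(sum(md$smoking == "yes" & md$sex == "M"), 4)
  expect_equal(sum(md$obese & md$sex == "F"), 7)
  expect_equal(sum(md$obese & md$sex == "M"), 2)
  expect_true(all(md$bmi > 0))
  expect_equal(md$obese, md$bmi >= 30)
  # truth round-trips through JSON
  tr <- read_truth(file.path(d1, "truth.json"))
  expect_equal(truth_abundance_matrix(tr), truth_abundance_matrix(c1$truth))
  expect_error(simulate_cohort(cfg, d1), "overwrite")
})

test_that("a haemolysis spike multiplies the blood-cell set before renormalisation", {
  ref <- make_reference(15, c(20, 22), rng_seed = 5)
  prof <- sample_profile(ref, 0.5, 0.85, rng_seed = 5)
  spike_set <- names(ref)[1:3]
  base <- cohort_config(n_subjects = 4, reads_per_subject = 200,
                        biological_cv = 0, reference = ref, profile = prof,
                        rng_seed = 31, compress = FALSE)
  spiked <- cohort_config(n_subjects = 4, reads_per_subject = 200,
                          biological_cv = 0, reference = ref, profile = prof,
                          rng_seed = 31, compress = FALSE,
                          haemolysis_spike = list(subject = "FA01",
                                                  mirnas = spike_set,
                                                  fold = 10))
  c0 <- simulate_cohort(base, file.path(tempdir(), "spike0"), overwrite = TRUE)
  c1 <- simulate_cohort(spiked, file.path(tempdir(), "spike1"), overwrite = TRUE)
  a0 <- c0$truth$subjects$FA01$abundance
  a1 <- c1$truth$subjects$FA01$abundance
  pre <- a0
  pre[spike_set] <- pre[spike_set] * 10
  expect_equal(a1, pre / sum(pre), tolerance = 1e-12)
  # other subjects untouched
  expect_equal(c1$truth$subjects$FA02$abundance,
               c0$truth$subjects$FA02$abundance)
})
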