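test_that("median quality uses the lower-middle convention", {
  expect_equal(median_quality(c(30, 30, 30)), 30)
  expect_equal(median_quality(c(10, 40)), 10)
  expect_equal(median_quality(c(40, 10, 20, 35)), 20)
  withr::with_seed(1, {
    q <- sample(0:41, 101, replace = TRUE)
    expect_equal(median_quality(q), sort(q)[51])
  })
  expect_equal(median_quality(int_to_phred(c(10, 40))), 10)
  expect_error(median_quality(integer(0)), "empty")
})

test_that("adapter trimming removes the leftmost adapter match, oracle-checked", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTAC"
  full <- trim_adapter(paste0(insert, adapter), adapter)
  expect_equal(full$sequence, insert)
  expect_true(full$adapter_trimmed)

  untouched <- trim_adapter("ACGTACGTACGTACGTACGTACGTAC", adapter)
  expect_equal(untouched$sequence, "ACGTACGTACGTACGTACGTACGTAC")
  expect_false(untouched$adapter_trimmed)

  # partial 3' overlaps: every prefix length, brute-force enumeration
  for (k in 0:nchar(adapter)) {
    read <- substr(paste0(insert, substr(adapter, 1, k)), 1, 50)
    got <- trim_adapter(read, adapter, min_overlap = 5)$sequence
    pos <- oracle_trim_pos(read, adapter, 5)
    want <- if (pos > 0) substr(read, 1, pos - 1) else read
    expect_identical(got, want, label = sprintf("overlap %d", k))
    if (k >= 5) expect_identical(got, insert)
  }

  # random reads with random planted adapter fragments
  withr::with_seed(99, {
    bases <- c("A", "C", "G", "T")
    for (i in 1:200) {
      r <- paste(sample(bases, sample(20:50, 1), TRUE), collapse = "")
      if (runif(1) < 0.5) {
        p <- sample(nchar(r), 1)
        r <- paste0(substr(r, 1, p - 1),
                    substr(adapter, 1, min(nchar(adapter), nchar(r) - p + 1)))
      }
      pos <- oracle_trim_pos(r, adapter, 5)
      want <- if (pos > 0) substr(r, 1, pos - 1) else r
      expect_identical(trim_adapter(r, adapter, 5)$sequence, want)
    }
  })
  # qualities are truncated in lockstep
  rd <- data.frame(sequence = paste0(insert, adapter),
                   quality = strrep("I", nchar(insert) + nchar(adapter)))
  out <- trim_adapter(rd, adapter)
  expect_equal(nchar(out$quality), nchar(out$sequence))
})

test_that("the length window is [15,35] inclusive after trimming", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  mk <- function(len) paste(rep("A", len), collapse = "")
  reads <- data.frame(id = paste0("r", 1:4),
                      sequence = paste0(vapply(c(14, 15, 35, 36), mk, ""),
                                        adapter),
                      stringsAsFactors = FALSE)
  reads$quality <- strrep("I", nchar(reads$sequence))
  res <- qc_filter(reads, adapter)
  expect_equal(res$report$reads_out, 2)
  expect_equal(res$report$length_filtered, 2)
  expect_equal(nchar(res$reads$sequence), c(15, 35))
})

test_that("reads below the median-Q30 screen are rejected and counted", {
  reads <- data.frame(id = c("ok", "low"),
                      sequence = c(strrep("A", 20), strrep("C", 20)),
                      quality = c(int_to_phred(rep(30, 20)),
                                  int_to_phred(rep(29, 20))),
                      stringsAsFactors = FALSE)
  res <- qc_filter(reads, adapter = NULL)
  expect_equal(res$report$failed_median_q, 1)
  expect_equal(res$reads$id, "ok")
  expect_error(qc_filter(data.frame(id = "x", sequence = "ACGT",
                                    quality = "II"), NULL), "malformed")
})

test_that("QC counts partition the input and survivors equal the generator's good set", {
  ref <- make_reference(14, c(18, 24), rng_seed = 6)
  prof <- sample_profile(ref, 0.6, 0.9, rng_seed = 6)
  cfg <- cohort_config(n_subjects = 2, reads_per_subject = 5000,
                       noise_read_fraction = 0, seq_error_rate = 0,
                       low_quality_fraction = 0.2, rng_seed = 6)
  # precondition for the exact accounting below: no reference entry carries
  # internal adapter-like sequence, so every insert survives trimming intact
  expect_true(all(vapply(unclass(ref), oracle_trim_pos, 0L,
                         cfg$adapter, 5L) == 0L))
  sim <- simulate_subject(ref, prof, cfg, list(subject_id = "S"), rng_seed = 12)
  res <- qc_filter(sim$reads, cfg$adapter)
  r <- res$report
  expect_equal(r$reads_in, r$reads_out + r$failed_median_q + r$length_filtered)
  expect_equal(sum(r$length_histogram), r$reads_out)
  # all inserts are in-window by construction: only quality rejections remain
  expect_equal(r$reads_out, r$reads_in - sim$truth$n_low_quality)
  len <- nchar(res$reads$sequence)
  expect_true(all(len >= 15 & len <= 35))
  med <- vapply(res$reads$quality, median_quality, 0L, USE.NAMES = FALSE)
  expect_true(all(med >= 30))
})

test_that("qc_filter is idempotent", {
  ref <- make_reference(14, c(18, 24), rng_seed = 13)
  prof <- sample_profile(ref, 0.6, 0.9, rng_seed = 13)
  cfg <- cohort_config(n_subjects = 2, reads_per_subject = 2000,
                       noise_read_fraction = 0.2, low_quality_fraction = 0.1,
                       rng_seed = 13)
  sim <- simulate_subject(ref, prof, cfg, list(subject_id = "S"), rng_seed = 14)
  once <- qc_filter(sim$reads, cfg$adapter)
  twice <- qc_filter(once$reads, cfg$adapter)
  expect_identical(twice$reads, once$reads)
  expect_equal(twice$report$reads_out, twice$report$reads_in)
  expect_equal(twice$report$failed_median_q, 0)
  expect_equal(twice$report$length_filtered, 0)
})

test_that("FASTQ round-trips through write and read", {
  reads <- data.frame(id = c("a", "b"),
                      sequence = c("ACGTACGTACGTACG", "TTTTACGTACGTACGTACGT"),
                      quality = c(int_to_phred(rep(38, 15)),
                                  int_to_phred(c(rep(12, 10), rep(38, 10)))),
                      stringsAsFactors = FALSE)
  fp <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fp)
  back <- read_fastq(fp)
  expect_equal(back, reads)
})
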