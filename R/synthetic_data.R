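#' Configuration for a synthetic plasma small-RNA cohort
#'
#' Bundles every knob of the cohort generator. Defaults emulate the design of
#' an 18-subject disease-free plasma cohort: 9 female / 9 male donors, 4
#' smokers per sex, 7 obese females and 2 obese males (obesity called at
#' BMI >= 30), a heavily top-skewed miRNA abundance profile (top species 60 %
#' of the miRNA load, top ten 90 %), between-subject lognormal abundance
#' variation, sequencing substitution error, 3' adapter read-through at a
#' fixed 50 nt read length, off-target/degradation ("noise") reads, and a
#' two-component quality model in which a known fraction of reads fails the
#' median-Q30 screen. `reads_per_subject` defaults to a desk-scale 1e5
#' (the sequenced cohort averaged ~8.1 million clean reads per sample; the
#' generator scales that down, not the structure).
#'
#' @param n_subjects number of donors (>= 2).
#' @param reads_per_subject reads simulated per donor.
#' @param seq_error_rate per-base substitution probability applied to inserts.
#' @param adapter 3' sequencing adapter (DNA alphabet) ligated to each insert.
#' @param noise_read_fraction fraction of reads drawn from random non-reference
#'   sequence (degradation products, other small RNAs).
#' @param low_quality_fraction fraction of reads generated with median
#'   Phred < 30 (these fail the quality screen by construction).
#' @param biological_cv between-subject coefficient of variation of each
#'   miRNA's abundance (lognormal perturbation before renormalisation).
#' @param planted_effects list of covariate effects, each
#'   `list(mirna=, covariate=, value=, fold=)`: the miRNA's abundance is
#'   multiplied by `fold` (before renormalisation) in subjects whose metadata
#'   column `covariate` equals `value`.
#' @param haemolysis_spike optional `list(subject=, mirnas=, fold=)`
#'   multiplying the named (blood-cell) miRNAs in one subject, emulating a
#'   haemolysed specimen.
#' @param read_length sequencer read length in nt.
#' @param n_mirnas reference size when the reference is generated.
#' @param ref_length_range mature-sequence length range (nt) for a generated
#'   reference.
#' @param top1_target,top10_target abundance-profile targets: fraction of the
#'   miRNA load carried by the top species and by the top ten.
#' @param sex_counts named counts `c(F=, M=)` of donors per sex.
#' @param smokers_per_sex named counts of smokers per sex.
#' @param obese_per_sex named counts of obese donors per sex.
#' @param obese_threshold BMI at or above which a donor is labelled obese.
#' @param compress write gzipped FASTQ when `TRUE`.
#' @param label_origins append `origin=<miRNA|noise>` to read ids (ground
#'   truth per read; useful at test scale).
#' @param reference,profile,metadata optional pre-built `MatureReference`,
#'   `AbundanceProfile` and metadata table; generated when `NULL`.
#' @param rng_seed integer seed; the whole cohort is bit-reproducible given
#'   the config.
#' @return a validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_subjects = 18L,
                          reads_per_subject = 1e5,
                          seq_error_rate = 0.005,
                          adapter = "TGGAATTCTCGGGTGCCAAGG",
                          noise_read_fraction = 0.2,
                          low_quality_fraction = 0.05,
                          biological_cv = 0.3,
                          planted_effects = list(),
                          haemolysis_spike = NULL,
                          read_length = 50L,
                          n_mirnas = 200L,
                          ref_length_range = c(20L, 24L),
                          top1_target = 0.60,
                          top10_target = 0.90,
                          sex_counts = NULL,
                          smokers_per_sex = NULL,
                          obese_per_sex = NULL,
                          obese_threshold = 30,
                          compress = TRUE,
                          label_origins = FALSE,
                          reference = NULL,
                          profile = NULL,
                          metadata = NULL,
                          rng_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) stop("n_subjects must be >= 2")
  if (is.null(sex_counts)) {
    nf <- ceiling(n_subjects / 2); sex_counts <- c(F = nf, M = n_subjects - nf)
  }
  if (sum(sex_counts) != n_subjects) {
    stop("sex_counts must sum to n_subjects")
  }
  # default covariate prevalences follow the 18-donor design: 4/9 smokers in
  # each sex, 7/9 obese females, 2/9 obese males
  if (is.null(smokers_per_sex)) {
    smokers_per_sex <- round(sex_counts * 4 / 9)
  }
  if (is.null(obese_per_sex)) {
    obese_per_sex <- round(sex_counts * c(F = 7, M = 2)[names(sex_counts)] / 9)
  }
  for (p in c(seq_error_rate, noise_read_fraction, low_quality_fraction)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  if (biological_cv < 0) stop("biological_cv must be >= 0")
  assert_dna(adapter, "adapter")
  for (eff in planted_effects) {
    if (!all(c("mirna", "covariate", "value", "fold") %in% names(eff))) {
      stop("each planted effect needs fields mirna, covariate, value, fold")
    }
    if (eff$fold <= 0) stop("planted fold changes must be > 0")
  }
  if (!is.null(haemolysis_spike)) {
    if (!all(c("subject", "mirnas", "fold") %in% names(haemolysis_spike))) {
      stop("haemolysis_spike needs fields subject, mirnas, fold")
    }
    if (haemolysis_spike$fold <= 0) stop("haemolysis fold must be > 0")
  }
  if (any(smokers_per_sex > sex_counts) || any(obese_per_sex > sex_counts)) {
    stop("per-sex smoker/obese counts cannot exceed the sex counts")
  }
  structure(list(
    n_subjects = n_subjects, reads_per_subject = as.integer(reads_per_subject),
    seq_error_rate = seq_error_rate, adapter = adapter,
    noise_read_fraction = noise_read_fraction,
    low_quality_fraction = low_quality_fraction,
    biological_cv = biological_cv, planted_effects = planted_effects,
    haemolysis_spike = haemolysis_spike, read_length = as.integer(read_length),
    n_mirnas = as.integer(n_mirnas),
    ref_length_range = as.integer(ref_length_range),
    top1_target = top1_target, top10_target = top10_target,
    sex_counts = sex_counts, smokers_per_sex = smokers_per_sex,
    obese_per_sex = obese_per_sex, obese_threshold = obese_threshold,
    compress = isTRUE(compress), label_origins = isTRUE(label_origins),
    reference = reference, profile = profile, metadata = metadata,
    rng_seed = as.integer(rng_seed)), class = "CohortConfig")
}

#' Generate a synthetic mature miRNA reference
#'
#' Draws `n_mirnas` uniquely named random DNA sequences with pairwise Hamming
#' distance >= `min_distance` between equal-length entries, so that
#' one-mismatch read assignment is unambiguous by construction.
#'
#' @param n_mirnas number of entries (>= 1).
#' @param length_range `c(min, max)` mature lengths in nt, within 15-35 so
#'   entries survive the pipeline's own length window.
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @param min_distance minimum pairwise Hamming distance at equal length.
#' @param max_tries rejection-sampling attempts per entry before declaring the
#'   distance request infeasible.
#' @param version version label stored on the reference.
#' @return a `MatureReference`.
#' @export
make_reference <- function(n_mirnas, length_range = c(20L, 24L), rng_seed = 1L,
                           min_distance = 3L, max_tries = 2000L,
                           version = "synthetic-mature-1") {
  n_mirnas <- as.integer(n_mirnas)
  if (n_mirnas < 1L) stop("n_mirnas must be >= 1")
  lo <- length_range[1]; hi <- length_range[2]
  if (lo < 15L || hi > 35L || lo > hi) {
    stop("length_range must lie within [15, 35] nt")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(rng_seed, {
    lens <- if (lo == hi) rep(lo, n_mirnas) else
      sample(seq(lo, hi), n_mirnas, replace = TRUE)
    seqs_int <- vector("list", n_mirnas)
    for (i in seq_len(n_mirnas)) {
      placed <- FALSE
      same_len <- which(lens[seq_len(i - 1L)] == lens[i])
      for (try in seq_len(max_tries)) {
        cand <- sample.int(4L, lens[i], replace = TRUE)
        ok <- TRUE
        for (j in same_len) {
          if (sum(cand != seqs_int[[j]]) < min_distance) { ok <- FALSE; break }
        }
        if (ok) { seqs_int[[i]] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        stop(sprintf(paste0("could not place reference entry %d with pairwise ",
                            "Hamming distance >= %d after %d attempts; ",
                            "request infeasible for this length/alphabet"),
                     i, min_distance, max_tries))
      }
    }
    seqs <- vapply(seqs_int, function(v) paste(bases[v], collapse = ""), "")
    names(seqs) <- sprintf("syn-miR-%0*d", max(3L, nchar(n_mirnas)),
                           seq_len(n_mirnas))
    as_mature_reference(seqs, version = version)
  })
}

#' Sample a top-skewed cohort abundance profile
#'
#' Builds per-miRNA relative abundances summing to one in which the most
#' abundant species carries exactly `top1_target` of the miRNA load and the
#' ten most abundant together carry `top10_target`. Ranks 2-10 and the tail
#' each follow a geometric decay renormalised to their mass, which spreads the
#' tail across several orders of magnitude. Rank-to-miRNA identity is a seeded
#' random permutation of the reference.
#'
#' @param reference `MatureReference` (>= 10 entries).
#' @param top1_target fraction of the load carried by the top species.
#' @param top10_target fraction carried by the ten most abundant species;
#'   `top1_target <= top10_target <= 1`.
#' @param rng_seed integer seed for the rank permutation.
#' @param head_decay geometric ratio across ranks 2-10.
#' @param tail_decay geometric ratio across tail ranks.
#' @return named numeric vector of class `AbundanceProfile`, aligned to the
#'   reference, summing to 1.
#' @export
sample_profile <- function(reference, top1_target = 0.60, top10_target = 0.90,
                           rng_seed = 1L, head_decay = 0.7, tail_decay = 0.95) {
  n <- length(reference)
  if (n < 10L) stop("reference too small for top-10 abundance targets (need >= 10 entries)")
  if (!(top1_target > 0 && top1_target <= top10_target && top10_target <= 1)) {
    stop("need 0 < top1_target <= top10_target <= 1")
  }
  head_mass <- top10_target - top1_target
  tail_mass <- 1 - top10_target
  nt <- n - 10L
  if (tail_mass > 0 && nt == 0L) {
    stop("infeasible targets: top10_target < 1 needs more than 10 reference entries")
  }
  geom_head <- function(q) head_mass * (1 - q) / (1 - q^9) * q^(0:8)
  head <- if (head_mass > 0) geom_head(head_decay) else rep(0, 9)
  tail <- rep(0, max(nt, 0L))
  if (tail_mass > 0) {
    f10 <- head[9]
    per_uniform <- tail_mass / nt
    if (head_mass > 0 && per_uniform > f10) {
      # a geometric tail would overtake rank 10; flatten the head just enough
      # that a uniform tail continues it monotonically
      if (per_uniform > head_mass / 9 * (1 + 1e-9)) {
        stop("infeasible targets: tail mass too large to stay below the top-10 ranks")
      }
      if (per_uniform >= geom_head(1 - 1e-9)[9]) {
        head <- rep(head_mass / 9, 9)
      } else {
        q <- uniroot(function(q) geom_head(q)[9] - per_uniform,
                     c(head_decay, 1 - 1e-9), tol = 1e-12)$root
        head <- geom_head(q)
      }
      tail <- rep(per_uniform, nt)
    } else {
      dr <- function(r) tail_mass * (1 - r) / (1 - r^nt)
      r <- tail_decay
      if (head_mass > 0 && dr(r) > f10) {
        # steepen is the wrong direction: raise r toward uniform until the
        # leading tail fraction drops to the rank-10 fraction
        r <- uniroot(function(r) dr(r) - f10, c(tail_decay, 1 - 1e-9),
                     tol = 1e-12)$root
      }
      tail <- dr(r) * r^(0:(nt - 1L))
    }
    if (tail[1] > top1_target + 1e-12) {
      stop("infeasible targets: leading tail fraction would exceed the top-1 fraction")
    }
  }
  if (head_mass > 0 && head[1] > top1_target + 1e-12) {
    stop("infeasible targets: rank-2 fraction would exceed the top-1 fraction")
  }
  fr <- c(top1_target, head, tail)
  fr <- fr / sum(fr)
  perm <- with_seed(rng_seed, sample.int(n))
  prof <- numeric(n)
  prof[perm] <- fr
  names(prof) <- names(reference)
  structure(prof, rank_names = names(reference)[perm],
            top1_target = top1_target, top10_target = top10_target,
            class = "AbundanceProfile")
}

# Realize one subject's true abundance vector: lognormal between-subject
# noise, planted covariate effects and the haemolysis spike, renormalised.
realize_abundance <- function(profile, config, subject_meta) {
  a <- as.numeric(profile)
  names(a) <- names(profile)
  cv <- config$biological_cv
  if (cv > 0) {
    sigma <- sqrt(log(1 + cv^2))
    a <- a * rlnorm(length(a), meanlog = -sigma^2 / 2, sdlog = sigma)
  }
  for (eff in config$planted_effects) {
    if (!eff$mirna %in% names(a)) {
      stop(sprintf("planted effect names unknown miRNA '%s'", eff$mirna))
    }
    cov_val <- subject_meta[[eff$covariate]]
    if (is.null(cov_val)) {
      stop(sprintf("planted effect covariate '%s' absent from metadata",
                   eff$covariate))
    }
    if (identical(as.character(cov_val), as.character(eff$value))) {
      a[eff$mirna] <- a[eff$mirna] * eff$fold
    }
  }
  sp <- config$haemolysis_spike
  if (!is.null(sp) && identical(subject_meta$subject_id, sp$subject)) {
    missing <- setdiff(sp$mirnas, names(a))
    if (length(missing)) {
      stop(sprintf("haemolysis spike names unknown miRNAs: %s",
                   paste(missing, collapse = ", ")))
    }
    a[sp$mirnas] <- a[sp$mirnas] * sp$fold
  }
  a / sum(a)
}

#' Simulate one subject's small-RNA FASTQ reads
#'
#' Realizes the subject's true abundance vector (profile perturbed by
#' lognormal between-subject noise, planted covariate effects and any
#' haemolysis spike, then renormalised), draws read origins from it
#' (multinomial, with a configured fraction of random noise inserts), applies
#' per-base substitution error to the insert, appends the 3' adapter with
#' read-through to the fixed read length, and attaches two-component Phred+33
#' qualities (good reads: all bases >= Q35; low-quality reads: all bases
#' < Q29, so the median-Q30 screen's pass set is exact).
#'
#' @param reference `MatureReference`.
#' @param profile `AbundanceProfile` aligned to the reference.
#' @param config `CohortConfig`.
#' @param subject_meta one-row list/data.frame with at least `subject_id` and
#'   any covariates referenced by planted effects.
#' @param rng_seed integer seed for this subject.
#' @param path optional FASTQ output file (`.gz` for gzip); reads are returned
#'   in memory when `NULL`.
#' @return list with `truth` (realized abundances, per-miRNA read counts,
#'   noise/low-quality read counts) and either `path` or `reads`.
#' @export
simulate_subject <- function(reference, profile, config, subject_meta,
                             rng_seed, path = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  assert_dna(config$adapter, "adapter")
  if (!identical(names(profile), names(reference))) {
    stop("profile is not aligned to the reference")
  }
  sid <- subject_meta$subject_id %||% "S1"
  n_reads <- config$reads_per_subject
  rl <- config$read_length
  bases <- c("A", "C", "G", "T")
  with_seed(rng_seed, {
    truth_ab <- realize_abundance(profile, config, subject_meta)
    n_noise <- rbinom(1L, n_reads, config$noise_read_fraction)
    mir_counts <- as.vector(rmultinom(1L, n_reads - n_noise, truth_ab))
    origin <- c(rep(names(reference), mir_counts), rep("noise", n_noise))
    inserts <- character(n_reads)
    is_mir <- origin != "noise"
    inserts[is_mir] <- unclass(reference)[origin[is_mir]]
    if (n_noise > 0) {
      nl <- sample(16:32, n_noise, replace = TRUE)
      pool <- paste(sample(bases, sum(nl), replace = TRUE), collapse = "")
      ends <- cumsum(nl)
      inserts[!is_mir] <- substring(pool, ends - nl + 1L, ends)
    }
    perm <- sample.int(n_reads)
    origin <- origin[perm]; inserts <- inserts[perm]
    # substitution errors on the insert only (the planted adapter is clean)
    if (config$seq_error_rate > 0) {
      L <- nchar(inserts)
      nerr <- rbinom(n_reads, L, config$seq_error_rate)
      for (i in which(nerr > 0L)) {
        s <- strsplit(inserts[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(L[i], nerr[i])
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
        inserts[i] <- paste(s, collapse = "")
      }
    }
    full <- paste0(inserts, config$adapter)
    short <- nchar(full) < rl
    if (any(short)) {
      # read-through filler past the adapter (sequencer noise; always trimmed)
      full[short] <- paste0(full[short],
                            strrep("A", rl - nchar(full[short])))
    }
    seqs <- substr(full, 1L, rl)
    bad <- runif(n_reads) < config$low_quality_fraction
    n_bad <- sum(bad)
    qual <- character(n_reads)
    if (n_bad < n_reads) {
      v <- sample(35:40, (n_reads - n_bad) * rl, replace = TRUE)
      allq <- intToUtf8(v + 33L)
      st <- seq(1L, by = rl, length.out = n_reads - n_bad)
      qual[!bad] <- substring(allq, st, st + rl - 1L)
    }
    if (n_bad > 0) {
      v <- sample(2:28, n_bad * rl, replace = TRUE)
      allq <- intToUtf8(v + 33L)
      st <- seq(1L, by = rl, length.out = n_bad)
      qual[bad] <- substring(allq, st, st + rl - 1L)
    }
    ids <- sprintf("%s_r%06d", sid, seq_len(n_reads))
    if (config$label_origins) ids <- paste0(ids, " origin=", origin)
    reads <- data.frame(id = ids, sequence = seqs, quality = qual,
                        stringsAsFactors = FALSE)
    truth <- list(subject_id = sid,
                  abundance = truth_ab,
                  mirna_reads = setNames(mir_counts, names(reference)),
                  n_reads = n_reads, n_noise = n_noise,
                  n_low_quality = n_bad, rng_seed = rng_seed)
    if (is.null(path)) {
      list(truth = truth, reads = reads)
    } else {
      write_fastq(reads, path)
      list(truth = truth, path = path)
    }
  })
}

# Donor metadata table mirroring the cohort design: exact per-sex smoker and
# obese counts, BMI drawn on the correct side of the obesity threshold, ages
# within each sex's observed range.
make_metadata <- function(config, rng_seed) {
  sc <- config$sex_counts
  thr <- config$obese_threshold
  with_seed(rng_seed, {
    rows <- list()
    for (sx in names(sc)) {
      ns <- sc[[sx]]
      if (ns == 0) next
      ids <- sprintf("%sA%02d", sx, seq_len(ns))
      smoke <- rep("no", ns)
      smoke[sample.int(ns, config$smokers_per_sex[[sx]])] <- "yes"
      obese <- rep(FALSE, ns)
      obese[sample.int(ns, config$obese_per_sex[[sx]])] <- TRUE
      age_rng <- if (sx == "F") 20:61 else 19:67
      bmi_hi <- if (sx == "F") 46 else 47
      bmi <- numeric(ns)
      bmi[obese] <- round(runif(sum(obese), thr, bmi_hi), 1)
      bmi[!obese] <- round(runif(sum(!obese), 18, thr - 0.6), 1)
      rows[[sx]] <- data.frame(subject_id = ids, sex = sx,
                               age = sample(age_rng, ns, replace = TRUE),
                               smoking = smoke, bmi = bmi,
                               obese = bmi >= thr,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Simulate a full synthetic plasma cohort
#'
#' Writes one FASTQ per donor, the mature reference FASTA, the donor metadata
#' table and a machine-readable ground-truth record (realized abundances,
#' planted effects, per-subject read provenance counts). Bit-reproducible
#' given the config.
#'
#' @param config `CohortConfig`.
#' @param out_dir output directory.
#' @param overwrite allow writing into a non-empty existing directory.
#' @return list with `dir`, `reference`, `profile`, `metadata`, `truth` and
#'   the per-subject FASTQ `files`.
#' @export
simulate_cohort <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "CohortConfig"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop(sprintf("output directory '%s' exists and is not empty (set overwrite = TRUE)",
                 out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$rng_seed, 3L + config$n_subjects)
  reference <- config$reference %||%
    make_reference(config$n_mirnas, config$ref_length_range, seeds[1])
  profile <- config$profile %||%
    sample_profile(reference, config$top1_target, config$top10_target, seeds[2])
  metadata <- config$metadata %||% make_metadata(config, seeds[3])
  if (nrow(metadata) != config$n_subjects) {
    stop("metadata row count does not match n_subjects")
  }
  write_reference(reference, file.path(out_dir, "reference.fa"))
  write_tsv(metadata, file.path(out_dir, "metadata.tsv"))
  ext <- if (config$compress) ".fastq.gz" else ".fastq"
  files <- character(0)
  subjects <- list()
  for (i in seq_len(nrow(metadata))) {
    sm <- as.list(metadata[i, ])
    fp <- file.path(out_dir, paste0(sm$subject_id, ext))
    res <- simulate_subject(reference, profile, config, sm,
                            rng_seed = seeds[3L + i], path = fp)
    files[sm$subject_id] <- fp
    subjects[[sm$subject_id]] <- res$truth
  }
  truth <- structure(list(profile = profile,
                          planted_effects = config$planted_effects,
                          haemolysis_spike = config$haemolysis_spike,
                          subjects = subjects),
                     class = "CohortTruth")
  write_truth(truth, file.path(out_dir, "truth.json"))
  list(dir = out_dir, reference = reference, profile = profile,
       metadata = metadata, truth = truth, files = files)
}

#' Serialize cohort ground truth to JSON
#'
#' @param truth `CohortTruth`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    profile = as.list(unclass(truth$profile)),
    planted_effects = truth$planted_effects,
    haemolysis_spike = truth$haemolysis_spike,
    subjects = lapply(truth$subjects, function(s) {
      list(subject_id = s$subject_id,
           abundance = as.list(s$abundance),
           mirna_reads = as.list(s$mirna_reads),
           n_reads = s$n_reads, n_noise = s$n_noise,
           n_low_quality = s$n_low_quality, rng_seed = s$rng_seed)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read cohort ground truth back from JSON
#'
#' @param path JSON file written by [write_truth()].
#' @return `CohortTruth`.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  subjects <- lapply(obj$subjects, function(s) {
    list(subject_id = s$subject_id,
         abundance = unlist(s$abundance),
         mirna_reads = unlist(s$mirna_reads),
         n_reads = s$n_reads, n_noise = s$n_noise,
         n_low_quality = s$n_low_quality, rng_seed = s$rng_seed)
  })
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  structure(list(profile = unlist(obj$profile),
                 planted_effects = lapply(obj$planted_effects, as.list),
                 haemolysis_spike = if (is.null(obj$haemolysis_spike)) NULL
                                    else as.list(obj$haemolysis_spike),
                 subjects = subjects),
            class = "CohortTruth")
}

#' True abundance matrix of a cohort
#'
#' @param truth `CohortTruth`.
#' @return miRNA x subject matrix of realized true abundances (fractions of
#'   the subject's miRNA load).
#' @export
truth_abundance_matrix <- function(truth) {
  stopifnot(inherits(truth, "CohortTruth"))
  m <- vapply(truth$subjects, function(s) s$abundance,
              numeric(length(truth$subjects[[1]]$abundance)))
  rownames(m) <- names(truth$subjects[[1]]$abundance)
  m
}
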