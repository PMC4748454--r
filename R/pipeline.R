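#' Pipeline configuration
#'
#' One structured object holding every threshold of the analysis: the
#' median-Q30 quality screen, the 15-35 nt length window, the one-mismatch
#' mapping, the 10-read / 3-subject detection filter, the t-test significance
#' level and the top-k load-fraction cutoff, plus paths and policy selectors.
#' Serializable to YAML and round-trippable with [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param reference path to the mature miRNA reference FASTA.
#' @param reads_dir directory with one FASTQ (`<subject_id>.fastq[.gz]`) per
#'   subject.
#' @param metadata path to the subject metadata TSV
#'   (`subject_id, sex, age, smoking, bmi, obese`).
#' @param out_dir output directory for all stage artifacts.
#' @param adapter 3' adapter to trim.
#' @param min_median_q,min_len,max_len,min_overlap QC thresholds.
#' @param max_mismatch,mode,ambiguous mapping policy, see [count_matrix()].
#' @param min_reads,min_subjects detection-filter thresholds.
#' @param alpha significance level for group comparisons.
#' @param adjust multiple-testing adjustment for comparisons
#'   (`"none"`/`"BH"`).
#' @param topk number of top species reported by the load-fraction stage.
#' @param blood_set optional character vector (or one-name-per-line file) of
#'   blood-cell-associated miRNAs for the haemolysis CV check.
#' @param factors covariates compared in the differential stage.
#' @param eliminate_others residualize the other factors before each
#'   comparison.
#' @param rng_seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(reference, reads_dir, metadata, out_dir,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_median_q = 30L, min_len = 15L, max_len = 35L,
                            min_overlap = 5L, max_mismatch = 1L,
                            mode = "containment", ambiguous = "discard",
                            min_reads = 10L, min_subjects = 3L,
                            alpha = 0.05, adjust = "none", topk = 10L,
                            blood_set = NULL,
                            factors = c("sex", "smoking", "obese"),
                            eliminate_others = TRUE, rng_seed = 1L) {
  cfg <- list(reference = reference, reads_dir = reads_dir,
              metadata = metadata, out_dir = out_dir, adapter = adapter,
              min_median_q = as.integer(min_median_q),
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              min_overlap = as.integer(min_overlap),
              max_mismatch = as.integer(max_mismatch), mode = mode,
              ambiguous = ambiguous, min_reads = as.integer(min_reads),
              min_subjects = as.integer(min_subjects), alpha = alpha,
              adjust = adjust, topk = as.integer(topk),
              blood_set = blood_set, factors = factors,
              eliminate_others = isTRUE(eliminate_others),
              rng_seed = as.integer(rng_seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$min_len <= cfg$max_len, cfg$min_len >= 1,
            cfg$max_mismatch >= 0, cfg$min_reads >= 1, cfg$min_subjects >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$topk >= 1,
            cfg$mode %in% c("containment", "end_to_end"),
            cfg$ambiguous %in% c("discard", "split", "first"),
            cfg$adjust %in% c("none", "BH"))
  if (!is.null(cfg$adapter)) assert_dna(cfg$adapter, "adapter")
  invisible(cfg)
}

#' Write a pipeline config as YAML
#' @param config `PipelineConfig`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline config from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$factors)) cfg$factors <- unlist(cfg$factors)
  if (!is.null(cfg$blood_set)) cfg$blood_set <- unlist(cfg$blood_set)
  validate_pipeline_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes qc -> tally -> map -> quantify -> stats -> compare
#' deterministically, writing tab-separated artifacts per stage under
#' `config$out_dir` plus a machine-readable run manifest and a run log.
#' With `resume = TRUE` a stage whose outputs already exist is skipped and
#' its cached artifacts feed the next stage.
#'
#' @param config `PipelineConfig` or path to its YAML serialization.
#' @param resume reuse existing stage outputs instead of recomputing.
#' @return list of key results: per-sample QC reports, `CountMatrix`,
#'   filtered and unfiltered `ExpressionMatrix`, stability/range/load-fraction
#'   tables, per-factor `DifferentialResult`s, and the artifact paths.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("qc", "tally", "counts", "expression", "stats", "compare")) {
    dir.create(file.path(out, d), showWarnings = FALSE)
  }
  log_path <- file.path(out, "run.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cfg_path <- file.path(out, "config.yaml")
  write_pipeline_config(config, cfg_path)

  metadata <- read_tsv(config$metadata)
  if (anyDuplicated(metadata$subject_id)) stop("duplicate subject ids in metadata")
  subjects <- metadata$subject_id
  fq <- find_fastq(config$reads_dir, subjects)

  # -- qc: median-quality screen, adapter trim, length window ---------------
  qc_reports <- list()
  clean_paths <- file.path(out, "qc", paste0(subjects, ".clean.fastq.gz"))
  report_paths <- file.path(out, "qc", paste0(subjects, ".qc.tsv"))
  names(clean_paths) <- names(report_paths) <- subjects
  stage("qc", function() {
    for (s in subjects) {
      if (resume && file.exists(clean_paths[s]) && file.exists(report_paths[s])) {
        logline("qc: %s cached", s); next
      }
      res <- qc_filter(read_fastq(fq[s]), adapter = config$adapter,
                       min_median_q = config$min_median_q,
                       min_len = config$min_len, max_len = config$max_len,
                       min_overlap = config$min_overlap)
      write_fastq(res$reads, clean_paths[s])
      write_qc_report(res$report, report_paths[s])
      logline("qc: %s %d -> %d reads (%d low quality, %d off-length)", s,
              res$report$reads_in, res$report$reads_out,
              res$report$failed_median_q, res$report$length_filtered)
    }
  })

  # -- tally: unique-sequence count tables ----------------------------------
  tally_paths <- file.path(out, "tally", paste0(subjects, ".tally.tsv"))
  names(tally_paths) <- subjects
  stage("tally", function() {
    for (s in subjects) {
      if (resume && file.exists(tally_paths[s])) { logline("tally: %s cached", s); next }
      tl <- build_tally(read_fastq(clean_paths[s]), s)
      write_tally(tl, tally_paths[s])
      logline("tally: %s %d unique sequences", s, nrow(tl))
    }
  })

  # -- map: one-mismatch assignment to the mature reference -----------------
  counts_path <- file.path(out, "counts", "counts.tsv")
  mapstats_path <- file.path(out, "counts", "mapstats.tsv")
  cm <- stage("map", function() {
    reference <- read_reference(config$reference)
    tallies <- lapply(subjects, function(s) read_tally(tally_paths[s], s))
    cm <- count_matrix(tallies, reference, max_mismatch = config$max_mismatch,
                       mode = config$mode, ambiguous = config$ambiguous)
    write_count_matrix(cm, counts_path, mapstats_path)
    logline("map: %.0f/%.0f reads mapped", sum(cm$mapped_total),
            sum(cm$total_reads))
    cm
  })

  # -- quantify: detection filter + relative expression ---------------------
  qres <- stage("quantify", function() {
    flt <- detection_filter(cm, min_reads = config$min_reads,
                            min_subjects = config$min_subjects)
    if (nrow(flt$counts$counts) == 0) {
      warning("detection filter removed every miRNA (check min_subjects vs cohort size)")
    }
    expr_all <- normalize_expression(cm)
    expr <- normalize_expression(flt$counts)
    write_tsv(flt$removed, file.path(out, "expression", "removed.tsv"))
    write_expression(expr, file.path(out, "expression", "expression.tsv"))
    write_expression(expr_all,
                     file.path(out, "expression", "expression_unfiltered.tsv"))
    pen <- penetrance(flt$counts)
    write_tsv(data.frame(mirna = names(pen$penetrance),
                         n_subjects = pen$penetrance,
                         ubiquitous = names(pen$penetrance) %in% pen$ubiquitous),
              file.path(out, "expression", "penetrance.tsv"))
    logline("quantify: %d miRNAs retained, %d removed", nrow(expr),
            nrow(flt$removed))
    list(expr = expr, expr_all = expr_all, removed = flt$removed, pen = pen)
  })

  # -- stats: load fractions, stability, ranges, haemolysis CV check --------
  sres <- stage("stats", function() {
    lf <- data.frame(k = seq_len(min(config$topk, nrow(qres$expr_all))))
    lf$load_fraction <- vapply(lf$k, function(k) load_fraction(qres$expr_all, k), 0)
    write_tsv(lf, file.path(out, "stats", "load_fraction.tsv"))
    if (nrow(qres$expr) > 0) {
      stab <- stability_rank(qres$expr)
      rng <- range_table(qres$expr)
    } else {
      logline("stats: no retained miRNAs, stability/range tables empty")
      stab <- data.frame(mirna = character(0), mean = numeric(0),
                         sem = numeric(0), dispersion = numeric(0),
                         rank = integer(0), top_decile = logical(0),
                         undefined = logical(0))
      rng <- data.frame(mirna = character(0), min = numeric(0),
                        q1 = numeric(0), median = numeric(0),
                        q3 = numeric(0), max = numeric(0))
    }
    write_tsv(as.data.frame(stab), file.path(out, "stats", "stability.tsv"))
    write_tsv(as.data.frame(rng), file.path(out, "stats", "ranges.tsv"))
    cvres <- NULL
    bset <- resolve_blood_set(config$blood_set)
    bset <- intersect(bset, rownames(qres$expr))
    rest <- setdiff(rownames(qres$expr), bset)
    if (length(bset) && length(rest)) {
      cv <- cv_compare(qres$expr, bset, rest)
      cvres <- data.frame(set = c("blood_cell", "other"),
                          n_mirnas = c(length(bset), length(rest)),
                          cv_percent = unname(cv))
      write_tsv(cvres, file.path(out, "stats", "cv_compare.tsv"))
    } else {
      logline("stats: blood-cell set absent from matrix, CV check skipped")
    }
    list(load_fraction = lf, stability = stab, ranges = rng, cv = cvres)
  })

  # -- compare: covariate differential expression + BMI correlation ---------
  cres <- stage("compare", function() {
    res <- list()
    if (nrow(qres$expr) == 0) {
      logline("compare: no retained miRNAs, comparisons skipped")
      return(res)
    }
    for (f in config$factors) {
      if (!f %in% names(metadata)) { logline("compare: no column '%s'", f); next }
      g <- metadata[[f]][match(colnames(qres$expr), metadata$subject_id)]
      if (length(unique(g)) != 2 || min(table(g)) < 2) {
        logline("compare: factor '%s' lacks two groups of >= 2, skipped", f)
        next
      }
      de <- tryCatch({
        e <- if (config$eliminate_others) {
          residualize(qres$expr, metadata, factor_to_keep = f)
        } else qres$expr
        t_test_de(e, g, alpha = config$alpha, adjust = config$adjust)
      }, error = function(err) {
        logline("compare: factor '%s' skipped (%s)", f, conditionMessage(err))
        NULL
      })
      if (is.null(de)) next
      write_tsv(as.data.frame(de), file.path(out, "compare", paste0(f, ".tsv")))
      sig <- de$mirna[de$significant]
      if (length(sig) >= 2) {
        hm <- heatmap_matrix(qres$expr[sig, , drop = FALSE])
        write_tsv(data.frame(mirna = rownames(hm), hm, check.names = FALSE),
                  file.path(out, "compare", paste0(f, "_heatmap.tsv")))
      }
      logline("compare: %s, %d significant at alpha %.3g", f,
              sum(de$significant), config$alpha)
      res[[f]] <- de
    }
    if ("bmi" %in% names(metadata)) {
      bc <- bmi_correlation(qres$expr, metadata, by_sex = "sex" %in% names(metadata))
      write_tsv(bc, file.path(out, "compare", "bmi_correlation.tsv"))
      res$bmi <- bc
    }
    res
  })

  manifest <- list(pipeline_version = as.character(utils::packageVersion("plasmiR")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   n_subjects = length(subjects),
                   reads_in = unname(sum(cm$total_reads)),
                   reads_mapped = unname(sum(cm$mapped_total)),
                   mirnas_detected = nrow(qres$expr),
                   stages = c("qc", "tally", "map", "quantify", "stats", "compare"))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, counts = cm, expression = qres$expr,
                 expression_unfiltered = qres$expr_all,
                 removed = qres$removed, penetrance = qres$pen,
                 stats = sres, compare = cres, out_dir = out))
}

find_fastq <- function(reads_dir, subjects) {
  fq <- setNames(character(length(subjects)), subjects)
  for (s in subjects) {
    cand <- file.path(reads_dir, paste0(s, c(".fastq.gz", ".fastq", ".fq.gz", ".fq")))
    hit <- cand[file.exists(cand)]
    if (!length(hit)) stop(sprintf("no FASTQ found for subject '%s' in %s", s, reads_dir))
    fq[s] <- hit[1]
  }
  fq
}

resolve_blood_set <- function(blood_set) {
  if (is.null(blood_set)) return(character(0))
  if (length(blood_set) == 1 && file.exists(blood_set)) {
    x <- readLines(blood_set)
    return(trimws(x[nzchar(trimws(x))]))
  }
  blood_set
}

#' Blood-cell-associated miRNA set
#'
#' The five most highly expressed plasma miRNAs known to be abundant in blood
#' cells (erythrocytes: miR-486-5p, miR-92a-3p; other blood cell types:
#' miR-181a-3p, miR-151a-3p, let-7f-5p). Used as the default sentinel set for
#' the haemolysis CV check; fully overridable.
#'
#' @return character vector of miRNA names.
#' @export
blood_cell_mirnas <- function() {
  resolve_blood_set(system.file("extdata", "blood_cell_mirnas.txt",
                                package = "plasmiR"))
}

#' Cohort RNA-mass table (printed fixture)
#'
#' Total RNA mass in micrograms extracted from 5 mL of plasma for each of the
#' 18 cohort donors, as printed in the source cohort's report.
#'
#' @return data frame: `sample_number`, `sample_name`, `total_mass_ug`.
#' @export
plasma_rna_mass <- function() {
  read_tsv(system.file("extdata", "table2_rna_mass.tsv", package = "plasmiR"))
}

#' Ubiquitous plasma miRNAs (printed fixture)
#'
#' The 53 miRNAs detected in all 18 cohort donors with their cohort-mean
#' normalized expression (percent of mapped miRNA reads).
#'
#' @return data frame: `mirna`, `normalised_expression`.
#' @export
ubiquitous_mirnas <- function() {
  read_tsv(system.file("extdata", "table3_ubiquitous.tsv", package = "plasmiR"))
}

#' Summarise the packaged cohort fixtures
#'
#' @param table2 RNA-mass table (defaults to the packaged fixture).
#' @param table3 ubiquitous-miRNA table (defaults to the packaged fixture).
#' @return list: `mean_rna_mass` (µg, half-up rounded to 2 decimals),
#'   `n_ubiquitous`, `max_mirna`, `max_expression`.
#' @export
fixture_summary <- function(table2 = plasma_rna_mass(),
                            table3 = ubiquitous_mirnas()) {
  if (!all(c("sample_name", "total_mass_ug") %in% names(table2)) ||
      nrow(table2) == 0 || any(is.na(table2$total_mass_ug))) {
    stop("malformed RNA-mass fixture")
  }
  if (!all(c("mirna", "normalised_expression") %in% names(table3)) ||
      nrow(table3) == 0 || any(table3$normalised_expression <= 0)) {
    stop("malformed ubiquitous-miRNA fixture")
  }
  imax <- which.max(table3$normalised_expression)
  list(mean_rna_mass = round_half_up(mean(table2$total_mass_ug), 2),
       n_ubiquitous = nrow(table3),
       max_mirna = table3$mirna[imax],
       max_expression = table3$normalised_expression[imax])
}
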