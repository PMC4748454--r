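# plasmiR

Baseline profiling of the circulating plasma miRNAome from small RNA
sequencing.

## The problem

Circulating microRNAs (miRNAs) are heavily studied as minimally invasive
biomarkers, but candidate screens need baseline answers first: which miRNAs
are present in disease-free plasma, at what relative level, how variable
they are between people, and how ordinary covariates — sex, smoking, body
mass index — shift them. plasmiR implements the complete analysis that
produces those answers from raw small-RNA reads, plus a ground-truthed
synthetic cohort generator to validate every step, for bioinformaticians
and biomarker researchers working with plasma (or serum) small-RNA-seq.

## The method

For subject *s* and miRNA *i*, with `n_is` reads assigned to *i* and
`N_s = Σ_i n_is` reads mapped to any miRNA, relative expression is

    x_is = 100 · n_is / N_s        (percent of the mapped miRNA load)

built from the chain:

* **QC** — keep reads with median Phred ≥ Q30; trim the 3′ adapter at the
  leftmost exact match (full adapter internally, or a ≥ 5 nt adapter prefix
  at the read end), repeated to a fixpoint; keep post-trim lengths in
  [15, 35] nt.
* **Tally** — collapse reads to unique-sequence counts.
* **Map** — assign each sequence to a mature reference entry with Hamming
  distance ≤ 1 over the full overlap of the shorter sequence inside the
  longer (handles 3′ length jitter); ambiguous ties are discarded by
  default (configurable: fractional split or first-by-name).
* **Detect** — drop miRNAs with < 10 supporting reads cohort-wide or
  present in < 3 subjects.
* **Describe** — penetrance, top-k load fractions, per-miRNA normal ranges,
  stability ranking by relative SEM (SEM/mean), and a blood-cell-vs-other
  CV comparison as a haemolysis sentinel.
* **Compare** — per-miRNA two-tailed Welch t-tests between covariate groups
  after least-squares elimination of the other factors; Pearson correlation
  of expression with BMI.

See `vignettes/circulating-mirnaome-methods.Rmd` for the full model,
parameter rationale and validation design.

## Worked example

Simulate a small cohort and run the full pipeline:

```r
library(plasmiR)

cfg <- cohort_config(n_subjects = 6, reads_per_subject = 20000,
                     n_mirnas = 50, rng_seed = 42)
cohort <- simulate_cohort(cfg, "readme_cohort")

pcfg <- pipeline_config(
  reference = "readme_cohort/reference.fa",
  reads_dir = "readme_cohort",
  metadata  = "readme_cohort/metadata.tsv",
  out_dir   = "readme_cohort/out")
res <- run_pipeline(pcfg)

res$counts
#> CountMatrix: 50 miRNAs x 6 samples; 90539 reads mapped, 23467 unmapped
#> (policy: discard, max mismatch 1, containment mode)

load_fraction(res$expression_unfiltered, 1)   # 0.5681
load_fraction(res$expression_unfiltered, 10)  # 0.8826

length(penetrance(res$counts)$ubiquitous)     # 50: all detected in all 6

head(res$stats$stability[, c("mirna", "mean", "sem", "dispersion", "rank")], 5)
#>         mirna       mean         sem dispersion rank
#> 1 syn-miR-046  1.2351593 0.073842534 0.05978382    1
#> 2 syn-miR-011  0.1060264 0.006386423 0.06023428    2
#> 3 syn-miR-008 56.8078201 3.438321536 0.06052550    3
#> 4 syn-miR-010  0.5343277 0.039205500 0.07337351    4
#> 5 syn-miR-007  0.1369033 0.012176060 0.08893913    5
```

Reading the output: about 79 % of reads map (the rest are simulated
degradation/noise reads and reads lost to sequencing error), the most
abundant species carries ~57 % of the miRNA load and the top ten ~88 % —
close to the generator's 60 %/90 % targets at this small depth — and the
stability ranking mixes abundant (57 %) and rare (0.1 %) miRNAs, as a
relative-SEM score should. Stage artifacts (QC reports, tallies, count and
expression matrices, stability/range/load-fraction tables, per-factor
differential results, run manifest) are tab-separated files under
`readme_cohort/out/`.

A thin command-line front end over the same functions is included at
`inst/cli/plasmir.R` (subcommands `simulate`, `qc`, `tally`, `map`, `run`).

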