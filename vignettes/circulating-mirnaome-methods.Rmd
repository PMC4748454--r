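---
title: "Methods: baseline profiling of the circulating plasma miRNAome"
author: "plasmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline profiling of the circulating plasma miRNAome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmiR)
```

# Scope and model

plasmiR reconstructs a complete desk-scale analysis of plasma circulating
microRNA (miRNA) small-RNA sequencing data. The scientific setting is the
baseline characterisation of the miRNAome of disease-free human plasma: which
mature miRNAs are present, at what relative level, how variable they are
between subjects, and how sex, smoking and obesity shift them. The analysis
chain is

1. **Read QC** — whole-read retention by *median* Phred quality (default
   threshold Q30), exact 3' adapter trimming, then a 15–35 nt post-trim
   length window (inclusive), the size range expected of mature miRNAs plus
   alignment slack.
2. **Tally** — reads collapse to a unique-sequence count table
   (`sequence → count`), the standard efficiency step for small-RNA data.
3. **Mapping** — each unique sequence is assigned to a mature miRNA
   reference allowing at most one substitution.
4. **Quantification** — relative expression is the percent of a sample's
   mapped miRNA reads attributable to each miRNA
   (`100 × count / mapped_total`), so an unfiltered expression column sums
   to 100. miRNAs supported by fewer than 10 reads cohort-wide or present in
   fewer than 3 subjects are excluded.
5. **Baseline statistics** — penetrance (number of subjects expressing each
   miRNA), top-*k* load fractions, per-miRNA normal ranges (five-number
   summaries), stability ranking by relative SEM, and a blood-cell versus
   other miRNA coefficient-of-variation (CV) comparison, the haemolysis
   sentinel.
6. **Cohort comparisons** — per-miRNA two-tailed t-tests between covariate
   groups (sex, smoking, obesity) with linear-model elimination of the other
   factors, plus Pearson correlation of expression with BMI.

# The mapper

The assignment step is the package's computational core. A query hits a
reference entry when the shorter of the two sequences matches inside the
longer at some ungapped offset with Hamming distance ≤ 1 over the full
overlap ("containment" mode). This tolerates the 3' length jitter that real
small-RNA reads exhibit after adapter trimming — a read one or two bases
shorter than the mature sequence still maps — without admitting gapped or
partial-overlap alignments. An exact end-to-end mode is available
(`mode = "end_to_end"`). `N` bases always count as mismatches.

Ambiguity (two or more entries tied at the minimal distance) is resolved by
policy. The default, `discard`, routes ambiguous counts to the unmapped
total: it is conservative and keeps counts integral. `split` (fractional
division among tied entries) and `first` (lexicographically first tied
entry) are selectable. The implementation is an early-exit exhaustive scan
over entries and offsets written in C++; with mature references of a few
hundred to a few thousand entries this is faster than any index worth
maintaining. Its contract is pinned, for every mode, mismatch budget and
ambiguity policy, to a pure-R exhaustive Hamming oracle in the test suite.

# Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_median_q` | 30 | Phred | retain reads whose *median* base quality is ≥ Q30; whole-read retention, not 3' quality trimming |
| `min_len`, `max_len` | 15, 35 | nt | inclusive post-trim window; shorter/longer reads are unlikely to map to mature miRNAs |
| `min_overlap` | 5 | nt | shortest adapter prefix accepted at the read 3' end; shorter matches are indistinguishable from chance |
| `max_mismatch` | 1 | substitutions | one mismatch absorbs a sequencing error or a common polymorphism without eroding specificity |
| `min_reads` | 10 | reads (cohort-wide) | detection floor; read cohort-wide rather than per sample, since real cohorts contain single-subject miRNAs at low counts |
| `min_subjects` | 3 | subjects | presence floor (presence = count > 0) |
| `alpha` | 0.05 | — | two-sided significance level for group comparisons |
| `topk` | 10 | species | load-fraction report depth |

The even-length median uses the lower-middle order statistic so the Q30
test is integer-exact. Adapter matching is exact-substring: either the full
adapter internally, or an adapter prefix of at least `min_overlap` bases
ending at the read 3' end, truncating at the leftmost such match.
Error-tolerant trimming is deliberately out of scope — the generator plants
adapters error-free, and the QC contract is defined by exact matching.
Within `qc_filter()` trimming is repeated to a fixpoint: a trimmed read
whose new 3' end happens to look like the start of the adapter is trimmed
again. This makes the filter idempotent (re-filtering its own output changes
nothing), at the price of occasionally over-trimming an insert whose own
sequence ends in adapter-like bases — the same ambiguity every exact trimmer
faces, and, in containment mapping, a harmless one for quantification as
long as at least 15 nt remain.

# Quantification choices

After detection filtering, expression columns are *not* renormalised:
values stay as percent of all originally mapped miRNA reads, so the load
fraction of an abundant species keeps its plain interpretation against the
unfiltered total. A `renormalize` flag restores column sums of 100 on the
filtered matrix when closed compositions are preferred.

Stability is scored by relative SEM (SEM/mean) rather than raw SEM: a set
of maximally stable miRNAs should be able to span several orders of
expression magnitude, which raw SEM cannot produce (it simply selects the
lowest expressed). Raw-SEM scoring remains available. Ranks break ties by
higher mean, then name; zero-mean miRNAs have undefined dispersion and are
ranked last and flagged. The top-decile stable set has size
`ceiling(0.10 × n)`.

The set-level CV for the haemolysis check is, by default, the mean of
per-miRNA between-subject CVs — a set-level summary of biological
variation. A pooled-values mode exists; with the two sets differing by
orders of magnitude in mean expression, pooling mostly measures
between-miRNA spread, so it is not the default. The shipped
blood-cell sentinel set is {miR-486-5p, miR-92a-3p, miR-181a-3p,
miR-151a-3p, let-7f-5p} (erythrocyte and general blood-cell miRNAs) and is
fully overridable.

Quartiles in range tables use linear interpolation between order statistics
(R `quantile` type 7); the convention is recorded on the output.

# Cohort comparisons

Group tests are Welch two-sample two-sided t-tests by default (the
pooled-variance form is a flag): with 9-versus-9 groups, assuming equal
variances buys little and risks anticonservatism. No multiple-testing
correction is applied by default — the baseline report is at raw P < 0.05 —
but Benjamini–Hochberg adjustment is one flag away and always reported
alongside. Fold changes are computed on a pseudocount-stabilised scale
(pseudocount = half the smallest nonzero value of the matrix) so that zero
group means keep the ordering finite; both the ≥ 1 magnitude-with-direction
form and a signed log2 form are emitted, since either convention is common.

"Eliminating" the other factors before a comparison means least-squares
residualisation: per miRNA, expression is regressed on the nuisance
covariates (binary-coded), and the residuals plus the miRNA's grand mean
are carried forward. This is the standard statistical reading of
factor-eliminated comparisons; it is linear and additive by construction,
and a rank check fails loudly when covariates are confounded (for example,
if all smokers were female, smoking effects cannot be separated from sex).
Heat-map exports standardise each significant miRNA row to mean 0, SD 1,
clipped to [−2, 2] — the conventional display scale for such figures.

# The synthetic cohort generator

Real plasma small-RNA data have a signature structure the generator
reproduces: a grossly top-skewed abundance profile (the single most
abundant species around 60 % of the mapped miRNA load, the top ten around
90 %), a long tail across several orders of magnitude, between-subject
biological variation, sequencing substitution error, 3' adapter
read-through at a fixed read length (50 nt), a fraction of reads from
degradation products and other small RNAs that map nowhere, and a fraction
of low-quality reads.

Specifics, each chosen once:

* **Profile construction.** Rank 1 carries exactly `top1_target`; ranks
  2–10 share `top10_target − top1_target` by geometric decay (ratio 0.7);
  the tail shares the rest by geometric decay (ratio 0.95), renormalised.
  When a geometric tail would overtake rank 10, the tail decay is flattened
  toward uniform, and if necessary the head decay is flattened to make a
  uniform tail continue it monotonically; genuinely impossible targets
  (for example a 90 % top-10 target with 11 reference entries) fail
  explicitly rather than being silently adjusted.
* **Reference.** Synthetic mature sequences of 20–24 nt with pairwise
  Hamming distance ≥ 3 at equal length, so one-mismatch assignment is
  provably unambiguous and recovery errors are attributable to the pipeline
  rather than to reference degeneracy.
* **Between-subject variation.** Each subject's abundance vector is the
  profile perturbed by lognormal noise with configurable CV
  (`biological_cv`, default 0.3 — a realistic between-subject scale for
  circulating miRNAs and the value used in the power simulations), then
  renormalised. Planted covariate effects multiply a miRNA's abundance by a
  fold change in matching subjects before renormalisation; a haemolysis
  spike does the same for a blood-cell set in one subject.
* **Quality model.** Two components: good reads draw all base qualities
  from Q35–Q40, low-quality reads from Q2–Q28. The median-Q30 screen's pass
  set is therefore knowable exactly, which turns QC accounting tests into
  exact identities instead of tolerances.
* **Reads.** Insert (mature sequence, or random 16–32 nt noise), per-base
  substitution error on the insert only, 3' adapter appended (adapters are
  planted error-free by design), then truncation to the 50 nt read length;
  reads shorter than that are padded past the adapter with a fixed filler
  base, standing in for the sequencer noise real read-through produces
  (always behind the trimmed adapter, hence invisible to the pipeline).
* **Cohort design.** 18 donors, 9 female / 9 male, 4 smokers per sex,
  7 obese females and 2 obese males, obesity called at BMI ≥ 30 (the
  threshold is configurable; the boundary convention is inclusive). Default
  reads per subject is 10^5 — the sequenced cohorts this emulates average
  around 8 million clean reads per sample; the generator scales depth down,
  not structure, and the spec-scale structure (profile, covariates, error
  rates) is unchanged by depth.

What the generator does **not** model: ligation bias, PCR duplicates, UMIs,
isomiR ground truth beyond what containment mapping absorbs, indels,
quality-dependent error profiles, and genome-level background reads.
Passing recovery tests therefore demonstrates that the pipeline measures
what the generator encodes — mapping, accounting and statistical fidelity —
not that it is robust to every artefact of real library preparation.

# Validation design and problem sizes

The test suite validates at three levels, with sizes chosen to keep the
default run in minutes:

* **Oracle equivalence.** The C++ mapper against a pure-R exhaustive
  Hamming scan (20 random references × 1 000 mutated reads, every
  ambiguity policy, plus end-to-end and zero-mismatch variants); the
  detection filter against a double-loop oracle (200 randomised matrices);
  SEM, quantiles and trimming against textbook re-implementations.
* **Recovery.** An 18-subject cohort at 10^5 reads/subject (top-1 target
  0.60, top-10 target 0.90, substitution error 0.005) run through the full
  pipeline from FASTQ; the recovered top-1 and top-10 load fractions are
  required within ±0.02 of target and per-miRNA mean expression within
  ±0.5 percentage points of the realized truth for miRNAs at ≥ 1 %
  abundance. This recovery cohort uses `biological_cv = 0.1` rather than
  the 0.3 default: a prior power analysis of the renormalised-abundance
  arithmetic alone showed that at CV 0.3 the cohort-mean top-1 fraction
  carries a sampling SD of ≈ 0.018 (plus a small renormalisation bias), so
  a ±0.02 recovery band would mostly measure cohort sampling noise; at CV
  0.1 the band cleanly measures pipeline fidelity.
* **Operating characteristics.** Planted 4-fold effects at 9 versus 9
  subjects with 30 % lognormal CV over 500 simulations (recovery of planted
  miRNAs at α = 0.05), 1 000 null miRNAs (empirical size against the
  nominal 0.05), and a planted two-class dispersion design for the
  stability top-decile (precision of the low-dispersion class).

`scripts/acceptance.R` re-runs these computations from scratch against the
installed package and writes the resulting quantities as JSON.

# Numerical and degenerate-input conventions

* Even-length medians: lower-middle value.
* Tally serialisation: descending count, ties lexicographic by sequence —
  files are reproducible byte for byte.
* Zero mapped totals fail normalisation loudly, naming the sample.
* Zero-variance miRNAs in a t-test are flagged and excluded from the
  significant set; zero-mean miRNAs rank last in stability.
* All generator functions take explicit seeds, restore the caller's RNG
  state, and derive per-subject child seeds reproducibly, so a cohort is
  bit-identical given its configuration.
* Determinism contracts for gzipped FASTQ are stated on content (parsed
  records), with byte-identity guaranteed for uncompressed output.

# Known limitations

* The mapper is ungapped: indel-bearing reads are unmapped rather than
  recovered.
* Containment mode requires full containment of the shorter sequence;
  partial overlaps (dovetails) never match.
* Factor elimination is linear-additive; interaction or non-linear
  confounding passes through.
* With 18 subjects the group comparisons are calibrated (type-I error near
  nominal) but not powerful for fold changes much below 2 at 30 % CV;
  conclusions at that scale need larger cohorts.
* The detection filter's cohort-wide read threshold is one of two
  defensible readings of a "fewer than 10 reads" exclusion; the per-sample
  reading is available as a flag.
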