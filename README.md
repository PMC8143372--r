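# plasmaSCNA

Copy-number profiling of circulating tumor DNA (ctDNA) from shallow
whole-genome plasma sequencing, with focal somatic copy-number alteration
(SCNA) calling, tumor-fraction estimation, resistance-gene annotation, and
the cohort-level statistics used to relate plasma SCNAs to treatment
outcome in EGFR-mutated lung adenocarcinoma.

## The problem

In advanced *EGFR*-mutated non-small-cell lung cancer, resistance to the
third-generation TKI osimertinib is driven both by *EGFR*-dependent
mechanisms (e.g. the C797S mutation) and by copy-number events in bypass
and cell-cycle genes — focal amplifications of *EGFR*, *ERBB2*, *MET*,
*CDK4/6*, *MDM2*, *AKT2*, *PIK3CA* and deletions of *CDKN2A* or *RB1*.
These resistance-related SCNAs (rrSCNAs) can be read directly from plasma:
cell-free DNA is sequenced at shallow genome-wide coverage (~0.1x), reads
are counted in 50 kb windows, and copy-number profiles are derived from
count ratios against a healthy-control panel. This package implements that
pipeline end to end, together with a synthetic-data generator that
reproduces the statistical structure of such cohorts so every stage is
testable without access to protected sequencing data.

## The method

**Per-bin model.** For a locus present at `c` copies in the tumor and a
plasma tumor fraction `TF`, the expected depth ratio against a diploid
reference is

    r(TF, c) = (TF * c + (1 - TF) * 2) / 2,   log2 r(1, 3) = 0.58

Counts in 50 kb bins are normalized by library size, corrected for GC
content by local regression, divided by the per-bin median of a
healthy-control panel, and segmented by exact penalized least-squares
change-point detection.

**Focal amplification criteria.** A segment is a focal amplification iff
it is < 20 Mb; mean log2 ratio > 0.2; contains 1–100 genes; exceeds the
length-weighted mean log2 of the 20 Mb flanks by ≥ 0.2 (if it contains a
known driver gene) or ≥ 0.58 (if not); is ≤ 50% covered by segmental
duplications; and does not match a known common CNV (reciprocal-50%
overlap by default). Focal deletions mirror this with mean log2 < −0.2, a
single neighbor-delta threshold of 0.2, and the requirement of a known
deletion-target gene. Focal events intersected with the direction-aware
resistance gene list yield the sample's rrSCNAs.

**Tumor fraction.** A 7-state (copies 0–6) Viterbi grid search over TF at
1 Mb resolution, with Gaussian emissions centered at `log2 r(TF, c)`,
sticky transitions, and a parsimony prior on non-diploid states. Samples
with TF < 3% are reported censored (`<3.0%`) — below that, focal SCNA
detection is unreliable.

**Cohort statistics.** ddPCR positivity (> 1 mutant copy/mL), the
evaluability gate (excluded iff TF < 5% *and* no SCNAs), chi-square and
Fisher tests, Mann–Whitney U, Spearman correlation with a censored-TF
policy, Kaplan–Meier medians, log-rank tests, and Cox proportional-hazards
models (Efron ties) with stepwise backward elimination.

## Worked example

Simulate a plasma sample at 5% tumor fraction carrying a 20-copy focal
*EGFR* amplification plus arm-level events, and run the full analysis:

```r
library(plasmaSCNA)

gm <- make_genome(4, 6e7, seed = 2)            # scaled synthetic genome
egfr <- subset(gm$genes, name == "EGFR")
events <- rbind(
  sim_event(egfr$chrom, egfr$start - 4e5, egfr$end + 4e5, copies = 20),
  sim_event("chr2", 5e6, 45e6, copies = 3),    # arm-level gain
  sim_event("chr3", 20e6, 50e6, copies = 1)    # arm-level loss
)
raw <- simulate_counts(gm, events,
                       sim_config(tumor_fraction = 0.05,
                                  total_reads = 6.5e6, seed = 7), "case")
panel <- simulate_control_panel(gm, 5, sim_config(seed = 11))
res <- analyze_sample(raw, panel, annotation_from_genome(gm))

res$tf
#> <tf_estimate> TF = 4.5% (raw 0.045), detectable, 238 bins, logLik 639.3
res$focal_events[, c("chrom", "start", "end", "mean_log2", "direction", "genes")]
#>   chrom    start      end mean_log2     direction genes
#> 1  chr1 46200000 47100000 0.5375702 amplification  EGFR
res$rrscna_genes
#> [1] "EGFR"
```

The estimated tumor fraction (4.5%) recovers the simulated 5%, and the
focal caller isolates the sub-megabase *EGFR* amplification at log2 0.54
— an amplitude far above the single-copy arm-level gain (log2 ≈ 0.035 at
this TF), which is why focal events remain detectable at tumor fractions
where gross SCNAs are not.

Cohort-level analysis of the bundled 43-patient reference tables:

```r
rec <- build_patient_records(
  read_cohort(cohort_fixture_path("mutations"), "mutations"),
  read_cohort(cohort_fixture_path("ddpcr"), "ddpcr")
)
summarize_cohort(rec)
#> <cohort_summary> 43 patients (31 evaluable, 12 excluded)
#>   pre-treatment rrSCNAs: 10 of 31 evaluable
#>   detection pre:  activating 34, T790M 43, C797S 0
#>   detection post: activating 30, T790M 17, C797S 8
#>   triple-positive post: 7; C797S with rrSCNAs: 3
#>   median TF: rrSCNA 17.0%, no rrSCNA 5.1%

chi_square_2x2(matrix(c(17, 4, 5, 5), 2, byrow = TRUE))$p_value
#> [1] 0.0759292
```

Patients with pre-treatment rrSCNAs respond less often (50% vs 81%,
chi-square p = 0.08) and carry much higher plasma tumor fractions (median
17.0% vs 5.1%).

## Package layout

- `R/genome.R`, `R/simulate.R`, `R/cohort-sim.R` — synthetic genomes,
  binned count profiles, control panels, clinical cohorts
- `R/profile.R`, `R/segment.R` — binning, normalization, GC correction,
  control normalization, rebinning, segmentation
- `R/focal.R` — the focal amplification/deletion rule engine
- `R/tumor-fraction.R` — the TF estimator and detection gate
- `R/cohort.R` — ddPCR calls, rrSCNA classification, evaluability, cohort
  table dialects, summaries
- `R/stats.R` — association tests and survival analysis
- `R/benchmarks.R` — the standard validation experiments
- `vignettes/plasma-scna-methods.Rmd` — the methods vignette
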