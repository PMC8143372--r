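---
title: "Methods: focal SCNA profiling of plasma ctDNA from shallow WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focal SCNA profiling of plasma ctDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaSCNA)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the
numerical behavior required a decision.

## 1. The measurement model

Cell-free DNA in plasma is a mixture: a fraction `TF` (the tumor fraction)
derives from tumor cells, the rest from normal (diploid) cells. If the
tumor carries `c` copies of a locus, the expected sequencing depth at that
locus, relative to a diploid reference, is

$$ r(\mathrm{TF}, c) \;=\; \frac{\mathrm{TF}\cdot c + (1-\mathrm{TF})\cdot 2}{2}. $$

`expected_log2()` is this quantity on the log2 scale, and it anchors
everything else: a pure-tumor three-copy gain sits at
`log2(3/2) = 0.585`, which rounds to the 0.58 used as the non-driver
amplitude threshold in the focal criteria; a 20-copy focal amplification
at `TF = 0.03` still produces `log2 r = 0.26`, which is why focal events
remain visible at tumor fractions where single-copy (arm-level) changes
are lost in the noise.

Shallow WGS reduces to counts of read starts in non-overlapping 50 kb
windows. The per-bin expected count is proportional to bin length,
sequencing depth, a GC-dependent library efficiency, and
`r(TF, c)`; the count noise family of real plasma libraries is not
settled, so the simulator exposes it as a parameter
(`overdispersion = 0`, i.e. Poisson, by default; negative binomial with
variance `mu + phi mu^2` otherwise) rather than asserting one.

## 2. Per-sample profiling

The profiling chain is `bin_counts()` (or `simulate_counts()`) →
`normalize_total()` → `gc_correct()` → `control_normalize()` →
`segment_profile()`.

**GC correction** fits a `lowess` curve (span 0.3) of the normalized
ratio on bin GC fraction across mappable bins and divides it out,
rescaling by the median so an unbiased profile passes through nearly
unchanged. The fitted curve is floored at `1e-6` of the median ratio so
the division can never blow up on dropout bins. The span is exposed;
0.3 is smooth enough that a 1–2 Mb amplification cannot carve its own
dip into the curve, yet flexible enough to absorb the curved dropout at
GC extremes.

**Control normalization** divides by the per-bin *median* ratio of a
healthy-control panel processed through the same stages — the median
because a panel of ~5–10 donors must tolerate one aberrant control. Bins
whose panel baseline falls below 5% of the median baseline are flagged
unusable; ratios are clipped at `1e-6` before the log. Re-running
`control_normalize()` on a profile that already has log2 ratios is an
error: double normalization would silently halve every amplitude.

**Segmentation** minimizes, per chromosome, the penalized weighted
least-squares cost `sum SSE_w + penalty * (#segments − 1)` by exact
dynamic programming (optimal partitioning). This was chosen over
CBS-style recursive splitting because it is deterministic, exactly
optimal for its cost function, and therefore checkable against an
exhaustive enumeration oracle at small n — the test suite certifies
equality of the optimal cost on all admissible partitions up to 14 bins.
Bins are weighted by length, so a short terminal bin is kept but cannot
dominate a breakpoint. The default penalty is `4 sigma^2 log n` with
`sigma` estimated robustly from the median absolute first difference;
plain BIC (`2 sigma^2 log n`) proved too lenient, splitting flat
stretches on noise excursions, while the doubled constant leaves a
0.6-log2 step in 0.1-noise recovered to within two bins. `min_bins = 3`
(150 kb) suppresses single-bin segments, which at 50 kb resolution are
indistinguishable from alignment artifacts.

## 3. Focal SCNA criteria

`call_focal_amplifications()` emits a segment iff **all** of:

1. length < 20 Mb;
2. mean log2 > 0.2;
3. 1–100 overlapping genes (gene content distinguishes a focal event
   from a gene desert and from a mislabeled arm);
4. mean log2 exceeds the length-weighted mean of the segments overlapping
   the 20 Mb flanks on both sides by ≥ 0.2 when the segment contains a
   known tumor driver gene, and by ≥ 0.58 (about three copies in pure
   tumor) when it does not;
5. segmental duplications cover ≤ 50% of the segment;
6. no match in the common-CNV (DGV-style) track.

Deletions mirror this with mean log2 < −0.2, a single neighbor delta of
≥ 0.2 *below* the flanks, and the additional requirement that the
segment contain a gene known to be affected by deletions (`CDKN2A`,
`RB1`, `PTEN` by default). Criteria are evaluated in a fixed
short-circuiting order (size, amplitude, gene content, deletion target,
neighbor delta, segmental duplications, common CNVs); the order is
visible only in the per-segment filter record, never in the called set,
and the test suite verifies the caller against a literal brute-force
checker on randomized profiles whose segment means cluster around the
decision boundaries.

Open points resolved here: "not more than 100 genes" is interpreted as
≤ 100 passing; "contains a gene" as ≥ 1 bp overlap; and the common-CNV
veto as a *reciprocal* 50% overlap with any single entry
(`dgv_mode = "reciprocal"`), because a literal any-overlap rule would
veto nearly every segment given the density of catalogued CNVs — the
literal mode remains available as `dgv_mode = "any"`, and the fraction is
configurable. At chromosome ends the available flank is used; a segment
with no covered flank falls back to the chromosome-wide mean excluding
itself (0 for a lone segment), so terminal segments are judged rather
than crashed on. Both neighbor-delta rules are applied *in addition to*
the absolute amplitude rule, so a segment sitting on an already elevated
arm must still stand out from that arm.

## 4. Tumor fraction

`estimate_tf()` is deliberately a desk-scale estimator, not a
re-implementation of the published HMM tool it stands in for: no
subclonal states, no ploidy search, no panel-of-normals beyond the
control normalization. It models 1 Mb log2 ratios with seven integer
copy states (0–6), Gaussian emissions centered at
`expected_log2(TF, c)` with one shared robust SD (MAD, floored at
`1e-3`), self-transition probability 0.99 (events at 1 Mb span many
bins), and maximizes the joint Viterbi score over a TF grid (step 0.005,
range 0–0.6), breaking ties toward the smaller TF so a flat profile is
called 0.

Three numerical choices matter:

- **Mode recentering.** Large aberrations shift the copy-neutral level of
  a total-count-normalized profile (the ploidy/centering effect); the
  estimator recenters the ratios at their density mode first, assuming
  most of the genome is copy-neutral. Profiles in which aberrant bins
  outnumber neutral ones would defeat this assumption.
- **Parsimony prior.** Per bin, a state prior `exp(-lambda |c - 2|)` with
  `lambda = 0.5`. Without it the likelihood cannot distinguish
  `(TF, c = 3)` from `(TF/2, c = 4)` — the fits are *identical* — and the
  smaller-TF tie-break would systematically halve estimates. The prior
  resolves the alias toward the fewer-extra-copies explanation. The value
  0.5 sits below the per-bin likelihood gain of the smallest aberration
  the estimator should resolve (a single-copy gain at 3% TF yields a gain
  of ~1.5 at the observed 1 Mb noise), so it breaks ties without
  suppressing real events; a prior of 1 measurably biased low-TF samples
  toward aliased higher fractions.
- **Outlier masking.** Isolated extreme bins (residual from a 5-bin
  running median beyond `max(6 MAD, 0.3)`) are excluded before fitting.
  A 20-copy focal amplification confined to one 1 Mb bin is regionally
  at a very high tumor fraction, and a single such bin can otherwise
  hijack the genome-wide estimate; reading sub-megabase events is
  exactly the division of labor assigned to the 50 kb focal caller.

The 3% detection gate (`detectable_for_focal()`) and the censored
`"<3.0%"` rendering reflect that focal calling below 3% TF is
unreliable; the raw estimate is always retained internally, and the
cohort tables round-trip the censored form.

## 5. Patient annotation and cohort statistics

ddPCR assays are positive strictly above 1 mutant copy/mL. rrSCNA
classification intersects focal amplifications with the amplification
gene set (`EGFR, ERBB2, MET, CDK4, CDK6, MDM2, AKT2, PIK3CA`) and focal
deletions with the deletion set (`CDKN2A, RB1`); the lists are arguments,
since any literature-derived resistance list evolves. A patient is
excluded from outcome analyses iff the pre-treatment TF is below 5%
*and* no SCNAs at all were detected — with a low TF and a quiet genome,
the absence of rrSCNAs cannot be asserted. A censored `"<3.0%"` TF
counts as below 5%; a TF of exactly 5% does not. Note the distinction
the gate relies on: *any* focal SCNA keeps a patient evaluable even if
none of them touches a resistance gene.

For rank statistics on tables with censored TF entries, every `"<3.0%"`
value enters at a common 2.9% (ties, average ranks). Any common value
below the smallest uncensored observation gives identical ranks, so the
statistic is insensitive to the exact choice; 2.9 keeps the substitute
on the natural scale. The response comparison defaults to Pearson
chi-square *without* continuity correction (Fisher's exact test is also
provided and reported alongside); Cox models use Efron tie handling,
Wald confidence intervals, and a convergence flag instead of silent
output; stepwise backward elimination removes the worst covariate with
term-level Wald p above `p_remove = 0.10` (the common statistics-package
default) until none remains removable, and an empty retained set is a
reported outcome, not an error.

## 6. What the synthetic cohort generator emulates

`simulate_cohort()` reproduces the *statistical structure* the analysis
consumes: rrSCNA prevalence 10/31 ≈ 0.32; group-wise log-normal tumor
fractions with medians near 17% (rrSCNA-positive) and 5%
(rrSCNA-negative), sd 0.45 on the log scale, clipped to [0.5%, 60%];
ddPCR copy numbers coupled to TF through a Gaussian copula calibrated to
a Spearman correlation of 0.46 (activating mutation) and 0.30 (T790M);
response probabilities 0.81 / 0.50 by rrSCNA status; exponential PFS and
OS with baseline medians 10.4 and 18.7 months whose hazards are
multiplied by `hr_rrscna` (default 3.33) and `hr_os` (2.54) in the
rrSCNA-positive group; administrative censoring at the 38.4-month
follow-up horizon; and null clinical covariates with realistic
marginals. It does **not** emulate correlated covariate effects (tissue
genotype is generated null even though it can be prognostic in real
cohorts), non-proportional hazards, dropout, or inter-assay ddPCR error
— so passing parameter-recovery tests demonstrates correctness of the
estimators under the stated model, not robustness to real-world
violations of it.

All randomness flows from one master seed through a splittable keyed
hash (`derive_seed()`), so adding a replicate to one experiment never
perturbs another.

## 7. Validation experiments and problem sizes

The standard experiments (exported as `benchmark_*()`, used by both the
test suite and `scripts/acceptance.R`) run on a scaled-down genome of 6
chromosomes × 80 Mb — 9,600 bins at 50 kb, 480 at 1 Mb — with ~6–6.9M
reads per library, giving per-bin depths comparable to shallow plasma
WGS, and a 5-donor control panel:

- **Focal spike-in recovery**: driver-gene amplifications spiked at
  (TF, copies) pairs (0.03, 16), (0.05, 10), (0.10, 6) — all with
  expected log2 ≥ 0.25 — must be recovered by segmentation plus the
  amplification criteria in ≥ 90% of 50 replicates.
- **TF recovery**: a fixed aberration set with gains at 5 and 3 copies
  and one single-copy loss (mixed levels pin the fraction uniquely; a
  single gained level is aliased by design) across true TFs 0.05–0.40,
  recovered within ±0.05 and strictly monotone.
- **Null calibration**: 10 simulated healthy controls, median estimated
  TF ≤ 2% with at least 4 at exactly 0.
- **GC decorrelation**: an injected linear bias leaves |Spearman rho|
  < 0.05 after correction.
- **Cox recovery**: median estimated hazard ratio over 5 cohorts of 500
  patients within ±15% of the true 3.33 (the median because a single
  replicate's sampling SE of the log hazard ratio, ~0.09, would make a
  ±15% check mostly a coin flip).
- **Log-rank calibration**: rejection rate at the 0.05 level on null
  cohorts, checked over 2,000 replicates so the Monte-Carlo error of the
  *estimate* (~±0.005) is small against the 0.03–0.07 acceptance band —
  at a few hundred replicates the band would mostly test simulation
  noise rather than the statistic.
- **Stepwise selection**: with one truly prognostic covariate among the
  full clinical set, the prognostic covariate must always be retained.
  The *exact* retained set equals the single prognostic covariate only
  about half the time — with six null covariates each surviving with
  probability ≈ `p_remove = 0.10`, the expected exact-set rate is
  bounded near `0.9^6 ≈ 0.53`. This is a property of stepwise selection
  at that threshold, not of the implementation; both rates are reported.

## 8. Known limitations

- The TF estimator assumes a mostly copy-neutral genome (mode
  recentering) and integer clonal copy states up to 6; heavily aneuploid
  or strongly subclonal samples violate both.
- Focal criteria operate on segments; an amplification split across a
  segmentation breakpoint can fail the amplitude or gene-content rule
  even when its union would pass.
- The simulator draws independent bin counts; real libraries carry
  wave artifacts and fragment-size effects that GC correction only
  partially removes.
- The per-patient survival analysis of a real cohort requires
  per-patient event times, which published tables typically do not
  include; survival methods here are therefore validated by parameter
  recovery on simulated cohorts, not by reproducing published hazard
  ratios.
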