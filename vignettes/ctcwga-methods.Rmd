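---
title: "Methods: WGA artifact filtering and CTC mutation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGA artifact filtering and CTC mutation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcwga)
```

## The analytical problem

Circulating tumor cells (CTCs) are rare; after size-based enrichment a
blood sample yields nanogram DNA inputs dominated by leukocyte DNA, so the
material must be whole-genome amplified (WGA) before amplicon panel
sequencing. WGA creates artifactual variant calls at low allele frequency.
Empirically these split into two populations: *recurrent* errors — the
same `chrom:pos:ref>alt` key appearing across independently amplified
samples, presumably at loci structurally prone to polymerase error — and
*random, non-recurrent* errors scattered across the panel. Genuine
tumor-derived variants in a CTC sample sit at a VAF of roughly
`tumor_fraction × true allele fraction`, i.e. a few percent, uncomfortably
close to the artifact band.

`ctcwga` implements a filtering cascade that exploits three independent
sources of evidence: amplified *normal* controls (artifacts only, by
construction), the matched primary tumor (an orthogonal, unamplified call
set), and independent WGA replicates of the same CTC capture.

## The cascade

**Artifact characterization.** For each of the control patients, variants
in the WGA-amplified normal absent from the matched unamplified normal
(set difference on normalized keys) are amplification errors. A key enters
the recurrent-error **blacklist** iff it occurs in at least
`min_recurrence` distinct control samples. "Recurrent" is not given a
precise definition in the liquid-biopsy literature; we adopt the weakest
defensible one — two independent occurrences — and expose it as a
parameter. `summarize_error_vafs()` partitions *all* error observations
(before any VAF thresholding) into recurrent/non-recurrent and reports the
median VAF of each; an empty partition yields `NA`, never a fabricated
zero.

**False-positive match rate.** Threshold-passing, non-blacklisted control
errors are pure artifacts; the fraction of them that match a somatic
variant of the same patient's tumor (`100 · n_match / n_total`, one
decimal) estimates the probability of misclassifying an artifact as a
tumor-derived CTC mutation. We also report the pre-blacklist count, since
either accounting of the denominator is defensible.

**Calling.** Per CTC sample: (1) remove blacklisted keys; (2) keep VAF
strictly greater than `min_vaf` (default 0.01 — the boundary value 1% is
*removed*, reading "keep > 1%" literally); (3) intersect with the matched
tumor. Stages (1) and (2) are key/VAF predicates and commute; matching is
placed last so the per-stage funnel counts (`filter_trace`) are maximally
informative. The funnel is asserted monotone on every run.

**Replicate-concordant private calls.** Tumor-matched calling is
deliberately blind to CTC-private subclones. Where two independent WGA
replicates of one capture exist, variants present in both, absent from the
blacklist and from the tumor, are reported as candidate disseminated-
subclone mutations, at the mean of the two replicate VAFs.

**Variant matching semantics.** Matching is exact on the normalized key:
common suffix trimmed, then common prefix (position advancing), one anchor
base retained for indels; no position-window fuzziness, because exactness
is reproducible and an uncertainty window would need a model we cannot
estimate from panel data. Pure allele trimming cannot left-align an indel
through a repeat run it does not span — full left-alignment would require
the reference sequence, which variant tables do not carry. Consequently
two representations of an insertion inside a homopolymer may normalize to
different keys; `variants_match()` is still an equivalence relation, and
the property suite tests exactly that (not the stronger, false claim that
any padded representation matches).

## Downstream statistics

**Spectrum.** SNVs are collapsed onto the pyrimidine-reference strand
(G>A → C>T, etc.), giving the conventional six classes. We do not use
96-trinucleotide contexts: a ~110 kb panel yields far too few SNVs to
stabilize 96 bins, and context normalization by panel composition would
dominate the signal. A 12-class mode (`collapse = FALSE`) is available.
Zero SNVs is an error, not an all-zero profile. Ties in
`dominant_class()` break toward the fixed class order.

**Clinical association.** The analysis unit is the tumor-matched CTC
variant VAF. Two modes exist because the variant-to-observation mapping
behind this kind of analysis is genuinely ambiguous:

* `mode = "pooled"` (default): every call is an observation. This matches
  scatter-style presentations with many points per group, but observations
  within a patient are correlated (they share the latent tumor fraction),
  so pooled p-values are anti-conservative and should be read as
  descriptive.
* `mode = "patient"`: each patient contributes their median AF;
  observations are independent and the tests hold their nominal size. The
  null-calibration test in the suite runs in this mode for precisely that
  reason (under a zero-slope clinical model, rejection at α = 0.05 over
  1,000 small cohorts is required to sit in 0.05 ± 0.02).

CEA is dichotomized at 5 ng/ml (the conventional abnormality cutoff;
≥ 5 is "high", missing values are excluded). Two groups use our
Mann-Whitney U: exact two-sided p by enumeration of the null U
distribution when `min(n, m) ≤ 8` and there are no ties, otherwise the
normal approximation with tie-corrected variance and 0.5 continuity
correction; identical inputs across groups give the degenerate p = 1.
Dukes' stage (up to 4 levels) uses `stats::kruskal.test`, age uses
Spearman correlation with asymptotic p. The four variables are reported
raw, without multiplicity correction — four tests on one cohort are
presented as exploratory.

## Read-level refinements

Amplicon products of ~158 bp sequenced 2 × 150 bp overlap by
`2 × 150 − 158 = 142` bp, so almost every base in the product is observed
twice. No published formula exists for combining the two observations in
this setting; we adopt the convention of overlap-consensus tools, which is
simple, monotone and auditable:

* agreement: both mates get `min(q1 + q2, 60)`;
* disagreement: the higher-quality mate keeps `max(q_hi − q_lo, 2)`, the
  other drops to Q2; on a tie, mate 1 is deemed the keeper and both drop
  to Q2 (a deterministic, maximally conservative tie-break);
* bases are never edited; non-overlapping positions are untouched; output
  qualities live in [2, 60].

The operation saturates rather than being idempotent: a second application
can move interior values, but positions at the cap or floor stay fixed —
the property suite asserts saturation, not idempotence.

Primer trimming compares each read's sequencing-orientation 5′ prefix to
every primer designed for the same chromosome by Hamming distance and
hard-trims the longest prefix with mismatch fraction ≤ 0.20 (so 4/21
mismatches trims, 5/21 does not); at most one trim per read. We remove
bases rather than soft-masking qualities, guaranteeing primer bases never
enter a pileup; forward-strand alignment starts advance by the trimmed
length, reverse-strand starts are unchanged (the trimmed bases are the
reference-orientation 3′ end). Whether to trim by removal or masking is an
open choice in amplicon pipelines; removal is the auditable one.

## The synthetic cohort generator

`cohort_config()` defaults *are* the study conditions the pipeline
targets, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 48 | cohort size of the target study design |
| `n_genes`, `total_length` | 39, 110 kb | colorectal amplicon panel scale |
| `n_amplified_normals` | 14 | WGA control arm size |
| `recurrent_vaf_median` | 0.005 | recurrent-error median VAF 0.5% |
| `random_vaf_median` | 0.010 | random-error median VAF 1% |
| `vaf_dispersion` | 0.8 | lognormal σ; keeps VAFs positive and right-skewed, with half of the random errors clearing the 1% threshold |
| `random_errors_per_amplified_normal` | 275 | ≈ 137 threshold-passing errors per control (≈ 1,915 across 14 controls) |
| `random_errors_per_ctc` | 150 | ≈ 75 threshold-passing errors + ~7 tumor-derived calls ≈ 84 retained per CTC sample |
| `n_recurrent_hotspots`, `hotspot_occurrence_prob` | 400, 0.5 | cohort-global hotspot set; per-sample Bernoulli occurrence |
| `ctc_positive_fraction` | 0.60 | fraction of patients whose CTC samples carry tumor DNA |
| `tumor_fraction_range` | 0.05–0.40 | latent tumor DNA fraction in positive captures |
| `tumor_mutations_mean` | 12 | Poisson mean somatic mutations per tumor |
| `coverage_mean`, `coverage_dispersion` | 400, 0.2 | negative-binomial per-locus depth, median ≈ 400× |
| `cea_intercept`, `cea_slope` | −2, 12 | logistic link P(CEA ≥ 5) vs tumor fraction; slope makes the association recoverable in direction |
| `ct_mass` | 0.45 | C>T mass among tumor SNVs; remaining five classes equal |

Distributional choices: error VAFs are lognormal parameterized by their
*median* (only medians are reported for WGA artifact populations; the
lognormal is the natural positive right-skewed family); error
`alt_count = round(vaf × depth)` with unobservable draws
(`alt_count == 0`) censored — which nudges the recovered recurrent median
a few percent above 0.005, an honest property of the observation model,
not a bug; tumor-derived CTC alt counts are Binomial(depth,
`tumor_fraction × true_vaf`). The CTC-positive subset is an exact
`round(fraction × n)` count rather than per-patient Bernoulli, so the
cohort-level detection proportion is reproduced deterministically. Every
patient receives `n_wga_replicates` CTC samples (negatives at tumor
fraction 0), since blood is processed for the whole cohort. A
`subclone_prob` flag plants an occasional CTC-private mutation shared by
both replicates, exercising the replicate-concordant caller.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: alignment and variant-calling error
(inputs are variant tables, not reads), sequence-context-dependent error
rates (hotspots are uniform in the panel; real WGA errors cluster by
context), copy-number variation (CNV records pass through as annotations
only), subclonal tumor phylogenies, germline variation in the normals, and
batch effects between WGA chemistry lots. Parameter-recovery results show
the cascade is *internally consistent* at study scale, not that the study
numbers are externally reproduced.

## Numerical and degenerate-input conventions

* VAF is always re-derived from counts (`alt_count / depth`); a supplied
  `vaf` column is checked to 1e-6.
* The AF threshold is strictly exclusive at `min_vaf`.
* Rates are rounded to one decimal in percent; detection percentages to
  the nearest integer; spectrum frequencies are exact fractions.
* `estimate_fp_match_rate()` with an empty denominator, a spectrum with
  zero SNVs, a blacklist from fewer than two controls, and an association
  with fewer than two non-empty groups are all *errors*, not silent zeros.
* All randomness flows from a single integer seed in the configuration;
  cohorts are byte-identical across runs of the same config.

## Problem sizes

The test suite exercises the full 48-patient default cohort for parameter
recovery, and deliberately small cohorts elsewhere: toy cohorts of ≤ 5
samples × ≤ 20 variants for brute-force oracle comparisons, 30-patient
cohorts with a 5 kb panel for the 1,000-replicate null calibration, and
exhaustive enumeration of all group assignments up to n + m = 10 for the
Mann-Whitney oracle. These sizes were chosen to make the oracles exact and
the distributional checks statistically decisive.

## Known limitations

* Matching cannot reconcile indel representations across repeat runs
  without a reference genome (see above).
* The blacklist is allele-level; a position-level (allele-agnostic) filter
  would be stricter but is not implemented.
* Pooled-mode association p-values are anti-conservative under
  within-patient correlation; use `mode = "patient"` for inference.
* The false-positive match rate is estimated from the control arm and
  assumes CTC artifact behavior matches amplified-normal artifact
  behavior.
* SAM support is the minimal dialect this package writes (ungapped
  alignments, 11 mandatory columns); it is a fixture format here, not a
  general-purpose parser.
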