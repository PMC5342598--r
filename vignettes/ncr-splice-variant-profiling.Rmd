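---
title: "Profiling NKp44 and NKp30 splice variants: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling NKp44 and NKp30 splice variants: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncrprofile)
```

## The biological question and the measurement model

The natural cytotoxicity receptors NKp44 (NCR2) and NKp30 (NCR3) are
expressed as splice variants with opposing functional roles: NKp44-1
carries an ITIM and can inhibit NK-cell function, while NKp44-2 and
NKp44-3 lack it; NKp30a and NKp30b signal activation while NKp30c is
linked to IL-10 and immunosuppression. `ncrprofile` turns bulk
transcript measurements of these variants into categorical
inhibitory/activating profile calls per sample, and into cohort-level
incidence and distribution statistics.

Two measurement routes feed the same downstream machinery.

**qPCR.** Each well yields a cycle threshold (Ct). Replicates for a
sample × assay are averaged over the *detected* wells; only when every
replicate is undetected is the aggregate undetected. This treats partial
detection as detection, which is deterministic and conservative toward
positivity — an undetected well in an otherwise detected triplicate is
more plausibly a pipetting failure than true absence. Relative expression
is the textbook \(2^{-\Delta Ct}\) against β-actin. The published primer
efficiencies for this panel all sit within a few percent of 100 (98.4 to
104.4), which is the regime where the uncorrected \(2^{-\Delta Ct}\)
estimator is standard practice; the efficiencies are carried as metadata
(`assay_metadata()`) and no efficiency correction is applied.

**RSEM tables.** TCGA-style `rsem.isoforms.normalized_results` /
`rsem.gene.normalized_results` files are read per sample, with a manifest
mapping barcodes to files. Sample type is the leading two digits of the
fourth dash-separated barcode section (so `TCGA-AB-2842-03A-…` is type
`03`); only `01` (primary solid tumor, PST) and `11` (solid tissue
normal, STN) enter the analysis. Study codes map to organ clusters
(Breast; Lung; Cervical/Uterine; Kidney; GI tract; GI accessory organs),
and the map is replaceable. Isoform identifiers are annotation-dependent,
so the isoform→variant map ships as an editable TSV
(`inst/extdata/variant_map_synthetic.tsv` documents the format); the
built-in synthetic identifiers are used by the generator and tests.

## From expressions to profiles

For variant expressions \(e_1, e_2, e_3\) the composition is
\(\mathrm{pct}_i = 100\, e_i / \sum_j e_j\). The denominator is
deliberately the **sum of the variant measurements**, not the
receptor-total assay: the total primer measures an overlapping amplicon
with its own efficiency, and dividing by it would not guarantee a
composition summing to 100. With the variant-sum denominator the
percentages are a well-defined composition (sum \(=100\pm10^{-9}\),
scale-invariant), and the qPCR and RSEM branches become structurally
identical — RSEM has no "total primer" to divide by in the first place.
The receptor-total qPCR assay is used for what it is good at: positivity.
Both conventions are reachable in principle, but the variant-sum is the
package default and the one all reported numbers use.

Positivity is route-specific:

* qPCR: positive iff the receptor-total assay has a detected aggregated
  Ct ≤ `max_cycles` (default 40 cycles, boundary inclusive). Forty cycles
  is the conventional end of a qPCR run; the cutoff is a parameter, not a
  fitted quantity.
* RSEM: positive iff the gene-level normalized count exceeds `epsilon`
  (default 0). The permissive default is the only rule consistent with
  essentially all tumor and normal samples being NKp30-positive while
  NKp44 positivity stays in the 10–20% range; `epsilon` is exposed for
  sensitivity analyses.

Profile calls are then pure threshold rules:

* NKp44: `NKP44_1_DOMINANT` iff %NKp44-1 ≥ 66 (inhibitory), else
  `NKP44_2_3`. The source literature states the rule both as "≥ 66%" in
  its text and "> 66%" in figure legends; the package defaults to the
  inclusive form and exposes `nkp44_boundary_inclusive` in
  `classifier_config()`. The two differ only for samples exactly at the
  threshold, which the synthetic generator avoids by construction.
* NKp30: `NKP30_AB` iff %NKp30a ≥ %NKp30c (tie to a/b, configurable),
  else `NKP30_C`. %NKp30b is measured and reported but never enters the
  rule — the package mirrors the established rule exactly rather than
  invent a three-way criterion.
* A sample that is receptor-negative, or positive with an undefined
  composition (a variant assay undetected, or all variant counts zero),
  is `NEGATIVE`. Classification is total: every sample gets exactly one
  label.

Matched pairs (one STN and one PST sample of the same patient; duplicate
aliquots resolved to the lexicographically smallest barcode for
determinism) are typed by `classify_shift()`. Pairs with both sides
defined are `IDENTICAL` or `NON_IDENTICAL` with NKp30 directions
`AB_TO_C` / `C_TO_AB`; a pair with a `NEGATIVE` side is *non-defined*. We
keep non-defined pairs out of the identical/non-identical denominator and
report them as their own bin, so the identity percentages and the
direction percentages refer to consistent denominators.

## Statistics

Group comparisons of binary categories (positive/negative incidence, or
the two-profile split among positive cases) use a **two-sided Fisher
exact test** implemented from first principles: with margins fixed, the
support of the (1,1) cell is enumerated, point probabilities are computed
from log binomial coefficients (numerically stable at TCGA-scale counts),
and the p-value sums every table whose point probability is at most the
observed one, with a relative tie tolerance of 1e-7 — the common
two-sided convention. A table with a zero margin carries no information
and returns p = 1 with a warning. The test suite checks this
implementation against a brute-force enumeration oracle on a thousand
random tables and against `stats::fisher.test`, which serve as
cross-checks only. Paired expression comparisons use the two-tailed
paired *t*-test (\(t = \bar d / (s_d/\sqrt n)\), \(n-1\) degrees of
freedom), with a hard error on zero-variance differences rather than a
silent p of 0 or 1. No multiple-testing correction is applied across the
pairwise Fisher tests — matching how such panels of per-cluster
comparisons are conventionally reported — but the reports carry the
number of tests performed so a reader can apply their own.

## What the synthetic cohorts emulate

`qpcr_cohort_spec()` / `gen_qpcr_cohort()` emulate a decidua-style qPCR
cohort: each sample is positive with `positivity_rate` (default 0.9,
within the 80–100% range seen across clinical decidua groups); positive
samples are NKp44-1-dominant with `p_dominant` (default 0.8) and NKp30a/b
with `p_ab` (default 0.6, matching the roughly 60/40 a/b-vs-c split seen
in tissue cohorts). Class-conditional Dirichlet draws give the variant
fractions — concentrations `(16, 2, 2)` for the dominant class (expected
NKp44-1 share 0.8) and `(4, 8, 8)` for the non-dominant class (expected
share 0.2) — and Ct values are back-computed so the
\(2^{-\Delta Ct}\) pipeline reproduces the drawn fractions exactly.
β-actin Ct is N(18, 1) cycles and receptor totals sit ~6 cycles above it,
i.e. expression a factor ~64 below the housekeeping gene, a realistic
order of magnitude for NK-receptor transcripts in bulk tissue.

`tcga_cohort_spec()` / `gen_tcga_cohort()` emulate the matched
tumor/normal arm: per patient one PST sample and, with
`matched_fraction`, an STN sample; NKp30 categories drawn from mixes over
{a/b, c, negative} (default 59/40/1, reflecting near-universal NKp30
positivity and the 60/40 profile split); the tumor category copies the
matched normal except with `shift_probability` (default 0.5, the reported
order of non-identical pairs) it is resampled independently; NKp44
positivity is Bernoulli at 0.15 in tumors and 0.05 in normals (the
10–20% tumor incidence range, lower in normal tissue) with dominant
profiles at 0.9 (the 80–100% range). Output files are byte-identical for
a fixed seed: each generator call runs a single RNG stream seeded from
`spec$seed` with a documented per-sample draw order, and restores the
caller's RNG state afterwards.

Two generator choices matter for testing. First, drawn fractions are
rejected into a **boundary-exclusion band**: at least 1 percentage point
away from the 66% dominance threshold and from %a = %c (configurable,
`boundary_band = 0` disables). Within the band a generated label and the
classifier's recovered label could legitimately disagree on floating-point
grounds; outside it, recovery is exact, which turns the whole pipeline
into a property test. Second, the default per-well Ct noise is 0 cycles:
with noise the recovered fractions are only asymptotically right and
label recovery near the threshold becomes probabilistic. Noise is there
(`noise_sd`) for robustness experiments, not for the default tests.
Consequently, passing tests demonstrate correctness of the bookkeeping
and the estimators on data whose generative model matches the analysis
assumptions — they do not demonstrate robustness to real-data features
the generator omits: amplification-efficiency drift, batch effects,
tumor-purity dilution of immune transcripts, annotation ambiguity in
isoform quantification, or dropout correlated with expression level.

## Numerical and edge-case conventions

* Undetected Ct wells are `NA` end to end; an undefined expression is
  never coerced to zero (zero would masquerade as infinite ΔCt).
* Samples with no detected β-actin are excluded with a warning — without
  the reference gene no expression statement is possible.
* All-zero variant counts give an undefined composition, hence a
  `NEGATIVE` call, not a division by zero.
* Percentages are reported at two decimals in output tables; internal
  computation is double precision throughout.
* Fisher tie tolerance 1e-7 (relative); enumeration, not approximation,
  so no continuity corrections anywhere.
* Report tables carry a header line with the package version and a hash
  of the run configuration, so emitted tables are traceable to settings.

## Problem sizes used by the test suite

The suite runs the full pipeline at cohort sizes chosen to make the
statistical property tests sharp but cheap: label-recovery and arm-level
round trips at 12–60 patients, mixture-fraction recovery at n = 400
(where three binomial standard deviations is ±6 percentage points), the
shift-rate recovery at 500 matched pairs, and barcode round-trips at
10,000 barcodes. The Fisher implementation is compared with the
enumeration oracle on 1,000 random tables with N ≤ 60. These sizes are
the package's own testing choices and complete in well under five
minutes on a single CPU.

## Known limitations

* Profile calls are hard thresholds; no uncertainty is propagated from
  Ct noise or RSEM estimation error into the categorical labels.
* The NKp30 rule ignores %NKp30b by construction (mirroring the
  established rule), so cohorts differing only in NKp30b are
  indistinguishable to the classifier.
* The Fisher tests are marginal; no multiplicity control is applied.
* Real-data ingestion expects one RSEM file per sample; merged
  expression matrices must be split (or a manifest written) upstream.
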