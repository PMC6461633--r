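---
title: "Methods: quantification, QC filtering and paired differential analysis of a targeted plasma lipidome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, QC filtering and paired differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gclipidr)
```

This vignette is the package's account of its statistical and numerical
choices: what each stage assumes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## Study design and data model

The pipeline targets paired before/after treatment designs measured on
targeted LC-MS panels. The motivating setting is two independent canine
experiments — 8 dogs under short-term prednisolone and 6 under long-term
tetracosactide (chronic ACTH stimulation), each roughly one-third female —
with plasma sampled once before and once at the end of treatment, and four
analytical panels: phospholipid/CE/DG, sphingolipid, S1P, and TG.

Inputs are long-format raw peak areas keyed by (sample, species) with a
panel label and an ISTD flag; sample metadata assigning subject, group,
timepoint and role (study, pooled QC, blank); and an ISTD map assigning
each analyte species one internal standard and its spiked molar
concentration.

## Lipid shorthand nomenclature

All class- and double-bond-driven logic runs off a strict parser for
shorthand species names (`parse_lipid_name()`). The class vocabulary is
closed by default — the twenty classes measured on the four panels — so a
typo fails loudly rather than silently dropping a species from its class
aggregate; the vocabulary is extensible via the `classes` argument.
Three structural conventions matter downstream:

* Ether (`-O`) and plasmalogen (`-P`) subclasses are distinct class tokens.
  PC-O/PC-P/PE-O/PE-P species therefore never contribute to acyl PC/PE
  totals, and lyso classes (LPC, LPE) are likewise separate.
* Sphingolipid totals include the sphingoid base: Cer d18:1/18:0 has 36
  carbons and 1 double bond. This keeps the sum semantics uniform; the
  double-bond stratification below is only applied to acyl
  glycerophospholipids, so the convention has no effect on it. For GM3 we
  count only base plus N-acyl chain — the glycan is part of the class
  token, not a chain.
* Sum-composition sphingolipids ("SM 34:0") carry no base field; class
  membership alone marks them as sphingolipids.

Formatting a parsed name reproduces the input byte-for-byte, which the test
suite asserts over the entire synthetic catalog.

## Quantification

Quantification is single-point against the assigned ISTD with implicit
response factor 1: normalized area = analyte area / ISTD area in the same
sample, relative concentration = normalized area × spiked ISTD
concentration (µmol/L). Concentrations are therefore *relative* molar
abundances — adequate for fold changes, CVs and multivariate structure, not
calibrated absolute concentrations. Every sample, including pooled QCs and
blanks, is normalised against its own ISTD areas, which cancels per-sample
injection and drift effects.

The S1P panel needs one correction before quantification: the M+2
isotopologue of S1P d18:1 co-elutes in the S1P d18:0 channel (two mass
units apart). The subtracted fraction defaults to the carbon-only binomial
ratio `choose(n,2)·(p/(1−p))²` with n = 18 carbons and p(13C) = 0.0107,
i.e. ≈ 0.0179. The literature method this emulates does not print its
factor, so the transparent theoretical value is the default and the
configuration accepts any empirical fraction instead; the choice is echoed
in the run manifest. Corrected areas that would go negative are clamped to
zero with a warning rather than erroring — blanks legitimately carry less
target signal than the predicted interference.

## The QC exclusion cascade

Three rules, evaluated per treatment group on the pooled-QC (PQC) and
blank samples:

1. **Area floor** (default 250, raw area units): median PQC raw area below
   the floor.
2. **Blank ratio** (default 5): median PQC raw area less than 5× the
   median blank area. A blank median of exactly zero passes the rule
   (ratio +∞): absent background cannot justify exclusion.
3. **%CV** (default 25%): the n−1 sample CV of ISTD-normalised PQC areas
   exceeds 25% — strictly greater, so a CV of exactly 25.0% passes —
   in *either* group.

Species on the override list survive rule 3 with decision
`kept_by_override`, preserving cross-group comparability for species that
are precise in one arm but noisy in the other; both CVs stay on record in
the QC report. Each species receives exactly one decision per group, with
the first failing rule as the recorded reason in the documented order
area → blank → CV. The order is a reporting convention only; the
kept/excluded outcome is order-independent, which a property test
verifies by construction of the rules (each rule reads disjoint inputs).

The final cross-group dataset intersects the groups' kept sets and
additionally requires a finite concentration in every study sample of both
groups; group-specific dropouts stay in their own group's reporting set and
are flagged not-quantified (NQ) for the other. Panel quality is summarised
as the median per-species %CV over kept species, per panel and group.

## Paired differential statistics

Per species and group, the per-subject effect is
`log2FC = log2(after/before)`; the test is a paired two-tailed t-test on
the log2 differences with n−1 degrees of freedom. Log2 is the natural scale
here: concentrations are positive, technical and biological noise are
multiplicative, and under the generator's lognormal noise the log2
differences are exactly normal, so the t-test is exact. Zero-variance
difference vectors yield an undefined p-value: the species is flagged
degenerate, reported NA, excluded from the FDR family size, and never
called significant.

Multiplicity is handled with Benjamini–Hochberg FDR. The scope is per
treatment group across the group's full reporting set (not per class, not
pooled across groups): each figure-style table reports one FDR-adjusted p
per species per treatment. Because the original correction's family is not
documented, the scope is configurable (`fdr_scope = "group"` or
`"class"`). Significance is called at FDR ≤ 0.05 with a two-star tier at
≤ 0.01.

Average fold change is the back-transformed arithmetic mean of per-subject
log2FC — the geometric mean of the ratios — displayed with the signed
convention (`2^m` for m ≥ 0, `−2^(−m)` otherwise), so a halving reads −2.
Clinical-chemistry panels are summarised with the *median* of per-subject
signed fold changes and unadjusted paired p-values (single-test panels).
Taking the median after the sign transform, rather than sign-transforming
the median ratio, matches how mixed-direction panels are conventionally
reported and is fixed by the package's reference examples.

Subject-exclusion sensitivity analyses (single influential animals) are
supported via `drop_subjects` rather than hard-coded dog lists.

## Saturation (double-bond) aggregates

For each acyl glycerophospholipid class (default PC, PE, PI), species are
stratified into ≤3 vs ≥4 total double bonds — the strata observed to move
in opposite directions under chronic glucocorticoid excess — and per-sample
stratum totals, their GE4/LE3 ratio, and four tests are computed: paired t
on log totals of each stratum, paired t on the log ratio, and a stratum
contrast of per-species mean log2FC. The contrast is implemented as an
unpaired Welch two-sample t with species as units: the strata have no
pairing structure across species, and Welch avoids assuming equal
species-to-species dispersion in the two strata. A paired-by-subject
variant of the ratio test is implicit in `p_ratio`, which is also exactly
invariant to per-sample global scaling (the ratio cancels it).

Stratified totals conserve the class total exactly (up to floating-point
summation order), which both the unit tests and the acceptance script
verify.

## Multivariate outputs

Abundance PCA operates on log2 concentrations, per-species centred and
scaled to unit variance (correlation-mode, as implied by "scaled, centred"
preprocessing), via singular value decomposition; fold-change PCA takes the
subjects × species log2FC matrix with the same centring/scaling.
Components are reported up to min(n − 1, p) and carry a deterministic sign
convention — the largest-magnitude loading of each component is positive —
so runs are bit-reproducible. Constant columns are an error (their scale is
undefined), as is an all-constant fold-change matrix.

Clustering reproduces the dual-dendrogram heatmap: species rows autoscaled
to z-scores of log2 values, Pearson distance (1 − r) on both axes, Ward
agglomeration. The Ward variant defaults to `ward.D2` (the
squared-distance-consistent form) with `ward.D` selectable, since heritage
heatmap code is ambiguous between the two. Ties break deterministically by
input order. Dendrograms export as Newick text.

## The synthetic-experiment generator

The generator exists so that every stage is testable without instrument
data; its defaults *are* the emulated study conditions and are not tuned
per analysis.

* **Design**: 8 + 6 subjects, paired sampling, ~1/3 female per group; 8 PQC
  injection replicates and 3 blanks per group. The study pooled one PQC per
  group and injected aliquots; the replicate count here (a config knob) is
  chosen so %CVs are estimable with reasonable stability.
* **Catalog**: a deterministic, seed-independent 262-species inventory
  across the 20 classes, mirroring the measured panel sizes (16 Cer, 10
  Hex1Cer, 12 PI, 37 PC, 31 TG, ...), plus 9 planted QC-failure species —
  3 below the area floor, 2 blank-contaminated, 4 with inflated PQC
  variability — giving 271 catalog species of which 262 survive the
  default cascade.
* **Abundances**: class-level baseline scales (order-of-magnitude plasma
  values, e.g. PC ≫ S1P) with a deterministic 0.3–3× within-class spread;
  between-subject biological variation is lognormal with 40% CV by
  default. Before/after concentrations share the subject baseline; the
  treatment effect enters as a true multiplier on the after sample,
  resolved with precedence species > class-and-stratum > class.
* **Noise**: all noise is multiplicative lognormal with unit mean
  (σ² = log(1 + CV²)), parameterised per panel: 5% (phospholipid/CE/DG),
  11% (sphingolipid), 9% (S1P), 18% (TG) technical CV — the order of the
  panels' reported median precisions — plus a 5% per-sample injection
  factor shared by all areas of a sample (cancelled by ISTD
  normalisation) and 2% ISTD noise. Lognormal is the natural choice:
  areas are positive, analyses are log2-based, and CV maps cleanly to σ.
* **QC materials**: the PQC pool is formed on the concentration scale as
  the arithmetic mean of the group's study samples (equal-volume pooling
  before extraction); blanks carry 1% of the pooled signal by default
  (50% for the planted blank-failure species). Species with a configured
  PQC %CV override follow a deterministic mean-zero unit-sd replicate
  pattern scaled to that CV, so the realized sample CV equals the
  configured value regardless of seed; the study preset uses this to pin
  the two override-retained sphingolipids at their documented CV quartet
  (27.8/30.1% in the tetracosactide arm, 7.3/10.9% in the prednisolone
  arm).
* **Isotope cross-talk**: S1P d18:0 areas receive `f × area(S1P d18:1)`
  before output, so the pipeline must subtract it; with the matching
  fraction the correction removes the injected interference exactly.
* **Effects preset** (`preset_gc_study()`): Hex1Cer up in both arms
  (×1.9 / ×2.2); PI down (×0.45) and S1P up (×1.5) under prednisolone;
  under tetracosactide, ether/plasmalogen PC and LPC-O down (×0.45–0.5),
  TG up (×4), ≥4-double-bond PC/PE/PI down with ≤3-double-bond strata up,
  S1P d16:1 halved, plus the documented single-species effects
  (Cer d18:2/18:0 ×2.7 prednisolone; Cer d18:1/18:0 ×3.3, DG 18:0_18:2
  ×4.4 tetracosactide, and others).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: chromatographic artefacts (retention-time drift,
peak-shape and integration error, co-elution beyond the single modelled
S1P interference), batch/run-order drift, missingness mechanisms other
than low abundance, heavy-tailed or correlated biological variation across
species (each species' biological noise is independent), matrix effects,
and non-unit ISTD response factors. Conclusions about rule logic,
statistical calibration and reproducibility transfer to real data;
conclusions about absolute power or CV magnitudes do not.

With TG technical CVs near 18% and a strict 25% cutoff estimated from 8
replicates, occasional non-planted TG exclusions are expected and
observed (~0–3 species per run); the exact catalog-minus-planted count is
therefore only asserted on configurations with benign technical CVs, where
the planted failures are provably the only exclusions.

## Numerical choices and degenerate inputs

* CV comparisons strict (> 25% fails); area/blank comparisons strict (<).
* Blank median 0 → ratio +∞ → pass.
* Negative isotope-corrected areas clamp to 0 with a warning.
* Zero-variance log2 differences → p undefined (NA), excluded from the BH
  family, never significant.
* NA p-values propagate through BH unchanged; the family size m counts
  defined entries only.
* PCA sign convention: largest-|loading| positive per component; variance
  fractions are reported over min(n − 1, p) components and sum to 100%.
* Clustering tie-break: input order (via the underlying agglomeration).
* All tabular I/O is UTF-8, tab-separated, '.' decimal; unicode minus
  signs in ingested clinical tables are normalised to ASCII on read.

## Problem sizes in the test and acceptance runs

The suite exercises the full 271-species, 14-subject design end-to-end
(sub-second per run). Statistical calibration uses 2000 lognormal null
replicates per sample size (n = 6 and 8) for the type-I error of the
paired test, 100 independent null-preset simulations for the FDR rate,
and 200 random p-value vectors (lengths 1–8 on a 0.01 grid) against the
brute-force BH oracle; clustering is checked against a naive O(n³)
Lance–Williams oracle on 6-sample fixtures, and PCA against a direct
eigendecomposition on 5 × 4 fixtures. These sizes make the whole suite run
in about a minute while keeping Monte-Carlo standard errors well inside
the asserted bands.

## Known limitations

* Single-point, response-factor-1 quantification: concentrations are
  relative; cross-species comparisons inherit ISTD class assignment error.
* No batch or drift correction; the QC cascade is the only signal-quality
  gate.
* No covariate adjustment (sex, age, weight) in the paired tests; sex
  effects are only visible descriptively in the fold-change PCA.
* The saturation contrast treats species as exchangeable units within a
  stratum; correlated species (shared fatty acids) make its p-values
  anti-conservative, so treat it as descriptive.
* sn-position and fatty-acid-level resolution are out of scope; strata are
  defined on total double bonds only.
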