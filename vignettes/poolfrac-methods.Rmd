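---
title: "Methods: ratio-sign-consistency analysis of pooled plasma EV and protein fractions"
author: "poolfrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratio-sign-consistency analysis of pooled plasma EV and protein fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolfrac)
library(SummarizedExperiment)
```

## The analysis problem

Blood plasma contains extracellular vesicles (EVs) alongside a vast
excess of free proteins and lipoprotein particles. Size-exclusion
chromatography (SEC) splits platelet-depleted plasma into an early,
EV-enriched eluate ("EV") and a later, free-protein-enriched eluate
("PROT"). A typical study design pools plasma from several donors to
average out individual variation before proteomics: donors are grouped
by biological sex (M, F) and age band (young, mid, old), pools mix
equal plasma volumes from a few unique donors of one group, and a
subset of pools per group is quantified by label-free mass
spectrometry in both fractions.

`poolfrac` implements the downstream analysis of such designs:
detection filtering, differential abundance between fractions and
between demographic groups, set-intersection triage of candidate
markers, marker-panel characterization, particle-count normalization,
and group statistics — together with a synthetic-data generator that
emulates the design, so the whole pipeline is testable end to end
without access to any proprietary dataset.

## The consistency rule for differential abundance

With only three pools per group, classical test statistics are
fragile. The pipeline instead uses a ratio-sign-consistency rule:

* **Paired fraction comparison.** For each protein quantified in both
  fractions, the per-pool ratio EV/PROT is formed across all matched
  pools (18 at the default design). The protein is EV-enriched if
  every ratio exceeds 1, PROT-enriched if every ratio is below 1.
* **Cross-group comparison.** For two groups with pools
  \(a_1..a_m\) and \(b_1..b_n\), all \(m \times n\) cross ratios
  \(a_i/b_j\) are formed (9 at 3 vs 3). The protein is called "up"
  (higher in the first-named group) if every ratio exceeds 1, "down"
  if every ratio is below 1.

The cross-group rule is equivalent to requiring
\(\min(a) > \max(b)\) or \(\max(a) < \min(b)\); the package tests
verify this equivalence against an independent min/max oracle on
randomized instances. Ties (a ratio exactly equal to 1) break
consistency and yield `not_DE` — the rule is strict. A protein missing
a value in any required pool is `not_evaluable`: the full ratio set the
rule is defined over does not exist, and imputation would silently
weaken the all-ratios requirement. (A configurable alternative that
evaluates over available pools was considered and rejected as the
default because it changes the rule's null behaviour per protein.)

The reported effect size `log2fc` is the mean of the log2 ratios,
i.e. the log2 ratio of geometric means. It is symmetric (swapping
groups negates it), tie-free and consistent with the verdicts.

### Analytic null rates

Under an exchangeable null (all \(m+n\) pool values i.i.d. continuous),
each direction of the cross-group rule fires with probability
\(1/\binom{m+n}{m}\), so

\[ P(\text{DE}) \;=\; \frac{2}{\binom{m+n}{m}} \;=\; 0.1
   \quad\text{at } m=n=3 . \]

For the paired rule with independent direction-symmetric ratios,
\(P(\text{DE}) = 2\,(1/2)^n = 2^{-17} \approx 7.6\times10^{-6}\) at
\(n = 18\). These are per-protein false-positive rates, not corrected
significance levels; `nullConsistencyRate()` and `nullPairedRate()`
expose them so observed DE counts can be judged against chance. The
test suite confirms both by exhaustive enumeration of orderings and by
Monte-Carlo simulation, and checks that the empirical DE rate on
simulated null data agrees with the analytic value within Monte-Carlo
error.

An important consequence of the 0.1 null rate: with universes of
hundreds of proteins, each 3-vs-3 comparison is expected to call
roughly 10% of proteins "DE" by chance alone. The set-intersection
stages below (requiring DE in multiple comparisons, in both sexes, or
in all age groups with a consistent direction) are what brings the
combined false-positive rate down; single-comparison DE lists should
be read accordingly.

## Detection filtering

A protein is *detected* in a pool when its value is present and
strictly positive; label-free quantification outputs commonly use 0
for absent proteins, so 0 is mapped to missing at I/O. The filter
keeps proteins detected in strictly more than a threshold share of a
fraction's pools — default 0.8, i.e. at least 15 of 18 pools. The rate
is computed per fraction over all of its pools jointly (not per
group); a per-group variant would be a different universe definition
and can be emulated by filtering subsets. Strictness matters at the
boundary: 14/18 ≈ 77.8% is dropped, 15/18 ≈ 83.3% is kept. The filter
is idempotent and monotone in the threshold, and both properties are
tested.

## Set-intersection triage

Downstream of the per-comparison DE calls, the package derives:

* `ageDynamicProteins()` — proteins DE in at least `min_comparisons`
  of the three age comparisons of one sex (default 2; the stricter
  all-three reading is a parameter away, and the result is monotone
  decreasing in the threshold).
* `sexCommonAgeProteins()` — proteins DE in both sexes for at least
  one common age comparison *with the same direction*, intersected
  with the age-dynamic proteins of either sex. Direction consistency
  is required because the DE definition itself is directional; an
  any-comparison relaxation is available as a switch.
* `sexConsistentAcrossAges()` — proteins DE between M and F in all
  three age bands with one direction throughout: the stable
  sex-associated markers.
* `vennSummary()` — exclusive-region counts for 2–4 protein sets with
  percentages of the union rounded half-up to one decimal (the
  conventional reporting style; note that base R's `round()` is
  half-even, so the package rounds explicitly).

## Synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
emulated study conditions: 20 donors per sex-by-age group (120 total),
ages uniform within group-specific bands (22–34 up to 64–79 years),
pools of 4 unique donors at 0.5 mL plasma each, 5 pools per group, the
first 3 of which are carried to proteomics (which 3 of the 5 pools a
real study sends to proteomics is not knowable from outside; "first k"
is an explicit arbitrary convention). Pool assignment sorts donors by
age and deals them round-robin, emulating deliberate age balancing
across pools.

Protein abundance follows a lognormal model, standard for label-free
proteomics intensities: per-protein log2 baselines
\(\mathcal N(20, 2^2)\) (MaxLFQ-like intensity scale); donor-level
biological noise \(\mathcal N(0, 0.5^2)\) on log2; pools average their
member donors on the *linear* scale, because pooling is a physical
mixture of equal plasma volumes; per-fraction technical noise
\(\mathcal N(0, 0.2^2)\) on log2 is then added independently per
fraction. Fraction-enriched proteins (35% EV-enriched, 10%
PROT-enriched by default, echoing the higher protein diversity of EV
eluates) receive a fixed ±2 log2 offset in their enriched fraction.
Age and sex effects are planted per protein as per-age-group log2
offsets, optionally scoped to one sex. Finally, pool values whose log2
abundance falls below the detection limit (default 16, two baseline
SDs below the mean) are censored to missing — after noise, mimicking
DIA dropout near the limit of detection. Censoring to missing rather
than zero keeps "absent" and "low" distinguishable downstream.

What the generator does *not* emulate: peptide-level quantification
and shared-peptide inference, batch effects beyond a single technical
term, correlated protein modules, and heavy-tailed contamination.
Passing recovery tests therefore demonstrate that the pipeline's logic
is correct under the stated model, not that the rule is robust to
every pathology of real DIA data.

Every randomized operation takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage seeds
deterministically from one top-level seed so stages can be re-run in
isolation.

## Group statistics

Plasma analytes (albumin in g/L; HDL/LDL in mg/dL) and normalized
particle concentrations are compared across the six groups with
Fisher's least significant difference test: one-way ANOVA pooled MSE,
pairwise \(t\) with \(df = N - k\), two-sided p, conventional star
bands. The unprotected form is used — pairwise results are reported
regardless of the omnibus F — because per-pair stars are the reporting
convention the pipeline targets; the omnibus F and an optional
Bonferroni correction are provided for users who want protection. The
implementation is cross-checked in tests against `aov()` for the MSE
and against the pooled-variance `t.test()` at two groups.

Particle counts are normalized to particles per mL of source plasma:
measured concentration × dilution factor × preparation volume ÷ plasma
input volume.

## Hierarchical clustering

`clusterHeatmap()` z-scores each protein's log2 abundance across the
selected pools (zero-variance proteins become all-zero rows and, under
correlation distance, are pushed to maximal distance with a warning),
then clusters rows and columns agglomeratively. Defaults are
Pearson-correlation distance with average linkage — common heatmap-tool
settings — with Euclidean distance and complete/Ward linkage available
as flags, since the upstream tool choice is rarely documented well
enough to pin one. Proteins are ordered by identifier before
clustering so results cannot depend on input row order. Dendrograms
export to Newick via `ape`; column clusters at a chosen cut are
labelled with `cutree`, and `clusterPurity()` scores them against
known group labels.

## The pipeline entry point

`runPipeline()` takes a nested configuration (R list or YAML file,
partial configs completed from `defaultConfig()`): simulate → filter →
DE plan → set analysis → group statistics → clustering, writing every
intermediate table as TSV plus a human-readable summary, a verbatim
config copy and a run log. Identical config and seed give
byte-identical bundles; for that reason the run log records stages,
seeds and row counts but no timestamps.

## Problem sizes used in tests

The shipped tests and the acceptance script run the full default
design (120 donors, 18 proteomics pools) with protein universes of
40–2,000, one 10,000-protein null simulation for the empirical null
rate, and a 2,000,000-replicate sign-pattern Monte Carlo for the
paired-rule null; these sizes give Monte-Carlo standard errors small
enough that the 3-SE acceptance bands are meaningful while keeping a
full run in the order of seconds.

## Known limitations

* The consistency rule's sensitivity drops quickly once effect sizes
  approach the pool-level noise scale; the recovery guarantee tested
  here (≥ 95% sensitivity) holds for effects at least 4× the donor SD.
* `not_evaluable` proteins are excluded from DE universes rather than
  imputed; fractions with heavy dropout therefore have smaller
  evaluable universes, which the summaries report explicitly.
* The LSD test assumes homoscedastic groups; no Welch-style variant is
  provided.
* Marker panels are static curated text files; gene-symbol aliasing is
  annotated in comments but never resolved automatically.
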