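---
title: "splicearray: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicearray: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicearray)
```

# Scope

`splicearray` implements the computational core of a splicing-phenotyping
study design in *Saccharomyces cerevisiae*: splicing-sensitive two-color
microarrays summarized as Intron Accumulation Indices with defect calls and
clustered profiles, plus integration of genetic-interaction screens and
gene-set enrichment with resampling-based family-wise correction. This
vignette documents the models, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the procedure was genuinely open.

# The splicing-array model

## From spots to feature ratios

Each intron-containing gene is probed at three features: the terminal exon
(total mRNA), the intron (pre-mRNA), and the exon–exon junction (mature
mRNA). Each feature is spotted `n_tech_reps` times (default 6) and each
biological replicate is hybridized twice — once forward (mutant in channel
1, the ~635 nm scan) and once dye-flipped.

Per spot, the statistic is the log2 ratio of the two channel median
intensities, re-oriented so it is always mutant over wild-type reference
(`spot_log_ratio()`); a dye-flipped array contributes the negated
channel-1/channel-2 ratio. Spots with a negative manual flag or a
non-positive intensity are excluded, and every exclusion is reported —
readers never drop data silently.

Per array, surviving spot ratios are **median-centered**: the array-wide
median log ratio is subtracted from every spot. The upstream protocol this
emulates defers normalization to an external reference; median centering is
the minimal scheme consistent with ratio-of-medians data — it is scale-free
and removes exactly the global dye-bias offset a common dye effect adds to
every spot (`combine_replicates` examples in the test suite exercise this).
No background subtraction is applied: ratios are formed from raw median
intensities.

Technical replicates are combined by the **median** (robust to residual bad
spots); a (gene, feature) with fewer than `min_spots` (default 3 of 6)
survivors is missing on that array. Biological replicates — forward and
flipped arrays on equal footing, since both are already
mutant-over-reference — are combined by the **unweighted mean** over arrays
where the value is defined (`average_biological()`).

## The Intron Accumulation Index

For each intron,

$$\mathrm{IAI} = \log_2\frac{I_{mut}}{I_{WT}} - \log_2\frac{E_{mut}}{E_{WT}}$$

i.e. `intron_lr − exon_lr` in log2 units. A change in transcription moves
intron and exon ratios equally and cancels exactly; the IAI therefore
isolates the splicing change from total-expression confounders. The
junction log ratio is carried in the profile but does not enter the IAI.

A gene is **defective** when any of its introns (second introns are tracked
as `<gene>_2` rows, sharing the parent's single exon probe set) has IAI
*strictly greater than* `iai_cutoff` (default 0.3 log2 units). The cutoff
interval stated alongside the original histogram figure ("−0.3 ≥ IAI ≥
0.3") is not a satisfiable interval; it is read here as the two one-sided
cutoffs at ±0.3, with the headline defect call using IAI > 0.3 only.
Severity is binned by the maximal IAI per gene with breakpoints
`severity_bins = c(0.3, 0.6, 1.0)` — bins (0.3, 0.6], (0.6, 1], > 1 —
configurable because the original inset did not state its bins. Genes with
undefined IAI are reported separately and excluded from the histogram.
Whether multi-intron genes should be aggregated or duplicated in per-gene
displays is not settled by the source material; the gene-level call here is
the maximum over introns, while profiles keep per-intron rows.

## Clustering

Profiles are clustered with **average linkage** on the distance
`1 − uncentered Pearson`, where the uncentered Pearson similarity is
`Σxy / (√Σx² √Σy²)` with pairwise exclusion of missing entries — the
classic expression-clustering combination, which treats the zero log ratio
(no change) as the anchor rather than the row mean. All-zero vectors have
undefined similarity and are assigned similarity 0 with a warning. The
agglomeration is delegated to `stats::hclust(method = "average")` on a
distance matrix the package computes; it is deterministic given the input
row order. Merge heights are invariant to tie-breaking for generic
real-valued inputs; the test suite checks them against an independent
from-scratch O(n³) average-linkage oracle for matrices up to 12 rows at
tolerance 1e−12 (the two algorithms accumulate floating error differently,
so exact bit equality is not the right notion).

# Screen integration and enrichment

## Integration

The integrated negative-interaction set is the union of (i) the 30 °C SGA
hit list, (ii) directed-genetics synthetic sick/lethal calls, and (iii)
E-MAP negatives at score ≤ −2.5 with the boundary included. The 37 °C SGA
list is carried with provenance but excluded from the default integrated
set: the stronger synthetic interactions come from the 30 °C screen, and
that is the list integration starts from. Suppressor (positive) calls are
never merged with the negative set. Systematic names are the join key
throughout. `screen_summary()` reports hit rates as half-up one-decimal
percentages of a user-supplied denominator — per-screen universe sizes
differ and are not hard-coded.

## Hypergeometric test and corrections

Enrichment of a size-*n* query against a size-*K* set in a size-*N*
universe uses the upper tail `P(X ≥ k)` computed in log space (log binomial
coefficients combined with log-sum-exp), exact to enumeration for all
N ≤ 12 and matching `phyper` at genome scale (both are test-suite
properties; `phyper` is a cross-check, not the implementation). The
universe is the declared screen universe — all deletion strains tested —
not the union of catalog members, because the screened set is the sampling
frame the query was actually drawn from. The ≥ k (not > k) tail is the
standard enrichment convention and is used throughout.

Family-wise correction for the complex catalog is the empirical **min-p
resampling** method: draw `B` (default 1000, unstated in the original
procedure) uniform random query sets of size *n* from the universe, record
each resample's minimum raw p across all catalog sets, and set

$$p_{adj}(s) = \frac{1 + \#\{b: \min_b p \le p_{raw}(s)\}}{B + 1}$$

The add-one estimator keeps adjusted values strictly positive; a
monotonicity pass makes the adjusted ordering agree with the raw ordering.
This is the best-p (family-wise) flavor of resampling correction;
per-set attribute permutation is out of scope. Process-level (GO-slim)
enrichment uses the simpler Bonferroni correction `min(1, m·p_raw)` with
*m* = 45 high-level terms in the original design.

# The synthetic-data generator

The generator is the package's stand-in for unreleased raw scans and
screen plates; its defaults are the study conditions, not tuning knobs.

* **Universe**: 4,800 synthetic systematic-style gene ids (the non-essential
  deletion collection scale); 300 intron-containing genes on the array, 10%
  with a second intron.
* **Catalog**: random sets of 3–30 members plus a fixed 3-member
  `RAD6_complex` trio that is always present, so complex-recovery
  experiments can target a known set. A separate
  `synthetic_cyc2008_catalog()` builds a 408-complex catalog with a
  dimer-heavy size distribution purely for catalog-bookkeeping checks — its
  membership is random, only the shape mimics the curated list.
* **E-MAP scores**: background Normal(0, 1); planted complex members are
  shifted by the planted amount (e.g. −4), putting most of them at or below
  the −2.5 calling threshold.
* **SGA screens**: noisy views of the planted negatives. False-positive and
  false-negative rates are free parameters of the emulation (the source
  material does not estimate them); the defaults `sga30_fp = 0.015`,
  `sga37_fp = 0.065`, `sga_fn = 0.2` were chosen once so the expected hit
  counts over 4,800 genes land near the reported screen rates (≈1.7% at
  30 °C, ≈6.9% at 37 °C), and are not revisited.
* **Arrays**: channel intensity = `baseline × 2^(effect + dye_bias +
  N(0, noise_sd))`, with a per-probe log-normal baseline, the dye bias on
  channel 1, per-channel noise (so a spot log ratio has standard deviation
  `noise_sd·√2`), `flag_rate` of spots flagged negative, and expected
  spot-level log2(mutant/WT) equal to `exon_effect` for exon and junction
  probes and `exon_effect + IAI` for intron probes. Junction probes track
  the total-transcript effect only: the IAI does not consume them, and
  modeling partial mature-mRNA depletion would add a parameter nothing
  downstream reads.
* **Reproducibility**: one root seed; each array draws from a substream
  derived by stable integer mixing of (replicate, orientation), so adding
  replicates never perturbs earlier arrays, and identical configurations
  give byte-identical outputs.

What the generator does **not** emulate: spatial array artifacts, print-tip
effects, probe cross-hybridization, intensity-dependent (loess-shaped) dye
bias, and correlated biological variation between genes. Passing tests
therefore demonstrate correctness of the computations under a clean noise
model, not robustness to every failure mode of real scans.

# Numerical choices and degenerate inputs

* Log-space hypergeometric tail, clamped to [0, 1]; argument violations are
  errors naming the constraint.
* Zero or negative spot intensities yield missing ratios, never -Inf.
* An array with zero usable spots returns an empty table with a warning.
* A single biological replicate is allowed with a warning.
* Result ordering ties break lexicographically by set id.
* Floats in TSV output carry 6 significant digits; round-trips are exact
  for integer fields and within that formatting precision for floats.

# Problem sizes

The test suite and the acceptance script run at the sizes the analyses are
designed around: the full 4,800-gene universe with 300 intron genes and 60
planted defects for array recovery; 100 simulated screens at genome scale
for planted-complex recovery; a 200-gene universe with 20 sets, 500 null
queries and B = 1000 for the family-wise calibration; exhaustive
enumeration up to N = 12 for the hypergeometric and clustering oracles.

# Known limitations

* The qPCR module consumes standard-curve starting quantities; curve
  fitting from Cq values is instrument-software territory and out of scope.
* Gel/Western densitometry is reduced to the final band-ratio arithmetic.
* GO term curation, DAG propagation, and network drawing are out of scope;
  gene sets are consumed as flat GMT lines.
* The clustered output is a matrix in leaf order plus the merge tree; no
  heat-map rendering.
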