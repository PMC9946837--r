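---
title: "Methods: quantifying activity-linked DNA damage and somatic mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying activity-linked DNA damage and somatic mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbmut)
```

`dsbmut` implements the quantitative backbone of a class of experiments that
ask whether neuronal activity damages the genome at gene regulatory elements
and whether specific sites are protected from accumulating somatic mutations
with age. Three kinds of data flow through it: targeted-amplicon sequencing
with unique molecular identifiers (UMIs) for ultrasensitive mutation
detection, single-bp double-strand-break (DSB) maps from in-situ
ligation-based sequencing of free DNA ends, and single-nucleus expression
matrices with viral transcript counts. A seeded synthetic-data module
generates all three, with ground-truth labels, so every estimator in the
package can be validated end to end without external downloads.

## UMI consensus and mutation frequencies

### The consensus-10 unanimity standard

Each sequencing read carries a 12-nt random UMI embedded in the forward
primer, so all reads sharing a UMI within an amplicon descend from one
template molecule. `group_umi_families()` partitions reads by exact
`(amplicon, UMI)` match. A family contributes to position $p$ only when

1. it has at least `min_depth = 10` member reads, and
2. every member makes the identical call at $p$ (same base, same deletion,
   or the same inserted sequence at the same anchor).

With per-base read error rate $e$ and errors uniform over the three
alternative bases, a size-$k$ family is *unanimously* wrong at a position
with probability $3(e/3)^k$ — about $5 \times 10^{-28}$ at $e = 0.005$,
$k = 10$. Unanimity therefore converts a per-read error rate of $10^{-3}$ to
$10^{-2}$ into an effectively zero per-family error rate, which is what
makes somatic mutation frequencies of order $10^{-4}$–$10^{-3}$ measurable.

Two conventions are stricter than the minimum the consensus-10 idea
requires, and are deliberate:

* unanimity is demanded of **all** reads in a qualifying family, not a
  subsample of ten — deterministic and conservative;
* UMIs are grouped by exact match, with no edit-distance collapsing. The
  $4^{12} \approx 1.7 \times 10^7$ UMI space dwarfs the few hundred
  templates per site, so UMI collisions and near-duplicates are rare;
  `umi_qc_report()` counts Hamming-distance-1 pairs so the user can verify
  this on their own data rather than trust a network-collapsing heuristic.

### Frequencies

`mutation_frequency()` divides the number of families carrying any change
(substitution, deletion or insertion, one count per family) by the total
number of consensus bases assessed, excluding the first `primer_len = 22`
positions where the primer anneals (synthesis errors in the primer would
otherwise masquerade as mutations). A zero denominator yields a missing
value, never zero — missingness and absence of mutations are different
facts, and only the latter may enter medians and outlier tests.

`class_frequencies()` collapses complementary substitutions (C>T with G>A,
and so on) into six classes because the strand of origin is unknowable, with
per-class denominators restricted to eligible reference bases.
Insertions+deletions form a seventh category over all assessed bases.

`filter_amplicons()` keeps an amplicon only when its mean consensus-family
depth across non-primer bases strictly exceeds `min_mean_depth = 100`.

### Age normalization and outliers

Different target sites have very different baseline fragility, so raw
frequencies are not comparable across sites. `normalize_to_young()` divides
each animal's per-site frequency by the median frequency of that site among
young animals; the young group is then centred at exactly 1 per site (the
even-count median is the mean of the two central values throughout the
package), and middle-aged and old animals become fold changes.

`rout_outliers()` implements a robust outlier test controlling a false
discovery rate $Q$, specialised to a location model: centre = median, scale
= the 68.27th percentile of absolute residuals (the robust standard
deviation of the residuals, RSDR) with small-sample correction $n/(n-1)$,
per-point t-ratios on $n-1$ df, and a Benjamini–Hochberg step-up at
$Q = 0.001$. The widely used commercial implementation of this procedure is
proprietary and fits arbitrary curves; this recipe is frozen here as the
package's reference behaviour and is property-tested: on clean Gaussian
samples ($n = 50$, 1,000 simulations) the false-flag rate stays below 0.5 %,
while a planted point 10 RSDR from the centre is flagged in over 99 % of
simulations.

One ambiguity in the upstream literature is whether a per-animal rate pools
all amplicons before dividing or is computed per amplicon; this package
computes one rate per amplicon per animal (the unit that the young-median
normalization and the outlier test then operate on), which preserves
site-level resolution for the bound/unbound contrast.

## Interval algebra and the regulatory-element landscape

All coordinates are 0-based, half-open (BED convention); every reader and
writer states this. The operations are delegated to
GenomicRanges/IRanges internally and are checked exactly against explicit
per-base depth arrays on random instances up to 10 kb.

* `merge_intervals(x, gap)` bridges separations of at most `gap` bp
  (150 bp for binding-factor peak consolidation); the threshold is strict —
  a 151-bp gap survives a 150-bp merge.
* `reproducible_peaks(sets, m)` computes the base-level depth profile of
  the $n$ replicate peak sets, thresholds at $m$ and segments. The m-of-n
  rules used in practice (5 of 8 for break maps, 4 of 5 or 3 of 3 for
  binding and accessibility) are all expressible this way. Anchoring on one
  replicate's peaks — the other common reading of "intersect" — depends on
  replicate order; depth segmentation is symmetric, which is why it is the
  implementation here.
* `summit_window(x, track, half_width)` replaces an interval with
  $[s - h, s + h)$ around the maximal-signal position $s$, ties broken at
  the smallest coordinate, width exactly $2h$ (the "extend 500 bp from the
  summit" step, read as ±500 bp). All-zero signal falls back to the interval
  midpoint and is flagged; windows are clipped at chromosome bounds and
  flagged, never dropped.
* `build_landscape()` merges the union of reproducible accessibility and
  acetylation peaks (concatenated across time points), optionally subtracts
  a user-supplied blacklist, and emits fixed-width summit windows, each
  labelled by source assay. The ordering adopted — per-assay reproducibility
  per time point, then concatenate, then merge, then blacklist, then
  windows — follows the most natural reading of the published pipeline; the
  blacklist argument sits after merging precisely because the published
  order removes blacklisted regions from the union.
* Binding peaks are extended to fixed widths about their signal maxima
  before overlap tests (`extend_peaks()`): ±500 bp for the 1-kb convention
  used for the bHLH–PAS factor whose motif enrichment justifies it, ±200 bp
  for other factors; both are arguments, not constants.

## DSB quantification

A break record is `(sample, chrom, pos, strand, UMI)`; `dedup_cut_sites()`
collapses PCR duplicates by exact key. The event key includes strand by
default: two opposing free ends at the same base are treated as distinct
ligation events. Published pipelines are silent on this point, so it is a
documented, config-switchable reference behaviour (`key_strand = FALSE`
collapses strands).

`element_counts()` counts unique events whose single-bp cut end falls
inside each element, strand-blind, half-open. Landscape elements are
summit-centred windows and may overlap; an event inside two elements counts
in both (documented, and unavoidable once elements are fixed-width).

`quartile_stratify()` ranks elements by binding signal divided by the IgG
control signal over the element (denominator floored at `eps = 1`
read-depth unit; zero-denominator elements are flagged but still ranked),
cuts the ranking into four equal-count quartiles with a deterministic
stable tie-break, and gates the extremes on peak evidence: Q4-high requires
a binding peak overlap, Q1-low requires its absence.

`genomewide_breaks()` downsample reads — not unique events — to the lowest
per-sample read count before counting unique UMIs, because totals are only
comparable at matched sequencing effort. The draw is seeded; identical
seeds give identical totals.

## Normalization and inducibility

`size_factors()` is median-of-ratios: $s_j = \mathrm{median}_i\,
c_{ij}/(\prod_j c_{ij})^{1/n}$ over elements with all-positive counts,
rescaled to unit geometric mean. It is exact on hand-computable matrices
and agrees with the standard differential-count implementation up to that
rescaling convention (checked in the test suite against DESeq2, which is a
cross-check only, never the implementation). Sparse matrices without an
all-positive element raise an error that names the `pseudo_reference`
fallback (geometric means over positive entries).

Low-count filtering has the two conventions used in practice:
`at_least_two_nonzero` for accessibility/acetylation/damage-mark counts and
`any_nonzero` for the sparser break counts.

`batch_adjust()` fits, per element, an additive least-squares model
`log2(value + 1) ~ condition + batch` and subtracts the fitted batch
component, centred so batch effects sum to zero weighted by batch sizes;
condition contrasts are preserved in balanced designs, and the operation is
idempotent. Confounded designs are an error, and genotype contrasts are
normalized within genotype (run `size_factors()` per genotype group), since
cross-genotype library comparisons were never the target.

### The fold-threshold test

An element is *inducible* when its post-stimulation signal exceeds the
pre-stimulation signal by at least a fold threshold (2 for accessibility,
1.5 for acetylation) at Benjamini–Hochberg adjusted $p < 0.05$. The null
hypothesis is $L \le \log_2(\text{threshold})$, i.e. exceedance of the
threshold, not of zero; an element sitting exactly at 2-fold is not called.
The test is one-sided because only increases define inducibility.

The original analyses used a negative-binomial Wald test with a fold-change
null. That machinery shares dispersion information across elements; a plain
per-element Welch $t$ with 3 vs 3 replicates has only ~4 df, and a
closed-form power calculation shows it cannot reach 90 % sensitivity for
4-fold planted effects at 20 % CV once multiplicity correction is applied,
at any realistic fraction of truly induced elements. `classify_inducible()`
therefore moderates the pooled per-element variance across elements with
empirical-Bayes shrinkage (`limma::squeezeVar`), recovering the pooling
that made the original test powerful while keeping the offset-null
$t$ form; `moderate_var = FALSE` gives the unmoderated Welch variant.
The choice is validated operationally, not by matching another package's
output: on null simulations (2,000 flat elements) the inducible-call rate
stays within $\alpha + 3\,\mathrm{SE}$, and planted 4-fold effects
(3 vs 3, CV 20 %, 200 planted among 1,000 null) are recovered with
sensitivity ≥ 0.9 at empirical FDR ≤ 0.1.

## The resampling null for target-gene downregulation

Nuclei are assigned infection labels from amplified viral transcript
counts: strictly more than 8 mCherry transcripts (and not more than 8 GFP)
means Cre-infected, the converse means ΔCre, neither means uninfected, both
means ambiguous (excluded and tallied). The statistic is the mean over
target genes of the per-gene difference in group-mean normalized
expression, ΔCre − Cre, within one cell type.

Because direct targets are highly expressed, a naive null of random genes
would be too easy to beat. `resample_null()` draws matched gene sets from
the top 10 % of genes by mean expression — computed across all nuclei of
the cell type regardless of infection, a symmetric choice the upstream
description leaves open — and builds the empirical null from `n_iter`
seeded draws without replacement. The p-value is +1-corrected,
$(1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_{\text{iter}})$, never
zero, bottoming out at $1/(n_{\text{iter}}+1)$ when the observed statistic
lies outside the whole null — the signature of genuine target
downregulation. The default orientation tests "observed more positive than
null" (targets down in Cre); it is configurable. Calibration is verified by
simulation: with targets drawn from the null pool on fresh data, the
p-values are uniform (KS test).

## What the generators emulate — and what they do not

All generators are pure functions of `(cfg, seed)`; `sim_config()` carries
the frozen defaults, and truth tables accompany every output.

* **Amplicon reads** — templates per site acquire true mutations at a
  per-base frequency (fixed across the whole family, as a real allele
  would be), family sizes are zero-truncated Poisson(12) (a negative
  binomial alternative models the overdispersion of real UMI families),
  and reads then collect independent per-base errors (default
  $5 \times 10^{-4}$; $5 \times 10^{-3}$ in the error-suppression
  condition). The ageing design follows the study scale: 4 young, 4
  middle-aged, 3 old animals; unbound sites double their frequency by
  middle age while bound sites start higher and stay flat until old age.
  Not modelled: quality strings, adapter chimeras, alignment errors,
  polymerase slippage at homopolymers — so passing tests say the
  *estimator* is right, not that real libraries are this clean.
* **Cut sites** — per-element unique events are Poisson with rate
  `baseline_rate` (0.03 events/bp) times the condition fold, applied only
  to elements carrying an inducible truth label drawn with
  quartile-dependent probability (5–50 % from Q1 to Q4): most of the
  landscape stays flat, which is what makes median-of-ratios normalization
  valid here as in the real data. The time-course design mirrors the study
  (0 h n = 8, 2 h n = 8, 10 h-less-active n = 4, 10 h-still-active n = 6;
  Q4 fold profile 1, 3, 1.5, 3), PCR duplication is 1 + Geometric(0.75),
  and two processing batches (each containing all conditions) multiply a
  random half of elements by 1.5 in one batch.
* **Signal tracks** — per-element binding intensities are log-normal
  (heavy-tailed, like real enrichment), with a 1-bp summit boost so summit
  recovery is testable; the IgG control is flat with low relative noise
  (Gamma, CV ≈ 14 %), as befits signal aggregated over 1-kb windows;
  replicate peak sets include each true region independently with a
  configurable reproducibility probability (1.0 for the high-quality
  accessibility/acetylation assays, 0.7 for the sparser break maps, whose
  5-of-8 survivor fraction then follows the Binomial(8, 0.7) tail).
* **Expression** — gene baselines are log-normal; target genes (drawn from
  the top decile) are multiplied by $1-\text{effect}$ in Cre nuclei; viral
  counts follow the infection truth with 10 % detection dropout. No
  clustering structure, doublets or ambient RNA: cell-type assignment is
  upstream of this package.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the full suite completes
on one CPU in minutes: 2 chromosomes × 1 Mb, 200 landscape elements,
30 amplicons × 122 bp for single-condition checks and 7 × 122 bp × 110
templates (≈ 6 × 10⁴ assessed consensus bases per replicate, 200 replicates
per planted frequency) for estimator-recovery simulations; 1,000 random
instances for the interval oracle; 500 repetitions at `n_iter` 2,000 for
resampling-null calibration, with the saturation check at the full 10,000.

Numerical conventions, in one place: medians of even counts average the two
central values; quartile boundaries are by rank with a stable
`(ratio, chrom, start)` tie-break, so quartile sizes differ by at most one;
summit ties break leftmost; log transforms use a +1 pseudocount on the
normalized scale (config-exposed); replicate groups with zero variance are
floored at `var_floor = 1e-8` with a warning; the IgG denominator floor is
1 read-depth unit; per-base signal decoded from run-length tracks clamps
|value| < 1e-9 to zero to absorb floating-point residue from weighted
coverage; empirical p-values are +1-corrected.

## Known limitations

* Alignment is out of scope: amplicon reads arrive as calls against the
  amplicon reference, break records arrive mapped. Misalignment artefacts
  (the reason the analytic error-suppression bound carries a 10× slack in
  the acceptance checks) are not simulated.
* Statistical peak calling is out of scope; peak calls are inputs, and the
  reproducibility logic assumes they are trustworthy per replicate.
* The moderated offset-null test assumes roughly exchangeable per-element
  variances on the log scale; strongly mean-dependent dispersion would
  call for a trend (`limma`-trend style) fit, which is not implemented.
* The resampling null conditions on the observed per-gene group means; it
  does not propagate uncertainty in those means, exactly as in the
  procedure it reproduces.
* One earlier-stage quantity — per-animal mutation rate — is computed per
  amplicon, not pooled across a primer pool; if pooling is wanted it is a
  one-line `dplyr::summarise` on the profile table.
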