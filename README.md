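# dsbmut

Quantifying activity-linked DNA double-strand breaks and somatic mutations
at neuronal gene regulatory elements.

Stimulus-driven transcription repeatedly breaks DNA at the promoters and
enhancers it activates. Postmitotic neurons cannot dilute that damage by
replication, so the questions of *where* breaks concentrate, *whether* they
resolve as activity subsides, and *whether* recurrently damaged sites
accumulate somatic mutations over a lifetime are quantitative ones — and
the measurements that answer them (UMI-tagged amplicon sequencing,
single-bp break maps, single-nucleus expression with viral barcodes) each
need specialised estimators. `dsbmut` implements that analysis stack for R,
with tibble-in/tibble-out functions, seeded synthetic-data generators with
ground-truth labels, and a validation suite that scores every estimator
against its generator truth or an independent brute-force oracle.

## What it computes

**Somatic mutation frequency from UMI consensus families.** Reads sharing
a 12-nt UMI descend from one template. A family of ≥ 10 reads that agree
*unanimously* at a position contributes one consensus call there; with
per-base error rate $e$, a family is unanimously wrong with probability
$3(e/3)^{10}$ (≈ 5 × 10⁻²⁸ at $e$ = 0.005), so mutation frequencies

$$f = \frac{\#\{\text{families with any change}\}}{\#\{\text{consensus bases assessed}\}}$$

of order 10⁻⁴–10⁻³ are measurable. Per-site frequencies are normalized to
the young-animal median (`normalize_to_young()`), and gross outliers are
removed by a robust FDR-controlled test (`rout_outliers()`, Q = 0.1 %).

**DSB landscapes.** Interval algebra (`merge_intervals()`,
`reproducible_peaks()`, `summit_window()`, `build_landscape()`) builds a
fixed-width, summit-centred regulatory-element landscape from replicate
peak calls (m-of-n base-level reproducibility: 5/8, 4/5, 3/3 …). Break
records are UMI-deduplicated (`dedup_cut_sites()`), counted per element
(`element_counts()`), normalized by median-of-ratios size factors
(`size_factors()`), batch-adjusted, and classified as activity-inducible by
a one-sided moderated *t* test against a fold-change null
(`classify_inducible()`; H₀: fold ≤ 2, BH-adjusted p < 0.05). Elements are
stratified into binding quartiles with peak-gated extremes
(`quartile_stratify()`), and genome-wide unique-break totals are compared
at matched read depth (`genomewide_breaks()`).

**Resampling null for target-gene downregulation.** In single-nucleus data
with viral infection labels (`assign_infection()`, > 8 transcripts), the
observed ΔCre − Cre expression difference of target genes is compared with
10,000 seeded resamples of equally highly expressed genes
(`resample_null()`); the +1-corrected empirical p bottoms out at
1/(n_iter + 1) when the observed statistic lies outside the whole null.

## Worked example

Simulate a full break time course, build the landscape, and classify
inducible elements:

```r
library(dsbmut)

res <- run_dsb_pipeline(list(seed = 11))

nrow(res$landscape)
#> [1] 200
dplyr::count(dplyr::inner_join(res$inducible,
  res$elements_truth[, c("element_id", "quartile")], by = "element_id"),
  quartile, inducible)
#> # A tibble: 5 × 3
#>   quartile inducible     n
#>   <chr>    <lgl>     <int>
#> 1 Q1       FALSE        50
#> 2 Q2       FALSE        50
#> 3 Q3       FALSE        50
#> 4 Q4       FALSE        37
#> 5 Q4       TRUE         13
head(res$genomewide, 3)
#> # A tibble: 3 × 4
#>   sample_id total_reads downsampled_reads unique_events
#>   <chr>           <int>             <int>         <int>
#> 1 0h_r1           10656             10630          7982
#> 2 0h_r2           12634             10630          8311
#> 3 0h_r3           10666             10630          8028
```

All 200 planted regulatory elements are recovered as 1-kb summit-centred
windows; inducible calls concentrate in the top binding quartile (13 in Q4,
none in Q1), the pattern expected when activity-induced breaks track
binding strength. `plot_timecourse(res$normalized, res$samples,
res$quartiles)` shows the damage-and-repair profile (rise at 2 h, return
toward baseline in less-active 10-h samples).

The ageing arm runs the amplicon side end to end:

```r
mut <- run_mutation_pipeline(list(seed = 3))
dplyr::left_join(mut$normalized,
                 mut$panel[, c("amplicon_id", "bound")], "amplicon_id") |>
  dplyr::group_by(bound, age_group) |>
  dplyr::summarise(mean_fold = mean(value, na.rm = TRUE), .groups = "drop")
#> # A tibble: 6 × 3
#>   bound age_group mean_fold
#>   <lgl> <chr>         <dbl>
#> 1 FALSE middle         2.00
#> 2 FALSE old            1.97
#> 3 FALSE young          1.03
#> 4 TRUE  middle         1.10
#> 5 TRUE  old            1.58
#> 6 TRUE  young          1.00
```

Unbound sites double their mutation frequency by middle age while bound
sites stay near baseline — the protection signature the pipeline is built
to detect (the folds are the generator's planted ageing gradient, recovered
by the estimator).

## Package layout

| Area | Functions |
|---|---|
| Intervals & landscape | `merge_intervals`, `reproducible_peaks`, `summit_window`, `build_landscape`, `overlap_flag`, `extend_peaks` |
| Amplicon UMI consensus | `amplicon_panel`, `group_umi_families`, `consensus_composition`, `filter_amplicons`, `umi_qc_report` |
| Mutation statistics | `mutation_frequency`, `class_frequencies`, `normalize_to_young`, `rout_outliers` |
| DSB quantification | `dedup_cut_sites`, `element_counts`, `quartile_stratify`, `genomewide_breaks` |
| Normalization & inducibility | `filter_low_counts`, `size_factors`, `normalize_counts`, `batch_adjust`, `classify_inducible`, `combine_inducible` |
| Resampling null | `assign_infection`, `observed_difference`, `resample_null` (+ `tidy`/`glance`/`autoplot`) |
| Synthetic data | `sim_config`, `simulate_amplicon_reads`, `simulate_cut_sites`, `simulate_signal_tracks`, `simulate_expression` |
| Pipelines & IO | `run_mutation_pipeline`, `run_dsb_pipeline`, BED/bedGraph/TSV readers and writers |

The methods vignette (`vignettes/dsbmut-methods.Rmd`) documents the models,
parameter defaults, generator assumptions, and numerical conventions.
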