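# t3chrom

Condition-dependent chromatin analysis of thyroid hormone (T3) action, as a
tidyverse-native R package.

Thyroid hormone receptors such as TR&beta; bind chromatin and rewire
transcription as hormone levels swing between hypothyroid (MMI) and
hyperthyroid (+T3) states. `t3chrom` implements the full analysis chain for
such a study at desk scale:

- **Island peak calling** — windowed Poisson enrichment with FDR control and
  control-genotype differential calling (50 bp / FDR 1e-6 transcription-factor
  profile; 200 bp / FDR 1e-3 histone profile).
- **Site classification** — *maintained* (bound in both conditions, ≥1 bp
  overlap), *abolished* (hypothyroid only) and *de novo* (hyperthyroid only)
  sites; TSS ±1 kb proximal/distal partition; 75%-overlap replicate
  intersection; the +T3/MMI occupancy-shift ratio at maintained sites.
- **Signal profiles** — site-anchored heatmap matrices (±4 kb, 50 bp bins,
  ranked by center intensity), average profile curves (±2 kb), and a
  center-notch statistic for the nucleosome-clearance dip at inducibly
  opened sites.
- **Differential counts** — exact conditional-binomial ATAC accessibility
  test (|log2FC| ≥ 0.58, BH-adjusted p ≤ 0.05), Student-t RNA response
  classes (≥1.5-fold, raw p < 0.05, CPM > 1 filter), Mann–Whitney group
  comparisons.
- **DR4 motif scanning** — AGGTCA half-site scanner with direct /
  palindromic / everted pairing over spacers 0–8 and hypergeometric
  per-spacer enrichment against a dinucleotide-shuffled background. The
  canonical T3 response element is the 4-spacer direct repeat (DR4):
  `AGGTCA NNNN AGGTCA`.
- **Gene association** — distance-resolved site–gene incidence curves to
  100 kb, knockout *blunting* classification of hormone-responsive genes,
  and the matched inducible-vs-constitutive open-chromatin comparison.
- **Synthetic data** — a seeded generator that plants all of the above
  structure (site categories, occupancy boost of 1.34, inducible opening,
  DR4 motifs, linked gene responses, knockout blunting) with ground-truth
  labels for parameter-recovery testing.

Everything takes and returns tibbles, chains with the pipe, and exposes
`tidy()` / `glance()` / `autoplot()` methods for each result type.

## Worked example

Simulate a small study and run the whole pipeline:

```r
library(t3chrom)

cfg <- t3_sim_config(
  n_chroms = 2, chrom_length = 1.5e6,
  n_sites = c(maintained = 30, abolished = 30, de_novo = 24),
  n_genes = 60, n_depleted_free = 4, rng_seed = 7)
run <- run_t3_pipeline(cfg)
run
#> <t3_run>
#> <category_result> MMI 60, +T3 54 -> maintained 30, abolished 30, de novo 24 (total 84)
#>   TSS partition: 17 proximal, 67 distal
#>   maintained occupancy shift (+T3/MMI): 1.323
#>   ATAC: 4 increased, 4 depleted; notch 0.52
#>   top DR spacer: 4
#>   RNA: 9 induced, 13 suppressed
#> # A tibble: 2 × 6
#>   response   total impaired unimpaired fraction_impaired pct_impaired
#>   <chr>      <int>    <int>      <int>             <dbl>        <dbl>
#> 1 induced        9        7          2             0.778           78
#> 2 suppressed    13        7          6             0.538           54
#>   site-category recovery: 100.0%
```

Reading the report: the differential caller found every planted site in
each condition (60 MMI and 54 +T3 peaks), the overlap classification
recovered the planted 30/30/24 category split exactly, the maintained-site
occupancy ratio 1.323 estimates the planted +T3 boost of 1.34, the
H3K27ac profile over inducibly opened sites shows a central notch (0.52 <
1), DR4 (spacer 4) tops the motif enrichment at maintained sites, and the
knockout blunting percentages are computed over the genes the RNA stage
called responsive. `glance(run)` returns the same numbers as a one-row
tibble; each stage's full result lives in `run$peaks`, `run$classification`,
`run$atac`, `run$enrichment`, `run$curve`, `run$matched`, ...

Individual stages work standalone on your own tibbles:

```r
best_dr_hit(reporter_elements()["dr4"])
#> # A tibble: 1 × 6
#>   seq_id offset spacer orientation strand mismatches
#>   <chr>   <int>  <int> <chr>       <chr>       <int>
#> 1 1           0      4 direct      +               0

blunting_summary(c("induced", "suppressed"), c(516, 714), c(460, 570))
#> # A tibble: 2 × 6
#>   response   total impaired unimpaired fraction_impaired pct_impaired
#>   <chr>      <int>    <int>      <int>             <dbl>        <dbl>
#> 1 induced      516      460         56             0.891           89
#> 2 suppressed   714      570        144             0.798           80
```

The methods vignette (`vignettes/t3-chromatin-methods.Rmd`) documents the
models, the open design decisions and their rationale, the generator's
defaults, and known limitations.

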