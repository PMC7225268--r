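# imetk

Benchmarking tools for chronic intracortical microelectrode (IME) studies
in rodents. The package addresses two questions a lab comparing rat and
mouse implant models has to answer quantitatively:

1. **Are the electrophysiological outcomes comparable?** Raw multi-channel
   extracellular recordings are reduced to five recording-quality metrics
   — per cent of working channels with single units, units per working
   channel, background noise level, unit peak-to-peak amplitude, and SNR —
   and the two animal groups are compared per metric over the total
   (weeks 1–8), acute (1–2) and chronic (3–8) ranges with a nested general
   linear model (animals nested within group; the group effect tested
   against the animal-within-group mean square, F(g−1, a−g)).
2. **Does implant micromotion strain the tissue differently in the two
   species?** A 3D linear-elastic finite-element model of a silicon shank
   (E = 200 GPa, ν = 0.27) embedded in cortex (E = 6 kPa, ν = 0.43)
   under a 20 µm tangential displacement at the shank top, solved on a
   graded tetrahedral mesh. Strain is summarized by the von Mises
   equivalent strain
   ε_e = 1/(1+ν)·√(½[(ε₁−ε₂)² + (ε₂−ε₃)² + (ε₃−ε₁)²]),
   normalized jointly across the rat and mouse models, profiled laterally
   at the brain top, probe mid-point and tip, and compared between species
   by Pearson correlation.

Because chronic animal recordings are rarely shareable, the package ships a
seeded synthetic-data module (16-channel sessions at 24.4 kHz with known
inserted units; two-group longitudinal studies with a declining yield) so
the whole pipeline — detection at 3.5× robust noise SD, 37-sample snippets,
PCA + Gaussian-mixture sorting with rule-based curation, metrics, GLM — is
testable against ground truth.

## Worked example: a two-group longitudinal study

```r
library(imetk)
library(dplyr)

study <- simulate_study(study_spec(seed = 42))          # 6 rats vs 14 mice
tbl   <- build_study_table(study_channel_truth(study))  # windowed metrics
head(tbl, 3)
#> # A tibble: 3 × 11
#>   group animal    week session pct_channels_with_units units_per_channel
#>   <chr> <chr>    <int>   <int>                   <dbl>             <dbl>
#> 1 mouse mouse_01     1       1                    37.5             0.375
#> 2 mouse mouse_01     1       2                    62.5             1.38
#> 3 mouse mouse_01     2       1                    62.5             1.12

run_comparison_suite(tbl) |>
  filter(metric == "units_per_channel") |>
  select(metric, time_range, f_statistic, df_num, df_den, p_value, significant)
#> # A tibble: 3 × 7
#>   metric            time_range f_statistic df_num df_den p_value significant
#> 1 units_per_channel total           0.192       1     18   0.667 FALSE
#> 2 units_per_channel acute           0.0779      1     18   0.783 FALSE
#> 3 units_per_channel chronic         0.497       1     18   0.490 FALSE
```

Seed 42 generates a *null* study (no group effect), and the suite finds
none: the F statistics are small and no comparison reaches α = 0.05. Add
`group_effect = list(group = "rat", metric = "units_per_channel",
value = 2, weeks = 1:2)` to the spec and the acute and total comparisons
become significant while the chronic one stays null. `plot_study_metrics(tbl)`
shows the weekly group means; `tidy()`/`glance()` work on single fits from
`fit_nested_glm()`.

To process raw voltage instead of ground truth, `simulate_study(...,
traces = TRUE)` produces full recordings and `process_session()` runs
filtering → common average reference → artifact rules → detection →
sorting, returning the same per-channel table shape.

## Worked example: the rat–mouse strain comparison

```r
cmp <- run_strain_comparison()   # builds, meshes and solves both models
cmp$correlation
#> [1] 0.9987785
cmp$joint_max$species            # model holding the global strain maximum
#> [1] "mouse"
plot_strain_profiles(cmp$profiles)
```

The normalized fields span [0, 1] jointly; the global maximum sits at the
mouse probe tip, and the two species' 3 × 51-point profiles correlate at
r ≈ 0.999 at the default mesh resolution (~31k tetrahedra rat, ~17k
mouse). `run_strain_comparison(out_dir = "...")` additionally writes VTK
fields, a profiles CSV and a JSON summary.

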