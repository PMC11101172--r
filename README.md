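# saltmig

Quantification of cyclic saltatory neuronal migration from time-lapse
tracks.

Neuroblasts travelling along the postnatal rostral migratory stream (RMS)
toward the olfactory bulb do not glide smoothly: they migrate in a
"two-stroke" cycle in which the centrosome first advances into a swelling of
the leading process (**centrokinesis, CK**), the nucleus then jumps forward
(**nucleokinesis, NK**), and the cell pauses before the cycle reinitiates.
`saltmig` turns manually tracked x,y,t coordinates of nuclei (and optionally
centrosomes) into the event-level and per-cell statistics used to compare
genotypes in this kind of experiment, and ships a calibrated stochastic
simulator of saltatory tracks so the entire pipeline can be exercised and
validated without microscope data.

## What it computes

For a nucleus track sampled every *dt* = 3 min:

- **NK events** — maximal runs of inter-frame displacements strictly
  greater than 6 µm; per event: timing, number of frames, path distance,
  net distance.
- **Speed** — total path length / total time (pauses included), µm/hr.
- **Pausing time** — % of time slots with displacement ≤ 6 µm.
- **Sinuosity** — path length / straight-line start-to-end distance (≥ 1).
- **Migration angle θ** — angle between the net displacement vector and
  the SVZ→OB reference axis, in [0°, 360°), 0° = straight toward the bulb;
  cohorts are summarised as four-dial **migration radars**
  (forward/left/backward/right, 90° each).
- **CK events** — on the centrosome–nucleus separation s(t): a rise > 2 µm
  above a local baseline followed by a fall > 2 µm below the running peak;
  a CK is **efficient** when an NK starts after its peak and before the
  next CK's onset.
- **QC** — cells tracked < 30 min or with zero NK are excluded (with
  machine-readable reasons).

The statistical layer mirrors standard practice for these data:
Kruskal–Wallis on ranks with Dunn's post hoc test (Benjamini–Hochberg
adjusted), Mann–Whitney for pairs, Pearson χ² and Fisher's exact test
(Monte-Carlo for R×C tables) for categorical outcomes, and median (IQR)
summaries throughout.

## Worked example

Simulate a control and an *Fmr1*-null cohort, compute per-cell metrics, and
compare them:

```r
library(saltmig)
library(dplyr)

ctrl <- simulate_cohort(preset("control"),   n_cells = 50, seed = 1, group = "control")
null <- simulate_cohort(preset("fmr1_null"), n_cells = 50, seed = 2, group = "fmr1_null")

metrics <- bind_rows(compute_cell_metrics(ctrl$cells),
                     compute_cell_metrics(null$cells)) |>
  filter(qc_pass)

summarize_groups(metrics, speed, group)
#> # A tibble: 2 × 6
#>   group         n median    q1    q3   iqr
#>   <chr>     <int>  <dbl> <dbl> <dbl> <dbl>
#> 1 control      50   60.3  51.3  66.9 15.5
#> 2 fmr1_null    48   38.8  35.0  43.9  8.85

glance(mann_whitney(metrics, speed, group))
#> # A tibble: 1 × 5
#>   test                       statistic    df  p.value n_groups
#>   <chr>                          <dbl> <dbl>    <dbl>    <int>
#> 1 Mann-Whitney rank sum test      2275    NA 2.18e-14        2
```

The simulated control cells migrate at a median ~60 µm/hr versus ~39 µm/hr
for the mutant preset, a slow-down the rank test calls at p < 0.001 — the
direction and rough magnitude of the genotype difference the presets are
calibrated to. Two mutant cells fail QC (no NK in 2.5 hr), visible in the
lower n. Radar and event-level views:

```r
radar_bin(metrics$angle_deg[metrics$group == "fmr1_null"])
#> # A tibble: 4 × 5
#>   dial     from_deg to_deg count   pct
#>   <chr>       <dbl>  <dbl> <int> <dbl>
#> 1 forward       315     45    35 72.9
#> 2 left           45    135     5 10.4
#> 3 backward      135    225     1  2.08
#> 4 right         225    315     7 14.6

autoplot(radar_bin(metrics$angle_deg[metrics$group == "control"]))  # rose plot
```

Real data enter through `read_tracks("tracks.csv")` (tidy CSV with
`cell_id, role, frame, t_min, x_um, y_um`), followed by `split_at_gaps()`,
`pair_cells()`, and the same metric functions — or in one step through
`run_pipeline(run_config(...))`, which also writes a traceable output
bundle (metrics and event CSVs, radar JSON, config, log). A thin command
line lives at `inst/cli/saltmig.R` with `simulate`, `convert`, `analyze`
and `compare` subcommands.

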