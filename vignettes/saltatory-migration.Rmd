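---
title: "Quantifying cyclic saltatory migration: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cyclic saltatory migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltmig)
library(dplyr)
```

## The measurement problem

Neuroblasts of the postnatal rostral migratory stream (RMS) move in a
cyclic, saltatory fashion: the centrosome advances into a swelling of the
leading process (centrokinesis, CK), the nucleus then translocates in a
discrete jump (nucleokinesis, NK), and the cell pauses. Time-lapse
experiments on acute slices record the nucleus — and, with a centrosomal
label, the centrosome — every 3 minutes for 2–3 hours, and migration
phenotypes (e.g. of *Fmr1*-null neurons) are described through event-level
and per-cell statistics of these tracks. `saltmig` implements that
quantification as a tested pipeline operating on x,y,t coordinates; image
processing and the manual tracking step itself are upstream and out of
scope.

## Event definitions and their numerical details

**NK.** An NK step is an inter-frame nuclear displacement *strictly*
greater than 6 µm (at the 3-min interval). A displacement of exactly 6 µm
is a pause — "greater than" is taken literally, which also makes pausing
time and NK detection exact complements
(`pausing_pct + supra-threshold % = 100`).

Consecutive supra-threshold steps are merged into a single NK event by
default, and the event's distance is the path length across its frames.
The rationale: per-NK distances reported for these neurons (medians
around 9–12 µm, upper quartiles well above) exceed what a single 3-min
step barely over threshold would produce, implying that translocations
spanning two frames are one biological jump, not two. Because the original
analysis does not state this choice, `merge = FALSE` (CLI `--nk-merge off`)
is provided as a sensitivity flag: it can only increase event counts and
decrease per-event distances.

**CK.** Forward and backward centrosome movement is measured on the scalar
centrosome–nucleus separation s(t), restricted to timepoints shared by the
two tracks. Working nucleus-relative keeps CK from being conflated with
whole-cell translocation (an NK moves the centrosome too); it also matches
an analysis that explicitly uses both the centrosome's and the
corresponding nucleus's coordinates. The alternative — projecting the
centrosome's position on the SVZ→OB axis — is available as
`ck_frame = "absolute"` for sensitivity analysis.

Detection scans s(t) greedily left to right: an event opens at the running
minimum (its baseline), is armed once s has risen more than 2 µm above the
minimum preceding some point, peaks at the highest armed point, and closes
at the first timepoint more than 2 µm below the running peak; the scan then
restarts at the close. Both amplitudes are therefore strictly > 2 µm by
construction, exactly 2 µm does not qualify, and events cannot overlap. An
exhaustive reference implementation (searching all onset/peak/close
triples) backs the scan in the test suite.

**CK efficiency.** "Followed by a subsequent NK" is formalised as: CK *k*
is efficient iff an NK starts in the window `(peak_t(k), onset_t(k+1)]`,
the last window ending at the end of the track. This is the tightest
non-overlapping assignment — a candidate NK must begin after the
centrosome's excursion peaks, and before the next excursion starts, so each
NK can validate at most one CK. CK speed, which the source conventions do
not define, is taken as the centrosome's path length over
`[onset_t, end_t]` divided by the event duration (µm/hr), reported per cell
as a median.

**Angles and radars.** The migration angle is the signed angle from the
user-supplied SVZ→OB reference vector to the cell's net displacement,
counter-clockwise positive, in [0°, 360°). The radar uses four 90° dials
centred on 0°/90°/180°/270° (forward `[315°, 45°)`, left, backward,
right); a boundary angle belongs to the dial it opens. The exact dial
edges are not printed in the source material; centred dials are the
natural reading of "four spatial dials" with forward aligned to the axis.

**QC and gaps.** Cells tracked < 30 min or performing no NK are excluded,
with machine-readable reasons (`too_short`, `no_nk`). Tracks with missing
frames are split at gaps rather than interpolated — a 6 µm / 3 min
threshold is undefined over a 9-min interval — and single-point fragments
are dropped (they carry no interval; a fragment shorter than 30 min is then
excluded by QC anyway). Raw coordinates are never smoothed. Metrics are
computed for all cells with a `qc_pass` flag so exclusions remain
auditable; group statistics should filter on it (the pipeline does).

Degenerate inputs: zero net displacement makes sinuosity and the migration
angle undefined — both return `NA` with a warning rather than an error, and
radar binning drops `NA`s. A missing centrosome track yields `NA` CK
metrics, not a failure.

## The synthetic-data generator

`simulate_cell()` implements the two-stroke cycle as a semi-Markov process
on the exact 3-min grid: a geometric pause; a CK in which the separation
rises by a lognormal amplitude over one frame and falls back over one or
two (2–3 intervals total, a triangular profile); then, with probability
`p_efficient_ck`, an NK — a lognormal path distance along a von Mises
heading centred on the SVZ→OB axis, split over two frames when it exceeds
twice the detectability floor. Inefficient CKs arise from cycles whose NK
coin-flip fails (plus an optional `extra_ck_rate`). Pause-frame positions
scatter around the cell's anchor path with isotropic Gaussian jitter;
jump frames are emitted exactly from the previously emitted position, so
every generated NK step exceeds the 6 µm threshold by construction and the
ground-truth event log is consistent with the emitted track. Cohorts use
seed-derived per-cell substreams, so any cell can be regenerated in
isolation and results are bit-reproducible from the master seed.

Parameter choices, with units and defaults:

| parameter | default (control) | meaning |
|---|---|---|
| `dt` | 3 min | frame interval of the emulated acquisition |
| `duration` | 150 min | track length (sessions run 2–3 hr) |
| `cycle_rate` | 2.5 /hr | expected NK rate |
| `p_efficient_ck` | 0.54 | P(CK followed by NK) |
| `nk_step_median`, `nk_step_logsd` | 11.5 µm, 0.25 | lognormal NK path distance |
| `nk_min_step` | 6.5 µm | left-truncation floor (detectability) |
| `ck_amplitude_median` | 4.5 µm | lognormal CK forward amplitude (floor 2.3 µm) |
| `jitter_sd` | 0.9 µm | pause-frame positional noise per frame |
| `sep_noise_sd` | 0.25 µm | noise on the separation trace |
| `heading_kappa` | 8 | von Mises concentration of NK headings |

The genotype presets pin NK rate, NK step size and CK efficiency to the
reported per-genotype values (control 2.5 NK/hr, ~11.5 µm, 54%;
*Fmr1*-null 1.2 NK/hr, ~9.3 µm, 33%) and encode the directionality
phenotype through `heading_kappa` (8 vs 1.5). The MAP1B-knockdown rescue
preset restores the control rates but keeps the mutant's low κ, because
trajectory straightness is the one parameter not rescued in that
condition. Free parameters were set once against the printed cohort
medians: `jitter_sd` ≈ 0.9 µm reproduces ~82–84% pausing in controls and
~93% in mutants while keeping P(jitter step > 6 µm) below 1e-4 (the
Rayleigh tail of the inter-frame jitter step), and the CK amplitudes give
control CK speeds near 80 µm/hr versus ~50–60 µm/hr for the mutant.

Two calibration tensions are worth stating honestly rather than hiding:

- The reported NK rate (2.5/hr), CK rate (3.3/hr) and CK efficiency (54%)
  cannot all hold in a model where every NK follows a CK
  (2.5/0.54 ≈ 4.6 CK/hr). The generator keeps the NK rate and the
  efficiency, so its emergent CK frequency is higher than the printed one;
  between-genotype ordering is preserved.
- Matching the printed interquartile ranges of per-cell NK distance would
  require a step log-SD large enough that the cohort median of per-cell
  means drifts more than 10% above `nk_step_median` (per-cell means of ~6
  draws are much tighter than single draws). The generator keeps the tight
  log-SD; printed IQRs are treated as approximate targets only.

**What passing the simulation-based checks shows — and what it does not.**
The generator produces exactly the structure the detectors assume: events
on the sampling grid, stationary pauses, noise well below threshold. Tests
against it therefore validate the *implementation* (detector correctness,
metric arithmetic, statistical ordering between regimes) — they do not
validate the 6 µm / 2 µm thresholds against biology, nor the detectors'
behaviour under tracking artefacts real data contain (drift of the slice,
mis-clicks, cells leaving focus, z-excursions projected into x,y). Real
tracks should be inspected with `plot_track()` and analysed with the
sensitivity flags before trusting borderline group differences.

## Statistical layer

Migration metrics in this setting are skewed and bounded, and the reported
comparisons are nonparametric throughout; the pipeline defaults to the
same path: Kruskal–Wallis (tie-corrected, χ² reference) with Dunn's post
hoc z tests from mean ranks, Benjamini–Hochberg adjusted; Mann–Whitney for
pairs (exact for small tie-free samples, tie-corrected normal approximation
otherwise); Pearson χ² without continuity correction and Fisher's exact
test for categorical tables (exact hypergeometric for 2×2; for R×C a
Monte-Carlo p over ≥ 1e5 margin-fixed tables with a fixed, recorded seed
and reported Monte-Carlo standard error — small tables make full network
enumeration unnecessary). Quantiles are type-7 (linear interpolation), so
"median (IQR)" summaries match the usual convention. Normality gating
(Shapiro–Wilk/Levene) is deliberately not an automatic switch: the
reproduced analysis path is the nonparametric one, and silently switching
tests on a gate would change results between datasets.

Dunn's test is implemented in-package (with the standard tie correction)
and verified against first-principles rank arithmetic in the tests; the
other tests wrap the standard `stats` implementations.

## Problem sizes used in validation

The shipped checks run at sizes chosen to make sampling error small
relative to the effects being verified: oracle equivalence of the three
event detectors on 1,000 random tracks of up to 30 steps; cohort
validation at 200 cells per preset (NK recovery ≥ 95% with ≤ 5% spurious
events — in practice 100%/0% by construction; per-cell NK distance medians
within 10% of the generating median; all eight metric orderings between
control and mutant at Mann–Whitney p < 0.01); and 5,000 null simulations
(3 × 20 observations) for the empirical type-I error of the
Kruskal–Wallis layer, expected at 0.05 ± 0.01. `scripts/acceptance.R`
recomputes all of this from scratch at any seed.

## Known limitations

- 2D only; z-motion is assumed negligible or projected away upstream.
- The SVZ→OB axis is user-supplied per dataset, not estimated from
  anatomy.
- The simulator is phenomenological: no leading-process morphology, no
  microtubule mechanics, no cell–cell interactions, and pause positions
  are white-noise jitter rather than slow drift — its sinuosity values are
  therefore higher than those of smooth real trajectories, and only
  relative (between-preset) comparisons of sinuosity are meaningful.
- CK speed has no published definition; values are comparable within this
  package but not necessarily to other toolchains.
- Gap splitting renames sub-tracks (`id.1`, `id.2`), so a heavily gapped
  cell contributes several shorter cells to the analysis rather than one
  long one.
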