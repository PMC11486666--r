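# prwalk

Persistent random walk analysis of 3D cell trajectories.

`prwalk` is for quantitative cell-migration studies — typically T cells
imaged by volumetric time-lapse microscopy in lymph nodes, on 2D adhesive
surfaces, or inside 3D collagen matrices — where the raw data are tables of
tracked positions and the questions are: how fast and how persistently do
the cells move, does the population hide distinct motility modes, and do
those modes shift between genotypes or treatments?

The package provides, as composable tidyverse-style functions:

* **Track I/O** — a tidy track table (`track_id`, `frame`, positions in µm,
  condition labels) read/written as CSV, with configurable column dialects
  for foreign tracker exports, timestamp-to-frame snapping, and implicit
  gap handling.
* **Classical motility metrics** — mean track speed, arrest coefficient
  (% of frame-to-frame speeds < 2 µm/min), ensemble mean squared
  displacement, turning angles, plus the standard eligibility presets
  (minimum duration, minimum net displacement, minimum valid velocities,
  continuous-tracking requirements).
* **Heterogeneous random-walk inference** — the core of the package. Cell
  velocity is modelled as a first-order autoregressive process
  `u_t = q_t u_{t-1} + a_t n_t`, with persistence `q ∈ [-1, 1]` and
  activity `a ≥ 0` (µm/min) allowed to vary in time. A grid-based
  sequential Bayesian filter (101 × 100 grid over `q ∈ [-1,1]`,
  `a ∈ (0,10]`) turns each cell's velocity series into per-step posteriors
  and point estimates, with a boxcar spreading kernel providing the
  forgetting that tracks parameter changes.
* **Sub-population analysis** — DBSCAN outlier removal and k-means
  clustering of per-cell `(q̄, ā)` averages, a deterministic geometric rule
  mapping clusters onto the ↑a↑q / ↓a↑q / ↓a↓q motility tags, bootstrap
  stability of the merged proportions (100 replicates), two-population
  proportion z tests between conditions, and 50/80/95% highest-density-
  region contours of the `(q, a)` parameter cloud.
* **A trajectory simulator** with per-step ground truth (constant, stepped,
  or smoothly varying parameters; population mixtures; acquisition gaps;
  immobile "dead" cells), so the whole pipeline is testable end to end
  without any external data.

## Worked example

Simulate a 60-cell cohort from the default four-mode mixture (fast
persistent, slow persistent, slow erratic, 10% immobile "dead" cells),
apply the clustering eligibility filter, infer per-cell parameters, and
recover the sub-population structure:

```r
library(prwalk)
library(dplyr)

cohort <- simulate_cohort(simulation_config(n_cells = 60, seed = 42,
                                            gap_rate = 0.03))
kept <- apply_track_filters(cohort$tracks, "clustering")
fit <- infer_cells(kept$tracks, method = "forward")
glance(fit)
#> # A tibble: 1 × 9
#>   n_cells n_eligible mean_q_bar mean_a_bar   n_q   n_a half_width_q half_width_a
#>     <int>      <int>      <dbl>      <dbl> <int> <int>        <int>        <int>
#> 1      60         60      0.476       1.32   101   100            3            3

eligible <- filter(fit$summary, eligible)
eligible %>% group_by(population) %>%
  summarise(n = n(), q_bar = mean(q_bar), a_bar = mean(a_bar))
#> # A tibble: 4 × 4
#>   population     n    q_bar a_bar
#> 1 dead           6 1.49e-17 0.120
#> 2 hi_a_hi_q     24 6.55e- 1 2.15
#> 3 lo_a_hi_q     15 6.31e- 1 1.11
#> 4 lo_a_lo_q     15 2.24e- 1 0.686
```

The per-population averages recover the generating parameters (fast mode
simulated at q = 0.7, a = 2; dead cells sit at the bottom of the activity
grid). Clustering and bootstrap then reproduce the mixture proportions —
dead cells land in the merged low-motility tag, as intended:

```r
mask <- remove_outliers(eligible)
report <- label_and_merge(cluster_cells(eligible[mask, ], k = 4, seed = 1))
report$proportions
#>   tag       proportion
#> 1 hi_a_hi_q      0.390
#> 2 lo_a_hi_q      0.254
#> 3 lo_a_lo_q      0.356

tidy(bootstrap_proportions(eligible, k = 4, n_reps = 100, seed = 1))
#>   tag       mean_proportion sd_proportion mean_cumsum sd_cumsum
#> 1 hi_a_hi_q           0.400        0.0702       0.400    0.0702
#> 2 lo_a_hi_q           0.258        0.0644       0.658    0.0722
#> 3 lo_a_lo_q           0.342        0.0722       1        0

two_proportion_z_test(30, 100, 50, 100)
#>   estimate1 estimate2     z p_value
#> 1       0.3       0.5 -2.89 0.00389
```

`run_pipeline(run_config(...))` (or the thin CLI in
`inst/scripts/prwalk.R`) chains all stages from a single seeded YAML config
and writes per-stage CSV/JSON artifacts plus a reconciled run manifest.
`autoplot()` methods cover MSD curves, per-cell estimate traces, contour
sets, and stacked proportion bars.

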