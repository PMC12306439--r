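# microfission

Lineage tracking and size-control analysis for time-lapse imaging of
confined *Chlamydomonas reinhardtii* microcolonies.

Quasi-2D colonies growing between a gel pad and a coverslip under a
12 h : 12 h light–dark cycle divide by **multiple fission**: a mother grows
through G1, commits to division once large enough, and at the light-to-dark
transition (LD12) executes *n* rapid fission rounds yielding 2ⁿ daughters.
Given per-frame segmentation tables (centroid, area, minor axis per cell),
this package reconstructs who-divided-into-whom and quantifies the two size
controls that organise the cycle:

* **growth**: exponential area growth *A(t) = A(0)·e^{μt}*, fitted per
  colony and cycle by log-linear least squares;
* **mitotic sizer**: *n* = clip(⌈log₂(A/A_d)⌉, 1, n_max) fission rounds from
  mother size, with the division target *A_d* fitted from tracked events;
* **commitment sizer**: the mitotic percentage (fraction of cells in a size
  bin entering S/M between consecutive frames) rises ~linearly with size and
  plateaus above a threshold; a continuous two-segment regression locates
  that knee (~75 µm²);
* **spatial structure**: radial ring statistics, kymographs of cell size
  over time × radius, and centre-vs-edge phase lags in crowded colonies.

A ground-truthed agent-based simulator (`simulate_colony()`) generates
synthetic colonies with diurnal division waves, the 2ⁿ sizer, gel-stiffness
effects and crowding, and is used to validate the tracker (precision/recall
against known lineages) and every downstream statistic. It is intended for
microbial cell-biology labs doing time-lapse microscopy of sessile,
synchronised microalgae, and for method developers who need a tracking
benchmark with known truth.

## Worked example

```r
library(microfission)

res <- run_pipeline(config = sim_config(seed = 1), n_colonies = 4)
res
#> <pipeline_result>
#>   colonies: 4, onsets: 16 (median interval 24 h)
#>   cycle-1 growth rate: 0.06665 /h
#>   commitment breakpoint: 75 um2, sizer target: 32.58 um2
#>   tracker P/R/F1 vs truth: 0.984 / 0.957 / 0.970
```

What the numbers mean: the four simulated colonies divide in nightly waves
(median spacing of detected division onsets = 24 h, the diurnal period); the
first-cycle exponential growth rate recovers the generator's light-phase
μ₀ ≈ 0.07 h⁻¹; the segmented fit to the pooled mitotic-percentage-vs-size
curve puts the commitment knee at 75 µm², the generator's threshold; the
fitted sizer target (32.6 µm²) sits ~7 % below the generating 35 µm² because
pre-division sizes are observed one frame (one hour of growth) before the
split; and against the simulator's ground-truth lineages the tracker links
parents to daughters with F1 = 0.97.

Individual stages compose with the pipe and have `tidy()` / `glance()` /
`autoplot()` methods:

```r
frames <- read_frame_table("frames.csv")           # or bind_sim_frames(...)
forest <- reconstruct_lineage(frames)              # persistent identities
series <- compute_size_series(frames)
onsets <- detect_division_onsets(series)
fit_growth_by_cycle(series, onsets)                # per-cycle mu
mp <- mitotic_percentage(frames, forest, binning = "size")
fit_commitment_breakpoint(mp)                      # commitment knee
fit_sizer(sizer_events(forest, mode = "area"))     # division target A_d
autoplot(series, schedule = light_schedule())
autoplot(radial_kymograph(frames, ring_width = 10))
```

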