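---
title: "Models and methods: lineage tracking and size control in confined microcolonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: lineage tracking and size control in confined microcolonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfission)
library(dplyr)
```

# The biological system

*Chlamydomonas reinhardtii* proliferates by multiple fission: a mother cell
grows through an extended G1 phase, enlarging up to an order of magnitude,
then executes $n$ rapid alternating rounds of DNA synthesis, mitosis and
cytokinesis (S/M), releasing $2^n$ daughters of roughly uniform size. Under a
12 h light : 12 h dark schedule the population synchronises: growth is
photosynthetic and happens mostly in the light, while division clusters
around the light-to-dark transition (called LD12 here) and extends into the
night.

Two size controls organise the cycle:

* a **commitment sizer** (primary arrest point): above a cross-sectional area
  threshold of about 75 µm² a cell is irreversibly committed to completing
  its cycle; below it the per-cycle probability of entering division rises
  approximately linearly with size, so the binned "mitotic percentage"
  (fraction of cells in a size bin that enter S/M between consecutive hourly
  frames) increases linearly and then plateaus — the knee of that curve
  estimates the commitment size;
* a **mitotic sizer**: the number of fission rounds is set by mother size,
  $n = \mathrm{clip}\!\left(\lceil \log_2 (A / A_d) \rceil,\, 1,\, n_{\max}\right)$,
  with division target $A_d \approx 35$ µm² and $n_{\max} = 5$, which
  reproduces the canonical bin-to-round mapping (mothers of 40–70 µm² divide
  once into 2 daughters, 70–100 µm² run two rounds into 4, larger mothers
  three or more) and keeps daughter sizes in a narrow band.

When colonies grow confined between a stiff pad and a coverslip, mechanics
enters: stiffer gels slow growth and delay division past LD12, and crowding
in the colony interior retards cells relative to the edge, which desynchronises
the colony radially and produces ring-like spatial patterns of cell size.

This package implements the measurement side (lineage tracking from
segmentation tables, onset detection, growth and sizer fits, spatially binned
statistics) together with an agent-based generator of synthetic colonies
whose ground truth exercises every stage.

# Pipeline stages

`run_pipeline()` chains the stages; each is usable on its own.

1. **Frame tables** (`read_frame_table()`, `frame_table()`): one row per
   segmented cell per frame with centroid (µm), cross-sectional area (µm²)
   and minor-axis length (µm). Time is decimal hours from the start; frames
   excluded upstream (e.g. out of focus) are simply absent and are handled
   as gaps. All coordinates are physical; pixel calibration belongs to
   segmentation, and `frames_from_labels()` therefore requires an explicit
   `um_per_px`.
2. **Lineage reconstruction** (`reconstruct_lineage()`): persistent
   identities by greedy nearest-neighbour linking, division calls by size
   drop, gap tolerance for temporarily missed cells (details below).
3. **Phenology** (`compute_size_series()`, `detect_division_onsets()`,
   `fit_growth_rate()`, `division_timing_shift()`): colony-level division
   onsets from the peak/valley structure of mean cell area, exponential
   growth-rate fits per cycle, and signed division-timing shifts relative to
   LD12.
4. **Spatial statistics** (`colony_geometry()`, `mitotic_percentage()`,
   `radial_kymograph()`, `ring_boxplot_summary()`): radial binning from the
   colony *edge* or *centre* — the two references answer different questions
   and every output records which one was used.
5. **Size-control fits** (`fit_sizer()`, `fit_commitment_breakpoint()`,
   `estimate_volume()`): data-driven estimates of $A_d$ and of the
   commitment knee; cell volumes by ellipsoid extrapolation
   $V = \tfrac{2}{3} A m$ (projected area $A$, minor axis $m$ taken as the
   z-extent), which reduces to the sphere formula when $m$ equals the
   equivalent diameter.

# The tracker

Cells are matched frame to frame by spatial proximity. For a parent $P$ with
area $A_P$ the candidate set is all next-frame cells within
$1.5 \times \sqrt{A_P/\pi}$ (1.5 times half the equivalent diameter) of its
centroid. A candidate $D$ is

* a **continuation** when $A_D > A_P / 1.5$ — same identity carried forward;
* a **daughter** when $A_P / A_D \ge 1.5$ — at the exact ratio the drop
  counts as a division.

Assignment is greedy by ascending centroid distance with a deterministic
tie-break on (distance, |area change|, labels); each next-frame cell receives
at most one parent, and a parent takes either one continuation or its
daughters, never both. On scenes of up to eight cells this greedy rule
provably matches a brute-force assignment that maximises link count and then
minimises total displacement, which is the regime here: confined cells move
far less than one diameter per frame. A track unseen for up to
`max_frame_gap = 5` frames is re-linked on reappearance (the search radius
is *not* inflated with gap length by default; `gap_radius_growth` makes that
configurable). The same 5-frame window bounds how far apart successive
fission rounds may lie and still be merged into one episode by
`division_episodes()`; raw per-split events remain available in
`forest$events`. A three-way split (a segmentation artifact) is flagged and
its round count floored.

Cells that leave the field of view terminate their track without a division
event. A parent with exactly one size-dropped daughter keeps the
parent-child edge but emits no division event, since an event requires at
least two daughters.

# The synthetic colony generator

`simulate_colony()` evolves disk-shaped cells in the plane with an internal
step no longer than one S/M round (0.6 h against hourly snapshots).

**Growth.** Area grows multiplicatively, $A \leftarrow A\,e^{\mu_\mathrm{eff}\,dt\,(1+\sigma z)}$, with

$$\mu_\mathrm{eff} = \mu_0 \cdot s \cdot \big(\text{light} \;?\; 1 : f_\mathrm{dark}\big) \cdot \max(0,\, 1 - \kappa\,\omega),$$

where $\mu_0 = 0.07\,\mathrm{h^{-1}}$ is anchored to the single-cell
trajectory of 30 µm² growing to ~140 µm² over 22 h; $s \in (0,1]$ is the gel
stiffness factor (1 for the softest pad); $f_\mathrm{dark} = 0.15$ keeps slow
heterotrophic (acetate) growth in the dark — the magnitude is not quantified
in the source data, so this is a package choice; $\kappa = 1$ converts the
local residual disk-overlap fraction $\omega$ into a crowding penalty; and
$\sigma = 0.05$ is a lognormal-style noise scale applied to growth
exponents, division delays and daughter partitions.

**Commitment and division.** A cell reaching 75 µm² is committed
unconditionally. Below the threshold, commitment follows the measured size
dependence of the mitotic rate: at each lights-off an uncommitted cell joins
that night's division with probability
$\mathrm{clip}\big((A - A_d)/(A_\mathrm{commit} - A_d),\, 0,\, 1\big)$ —
a ramp anchored at the two existing size constants, adding no free
parameter. Division anchors to the LD12 transition of the cycle in which
commitment happened: committed-in-light cells divide at the next transition;
a cell crossing the threshold during the dark (divisions extend hours past
lights-off) divides immediately within the same night. Stiff gels add a
nonnegative delay with mean $\delta (1-s)\, h(A)$, $h(A) =
\mathrm{clip}(A_\mathrm{commit}/A, 0.2, 1)$ and $\delta = 4$ h, so larger
committed cells divide earlier — $\delta$ is a package choice pinned by the
worked configuration $s = 0.5,\ A = A_\mathrm{commit} \Rightarrow \Delta = 2$ h.
Fission executes as successive binary rounds 0.6 h apart, so multi-round
episodes can straddle hourly snapshots and exercise the tracker's episode
merging; each round splits area exactly (noise perturbs the partition, the
sum is preserved to machine precision).

**Mechanics.** After every step, overlapping disk pairs are pushed apart
along their centre line by a fraction of the overlap depth (Rcpp kernel;
6 sweeps of step 0.4 per internal step). Deliberately *incomplete* relaxation
leaves residual overlap that is largest in the interior — this is the
crowding signal: measured on a default colony late in its life, interior
cells carry an overlap fraction near 0.2 against 0.05 at the edge, hence
grow ~15 % slower, which yields the centre-to-edge commitment lag and the
non-monotone radial size bands the spatial statistics detect. Crowding is a
contact proxy, not a nutrient field: no diffusion is simulated.

**What the generator does and does not emulate.** It reproduces diurnal
division waves with 24 h median onset spacing, the $2^n$ sizer mapping, the
commitment knee at 75 µm², gel-stiffness ordering of growth and division
timing, and radial desynchronisation. It does not model 3-D doming,
motility, palmelloid states, or oxygen/irradiance gradients. Because the
growth constants are anchored to the per-cell trajectory above, simulated
colonies reach on the order of $10^2$ cells by 120 h rather than the
$10^3$ of real dense colonies; all statistics the tests check are ratios,
rates or ranks and do not depend on that scale. Passing tests therefore
validate the measurement machinery on data with this structure, not the
biology of any particular real colony.

# Numerical and statistical choices

* **Onset detection**: a local maximum of mean area followed by a relative
  drop of at least `min_drop_frac = 0.2` *and* a strict cell-count
  increase, with at least `min_separation_h = 12` between onsets. The two
  defaults are set so hourly sampling of the generator yields one onset per
  diurnal cycle; the count requirement can be disabled for single-cell
  series.
* **Growth fitting** is log-linear least squares of $\ln A$ on time —
  identical optimum to a nonlinear exponential fit under multiplicative
  noise, and deterministic. On noiseless exponential input it recovers
  $\mu$ and $A(0)$ to 1e-12.
* **Sizer fitting** minimises squared round-count error over a log-spaced
  threshold grid augmented with the objective's exact knots $A/2^k$ (the SSE
  is piecewise constant between knots, so the search is exact); all equally
  optimal thresholds are reported as an interval with the geometric midpoint
  as the point estimate, and a single observed round count flags a
  degenerate fit.
* **Breakpoint fitting** is continuous two-segment regression,
  $y \sim \beta_0 + \beta_1 \min(x, c) + \beta_2 \max(x - c, 0)$, by
  ordinary least squares over an exhaustive grid of interior bin midpoints
  (at least two bins per segment). Bins whose percentage rests on fewer than
  `min_denominator = 10` cells are excluded from the fit — a proportion
  estimated from a handful of cells can dominate an unweighted knee search —
  while binned outputs always keep every bin so that ring denominators
  partition the population exactly. When the knot reduces the SSE of a
  single line by less than 5 % the fit is flagged as carrying no breakpoint
  evidence.
* **Bimodal decoupling** fits a two-component Gaussian mixture (mclust) and
  thresholds at equal posteriors; BIC model selection against a
  one-component fit supplies the unimodality flag, and an Otsu fallback
  maximises between-class variance on a histogram, returning the midpoint of
  the maximal plateau so the threshold sits mid-gap.
* **Quartiles** use linear interpolation (R type 7) throughout; timing
  shifts are signed (an onset shortly before LD12 is a small negative
  shift); the colony-size CV uses the sample (n−1) standard deviation.
* **Degenerate inputs** are first-class: empty bins are reported missing
  (never 0), zero-variance correlation inputs are flagged rather than
  returning a number, single-cell colonies get circular geometry, and
  identical-area samples are unimodal by definition.

# Problem sizes used by the tests

The test suite validates the pipeline against the generator's ground truth
on a cohort of 20 default-configuration colonies (seeds 1–20, 120 h, hourly
frames, ~60,000 cell observations in total), built once and shared across
tests. Tracker precision and recall are pooled over the cohort; the
commitment breakpoint is fitted to the mitotic-percentage curve pooled over
all 20 colonies; stiffness orderings use four gel factors on matched seeds.
Smaller constructed scenes cover every exact rule (radius and ratio
thresholds, gap boundaries, oracle equivalence on up to eight cells).

# Worked example

```{r example, eval = FALSE}
res <- run_pipeline(config = sim_config(seed = 1), n_colonies = 4)
res
glance(res$breakpoint)   # knee of mitotic % vs size
glance(res$sizer)        # fitted division target A_d
autoplot(res$series, schedule = light_schedule())
autoplot(res$mitotic_size)
```

The fitted division target lands slightly below the generator's
$A_d = 35$ µm² because pre-division areas are observed at the last frame
before the split, one hour (about 7 % of growth) before division — a
measurement-lag effect the fit faithfully reports.

# Known limitations

* The tracker assumes sessile cells; it has no motion model and will fail on
  motile or fast-flowing scenes.
* Colony geometry uses a convex boundary; strongly concave colonies will
  misassign edge distances (an alpha-shape variant is a natural extension).
* The generator's dark-phase growth fraction and division-delay scale are
  calibrated choices, not measured constants; conclusions that hinge on
  their exact values should be re-examined against real data.
* Sub-threshold commitment is modelled as a per-cycle Bernoulli draw with a
  linear ramp; real commitment kinetics are surely smoother in time.
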