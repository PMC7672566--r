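---
title: "From calcium movies to functional astrocyte networks: the astronet method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calcium movies to functional astrocyte networks: the astronet method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astronet)
```

## The problem

Astrocytes are not electrically excitable, but they signal through transient
rises of intracellular Ca²⁺ that can propagate between cells through gap
junctions and extracellular messengers. Whether a culture of astrocytes acts
as a mere collection of independently flickering cells or as a *functional
network* — and how stressors such as oxygen–glucose deprivation or stimulants
such as ATP reshape that network — is a question one can answer from
time-lapse fluorescence recordings alone, provided two ingredients:

1. a reliable way to turn a noisy movie into discrete, per-cell **calcium
   events**, and
2. a statistic that separates genuine inter-cell coordination from the
   coincidental co-activity that any two event trains display over a finite
   recording.

`astronet` implements both: a noise-calibrated event-extraction pipeline for
paired *activity* / *cell-free* image stacks, and a lag-aware correlation
network over the segmented cells, together with a fully ground-truthed
synthetic-movie generator used to validate every stage.

## Input model

The pipeline takes two stacks of identical geometry from the same microscope:

* the **activity stack** `A[t, y, x]` — the culture loaded with a calcium
  dye, and
* the **cell-free stack** `C[t, y, x]` — plain medium, which carries the
  camera offset, the medium fluorescence and, crucially, the sensor noise
  under identical optics.

Both carry a physical calibration: frame rate (default 2 Hz) and pixel size
(default 420/512 ≈ 0.82 µm/px, a 512-pixel field covering 420 µm).

## Event extraction

The preprocessing follows five steps, each calibrated on the cell-free stack:

1. **Offset subtraction.** The per-pixel temporal mean of `C` is subtracted
   from every frame of `A`; negative excursions are kept so that later
   relative signals are unbiased.
2. **Denoising.** An optional plug-in video denoiser (none by default) is
   followed by a separable 3-D box filter, default window 3×3×3
   (frames × px × px), with symmetric reflection at the edges so border
   pixels are not dimmed.
3. **Baseline.** The per-pixel fluorescence baseline `F0` is the temporal
   mean of the denoised cell-free stack; the **relative signal** is
   `(F − F0)/F0` (ΔF/F).
4. **Resting-level correction and adaptive threshold.** Pixels inside cells
   carry resting dye fluorescence above the medium, which appears as a
   static positive ΔF/F. The per-pixel temporal *median* of the relative
   signal estimates this resting level (robust while a pixel is active less
   than half the time) and is subtracted, so only *dynamic* signal remains.
   The activity threshold is `k_sigma` (default 3) times the per-pixel
   temporal standard deviation of the denoised, offset-subtracted cell-free
   signal in relative units — the noise that actually survives filtering.
   Because the relative signal and the threshold share the same `1/F0`
   factor, the detected active set is invariant to adding a constant offset
   to both stacks; the threshold map itself, expressed in relative units,
   scales with the baseline.
5. **Spatiotemporal clustering.** Space is tiled into `spatial_window`-sized
   squares (default 16 px) with half-window overlap; within each tile,
   active voxels are clustered by density over the time axis (DBSCAN: a
   frame is a core frame when at least `min_pts = 5` active voxels lie
   within `eps_t = 2` frames of it; border frames attach to the nearest
   core frame, ties toward the earlier one). Clusters from overlapping
   tiles that share voxels are merged by union, so events spanning tile
   boundaries are not split. The procedure has no randomized initialisation
   and is fully deterministic.

Cells are delineated independently on the **long-exposure image** (the
temporal mean of the denoised activity stack) by marker-controlled
watershed: Gaussian smoothing (`smoothing_sigma = 2` px), an Otsu background
floor computed on the image's own intensity range (hence invariant to affine
rescaling), seeds with prominence at least `h_min_frac = 10%` of the dynamic
range, and a minimum region area (`min_cell_area = 30` px). Events are then
cut by cell boundaries: voxels on background are dropped and an event
overlapping several cells is split per cell, conserving in-cell voxels
exactly. A final size floor (`min_event_size = 50` voxels) removes
sub-cellular fragments: residual noise after the box filter is spatially
correlated and crosses the threshold in clumps of up to roughly the filter
support (~27 voxels), while a genuine transient covers much of a cell body
for seconds — thousands of voxels at the default calibration. Same-cell
activations that overlap in time are merged into one event unless they are
spatially disjoint; this is a deliberate property of the detector, and it
bounds the temporal resolution of per-cell event counting.

## Activity statistics

Per recording, the package reports the percentage of *working cells* (cells
with at least one event), per-cell oscillation frequency (events/min),
per-event duration (s), and the spectral energy bounds: per intensity trace,
the one-sided periodogram (linear detrend, no taper, DC excluded) is
accumulated and the frequencies at which the cumulative energy first reaches
10% and 90% are averaged over cells. Summaries are printed as
`"M [Q1; Q3]"` — median and inclusive linear-interpolation quartiles, three
significant digits.

## The network statistic

Let `x_k` be a cell's signal at frame `k` — either the mean ΔF/F over its
pixels (*intensity* trace) or the number of its event voxels active at `k`
(*event-size* trace); both network variants are computed and reported
separately, intensity first. Each trace is detrended with a **trailing
moving average**:

    x̌_k = x_k − mean(x over [k − w, k])

with the first `w` frames excluded as warm-up, and pairs are scored with the
**uncentered correlation**

    ρ_ij = Σ_k x̌_k^i x̌_k^j / sqrt(Σ_k (x̌_k^i)² · Σ_k (x̌_k^j)²)

evaluated on lag-shifted overlapping segments for every integer lag in
`[−max_lag, max_lag]` (default 20 frames = 10 s). The maximising lag and
value define `lag_star` and `rho_max`; ties break toward the smallest `|lag|`
and then toward the negative lag. A positive `lag_star` means cell *i*
leads.

**Why `window_w = 12` frames (6 s).** The window must be long enough that a
transient is not erased, and short enough that the detrended signal is
dominated by transient *onsets* rather than their slow tails. A short window
acts as a high-pass: it shortens the autocorrelation time of the detrended
trace, which raises the effective number of independent samples in the
correlation sum and thereby suppresses the spurious lag-maximised
correlations that any two independent event trains produce over a finite
recording. With ~13 s transients sampled at 2 Hz, 12 frames sits at the
rise-plus-peak scale: true shifted-copy correlations are preserved (the same
filter is applied to both traces) while the null is sharpened. Users
analysing much slower dynamics should scale `window_w` with the transient
rise time.

**Threshold.** An edge is drawn when `rho_max` exceeds a threshold, default
0.3 — a conservative bound on the correlation attainable by chance between
unrelated cells, as the white-noise null in the test suite verifies.
Optionally the threshold can be *calibrated from the data*: cells separated
by at least 100 µm (beyond direct astrocyte contact, given a typical cell
size of up to ~40 µm) are taken as a no-interaction reference, and the 95th
percentile of their `rho_max` becomes the threshold. Pairs are banded as
adjacent (< 40 µm), intermediate (40–300 µm) and distant (≥ 300 µm) for
distance–correlation profiles; band edges are half-open `[lo, hi)`.

**Direction and speed.** An edge with `|lag_star| ≥ min_lag_frames`
(default 1) is directed from the leading cell; zero-lag edges stay
undirected because sub-frame delays are unresolvable at 2 Hz. Per directed
edge, the propagation speed is `distance_um / (|lag_star| / frame_rate)`;
the network summary averages it over directed edges and reports `NA` when
none exist. Other summary statistics: total edges, mean connections per
cell (`2|E|/N`), mean *long-distance* connections per cell (edges spanning
at least `long_distance_um = 100` µm), the mean of `rho_max` over **all**
evaluated pairs (not only edges), the number of connected components and
the **giant component fraction** (largest component size / N, direction
ignored). The emergence of a giant component — a connected subgraph of the
order of the whole culture — is the signature of a consolidated network
response.

## The synthetic generator

`generate_culture()` renders ground-truthed movies: cells are compact 2-D
Gaussian footprints (radius 16 µm, non-overlapping) on a homogeneous
background of 100 a.u.; each calcium event adds a double-exponential
transient (rise 1 s, decay 6 s, peak 1.0 ΔF/F) to the cell's pixels;
i.i.d. Gaussian sensor noise (`noise_sigma = 0.2` relative, i.e. transient
SNR 5) is added to both the activity and the matched cell-free stack. The
default field is 160×160 px covering the same 420 µm field of view as the
supported acquisition protocol — the lower sampling (2.6 µm/px) keeps
desk-scale runs fast while leaving ~12 px across a cell body.

Coupling is modelled as **assemblies**: groups of cells that fire as a
unit. An assembly initiates events as a Poisson process; at each initiation
every member participates independently with probability `participation`
(0.9 by default) and fires at a fixed member-specific delay — its
activation rank times `delay_step_frames`. Two consequences make this the
right validation target for a correlation method:

* every coupled pair has a *single, exact* ground-truth lag (the difference
  of activation delays) and an unambiguous leader, so lag and direction
  recovery can be asserted exactly; and
* the ground-truth coupling graph is the *transitive closure* of the
  activation order. A correlation network cannot distinguish direct from
  relayed coupling — with any chain-like ground truth, relayed pairs would
  be counted as false positives even though their signals genuinely
  correlate — so the closure is the fair reference for edge precision and
  recall.

Ground-truth event extents are recorded where the clean transient exceeds
5% of its peak: an event remains detectable while any of the cell's
brighter pixels still cross the activity threshold, which holds down to a
few per cent of the peak amplitude.

Three presets encode the study conditions, with rates typical of cultured
astrocytes: `control` (2.0 events/min/cell; three spatially clustered
assemblies of 10 within 110 µm discs — short-range coupling, with the
occasional pair stretching beyond 100 µm), `atp` (2.9 events/min; two
field-spanning assemblies of 15 — abundant long-range coupling), and
`ischemia` (1.6 events/min; coupling removed entirely, events persist).
The qualitative contrast these presets must reproduce is: ATP multiplies
long-distance connections and consolidates the giant component; ischemia
dissolves both while calcium activity itself continues.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real recordings: photobleaching and drift, cell motion,
overlapping or irregularly shaped cells, amplitude and kinetics
heterogeneity between events, regenerative wave physics
(IP₃/Ca²⁺ reaction–diffusion), subcellular microdomains, and non-Gaussian
or temporally correlated sensor noise. The validation demonstrates that the
algorithmic chain is correct and well calibrated under its stated noise
model, not that these defaults are optimal for any particular microscope.

## Numerical choices and degenerate inputs

* All operations are deterministic; the generator's seed fully determines
  its output, and reruns of the pipeline write byte-identical tables.
* Correlation of a zero-norm (silent) trace is undefined: such pairs carry
  `NA` and are excluded from edges; constant traces are skipped (and
  counted) by the spectral estimator.
* Degenerate inputs error early with stage-specific messages: mismatched
  stack geometry, all-zero baselines, cell-free stacks shorter than 8
  frames, empty samples in `describe()`.
* An empty field (no watershed seeds) yields an empty cell map, not an
  error; an empty mask yields an empty event list.
* Lag ties break deterministically (smallest `|lag|`, then negative);
  greedy centroid matching in the validation helpers resolves by smallest
  distance.
* Problem sizes used by the test-suite validations were chosen to finish a
  full run in minutes on a single core: 30-cell cultures at T = 1200 frames
  for network recovery and regime contrast, a 15-cell culture at
  0.3 events/min for event-pipeline closure (sparse enough that same-cell
  transients rarely overlap, which the detector would merge by design),
  white-noise nulls at T = 1000 over ~1200 pairs, and spectral checks at
  T = 2048–4096.

## Known limitations

* Event counting saturates as per-cell activity approaches a ~50% duty
  cycle: the resting-level median biases upward and temporally adjacent
  transients merge, so reported oscillation frequencies under-count at high
  rates.
* The adaptive threshold is a `k·σ` model on cell-free noise; structured
  noise (e.g. flicker correlated across pixels) would require a richer
  model, for which the video-denoiser plug-in hook is the intended entry
  point.
* The correlation network is associational: even with the distance
  calibration, an edge is evidence of coordinated timing, not of a specific
  biophysical pathway, and common drive can produce edges between cells
  that never interact.
* Segmentation assumes cells are bright, compact and separable on the
  long-exposure image; densely confluent cultures may need externally
  supplied label maps, which every downstream function accepts.

## A worked example

```{r example, eval = FALSE}
library(astronet)

sim <- simulate_culture("control", seed = 7)
res <- run_pipeline(sim$activity, sim$cellfree, run_config())

res$activity_summary       # working cells, frequency, duration
res$stats                  # edges, long-distance connections, giant component
res$network                # the functional network object

# validation against the generator's ground truth
mc  <- match_cells(sim$truth$cells, res$cells$cells)
edge_recovery(res$network, sim$truth$coupling, mc)
```
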