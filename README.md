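# astronet

Calcium event detection and functional network reconstruction for astrocyte
cultures imaged by time-lapse fluorescence microscopy.

Astrocytes signal through intracellular Ca²⁺ transients rather than action
potentials. Whether a culture behaves as a collection of independent cells or
as a coordinated *functional network* — and how stimulants (ATP) or
ischemia-like stress reshape that network — can be read out from a
fluorescence movie, if one can (a) extract discrete per-cell calcium events
from noisy image stacks and (b) distinguish genuine inter-cell coordination
from chance co-activity. `astronet` provides the full chain for researchers
working with such recordings, plus a ground-truthed synthetic-movie generator
for validating every stage.

## Method at its core

Given an activity stack and a *cell-free* stack (plain medium, same
microscope) of identical `T × H × W` geometry:

1. **Events** — subtract the cell-free temporal mean (offset), denoise with a
   3-D box filter, convert to ΔF/F against the cell-free baseline, remove the
   per-pixel resting level, threshold at `k·σ` of the denoised cell-free
   noise, and cluster supra-threshold voxels into events (DBSCAN over time in
   overlapping spatial tiles). Cells are delineated by watershed on the
   long-exposure image, and events are cut per cell.
2. **Network** — for each cell pair, detrend the per-cell signals with a
   trailing moving average (window `w`),

       x̌ₖ = xₖ − ⟨xₛ⟩ over s ∈ [k−w, k]

   and score the pair by the uncentered correlation maximised over integer
   lags in `[−max_lag, max_lag]`:

       ρᵢⱼ = Σₖ x̌ₖⁱ x̌ₖʲ / √(Σₖ(x̌ₖⁱ)² · Σₖ(x̌ₖʲ)²)

   An edge is drawn when the lag-maximised ρ exceeds a threshold (0.3 by
   default, or calibrated as the 95th percentile of ρ among cells ≥ 100 µm
   apart); edges with a non-zero optimal lag are directed from the leading
   cell, giving per-edge propagation speeds. Summary statistics include mean
   connections per cell, long-distance (≥ 100 µm) connections per cell, mean
   ρ over all pairs, and the giant-component fraction.

## Worked example

Simulate a 30-cell "control" culture (10 min at 2 Hz, transient SNR 5) and
run the full pipeline:

```r
library(astronet)

sim <- simulate_culture("control", seed = 7)
res <- run_pipeline(sim$activity, sim$cellfree, run_config())

res$activity_summary
#> 160 events in 30 cells; working cells 100%
#> frequency (osc/min): 0.5 [0.5; 0.6]
#> duration (s): 37.2 [20; 78.8]

res$stats
#> edges 135 | connections/cell 9 | long-distance (>=100 um)/cell 4.8
#> mean rho_max 0.339 | giant component 0.333 | components 3 | speed 46.9 um/s
```

The activity summary gives the fraction of cells with at least one event,
per-cell event frequency and per-event durations as `median [Q1; Q3]` (the
synchronized assemblies of the control preset merge many overlapping
activations, so detected per-cell frequency under-counts the configured
2/min). The network summary shows the 135 within-assembly edges recovered as
three connected components (one per assembly, giant fraction 10/30 = 0.333),
with delays along the activation order giving a mean propagation speed of
~47 µm/s. Comparing against the generator's ground truth:

```r
mc <- match_cells(sim$truth$cells, res$cells$cells)
edge_recovery(res$network, sim$truth$coupling, mc)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/astronet.R simulate --preset control --seed 7 --out fix/
Rscript inst/cli/astronet.R run --activity fix/activity.tif --cellfree fix/cellfree.tif --out results/
```

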