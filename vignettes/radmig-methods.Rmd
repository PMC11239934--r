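---
title: "Methods: quantifying radial migration and subplate reporter dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying radial migration and subplate reporter dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmig)
```

# The problem

During fetal corticogenesis, excitatory neurons born at the ventricle
migrate radially toward the pial surface. At the subplate (SP) — a
transient band below the cortical plate — they switch from a multipolar
(MP) morphology with several short processes to a bipolar (BP) one with a
single pia-directed leading process, and change migration mode. Slice
time-lapse experiments probing this step produce several kinds of
quantitative readout:

* movies of a **bioluminescent signaling reporter** (a
  destabilized-luciferase construct responsive to TGF-β signaling), whose
  transient activation near the SP must be separated from background and
  from cosmic-ray camera artifacts;
* movies of **sparsely labeled migrating cells**, from which radial
  migration velocities and MP/BP compositions are measured;
* fixed **sections**, where the laminar position of labeled neurons is
  summarized by equal-height BIN counts between the pial and ventricular
  boundaries;
* **in situ zymography** movies (DQ-gelatin), where per-cell protease
  signal is compared between laminar zones.

`radmig` implements these quantifications as a tested pipeline, together
with a ground-truthed synthetic generator so that every estimator can be
validated without any imaging download.

# Coordinate and data conventions

Stacks are `ImageStack` objects: a `(row, col, time)` array of finite,
non-negative intensities plus the frame interval (h), pixel size (µm) and
an optional start offset `t0H`. Frame timestamps are frame-start times.
The radial axis is the image row axis; slices are assumed oriented with
the cortical surface horizontal (arbitrary-angle radial axes are out of
scope). Pixel indices are 1-based (row 1 at the image top), and all
spatial partitions — grid squares, laminar bins, zones — use half-open
intervals so every coordinate belongs to exactly one cell of a partition.
A `LayerAnnotation` supplies the pial row, ventricular row, SP-centre row
and the orientation flag `radialUp` (TRUE when decreasing row index points
pial-ward); its validity method enforces consistency. Readers reject NaN
or negative intensities outright rather than clipping.

The acquisition frame interval is deliberately a *required* argument of
`readStack()`: it is not recoverable from plain TIFF and silently guessing
it would corrupt every time axis downstream. TIFF stacks are stored as
16-bit counts with an explicit `scale` factor (the camera-count
convention), so integer-valued movies round-trip losslessly.

# Reporter quantification

`quantifyReporter()` composes six stages, each independently exposed and
tested:

1. **Grid averaging** (`gridAverage`). Each frame is partitioned into a
   16 × 14 grid (16 columns across the slice, 14 rows along the radial
   axis) of axis-aligned rectangles with rounded integer boundaries
   `round(i·H/14)`, `round(j·W/16)`, so any image size is accepted without
   a divisibility requirement. The value per square per frame is the
   arithmetic mean intensity.
2. **Initial-window exclusion** (`excludeInitial`). Frames with start
   time strictly below 4.5 h are dropped: the window immediately after
   onset is dominated by high background. Comparing frame-*start* times
   keeps the retained frame count reproducible for any cadence (at
   0.25 h/frame, exactly the first 18 frames go and the frame at
   t = 4.5 h is retained).
3. **Temporal DFT** (`temporalSpectrum`). Each square's time series is
   Fourier transformed; the one-sided spectrum |X[k]|, k = 0…⌊N/2⌋, is
   kept. "Frequency" here is the DFT **bin index** along the frame axis,
   not physical hertz: at time-lapse cadences of minutes to hours per
   frame, bands quoted in tens of hertz can only be meaningful as bin
   indices. Magnitudes are summed by default; `spectrum_type = "power"`
   switches to |X[k]|², since which of the two the convention intends is
   not decidable from its description.
4. **Band summation** (`bandPower`). The low band is bins [2, 30]
   inclusive (29 bins — bin 0 is the DC offset and bin 1 the
   full-length trend, both excluded); the high band is bins [30, 75].
   The two bands overlap at bin 30 as printed; a config edit
   (`high_band: [31, 75]`) removes the overlap. Bands reaching above the
   Nyquist bin are clipped with a warning; the effective bin counts are
   carried into the correction.
5. **Cosmic-ray correction** (`spikeCorrect`). A cosmic ray is a
   single-pixel, single-frame impulse, and an impulse has a *flat*
   magnitude spectrum. The default `broadband_subtract` mode estimates
   that flat floor from the high band — which genuine slow reporter
   dynamics do not reach — and removes it from the low band:
   B* = max(0, B − n_low·H/n_high). A pure impulse is annihilated exactly
   (to rounding) and a pure low-band tone passes unchanged. A literal
   low-pass masking of the high band cannot affect a disjoint low-band
   sum; that reading ships as `spike_correction: "mask"` and is documented
   as a near no-op. `none` disables correction.
6. **SP-row selection** (`selectSpRows`). The grid row containing the
   annotated SP centre is located, and the 4 grid rows immediately above
   plus the 4 immediately below are retained (clipped at image edges with
   a warning). Whether the centre row itself belongs to the selection is
   not specified by the convention; the default excludes it and
   `include_sp_center: true` includes it.

The output is one corrected value per grid square in a long-format table
(condition, slice, grid coordinates, B, H, B*, selection flag), displayed
as a violin plot (`plotReporterViolin`). The computation is
condition-blind, deterministic and linear in the input intensities
(B scales exactly; B* scales exactly while unclamped).

**A caveat on the correction.** Broadband subtraction is exact for an
impulse on empty background. When a square contains strong low-band
signal, an added impulse raises the high band almost coherently
(≈ +a per bin) but raises the low band only in quadrature with the
signal's phases, so the correction slightly *over*-subtracts there. In
practice the reported quantity — the SP-selected median of B* — moves by
a few percent under a heavy cosmic-ray load (3 events/frame at 50× the
noise sd) while the uncorrected grid-wide median moves by tens of
percent; the package's acceptance checks assert exactly these two
statements on the packaged synthetic movie.

**Grids versus slices.** Whether "n" in a reporter comparison should be
grid squares or slices is an open design choice in this kind of
experiment; `makeReport()` therefore writes the per-grid table *and* a
per-slice median aggregation (`reporter_slice_medians.csv`) so either can
be tested.

# Migration velocity

`detectCells()` thresholds a frame, labels connected components
(4-connectivity), filters by minimum area (5 px default) and returns
intensity-weighted centroids. `linkTracks()` performs greedy
nearest-neighbour linking in order of ascending pair distance with a hard
displacement gate (15 µm/frame default); unmatched detections start new
tracks and gaps are not bridged. Greedy distance-ordered assignment is
deterministic, dependency-free and adequate at the sparse labeling
densities these experiments use; ties (measure-zero for continuous
centroids) break by track then detection index.

`radialVelocity()` defines a track's velocity as the **net radial
displacement between its first and last point divided by elapsed time**,
in µm/h, positive toward the pial surface for either slice orientation.
Endpoint displacement is the default because "migration speed toward the
brain surface" is otherwise underspecified; a least-squares
regression-slope mode is available (`velocity_mode: "regression"`) and
agrees with the endpoint definition on linear motion. Purely lateral
motion scores zero. Single-point tracks are excluded with a warning.

`compareVelocity()` reports per-group mean ± SEM and the unpaired
two-tailed t-test.

# Morphology, BINs and zones

`classifyPolarity()` is a reproducible surrogate for the by-eye MP/BP
call. The soma is the largest inscribed disk of the mask (Euclidean
distance-transform maximum, minimum radius 2.5 px); removing it splits
the mask into candidate neurites, and components touching the soma
boundary that extend ≥ 4 px beyond it count as primary neurites. The
longest neurite is the leading-process candidate; it is pia-directed when
its tip direction lies within ±45° of the radial axis. ≥ 3 neurites ⇒
MP; 1–2 neurites with a pia-directed leading process ⇒ BP; anything else
(including bare somata) ⇒ ambiguous. All three thresholds are explicit
arguments: a visual criterion has no canonical constants, so the package
states its own and tests them against construction-time ground truth
(100% agreement on noiseless rendered cells; translation- and
lateral-mirror-invariance are asserted as properties).

`mpBpComposition()` tabulates MP/BP fractions at the start of imaging and
after 10 h (the conventional follow-up), excluding and reporting
ambiguous cells; fractions sum to 1 per timepoint.

`assignBins()` divides the pial-to-ventricular span into `n_bins`
equal-height half-open intervals, BIN 1 pial-most, last bin closed at the
ventricular boundary. The BIN count used in the original section analyses
is not stated anywhere in their description, only that BIN 1–2 are
pial-most; it is therefore a parameter (default 5) echoed in every
output, never a hard-coded constant. Reflecting all positions about the
mid-span maps BIN k to BIN n+1−k, which is asserted as a property.
Out-of-span cells are excluded and counted separately.

`zoneSignal()` assigns cells to below_SP / in_SP / above_SP from their
centroid row versus an inclusive SP band (same half-open conventions on
the flanks) and reads the mean secondary-channel intensity over a
fixed-radius disk (3 px default) at the matching frame — the zymography
readout, where protease signal is expected inside the SP band only.
Zymography movies are conventionally acquired at 10-min frame intervals;
the frame interval is, as everywhere, explicit metadata.

# Statistics

All summaries are mean ± SEM with SEM = sd/√n (n−1 denominator).
`tTestUnpaired()` is the unpaired two-tailed t-test, pooled-variance
Student's form by default (Welch optional), with explicit degenerate
handling: zero variance in both groups with equal means gives t = 0,
p = 1; zero variance with unequal means is flagged and reported as p = 0.
Significance stars use strict thresholds (*p < 0.05, **p < 0.01,
***p < 0.001), so p = 0.05 exactly is "ns". No multiple-testing
correction is applied — the source analyses apply none — but the report
counts its comparisons so users can correct externally. The test suite
validates t, df and p against an independent direct-formula
implementation to 1e−10.

# The synthetic generator

`generateMigrationMovie()` draws per-cell radial velocities from
N(mean, sd), moves cells along straight radial paths with iid per-frame
Gaussian jitter, and renders them as isotropic Gaussian somata (σ = 2 px)
with 2-px-wide polyline processes: 3–5 radiating arms before the
transition row, a single elongated pia-ward leading process (plus short
trailing process) after it. Cells that would exit the frame are clamped
at a margin and flagged. `generateLuminescenceMovie()` adds the reporter
channel: each cell bursts once, for `burstDurationH` hours, at an onset
drawn uniformly over its transit through the burst-permissive band, and
emits a uniform disk of `burstAmplitude` only on frames where it is
inside the band. `injectCosmicRays()` adds Poisson-count single-pixel,
single-frame impulses — the temporal-impulse model that the band
correction targets. `generateSection()` draws section coordinates from a
programmable per-bin mixture. Everything is bit-reproducible under a
fixed seed, and the returned ground truth (trajectories, drawn
velocities, per-frame classes, burst windows, spike lists) is sufficient
to score every estimator without re-simulation.

Default study conditions: a 140 × 160 px field at 2 µm/px (10 px per
square of the default grid), 160 frames at 0.5 h/frame, migration at
10 ± 1 µm/h over 24 h for tracking fixtures, burst amplitude 10× the
background noise sd. The 0.5 h cadence is chosen so that after the 4.5 h
exclusion exactly 151 frames remain and the full printed band (bins up
to 75) exists in the one-sided spectrum. The luminescence fixture slows
migration to ~1 µm/h: cells dwell in the SP vicinity during the MP
phase, which both matches the biology of the transition and spreads
bursts across the band. No instrument noise statistics are published for
these acquisitions, so the noise defaults are stated configuration, not
a claim about any camera. The generator renders geometry for centroid-
and skeleton-level estimators; it deliberately does *not* emulate optics
(PSF, depth attenuation), luciferin kinetics, cell division, overlap
occlusion in dense fields, or tissue drift — so passing tests validate
the estimators' logic and calibration, not their robustness to those
real-data effects.

# Numerical and degenerate-input choices

* Grid boundaries use round-half-up, making partitions reproducible
  across platforms; images smaller than the grid are an error.
* Fewer than 2 frames after exclusion, bands entirely above Nyquist
  (for the signal band), non-uniform timestamps, disconnected cell
  masks, frame indices out of range, and all-ambiguous compositions are
  errors; band clipping, SP-edge clipping, empty high band (correction
  disabled) and single-point tracks warn and continue.
* Ties in the distance transform (soma centre) and in greedy linking
  break deterministically by index order.
* Test problem sizes are chosen to exercise the full pipeline briskly:
  120-cell 160-frame luminescence fixtures, 20-cell tracking movies,
  40-cell composition movies, 1000-point binning oracles, 100-sample
  statistical oracles.

# Known limitations

Tracking has no gap closing or mitosis handling; velocity is
net-displacement over the track's lifetime, so heavy fragmentation
shortens the averaging window rather than biasing the estimate.
Morphology classification assumes one connected, moderately isolated
cell per mask — clumped cells must be separated upstream. The laminar
geometry is a 1-D row model; curved cortical walls need prior
flattening. The reporter quantification is per-grid-square, not
per-cell.
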