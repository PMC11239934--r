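# radmig

Quantification of radial neuronal migration and subplate reporter
dynamics in embryonic cortical slice time-lapse imaging.

During corticogenesis, newborn excitatory neurons migrate radially from
the ventricular zone toward the pial surface and, at the subplate (SP)
layer, switch from a multipolar to a bipolar morphology and migration
mode. Slice-culture experiments probing this step generate bioluminescent
signaling-reporter movies, labeled-cell migration movies, fixed sections,
and in situ zymography movies. `radmig` implements their quantification
layer for R users:

* **Reporter quantification** — each movie frame is averaged over a
  16 × 14 grid; each square's time series x[n] (first 4.5 h excluded) is
  Fourier transformed, and the low-band sum
  B = Σ<sub>k=2..30</sub> |X[k]| is corrected for cosmic-ray impulses
  using the high band as a flat-spectrum noise floor,
  B\* = max(0, B − n<sub>low</sub>·H/n<sub>high</sub>) with
  H = Σ<sub>k=30..75</sub> |X[k]| (an impulse has a flat magnitude
  spectrum, so it is annihilated exactly while slow reporter dynamics
  pass through). Values are reported for the four grid rows above and
  below the annotated SP centre and summarized as violin plots.
* **Migration velocity** — threshold/label/centroid detection, greedy
  nearest-neighbour track linking with a displacement gate, and radial
  velocity v = Δ(radial position)/Δt in µm/h, positive toward the pia.
* **Morphology** — multipolar (≥ 3 primary neurites) vs bipolar (1–2
  neurites with a pia-directed leading process) classification from cell
  masks via distance-transform soma extraction, and MP:BP composition at
  0 h and 10 h.
* **Laminar BINs and zones** — equal-height half-open bins between the
  pial and ventricular boundaries (BIN 1 pial-most) and zone-wise
  (below/in/above SP) per-cell signal for zymography channels.
* **Statistics** — mean ± SEM and unpaired two-tailed t-tests
  (pooled-variance Student's by default, Welch optional) with strict
  star thresholds.
* **Synthetic data** — a ground-truthed generator for migration movies,
  SP-confined luminescence bursts, cosmic-ray spikes and section BIN
  profiles, so the whole pipeline is testable with no imaging download.

The methods vignette (`vignettes/radmig-methods.Rmd`) documents every
model, convention and default.

## Worked example

```r
library(radmig)

# a synthetic slice: 120 labeled cells drifting through an SP-centred
# burst band, reporter bursts at 10x background noise
params <- simParams(nCells = 120L, velocityMeanUmPerH = 1,
                    velocitySdUmPerH = 0.2, jitterSdPx = 0.5,
                    startRows = withr::with_seed(110L, runif(120, 35, 125)),
                    seed = 11L)
mig <- generateMigrationMovie(params)
lum <- generateLuminescenceMovie(params, mig$truth)

ann <- LayerAnnotation(pialRow = 1, ventricularRow = 140, spCenterRow = 75)
tab <- quantifyReporter(lum$stack, ann)
tapply(tab$B_star, tab$in_sp_selection, median)
#> median corrected band power: SP rows 85.9, elsewhere 0.50

# migration velocity, control vs a slowed condition, n = 10 cells each
annT <- LayerAnnotation(1, 240, 120)
vOf <- function(vMean, seed) {
  p <- simParams(nCells = 10L, nFrames = 49L, imageShape = c(240L, 300L),
                 velocityMeanUmPerH = vMean, velocitySdUmPerH = 1,
                 transitionRow = 120, seed = seed)
  trackMovie(generateMigrationMovie(p)$stack, annT,
             minPoints = 10L)$velocities$v_um_per_h
}
compareVelocity(list(control = vOf(10, 31L), knockdown = vOf(5, 32L)))
#> Unpaired two-tailed t-test (student)
#>   control: mean 10.43 +/- 0.3101 SEM (n = 10)
#>   knockdown: mean 5.315 +/- 0.2026 SEM (n = 10)
#>   t = 13.81, df = 18, p = 5.087e-11  [***]
```

The corrected band power concentrates in the SP-selected grid rows
(median 85.9 vs 0.50 elsewhere — the bursts are SP-confined and the
broadband correction removes the flat noise/impulse floor), and the true
5 µm/h velocity difference is recovered (10.4 vs 5.3 µm/h) and detected
by the t-test.

A thin command-line wrapper over the same functions is provided at
`inst/scripts/radmig.R` (`simulate`, `quantify`, `track`, `classify`,
`bins`, `report` subcommands).

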