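# Shared oracles and fixture builders.  Everything is generated in code;
# expensive fixtures are memoised per test run.

# ---- independent oracles ---------------------------------------------------

# Naive O(N^2) direct-sum DFT magnitudes for bins 0..floor(N/2).
naiveDFTmag <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  vapply(0:(N %/% 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * n / N)))
  }, numeric(1))
}

# Direct-formula unpaired two-tailed t-test (pooled or Welch).
tOracle <- function(a, b, variant = "student") {
  n1 <- length(a); n2 <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- va / n1 + vb / n2
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / n1)^2 / (n1 - 1) + (vb / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# ---- small builders --------------------------------------------------------

# A 1 x 1 grid series holding one plain time series.
seriesFromVector <- function(x, dt = 1) {
  new("GridSeries", values = array(x, c(1L, 1L, length(x))),
      rowBreaks = c(0, 1), colBreaks = c(0, 1),
      timestamps = (seq_along(x) - 1) * dt)
}

constantStack <- function(value = 0, dims = c(140L, 160L), nFrames = 160L,
                          dt = 0.5, px = 2) {
  ImageStack(array(value, c(dims, nFrames)), frameIntervalH = dt,
             pixelSizeUm = px)
}

defaultAnnotation <- function() LayerAnnotation(1, 140, 75)

# ---- study-condition fixtures ---------------------------------------------

# Packaged synthetic luminescence movie: 160 frames at 0.5 h (151 frames
# and a full bin-75 band survive the 4.5 h exclusion), burst amplitude
# 10x the noise sd, 120 slowly migrating cells entering a broad
# SP-centred burst band, fixed seed.
burstFixtureParams <- function(seed = 11L) {
  start <- withr::with_seed(seed + 99L, stats::runif(120, 35, 125))
  simParams(nCells = 120L, nFrames = 160L, frameIntervalH = 0.5,
            imageShape = c(140L, 160L), pixelSizeUm = 2,
            velocityMeanUmPerH = 1, velocitySdUmPerH = 0.2,
            jitterSdPx = 0.5, burstAmplitude = 10, noiseSd = 1,
            burstDurationH = 3, burstBandRows = c(31, 120),
            startRows = start, seed = seed)
}

# Tracking fixture: 20 cells at a common true radial speed.
velocityFixtureParams <- function(vMean = 10, vSd = 0, nCells = 20L,
                                  seed = 7L) {
  simParams(nCells = as.integer(nCells), nFrames = 49L,
            frameIntervalH = 0.5, imageShape = c(240L, 300L),
            pixelSizeUm = 2, velocityMeanUmPerH = vMean,
            velocitySdUmPerH = vSd, jitterSdPx = 1, noiseSd = 1,
            transitionRow = 120, seed = as.integer(seed))
}

.fixtureCache <- new.env(parent = emptyenv())

burstFixture <- function() {
  if (is.null(.fixtureCache$burst)) {
    p <- burstFixtureParams()
    mm <- generateMigrationMovie(p)
    lum <- generateLuminescenceMovie(p, mm$truth)
    .fixtureCache$burst <- list(params = p, stack = lum$stack,
                                truth = lum$truth,
                                annotation = defaultAnnotation())
  }
  .fixtureCache$burst
}

trackingFixture <- function() {
  if (is.null(.fixtureCache$track)) {
    p <- velocityFixtureParams()
    .fixtureCache$track <- c(generateMigrationMovie(p), list(params = p))
  }
  .fixtureCache$track
}

# Morphology-transition fixture: start rows programmed so the true MP
# fraction is 80% at t = 0 h and 20% at t = 10 h (cells cross the
# transition row at 10 um/h over a 10 h movie).
compositionFixtureParams <- function(seed = 5L) {
  start <- withr::with_seed(seed + 7L, c(
    stats::runif(8, 155, 165),    # MP throughout
    stats::runif(24, 105, 145),   # MP -> BP within 10 h
    stats::runif(8, 60, 90)))     # BP throughout
  simParams(nCells = 40L, nFrames = 21L, frameIntervalH = 0.5,
            imageShape = c(200L, 1600L), pixelSizeUm = 2,
            velocityMeanUmPerH = 10, velocitySdUmPerH = 0.5,
            jitterSdPx = 0.5, noiseSd = 0.5, transitionRow = 100,
            startRows = start, seed = seed)
}
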