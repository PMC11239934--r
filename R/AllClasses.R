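#' @import methods
NULL

#' Single-channel time-lapse image stack
#'
#' Container for one channel of a slice time-lapse movie: a 3-D intensity
#' array laid out as (row, col, time) together with the acquisition
#' metadata every downstream quantification needs.  Intensities are
#' arbitrary non-negative camera units.  Frame timestamps are frame-start
#' times \code{t0H + (i - 1) * frameIntervalH} (hours), so they are
#' strictly increasing by construction.
#'
#' Pixel coordinates are 1-based with row 1 at the image top; spatial
#' intervals throughout the package are half-open.  The radial (pial to
#' ventricular) axis is the row axis.
#'
#' @slot frames numeric array, dim (rows, cols, frames); finite, >= 0.
#' @slot frameIntervalH hours per frame, > 0.
#' @slot pixelSizeUm micrometres per pixel, > 0.
#' @slot t0H acquisition-start offset in hours (default 0).
#'
#' @examples
#' s <- ImageStack(array(1, c(8, 8, 3)), frameIntervalH = 0.5, pixelSizeUm = 2)
#' frameTimes(s)
#' @export
setClass("ImageStack",
  representation(
    frames = "array",
    frameIntervalH = "numeric",
    pixelSizeUm = "numeric",
    t0H = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character(0)
  d <- dim(object@frames)
  if (length(d) != 3L) {
    msg <- c(msg, "frames must be a 3-D array (row, col, time)")
  } else {
    if (any(d < 1L)) msg <- c(msg, "all dimensions must be >= 1")
  }
  if (!all(is.finite(object@frames))) {
    msg <- c(msg, "intensities must all be finite (no NA/NaN/Inf)")
  } else if (any(object@frames < 0)) {
    msg <- c(msg, "intensities must be non-negative")
  }
  if (length(object@frameIntervalH) != 1L || !is.finite(object@frameIntervalH) ||
      object@frameIntervalH <= 0) {
    msg <- c(msg, "frameIntervalH must be a single positive number")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0) {
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  }
  if (length(object@t0H) != 1L || !is.finite(object@t0H)) {
    msg <- c(msg, "t0H must be a single finite number")
  }
  if (length(msg)) msg else TRUE
})

#' @param frames numeric array, dim (rows, cols, frames).
#' @param frameIntervalH hours per frame.
#' @param pixelSizeUm micrometres per pixel.
#' @param t0H start-time offset in hours.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(frames, frameIntervalH, pixelSizeUm, t0H = 0) {
  new("ImageStack", frames = frames, frameIntervalH = frameIntervalH,
      pixelSizeUm = pixelSizeUm, t0H = t0H)
}

#' Laminar annotation of one cortical slice
#'
#' Geometric description of the cortical wall for one slice: the pixel
#' rows of the pial and ventricular boundaries, the centre row of the
#' subplate (SP) band, and the orientation of the radial axis.
#' \code{radialUp = TRUE} means decreasing row index points toward the
#' pial surface (pial boundary above the ventricular one), which is also
#' enforced by the validity method.  Rows may be fractional.
#'
#' @slot pialRow pixel row of the pial surface.
#' @slot ventricularRow pixel row of the ventricular surface.
#' @slot spCenterRow pixel row of the SP-band centre, strictly between the
#'   two boundaries.
#' @slot radialUp logical; TRUE when decreasing row index points pial-ward.
#'
#' @examples
#' LayerAnnotation(pialRow = 1, ventricularRow = 140, spCenterRow = 75)
#' @export
setClass("LayerAnnotation",
  representation(
    pialRow = "numeric",
    ventricularRow = "numeric",
    spCenterRow = "numeric",
    radialUp = "logical"
  )
)

setValidity("LayerAnnotation", function(object) {
  msg <- character(0)
  p <- object@pialRow; v <- object@ventricularRow; s <- object@spCenterRow
  if (length(p) != 1L || length(v) != 1L || length(s) != 1L ||
      !all(is.finite(c(p, v, s)))) {
    return("pialRow, ventricularRow and spCenterRow must be single finite numbers")
  }
  if (p == v) msg <- c(msg, "pialRow must differ from ventricularRow")
  if (!(s > min(p, v) && s < max(p, v))) {
    msg <- c(msg, "spCenterRow must lie strictly between pialRow and ventricularRow")
  }
  if (length(object@radialUp) != 1L || is.na(object@radialUp)) {
    msg <- c(msg, "radialUp must be TRUE or FALSE")
  } else if (object@radialUp != (p < v)) {
    msg <- c(msg, "radialUp inconsistent with boundary rows (radialUp = TRUE requires pialRow < ventricularRow)")
  }
  if (length(msg)) msg else TRUE
})

#' @param pialRow,ventricularRow,spCenterRow pixel rows (may be fractional).
#' @param radialUp logical orientation flag.
#' @rdname LayerAnnotation-class
#' @export
LayerAnnotation <- function(pialRow, ventricularRow, spCenterRow,
                            radialUp = pialRow < ventricularRow) {
  new("LayerAnnotation", pialRow = as.numeric(pialRow),
      ventricularRow = as.numeric(ventricularRow),
      spCenterRow = as.numeric(spCenterRow), radialUp = radialUp)
}

#' Per-grid-cell mean-intensity time series
#'
#' Result of partitioning each movie frame into a grid of axis-aligned
#' rectangles and averaging intensities per rectangle.  \code{values} is a
#' (gridRow, gridCol, time) array; \code{rowBreaks}/\code{colBreaks} are
#' the integer pixel boundaries of the partition (length nrow + 1 /
#' ncol + 1, starting at 0), so grid row i covers pixel rows
#' \code{(rowBreaks[i], rowBreaks[i + 1]]} — a half-open partition that
#' covers every pixel exactly once.
#'
#' @slot values numeric array (gridRow, gridCol, time).
#' @slot rowBreaks,colBreaks integer pixel boundaries of the partition.
#' @slot timestamps frame-start times in hours, strictly increasing.
#' @export
setClass("GridSeries",
  representation(
    values = "array",
    rowBreaks = "numeric",
    colBreaks = "numeric",
    timestamps = "numeric"
  )
)

setValidity("GridSeries", function(object) {
  msg <- character(0)
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be (gridRow, gridCol, time)")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(d) == 3L) {
    if (length(object@rowBreaks) != d[1] + 1L) msg <- c(msg, "rowBreaks length must be nrow + 1")
    if (length(object@colBreaks) != d[2] + 1L) msg <- c(msg, "colBreaks length must be ncol + 1")
    if (length(object@timestamps) != d[3]) msg <- c(msg, "timestamps length must equal frame count")
  }
  if (any(diff(object@rowBreaks) <= 0) || any(diff(object@colBreaks) <= 0)) {
    msg <- c(msg, "grid breaks must be strictly increasing")
  }
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0)) {
    msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Per-grid-cell one-sided DFT magnitude (or power) spectra
#'
#' Discrete Fourier transform of each grid cell's intensity time series.
#' Bin k (0-based, k = 0 ... floor(N/2)) is stored at index k + 1 of the
#' third dimension.  \code{type} records whether magnitudes |X[k]| or
#' powers |X[k]|^2 are stored; band summaries sum whatever is stored.
#'
#' @slot values numeric array (gridRow, gridCol, frequency bin).
#' @slot nFramesUsed number of frames N entering the transform.
#' @slot type "magnitude" or "power".
#' @slot rowBreaks,colBreaks grid geometry carried from the GridSeries.
#' @export
setClass("SpectrumGrid",
  representation(
    values = "array",
    nFramesUsed = "integer",
    type = "character",
    rowBreaks = "numeric",
    colBreaks = "numeric"
  )
)

setValidity("SpectrumGrid", function(object) {
  msg <- character(0)
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be (gridRow, gridCol, bin)")
  if (any(object@values < 0)) msg <- c(msg, "spectral values must be >= 0")
  if (length(d) == 3L && d[3] != object@nFramesUsed %/% 2L + 1L) {
    msg <- c(msg, "bin count must be floor(N/2) + 1")
  }
  if (!object@type %in% c("magnitude", "power")) {
    msg <- c(msg, "type must be 'magnitude' or 'power'")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic slice-movie generator
#'
#' One object holds every knob of the forward model: geometry and cadence
#' of the movie, the migrating-cell population (radial velocity draw,
#' per-frame positional jitter, rendering amplitudes), the
#' multipolar-to-bipolar transition row, the subplate-confined
#' luminescence-burst model, cosmic-ray spike statistics, and additive
#' Gaussian background noise.  All generators are bit-reproducible under
#' a fixed \code{seed}.
#'
#' Defaults describe the emulated study conditions: a 140 x 160 px field
#' (10 px per cell of the default 16 x 14 analysis grid) at 2 um/px,
#' 160 frames at 0.5 h/frame (so the full printed frequency band exists
#' after the 4.5 h initial-window exclusion), radial velocity
#' 10 +/- 1 um/h, 1 px/frame jitter, and burst amplitude 10x the
#' background noise sd.
#'
#' @slot imageShape integer (rows, cols).
#' @slot nFrames number of frames, >= 2.
#' @slot frameIntervalH hours per frame.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot nCells number of labeled cells.
#' @slot velocityMeanUmPerH,velocitySdUmPerH radial-speed draw (um/h).
#' @slot jitterSdPx sd of iid per-frame positional jitter (px).
#' @slot transitionRow pixel row of the MP->BP morphology switch.
#' @slot burstAmplitude luminescence emission intensity during a burst.
#' @slot burstDurationH burst length (hours).
#' @slot burstBandRows inclusive pixel-row interval permitting bursts.
#' @slot spikeRatePerFrame expected cosmic-ray events per frame.
#' @slot spikeAmplitude cosmic-ray spike height.
#' @slot noiseSd sd of additive Gaussian background noise.
#' @slot cellAmplitude peak soma intensity in the label channel.
#' @slot somaSigmaPx Gaussian soma radius parameter (px).
#' @slot radialUp orientation flag (TRUE: pia at small row indices).
#' @slot startRows,startCols optional explicit start positions (length
#'   nCells each, or empty for automatic placement).
#' @slot seed RNG seed.
#' @export
setClass("SimParams",
  representation(
    imageShape = "integer",
    nFrames = "integer",
    frameIntervalH = "numeric",
    pixelSizeUm = "numeric",
    nCells = "integer",
    velocityMeanUmPerH = "numeric",
    velocitySdUmPerH = "numeric",
    jitterSdPx = "numeric",
    transitionRow = "numeric",
    burstAmplitude = "numeric",
    burstDurationH = "numeric",
    burstBandRows = "numeric",
    spikeRatePerFrame = "numeric",
    spikeAmplitude = "numeric",
    noiseSd = "numeric",
    cellAmplitude = "numeric",
    somaSigmaPx = "numeric",
    radialUp = "logical",
    startRows = "numeric",
    startCols = "numeric",
    seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character(0)
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L)) {
    msg <- c(msg, "imageShape must be (rows, cols), each >= 16")
  }
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (object@frameIntervalH <= 0) msg <- c(msg, "frameIntervalH must be > 0")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  for (nm in c("velocitySdUmPerH", "jitterSdPx", "burstAmplitude",
               "burstDurationH", "spikeRatePerFrame", "spikeAmplitude",
               "noiseSd")) {
    if (slot(object, nm) < 0) msg <- c(msg, paste(nm, "must be >= 0"))
  }
  b <- object@burstBandRows
  if (length(b) != 2L || b[1] > b[2] || b[1] < 1 || b[2] > object@imageShape[1]) {
    msg <- c(msg, "burstBandRows must be an increasing pair inside the image")
  }
  if (length(object@startRows) && length(object@startRows) != object@nCells) {
    msg <- c(msg, "startRows must be empty or length nCells")
  }
  if (length(object@startCols) && length(object@startCols) != object@nCells) {
    msg <- c(msg, "startCols must be empty or length nCells")
  }
  if (length(msg)) msg else TRUE
})

#' @param imageShape,nFrames,frameIntervalH,pixelSizeUm,nCells see slots.
#' @param velocityMeanUmPerH,velocitySdUmPerH,jitterSdPx see slots.
#' @param transitionRow,burstAmplitude,burstDurationH,burstBandRows see slots.
#' @param spikeRatePerFrame,spikeAmplitude,noiseSd see slots.
#' @param cellAmplitude,somaSigmaPx,radialUp,startRows,startCols,seed see slots.
#' @rdname SimParams-class
#' @export
simParams <- function(imageShape = c(140L, 160L),
                      nFrames = 160L,
                      frameIntervalH = 0.5,
                      pixelSizeUm = 2,
                      nCells = 30L,
                      velocityMeanUmPerH = 10,
                      velocitySdUmPerH = 1,
                      jitterSdPx = 1,
                      transitionRow = 70,
                      burstAmplitude = 10,
                      burstDurationH = 3,
                      burstBandRows = c(31, 120),
                      spikeRatePerFrame = 0,
                      spikeAmplitude = 50,
                      noiseSd = 1,
                      cellAmplitude = 100,
                      somaSigmaPx = 2,
                      radialUp = TRUE,
                      startRows = numeric(0),
                      startCols = numeric(0),
                      seed = 1L) {
  new("SimParams",
      imageShape = as.integer(imageShape), nFrames = as.integer(nFrames),
      frameIntervalH = frameIntervalH, pixelSizeUm = pixelSizeUm,
      nCells = as.integer(nCells),
      velocityMeanUmPerH = velocityMeanUmPerH,
      velocitySdUmPerH = velocitySdUmPerH, jitterSdPx = jitterSdPx,
      transitionRow = transitionRow, burstAmplitude = burstAmplitude,
      burstDurationH = burstDurationH,
      burstBandRows = as.numeric(burstBandRows),
      spikeRatePerFrame = spikeRatePerFrame, spikeAmplitude = spikeAmplitude,
      noiseSd = noiseSd, cellAmplitude = cellAmplitude,
      somaSigmaPx = somaSigmaPx, radialUp = radialUp,
      startRows = as.numeric(startRows), startCols = as.numeric(startCols),
      seed = as.integer(seed))
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageStack: %d x %d px, %d frames @ %g h/frame (t0 = %g h), %g um/px\n",
    d[1], d[2], d[3], object@frameIntervalH, object@t0H, object@pixelSizeUm))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@frames), max(object@frames)))
})

setMethod("show", "LayerAnnotation", function(object) {
  cat(sprintf(
    "LayerAnnotation: pial row %g, ventricular row %g, SP centre row %g (%s)\n",
    object@pialRow, object@ventricularRow, object@spCenterRow,
    if (object@radialUp) "pia toward row 1" else "pia toward last row"))
})

setMethod("show", "GridSeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridSeries: %d x %d grid, %d frames (t = %g ... %g h)\n",
              d[1], d[2], d[3], object@timestamps[1],
              object@timestamps[d[3]]))
})

setMethod("show", "SpectrumGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectrumGrid: %d x %d grid, bins 0..%d (%s, N = %d)\n",
              d[1], d[2], d[3] - 1L, object@type, object@nFramesUsed))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d x %d px, %d frames @ %g h, %d cells, v = %g +/- %g um/h, seed %d\n",
    object@imageShape[1], object@imageShape[2], object@nFrames,
    object@frameIntervalH, object@nCells, object@velocityMeanUmPerH,
    object@velocitySdUmPerH, object@seed))
})
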