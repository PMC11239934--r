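#' Grid-average a movie into per-square mean-intensity time series
#'
#' Partitions every frame into \code{gridRows x gridCols} axis-aligned
#' rectangles and records the arithmetic mean intensity of each rectangle
#' per frame.  Boundaries are the rounded integers
#' \code{round(i * H / gridRows)} (half-open intervals), so any image at
#' least as large as the grid is accepted with no divisibility
#' requirement; every pixel belongs to exactly one square.
#'
#' The default 16 x 14 grid is the reporter-quantification convention this
#' package implements: 16 columns across the slice and 14 rows along the
#' radial axis.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param gridRows,gridCols grid dimensions (rows along the radial axis).
#' @return a \linkS4class{GridSeries} with values (gridRow, gridCol, time).
#' @export
gridAverage <- function(stack, gridRows = 14L, gridCols = 16L) {
  d <- frameDim(stack)
  rb <- .gridBreaks(d[1], gridRows)
  cb <- .gridBreaks(d[2], gridCols)
  x <- frames(stack)
  tN <- nFrames(stack)
  vals <- array(0, dim = c(gridRows, gridCols, tN))
  for (i in seq_len(gridRows)) {
    rows <- (rb[i] + 1L):rb[i + 1L]
    for (j in seq_len(gridCols)) {
      cols <- (cb[j] + 1L):cb[j + 1L]
      block <- x[rows, cols, , drop = FALSE]
      vals[i, j, ] <- colMeans(matrix(block, ncol = tN))
    }
  }
  new("GridSeries", values = vals, rowBreaks = rb, colBreaks = cb,
      timestamps = frameTimes(stack))
}

#' Drop the initial high-background window from a grid series
#'
#' Removes every frame whose start time is strictly below \code{cutoffH}
#' hours (the immediate post-onset window is dominated by background and
#' excluded from spectral analysis; 4.5 h by default in the composed
#' pipeline).  Remaining timestamps are preserved unchanged.
#'
#' @param series a \linkS4class{GridSeries}.
#' @param cutoffH exclusion cutoff in hours; frames with t < cutoffH go.
#' @return the shortened \linkS4class{GridSeries}.
#' @export
excludeInitial <- function(series, cutoffH) {
  keep <- series@timestamps >= cutoffH
  if (sum(keep) < 2L) stop("stack too short after exclusion (",
                           sum(keep), " frames remain)")
  new("GridSeries", values = series@values[, , keep, drop = FALSE],
      rowBreaks = series@rowBreaks, colBreaks = series@colBreaks,
      timestamps = series@timestamps[keep])
}

#' Temporal DFT of every grid cell's time series
#'
#' Computes, per grid cell, the discrete Fourier transform
#' \code{X[k] = sum_n x[n] exp(-2 pi i k n / N)} of the mean-intensity
#' time series and stores the one-sided spectrum for bins
#' k = 0 ... floor(N/2), either as magnitudes |X[k]| (default) or as
#' powers |X[k]|^2.  Frequencies are indexed by DFT bin along the frame
#' axis, not by physical hertz: at time-lapse cadences of minutes to
#' hours per frame the analysis bands are bin ranges.
#'
#' @param series a \linkS4class{GridSeries} with uniformly spaced
#'   timestamps (non-uniform spacing is an error).
#' @param type "magnitude" or "power".
#' @return a \linkS4class{SpectrumGrid}.
#' @export
temporalSpectrum <- function(series, type = c("magnitude", "power")) {
  type <- match.arg(type)
  ts <- series@timestamps
  n <- length(ts)
  if (n < 2L) stop("need at least 2 frames")
  dt <- diff(ts)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop("non-uniform timestamps; the DFT requires equal frame spacing")
  }
  d <- dim(series@values)
  x <- matrix(aperm(series@values, c(3, 1, 2)), nrow = n)
  mags <- Mod(stats::mvfft(x))[seq_len(n %/% 2L + 1L), , drop = FALSE]
  if (type == "power") mags <- mags^2
  new("SpectrumGrid",
      values = aperm(array(mags, dim = c(n %/% 2L + 1L, d[1], d[2])),
                     c(2, 3, 1)),
      nFramesUsed = as.integer(n), type = type,
      rowBreaks = series@rowBreaks, colBreaks = series@colBreaks)
}

#' Sum spectral values over an inclusive bin band
#'
#' \code{B[g] = sum_{k in [band[1], band[2]]} |X_g[k]|} (or powers,
#' matching the spectrum type).  Bins are 0-based DFT indices.  A band
#' reaching above the Nyquist bin floor(N/2) is clipped with a warning; a
#' band entirely above Nyquist is an error by default, or zero with a
#' warning when the band is a noise-estimation band
#' (\code{onAboveNyquist = "zero"}).
#'
#' @param spec a \linkS4class{SpectrumGrid}.
#' @param band inclusive 0-based bin range, e.g. \code{c(2, 30)}.
#' @param onAboveNyquist "error" or "zero".
#' @return numeric matrix (gridRow x gridCol) with attribute
#'   \code{nBins}, the number of bins actually summed.
#' @export
bandPower <- function(spec, band, onAboveNyquist = c("error", "zero")) {
  onAboveNyquist <- match.arg(onAboveNyquist)
  if (length(band) != 2L || band[1] > band[2] || band[1] < 0) {
    stop("band must be an increasing pair of non-negative bin indices")
  }
  kmax <- spec@nFramesUsed %/% 2L
  lo <- band[1]; hi <- band[2]
  if (lo > kmax) {
    if (onAboveNyquist == "error") {
      stop("band [", lo, ", ", hi, "] lies entirely above Nyquist bin ", kmax)
    }
    warning("band [", lo, ", ", hi, "] lies above Nyquist bin ", kmax,
            "; returning zeros")
    out <- matrix(0, dim(spec@values)[1], dim(spec@values)[2])
    attr(out, "nBins") <- 0L
    return(out)
  }
  if (hi > kmax) {
    warning("band [", lo, ", ", hi, "] clipped to Nyquist bin ", kmax)
    hi <- kmax
  }
  sub <- spec@values[, , (lo + 1L):(hi + 1L), drop = FALSE]
  out <- apply(sub, c(1, 2), sum)
  attr(out, "nBins") <- as.integer(hi - lo + 1L)
  out
}

#' Cosmic-ray spike correction of low-band sums
#'
#' A cosmic ray is a single-frame impulse, whose DFT magnitude is flat
#' across all bins.  The default \code{broadband_subtract} mode estimates
#' that flat floor from the high band and removes it from the low band:
#' \code{B* = max(0, B - nLow * H / nHigh)}, with nLow/nHigh the bin
#' counts actually summed.  A pure impulse is annihilated exactly while a
#' genuine low-frequency signal (zero high-band content) passes through
#' unchanged.  \code{mask} re-sums the low band after zeroing high-band
#' bins — a literal low-pass reading which has no effect when the bands
#' are disjoint — and \code{none} returns B unchanged.
#'
#' @param B low-band sums (matrix from \code{\link{bandPower}}).
#' @param H high-band sums.
#' @param lowBand,highBand the inclusive bin ranges used.
#' @param mode "broadband_subtract", "mask" or "none".
#' @param spec the \linkS4class{SpectrumGrid}; required for mode "mask".
#' @return corrected matrix B*; \code{B* = B} when mode is "none".
#' @export
spikeCorrect <- function(B, H, lowBand, highBand,
                         mode = c("broadband_subtract", "mask", "none"),
                         spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(B)
  if (mode == "mask") {
    if (is.null(spec)) stop("mode 'mask' needs the SpectrumGrid")
    keep <- setdiff(lowBand[1]:lowBand[2], highBand[1]:highBand[2])
    kmax <- spec@nFramesUsed %/% 2L
    keep <- keep[keep <= kmax]
    if (!length(keep)) {
      out <- matrix(0, dim(spec@values)[1], dim(spec@values)[2])
      attr(out, "nBins") <- 0L
      return(out)
    }
    sub <- spec@values[, , keep + 1L, drop = FALSE]
    out <- apply(sub, c(1, 2), sum)
    attr(out, "nBins") <- length(keep)
    return(out)
  }
  nLow <- attr(B, "nBins"); nHigh <- attr(H, "nBins")
  if (is.null(nLow)) nLow <- lowBand[2] - lowBand[1] + 1L
  if (is.null(nHigh)) nHigh <- highBand[2] - highBand[1] + 1L
  if (nHigh == 0L) {
    warning("empty high band; spike correction disabled")
    return(B)
  }
  out <- pmax(0, B - nLow * (H / nHigh))
  attr(out, "nBins") <- nLow
  out
}

#' Select the grid rows flanking the subplate band
#'
#' Finds the grid row containing \code{spCenterRow} and retains the
#' \code{spHalfRows} grid rows immediately above it and the
#' \code{spHalfRows} immediately below it (the "top and bottom four rows"
#' convention at the default).  The centre row itself is excluded unless
#' \code{includeCenter}.  Selections are clipped at the image edge with a
#' warning.  All grid columns are kept.
#'
#' @param spec a \linkS4class{GridSeries} or \linkS4class{SpectrumGrid}
#'   (anything carrying \code{rowBreaks}).
#' @param annotation a \linkS4class{LayerAnnotation} bound to the same
#'   image.
#' @param spHalfRows grid rows kept on each side of the SP centre row.
#' @param includeCenter also keep the centre row itself.
#' @return logical vector over grid rows with attribute \code{spGridRow},
#'   the centre grid row.
#' @export
selectSpRows <- function(spec, annotation, spHalfRows = 4L,
                         includeCenter = FALSE) {
  rb <- spec@rowBreaks
  nr <- length(rb) - 1L
  # grid row g covers the half-open pixel interval (rb[g], rb[g + 1]];
  # pixel row r (centre coordinate r - 0.5) lands in the interval below.
  g0 <- findInterval(annotation@spCenterRow - 0.5, rb,
                     rightmost.closed = TRUE)
  g0 <- min(max(g0, 1L), nr)
  want <- c((g0 - spHalfRows):(g0 - 1L), (g0 + 1L):(g0 + spHalfRows))
  sel <- want[want >= 1L & want <= nr]
  if (length(sel) < length(want)) {
    warning("SP selection clipped at image edge (",
            length(want) - length(sel), " grid rows dropped)")
  }
  if (includeCenter) sel <- sort(c(sel, g0))
  mask <- seq_len(nr) %in% sel
  attr(mask, "spGridRow") <- g0
  mask
}

#' Full grid-Fourier reporter quantification of one slice movie
#'
#' Composes the whole reporter pipeline:
#' grid averaging, initial-window exclusion, temporal DFT, low/high band
#' summation, cosmic-ray correction and SP-row selection, and returns one
#' corrected value per grid cell in a long-format table ready for violin
#' plotting and group statistics.  Errors raised inside a stage are
#' labeled with the stage name.  The computation is condition-blind and
#' fully deterministic.
#'
#' @param stack an \linkS4class{ImageStack} (reporter channel).
#' @param annotation a \linkS4class{LayerAnnotation} for the slice.
#' @param config configuration list, see \code{\link{defaultConfig}}.
#' @param condition condition label attached to every row.
#' @param sliceId slice identifier attached to every row.
#' @return data.frame with columns condition, slice_id, grid_row,
#'   grid_col, B, H, B_star, in_sp_selection, plus attributes
#'   \code{nFramesUsed} and \code{config}.
#' @export
quantifyReporter <- function(stack, annotation, config = defaultConfig(),
                             condition = "control", sliceId = "slice1") {
  config <- validateConfig(config)
  .stage("annotation", checkAnnotation(annotation, stack))
  gs <- .stage("grid_average",
               gridAverage(stack, config$grid_rows, config$grid_cols))
  gs <- .stage("exclude_initial",
               excludeInitial(gs, config$exclude_initial_h))
  sp <- .stage("temporal_spectrum",
               temporalSpectrum(gs, config$spectrum_type))
  B <- .stage("band_power_low",
              bandPower(sp, config$low_band, onAboveNyquist = "error"))
  H <- .stage("band_power_high",
              bandPower(sp, config$high_band, onAboveNyquist = "zero"))
  Bs <- .stage("spike_correct",
               spikeCorrect(B, H, config$low_band, config$high_band,
                            mode = config$spike_correction, spec = sp))
  rowMask <- .stage("select_sp_rows",
                    selectSpRows(sp, annotation, config$sp_half_rows,
                                 config$include_sp_center))
  nr <- nrow(B); nc <- ncol(B)
  out <- data.frame(
    condition = condition,
    slice_id = sliceId,
    grid_row = rep(seq_len(nr), times = nc),
    grid_col = rep(seq_len(nc), each = nr),
    B = as.vector(B),
    H = as.vector(H),
    B_star = as.vector(Bs),
    in_sp_selection = rep(rowMask, times = nc),
    stringsAsFactors = FALSE
  )
  attr(out, "nFramesUsed") <- sp@nFramesUsed
  attr(out, "config") <- config
  out
}

#' Violin plot of corrected reporter band power
#'
#' Renders the distribution of SP-selected corrected band-power values per
#' condition as a violin plot, the summary display convention for this
#' quantification.
#'
#' @param table output of \code{\link{quantifyReporter}} (rows from
#'   several slices/conditions may be concatenated).
#' @param value column to plot ("B_star" by default).
#' @param spOnly restrict to SP-selected grid cells (default TRUE).
#' @return a ggplot object.
#' @export
plotReporterViolin <- function(table, value = "B_star", spOnly = TRUE) {
  if (spOnly) table <- table[table$in_sp_selection, , drop = FALSE]
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$condition, y = .data[[value]])) +
    ggplot2::geom_violin(fill = "grey80", scale = "width") +
    ggplot2::geom_jitter(width = 0.08, size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "corrected band power (a.u.)") +
    ggplot2::theme_classic()
}
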