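# Synthetic slice-movie generators.  These are the package's forward
# model: ground-truthed emulations of the statistical structure the
# analyses assume (radially migrating labeled cells, an MP->BP morphology
# switch at a configurable row, SP-confined transient luminescence
# bursts, cosmic-ray impulses, Gaussian background), not photorealistic
# microscopy.

# ---- low-level rendering ---------------------------------------------------

# Add a truncated Gaussian soma at (row0, col0) to img (in place value).
.paintSoma <- function(img, row0, col0, amplitude, sigma) {
  d <- dim(img)
  w <- ceiling(3 * sigma)
  rr <- max(1L, floor(row0 - w)):min(d[1], ceiling(row0 + w))
  cc <- max(1L, floor(col0 - w)):min(d[2], ceiling(col0 + w))
  if (!length(rr) || !length(cc)) return(img)
  g <- exp(-(outer((rr - row0)^2, (cc - col0)^2, "+")) / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + amplitude * g
  img
}

# Pixels of a 2 px thick segment from (row0, col0) along unit direction
# (dr, dc) for `len` px.  Each sampled pixel also paints its right and
# lower neighbour so diagonal segments stay 4-connected.
.segmentPixels <- function(row0, col0, dr, dc, len, dims) {
  s <- seq(0, len, by = 0.5)
  r <- round(row0 + dr * s); c <- round(col0 + dc * s)
  px <- rbind(cbind(r, c), cbind(r, c + 1), cbind(r + 1, c))
  px <- px[px[, 1] >= 1 & px[, 1] <= dims[1] &
           px[, 2] >= 1 & px[, 2] <= dims[2], , drop = FALSE]
  unique(px)
}

# Per-cell static process geometry.  MP: 3-5 arms, 10-13 px, angles with
# >= 50 degree separation.  BP: one 16 px leading process pointing
# pial-ward plus a 9 px trailing process.  Angles are measured in the
# (row, col) plane; pialward is (-1, 0) when radialUp.
.drawArmGeometry <- function(nCells, radialUp) {
  pial <- if (radialUp) -pi / 2 else pi / 2   # angle of pia-ward direction
  lapply(seq_len(nCells), function(i) {
    k <- sample(3:5, 1L)
    repeat {
      ang <- sort(stats::runif(k, 0, 2 * pi))
      gaps <- diff(c(ang, ang[1] + 2 * pi))
      if (min(gaps) > 50 * pi / 180) break
    }
    list(
      mpAngles = ang,
      mpLens = stats::runif(k, 10, 13),
      bpLead = pial + stats::runif(1, -10, 10) * pi / 180,
      bpLeadLen = 16,
      bpTrailLen = 9
    )
  })
}

# Render one frame of the label channel: somata plus class-dependent
# processes for every cell.
.renderLabelFrame <- function(dims, rows, cols, classes, geom, amplitude,
                              sigma) {
  img <- matrix(0, dims[1], dims[2])
  for (i in seq_along(rows)) {
    img <- .paintSoma(img, rows[i], cols[i], amplitude, sigma)
    g <- geom[[i]]
    if (classes[i] == "MP") {
      for (a in seq_along(g$mpAngles)) {
        px <- .segmentPixels(rows[i], cols[i], sin(g$mpAngles[a]),
                             cos(g$mpAngles[a]), g$mpLens[a], dims)
        img[px] <- img[px] + 0.6 * amplitude
      }
    } else {
      px <- .segmentPixels(rows[i], cols[i], sin(g$bpLead), cos(g$bpLead),
                           g$bpLeadLen, dims)
      img[px] <- img[px] + 0.6 * amplitude
      px <- .segmentPixels(rows[i], cols[i], -sin(g$bpLead), -cos(g$bpLead),
                           g$bpTrailLen, dims)
      img[px] <- img[px] + 0.6 * amplitude
    }
  }
  img
}

# ---- generators ------------------------------------------------------------

#' Generate a ground-truthed migration movie (label channel)
#'
#' Simulates \code{nCells} labeled neurons migrating toward the pial
#' surface.  Each cell draws a radial velocity from
#' N(velocityMeanUmPerH, velocitySdUmPerH), follows a straight radial
#' path with iid per-frame Gaussian jitter (sd \code{jitterSdPx} per
#' axis), and is rendered as a Gaussian soma with class-dependent
#' processes: several short radiating arms while on the ventricular side
#' of \code{transitionRow} (multipolar) and a single elongated pia-ward
#' leading process after crossing it (bipolar).  Gaussian background
#' noise is added and intensities are clamped at zero.  Cells that would
#' exit the frame are clamped at a margin and flagged.  Identical seeds
#' give bit-identical output.
#'
#' @param params a \linkS4class{SimParams}.
#' @return list with elements \code{stack} (an \linkS4class{ImageStack})
#'   and \code{truth}, a list of class \code{radmigTruth} holding
#'   \code{tracks} (cell_id, frame, t_h, row, col, morphology),
#'   \code{velocities} (cell_id, v_um_per_h, displacement_um, clamped)
#'   and the annotation-free geometry needed to score every estimator.
#' @export
generateMigrationMovie <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  p <- params
  d <- p@imageShape
  .withSeed(p@seed, {
    v <- stats::rnorm(p@nCells, p@velocityMeanUmPerH, p@velocitySdUmPerH)
    margin <- 7
    if (length(p@startRows)) {
      row0 <- p@startRows
    } else {
      lo <- if (p@radialUp) 0.60 * d[1] else 0.10 * d[1]
      row0 <- stats::runif(p@nCells, lo, lo + 0.30 * d[1])
    }
    if (length(p@startCols)) {
      col0 <- p@startCols
    } else {
      col0 <- (seq_len(p@nCells) - 0.5) * d[2] / p@nCells +
        stats::runif(p@nCells, -2, 2)
      col0 <- pmin(pmax(col0, margin), d[2] - margin)
    }
    geom <- .drawArmGeometry(p@nCells, p@radialUp)
    tH <- (seq_len(p@nFrames) - 1L) * p@frameIntervalH
    vPx <- v / p@pixelSizeUm
    dirSign <- if (p@radialUp) -1 else 1
    rows <- outer(vPx, tH) * dirSign + row0 +
      matrix(stats::rnorm(p@nCells * p@nFrames, 0, p@jitterSdPx),
             p@nCells, p@nFrames)
    cols <- matrix(stats::rnorm(p@nCells * p@nFrames, 0, p@jitterSdPx),
                   p@nCells, p@nFrames) + col0
    clampedRows <- pmin(pmax(rows, margin), d[1] - margin)
    clampedCols <- pmin(pmax(cols, margin), d[2] - margin)
    clamped <- rowSums(clampedRows != rows | clampedCols != cols) > 0
    rows <- clampedRows; cols <- clampedCols
    # morphology: MP on the ventricular side of transitionRow, BP after.
    mp <- if (p@radialUp) rows > p@transitionRow else rows < p@transitionRow
    classes <- ifelse(mp, "MP", "BP")
    arr <- array(0, dim = c(d[1], d[2], p@nFrames))
    for (t in seq_len(p@nFrames)) {
      fr <- .renderLabelFrame(d, rows[, t], cols[, t], classes[, t], geom,
                              p@cellAmplitude, p@somaSigmaPx)
      if (p@noiseSd > 0) {
        fr <- fr + matrix(stats::rnorm(d[1] * d[2], 0, p@noiseSd), d[1], d[2])
      }
      arr[, , t] <- pmax(fr, 0)
    }
    truth <- structure(list(
      params = p,
      tracks = data.frame(
        cell_id = rep(seq_len(p@nCells), times = p@nFrames),
        frame = rep(seq_len(p@nFrames), each = p@nCells),
        t_h = rep(tH, each = p@nCells),
        row = as.vector(rows), col = as.vector(cols),
        morphology = as.vector(classes),
        stringsAsFactors = FALSE
      ),
      velocities = data.frame(
        cell_id = seq_len(p@nCells),
        v_um_per_h = v,
        displacement_um = v * (p@nFrames - 1L) * p@frameIntervalH,
        clamped = clamped
      ),
      bursts = NULL,
      spikes = NULL
    ), class = "radmigTruth")
    list(
      stack = ImageStack(arr, frameIntervalH = p@frameIntervalH,
                         pixelSizeUm = p@pixelSizeUm),
      truth = truth
    )
  })
}

#' Generate the luminescence (reporter) channel for a migration movie
#'
#' Given the trajectories in \code{truth}, simulates transient
#' reporter bursts confined to the burst-permissive band
#' \code{burstBandRows}: for each cell the burst onset is drawn uniformly
#' over its in-band transit interval, the burst lasts
#' \code{burstDurationH}, and emission (a uniform disk of
#' \code{burstAmplitude}, radius \code{lumRadiusPx}) occurs only on
#' frames where the burst window and band membership coincide.  Gaussian
#' background noise is added and intensities clamped at zero.
#'
#' @param params a \linkS4class{SimParams}.
#' @param truth ground truth from \code{\link{generateMigrationMovie}}.
#' @param lumRadiusPx radius of the emitting disk (px).
#' @return list with \code{stack} (the luminescence
#'   \linkS4class{ImageStack}) and \code{truth} updated with a
#'   \code{bursts} data.frame (cell_id, start_h, end_h; NA when a cell
#'   never bursts).
#' @export
generateLuminescenceMovie <- function(params, truth, lumRadiusPx = 3) {
  stopifnot(is(params, "SimParams"), inherits(truth, "radmigTruth"))
  p <- params
  d <- p@imageShape
  tr <- truth$tracks
  tH <- sort(unique(tr$t_h))
  nT <- length(tH)
  rowM <- matrix(NA_real_, p@nCells, nT)
  colM <- matrix(NA_real_, p@nCells, nT)
  rowM[cbind(tr$cell_id, tr$frame)] <- tr$row
  colM[cbind(tr$cell_id, tr$frame)] <- tr$col
  .withSeed(p@seed + 1L, {
    inBand <- rowM >= p@burstBandRows[1] & rowM <= p@burstBandRows[2]
    startH <- rep(NA_real_, p@nCells)
    endH <- rep(NA_real_, p@nCells)
    for (i in seq_len(p@nCells)) {
      if (!any(inBand[i, ])) next
      tin <- tH[inBand[i, ]]
      slack <- max(0, (max(tin) - min(tin)) - p@burstDurationH)
      startH[i] <- min(tin) + stats::runif(1, 0, slack)
      endH[i] <- startH[i] + p@burstDurationH
    }
    arr <- array(0, dim = c(d[1], d[2], nT))
    for (t in seq_len(nT)) {
      img <- matrix(0, d[1], d[2])
      on <- which(!is.na(startH) & tH[t] >= startH & tH[t] <= endH &
                    inBand[, t])
      for (i in on) {
        px <- .diskPixels(rowM[i, t], colM[i, t], lumRadiusPx, d)
        img[px] <- img[px] + p@burstAmplitude
      }
      if (p@noiseSd > 0) {
        img <- img + matrix(stats::rnorm(d[1] * d[2], 0, p@noiseSd),
                            d[1], d[2])
      }
      arr[, , t] <- pmax(img, 0)
    }
    truth$bursts <- data.frame(cell_id = seq_len(p@nCells),
                               start_h = startH, end_h = endH)
    list(
      stack = ImageStack(arr, frameIntervalH = p@frameIntervalH,
                         pixelSizeUm = p@pixelSizeUm),
      truth = truth
    )
  })
}

#' Inject cosmic-ray spikes into a stack
#'
#' Adds Poisson(rate)-many single-pixel, single-frame additive spikes of
#' height \code{amplitude} per frame, at uniformly random pixels.  The
#' returned spike list is exhaustive, so
#' \code{sum(out) - sum(in) = amplitude * nrow(spikes)} always holds.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param rate expected events per frame (>= 0).
#' @param amplitude spike height (intensity units).
#' @param seed RNG seed.
#' @return list with \code{stack} (spiked copy) and \code{spikes}, a
#'   data.frame (frame, row, col).
#' @export
injectCosmicRays <- function(stack, rate, amplitude, seed = 1L) {
  stopifnot(rate >= 0)
  arr <- frames(stack)
  d <- dim(arr)
  .withSeed(seed, {
    counts <- stats::rpois(d[3], rate)
    n <- sum(counts)
    spikes <- data.frame(frame = rep(seq_len(d[3]), counts),
                         row = sample.int(d[1], n, replace = TRUE),
                         col = sample.int(d[2], n, replace = TRUE))
    if (n > 0) {
      idx <- cbind(spikes$row, spikes$col, spikes$frame)
      for (k in seq_len(n)) {
        arr[idx[k, 1], idx[k, 2], idx[k, 3]] <-
          arr[idx[k, 1], idx[k, 2], idx[k, 3]] + amplitude
      }
    }
    list(stack = ImageStack(arr, frameIntervalH = frameInterval(stack),
                            pixelSizeUm = pixelSize(stack), t0H = stack@t0H),
         spikes = spikes)
  })
}

#' Generate a labeled-cell section with a programmable BIN profile
#'
#' Draws \code{n} labeled-cell coordinates between the pial and
#' ventricular boundaries of \code{annotation} from a per-bin multinomial
#' mixture, so any target laminar profile can be synthesized.  Each
#' cell's ground-truth bin is recorded under the same half-open binning
#' convention as \code{\link{assignBins}} (BIN 1 pial-most).
#'
#' @param n number of cells.
#' @param binWeights numeric vector of per-bin mixture weights (length =
#'   number of bins); normalized internally.
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param imageCols lateral extent for column draws.
#' @param seed RNG seed.
#' @return data.frame (cell_id, row, col, bin_true).
#' @export
generateSection <- function(n, binWeights, annotation, imageCols = 160,
                            seed = 1L) {
  stopifnot(n >= 1, length(binWeights) >= 2, all(binWeights >= 0),
            sum(binWeights) > 0)
  nb <- length(binWeights)
  w <- binWeights / sum(binWeights)
  p0 <- annotation@pialRow; v0 <- annotation@ventricularRow
  .withSeed(seed, {
    bins <- sample.int(nb, n, replace = TRUE, prob = w)
    # bin k covers u in [(k-1)/nb, k/nb) measured pial -> ventricular
    u <- (bins - 1 + stats::runif(n)) / nb
    rows <- p0 + u * (v0 - p0)
    data.frame(cell_id = seq_len(n),
               row = rows,
               col = stats::runif(n, 1, imageCols),
               bin_true = bins)
  })
}

#' Render a single synthetic cell mask of known morphology
#'
#' Draws one cell on its own canvas: a filled soma disk plus either
#' \code{nArms} radiating arms (multipolar) or a long pia-ward leading
#' process with a short trailing process (bipolar).  Used to test and
#' calibrate \code{\link{classifyPolarity}} against construction-time
#' ground truth.
#'
#' @param morphology "MP" or "BP".
#' @param nArms number of arms for MP cells (3-5).
#' @param canvas canvas size in px (square).
#' @param somaRadiusPx soma disk radius.
#' @param armLenPx arm length for MP cells.
#' @param radialUp orientation flag (pia toward row 1 when TRUE).
#' @param seed RNG seed for arm angles.
#' @return binary matrix (canvas x canvas) with the cell centred.
#' @export
renderCellMask <- function(morphology = c("MP", "BP"), nArms = 4L,
                           canvas = 48L, somaRadiusPx = 4, armLenPx = 12,
                           radialUp = TRUE, seed = 1L) {
  morphology <- match.arg(morphology)
  dims <- c(canvas, canvas)
  ctr <- (canvas + 1) / 2
  img <- matrix(0, canvas, canvas)
  img[.diskPixels(ctr, ctr, somaRadiusPx, dims)] <- 1
  .withSeed(seed, {
    if (morphology == "MP") {
      stopifnot(nArms >= 3)
      repeat {
        ang <- sort(stats::runif(nArms, 0, 2 * pi))
        gaps <- diff(c(ang, ang[1] + 2 * pi))
        if (min(gaps) > 50 * pi / 180) break
      }
      for (a in ang) {
        img[.segmentPixels(ctr, ctr, sin(a), cos(a), armLenPx, dims)] <- 1
      }
    } else {
      lead <- (if (radialUp) -pi / 2 else pi / 2) +
        stats::runif(1, -10, 10) * pi / 180
      img[.segmentPixels(ctr, ctr, sin(lead), cos(lead), 16, dims)] <- 1
      img[.segmentPixels(ctr, ctr, -sin(lead), -cos(lead), 9, dims)] <- 1
    }
  })
  img
}
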