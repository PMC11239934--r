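#' Classify a cell mask as multipolar or bipolar
#'
#' Reproducible surrogate for the by-eye morphology call: the soma is the
#' largest inscribed disk of the mask (distance-transform maximum); after
#' removing the soma disk, the remaining connected components that touch
#' the soma boundary and extend at least \code{minNeuritePx} beyond it
#' are the primary neurites.  The leading process is the longest primary
#' neurite; it counts as pia-directed when its tip direction lies within
#' \code{coneDeg} degrees of the pial axis.  Cells with >= 3 primary
#' neurites are multipolar (MP); cells with 1-2 neurites whose leading
#' process is pia-directed are bipolar (BP); anything else (including
#' zero neurites) is ambiguous.
#'
#' The classification is invariant to mask translation and to mirroring
#' of the lateral axis (the pial direction is fixed by the annotation).
#'
#' @param mask binary matrix, one connected component.
#' @param annotation a \linkS4class{LayerAnnotation} (supplies the pial
#'   direction via \code{radialUp}).
#' @param minSomaRadiusPx minimum inscribed-disk radius for a valid soma.
#' @param minNeuritePx minimum neurite extension beyond the soma (px).
#' @param coneDeg half-angle of the pia-directed cone (degrees).
#' @return list (morphology = "MP"/"BP"/"ambiguous", nPrimaryNeurites,
#'   leadingProcess).
#' @export
classifyPolarity <- function(mask, annotation, minSomaRadiusPx = 2.5,
                             minNeuritePx = 4, coneDeg = 45) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1L) stop("disconnected mask (", max(lab), " components)")
  d <- EBImage::distmap(mask)
  r <- max(d)
  if (r < minSomaRadiusPx) {
    stop("no soma: largest inscribed disk radius ", signif(r, 3),
         " < ", minSomaRadiusPx)
  }
  ctr <- which(d == r, arr.ind = TRUE)[1, ]
  dims <- dim(mask)
  rest <- mask
  rest[.diskPixels(ctr[1], ctr[2], r + 0.5, dims)] <- FALSE
  neur <- data.frame(len = numeric(0), tipRow = numeric(0),
                     tipCol = numeric(0))
  if (any(rest)) {
    labr <- EBImage::bwlabel(rest)
    for (k in seq_len(max(labr))) {
      px <- which(labr == k, arr.ind = TRUE)
      dist <- sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
      if (min(dist) > r + 2) next       # not attached to the soma
      len <- max(dist) - r
      if (len < minNeuritePx) next
      tip <- px[which.max(dist), ]
      neur <- rbind(neur, data.frame(len = len, tipRow = tip[1],
                                     tipCol = tip[2]))
    }
  }
  n <- nrow(neur)
  leading <- FALSE
  if (n > 0) {
    lead <- neur[which.max(neur$len), ]
    dir <- c(lead$tipRow - ctr[1], lead$tipCol - ctr[2])
    pia <- if (annotation@radialUp) c(-1, 0) else c(1, 0)
    cosang <- sum(dir * pia) / sqrt(sum(dir^2))
    leading <- cosang >= cos(coneDeg * pi / 180)
  }
  morph <- if (n >= 3) "MP"
           else if (n >= 1 && leading) "BP"
           else "ambiguous"
  list(morphology = morph, nPrimaryNeurites = n, leadingProcess = leading)
}

#' Classify every detected cell in a frame
#'
#' Thresholds a frame, splits it into connected components and runs
#' \code{\link{classifyPolarity}} on each sufficiently large component.
#' Components that fail the soma precondition are reported as ambiguous.
#'
#' @param frame numeric matrix.
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param threshold intensity threshold.
#' @param minArea minimum component area (px).
#' @param ... passed to \code{\link{classifyPolarity}}.
#' @return data.frame (cell_id, row, col, morphology, n_primary_neurites,
#'   leading_process).
#' @export
classifyFrame <- function(frame, annotation, threshold, minArea = 20L, ...) {
  bw <- frame > threshold
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  res <- list()
  for (k in seq_len(n)) {
    m <- lab == k
    if (sum(m) < minArea) next
    px <- which(m, arr.ind = TRUE)
    cl <- tryCatch(classifyPolarity(m, annotation, ...),
                   error = function(e) list(morphology = "ambiguous",
                                            nPrimaryNeurites = 0L,
                                            leadingProcess = FALSE))
    res[[length(res) + 1L]] <- data.frame(
      cell_id = length(res) + 1L,
      row = mean(px[, 1]), col = mean(px[, 2]),
      morphology = cl$morphology,
      n_primary_neurites = cl$nPrimaryNeurites,
      leading_process = cl$leadingProcess)
  }
  if (!length(res)) {
    return(data.frame(cell_id = integer(0), row = numeric(0),
                      col = numeric(0), morphology = character(0),
                      n_primary_neurites = integer(0),
                      leading_process = logical(0)))
  }
  do.call(rbind, res)
}

#' Multipolar/bipolar composition at two timepoints
#'
#' Counts MP and BP cells at the start of imaging and after the follow-up
#' interval (10 h by convention) and reports fractions per timepoint.
#' Ambiguous cells are excluded from the fractions and reported
#' separately; fractions sum to 1 at each timepoint.
#'
#' @param records0,records1 data.frames with a \code{morphology} column
#'   (e.g. from \code{\link{classifyFrame}}), at t0 and t1.
#' @param t0H,t1H timepoint labels in hours.
#' @return data.frame (t_h, n_mp, n_bp, n_ambiguous, frac_mp, frac_bp).
#' @export
mpBpComposition <- function(records0, records1, t0H = 0, t1H = 10) {
  one <- function(rec, tH) {
    nm <- sum(rec$morphology == "MP")
    nb <- sum(rec$morphology == "BP")
    na_ <- sum(rec$morphology == "ambiguous")
    if (nm + nb == 0L) stop("all cells ambiguous at t = ", tH, " h")
    data.frame(t_h = tH, n_mp = nm, n_bp = nb, n_ambiguous = na_,
               frac_mp = nm / (nm + nb), frac_bp = nb / (nm + nb))
  }
  rbind(one(records0, t0H), one(records1, t1H))
}

#' Assign labeled cells to laminar BINs
#'
#' Divides the span between the pial and ventricular boundaries into
#' \code{nBins} equal-height half-open intervals (BIN 1 adjacent to the
#' pial surface; the last bin is closed at the ventricular boundary) and
#' assigns each cell by its row coordinate.  Cells outside the span get
#' \code{NA} and are counted in the \code{n_out_of_span} attribute.
#'
#' @param rows numeric vector of cell row coordinates (px).
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param nBins number of bins (>= 2); the bin count is a reporting
#'   parameter, not a fixed constant, and is echoed in all outputs.
#' @return integer vector of 1-based bin indices (NA = out of span) with
#'   attributes \code{nBins} and \code{n_out_of_span}.
#' @export
assignBins <- function(rows, annotation, nBins = 5L) {
  if (nBins < 2L) stop("nBins must be >= 2")
  p <- annotation@pialRow; v <- annotation@ventricularRow
  u <- (rows - p) / (v - p)
  bins <- ifelse(u < 0 | u > 1, NA_integer_,
                 pmin(nBins, floor(u * nBins) + 1L))
  structure(as.integer(bins), nBins = as.integer(nBins),
            n_out_of_span = sum(is.na(bins)))
}

#' Per-bin counts and fractions
#'
#' @param bins output of \code{\link{assignBins}} (NAs excluded).
#' @param nBins number of bins; defaults to the attribute on \code{bins}.
#' @return data.frame (bin, count, fraction); fractions sum to 1.
#' @export
binDistribution <- function(bins, nBins = attr(bins, "nBins")) {
  b <- bins[!is.na(bins)]
  counts <- tabulate(b, nbins = nBins)
  data.frame(bin = seq_len(nBins), count = counts,
             fraction = counts / sum(counts))
}

#' Zone assignment and zone-wise signal per cell
#'
#' Assigns each cell to below_SP / in_SP / above_SP by comparing its
#' centroid row with the inclusive SP band rows (above = pial side, in
#' the radial sense), and measures the mean intensity of a secondary
#' signal channel over a fixed-radius disk around the centroid at the
#' matching frame.  Used for zone-wise zymography quantification
#' (protease-activity signal of migrating neurons inside versus outside
#' the SP band).
#'
#' @param cells data.frame with columns row, col and optionally frame
#'   (default: frame 1 for every cell).
#' @param stack the signal \linkS4class{ImageStack}, co-registered.
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param spBandRows inclusive pixel-row interval c(lo, hi) of the SP
#'   band.
#' @param radiusPx disk radius for the signal readout.
#' @return \code{cells} with added columns \code{zone} and
#'   \code{zone_signal}.
#' @export
zoneSignal <- function(cells, stack, annotation, spBandRows, radiusPx = 3) {
  stopifnot(length(spBandRows) == 2L, spBandRows[1] <= spBandRows[2])
  checkAnnotation(annotation, stack)
  fr <- if ("frame" %in% names(cells)) cells$frame else rep(1L, nrow(cells))
  if (any(fr < 1L | fr > nFrames(stack))) {
    stop("frame index out of range [1, ", nFrames(stack), "]")
  }
  d <- frameDim(stack)
  zone <- character(nrow(cells))
  sig <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- cells$row[i]
    zone[i] <- if (r >= spBandRows[1] && r <= spBandRows[2]) "in_SP"
      else if ((r < spBandRows[1]) == annotation@radialUp) "above_SP"
      else "below_SP"
    px <- .diskPixels(r, cells$col[i], radiusPx, d)
    img <- frames(stack)[, , fr[i]]
    sig[i] <- mean(img[px])
  }
  cells$zone <- zone
  cells$zone_signal <- sig
  cells
}
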