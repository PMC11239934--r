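#' Detect labeled cells in one frame
#'
#' Thresholds the frame, labels connected components (4-connectivity),
#' drops components smaller than \code{minArea} pixels and returns
#' intensity-weighted centroids.  An empty result is allowed.
#'
#' @param frame numeric matrix (one movie frame).
#' @param threshold intensity threshold, above background.
#' @param minArea minimum component area in pixels.
#' @return data.frame (row, col, area, total_intensity), one row per
#'   detection.
#' @export
detectCells <- function(frame, threshold, minArea = 5L) {
  bw <- frame > threshold
  if (!any(bw)) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      area = integer(0), total_intensity = numeric(0)))
  }
  lab <- EBImage::bwlabel(bw)
  idx <- which(lab > 0)
  labv <- lab[idx]
  wv <- frame[idx]
  rv <- (idx - 1L) %% nrow(frame) + 1L
  cv <- (idx - 1L) %/% nrow(frame) + 1L
  area <- tabulate(labv)
  wsum <- as.vector(tapply(wv, labv, sum))
  rC <- as.vector(tapply(wv * rv, labv, sum)) / wsum
  cC <- as.vector(tapply(wv * cv, labv, sum)) / wsum
  keep <- area >= minArea
  data.frame(row = rC[keep], col = cC[keep], area = area[keep],
             total_intensity = wsum[keep])
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking: for each consecutive frame pair,
#' candidate links (distance <= maxDispUm) are assigned in order of
#' ascending distance (ties broken by active-track then detection index).
#' Unmatched detections start new tracks; a missed detection terminates
#' its track (no gap bridging).  Linking is deterministic and, up to the
#' measure-zero event of exactly tied distances, invariant to the order
#' of detections within a frame.
#'
#' @param detections list of data.frames from \code{\link{detectCells}},
#'   one per frame, in time order (>= 2 frames).
#' @param maxDispUm maximum per-frame displacement in micrometres.
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalH hours per frame.
#' @param t0H start-time offset in hours.
#' @return data.frame (track_id, frame, t_h, row, col).
#' @export
linkTracks <- function(detections, maxDispUm, pixelSizeUm, frameIntervalH,
                       t0H = 0) {
  nF <- length(detections)
  if (nF < 2L) stop("need at least 2 frames to link")
  maxDispPx <- maxDispUm / pixelSizeUm
  out <- list()
  nextId <- 1L
  # active: data.frame(track_id, row, col)
  d1 <- detections[[1]]
  active <- data.frame(track_id = seq_len(nrow(d1)) + nextId - 1L,
                       row = d1$row, col = d1$col)
  nextId <- nextId + nrow(d1)
  emit <- function(frame, ids, rows, cols) {
    data.frame(track_id = ids, frame = frame,
               t_h = t0H + (frame - 1L) * frameIntervalH,
               row = rows, col = cols)
  }
  out[[1]] <- emit(1L, active$track_id, active$row, active$col)
  for (f in 2:nF) {
    det <- detections[[f]]
    nA <- nrow(active); nD <- nrow(det)
    assignA <- rep(NA_integer_, nA)
    takenD <- rep(FALSE, nD)
    if (nA > 0 && nD > 0) {
      dm <- outer(active$row, det$row, "-")^2 + outer(active$col, det$col, "-")^2
      cand <- which(dm <= maxDispPx^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dm[cand], cand[, 1], cand[, 2])
        for (k in ord) {
          a <- cand[k, 1]; dd <- cand[k, 2]
          if (is.na(assignA[a]) && !takenD[dd]) {
            assignA[a] <- dd
            takenD[dd] <- TRUE
          }
        }
      }
    }
    newActive <- list()
    for (a in seq_len(nA)) {
      if (!is.na(assignA[a])) {
        dd <- assignA[a]
        newActive[[length(newActive) + 1L]] <-
          data.frame(track_id = active$track_id[a],
                     row = det$row[dd], col = det$col[dd])
      }
    }
    for (dd in which(!takenD)) {
      newActive[[length(newActive) + 1L]] <-
        data.frame(track_id = nextId, row = det$row[dd], col = det$col[dd])
      nextId <- nextId + 1L
    }
    active <- if (length(newActive)) do.call(rbind, newActive) else
      data.frame(track_id = integer(0), row = numeric(0), col = numeric(0))
    if (nrow(active)) {
      out[[f]] <- emit(f, active$track_id, active$row, active$col)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Radial migration velocity of tracks
#'
#' Velocity is the net radial displacement between the first and last
#' track point divided by the elapsed time, in micrometres per hour,
#' positive toward the pial surface whatever the slice orientation
#' (\code{radialUp}) is.  Purely lateral motion therefore scores zero.
#' \code{mode = "regression"} instead fits a least-squares line of radial
#' coordinate against time and reports its slope.  Single-point tracks
#' are excluded with a warning.
#'
#' @param tracks data.frame from \code{\link{linkTracks}}.
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param pixelSizeUm micrometres per pixel.
#' @param mode "endpoint" (default) or "regression".
#' @return data.frame (track_id, n_points, duration_h, v_um_per_h).
#' @export
radialVelocity <- function(tracks, annotation, pixelSizeUm,
                           mode = c("endpoint", "regression")) {
  mode <- match.arg(mode)
  ids <- unique(tracks$track_id)
  res <- lapply(ids, function(id) {
    tk <- tracks[tracks$track_id == id, , drop = FALSE]
    tk <- tk[order(tk$t_h), , drop = FALSE]
    if (nrow(tk) < 2L) return(NULL)
    rad <- .radialUm(tk$row, annotation, pixelSizeUm)
    v <- if (mode == "endpoint") {
      (rad[nrow(tk)] - rad[1]) / (tk$t_h[nrow(tk)] - tk$t_h[1])
    } else {
      unname(stats::coef(stats::lm(rad ~ tk$t_h))[2])
    }
    data.frame(track_id = id, n_points = nrow(tk),
               duration_h = tk$t_h[nrow(tk)] - tk$t_h[1], v_um_per_h = v)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " single-point track(s) excluded (velocity undefined)")
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), n_points = integer(0),
                      duration_h = numeric(0), v_um_per_h = numeric(0))
  }
  out
}

#' Track a movie end to end
#'
#' Convenience composition of per-frame \code{\link{detectCells}},
#' \code{\link{linkTracks}} and \code{\link{radialVelocity}}.
#'
#' @param stack an \linkS4class{ImageStack} (label channel).
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param config configuration list, see \code{\link{defaultConfig}}.
#' @param minPoints minimum track length (points) entering velocities.
#' @return list with \code{tracks} and \code{velocities} data.frames.
#' @export
trackMovie <- function(stack, annotation, config = defaultConfig(),
                       minPoints = 5L) {
  checkAnnotation(annotation, stack)
  dets <- lapply(seq_len(nFrames(stack)), function(t) {
    detectCells(frames(stack)[, , t], config$detect_threshold,
                config$min_area)
  })
  tracks <- linkTracks(dets, config$linking_max_disp_um, pixelSize(stack),
                       frameInterval(stack), t0H = stack@t0H)
  counts <- table(tracks$track_id)
  keep <- as.integer(names(counts)[counts >= minPoints])
  vel <- radialVelocity(tracks[tracks$track_id %in% keep, , drop = FALSE],
                        annotation, pixelSize(stack),
                        mode = config$velocity_mode)
  list(tracks = tracks, velocities = vel)
}

#' Compare radial velocities between conditions
#'
#' Per-condition mean +/- SEM plus an unpaired two-tailed t-test between
#' the two groups (pooled-variance Student's test by default).
#'
#' @param groups named list of per-condition velocity vectors (two
#'   groups, each n >= 2).
#' @param variant "student" or "welch".
#' @return a \code{GroupStats} object, see \code{\link{tTestUnpaired}}.
#' @export
compareVelocity <- function(groups, variant = "student") {
  stopifnot(is.list(groups), length(groups) == 2L,
            all(vapply(groups, length, 1L) >= 2L))
  tTestUnpaired(groups[[1]], groups[[2]], variant = variant,
                names = names(groups))
}
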