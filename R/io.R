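#' Read a multi-frame grayscale TIFF as an ImageStack
#'
#' Reads every page of a grayscale TIFF into an \linkS4class{ImageStack}.
#' Pages must be single-channel and share one shape; frames are kept in
#' storage order.  Stored sample values (TIFF convention: fractions of
#' full scale) are converted to camera counts by multiplying with 65535
#' and then divided by \code{scale}, the inverse of the convention used by
#' \code{\link{writeStack}}.
#'
#' The acquisition frame interval is required metadata: it is not encoded
#' in plain TIFF and is never guessed.
#'
#' @param path path to a readable multi-frame grayscale TIFF.
#' @param frameIntervalH hours per frame (> 0).
#' @param pixelSizeUm micrometres per pixel (> 0).
#' @param t0H acquisition-start offset in hours.
#' @param scale intensity scale used at write time (counts are divided by
#'   it on read).
#' @return an \linkS4class{ImageStack}.
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, frameIntervalH, pixelSizeUm, t0H = 0, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty stack: ", path)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L) {
      stop("page ", i, " is multi-channel; expected grayscale")
    }
    if (!identical(dim(pages[[i]]), dim(pages[[1]]))) {
      stop("page ", i, " shape (", paste(dim(pages[[i]]), collapse = "x"),
           ") differs from page 1 (", paste(dim(pages[[1]]), collapse = "x"), ")")
    }
  }
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dim(pages[[1]]), length(pages)))
  arr <- arr * 65535 / scale
  if (anyNA(arr)) stop("stack contains NA/NaN intensities")
  if (any(arr < 0)) stop("stack contains negative intensities")
  ImageStack(arr, frameIntervalH = frameIntervalH,
             pixelSizeUm = pixelSizeUm, t0H = t0H)
}

#' Write an ImageStack as a multi-frame 16-bit grayscale TIFF
#'
#' Intensities are multiplied by \code{scale}, quantized to 16-bit counts
#' and written one page per frame.  \code{scale * max(intensity)} must not
#' exceed 65535.  With integer-valued intensities and \code{scale = 1} the
#' write/read cycle is lossless and repeated writes are byte-identical.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output path.
#' @param scale counts per intensity unit (default 1).
#' @param compression "none" (default) or "deflate".
#' @return invisibly \code{path}.
#' @export
writeStack <- function(stack, path, scale = 1, compression = "none") {
  v <- frames(stack) * scale / 65535
  if (max(v) > 1) {
    stop("intensity ", max(frames(stack)), " exceeds 16-bit range at scale ",
         scale)
  }
  pages <- lapply(seq_len(nFrames(stack)), function(t) v[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = compression)
  invisible(path)
}

#' Maximum-intensity projection of a z-stack movie
#'
#' Collapses the z dimension of a (row, col, z, time) array by the
#' per-pixel maximum, producing the 2-D frames the rest of the pipeline
#' consumes (acquisitions are assumed to be 10-15 z-planes which are
#' projected before analysis).
#'
#' @param zstack numeric 4-D array (row, col, z, time), z >= 1.
#' @param frameIntervalH hours per frame.
#' @param pixelSizeUm micrometres per pixel.
#' @param t0H start-time offset in hours.
#' @return an \linkS4class{ImageStack} with
#'   \code{out[r, c, t] = max_z zstack[r, c, z, t]}.
#' @export
maxIntensityProject <- function(zstack, frameIntervalH, pixelSizeUm, t0H = 0) {
  d <- dim(zstack)
  if (length(d) != 4L) stop("zstack must be 4-D (row, col, z, time)")
  if (d[3] < 1L) stop("z dimension must be >= 1")
  out <- array(zstack[, , 1L, ], dim = d[c(1, 2, 4)])
  if (d[3] > 1L) {
    for (z in 2:d[3]) out <- pmax(out, array(zstack[, , z, ], dim = d[c(1, 2, 4)]))
  }
  ImageStack(out, frameIntervalH = frameIntervalH,
             pixelSizeUm = pixelSizeUm, t0H = t0H)
}

#' Read a layer annotation from JSON or YAML
#'
#' The file must provide the keys \code{pial_row}, \code{ventricular_row},
#' \code{sp_center_row} and \code{radial_up}; missing or non-scalar fields
#' are reported together in the error.  Validity (SP centre strictly
#' between the boundaries, orientation consistent) is enforced by the
#' \linkS4class{LayerAnnotation} class.
#'
#' @param path path to a .json, .yaml or .yml file.
#' @return a \linkS4class{LayerAnnotation}.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  req <- c("pial_row", "ventricular_row", "sp_center_row", "radial_up")
  bad <- req[!vapply(req, function(k) {
    length(x[[k]]) == 1L && !is.na(x[[k]])
  }, logical(1))]
  if (length(bad)) {
    stop("annotation schema violation; missing/invalid fields: ",
         paste(bad, collapse = ", "))
  }
  LayerAnnotation(pialRow = x$pial_row, ventricularRow = x$ventricular_row,
                  spCenterRow = x$sp_center_row,
                  radialUp = isTRUE(as.logical(x$radial_up)))
}

#' Write a layer annotation to JSON or YAML
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param path output path; format chosen by extension (.json vs .yaml/.yml).
#' @return invisibly \code{path}.
#' @export
writeAnnotation <- function(annotation, path) {
  x <- list(pial_row = annotation@pialRow,
            ventricular_row = annotation@ventricularRow,
            sp_center_row = annotation@spCenterRow,
            radial_up = annotation@radialUp)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Write / read a rectangular results table as CSV
#'
#' Thin wrappers around \code{utils::write.csv}/\code{read.csv} fixing the
#' package conventions: header, no row names, full double precision.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return \code{writeResults}: invisibly \code{path};
#'   \code{readResults}: a data.frame.
#' @export
writeResults <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML
#'
#' Returns the analysis configuration used by the composed pipelines,
#' filling unstated fields from \code{\link{defaultConfig}}.  Recognized
#' keys (snake_case in the file) mirror the arguments of the individual
#' operations: \code{grid_cols}, \code{grid_rows}, \code{low_band},
#' \code{high_band}, \code{exclude_initial_h}, \code{sp_half_rows},
#' \code{n_bins}, \code{spike_correction}, \code{spectrum_type},
#' \code{include_sp_center}, \code{t_test_variant}, \code{velocity_mode},
#' \code{linking_max_disp_um}, \code{detect_threshold}, \code{min_area},
#' \code{min_neurite_px}, \code{min_soma_radius_px}, \code{seed}.
#'
#' @param path path to a YAML file (optional; NULL gives the defaults).
#' @return a named list of configuration values.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(x)] <- x
  validateConfig(cfg)
}

#' Default run configuration
#'
#' The printed analysis constants of the emulated study: a 16 x 14 grid,
#' low band bins [2, 30], high band bins [30, 75], first 4.5 h excluded,
#' four SP grid rows on each side of the SP centre, 5 laminar bins,
#' broadband spike correction, pooled-variance t-tests.
#'
#' @return named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    grid_cols = 16L,
    grid_rows = 14L,
    low_band = c(2L, 30L),
    high_band = c(30L, 75L),
    exclude_initial_h = 4.5,
    sp_half_rows = 4L,
    n_bins = 5L,
    spike_correction = "broadband_subtract",
    spectrum_type = "magnitude",
    include_sp_center = FALSE,
    t_test_variant = "student",
    velocity_mode = "endpoint",
    linking_max_disp_um = 15,
    detect_threshold = 20,
    min_area = 5L,
    min_neurite_px = 4,
    min_soma_radius_px = 2.5,
    seed = 1L
  )
}

#' @rdname readRunConfig
#' @param cfg a configuration list.
#' @export
validateConfig <- function(cfg) {
  stopifnot(cfg$grid_cols >= 1L, cfg$grid_rows >= 1L, cfg$n_bins >= 2L)
  for (b in list(cfg$low_band, cfg$high_band)) {
    if (length(b) != 2L || b[1] > b[2] || b[1] < 0) {
      stop("band ranges must be non-empty increasing pairs of bin indices")
    }
  }
  if (!cfg$spike_correction %in% c("broadband_subtract", "mask", "none")) {
    stop("spike_correction must be broadband_subtract, mask or none")
  }
  if (!cfg$spectrum_type %in% c("magnitude", "power")) {
    stop("spectrum_type must be magnitude or power")
  }
  if (!cfg$t_test_variant %in% c("student", "welch")) {
    stop("t_test_variant must be student or welch")
  }
  if (!cfg$velocity_mode %in% c("endpoint", "regression")) {
    stop("velocity_mode must be endpoint or regression")
  }
  cfg
}
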