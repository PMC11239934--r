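#' Number of frames in a stack or grid series
#' @param x an \linkS4class{ImageStack} or \linkS4class{GridSeries}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame-start timestamps in hours
#' @param x an \linkS4class{ImageStack} or \linkS4class{GridSeries}.
#' @return numeric vector of strictly increasing frame-start times (h).
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Intensity array of a stack
#' @param x an \linkS4class{ImageStack}.
#' @return numeric array (row, col, time).
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Pixel size in micrometres
#' @param x an \linkS4class{ImageStack}.
#' @return micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Frame interval in hours
#' @param x an \linkS4class{ImageStack}.
#' @return hours per frame.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname nFrames
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3])
#' @rdname nFrames
setMethod("nFrames", "GridSeries", function(x) dim(x@values)[3])

#' @rdname frameTimes
setMethod("frameTimes", "ImageStack", function(x) {
  x@t0H + (seq_len(nFrames(x)) - 1L) * x@frameIntervalH
})
#' @rdname frameTimes
setMethod("frameTimes", "GridSeries", function(x) x@timestamps)

#' @rdname frames
setMethod("frames", "ImageStack", function(x) x@frames)

#' @rdname pixelSize
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeUm)

#' @rdname frameInterval
setMethod("frameInterval", "ImageStack", function(x) x@frameIntervalH)

#' Spatial dimensions (rows, cols) of a stack
#' @param x an \linkS4class{ImageStack}.
#' @return integer (rows, cols).
#' @export
frameDim <- function(x) dim(x@frames)[1:2]

#' Check that an annotation is consistent with a stack
#'
#' Verifies that all annotated rows fall inside the image height of
#' \code{stack}.  Called by every operation that binds a
#' \linkS4class{LayerAnnotation} to pixel data.
#'
#' @param annotation a \linkS4class{LayerAnnotation}.
#' @param stack an \linkS4class{ImageStack} (or anything with frames).
#' @return invisibly TRUE; stops on inconsistency.
#' @export
checkAnnotation <- function(annotation, stack) {
  h <- frameDim(stack)[1]
  rows <- c(annotation@pialRow, annotation@ventricularRow,
            annotation@spCenterRow)
  if (any(rows < 1 | rows > h)) {
    stop("annotation rows [", paste(signif(rows, 6), collapse = ", "),
         "] fall outside image height ", h)
  }
  invisible(TRUE)
}
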