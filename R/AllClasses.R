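#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib thermotrack, .registration = TRUE
NULL

#' thermotrack: multi-mouse tracking and behaviour classification in thermal video
#'
#' Pipeline for top-view thermal recordings of group-housed mice: foreground
#' extraction by CDF thresholding, touching-body separation with an
#' EM-iterated seeded watershed, identity preservation by greedy distance
#' matching with Kolmogorov-Smirnov heat-signature recovery, 13-measurement
#' pair features, and a Temporal Random Forest producing a per-frame,
#' per-mouse ethogram.
#'
#' Conventions used throughout: frames are numeric matrices with
#' \code{nrow = height} (y) and \code{ncol = width} (x), holding temperature
#' in abstract linear units (monotone in degrees Celsius; the camera
#' calibration is irrelevant to every algorithm, which are all threshold or
#' distribution based). Coordinates are 0-based pixel centres with
#' \code{x} = column and \code{y} = row; frame indices are 0-based.
#'
#' @name thermotrack-package
#' @aliases thermotrack
"_PACKAGE"

#' ThermalVideo: a stack of single-channel thermal frames
#'
#' Frames are exposed through an accessor function so that large synthetic
#' videos can be rendered lazily, frame by frame, instead of being held in
#' memory. All frames share dimensions; indices are 0-based and contiguous.
#'
#' @slot nframes number of frames.
#' @slot dim integer \code{c(height, width)} in pixels.
#' @slot period seconds per frame (1/fps).
#' @slot frameFun function taking a 0-based frame index and returning the
#'   frame as a numeric matrix in temperature units.
#' @exportClass ThermalVideo
setClass("ThermalVideo",
  representation(nframes = "integer", dim = "integer", period = "numeric",
                 frameFun = "function"),
  validity = function(object) {
    if (length(object@nframes) != 1L || object@nframes < 1L)
      return("a ThermalVideo must contain at least one frame")
    if (length(object@dim) != 2L || any(object@dim < 1L))
      return("dim must be c(height, width), both positive")
    if (length(object@period) != 1L || !is.finite(object@period) ||
        object@period <= 0)
      return("period must be a positive number of seconds per frame")
    TRUE
  })

#' Construct a ThermalVideo from a list of frames
#'
#' @param frames list of numeric matrices, all with identical dimensions and
#'   finite values.
#' @param period seconds per frame; default 1/30 (30 fps).
#' @return A \linkS4class{ThermalVideo}.
#' @examples
#' v <- thermalVideo(list(matrix(20, 4, 5), matrix(21, 4, 5)))
#' nFrames(v)
#' @export
thermalVideo <- function(frames, period = 1 / 30) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("thermotrack_empty_video: no frames supplied")
  dims <- vapply(frames, function(f) dim(f), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("thermotrack_dim_mismatch: frames differ in dimensions")
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1))))
    stop("all frame values must be finite")
  new("ThermalVideo", nframes = length(frames), dim = dims[, 1],
      period = period,
      frameFun = local({
        fr <- frames
        function(t) fr[[t + 1L]]
      }))
}

#' Construct a lazily rendered ThermalVideo
#'
#' @param nframes number of frames.
#' @param dim integer \code{c(height, width)}.
#' @param frameFun function mapping a 0-based frame index to a matrix.
#' @param period seconds per frame.
#' @return A \linkS4class{ThermalVideo}.
#' @export
lazyThermalVideo <- function(nframes, dim, frameFun, period = 1 / 30) {
  new("ThermalVideo", nframes = as.integer(nframes), dim = as.integer(dim),
      period = period, frameFun = frameFun)
}

#' @describeIn thermalVideo number of frames.
#' @param x a \code{ThermalVideo}.
#' @export
nFrames <- function(x) x@nframes

#' @describeIn thermalVideo frame dimensions, \code{c(height, width)}.
#' @export
frameDim <- function(x) x@dim

#' @describeIn thermalVideo seconds per frame.
#' @export
framePeriod <- function(x) x@period

#' @describeIn thermalVideo extract frame \code{t} (0-based) as a matrix.
#' @param t 0-based frame index.
#' @export
getFrame <- function(x, t) {
  t <- as.integer(t)
  if (t < 0L || t >= x@nframes) stop("frame index out of range: ", t)
  x@frameFun(t)
}

setMethod("show", "ThermalVideo", function(object) {
  cat(sprintf("ThermalVideo: %d frames of %dx%d px, %.4g s/frame (%.3g fps)\n",
              object@nframes, object@dim[2], object@dim[1], object@period,
              1 / object@period))
})

#' MouseTracks: identified per-frame poses for all mice in a video
#'
#' One row per mouse per frame (frames skipped during re-initialisation are
#' retained with \code{flag = "reinit"} and empty keypoints, never omitted).
#' Keypoints are 0-based pixel coordinates.
#'
#' @slot data data.frame with columns \code{frame, mouse_id, nose_x, nose_y,
#'   genitals_x, genitals_y, centroid_x, centroid_y, length, flag, hu1, area,
#'   strategy}.
#' @slot nMice number of mice tracked.
#' @slot period seconds per frame.
#' @exportClass MouseTracks
setClass("MouseTracks",
  representation(data = "data.frame", nMice = "integer", period = "numeric"),
  validity = function(object) {
    need <- c("frame", "mouse_id", "nose_x", "nose_y", "genitals_x",
              "genitals_y", "centroid_x", "centroid_y", "length", "flag")
    if (!all(need %in% names(object@data)))
      return(paste("tracks data must contain columns:",
                   paste(need, collapse = ", ")))
    if (object@nMice < 1L) return("nMice must be >= 1")
    TRUE
  })

#' Build a MouseTracks object from a pose table
#'
#' @param data pose data.frame (see \linkS4class{MouseTracks}).
#' @param nMice number of mice.
#' @param period seconds per frame.
#' @return A \linkS4class{MouseTracks}.
#' @export
mouseTracks <- function(data, nMice, period = 1 / 30) {
  if (!"hu1" %in% names(data)) data$hu1 <- NA_real_
  if (!"area" %in% names(data)) data$area <- NA_real_
  if (!"strategy" %in% names(data)) data$strategy <- NA_character_
  new("MouseTracks", data = data, nMice = as.integer(nMice), period = period)
}

#' @describeIn mouseTracks the underlying pose table.
#' @param x a \code{MouseTracks}.
#' @export
poses <- function(x) x@data

#' @describeIn mouseTracks number of mice.
#' @export
trackedMice <- function(x) x@nMice

setMethod("show", "MouseTracks", function(object) {
  d <- object@data
  nfr <- length(unique(d$frame))
  ok <- sum(d$flag == "ok") / max(1L, nrow(d))
  cat(sprintf("MouseTracks: %d mice over %d frames (%.1f%% rows tracked ok)\n",
              object@nMice, nfr, 100 * ok))
})
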