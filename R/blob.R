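# Blob detection: foreground/background separation by a threshold estimated
# from the temperature CDF of an initialisation window, tail removal by
# oriented morphological openings, 8-connected component extraction, and
# correction of blob-count failures.

#' Estimate the foreground temperature threshold
#'
#' Scans candidate thresholds drawn from the empirical temperature
#' distribution of a window of \code{init_window} consecutive frames and
#' returns the smallest candidate for which every frame in the window shows
#' exactly \code{n_mice} 8-connected foreground components with a total
#' foreground area between \code{n_mice * min_mouse_area} and
#' \code{n_mice * area_upper_factor * min_mouse_area}. The window is slid
#' forward from the start of the video until the condition holds. Once
#' estimated, the threshold is used unchanged for all following frames.
#'
#' @param video a \linkS4class{ThermalVideo} (or list of frame matrices).
#' @param cfg a \code{\link{detectionConfig}}.
#' @param max_candidates cap on the candidate grid: candidates are spaced
#'   evenly over the window's temperature range, making the scan
#'   resolution-independent.
#' @return A list with \code{threshold} (temperature units), \code{window}
#'   (0-based first and last frame of the accepted window).
#' @export
estimateThreshold <- function(video, cfg, max_candidates = 512L) {
  frames <- if (is.list(video)) video else
    lapply(seq_len(nFrames(video)) - 1L, function(t) getFrame(video, t))
  nfr <- length(frames)
  W <- cfg$init_window
  if (nfr < W)
    stop("thermotrack_init_failure: fewer frames (", nfr,
         ") than init_window (", W, ")")
  loA <- cfg$n_mice * cfg$min_mouse_area
  hiA <- cfg$n_mice * cfg$area_upper_factor * cfg$min_mouse_area
  sortedVals <- vector("list", nfr)
  lastStart <- NA_integer_
  for (s in 0:(nfr - W)) {
    lastStart <- s
    idx <- (s + 1L):(s + W)
    for (i in idx) if (is.null(sortedVals[[i]]))
      sortedVals[[i]] <- sort.int(as.vector(frames[[i]]), method = "quick")
    # candidates evenly spaced over the window's temperature range (a
    # rank-based grid would skip the sparse band between the background
    # maximum and the body minimum, where the feasible thresholds live)
    lo <- min(vapply(idx, function(i) sortedVals[[i]][1L], numeric(1)))
    hi <- max(vapply(idx, function(i) {
      v <- sortedVals[[i]]; v[length(v)]
    }, numeric(1)))
    pool <- seq(lo, hi, length.out = max_candidates + 2L)
    pool <- pool[-c(1L, length(pool))]
    for (tau in pool) {
      ok <- TRUE
      for (i in idx) {
        v <- sortedVals[[i]]
        area <- length(v) - findInterval(tau, v)  # pixels strictly above tau
        if (area < loA || area > hiA) { ok <- FALSE; break }
        ncomp <- max(cpp_label8(frames[[i]] > tau))
        if (ncomp != cfg$n_mice) { ok <- FALSE; break }
      }
      if (ok)
        return(list(threshold = tau, window = c(s, s + W - 1L)))
    }
  }
  stop("thermotrack_init_failure: no window satisfied the threshold ",
       "condition (last window tried started at frame ", lastStart, ")")
}

lineBrushes <- function(len) {
  lapply(c(0, 45, 90), function(ang)
    EBImage::makeBrush(len, shape = "line", angle = ang))
}

#' Extract the foreground mask of a frame
#'
#' Thresholds the frame and removes thin structures (most importantly the
#' tails, which frequently disappear from thermal video) by a morphological
#' opening: a pixel stays foreground iff it survives the opening with at
#' least one of three linear structuring elements of length
#' \code{opening_length} rotated at 0, 45 and 90 degrees.
#'
#' @param frame numeric temperature matrix.
#' @param threshold temperature threshold (see \code{\link{estimateThreshold}};
#'   a list with a \code{threshold} element is also accepted).
#' @param cfg a \code{\link{detectionConfig}} (only \code{opening_length} is
#'   used).
#' @return A list of class \code{foregroundMask} with \code{mask} (logical
#'   matrix) and \code{threshold} (the value used).
#' @export
segmentForeground <- function(frame, threshold, cfg = detectionConfig(1)) {
  if (is.list(threshold)) threshold <- threshold$threshold
  stopifnot(is.finite(threshold))
  raw <- (frame > threshold) * 1
  opened <- Reduce(`|`, lapply(lineBrushes(cfg$opening_length), function(k)
    EBImage::opening(raw, k) > 0.5))
  structure(list(mask = opened, threshold = threshold),
            class = "foregroundMask")
}

asMask <- function(x) if (inherits(x, "foregroundMask")) x$mask else x

#' Extract blobs from a foreground mask
#'
#' Blobs are the 8-connected components of the mask, returned sorted by
#' decreasing area. Centroids are first-order moments in 0-based (x, y)
#' pixel coordinates.
#'
#' @param mask a \code{foregroundMask} or logical matrix.
#' @return A list of blobs, each a list with \code{pixels} (linear indices
#'   into the frame matrix), \code{area}, \code{centroid} and \code{bbox}
#'   (\code{c(x0, y0, x1, y1)}).
#' @export
extractBlobs <- function(mask) {
  m <- asMask(mask)
  lab <- cpp_label8(m)
  n <- max(lab)
  if (n == 0L) return(list())
  nr <- nrow(m)
  blobs <- lapply(seq_len(n), function(i) {
    px <- which(lab == i)
    xy <- linToXY(px, nr)
    list(pixels = px, area = length(px),
         centroid = c(mean(xy[, 1]), mean(xy[, 2])),
         bbox = c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2])))
  })
  blobs[order(vapply(blobs, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Reconcile the blob count with the expected number of mice
#'
#' Components far too small to be a mouse (area below
#' \code{min_blob_frac * min_mouse_area}; typically residual tail or
#' reflection specks) are unfeasible structures and are removed first. If
#' the mask then shows exactly \code{n_mice} blobs it is returned with
#' \code{status = "ok"}. With more blobs than mice (a mouse split into
#' fragments by thresholding) the mask is iteratively dilated with a 3x3
#' element, up to \code{max_dilations} times, until the counts agree;
#' failing that, the frame is handed back for re-initialisation
#' (\code{status = "reinit"}). With fewer blobs than mice (mice in contact),
#' the mask is left unchanged and deferred to the temporal watershed
#' (\code{status = "merged_for_watershed"}).
#'
#' @param mask a \code{foregroundMask} or logical matrix.
#' @param cfg a \code{\link{detectionConfig}}.
#' @param min_blob_frac fraction of \code{min_mouse_area} below which a
#'   component is discarded as unfeasible.
#' @return A list with \code{mask} (logical matrix), \code{status} and
#'   \code{n_blobs}.
#' @export
reconcileBlobCount <- function(mask, cfg, min_blob_frac = 0.25) {
  m <- asMask(mask)
  lab <- cpp_label8(m)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    small <- which(sizes < min_blob_frac * cfg$min_mouse_area)
    if (length(small)) m[lab %in% small] <- FALSE
  }
  n <- max(cpp_label8(m))
  if (n == cfg$n_mice)
    return(list(mask = m, status = "ok", n_blobs = n))
  if (n < cfg$n_mice)
    return(list(mask = m, status = "merged_for_watershed", n_blobs = n))
  box <- EBImage::makeBrush(3, "box")
  cur <- m
  for (i in seq_len(cfg$max_dilations)) {
    cur <- EBImage::dilate(cur * 1, box) > 0.5
    n <- max(cpp_label8(cur))
    if (n <= cfg$n_mice)
      return(list(mask = cur,
                  status = if (n == cfg$n_mice) "ok"
                           else "merged_for_watershed",
                  n_blobs = n))
  }
  list(mask = m, status = "reinit", n_blobs = n)
}
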