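# The 13-measurement spatio-temporal feature vector for every ordered
# (reference, target) mouse pair: four keypoint distances + nearest-body
# distance (relative position), first Hu moment + area of the reference
# (shape/attitude), and centroid displacements at six signed time offsets
# (multi-scale movement).

#' Default time offsets of the movement features
#'
#' Six signed frame offsets, symmetric multi-scale over past and future.
#'
#' @return Integer vector \code{c(-15, -5, -1, 1, 5, 15)}.
#' @export
defaultOffsets <- function() c(-15L, -5L, -1L, 1L, 5L, 15L)

offsetNames <- function(offsets) {
  paste0("disp_", ifelse(offsets < 0, paste0("m", -offsets),
                         paste0("p", offsets)))
}

#' Feature column names
#'
#' @param offsets signed frame offsets of the movement features.
#' @return Character vector of the 13 feature column names, in the fixed
#'   order used by \code{\link{buildPairFeatures}}.
#' @export
featureNames <- function(offsets = defaultOffsets()) {
  c("head2head", "head2body", "head2genitals", "genitals2genitals",
    "body2body", "hu1", "area", offsetNames(offsets))
}

#' Relative-position features of an ordered pair
#'
#' head2head, head2body, head2genitals and genitals2genitals are keypoint
#' distances from the reference to the target; body2body is the centroid
#' distance from the reference to its nearest conspecific (which need not be
#' the target).
#'
#' @param ref,target single-row pose data.frames sharing a frame.
#' @param allPoses pose data.frame of every mouse at that frame.
#' @return Named numeric vector of the five distances.
#' @export
relativePositionFeatures <- function(ref, target, allPoses) {
  d2 <- function(ax, ay, bx, by) sqrt((ax - bx)^2 + (ay - by)^2)
  others <- allPoses[allPoses$mouse_id != ref$mouse_id, , drop = FALSE]
  c(head2head = d2(ref$nose_x, ref$nose_y, target$nose_x, target$nose_y),
    head2body = d2(ref$nose_x, ref$nose_y, target$centroid_x,
                   target$centroid_y),
    head2genitals = d2(ref$nose_x, ref$nose_y, target$genitals_x,
                       target$genitals_y),
    genitals2genitals = d2(ref$genitals_x, ref$genitals_y,
                           target$genitals_x, target$genitals_y),
    body2body = min(d2(ref$centroid_x, ref$centroid_y, others$centroid_x,
                       others$centroid_y)))
}

#' Shape features of the reference mouse
#'
#' @param shape logical matrix or linear pixel-index vector of the mouse's
#'   body mask.
#' @param nr number of matrix rows (needed when \code{shape} is an index
#'   vector).
#' @return Named vector \code{c(hu1, area)}: first Hu moment
#'   (eta20 + eta02 of the normalised central moments) and pixel count.
#' @export
shapeFeatures <- function(shape, nr = nrow(shape)) {
  px <- if (is.matrix(shape)) which(shape) else shape
  if (length(px) == 0L) stop("empty shape")
  mm <- shapeMoments(px, nr)
  c(hu1 = mm$hu1, area = mm$area)
}

#' Movement features of the reference mouse
#'
#' Euclidean distances between the centroid at frame \code{t} and the
#' centroids at \code{t + offset} for each signed offset. Offsets reaching
#' beyond the track are clamped to the first/last available frame, so every
#' frame stays classifiable.
#'
#' @param track two-column matrix of centroid (x, y) per frame, ordered.
#' @param t 1-based row index of the current frame within \code{track}.
#' @param offsets signed frame offsets.
#' @return Numeric vector of displacements, one per offset.
#' @export
movementFeatures <- function(track, t, offsets = defaultOffsets()) {
  j <- clampNum(t + offsets, 1L, nrow(track))
  sqrt((track[j, 1] - track[t, 1])^2 + (track[j, 2] - track[t, 2])^2)
}

#' Build the pair-feature table of a tracked video
#'
#' One row per ordered mouse pair per valid frame (rows from frames flagged
#' \code{reinit}/\code{mistrack} are excluded). Movement offsets are indexed
#' by frame number and redirected to the nearest valid frame when they land
#' on an excluded one.
#'
#' @param tracks a \linkS4class{MouseTracks} (or its pose data.frame).
#' @param offsets signed frame offsets of the movement features.
#' @return A data.frame with columns \code{frame, ref_id, target_id} and the
#'   13 features of \code{\link{featureNames}}.
#' @export
buildPairFeatures <- function(tracks, offsets = defaultOffsets()) {
  d <- if (is(tracks, "MouseTracks")) poses(tracks) else tracks
  ids <- sort(unique(d$mouse_id))
  m <- length(ids)
  if (m < 2L) stop("pair features require at least two mice")
  ok <- d[d$flag == "ok", ]
  validFrames <- sort(unique(ok$frame))
  nv <- length(validFrames)
  # per-mouse keypoint tables aligned on the valid frames
  perMouse <- lapply(ids, function(id) {
    dm <- ok[ok$mouse_id == id, ]
    dm[match(validFrames, dm$frame), ]
  })
  names(perMouse) <- as.character(ids)
  # nearest-conspecific centroid distance per reference mouse per frame
  cenD <- function(i, j)
    sqrt((perMouse[[i]]$centroid_x - perMouse[[j]]$centroid_x)^2 +
         (perMouse[[i]]$centroid_y - perMouse[[j]]$centroid_y)^2)
  body2body <- lapply(seq_len(m), function(ri) {
    do.call(pmin, lapply(setdiff(seq_len(m), ri), function(oi) cenD(ri, oi)))
  })
  # clamped frame-offset indices into the valid-frame sequence
  offIdx <- lapply(offsets, function(o) clampNum(seq_len(nv) + o, 1L, nv))
  onames <- offsetNames(offsets)
  out <- vector("list", m * (m - 1L))
  k <- 0L
  for (ri in seq_len(m)) {
    pr <- perMouse[[ri]]
    mv <- vapply(offIdx, function(j)
      sqrt((pr$centroid_x[j] - pr$centroid_x)^2 +
           (pr$centroid_y[j] - pr$centroid_y)^2), numeric(nv))
    if (nv == 1L) mv <- matrix(mv, 1L)
    colnames(mv) <- onames
    for (ti in seq_len(m)) {
      if (ti == ri) next
      pt <- perMouse[[ti]]
      k <- k + 1L
      out[[k]] <- data.frame(
        frame = validFrames, ref_id = ids[ri], target_id = ids[ti],
        head2head = sqrt((pr$nose_x - pt$nose_x)^2 +
                         (pr$nose_y - pt$nose_y)^2),
        head2body = sqrt((pr$nose_x - pt$centroid_x)^2 +
                         (pr$nose_y - pt$centroid_y)^2),
        head2genitals = sqrt((pr$nose_x - pt$genitals_x)^2 +
                             (pr$nose_y - pt$genitals_y)^2),
        genitals2genitals = sqrt((pr$genitals_x - pt$genitals_x)^2 +
                                 (pr$genitals_y - pt$genitals_y)^2),
        body2body = body2body[[ri]],
        hu1 = pr$hu1, area = pr$area, mv)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$ref_id, res$target_id), ]
  rownames(res) <- NULL
  res
}

#' Write / read a pair-feature table
#'
#' CSV with the fixed 16-column header \code{frame, ref_id, target_id}
#' followed by the 13 feature columns.
#'
#' @param features a feature data.frame from \code{\link{buildPairFeatures}}.
#' @param path CSV path.
#' @return \code{path} invisibly / the feature data.frame.
#' @export
writePairFeatures <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairFeatures
#' @export
readPairFeatures <- function(path) {
  if (!file.exists(path)) stop("thermotrack_missing_path: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
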