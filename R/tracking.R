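# Full tracking pipeline: per frame, foreground extraction -> blob
# reconciliation -> temporal watershed -> identity matching (greedy distance
# matching, overridden by heat-signature matching while the Hu-moment sanity
# check reports a global misdetection).

orientTo <- function(pose, prev) {
  e1 <- c(pose$nose_x, pose$nose_y)
  e2 <- c(pose$genitals_x, pose$genitals_y)
  keepCost <- sum((e1 - c(prev$nose_x, prev$nose_y))^2) +
    sum((e2 - c(prev$genitals_x, prev$genitals_y))^2)
  swapCost <- sum((e2 - c(prev$nose_x, prev$nose_y))^2) +
    sum((e1 - c(prev$genitals_x, prev$genitals_y))^2)
  if (swapCost < keepCost) swapNoseGenitals(pose) else pose
}

emptyPoseRows <- function(t, n_mice, flag, strategy) {
  data.frame(frame = t, mouse_id = seq_len(n_mice), nose_x = NA_real_,
             nose_y = NA_real_, genitals_x = NA_real_, genitals_y = NA_real_,
             centroid_x = NA_real_, centroid_y = NA_real_,
             length = NA_real_, flag = flag, hu1 = NA_real_,
             area = NA_real_, strategy = strategy, converged = NA)
}

#' Track all mice through a thermal video
#'
#' Orchestrates the tracking pipeline. The foreground threshold is estimated
#' once from an initialisation window and then kept fixed. The first tracked
#' frame requires all mice disjoint (poses bootstrapped from blob moments);
#' frames consumed before or during (re-)initialisation are emitted with
#' \code{flag = "reinit"} and excluded from downstream feature extraction.
#' Identity matching is distance-based by default; while the shape sanity
#' check flags two or more mice in the same frame, the Kolmogorov-Smirnov
#' heat-signature assignment overrides the distance permutation
#' (\code{policy = "combined"}). \code{policy = "distance"} and
#' \code{policy = "heat"} force a single strategy throughout (heat falls
#' back to distance while any signature buffer is still empty).
#'
#' @param video a \linkS4class{ThermalVideo}.
#' @param n_mice number of mice in the arena.
#' @param det a \code{\link{detectionConfig}}; default
#'   \code{detectionConfig(n_mice)}.
#' @param ws a \code{\link{watershedConfig}}.
#' @param mc a \code{\link{matchingConfig}}.
#' @param policy identity-matching policy: \code{"combined"} (default),
#'   \code{"distance"} or \code{"heat"}.
#' @param threshold optional precomputed foreground threshold (skips
#'   estimation).
#' @return A \linkS4class{MouseTracks}. The estimated threshold is attached
#'   as attribute \code{"threshold"} of the pose table.
#' @export
trackMice <- function(video, n_mice, det = NULL, ws = watershedConfig(),
                      mc = matchingConfig(),
                      policy = c("combined", "distance", "heat"),
                      threshold = NULL) {
  policy <- match.arg(policy)
  if (is.null(det)) det <- detectionConfig(n_mice)
  stopifnot(det$n_mice == n_mice)
  if (is.null(threshold)) threshold <- estimateThreshold(video, det)
  tau <- if (is.list(threshold)) threshold$threshold else threshold
  nfr <- nFrames(video)
  dm <- frameDim(video)

  state <- NULL          # current pose data.frame, rows ordered by mouse_id
  lastPoses <- NULL      # last accepted poses (for re-identification)
  lenHist <- rep(list(numeric(0)), n_mice)
  signs <- rep(list(numeric(0)), n_mice)
  sigs <- heatSignatures(n_mice, mc$buffer_frames)
  hu1rec <- numeric(0)
  model <- NULL
  lastFitN <- 0L
  rows <- vector("list", nfr)

  sigReady <- function() all(lengths(sigs$frames) > 0L)

  for (t in 0:(nfr - 1L)) {
    fr <- getFrame(video, t)
    fgObj <- segmentForeground(fr, tau, det)
    rec <- reconcileBlobCount(fgObj$mask, det)

    if (is.null(state)) {
      boot <- NULL
      if (rec$status == "ok")
        boot <- bootstrapPoses(extractBlobs(rec$mask), dm, n_mice)
      if (is.null(boot)) {
        rows[[t + 1L]] <- emptyPoseRows(t, n_mice, "reinit", NA_character_)
        next
      }
      shapes <- poseShapes(boot)
      if (!is.null(lastPoses)) {
        # re-identify after a tracking gap
        perm <- if (sigReady())
          heatAssign(lapply(shapes, function(px) fr[px]), sigs)
        else
          greedyAssign(distanceMatrix(lastPoses, boot))
        boot <- poseSet(boot[perm, , drop = FALSE], shapes[perm])
        shapes <- poseShapes(boot)
        for (i in seq_len(n_mice))
          boot[i, ] <- orientTo(boot[i, ], lastPoses[i, ])
      }
      boot$mouse_id <- seq_len(n_mice)
      state <- boot
      signs <- rep(list(numeric(0)), n_mice)
      for (i in seq_len(n_mice))
        lenHist[[i]] <- utils::tail(c(lenHist[[i]], state$length[i]),
                                    ws$history_window)
      hu1rec <- c(hu1rec, state$hu1)
      sigs <- updateHeatSignatures(sigs, lapply(shapes, function(px) fr[px]))
      rows[[t + 1L]] <- data.frame(frame = t, state, flag = "ok",
                                   strategy = "init", converged = TRUE)
      lastPoses <- state
      next
    }

    if (rec$status == "reinit") {
      lastPoses <- state
      state <- NULL
      rows[[t + 1L]] <- emptyPoseRows(t, n_mice, "reinit", NA_character_)
      next
    }

    em <- emSegment(fr, rec$mask, state, ws, lenHist)
    cur <- em$poses
    shapes <- poseShapes(cur)
    mist <- em$mistracked
    samples <- lapply(shapes, function(px) fr[px])

    sc <- shapeSanityCheck(model, cur$hu1, mc$alpha)
    useHeat <- switch(policy, combined = sc$global, distance = FALSE,
                      heat = TRUE)
    if (useHeat && sigReady() && !any(lengths(samples) == 0L)) {
      perm <- heatAssign(samples, sigs)
      strat <- "heat"
    } else {
      perm <- greedyAssign(distanceMatrix(state, cur))
      strat <- "distance"
    }
    cur <- cur[perm, , drop = FALSE]
    shapes <- shapes[perm]
    samples <- samples[perm]
    mist <- mist[perm]
    flagsSC <- sc$flags[perm]
    cur$mouse_id <- seq_len(n_mice)

    for (i in seq_len(n_mice)) {
      cur[i, ] <- orientTo(cur[i, ], state[i, ])
      upd <- orientationVoteUpdate(signs[[i]], state[i, ], cur[i, ], ws)
      cur[i, ] <- upd$pose
      signs[[i]] <- upd$signs
    }

    accepted <- !sc$global && !any(mist)
    if (accepted) {
      hu1rec <- c(hu1rec, cur$hu1)
      sigs <- updateHeatSignatures(sigs, samples)
      nAcc <- length(hu1rec)
      if (nAcc >= mc$min_shape_history &&
          (is.null(model) || nAcc - lastFitN >= mc$refit_every)) {
        model <- fitShapeModel(hu1rec)
        lastFitN <- nAcc
      }
      for (i in seq_len(n_mice))
        lenHist[[i]] <- utils::tail(c(lenHist[[i]], cur$length[i]),
                                    ws$history_window)
      lastPoses <- cur
    }
    flag <- ifelse(mist, "mistrack", "ok")
    rows[[t + 1L]] <- data.frame(frame = t, cur, flag = flag,
                                 strategy = strat, converged = em$converged)
    state <- cur
  }

  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  attr(d, "threshold") <- tau
  mouseTracks(d, nMice = n_mice, period = framePeriod(video))
}
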