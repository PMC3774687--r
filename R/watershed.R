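# Temporal watershed: EM-iterated seeded watershed segmentation that splits
# touching mice into individual shapes using seeds propagated from the
# previous frame, plus moment-based pose extraction and movement-based
# nose/genitals orientation voting.

# pose sets are data.frames (one row per mouse) with the keypoint columns
# plus an attribute "shapes": a list of linear pixel-index vectors
poseSet <- function(df, shapes) {
  attr(df, "shapes") <- shapes
  df
}

#' Shapes attached to a pose set
#'
#' @param poses a pose data.frame as returned by \code{\link{bootstrapPoses}}
#'   or \code{\link{emSegment}}.
#' @return A list of linear pixel-index vectors, one per mouse.
#' @export
poseShapes <- function(poses) attr(poses, "shapes")

# moment analysis of a pixel set: centroid, major-axis length and direction
# (eigen-decomposition of the second-order central moment matrix), first Hu
# moment. `prevAxis` breaks the eigenvalue tie of circular shapes.
shapeMoments <- function(px, nr, prevAxis = NULL) {
  xy <- linToXY(px, nr)
  n <- length(px)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  dx <- xy[, 1] - cx; dy <- xy[, 2] - cy
  sxx <- sum(dx * dx); syy <- sum(dy * dy); sxy <- sum(dx * dy)
  hu1 <- (sxx + syy) / n^2
  # covariance with the 1/12 pixel-extent term for numerical stability of
  # the axis length on tiny shapes
  cxx <- sxx / n + 1 / 12; cyy <- syy / n + 1 / 12; cxy <- sxy / n
  tr <- cxx + cyy; dis <- sqrt(max(0, (cxx - cyy)^2 + 4 * cxy^2))
  l1 <- (tr + dis) / 2
  if (dis < 1e-9 * max(tr, 1e-12)) {
    v <- if (!is.null(prevAxis) && sum(prevAxis^2) > 0)
      prevAxis / sqrt(sum(prevAxis^2)) else c(1, 0)
  } else if (abs(cxy) > 1e-12) {
    v <- c(l1 - cyy, cxy); v <- v / sqrt(sum(v^2))
  } else {
    v <- if (cxx >= cyy) c(1, 0) else c(0, 1)
  }
  L <- 4 * sqrt(l1)
  list(centroid = c(cx, cy), L = L, axis = v, hu1 = hu1, area = n)
}

posesRowFromMoments <- function(id, mm, orient = NULL) {
  e1 <- mm$centroid + (mm$L / 2) * mm$axis
  e2 <- mm$centroid - (mm$L / 2) * mm$axis
  if (!is.null(orient)) {
    # choose the endpoint pairing closest to the previous nose/genitals
    keep <- sum((e1 - orient$nose)^2) + sum((e2 - orient$gen)^2) <=
      sum((e2 - orient$nose)^2) + sum((e1 - orient$gen)^2)
    if (!keep) { tmp <- e1; e1 <- e2; e2 <- tmp }
  } else if (e1[1] < e2[1] || (e1[1] == e2[1] && e1[2] < e2[2])) {
    tmp <- e1; e1 <- e2; e2 <- tmp  # provisional: nose gets the +x extreme
  }
  data.frame(mouse_id = id, nose_x = e1[1], nose_y = e1[2],
             genitals_x = e2[1], genitals_y = e2[2],
             centroid_x = mm$centroid[1], centroid_y = mm$centroid[2],
             length = mm$L, hu1 = mm$hu1, area = mm$area)
}

poseOrient <- function(poses, i) {
  list(nose = c(poses$nose_x[i], poses$nose_y[i]),
       gen = c(poses$genitals_x[i], poses$genitals_y[i]))
}

#' Bootstrap poses from disjoint blobs
#'
#' Estimates the initial pose of every mouse directly from the blob-detection
#' output by moment analysis of each blob's major axis. Requires all mice to
#' be disjoint (one blob per mouse); otherwise the frame must be skipped.
#' The nose/genitals orientation is provisional (the +x major-axis extreme is
#' recorded as the nose) until movement voting fixes it.
#'
#' @param blobs list of blobs from \code{\link{extractBlobs}}.
#' @param dim frame dimensions \code{c(height, width)}.
#' @param n_mice expected number of mice.
#' @return A pose data.frame with shapes attached, or \code{NULL} if the
#'   blob count disagrees with \code{n_mice} (skip-frame status).
#' @export
bootstrapPoses <- function(blobs, dim, n_mice) {
  if (length(blobs) != n_mice) return(NULL)
  nr <- dim[1]
  rows <- vector("list", n_mice)
  shapes <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    mm <- shapeMoments(blobs[[i]]$pixels, nr)
    rows[[i]] <- posesRowFromMoments(i, mm)
    shapes[[i]] <- blobs[[i]]$pixels
  }
  poseSet(do.call(rbind, rows), shapes)
}

#' Build the seed image for the seeded watershed
#'
#' Each mouse contributes a linear seed of three collinear points (nose,
#' centroid, genitals positions of the previous-frame pose, with the seed
#' span shrunk to the history-averaged major-axis length minus \code{slack}
#' and centred on the previous centroid along the previous axis). The
#' background seed is the 3x3-eroded complement of the current foreground.
#' Conflicting seed points are assigned to the mouse with the nearer
#' previous centroid.
#'
#' @param prevPoses previous-frame pose data.frame.
#' @param foreground a \code{foregroundMask} or logical matrix for the
#'   current frame.
#' @param cfg a \code{\link{watershedConfig}}.
#' @param lengthHistory optional list (per mouse) of recent major-axis
#'   lengths; defaults to each mouse's previous length.
#' @return An integer matrix: 0 = unknown, 1..M = mouse seeds,
#'   M + 1 = background seed.
#' @export
buildSeeds <- function(prevPoses, foreground, cfg = watershedConfig(),
                       lengthHistory = NULL) {
  fg <- asMask(foreground)
  nr <- nrow(fg); ncl <- ncol(fg)
  m <- nrow(prevPoses)
  seeds <- matrix(0L, nr, ncl)
  owner <- list()
  for (i in seq_len(m)) {
    hist <- if (!is.null(lengthHistory)) lengthHistory[[i]] else
      prevPoses$length[i]
    hist <- utils::tail(hist, cfg$history_window)
    span <- max(2, mean(hist) - cfg$slack)
    cen <- c(prevPoses$centroid_x[i], prevPoses$centroid_y[i])
    d <- c(prevPoses$nose_x[i] - prevPoses$genitals_x[i],
           prevPoses$nose_y[i] - prevPoses$genitals_y[i])
    nd <- sqrt(sum(d^2))
    pts <- if (nd < 1e-9) matrix(cen, 1) else {
      d <- d / nd
      rbind(cen + (span / 2) * d, cen, cen - (span / 2) * d)
    }
    px <- clampNum(round(pts[, 1]), 0, ncl - 1)
    py <- clampNum(round(pts[, 2]), 0, nr - 1)
    for (j in seq_len(nrow(pts))) {
      li <- xyToLin(px[j], py[j], nr)
      cur <- seeds[li]
      if (cur == 0L) {
        seeds[li] <- i
      } else {
        # conflict: keep the mouse whose previous centroid is nearer
        other <- c(prevPoses$centroid_x[cur], prevPoses$centroid_y[cur])
        pt <- c(px[j], py[j])
        if (sum((pt - cen)^2) < sum((pt - other)^2)) seeds[li] <- i
      }
    }
  }
  bg <- (!fg) * 1
  if (cfg$bg_erode_iters > 0) {
    box <- EBImage::makeBrush(3, "box")
    for (k in seq_len(cfg$bg_erode_iters)) {
      er <- EBImage::erode(bg, box)
      if (sum(er) < 1) break  # keep at least one background pixel
      bg <- er
    }
  }
  seeds[bg > 0.5 & seeds == 0L] <- m + 1L
  seeds
}

#' EM-iterated seeded watershed segmentation of one frame
#'
#' Alternates an expectation step — marker-controlled watershed on the
#' negated-temperature relief (warm body interiors are deep basins),
#' restricted to the foreground so the per-mouse shapes always partition it
#' exactly — with a maximization step that re-estimates each mouse's
#' centroid, major-axis length and endpoints from the current shapes.
#' Seeds for the first iteration come from the previous frame's poses
#' (\code{\link{buildSeeds}}); later iterations rebuild seeds from the
#' current pose estimates. The loop stops when the fraction of foreground
#' pixels that changed owner drops below \code{convergence_tol}, or after
#' \code{max_em_iters} iterations. When the mice are disjoint (as many blobs
#' as mice) the blobs themselves are the converged shapes.
#'
#' @param frame numeric temperature matrix.
#' @param foreground a \code{foregroundMask} or logical matrix.
#' @param prevPoses previous-frame pose data.frame (one row per mouse).
#' @param cfg a \code{\link{watershedConfig}}.
#' @param lengthHistory optional per-mouse length histories for seed
#'   construction.
#' @return A list with \code{poses} (pose data.frame with shapes attached,
#'   ordered like \code{prevPoses}), \code{iters}, \code{converged} and
#'   \code{mistracked} (logical per mouse: empty shape after watershed).
#' @export
emSegment <- function(frame, foreground, prevPoses, cfg = watershedConfig(),
                      lengthHistory = NULL) {
  fg <- asMask(foreground)
  if (!any(fg)) stop("emSegment requires a non-empty foreground")
  m <- nrow(prevPoses)
  nr <- nrow(fg)
  lab <- cpp_label8(fg)
  nblob <- max(lab)
  prevCen <- cbind(prevPoses$centroid_x, prevPoses$centroid_y)

  finishPoses <- function(shapes) {
    rows <- vector("list", m)
    mistracked <- logical(m)
    for (i in seq_len(m)) {
      if (length(shapes[[i]]) == 0L) {
        mistracked[i] <- TRUE
        rows[[i]] <- prevPoses[i, c("mouse_id", "nose_x", "nose_y",
                                    "genitals_x", "genitals_y",
                                    "centroid_x", "centroid_y", "length",
                                    "hu1", "area")]
        next
      }
      prevAxis <- c(prevPoses$nose_x[i] - prevPoses$genitals_x[i],
                    prevPoses$nose_y[i] - prevPoses$genitals_y[i])
      mm <- shapeMoments(shapes[[i]], nr, prevAxis = prevAxis)
      rows[[i]] <- posesRowFromMoments(prevPoses$mouse_id[i], mm,
                                       orient = poseOrient(prevPoses, i))
    }
    list(poses = poseSet(do.call(rbind, rows), shapes),
         mistracked = mistracked)
  }

  if (nblob == m) {
    # disjoint mice: shapes are the blobs, matched to identities by centroid
    blobCen <- t(vapply(seq_len(m), function(b) {
      xy <- linToXY(which(lab == b), nr)
      c(mean(xy[, 1]), mean(xy[, 2]))
    }, numeric(2)))
    costs <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j)
      sqrt(sum((prevCen[i, ] - blobCen[j, ])^2))))
    perm <- greedyAssign(costs)
    shapes <- lapply(seq_len(m), function(i) which(lab == perm[i]))
    fin <- finishPoses(shapes)
    return(list(poses = fin$poses, iters = 1L, converged = TRUE,
                mistracked = fin$mistracked))
  }

  relief <- -frame
  curPoses <- prevPoses
  prevOwner <- NULL
  iters <- 0L
  converged <- FALSE
  nfg <- sum(fg)
  shapes <- vector("list", m)
  repeat {
    iters <- iters + 1L
    seeds <- buildSeeds(curPoses, fg,
                        cfg = if (iters == 1L) cfg else
                          utils::modifyList(cfg, list(bg_erode_iters = 0L)),
                        lengthHistory = if (iters == 1L) lengthHistory
                                        else NULL)
    seeds[seeds == m + 1L] <- 0L  # flooding is restricted to the foreground
    # rescue mice whose seed points all fell outside the foreground
    for (i in seq_len(m)) {
      if (!any(seeds == i & fg)) {
        cand <- which(fg & seeds == 0L)
        if (length(cand)) {
          xy <- linToXY(cand, nr)
          d2 <- (xy[, 1] - curPoses$centroid_x[i])^2 +
            (xy[, 2] - curPoses$centroid_y[i])^2
          if (min(d2) <= (2 * cfg$slack + curPoses$length[i] / 2)^2)
            seeds[cand[which.min(d2)]] <- i
        }
      }
    }
    owner <- cpp_seeded_flood(relief, seeds, fg)
    # orphan components (no seed reached them): nearest-centroid ownership
    orphan <- fg & owner == 0L
    if (any(orphan)) {
      olab <- cpp_label8(orphan)
      for (b in seq_len(max(olab))) {
        px <- which(olab == b)
        xy <- linToXY(px, nr)
        oc <- c(mean(xy[, 1]), mean(xy[, 2]))
        d2 <- (curPoses$centroid_x - oc[1])^2 +
          (curPoses$centroid_y - oc[2])^2
        owner[px] <- which.min(d2)
      }
    }
    changed <- if (is.null(prevOwner)) 1 else
      sum(owner[fg] != prevOwner[fg]) / nfg
    prevOwner <- owner
    shapes <- lapply(seq_len(m), function(i) which(owner == i & fg))
    fin <- finishPoses(shapes)
    curPoses <- fin$poses
    if (changed < cfg$convergence_tol) { converged <- TRUE; break }
    if (iters >= cfg$max_em_iters) break
  }
  fin <- finishPoses(shapes)
  list(poses = fin$poses, iters = iters, converged = converged,
       mistracked = fin$mistracked)
}

#' Correct the nose/genitals orientation by movement voting
#'
#' Pools the sign of the inner product between the frame-to-frame movement
#' vector and the body direction (nose minus genitals) over the last
#' \code{vote_window} frames; frames with negligible movement contribute
#' zero. A negative vote means the body has been tracked back-to-front, and
#' the nose and genitals of the current pose are swapped. After acting on a
#' swap the caller must discard the pose history that preceded it (those
#' rows were recorded back-to-front); the online tracker does this via
#' \code{\link{orientationVoteUpdate}}.
#'
#' @param history pose data.frame of this mouse's preceding frames (oldest
#'   first; at least one row).
#' @param current single-row pose data.frame for the current frame.
#' @param cfg a \code{\link{watershedConfig}}.
#' @return A list with \code{pose} (possibly swapped current pose),
#'   \code{swapped} and \code{vote}.
#' @export
correctOrientation <- function(history, current, cfg = watershedConfig()) {
  seqp <- rbind(history[, names(current)], current)
  n <- nrow(seqp)
  if (n < 2L) return(list(pose = current, swapped = FALSE, vote = 0))
  mv <- cbind(diff(seqp$centroid_x), diff(seqp$centroid_y))
  dir <- cbind(seqp$nose_x - seqp$genitals_x,
               seqp$nose_y - seqp$genitals_y)[-1, , drop = FALSE]
  s <- voteSigns(mv, dir, cfg$min_move)
  vote <- sum(utils::tail(s, cfg$vote_window))
  pose <- current
  if (vote < 0) pose <- swapNoseGenitals(pose)
  list(pose = pose, swapped = vote < 0, vote = vote)
}

#' Incremental orientation voting (tracker state)
#'
#' The online form of \code{\link{correctOrientation}} used by
#' \code{\link{trackMice}}: keeps the per-mouse buffer of movement/direction
#' agreement signs, appends the current frame's sign, swaps the pose when
#' the windowed vote turns negative, and clears the buffer after a swap
#' (the buffered signs predate the correction), which guarantees at most
#' one swap per inversion event.
#'
#' @param signs numeric vector, the mouse's current sign buffer.
#' @param prev,current single-row pose data.frames of the previous and
#'   current frame.
#' @param cfg a \code{\link{watershedConfig}}.
#' @return A list with \code{pose} (possibly swapped), \code{signs} (updated
#'   buffer) and \code{swapped}.
#' @export
orientationVoteUpdate <- function(signs, prev, current,
                                  cfg = watershedConfig()) {
  mv <- c(current$centroid_x - prev$centroid_x,
          current$centroid_y - prev$centroid_y)
  dir <- c(current$nose_x - current$genitals_x,
           current$nose_y - current$genitals_y)
  s <- voteSigns(matrix(mv, 1), matrix(dir, 1), cfg$min_move)
  signs <- utils::tail(c(signs, s), cfg$vote_window)
  if (sum(signs) < 0)
    list(pose = swapNoseGenitals(current), signs = numeric(0),
         swapped = TRUE)
  else
    list(pose = current, signs = signs, swapped = FALSE)
}

voteSigns <- function(mv, dir, min_move) {
  dp <- rowSums(mv * dir)
  s <- sign(dp)
  s[sqrt(rowSums(mv^2)) < min_move] <- 0
  s
}

swapNoseGenitals <- function(pose) {
  tmp <- pose[, c("nose_x", "nose_y")]
  pose[, c("nose_x", "nose_y")] <- pose[, c("genitals_x", "genitals_y")]
  pose[, c("genitals_x", "genitals_y")] <- tmp
  pose
}
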