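# Synthetic thermal-video generator. Mice are warm ellipses with thin tails
# moving over a cooler noisy background along scripted motion primitives;
# every scenario carries ground-truth poses, shape masks and per-pair
# behaviour labels, so each pipeline stage can be tested without recordings.

#' Motion primitives for scripted scenarios
#'
#' A primitive describes one mouse's trajectory over one scenario segment.
#' \code{motionStand} keeps the mouse at \code{pos} with a fixed
#' \code{heading} (radians; 0 points along +x, y grows downwards).
#' \code{motionLine} interpolates linearly from \code{from} to \code{to},
#' heading along the direction of motion unless \code{heading} is given.
#' \code{motionArc} moves along a circular arc from angle \code{a0} to
#' \code{a1} (radians) around \code{center}, heading tangential.
#'
#' @param pos,from,to,center 0-based (x, y) pixel coordinates.
#' @param heading heading in radians, or NULL for along-motion.
#' @param radius arc radius in px.
#' @param a0,a1 start and end angle of the arc.
#' @return A motion-primitive object.
#' @export
motionStand <- function(pos, heading) {
  structure(list(type = "stand", pos = pos, heading = heading),
            class = "motionPrimitive")
}

#' @rdname motionStand
#' @export
motionLine <- function(from, to, heading = NULL) {
  structure(list(type = "line", from = from, to = to, heading = heading),
            class = "motionPrimitive")
}

#' @rdname motionStand
#' @export
motionArc <- function(center, radius, a0, a1) {
  structure(list(type = "arc", center = center, radius = radius,
                 a0 = a0, a1 = a1), class = "motionPrimitive")
}

#' A scripted scenario segment
#'
#' @param start,end first and last frame of the segment (0-based, inclusive).
#' @param motions list of one motion primitive per mouse.
#' @param labels named character vector of ground-truth behaviour labels for
#'   ordered mouse pairs, names of the form \code{"1>2"} (reference >
#'   target). Required for every ordered pair when two or more mice are
#'   present.
#' @return A segment specification.
#' @export
segmentSpec <- function(start, end, motions, labels = character(0)) {
  stopifnot(end >= start)
  structure(list(start = as.integer(start), end = as.integer(end),
                 motions = motions, labels = labels), class = "segmentSpec")
}

#' Specification of a synthetic thermal-video scenario
#'
#' Defaults emulate the reference recording geometry: a 40 cm arena imaged at
#' 4 px/cm (160 px) and 30 fps, adult mice about 7 x 2.5 cm (half-axes 14 x 5
#' px) with 20 px tails, and body temperature offsets well above background
#' noise.
#'
#' @param nframes number of frames.
#' @param segments list of \code{\link{segmentSpec}} objects tiling
#'   \code{0:(nframes-1)} without gaps or overlap.
#' @param mice either the number of mice (defaults are then used) or a
#'   data.frame with columns \code{a, b} (body half-axes, px), \code{offset}
#'   (body temperature above background, units) and \code{tail} (px).
#' @param arena \code{c(width, height)} in px.
#' @param bg_mean,noise_sd background temperature mean and Gaussian noise sd
#'   (units).
#' @param px_per_cm pixel scale used only to turn the behaviour definitions'
#'   cm thresholds into px for label scripting.
#' @param period seconds per frame.
#' @param seed integer seed; scenario generation is a pure function of
#'   spec + seed.
#' @return A list of class \code{scenarioSpec}.
#' @export
scenarioSpec <- function(nframes, segments, mice = 2, arena = c(160, 160),
                         bg_mean = 20, noise_sd = 0.5, px_per_cm = 4,
                         period = 1 / 30, seed = 1) {
  if (is.numeric(mice) && length(mice) == 1L) {
    m <- as.integer(mice)
    mice <- data.frame(a = rep(14, m), b = rep(5, m),
                       offset = 5 + 1.5 * seq_len(m) - 1.5,
                       tail = rep(20, m))
  }
  stopifnot(nrow(mice) >= 1, noise_sd > 0, all(mice$offset > noise_sd),
            nframes >= 1)
  starts <- vapply(segments, `[[`, integer(1), "start")
  ends <- vapply(segments, `[[`, integer(1), "end")
  o <- order(starts)
  segments <- segments[o]; starts <- starts[o]; ends <- ends[o]
  if (starts[1] != 0L || ends[length(ends)] != nframes - 1L ||
      (length(starts) > 1L && any(starts[-1] != ends[-length(ends)] + 1L)))
    stop("segments must tile 0:(nframes-1) without overlap")
  for (s in segments) {
    if (length(s$motions) != nrow(mice))
      stop("each segment needs one motion primitive per mouse")
    if (nrow(mice) > 1L) {
      want <- orderedPairNames(nrow(mice))
      if (!all(want %in% names(s$labels)))
        stop("segment labels must cover all ordered pairs: ",
             paste(setdiff(want, names(s$labels)), collapse = ", "))
    }
  }
  structure(list(nframes = as.integer(nframes), segments = segments,
                 mice = mice, arena = as.integer(arena), bg_mean = bg_mean,
                 noise_sd = noise_sd, px_per_cm = px_per_cm, period = period,
                 seed = as.integer(seed)),
            class = "scenarioSpec")
}

orderedPairNames <- function(m) {
  g <- expand.grid(ref = seq_len(m), tgt = seq_len(m))
  g <- g[g$ref != g$tgt, ]
  paste0(g$ref, ">", g$tgt)
}

primitivePose <- function(prim, s) {
  switch(prim$type,
    stand = c(prim$pos, prim$heading),
    line = {
      p <- prim$from + s * (prim$to - prim$from)
      h <- if (!is.null(prim$heading)) prim$heading else {
        d <- prim$to - prim$from
        if (all(d == 0)) 0 else atan2(d[2], d[1])
      }
      c(p, h)
    },
    arc = {
      a <- prim$a0 + s * (prim$a1 - prim$a0)
      p <- prim$center + prim$radius * c(cos(a), sin(a))
      c(p, a + sign(prim$a1 - prim$a0) * pi / 2)
    },
    stop("unknown motion primitive: ", prim$type))
}

# evaluate RNG-dependent code under a derived seed without disturbing the
# caller's RNG stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

frameSeed <- function(seed, t) {
  as.integer((abs(as.numeric(seed)) * 100003 + as.numeric(t) * 7919 + 13) %%
               2147483629)
}

#' Generate a synthetic thermal video with ground truth
#'
#' Deterministic given \code{spec} (which carries the seed): two calls with
#' the same spec yield bit-identical frame stacks. Frames are rendered
#' lazily, so long scenarios never hold the full stack in memory.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @return A list of class \code{thermalScenario} with elements
#'   \code{video} (a \linkS4class{ThermalVideo}), \code{poses} (ground-truth
#'   keypoints per mouse per frame), \code{labels} (ground-truth behaviour
#'   label per ordered pair per frame) and \code{spec}.
#' @export
generateScenario <- function(spec) {
  nfr <- spec$nframes
  m <- nrow(spec$mice)
  traj <- array(NA_real_, c(nfr, m, 3L))  # cx, cy, heading
  labRows <- vector("list", length(spec$segments))
  for (si in seq_along(spec$segments)) {
    seg <- spec$segments[[si]]
    fr <- seg$start:seg$end
    s <- if (length(fr) == 1L) 0 else (fr - seg$start) / (seg$end - seg$start)
    for (k in seq_len(m)) {
      p <- vapply(s, function(ss) primitivePose(seg$motions[[k]], ss),
                  numeric(3))
      traj[fr + 1L, k, ] <- t(p)
    }
    if (m > 1L && length(seg$labels)) {
      pr <- strsplit(names(seg$labels), ">", fixed = TRUE)
      labRows[[si]] <- data.frame(
        frame = rep(fr, each = length(seg$labels)),
        ref_id = rep(as.integer(vapply(pr, `[`, "", 1L)), length(fr)),
        target_id = rep(as.integer(vapply(pr, `[`, "", 2L)), length(fr)),
        label = rep(unname(seg$labels), length(fr)))
    }
  }
  # feasibility: bodies must stay inside the arena
  for (k in seq_len(m)) {
    ext <- spec$mice$a[k] + 1
    if (any(traj[, k, 1] < ext) || any(traj[, k, 1] > spec$arena[1] - 1 - ext) ||
        any(traj[, k, 2] < ext) || any(traj[, k, 2] > spec$arena[2] - 1 - ext))
      stop("thermotrack_infeasible_script: mouse ", k,
           " leaves the arena")
  }
  dirs <- array(c(cos(traj[, , 3]), sin(traj[, , 3])), c(nfr, m, 2L))
  a <- spec$mice$a
  posesDf <- do.call(rbind, lapply(seq_len(m), function(k) {
    data.frame(frame = 0:(nfr - 1L), mouse_id = k,
               nose_x = traj[, k, 1] + a[k] * dirs[, k, 1],
               nose_y = traj[, k, 2] + a[k] * dirs[, k, 2],
               genitals_x = traj[, k, 1] - a[k] * dirs[, k, 1],
               genitals_y = traj[, k, 2] - a[k] * dirs[, k, 2],
               centroid_x = traj[, k, 1], centroid_y = traj[, k, 2],
               heading = traj[, k, 3], length = 2 * a[k])
  }))
  posesDf <- posesDf[order(posesDf$frame, posesDf$mouse_id), ]
  rownames(posesDf) <- NULL
  labels <- if (m > 1L) {
    ld <- do.call(rbind, labRows)
    ld <- ld[order(ld$frame, ld$ref_id, ld$target_id), ]
    rownames(ld) <- NULL
    ld
  } else data.frame(frame = integer(0), ref_id = integer(0),
                    target_id = integer(0), label = character(0))
  video <- lazyThermalVideo(
    nframes = nfr, dim = c(spec$arena[2], spec$arena[1]),
    period = spec$period,
    frameFun = local({
      sp <- spec; tr <- traj
      function(t) renderScenarioFrame(sp, tr[t + 1L, , , drop = FALSE], t)
    }))
  structure(list(video = video, poses = posesDf, labels = labels,
                 spec = spec),
            class = "thermalScenario")
}

#' @export
print.thermalScenario <- function(x, ...) {
  cat(sprintf("thermalScenario: %d mice, %d frames, arena %dx%d px, seed %d\n",
              nrow(x$spec$mice), x$spec$nframes, x$spec$arena[1],
              x$spec$arena[2], x$spec$seed))
  invisible(x)
}

# render one frame; pose is a 1 x m x 3 slice of the trajectory array
renderScenarioFrame <- function(spec, pose, t) {
  h <- spec$arena[2]; w <- spec$arena[1]
  withSeed(frameSeed(spec$seed, t), {
    img <- matrix(stats::rnorm(h * w, spec$bg_mean, spec$noise_sd), h, w)
    for (k in seq_len(nrow(spec$mice))) {
      cx <- pose[1, k, 1]; cy <- pose[1, k, 2]; th <- pose[1, k, 3]
      a <- spec$mice$a[k]; b <- spec$mice$b[k]
      ep <- ellipsePixels(cx, cy, th, a, b, h, w, radial = TRUE)
      # radial temperature profile: warm core, cooler fur rim (70% of the
      # offset at the contour) — this is what real thermal mice look like,
      # and it is what gives the watershed relief its ridge where two
      # bodies touch
      warm <- spec$bg_mean +
        spec$mice$offset[k] * (0.7 + 0.3 * (1 - ep$q)) +
        stats::rnorm(length(ep$idx), 0, spec$noise_sd)
      img[ep$idx] <- pmax(img[ep$idx], warm)
      # 1 px curled tail behind the genitals, fading to background towards
      # the tip (tails are hairless and cool, and frequently vanish from
      # thermal video); the curl keeps the rendered tail from lining up
      # with any single linear structuring element
      tl <- spec$mice$tail[k]
      if (tl > 0) {
        side <- if (k %% 2L == 0L) 1 else -1
        s <- seq(0, tl, by = 0.5)
        psi <- th + pi + side * (0.8 + s / 6)
        tx <- clampNum(round(cx - a * cos(th) + 0.5 * cumsum(cos(psi))),
                       0, w - 1)
        ty <- clampNum(round(cy - a * sin(th) + 0.5 * cumsum(sin(psi))),
                       0, h - 1)
        keyi <- xyToLin(tx, ty, h)
        keep <- !duplicated(keyi)
        tidx <- keyi[keep]
        # warm base, distal tail at near-ambient (a gradual fade would
        # leave a flickering segment at any threshold and fragment the
        # connected components)
        fade <- ifelse(s[keep] <= min(8, tl / 2), 0.9, 0.15)
        img[tidx] <- pmax(img[tidx],
                          spec$bg_mean + spec$mice$offset[k] * fade +
                            stats::rnorm(length(tidx), 0, spec$noise_sd))
      }
    }
    img
  })
}

# linear indices of the pixels inside a rotated ellipse; with radial = TRUE
# also the squared normalised radius q in [0, 1] of each pixel
ellipsePixels <- function(cx, cy, th, a, b, h, w, radial = FALSE) {
  x0 <- max(0, floor(cx - a - 1)); x1 <- min(w - 1, ceiling(cx + a + 1))
  y0 <- max(0, floor(cy - a - 1)); y1 <- min(h - 1, ceiling(cy + a + 1))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys * 0, xs - cx, `+`)
  dy <- outer(ys - cy, xs * 0, `+`)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  q <- (u / a)^2 + (v / b)^2
  inside <- q <= 1
  sub <- which(inside, arr.ind = TRUE)
  idx <- xyToLin(xs[sub[, 2]], ys[sub[, 1]], h)
  if (radial) list(idx = idx, q = q[inside]) else idx
}

#' Ground-truth body mask of one mouse at one frame
#'
#' The mask covers the elliptical body only (the tail is part of the rendered
#' image but not of the shape ground truth, mirroring the tracker's
#' tail-removal step).
#'
#' @param scenario a \code{thermalScenario}.
#' @param t 0-based frame index.
#' @param mouse mouse id (1-based).
#' @return A logical matrix of the frame's dimensions.
#' @export
groundTruthMask <- function(scenario, t, mouse) {
  p <- scenario$poses[scenario$poses$frame == t &
                        scenario$poses$mouse_id == mouse, ]
  h <- scenario$spec$arena[2]; w <- scenario$spec$arena[1]
  mk <- matrix(FALSE, h, w)
  idx <- ellipsePixels(p$centroid_x, p$centroid_y, p$heading,
                       scenario$spec$mice$a[mouse],
                       scenario$spec$mice$b[mouse], h, w)
  mk[idx] <- TRUE
  mk
}

#' Ground-truth poses as a MouseTracks object
#'
#' Useful for exercising the feature and classification stages on clean
#' geometry. Hu moment and area are the analytic values of the elliptical
#' body (\code{hu1 = (a^2 + b^2) / (4 pi a b)}, \code{area = pi a b}).
#'
#' @param scenario a \code{thermalScenario}.
#' @return A \linkS4class{MouseTracks} with every row flagged \code{"ok"}.
#' @export
truthTracks <- function(scenario) {
  d <- scenario$poses
  a <- scenario$spec$mice$a[d$mouse_id]
  b <- scenario$spec$mice$b[d$mouse_id]
  d$hu1 <- (a^2 + b^2) / (4 * pi * a * b)
  d$area <- pi * a * b
  d$flag <- "ok"
  d$strategy <- "truth"
  d$heading <- NULL
  mouseTracks(d, nMice = nrow(scenario$spec$mice),
              period = scenario$spec$period)
}

# ---- scripted presets ------------------------------------------------------

#' Scripted scenario presets
#'
#' Ready-made study scenarios used by the test-suite and the acceptance
#' script:
#' \describe{
#'   \item{scenarioThreeMiceDisjoint}{three mice circling disjoint regions of
#'     the arena; never in contact.}
#'   \item{scenarioTouchingPair}{two mice approach, then translate
#'     side-by-side in contact for the rest of the video.}
#'   \item{scenarioCrossingPair}{two mice walk antiparallel lanes 10.5 px
#'     apart, brushing past each other mid-video.}
#'   \item{scenarioCrossingTrio}{the crossing pair plus a third mouse cutting
#'     across the arena.}
#'   \item{scenarioFourClass}{a repeating 1080-frame choreography of
#'     WalkAlone, Following, Nose2Nose and StandAlone episodes for two mice,
#'     with contact during the nose-to-nose bouts.}
#' }
#'
#' @param nframes number of frames.
#' @param seed scenario seed.
#' @return A \code{\link{scenarioSpec}}.
#' @name scenarioPresets
NULL

walkAloneAll <- function(m) {
  stats::setNames(rep("WalkAlone", m * (m - 1L)), orderedPairNames(m))
}

#' @rdname scenarioPresets
#' @export
scenarioThreeMiceDisjoint <- function(nframes = 300, seed = 1) {
  # tails kept at 10 px so that even tail tips cannot bridge two mice while
  # the threshold is being initialised
  seg <- segmentSpec(0, nframes - 1L, list(
    motionArc(c(45, 45), 18, 0, 2 * pi * nframes / 150),
    motionArc(c(115, 45), 18, pi / 2, pi / 2 + 2 * pi * nframes / 150),
    motionArc(c(80, 120), 18, pi, pi + 2 * pi * nframes / 150)),
    labels = walkAloneAll(3))
  scenarioSpec(nframes, list(seg),
               mice = data.frame(a = 14, b = 5, offset = c(5, 6.5, 8),
                                 tail = 10),
               seed = seed)
}

#' @rdname scenarioPresets
#' @export
scenarioTouchingPair <- function(nframes = 200, seed = 1) {
  stopifnot(nframes >= 80)
  y1 <- 74.75; y2 <- 85.25
  segs <- list(
    # walk in, well separated
    segmentSpec(0, 19, list(
      motionLine(c(40, 70), c(50, 75.5)),
      motionLine(c(40, 90), c(50, 95.5))),
      labels = walkAloneAll(2)),
    # already parallel, lanes converging until the flanks touch
    segmentSpec(20, 49, list(
      motionLine(c(50, 75.5), c(70, y1), heading = 0),
      motionLine(c(50, 95.5), c(70, y2), heading = 0)),
      labels = c("1>2" = "Following", "2>1" = "Following")),
    # side-by-side contact, translating together
    segmentSpec(50, nframes - 1L, list(
      motionLine(c(70, y1), c(120, y1), heading = 0),
      motionLine(c(70, y2), c(120, y2), heading = 0)),
      labels = c("1>2" = "Following", "2>1" = "Following")))
  scenarioSpec(nframes, segs, mice = 2, seed = seed)
}

#' @rdname scenarioPresets
#' @export
scenarioCrossingPair <- function(nframes = 300, seed = 1) {
  seg <- segmentSpec(0, nframes - 1L, list(
    motionLine(c(30, 76), c(130, 76)),
    motionLine(c(130, 86.5), c(30, 86.5))),
    labels = walkAloneAll(2))
  scenarioSpec(nframes, list(seg), mice = 2, seed = seed)
}

#' @rdname scenarioPresets
#' @export
scenarioCrossingTrio <- function(nframes = 400, seed = 1) {
  seg <- segmentSpec(0, nframes - 1L, list(
    motionLine(c(30, 76), c(130, 76)),
    motionLine(c(130, 86.5), c(30, 86.5)),
    motionLine(c(110, 30), c(110, 130))),
    labels = walkAloneAll(3))
  scenarioSpec(nframes, list(seg), mice = 3, seed = seed)
}

#' @rdname scenarioPresets
#' @export
scenarioFourClass <- function(nframes = 5400, seed = 1) {
  cyc <- 1080L
  stopifnot(nframes %% cyc == 0)
  wa <- walkAloneAll(2)
  dd <- c(cos(3 * pi / 4), sin(3 * pi / 4))  # follow direction, down-left
  m1B0 <- c(120, 40); m1B1 <- m1B0 + 240 * 0.5 * dd
  trail <- 32 * -dd
  cycleSegs <- function(off) list(
    # A: both walk far apart
    segmentSpec(off, off + 179L, list(
      motionLine(c(30, 40), m1B0),
      motionLine(c(130, 120), m1B0 + trail)),
      labels = wa),
    # B: mouse 2 follows mouse 1 down the diagonal, 32 px behind
    segmentSpec(off + 180L, off + 419L, list(
      motionLine(m1B0, m1B1),
      motionLine(m1B0 + trail, m1B1 + trail)),
      labels = c("1>2" = "WalkAlone", "2>1" = "Following")),
    # C1: reposition on opposite sides of the meeting axis
    segmentSpec(off + 420L, off + 539L, list(
      motionLine(m1B1, c(40, 80)),
      motionLine(m1B1 + trail, c(125, 80))),
      labels = wa),
    # C2: head-on approach until the noses are 1.5 px apart
    segmentSpec(off + 540L, off + 599L, list(
      motionLine(c(40, 80), c(66, 80), heading = 0),
      motionLine(c(125, 80), c(95.5, 80), heading = pi)),
      labels = wa),
    # D: stationary nose-to-nose contact
    segmentSpec(off + 600L, off + 839L, list(
      motionStand(c(66, 80), 0),
      motionStand(c(95.5, 80), pi)),
      labels = c("1>2" = "Nose2Nose", "2>1" = "Nose2Nose")),
    # E: retreat to the far corners
    segmentSpec(off + 840L, off + 899L, list(
      motionLine(c(66, 80), c(30, 40)),
      motionLine(c(95.5, 80), c(130, 120))),
      labels = wa),
    # F: stand still far apart
    segmentSpec(off + 900L, off + 1079L, list(
      motionStand(c(30, 40), atan2(-40, -36)),
      motionStand(c(130, 120), atan2(40, 34.5))),
      labels = c("1>2" = "StandAlone", "2>1" = "StandAlone")))
  segs <- unlist(lapply(seq_len(nframes %/% cyc) - 1L,
                        function(i) cycleSegs(i * cyc)), recursive = FALSE)
  scenarioSpec(nframes, segs, mice = 2, seed = seed)
}
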