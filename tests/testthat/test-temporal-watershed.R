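# Pose bootstrap from blob moments, seed construction, EM-iterated seeded
# watershed, and orientation voting.

rasterEllipse <- function(cx, cy, th, a, b, h = 120, w = 160) {
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  dx <- outer(rep(1, h), xs - cx); dy <- outer(ys - cy, rep(1, w))
  u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

test_that("bootstrap poses match analytic ellipse moments", {
  m <- rasterEllipse(50, 60, 0, 20, 8)
  bl <- extractBlobs(m)
  p <- bootstrapPoses(bl, dim(m), 1)
  expect_equal(c(p$centroid_x, p$centroid_y), c(50, 60), tolerance = 0.5)
  expect_lt(abs(p$length - 40) / 40, 0.05)
  ends <- rbind(c(p$nose_x, p$nose_y), c(p$genitals_x, p$genitals_y))
  expect_setequal(round(ends[, 2]), 60)
  expect_lt(min(abs(ends[, 1] - 30)), 2.5)
  expect_lt(min(abs(ends[, 1] - 70)), 2.5)

  # circle: degenerate axes; length ~ diameter, endpoints on a diameter
  cm <- rasterEllipse(40, 40, 0, 15, 15, h = 80, w = 80)
  pc <- bootstrapPoses(extractBlobs(cm), dim(cm), 1)
  expect_lt(abs(pc$length - 30) / 30, 0.05)
  dvec <- c(pc$nose_x - pc$genitals_x, pc$nose_y - pc$genitals_y)
  expect_equal(sqrt(sum(dvec^2)), pc$length, tolerance = 1e-6)

  # wrong blob count -> skip status (NULL)
  expect_null(bootstrapPoses(extractBlobs(m), dim(m), 3))
})

test_that("seed spans shrink to the history mean minus slack", {
  fg <- rasterEllipse(60, 40, 0, 20, 8, h = 80, w = 120)
  prev <- makePose(1, nose = c(80, 40), gen = c(40, 40), len = 40)
  cfg <- watershedConfig(slack = 6)
  seeds <- buildSeeds(prev, fg, cfg, lengthHistory = list(c(40, 40, 40)))
  pts <- which(seeds == 1L)
  xy <- cbind((pts - 1) %/% 80, (pts - 1) %% 80)
  expect_equal(nrow(xy), 3L)                      # nose, centroid, genitals
  expect_equal(max(xy[, 1]) - min(xy[, 1]), 34)   # span = mean(40) - 6
  expect_equal(unique(xy[, 2]), 40)
  # background seed: eroded complement, labelled M + 1, never on foreground
  expect_true(all(seeds[fg] != 2L))
  expect_gt(sum(seeds == 2L), 0)
  er <- EBImage::erode(EBImage::erode((!fg) * 1, EBImage::makeBrush(3, "box")),
                       EBImage::makeBrush(3, "box"))
  expect_identical(unname(seeds == 2L), unname(er > 0.5 & seeds != 1L))

  # conflicting candidate points go to the nearer previous centroid: the
  # two seed triplets round to the same three pixels; the far endpoint is
  # nearer to mouse 2's centroid, the rest stay with mouse 1
  prev2 <- rbind(makePose(1, c(70, 40), c(50, 40)),
                 makePose(2, c(70.4, 40), c(50.4, 40)))
  seeds2 <- buildSeeds(prev2, fg, cfg)
  expect_equal(sum(seeds2 == 1L), 2L)
  expect_equal(sum(seeds2 == 2L), 1L)
  expect_equal(which(seeds2 == 2L), 40L + 1L + 67L * 80L)

  # degenerate previous pose (zero length) -> point seed at the centroid
  prev3 <- makePose(1, c(60, 40), c(60, 40), len = 0)
  seeds3 <- buildSeeds(prev3, fg, cfg, lengthHistory = list(0))
  expect_equal(sum(seeds3 == 1L), 1L)
})

test_that("disjoint mice make the EM return the blobs themselves", {
  fg <- rasterEllipse(40, 30, 0, 16, 6, h = 90, w = 140) |
    rasterEllipse(100, 60, pi / 3, 16, 6, h = 90, w = 140)
  frame <- matrix(20, 90, 140); frame[fg] <- 26
  prev <- rbind(makePose(1, c(55, 30), c(25, 30)),
                makePose(2, c(108, 74), c(92, 46)))
  em <- emSegment(frame, fg, prev)
  expect_true(em$converged)
  expect_lte(em$iters, 2L)
  sh <- poseShapes(em$poses)
  expect_setequal(sort(c(sh[[1]], sh[[2]])), which(fg))
  expect_length(intersect(sh[[1]], sh[[2]]), 0L)
  expect_equal(sh[[1]], which(rasterEllipse(40, 30, 0, 16, 6, 90, 140)))
})

test_that("EM splits touching mice near ground truth and partitions exactly", {
  sc <- generateScenario(scenarioTouchingPair(120, seed = 8))
  det <- detectionConfig(2, init_window = 20)
  thr <- estimateThreshold(sc$video, det)
  # previous poses: ground truth of frame 79 (displaced less than slack
  # from frame 80); frame 80 is deep inside the contact episode
  gt <- function(f) {
    p <- sc$poses[sc$poses$frame == f, ]
    p$hu1 <- 0.25; p$area <- 220
    p[order(p$mouse_id),
      c("mouse_id", "nose_x", "nose_y", "genitals_x", "genitals_y",
        "centroid_x", "centroid_y", "length", "hu1", "area")]
  }
  fr <- getFrame(sc$video, 80)
  fg <- segmentForeground(fr, thr, det)
  em <- emSegment(fr, fg, gt(79))
  sh <- poseShapes(em$poses)
  # hard partition of the foreground
  expect_setequal(sort(unlist(sh)), which(fg$mask))
  expect_length(intersect(sh[[1]], sh[[2]]), 0L)
  truth <- gt(80)
  cerr <- sqrt((em$poses$centroid_x - truth$centroid_x)^2 +
                 (em$poses$centroid_y - truth$centroid_y)^2)
  expect_true(all(cerr <= 3))
  # robustness to initialisation error below the slack constant
  prev <- gt(79)
  prev[, c("nose_x", "genitals_x", "centroid_x")] <-
    prev[, c("nose_x", "genitals_x", "centroid_x")] + 4
  em2 <- emSegment(fr, fg, prev)
  cerr2 <- sqrt((em2$poses$centroid_x - truth$centroid_x)^2 +
                  (em2$poses$centroid_y - truth$centroid_y)^2)
  expect_true(all(cerr2 <= 3))
})

test_that("orientation voting follows the signed-agreement arithmetic", {
  cfg <- watershedConfig(vote_window = 10)
  straight <- function(n, dsign = 1) {
    do.call(rbind, lapply(seq_len(n), function(i)
      makePose(1, nose = c(10 + 2 * i + dsign * 14, 50),
               gen = c(10 + 2 * i - dsign * 14, 50),
               cen = c(10 + 2 * i, 50))))
  }
  # d aligned with +x movement on all frames: vote +k, no swap
  h <- straight(11)
  r <- correctOrientation(h[1:10, ], h[11, ], cfg)
  expect_false(r$swapped)
  expect_equal(r$vote, 10)
  # d opposed to movement on all frames: vote -k, forced swap
  hi <- straight(11, dsign = -1)
  ri <- correctOrientation(hi[1:10, ], hi[11, ], cfg)
  expect_true(ri$swapped)
  expect_equal(ri$vote, -10)
  expect_equal(c(ri$pose$nose_x, ri$pose$genitals_x),
               c(hi$genitals_x[11], hi$nose_x[11]))
  # 6 agreeing vs 4 disagreeing frames: vote +2, no swap
  hm <- straight(11)
  flip <- 5:8  # four disagreeing movement/direction pairs
  hm[flip + 1, c("nose_x", "genitals_x")] <-
    hm[flip + 1, c("genitals_x", "nose_x")]
  rm2 <- correctOrientation(hm[1:10, ], hm[11, ], cfg)
  expect_equal(rm2$vote, 2)
  expect_false(rm2$swapped)
  # stationary frames contribute zero
  still <- do.call(rbind, lapply(1:6, function(i)
    makePose(1, c(24, 50), c(-4, 50), cen = c(10, 50))))
  rs <- correctOrientation(still[1:5, ], still[6, ], cfg)
  expect_equal(rs$vote, 0)
  expect_false(rs$swapped)
})

test_that("a forced inversion is corrected once, without oscillation", {
  cfg <- watershedConfig(vote_window = 10)
  n <- 40; flipAt <- 15
  trial <- function(seed) {
    set.seed(seed)
    th <- stats::runif(1, 0, 2 * pi)
    sp <- stats::runif(1, 1, 3)
    d <- c(cos(th), sin(th))
    signs <- numeric(0)
    orient <- 1   # tracked orientation sign (propagated frame to frame)
    swaps <- integer(0)
    prevPose <- NULL
    for (i in seq_len(n)) {
      cen <- c(60, 60) + i * sp * d
      if (i == flipAt) orient <- -orient  # inversion event
      pose <- makePose(1, cen + orient * 14 * d, cen - orient * 14 * d,
                       cen = cen)
      if (i > 1) {
        upd <- orientationVoteUpdate(signs, prevPose, pose, cfg)
        signs <- upd$signs
        if (upd$swapped) {
          swaps <- c(swaps, i)
          orient <- -orient            # correction propagates
          pose <- upd$pose
        }
      }
      prevPose <- pose
    }
    list(swaps = swaps, finalOk = orient == 1)
  }
  res <- lapply(1:50, trial)
  expect_true(all(vapply(res, function(r) length(r$swaps) == 1L, logical(1))))
  expect_true(all(vapply(res, function(r)
    r$swaps[1] - flipAt <= cfg$vote_window, logical(1))))
  expect_true(all(vapply(res, `[[`, logical(1), "finalOk")))
})
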