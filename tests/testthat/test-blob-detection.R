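# Foreground thresholding, tail-removing openings, 8-connected components
# and blob-count reconciliation.

twoLevelVideo <- function(nfr = 12, body = 30, bg = 20) {
  # M = 1: a 12x12 square at `body` over a uniform background
  frames <- lapply(seq_len(nfr), function(i) {
    f <- matrix(bg, 60, 60)
    f[20:31, 20:31] <- body
    f
  })
  thermalVideo(frames)
}

test_that("threshold estimation brackets background and body temperatures", {
  sc <- generateScenario(scenarioThreeMiceDisjoint(120, seed = 4))
  det <- detectionConfig(3, init_window = 90)
  frames <- lapply(0:119, function(t) getFrame(sc$video, t))
  thr <- estimateThreshold(sc$video, det)
  # oracle: exhaustive scan over a fine value grid on the known synthetic
  # temperatures — the returned threshold must lie strictly between the
  # background 99.9th percentile and the minimum body temperature, and give
  # exactly 3 components on every window frame
  bgq <- stats::quantile(unlist(lapply(frames[1:10], function(f) {
    f[f < sc$spec$bg_mean + 2] })), 0.999)
  # bodies carry a warm-core/cool-rim profile, so the relevant upper bound
  # is the expected contour temperature of the coolest mouse
  rimMin <- sc$spec$bg_mean + 0.7 * min(sc$spec$mice$offset)
  expect_gt(thr$threshold, bgq)
  expect_lt(thr$threshold, rimMin)
  wf <- (thr$window[1]:thr$window[2]) + 1L
  ncomp <- vapply(frames[wf], function(f)
    length(extractBlobs(f > thr$threshold)), integer(1))
  expect_true(all(ncomp == 3L))
  # determinism
  expect_identical(thr, estimateThreshold(sc$video, det))
})

test_that("two-level image yields a threshold between the two levels", {
  det <- detectionConfig(1, min_mouse_area = 100, init_window = 10)
  thr <- estimateThreshold(twoLevelVideo(), det)
  expect_gt(thr$threshold, 20)
  expect_lt(thr$threshold, 30)
})

test_that("permanently touching mice defeat initialisation with a named error", {
  # two mice in contact on every frame: component count is always 1 != 2
  spec <- scenarioSpec(40, list(segmentSpec(0, 39, list(
    motionLine(c(60, 74.75), c(90, 74.75), heading = 0),
    motionLine(c(60, 85.25), c(90, 85.25), heading = 0)),
    labels = c("1>2" = "Following", "2>1" = "Following"))),
    mice = 2, seed = 9)
  sc <- generateScenario(spec)
  det <- detectionConfig(2, init_window = 30)
  expect_error(estimateThreshold(sc$video, det),
               "thermotrack_init_failure")
  # and so does asking for more initialisation frames than exist
  expect_error(estimateThreshold(twoLevelVideo(4),
                                 detectionConfig(1, init_window = 10)),
               "thermotrack_init_failure")
})

test_that("the oriented openings remove tails but keep bodies and bars", {
  # ellipse body (minor axis 9 px) with a thin attached tail, as a pure
  # two-level image; oracle = direct set-based morphology
  m <- matrix(15, 50, 70)
  for (x in 0:69) for (y in 0:49) {
    if (((x - 30) / 15)^2 + ((y - 25) / 4.5)^2 <= 1) m[y + 1, x + 1] <- 30
  }
  tail_xy <- cbind(x = 45:60, y = round(25 + 0.7 * (0:15)))  # oblique tail
  m[cbind(tail_xy[, "y"] + 1, tail_xy[, "x"] + 1)] <- 30
  fg <- segmentForeground(m, 22, detectionConfig(1))
  oracle <- oracleOpening(m > 22)
  expect_identical(unname(fg$mask), unname(oracle))
  body <- sum(((col(m) - 1 - 30) / 15)^2 + ((row(m) - 1 - 25) / 4.5)^2 <= 1)
  expect_lt(abs(sum(fg$mask) - body) / body, 0.1)   # body change < 10%
  expect_lt(sum(fg$mask[cbind(tail_xy[, "y"] + 1, tail_xy[, "x"] + 1)]), 4)

  # all-background frame -> empty mask
  expect_equal(sum(segmentForeground(matrix(20, 30, 30), 25)$mask), 0)

  # a 5x1 bar exactly matching one structuring element survives intact
  bar <- matrix(0, 20, 20)
  bar[10, 8:12] <- 1
  fgb <- segmentForeground(bar, 0.5)
  expect_equal(which(fgb$mask), which(bar > 0.5))

  # opening idempotence: applying the operator to its own binary output is
  # a fixed point
  again <- segmentForeground(fg$mask * 30, 22, detectionConfig(1))
  expect_identical(again$mask, fg$mask)
})

test_that("blob extraction is 8-connected with moment centroids", {
  m <- matrix(FALSE, 30, 30)
  m[5:7, 5:7] <- TRUE          # area 9 centred at (5, 5) in 0-based x,y
  m[20:22, 24:26] <- TRUE
  bl <- extractBlobs(m)
  expect_length(bl, 2L)
  expect_equal(vapply(bl, `[[`, numeric(1), "area"), c(9, 9))
  cents <- t(vapply(bl, `[[`, numeric(2), "centroid"))
  expect_setequal(paste(cents[, 1], cents[, 2]), c("5 5", "24 20"))

  expect_length(extractBlobs(matrix(FALSE, 5, 5)), 0L)

  # L-shape with a diagonal-only join stays one blob under 8-connectivity;
  # oracle = recursive flood fill
  L <- matrix(FALSE, 10, 10)
  L[2:5, 2] <- TRUE
  L[6, 3] <- TRUE              # touches (5,2) only diagonally
  L[6:8, 4] <- TRUE
  expect_length(extractBlobs(L), max(oracleFlood8(L)))
  expect_length(extractBlobs(L), 1L)

  # blobs come sorted by decreasing area
  m[10:12, 10:16] <- TRUE
  bl <- extractBlobs(m)
  expect_equal(vapply(bl, `[[`, numeric(1), "area"), c(21, 9, 9))
})

test_that("blob-count reconciliation dilates, defers or reinitialises", {
  det <- detectionConfig(3, min_mouse_area = 8, max_dilations = 5)
  ok <- matrix(FALSE, 40, 40)
  ok[5:8, 5:8] <- TRUE; ok[20:23, 20:23] <- TRUE; ok[30:33, 5:8] <- TRUE
  r <- reconcileBlobCount(ok, det)
  expect_equal(r$status, "ok")
  expect_identical(r$mask, ok)

  # M = 2: one mouse split into two fragments 1 px apart; a single 3x3
  # dilation merges them (oracle: dilating the fixture by hand)
  det2 <- detectionConfig(2, min_mouse_area = 8, max_dilations = 5)
  split <- matrix(FALSE, 40, 40)
  split[10:13, 5:8] <- TRUE
  split[10:13, 10:13] <- TRUE   # 1 px gap at column 9
  split[30:33, 30:33] <- TRUE
  r2 <- reconcileBlobCount(split, det2)
  expect_equal(r2$status, "ok")
  expect_equal(r2$n_blobs, 2L)
  expect_true(all(r2$mask[split]))

  # M = 3 but only 2 blobs: mice touching, deferred to the watershed
  two <- matrix(FALSE, 40, 40)
  two[5:10, 5:10] <- TRUE; two[20:25, 20:25] <- TRUE
  r3 <- reconcileBlobCount(two, det)
  expect_equal(r3$status, "merged_for_watershed")
  expect_identical(r3$mask, two)

  # fragments that dilation cannot merge within max_dilations -> reinit
  far <- matrix(FALSE, 60, 60)
  far[5:8, 5:8] <- TRUE; far[5:8, 30:33] <- TRUE
  far[30:33, 5:8] <- TRUE; far[50:53, 50:53] <- TRUE
  r4 <- reconcileBlobCount(far, det)
  expect_equal(r4$status, "reinit")
})

test_that("raising the threshold never increases foreground area", {
  sc <- generateScenario(scenarioTouchingPair(85, seed = 6))
  f <- getFrame(sc$video, 40)
  taus <- seq(21, 26, by = 0.25)
  areas <- vapply(taus, function(tau) sum(f > tau), numeric(1))
  expect_true(all(diff(areas) <= 0))
  # morphological opening is monotone in set inclusion, so the property
  # survives the tail-removal step exactly
  opened <- vapply(taus, function(tau)
    sum(segmentForeground(f, tau)$mask), numeric(1))
  expect_true(all(diff(opened) <= 0))
})
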