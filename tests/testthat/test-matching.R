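# Distance matrices, greedy assignment, Hu-moment sanity check, heat
# signatures and KS-based identity recovery.

test_that("pose distances are 6-D Euclidean on (nose, genitals, centroid)", {
  a <- rbind(makePose(1, c(10, 10), c(20, 20)),
             makePose(2, c(100, 100), c(110, 110)))
  expect_equal(diag(distanceMatrix(a, a)), c(0, 0))
  # rigid (3, 4) shift displaces each of the three keypoints by 5
  b1 <- makePose(1, c(13, 14), c(23, 24))
  expect_equal(distanceMatrix(a[1, ], b1)[1, 1], sqrt(3 * 25))
  expect_equal(distanceMatrix(a[1, ], b1)[1, 1], 8.660, tolerance = 1e-3)
  # swapped distant poses: off-diagonal cheaper than diagonal
  sw <- a[2:1, ]; sw$mouse_id <- 1:2
  D <- distanceMatrix(a, sw)
  expect_true(all(c(D[1, 2], D[2, 1]) < c(D[1, 1], D[2, 2])))
  expect_error(distanceMatrix(a, a[1, ]), "pose counts")
})

test_that("greedy assignment picks global minima with row-major ties", {
  expect_equal(greedyAssign(diag(0, 3) + 10 - 10 * diag(3)), 1:3)
  expect_equal(greedyAssign(matrix(c(1, 10, 10, 2), 2, byrow = TRUE)), 1:2)
  expect_equal(greedyAssign(matrix(c(5, 1, 2, 9), 2, byrow = TRUE)),
               c(2L, 1L))
  expect_equal(greedyAssign(matrix(1, 3, 3)), 1:3)  # all ties: row-major
})

test_that("greedy assignment agrees with naive and optimal oracles", {
  set.seed(101)
  agreeHungarianWhenUnique <- 0L; uniqueCases <- 0L
  softAgree <- 0L; n3 <- 0L
  for (i in 1:1000) {
    n <- sample(2:4, 1)
    costs <- matrix(stats::runif(n * n), n, n)
    g <- greedyAssign(costs)
    expect_identical(g, oracleGreedy(costs))
    h <- oracleHungarian(costs)
    if (greedyUnique(costs) &&
        sum(costs[cbind(seq_len(n), g)]) ==
          sum(costs[cbind(seq_len(n), h)])) {
      uniqueCases <- uniqueCases + 1L
      agreeHungarianWhenUnique <- agreeHungarianWhenUnique +
        as.integer(identical(g, h))
    }
    # bijection on every input
    expect_setequal(g, seq_len(n))
  }
  expect_equal(agreeHungarianWhenUnique, uniqueCases)

  # soft bound against the optimum on the matrices the tracker actually
  # sees: 6-D pose distances after random per-mouse displacements
  for (i in 1:1000) {
    prev <- matrix(stats::runif(18, 0, 160), 3, 6)
    cur <- prev + matrix(stats::rnorm(18, 0, stats::runif(1, 1, 10)), 3, 6)
    costs <- as.matrix(stats::dist(rbind(prev, cur)))[1:3, 4:6]
    n3 <- n3 + 1L
    if (identical(greedyAssign(costs), oracleHungarian(costs)))
      softAgree <- softAgree + 1L
  }
  expect_gte(softAgree / n3, 0.9)
})

test_that("the Student-t shape check flags tail hu1 values, two mice raise the global state", {
  set.seed(7)
  rec <- 0.25 + 0.01 * stats::rt(500, df = 8)
  model <- fitShapeModel(rec)
  expect_lt(abs(model$m - 0.25), 0.005)
  # value at the running mean: never flagged
  sc <- shapeSanityCheck(model, c(model$m, model$m), alpha = 0.01)
  expect_false(any(sc$flags))
  expect_false(sc$global)
  # value at the 0.1st percentile of the fitted t: flagged at alpha = 0.01
  q <- model$m + model$s * stats::qt(0.001, df = model$df)
  sc2 <- shapeSanityCheck(model, c(q, model$m), alpha = 0.01)
  expect_true(sc2$flags[1])
  expect_false(sc2$flags[2])
  expect_false(sc2$global)     # exactly one mouse flagged: not global
  sc3 <- shapeSanityCheck(model, c(q, q), alpha = 0.01)
  expect_true(sc3$global)
  # cold start: no model, all flags FALSE
  sc4 <- shapeSanityCheck(NULL, c(0, 9), alpha = 0.01)
  expect_false(any(sc4$flags))
})

test_that("heat-signature buffers span exactly B frames after warm-up", {
  sigs <- heatSignatures(2, buffer_frames = 3)
  for (i in 1:4)
    sigs <- updateHeatSignatures(sigs, list(rep(i, 5), rep(-i, 5)))
  expect_length(sigs$frames[[1]], 3L)
  expect_equal(unique(unlist(sigs$frames[[1]])), c(2, 3, 4))  # oldest evicted
  expect_equal(unique(unlist(sigs$frames[[2]])), c(-2, -3, -4))
  # constant-temperature mouse: the signature ECDF is a single step
  e <- stats::ecdf(signatureSamples(sigs)[[1]])
  expect_equal(e(1.99), 0); expect_gt(e(2), 0)
})

test_that("rendered mice with offsets 1 unit apart differ by ~1 in signature mean", {
  spec <- scenarioSpec(9, list(segmentSpec(0, 8, list(
    motionStand(c(40, 40), 0), motionStand(c(100, 80), pi)),
    labels = c("1>2" = "StandAlone", "2>1" = "StandAlone"))),
    mice = data.frame(a = 14, b = 5, offset = c(30, 31), tail = 0),
    seed = 4)
  sc <- generateScenario(spec)
  sigs <- heatSignatures(2, 9)
  for (t in 0:8) {
    fr <- getFrame(sc$video, t)
    sigs <- updateHeatSignatures(sigs, list(
      fr[groundTruthMask(sc, t, 1)], fr[groundTruthMask(sc, t, 2)]))
  }
  mns <- vapply(signatureSamples(sigs), mean, numeric(1))
  # bodies carry the radial profile 0.7 + 0.3 (1 - q); with q uniform over
  # the ellipse the in-shape mean offset is 0.85 per unit, so signatures one
  # unit apart differ by ~0.85 units
  expect_equal(mns[2] - mns[1], 0.85, tolerance = 0.1)
})

test_that("KS-greedy matching undoes identity swaps", {
  set.seed(11)
  sigs <- heatSignatures(2, 9)
  for (i in 1:9)
    sigs <- updateHeatSignatures(sigs, list(stats::rnorm(200, 25, 0.5),
                                            stats::rnorm(200, 26.5, 0.5)))
  # identical samples vs own signature: KS = 0 on the diagonal
  own <- signatureSamples(sigs)
  perm0 <- heatAssign(own, sigs)
  expect_equal(perm0, 1:2, ignore_attr = TRUE)
  expect_equal(diag(attr(perm0, "costs")), c(0, 0))
  # disjoint supports, labels swapped upstream: permutation undoes the swap
  swapped <- list(stats::rnorm(200, 26.5, 0.5), stats::rnorm(200, 25, 0.5))
  permS <- heatAssign(swapped, sigs)
  expect_equal(permS, c(2L, 1L), ignore_attr = TRUE)
  # same-distribution draws recover identity in >= 95/100 seeded trials
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    cur <- list(stats::rnorm(150, 25, 0.5), stats::rnorm(150, 26.5, 0.5))
    if (identical(as.integer(heatAssign(cur, sigs)), 1:2)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  # empty shape: sentinel cost, still a bijection
  permE <- heatAssign(list(numeric(0), stats::rnorm(50, 25, 0.5)), sigs)
  expect_setequal(permE, 1:2)
  expect_true(all(attr(permE, "costs")[, 1] > 1))
})

test_that("KS statistic stays in [0, 1] and vanishes only on identical ECDFs", {
  set.seed(3)
  for (i in 1:20) {
    x <- stats::rnorm(50); y <- stats::rnorm(50, sample(0:3, 1))
    D <- thermotrack:::ksStatistic(x, y)
    expect_gte(D, 0); expect_lte(D, 1)
  }
  x <- stats::rnorm(40)
  expect_equal(thermotrack:::ksStatistic(x, sample(x)), 0)
})

test_that("never-touching mice keep their identities throughout", {
  sc <- generateScenario(scenarioThreeMiceDisjoint(150, seed = 12))
  tr <- trackMice(sc$video, 3)
  ag <- trackingAgreement(tr, sc)
  expect_equal(ag$agreement, 1)
  expect_equal(ag$switches, 0L)
  expect_true(all(poses(tr)$flag == "ok"))
  expect_true(all(poses(tr)$strategy[poses(tr)$frame > 0] == "distance"))
})
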