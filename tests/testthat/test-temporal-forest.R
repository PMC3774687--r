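# Temporal Random Forest: training design, vote counts, mode with priority
# tie-breaks, temporal regularisation, determinism and pair transfer.

test_that("vote counts equal (2w+1) * N and constant training is degenerate", {
  labs <- rep(c("WalkAlone", "Nose2Nose"), each = 40)
  ft <- simFeatureSequence(labs, noise_sd = 0.5, seed = 1)
  m0 <- temporalForest(ft, labs, forestConfig(n_trees = 25, window = 0,
                                              seed = 2))
  expect_length(temporalForestVotes(m0, ft, 10), 25L)
  m15 <- temporalForest(ft, labs, forestConfig(n_trees = 5, window = 15,
                                               seed = 2))
  expect_length(temporalForestVotes(m15, ft, 40), (2 * 15 + 1) * 5)

  # constant features, constant label: unanimous votes, training succeeds
  cft <- ft; cft[, featureNames()] <- 1
  expect_warning(mc <- temporalForest(cft, rep("Above", nrow(cft)),
                                      forestConfig(n_trees = 3, window = 2)),
                 "single-class")
  v <- temporalForestVotes(mc, cft, 10)
  expect_true(all(v == "Above"))
  expect_equal(classifyFrame(mc, cft, 10), "Above")
})

test_that("w=0 separable training reaches 100% training accuracy", {
  labs <- rep(c("WalkAlone", "Nose2Nose"), each = 60)
  ft <- simFeatureSequence(labs, noise_sd = 0, seed = 3)  # separable
  m <- temporalForest(ft, labs, forestConfig(n_trees = 25, window = 0,
                                             subspace_dim = 13, seed = 4))
  pred <- classifySequence(m, ft)
  expect_equal(mean(pred$label == labs), 1)
})

test_that("mode ties break by behaviour priority, then the vote wins", {
  counts <- matrix(c(10, 10), 1,
                   dimnames = list(NULL, c("StandAlone", "Nose2Body")))
  got <- thermotrack:::modeWithPriority(counts, c("StandAlone", "Nose2Body"),
                                        priorityTable())
  expect_equal(got, "Nose2Body")
  counts2 <- matrix(c(60, 40), 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(thermotrack:::modeWithPriority(counts2, c("A", "B"),
                                              priorityTable()), "A")
})

test_that("training and prediction are deterministic given the seed", {
  labs <- segmentLabels(6, 30, seed = 5)
  ft <- simFeatureSequence(labs, noise_sd = 2, seed = 5)
  m1 <- temporalForest(ft, labs, forestConfig(seed = 9))
  m2 <- temporalForest(ft, labs, forestConfig(seed = 9))
  p1 <- classifySequence(m1, ft)
  p2 <- classifySequence(m2, ft)
  expect_identical(p1, p2)
  # a different seed draws different subspaces/bootstraps
  m3 <- temporalForest(ft, labs, forestConfig(seed = 10))
  vars1 <- lapply(m1@trees, function(o) lapply(o, `[[`, "vars"))
  vars3 <- lapply(m3@trees, function(o) lapply(o, `[[`, "vars"))
  expect_false(identical(vars1, vars3))
})

test_that("the windowed vote smooths isolated single-frame flips", {
  labs <- rep(c("WalkAlone", "Nose2Nose", "StandAlone"), each = 62)
  train <- simFeatureSequence(labs, noise_sd = 0.5, seed = 6)
  m <- temporalForest(train, labs, forestConfig(seed = 7))
  # clean test sequence whose frame 90 carries the features of another
  # class inside a stable >= (2w+1) context
  test <- simFeatureSequence(labs, noise_sd = 0.5, seed = 8)
  flipRow <- simFeatureSequence(rep("WalkAlone", nrow(test)),
                                noise_sd = 0.5, seed = 9)[91, ]
  test[91, featureNames()] <- flipRow[, featureNames()]
  pred <- classifySequence(m, test)
  expect_equal(pred$label[91], "Nose2Nose")   # context label, flip absent
  # a w=0 forest has no such context and follows the flipped features
  m0 <- temporalForest(train, labs, forestConfig(window = 0, n_trees = 25,
                                                 seed = 7))
  expect_equal(classifySequence(m0, test)$label[91], "WalkAlone")
})

test_that("the temporal window regularises noisy sequences (w=15 >= w=0)", {
  acc <- vapply(1:6, function(rep) {
    labs <- segmentLabels(6, 60, seed = 100 + rep)
    train <- simFeatureSequence(labs, noise_sd = 6, seed = 200 + rep)
    test <- simFeatureSequence(labs, noise_sd = 6, seed = 300 + rep)
    m15 <- temporalForest(train, labs, forestConfig(seed = 1))
    m0 <- temporalForest(train, labs,
                         forestConfig(window = 0, n_trees = 5, seed = 1))
    c(mean(classifySequence(m15, test)$label == labs),
      mean(classifySequence(m0, test)$label == labs))
  }, numeric(2))
  expect_gte(mean(acc[1, ]), mean(acc[2, ]))
})

test_that("a model trained on one pair classifies another pair's table", {
  labs <- segmentLabels(4, 40, seed = 11)
  ftA <- simFeatureSequence(labs, noise_sd = 1, seed = 12, pair = c(1L, 2L))
  m <- temporalForest(ftA, labs, forestConfig(seed = 13))
  ftB <- simFeatureSequence(labs, noise_sd = 1, seed = 14, pair = c(3L, 1L))
  predB <- classifySequence(m, ftB)
  expect_equal(nrow(predB), nrow(ftB))
  expect_gt(mean(predB$label == labs), 0.9)
})

test_that("forest archives restore to an identical predictor", {
  dirp <- withr::local_tempdir()
  labs <- rep(c("WalkAlone", "Nose2Nose"), each = 30)
  ft <- simFeatureSequence(labs, noise_sd = 1, seed = 15)
  m <- temporalForest(ft, labs, forestConfig(n_trees = 3, window = 2,
                                             seed = 16))
  p <- file.path(dirp, "forest.rds")
  saveTemporalForest(m, p)
  m2 <- loadTemporalForest(p)
  expect_identical(classifySequence(m2, ft), classifySequence(m, ft))
  expect_error(loadTemporalForest(
    { q <- file.path(dirp, "x.rds"); saveRDS(1, q); q }), "not a thermotrack")
})
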