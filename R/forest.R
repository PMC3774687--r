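# Temporal Random Forest: for every temporal offset in -w..w an ensemble of
# N unpruned, information-gain CART trees, each grown on a random feature
# subspace (and a bootstrap resample) of the pair-feature vectors at frame
# t + offset against the label of the central frame t. At prediction time
# all (2w+1)*N trees vote and the mode (priority tie-break) is the label —
# the windowed vote acts as a temporal regulariser.

#' The eight behaviour classes
#'
#' @return Character vector of the class vocabulary: five social behaviours
#'   (Nose2Body, Nose2Nose, Nose2Genitals, Above, Following), two non-social
#'   (WalkAlone, StandAlone), and StandTogether, whose social status is
#'   reported separately.
#' @export
behaviourClasses <- function() {
  c("Above", "Nose2Genitals", "Nose2Nose", "Nose2Body", "Following",
    "StandTogether", "WalkAlone", "StandAlone")
}

#' TemporalForest: per-offset tree ensembles voting across a window
#'
#' @slot trees list indexed by offset; each element a list of N trees, each
#'   a list with the fitted \code{rpart} model and its feature subspace.
#' @slot offsets integer offsets \code{-w:w}.
#' @slot classes class vocabulary (training levels).
#' @slot featNames names of the 13 feature columns used.
#' @slot config the \code{\link{forestConfig}} used.
#' @slot priorities named integer priority table used for vote tie-breaks.
#' @exportClass TemporalForest
setClass("TemporalForest",
  representation(trees = "list", offsets = "integer", classes = "character",
                 featNames = "character", config = "list",
                 priorities = "integer"))

setMethod("show", "TemporalForest", function(object) {
  cat(sprintf(paste0("TemporalForest: %d offsets x %d trees = %d trees, ",
                     "subspace %d of %d features, %d classes\n"),
              length(object@offsets), object@config$n_trees,
              length(object@offsets) * object@config$n_trees,
              object@config$subspace_dim, length(object@featNames),
              length(object@classes)))
})

rpartCtrl <- function() {
  rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                       maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)
}

# clamped row index of frame position i + offset within a sequence of n rows
clampIdx <- function(i, off, n) clampNum(i + off, 1L, n)

splitPairs <- function(features) {
  key <- paste(features$ref_id, features$target_id, sep = ">")
  idx <- split(seq_len(nrow(features)), key)
  lapply(idx, function(ix) ix[order(features$frame[ix])])
}

#' Fit a Temporal Random Forest
#'
#' For each offset \code{delta} in \code{-w:w}, each of N trees is grown on
#' the pairs (feature vector at frame t + delta restricted to the tree's
#' random d-dimensional subspace, label at frame t), pooled over all
#' training pairs and frames; offsets beyond a sequence's ends are clamped.
#' Trees are unpruned and split on information gain; each tree sees an
#' independent bootstrap resample of the training rows. Training is
#' deterministic given \code{cfg$seed}. A model trained on one mouse pair
#' classifies any other pair's feature table without retraining.
#'
#' @param features data.frame with columns \code{frame, ref_id, target_id}
#'   and the 13 feature columns (\code{\link{featureNames}}); sequences are
#'   keyed by ordered pair.
#' @param labels character/factor vector of behaviour labels aligned to the
#'   rows of \code{features}.
#' @param cfg a \code{\link{forestConfig}}.
#' @param priorities priority table for vote tie-breaks
#'   (\code{\link{priorityTable}}).
#' @return A \linkS4class{TemporalForest}.
#' @export
temporalForest <- function(features, labels, cfg = forestConfig(),
                           priorities = priorityTable()) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    warning("single-class training set: the forest is a constant predictor")
  fn <- setdiff(names(features), c("frame", "ref_id", "target_id"))
  d <- min(cfg$subspace_dim, length(fn))
  seqs <- splitPairs(features)
  featMat <- features[, fn, drop = FALSE]
  offsets <- (-cfg$window):(cfg$window)
  # training design per offset: features at t + delta, label at t
  designs <- lapply(offsets, function(off) {
    rows <- unlist(lapply(seqs, function(ix)
      ix[clampIdx(seq_along(ix), off, length(ix))]), use.names = FALSE)
    rows
  })
  centralRows <- unlist(seqs, use.names = FALSE)
  y <- factor(labels[centralRows], levels = classes)
  ntrain <- length(centralRows)
  trees <- withSeed(cfg$seed, {
    lapply(seq_along(offsets), function(oi) {
      X <- featMat[designs[[oi]], , drop = FALSE]
      lapply(seq_len(cfg$n_trees), function(k) {
        vars <- sort(sample(fn, d))
        rows <- if (cfg$bootstrap) {
          if (cfg$balanced_bootstrap) {
            per <- ceiling(ntrain / length(classes))
            unlist(lapply(classes, function(cl) {
              cand <- which(y == cl)
              if (length(cand)) sample(cand, per, replace = TRUE)
              else integer(0)
            }))
          } else sample.int(ntrain, replace = TRUE)
        } else seq_len(ntrain)
        df <- data.frame(.y = y[rows], X[rows, vars, drop = FALSE])
        fit <- if (length(classes) < 2L) NULL else
          rpart::rpart(.y ~ ., data = df, method = "class",
                       parms = list(split = "information"),
                       control = rpartCtrl())
        list(fit = fit, vars = vars)
      })
    })
  })
  new("TemporalForest", trees = trees, offsets = as.integer(offsets),
      classes = classes, featNames = fn, config = unclass(cfg),
      priorities = priorities)
}

treeVotesMatrix <- function(model, featMat, seqIdx) {
  # counts[frame, class] of votes over all offsets and trees for one pair
  n <- length(seqIdx)
  counts <- matrix(0L, n, length(model@classes),
                   dimnames = list(NULL, model@classes))
  for (oi in seq_along(model@offsets)) {
    rows <- seqIdx[clampIdx(seq_len(n), model@offsets[oi], n)]
    X <- featMat[rows, , drop = FALSE]
    for (tr in model@trees[[oi]]) {
      v <- if (is.null(tr$fit)) rep(model@classes[1], n) else
        as.character(predict(tr$fit, X[, tr$vars, drop = FALSE],
                             type = "class"))
      ij <- cbind(seq_len(n), match(v, model@classes))
      counts[ij] <- counts[ij] + 1L
    }
  }
  counts
}

modeWithPriority <- function(counts, classes, priorities) {
  prio <- priorities[classes]
  prio[is.na(prio)] <- max(priorities, 0L) + 1L
  ord <- order(prio, classes)
  countsOrd <- counts[, ord, drop = FALSE]
  classes[ord][max.col(countsOrd, ties.method = "first")]
}

#' Votes of the forest for one frame
#'
#' Returns the full multiset of \code{(2w+1) * N} class votes for frame
#' \code{t} of one pair's feature sequence: the offset-\code{delta} trees
#' are evaluated on the feature vector of frame \code{t + delta} (clamped at
#' the sequence edges).
#'
#' @param model a \linkS4class{TemporalForest}.
#' @param features feature table of a single ordered pair.
#' @param t frame number (must appear in \code{features$frame}).
#' @return Character vector of votes.
#' @export
temporalForestVotes <- function(model, features, t) {
  ord <- order(features$frame)
  features <- features[ord, ]
  i <- match(t, features$frame)
  if (is.na(i)) stop("frame ", t, " not present in the feature sequence")
  n <- nrow(features)
  votes <- character(0)
  for (oi in seq_along(model@offsets)) {
    x <- features[clampIdx(i, model@offsets[oi], n), model@featNames,
                  drop = FALSE]
    for (tr in model@trees[[oi]]) {
      v <- if (is.null(tr$fit)) model@classes[1] else
        as.character(predict(tr$fit, x[, tr$vars, drop = FALSE],
                             type = "class"))
      votes <- c(votes, v)
    }
  }
  votes
}

#' Classify one frame
#'
#' The label is the mode of the windowed votes; ties are broken by the
#' behaviour priority table, then lexicographically.
#'
#' @inheritParams temporalForestVotes
#' @return A single behaviour label.
#' @export
classifyFrame <- function(model, features, t) {
  v <- temporalForestVotes(model, features, t)
  counts <- matrix(tabulate(match(v, model@classes),
                            nbins = length(model@classes)), 1,
                   dimnames = list(NULL, model@classes))
  modeWithPriority(counts, model@classes, model@priorities)
}

#' Classify every frame of one or more pair sequences
#'
#' Sliding-window classification with edge clamping; each ordered pair in
#' the table is classified independently (the model transfers across
#' pairs).
#'
#' @param model a \linkS4class{TemporalForest}.
#' @param features feature table with \code{frame, ref_id, target_id} and
#'   the model's feature columns.
#' @return data.frame \code{frame, ref_id, target_id, label}, one row per
#'   input row.
#' @export
classifySequence <- function(model, features) {
  featMat <- features[, model@featNames, drop = FALSE]
  seqs <- splitPairs(features)
  out <- lapply(seqs, function(ix) {
    counts <- treeVotesMatrix(model, featMat, ix)
    data.frame(frame = features$frame[ix],
               ref_id = features$ref_id[ix],
               target_id = features$target_id[ix],
               label = modeWithPriority(counts, model@classes,
                                        model@priorities))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$ref_id, res$target_id), ]
  rownames(res) <- NULL
  res
}

#' Persist / restore a fitted Temporal Random Forest
#'
#' The archive is a versioned list holding the configuration and the
#' serialized trees.
#'
#' @param model a \linkS4class{TemporalForest}.
#' @param path file path (.rds).
#' @return \code{path} invisibly / the restored model.
#' @export
saveTemporalForest <- function(model, path) {
  saveRDS(list(format = "thermotrack-forest", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname saveTemporalForest
#' @export
loadTemporalForest <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "thermotrack-forest"))
    stop("not a thermotrack forest archive: ", path)
  x$model
}
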