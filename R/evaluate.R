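# Evaluation: frame-by-frame agreement (full vocabulary and the
# social/non-social grouping), per-group precision, total-duration
# differences, contiguous k-fold splits, and tracking-identity metrics
# against simulator ground truth.

#' Social / non-social meta-class map
#'
#' Nose2Body, Nose2Nose, Nose2Genitals, Above and Following are social;
#' WalkAlone and StandAlone are non-social. The status of StandTogether is
#' arguable, so it is assigned by argument: \code{"nonsocial"} (default,
#' used for agreement metrics), \code{"social"}, or \code{"separate"} (its
#' own bucket, for aggregate summaries).
#'
#' @param standTogether one of "nonsocial", "social", "separate".
#' @return Named character vector mapping class -> "social" / "nonsocial" /
#'   "standtogether".
#' @export
socialMap <- function(standTogether = c("nonsocial", "social", "separate")) {
  standTogether <- match.arg(standTogether)
  m <- c(Nose2Body = "social", Nose2Nose = "social",
         Nose2Genitals = "social", Above = "social", Following = "social",
         WalkAlone = "nonsocial", StandAlone = "nonsocial",
         StandTogether = switch(standTogether, nonsocial = "nonsocial",
                                social = "social",
                                separate = "standtogether"))
  m
}

#' Frame-by-frame agreement between two label tracks
#'
#' Frames where either track is \code{"unknown"} are excluded pairwise.
#' \code{acc_full} is the percentage of frames with identical class over the
#' full vocabulary; \code{acc_soc_vs_nsoc} the percentage agreeing after
#' grouping into social/non-social meta-classes. Precision treats the named
#' group as positive: \code{prec_soc = TP / (TP + FP)} with social positive,
#' \code{prec_nsoc} analogously with non-social positive.
#'
#' @param pred,truth character vectors of equal length.
#' @param social a \code{\link{socialMap}}.
#' @return A list with \code{acc_full}, \code{acc_soc_vs_nsoc},
#'   \code{prec_soc}, \code{prec_nsoc} (all percentages), \code{n} (frames
#'   compared) and \code{confusion} (full class confusion matrix, truth in
#'   rows).
#' @export
frameAgreement <- function(pred, truth, social = socialMap()) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length")
  keep <- pred != "unknown" & truth != "unknown"
  pred <- pred[keep]; truth <- truth[keep]
  lev <- union(names(social), union(unique(pred), unique(truth)))
  conf <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  accFull <- 100 * mean(pred == truth)
  gp <- social[pred]; gt <- social[truth]
  accG <- 100 * mean(gp == gt)
  precOf <- function(pos) {
    tp <- sum(gp == pos & gt == pos)
    fp <- sum(gp == pos & gt != pos)
    if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  }
  list(acc_full = accFull, acc_soc_vs_nsoc = accG,
       prec_soc = precOf("social"), prec_nsoc = precOf("nonsocial"),
       n = length(pred), confusion = conf)
}

#' Total-duration differences between two label tracks
#'
#' Absolute differences between the total time each behaviour (and each
#' social/non-social group) occupies in the two tracks, in seconds and as a
#' percentage of the video length. Unknown frames are excluded pairwise.
#'
#' @param pred,truth character label vectors of equal length.
#' @param period seconds per frame.
#' @param social a \code{\link{socialMap}}.
#' @return A list with \code{per_class} (data.frame class, seconds,
#'   percent), \code{social}, \code{nonsocial} (each c(seconds, percent))
#'   and \code{video_seconds}.
#' @export
durationDifference <- function(pred, truth, period = 1 / 30,
                               social = socialMap()) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length")
  keep <- pred != "unknown" & truth != "unknown"
  pred <- pred[keep]; truth <- truth[keep]
  tot <- length(pred) * period
  lev <- union(names(social), union(unique(pred), unique(truth)))
  dsec <- vapply(lev, function(cl)
    abs(sum(pred == cl) - sum(truth == cl)) * period, numeric(1))
  grp <- function(g) {
    cls <- names(social)[social == g]
    abs(sum(pred %in% cls) - sum(truth %in% cls)) * period
  }
  soc <- grp("social"); nsoc <- grp("nonsocial")
  list(per_class = data.frame(class = lev, seconds = unname(dsec),
                              percent = unname(100 * dsec / tot)),
       social = c(seconds = soc, percent = 100 * soc / tot),
       nonsocial = c(seconds = nsoc, percent = 100 * nsoc / tot),
       video_seconds = tot)
}

#' Contiguous k-fold partition
#'
#' Splits \code{1:n} into k contiguous, disjoint, exhaustive test blocks
#' (sizes differing by at most one frame), leaving the frame ordering
#' intact; the training set of each fold is the complement.
#'
#' @param n number of frames.
#' @param k number of folds (default 3).
#' @return A list of k lists with 1-based integer vectors \code{train} and
#'   \code{test}.
#' @export
contiguousKFold <- function(n, k = 3L) {
  if (k > n) stop("more folds than frames")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- starts[i]:ends[i]
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Tracking-identity agreement against ground truth
#'
#' For every frame where all mice are tracked, the tracked centroids are
#' matched to the ground-truth centroids by greedy minimum distance. The
#' reference mapping is the one of the first tracked frame;
#' \code{agreement} is the fraction of frames whose mapping equals it, and
#' \code{switches} counts frames whose mapping differs from the previous
#' tracked frame's (identity-switch events).
#'
#' @param tracks a \linkS4class{MouseTracks}.
#' @param scenario a \code{thermalScenario} (or its ground-truth pose
#'   data.frame).
#' @return A list with \code{agreement}, \code{switches}, \code{n_frames}
#'   and \code{per_frame} (data.frame frame, mapping as a collapsed string,
#'   match flag).
#' @export
trackingAgreement <- function(tracks, scenario) {
  truth <- if (is.data.frame(scenario)) scenario else scenario$poses
  d <- poses(tracks)
  d <- d[d$flag == "ok", ]
  frames <- sort(unique(d$frame))
  nM <- trackedMice(tracks)
  maps <- character(length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    dt <- d[d$frame == f, ]
    dt <- dt[order(dt$mouse_id), ]
    gt <- truth[truth$frame == f, ]
    gt <- gt[order(gt$mouse_id), ]
    costs <- outer(seq_len(nM), seq_len(nM), Vectorize(function(i, j)
      sqrt((dt$centroid_x[i] - gt$centroid_x[j])^2 +
           (dt$centroid_y[i] - gt$centroid_y[j])^2)))
    maps[fi] <- paste(greedyAssign(costs), collapse = ",")
  }
  agreement <- mean(maps == maps[1])
  switches <- sum(maps[-1] != maps[-length(maps)])
  list(agreement = agreement, switches = switches,
       n_frames = length(frames),
       per_frame = data.frame(frame = frames, mapping = maps,
                              match = maps == maps[1]))
}
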