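# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately re-derive results by different means than the
# package code paths they check.

# ---- set-based binary morphology (oracle for the opening) -----------------

shiftMask <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  ok_y <- ys >= 1 & ys <= nr; ok_x <- xs >= 1 & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

# erosion/dilation with a structuring element given as (dy, dx) offsets
setErode <- function(m, offs) {
  Reduce(`&`, lapply(seq_len(nrow(offs)), function(i)
    shiftMask(m, -offs[i, 1], -offs[i, 2])))
}

setDilate <- function(m, offs) {
  Reduce(`|`, lapply(seq_len(nrow(offs)), function(i)
    shiftMask(m, offs[i, 1], offs[i, 2])))
}

setOpen <- function(m, offs) setDilate(setErode(m, offs), offs)

lineOffsets <- function(len, angle) {
  r <- -(len %/% 2):(len %/% 2)
  switch(as.character(angle),
         "0" = cbind(0L, r),
         "90" = cbind(r, 0L),
         "45" = cbind(r, r))
}

oracleOpening <- function(m) {
  Reduce(`|`, lapply(c(0, 45, 90), function(a) setOpen(m, lineOffsets(5, a))))
}

# ---- recursive flood fill (oracle for 8-connected labeling) ---------------

oracleFlood8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        y <- p[1] + dy; x <- p[2] + dx
        if (y >= 1 && y <= nr && x >= 1 && x <= nc &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
  }
  lab
}

# ---- assignment oracles ---------------------------------------------------

# naive global-min-first greedy, written as explicit nested scans
oracleGreedy <- function(costs) {
  n <- nrow(costs)
  perm <- integer(n)
  usedR <- logical(n); usedC <- logical(n)
  for (step in seq_len(n)) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(n)) {
      if (usedR[i]) next
      for (j in seq_len(n)) {
        if (usedC[j]) next
        if (costs[i, j] < best) { best <- costs[i, j]; bi <- i; bj <- j }
      }
    }
    perm[bi] <- bj; usedR[bi] <- TRUE; usedC[bj] <- TRUE
  }
  perm
}

# exhaustive minimum-total-cost assignment (n <= 5)
oracleHungarian <- function(costs) {
  n <- nrow(costs)
  perms <- permuteAll(seq_len(n))
  tot <- vapply(perms, function(p) sum(costs[cbind(seq_len(n), p)]),
                numeric(1))
  perms[[which.min(tot)]]
}

permuteAll <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permuteAll(v[-i]), function(p) c(v[i], p)))
  out
}

# whether the greedy choice sequence is unique at every step
greedyUnique <- function(costs) {
  n <- nrow(costs)
  usedR <- logical(n); usedC <- logical(n)
  for (step in seq_len(n)) {
    sub <- costs[!usedR, !usedC, drop = FALSE]
    if (sum(sub == min(sub)) > 1L) return(FALSE)
    hit <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    usedR[which(!usedR)[hit[1]]] <- TRUE
    usedC[which(!usedC)[hit[2]]] <- TRUE
  }
  TRUE
}

# ---- pose / scenario helpers ----------------------------------------------

makePose <- function(id, nose, gen, cen = (nose + gen) / 2,
                     len = sqrt(sum((nose - gen)^2)), hu1 = 0.25,
                     area = 220) {
  data.frame(mouse_id = id, nose_x = nose[1], nose_y = nose[2],
             genitals_x = gen[1], genitals_y = gen[2],
             centroid_x = cen[1], centroid_y = cen[2], length = len,
             hu1 = hu1, area = area)
}

# map tracked mouse ids onto ground-truth ids via the first frame, then
# return per-row keypoint/centroid errors against the scenario ground truth
trackErrors <- function(tracks, scenario) {
  ag <- trackingAgreement(tracks, scenario)
  map <- as.integer(strsplit(ag$per_frame$mapping[1], ",")[[1]])
  d <- poses(tracks)
  okd <- d[d$flag == "ok", ]
  okd$gt_id <- map[okd$mouse_id]
  mrg <- merge(okd, scenario$poses, by.x = c("frame", "gt_id"),
               by.y = c("frame", "mouse_id"), suffixes = c("", ".gt"))
  mrg$cerr <- sqrt((mrg$centroid_x - mrg$centroid_x.gt)^2 +
                     (mrg$centroid_y - mrg$centroid_y.gt)^2)
  mrg$nerr <- sqrt((mrg$nose_x - mrg$nose_x.gt)^2 +
                     (mrg$nose_y - mrg$nose_y.gt)^2)
  mrg$gerr <- sqrt((mrg$genitals_x - mrg$genitals_x.gt)^2 +
                     (mrg$genitals_y - mrg$genitals_y.gt)^2)
  list(agreement = ag$agreement, switches = ag$switches, rows = mrg)
}

# ---- synthetic pair-feature sequences (for classifier tests) ---------------

# class-conditional feature means with iid per-frame Gaussian noise; one
# ordered pair, contiguous behaviour segments
simFeatureSequence <- function(labels, noise_sd = 3, seed = 1,
                               pair = c(1L, 2L)) {
  cls <- c("Nose2Nose", "Following", "WalkAlone", "StandAlone")
  stopifnot(all(labels %in% cls))
  fn <- featureNames()
  mu <- outer(match(labels, cls), seq_along(fn),
              function(k, j) 4 * ((k * j) %% 4))
  withr::with_seed(seed, {
    X <- mu + matrix(stats::rnorm(length(labels) * length(fn), 0, noise_sd),
                     nrow = length(labels))
  })
  colnames(X) <- fn
  data.frame(frame = seq_along(labels) - 1L, ref_id = pair[1],
             target_id = pair[2], X)
}

segmentLabels <- function(nseg, seg_len, seed = 1) {
  cls <- c("Nose2Nose", "Following", "WalkAlone", "StandAlone")
  withr::with_seed(seed, {
    labs <- character(nseg)
    labs[1] <- sample(cls, 1)
    for (i in seq_len(nseg)[-1])
      labs[i] <- sample(setdiff(cls, labs[i - 1]), 1)
  })
  rep(labs, each = seg_len)
}
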