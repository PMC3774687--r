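# Identity preservation: greedy distance matching frame to frame, a
# Hu-moment shape sanity check that flags mistracking, and heat-signature
# re-identification with the two-sample Kolmogorov-Smirnov statistic.

#' Distance matrix between two pose sets
#'
#' Entry (i, j) is the Euclidean distance between the 6-D position vectors
#' (nose, genitals, centroid) of previous mouse i and current shape j.
#'
#' @param prevPoses,curPoses pose data.frames with equal row counts.
#' @return A square numeric cost matrix.
#' @export
distanceMatrix <- function(prevPoses, curPoses) {
  if (nrow(prevPoses) != nrow(curPoses))
    stop("pose counts differ between frames")
  zc <- c("nose_x", "nose_y", "genitals_x", "genitals_y",
          "centroid_x", "centroid_y")
  a <- as.matrix(prevPoses[, zc])
  b <- as.matrix(curPoses[, zc])
  m <- nrow(a)
  outer(seq_len(m), seq_len(m),
        Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
}

#' Greedy minimum-distance assignment
#'
#' Repeatedly selects the globally smallest remaining cost entry, fixes that
#' (row, column) pair, and deletes its row and column until every row is
#' assigned. Ties are broken by the smallest row index, then the smallest
#' column index. This is the fast approximation of the optimal (Hungarian)
#' assignment used for frame-to-frame identity matching; the two agree
#' whenever the greedy choice sequence is unambiguous.
#'
#' @param costs square numeric matrix of finite non-negative costs.
#' @return An integer permutation \code{p}: row (identity) \code{i} is
#'   assigned to column (shape) \code{p[i]}.
#' @export
greedyAssign <- function(costs) {
  stopifnot(is.matrix(costs), nrow(costs) == ncol(costs),
            all(is.finite(costs)))
  n <- nrow(costs)
  perm <- integer(n)
  rowsLeft <- rep(TRUE, n); colsLeft <- rep(TRUE, n)
  for (k in seq_len(n)) {
    sub <- costs[rowsLeft, colsLeft, drop = FALSE]
    best <- min(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    # smallest row index first, then smallest column index
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    ri <- which(rowsLeft)[hit[1]]
    ci <- which(colsLeft)[hit[2]]
    perm[ri] <- ci
    rowsLeft[ri] <- FALSE; colsLeft[ci] <- FALSE
  }
  perm
}

#' Fit the baseline shape distribution
#'
#' Fits a Student-t location-scale model to the record of first Hu moments
#' of all accepted shapes, by maximum likelihood with a moment-based
#' fallback when the likelihood fit fails to converge.
#'
#' @param hu1record numeric vector of accepted hu1 values.
#' @return A list with \code{m}, \code{s}, \code{df} and \code{n}.
#' @export
fitShapeModel <- function(hu1record) {
  x <- hu1record[is.finite(hu1record)]
  n <- length(x)
  if (n < 2L) stop("need at least two accepted shapes to fit")
  fallback <- list(m = mean(x), s = max(stats::sd(x), 1e-12), df = 30,
                   n = n)
  fit <- tryCatch({
    suppressWarnings({
      f <- MASS::fitdistr(x, "t",
                          start = list(m = stats::median(x),
                                       s = max(stats::mad(x), 1e-6),
                                       df = 5),
                          lower = c(-Inf, 1e-9, 1))
      list(m = unname(f$estimate["m"]), s = unname(f$estimate["s"]),
           df = unname(f$estimate["df"]), n = n)
    })
  }, error = function(e) fallback)
  fit
}

#' Hu-moment shape sanity check
#'
#' Flags a mouse when the two-sided tail probability of its current hu1
#' under the fitted baseline Student-t distribution falls below
#' \code{alpha}; the global misdetection state (which triggers the switch to
#' heat-signature matching) is raised only when two or more mice are flagged
#' in the same frame. With no fitted model (cold start) all flags are FALSE.
#'
#' @param model a fitted shape model from \code{\link{fitShapeModel}}, or
#'   \code{NULL} during the cold start.
#' @param hu1 numeric vector of current per-mouse hu1 values.
#' @param alpha significance level.
#' @return A list with \code{flags} (logical per mouse), \code{global}
#'   (TRUE iff >= 2 flags) and \code{p} (tail probabilities).
#' @export
shapeSanityCheck <- function(model, hu1, alpha = 0.01) {
  if (is.null(model))
    return(list(flags = rep(FALSE, length(hu1)), global = FALSE,
                p = rep(NA_real_, length(hu1))))
  p <- 2 * stats::pt(-abs((hu1 - model$m) / model$s), df = model$df)
  flags <- is.finite(p) & p < alpha
  list(flags = flags, global = sum(flags) >= 2L, p = p)
}

#' Heat signatures: per-mouse temperature-sample buffers
#'
#' A heat signature is the empirical distribution of the temperature samples
#' collected inside one mouse's segmented shape over the last
#' \code{buffer_frames} frames (about 0.3 s of video by default). Signatures
#' are updated only from accepted (unflagged) frames.
#'
#' @param n_mice number of mice.
#' @param buffer_frames buffer length B in frames.
#' @return An empty signature store.
#' @export
heatSignatures <- function(n_mice, buffer_frames = 9) {
  structure(list(frames = rep(list(list()), n_mice),
                 B = as.integer(buffer_frames)),
            class = "heatSignatures")
}

#' @rdname heatSignatures
#' @param signatures a signature store.
#' @param samples list (per mouse) of this frame's in-shape temperature
#'   samples.
#' @return The updated store; each buffer spans at most B frames, oldest
#'   evicted first.
#' @export
updateHeatSignatures <- function(signatures, samples) {
  for (i in seq_along(samples)) {
    buf <- c(signatures$frames[[i]], list(samples[[i]]))
    if (length(buf) > signatures$B)
      buf <- buf[(length(buf) - signatures$B + 1L):length(buf)]
    signatures$frames[[i]] <- buf
  }
  signatures
}

#' @rdname heatSignatures
#' @export
signatureSamples <- function(signatures) {
  lapply(signatures$frames, function(b) as.numeric(unlist(b)))
}

# two-sample Kolmogorov-Smirnov statistic (distribution-free; used directly
# as a cost, p-values are never needed)
ksStatistic <- function(x, y) {
  suppressWarnings(unname(stats::ks.test(x, y)$statistic))
}

#' Heat-signature identity assignment
#'
#' Builds a cost matrix of two-sample Kolmogorov-Smirnov statistics between
#' each stored signature and each current shape's temperature samples, then
#' resolves identities with the same greedy minimum-cost search used for
#' distance matching. Empty current shapes receive a sentinel cost above the
#' KS maximum of 1.
#'
#' @param curSamples list of temperature-sample vectors, one per current
#'   shape.
#' @param signatures a \code{\link{heatSignatures}} store with non-empty
#'   buffers.
#' @return An integer permutation as in \code{\link{greedyAssign}}, with the
#'   cost matrix attached as attribute \code{"costs"}.
#' @export
heatAssign <- function(curSamples, signatures) {
  sig <- signatureSamples(signatures)
  if (any(vapply(sig, length, integer(1)) == 0L))
    stop("heat signatures are empty; track more frames first")
  m <- length(sig)
  costs <- matrix(0, m, m)
  for (j in seq_len(m)) {
    if (length(curSamples[[j]]) == 0L) {
      costs[, j] <- 2  # sentinel above the KS maximum
      next
    }
    for (i in seq_len(m))
      costs[i, j] <- ksStatistic(sig[[i]], curSamples[[j]])
  }
  perm <- greedyAssign(costs)
  attr(perm, "costs") <- costs
  perm
}
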