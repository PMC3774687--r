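# Collapsing the M-1 pairwise labels of each mouse at each frame into a
# single behaviour by a priority table, and summarising label tracks into
# per-class durations (the ethogram).

#' Behaviour priority table
#'
#' Maps each class to an integer priority (1 = highest). When a mouse's
#' pairwise classifications disagree, the label with the smallest priority
#' number wins: contact behaviours dominate locomotion and rest (so a mouse
#' sniffing one conspecific while ignoring another is "Nose2Body", not
#' "StandAlone"). Fully overridable.
#'
#' @param order character vector of classes from highest to lowest priority.
#' @return Named integer vector of priorities.
#' @export
priorityTable <- function(order = c("Above", "Nose2Genitals", "Nose2Nose",
                                    "Nose2Body", "Following",
                                    "StandTogether", "WalkAlone",
                                    "StandAlone")) {
  stopifnot(!anyDuplicated(order))
  stats::setNames(seq_along(order), order)
}

#' Combine the pairwise labels of one mouse at one frame
#'
#' @param labels character vector of pairwise labels (mouse vs each
#'   conspecific); must be non-empty. \code{"unknown"} entries are ignored
#'   unless all entries are unknown.
#' @param table a \code{\link{priorityTable}}.
#' @return The highest-priority label.
#' @export
combineMouse <- function(labels, table = priorityTable()) {
  if (length(labels) == 0L)
    stop("combineMouse requires at least one pairwise label (M >= 2)")
  known <- labels[labels != "unknown"]
  if (length(known) == 0L) return("unknown")
  bad <- setdiff(known, names(table))
  if (length(bad)) stop("labels missing from the priority table: ",
                        paste(bad, collapse = ", "))
  known[which.min(table[known])]
}

#' Build the per-mouse ethogram and duration summary
#'
#' Collapses per-pair label tracks to one label per mouse per frame, filling
#' frames absent from the tracks (flagged during tracking) with
#' \code{"unknown"}, and summarises the total time spent in each behaviour.
#' Unknown frames are excluded from the per-class durations and reported
#' separately; per mouse, class durations plus the unknown duration always
#' sum exactly to the video length.
#'
#' @param pairLabels data.frame \code{frame, ref_id, target_id, label} (from
#'   \code{\link{classifySequence}} or an annotation file).
#' @param table a \code{\link{priorityTable}}.
#' @param nframes total number of video frames; defaults to
#'   \code{max(frame) + 1}.
#' @param period seconds per frame.
#' @return A list with \code{ethogram} (data.frame
#'   \code{frame, mouse_id, label}) and \code{durations} (data.frame
#'   \code{mouse_id, class, frames, seconds, occurrences}; class includes
#'   \code{"unknown"}; occurrences counts bouts of consecutive frames).
#'   Per mouse the \code{frames} column sums to \code{nframes} exactly
#'   (duration conservation at the integer frame level).
#' @export
buildEthogram <- function(pairLabels, table = priorityTable(),
                          nframes = NULL, period = 1 / 30) {
  if (is.null(nframes)) nframes <- max(pairLabels$frame) + 1L
  if (any(pairLabels$frame < 0L | pairLabels$frame >= nframes))
    stop("pair labels reference frames outside 0:(nframes-1)")
  mice <- sort(unique(pairLabels$ref_id))
  classes <- union(names(table), "unknown")
  eth <- vector("list", length(mice))
  dur <- vector("list", length(mice))
  for (mi in seq_along(mice)) {
    mlab <- pairLabels[pairLabels$ref_id == mice[mi], ]
    byFrame <- vapply(split(mlab$label, mlab$frame), combineMouse,
                      character(1), table = table)
    lab <- rep("unknown", nframes)
    lab[as.integer(names(byFrame)) + 1L] <- byFrame
    eth[[mi]] <- data.frame(frame = 0:(nframes - 1L), mouse_id = mice[mi],
                            label = lab)
    counts <- table(factor(lab, levels = classes))
    r <- rle(lab)
    occ <- table(factor(r$values, levels = classes))
    dur[[mi]] <- data.frame(mouse_id = mice[mi], class = classes,
                            frames = as.integer(counts),
                            seconds = as.numeric(counts) * period,
                            occurrences = as.integer(occ))
  }
  list(ethogram = do.call(rbind, eth), durations = do.call(rbind, dur))
}

#' Write ethogram / duration tables
#'
#' @param ethogram result of \code{\link{buildEthogram}}.
#' @param eth_path,dur_path output CSV paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
writeEthogram <- function(ethogram, eth_path = NULL, dur_path = NULL) {
  if (!is.null(eth_path))
    utils::write.csv(ethogram$ethogram, eth_path, row.names = FALSE)
  if (!is.null(dur_path))
    utils::write.csv(ethogram$durations, dur_path, row.names = FALSE)
  invisible(c(eth_path, dur_path))
}
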