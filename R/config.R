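# Configuration constructors. Every tunable of the pipeline lives here with
# its default; readTrackerConfig() merges a key-value YAML file over these.

#' Blob-detection configuration
#'
#' @param n_mice expected number of mice in the arena (M).
#' @param min_mouse_area expected size of the smallest mouse, px^2.
#' @param init_window number of consecutive frames over which the foreground
#'   threshold condition must hold during initialisation.
#' @param opening_length length (px, odd) of the linear structuring elements
#'   (applied at 0, 45 and 90 degrees) used to remove tails.
#' @param area_upper_factor the total foreground area must not exceed
#'   \code{n_mice * area_upper_factor * min_mouse_area}.
#' @param max_dilations cap on corrective 3x3 dilation iterations when more
#'   blobs than mice are found.
#' @param units_scale,units_offset linear map from raw image counts to
#'   temperature units: \code{units = counts * units_scale + units_offset}.
#' @return A list of class \code{detectionConfig}.
#' @export
detectionConfig <- function(n_mice, min_mouse_area = 120, init_window = 90,
                            opening_length = 5, area_upper_factor = 4,
                            max_dilations = 5, units_scale = 1,
                            units_offset = 0) {
  stopifnot(n_mice >= 1, min_mouse_area >= 1, init_window >= 1,
            opening_length %% 2 == 1, area_upper_factor > 1,
            max_dilations >= 0)
  structure(list(n_mice = as.integer(n_mice),
                 min_mouse_area = min_mouse_area,
                 init_window = as.integer(init_window),
                 opening_length = as.integer(opening_length),
                 area_upper_factor = area_upper_factor,
                 max_dilations = as.integer(max_dilations),
                 units_scale = units_scale, units_offset = units_offset),
            class = "detectionConfig")
}

#' Temporal-watershed configuration
#'
#' @param history_window frames over which the major-axis length is averaged
#'   when building seeds.
#' @param slack constant (px) subtracted from the smoothed length so the seed
#'   stays inside the body despite inter-frame displacement and non-rigid
#'   length changes.
#' @param max_em_iters cap on EM iterations per frame.
#' @param convergence_tol EM stops when the fraction of shape pixels that
#'   changed owner between iterations falls below this value.
#' @param vote_window number of recent frames (k) pooled by the
#'   nose/genitals orientation vote.
#' @param bg_erode_iters 3x3 erosion iterations applied to the inverted
#'   foreground when building the background seed.
#' @param min_move displacements below this norm (px) contribute zero to the
#'   orientation vote (tracking jitter of a stationary mouse carries no
#'   directional information).
#' @return A list of class \code{watershedConfig}.
#' @export
watershedConfig <- function(history_window = 10, slack = 6, max_em_iters = 10,
                            convergence_tol = 0.01, vote_window = 10,
                            bg_erode_iters = 2, min_move = 0.5) {
  stopifnot(history_window >= 1, slack >= 0, max_em_iters >= 1,
            convergence_tol > 0, convergence_tol < 1, vote_window >= 2,
            bg_erode_iters >= 0, min_move >= 0)
  structure(list(history_window = as.integer(history_window), slack = slack,
                 max_em_iters = as.integer(max_em_iters),
                 convergence_tol = convergence_tol,
                 vote_window = as.integer(vote_window),
                 bg_erode_iters = as.integer(bg_erode_iters),
                 min_move = min_move),
            class = "watershedConfig")
}

#' Identity-matching configuration
#'
#' @param buffer_frames length B of the heat-signature buffer in frames
#'   (default 9, about 0.3 s at 30 fps).
#' @param alpha significance level of the Hu-moment shape sanity check.
#' @param min_shape_history accepted shapes required before the sanity check
#'   activates (all flags stay FALSE during the cold start).
#' @param refit_every the Student-t shape model is refitted every this many
#'   accepted frames.
#' @param joint_fit fit one baseline shape distribution over all mice
#'   (default) rather than one per mouse.
#' @return A list of class \code{matchingConfig}.
#' @export
matchingConfig <- function(buffer_frames = 9, alpha = 0.01,
                           min_shape_history = 100, refit_every = 100,
                           joint_fit = TRUE) {
  stopifnot(buffer_frames >= 1, alpha > 0, alpha < 1, min_shape_history >= 2,
            refit_every >= 1)
  structure(list(buffer_frames = as.integer(buffer_frames), alpha = alpha,
                 min_shape_history = as.integer(min_shape_history),
                 refit_every = as.integer(refit_every),
                 joint_fit = isTRUE(joint_fit)),
            class = "matchingConfig")
}

#' Temporal Random Forest configuration
#'
#' @param n_trees trees per temporal offset (N).
#' @param window window radius in frames (w); trees exist for every offset in
#'   \code{-w:w}, so the forest holds \code{(2w+1) * n_trees} trees and casts
#'   that many votes per frame.
#' @param subspace_dim number of features (d) in each tree's random subspace.
#' @param seed RNG seed controlling subspaces and bootstrap draws.
#' @param bootstrap draw a bootstrap resample of the training rows for each
#'   tree (bagging).
#' @param per_split draw a fresh random subspace at every split instead of
#'   once per tree.
#' @param balanced_bootstrap equalise class frequencies in each bootstrap
#'   draw (off by default: rare classes are left rare, and degrade, as they
#'   do in practice).
#' @return A list of class \code{forestConfig}.
#' @export
forestConfig <- function(n_trees = 5, window = 15, subspace_dim = 4,
                         seed = 1, bootstrap = TRUE, per_split = FALSE,
                         balanced_bootstrap = FALSE) {
  stopifnot(n_trees >= 1, window >= 0, subspace_dim >= 1)
  structure(list(n_trees = as.integer(n_trees), window = as.integer(window),
                 subspace_dim = as.integer(subspace_dim),
                 seed = as.integer(seed), bootstrap = isTRUE(bootstrap),
                 per_split = isTRUE(per_split),
                 balanced_bootstrap = isTRUE(balanced_bootstrap)),
            class = "forestConfig")
}

#' Read a key-value configuration file
#'
#' The YAML file may contain any subset of the keys accepted by
#' \code{\link{detectionConfig}}, \code{\link{watershedConfig}},
#' \code{\link{matchingConfig}} and \code{\link{forestConfig}}, either flat
#' or grouped under \code{detection:}, \code{watershed:}, \code{matching:},
#' \code{forest:} headings. Values present in the file override the package
#' defaults.
#'
#' @param path path to a YAML file.
#' @param n_mice expected mouse count (required by the detection block if the
#'   file does not provide it).
#' @return A list with elements \code{detection}, \code{watershed},
#'   \code{matching}, \code{forest}.
#' @export
readTrackerConfig <- function(path, n_mice = NULL) {
  if (!file.exists(path)) stop("thermotrack_missing_path: ", path)
  raw <- yaml::read_yaml(path)
  grab <- function(group, fn, extra = list()) {
    keys <- names(formals(fn))
    vals <- raw[[group]]
    if (is.null(vals)) vals <- list()
    flat <- raw[intersect(names(raw), keys)]
    vals <- utils::modifyList(flat, vals)
    vals <- vals[intersect(names(vals), keys)]
    do.call(fn, utils::modifyList(extra, vals))
  }
  nm <- if (!is.null(raw$n_mice)) raw$n_mice else n_mice
  if (is.null(nm)) stop("n_mice must be given in the file or as an argument")
  list(detection = grab("detection", detectionConfig, list(n_mice = nm)),
       watershed = grab("watershed", watershedConfig),
       matching = grab("matching", matchingConfig),
       forest = grab("forest", forestConfig))
}

# ---- internal coordinate helpers ------------------------------------------

# linear indices (column-major, 1-based) -> 0-based (x, y) pixel coords
linToXY <- function(idx, nr) {
  cbind(x = (idx - 1L) %/% nr, y = (idx - 1L) %% nr)
}

# 0-based (x, y) -> linear index; no bounds check
xyToLin <- function(x, y, nr) {
  as.integer(round(y)) + 1L + as.integer(round(x)) * nr
}

clampNum <- function(v, lo, hi) pmin(pmax(v, lo), hi)
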