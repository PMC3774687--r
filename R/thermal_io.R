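# Reading and writing thermal frame stacks and the tracking / annotation
# tables. Raw 16-bit image counts are mapped to temperature units by the
# linear scale of detectionConfig (units = counts * scale + offset); the
# default scale of 1 keeps units equal to counts.

frameExt <- c("png", "pgm", "tif", "tiff")

#' Read a thermal video
#'
#' Accepts either a multi-page 16-bit grayscale TIFF or a directory of
#' same-sized 16-bit PNG/PGM frames, taken in lexicographic filename order.
#'
#' @param path file or directory path.
#' @param period seconds per frame (1/fps), default 1/30.
#' @param units_scale,units_offset linear map from image counts to
#'   temperature units.
#' @return A \linkS4class{ThermalVideo} with contiguous 0-based indices.
#' @export
readThermalVideo <- function(path, period = 1 / 30, units_scale = 1,
                             units_offset = 0) {
  if (!file.exists(path)) stop("thermotrack_missing_path: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[tolower(tools::file_ext(files)) %in% frameExt]
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L) stop("thermotrack_empty_video: ", path)
    frames <- unlist(lapply(files, readFrameFile), recursive = FALSE)
  } else {
    frames <- readFrameFile(path)
  }
  if (length(frames) == 0L) stop("thermotrack_empty_video: ", path)
  frames <- lapply(frames, function(f) f * units_scale + units_offset)
  thermalVideo(frames, period = period)
}

# one file -> list of count matrices
readFrameFile <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(file, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, toGray)
  } else if (ext == "png") {
    list(toGray(png::readPNG(file)) * 65535)
  } else if (ext == "pgm") {
    list(readPGM(file))
  } else {
    stop("unsupported frame format: ", file)
  }
}

toGray <- function(x) {
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  storage.mode(x) <- "double"
  x
}

#' Write a thermal video as a multi-page 16-bit TIFF
#'
#' @param video a \linkS4class{ThermalVideo}.
#' @param path output file path (.tif).
#' @param units_scale,units_offset inverse of the read-side map: counts =
#'   (units - offset) / scale, clamped to the 16-bit range.
#' @return \code{path}, invisibly.
#' @export
writeThermalVideo <- function(video, path, units_scale = 1,
                              units_offset = 0) {
  frames <- lapply(seq_len(nFrames(video)) - 1L, function(t) {
    counts <- round((getFrame(video, t) - units_offset) / units_scale)
    clampNum(counts, 0, 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

# Minimal PGM (P2 ascii / P5 binary) reader; 8- or 16-bit, 16-bit big-endian.
readPGM <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  tok <- pgmTokens(con, 4L)
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (magic == "P5") {
    size <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                    endian = "big")
  } else stop("not a PGM file: ", file)
  if (length(vals) != n) stop("truncated PGM file: ", file)
  matrix(as.double(vals), nrow = h, ncol = w, byrow = TRUE)
}

# read whitespace/comment-separated header tokens, leaving the connection at
# the first data byte
pgmTokens <- function(con, n) {
  tok <- character(0); cur <- ""
  while (length(tok) < n) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(cur)) { tok <- c(tok, cur); cur <- "" }
    } else cur <- paste0(cur, ch)
  }
  tok
}

#' Write a PGM frame (plain-text P2)
#'
#' @param frame numeric matrix of non-negative integer counts.
#' @param path output path.
#' @param maxval maximum sample value declared in the header.
#' @return \code{path}, invisibly.
#' @export
writePGM <- function(frame, path, maxval = 65535) {
  counts <- round(clampNum(frame, 0, maxval))
  lines <- c("P2", paste(ncol(frame), nrow(frame)), as.character(maxval),
             apply(counts, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

trackCols <- c("frame", "mouse_id", "nose_x", "nose_y", "genitals_x",
               "genitals_y", "centroid_x", "centroid_y", "length", "flag",
               "hu1", "area", "strategy")

#' Write a tracking table to CSV
#'
#' One row per mouse per frame, including frames skipped during
#' re-initialisation (flagged \code{"reinit"}, keypoints empty). Values
#' round-trip through \code{\link{readTracks}} to within 1e-6.
#'
#' @param tracks a \linkS4class{MouseTracks} or a pose data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  d <- if (is(tracks, "MouseTracks")) poses(tracks) else tracks
  for (cc in setdiff(trackCols, names(d))) d[[cc]] <- NA
  d <- d[, trackCols]
  ok <- tryCatch({ con <- file(path, "w"); close(con); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("thermotrack_unwritable_path: ", path)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tracking table written by \code{\link{writeTracks}}
#'
#' @param path CSV path.
#' @param period seconds per frame for the returned object.
#' @return A \linkS4class{MouseTracks}.
#' @export
readTracks <- function(path, period = 1 / 30) {
  if (!file.exists(path)) stop("thermotrack_missing_path: ", path)
  d <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  d$flag <- as.character(d$flag)
  mouseTracks(d, nMice = length(unique(d$mouse_id)), period = period)
}

#' Read / write per-frame behaviour annotations
#'
#' The annotation CSV has header \code{frame,ref_id,target_id,label}: one row
#' per ordered (reference, target) mouse pair per annotated frame.
#'
#' @param path CSV path.
#' @return \code{readAnnotations}: a data.frame with those four columns.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("thermotrack_missing_path: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "ref_id", "target_id", "label")
  if (!all(need %in% names(d)))
    stop("annotation file must have header frame,ref_id,target_id,label")
  d[, need]
}

#' @rdname readAnnotations
#' @param annotations data.frame with columns
#'   \code{frame, ref_id, target_id, label}.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("frame", "ref_id", "target_id", "label")],
                   path, row.names = FALSE)
  invisible(path)
}
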