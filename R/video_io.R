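#' Construct a frame sequence
#'
#' The universal video currency of the pipeline: an ordered list of
#' grayscale frames (integer intensities 0--255, stored as numeric
#' matrices with row 0 at the top of the image) together with a frame
#' rate.
#'
#' @param frames list of numeric matrices, all of identical dimensions,
#'   values in \[0, 255\].
#' @param fps frames per second (Hz, > 0).
#' @param t0 timestamp of frame 1 in seconds (default 0); frame i is at
#'   `t0 + (i - 1) / fps`.
#' @return an object of class `"frame_sequence"`.
#' @export
#' @examples
#' fs <- frame_sequence(list(matrix(128, 4, 4), matrix(64, 4, 4)), fps = 240)
#' length(fs$frames)
frame_sequence <- function(frames, fps, t0 = 0) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a matrix", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions", call. = FALSE)
  rng <- range(vapply(frames, function(f) range(f), numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number", call. = FALSE)
  structure(list(frames = frames, fps = fps, t0 = t0),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence: %d frames of %d x %d px, %.6g fps (%.3f s)\n",
              length(x$frames), d[1], d[2], x$fps,
              length(x$frames) / x$fps))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Frame timestamps
#' @param seq a `frame_sequence`.
#' @return numeric vector of per-frame times in seconds.
#' @export
frame_times <- function(seq) {
  seq$t0 + (seq_along(seq$frames) - 1) / seq$fps
}

# Rec.601 luma conversion of an H x W x 3 array on the 0-255 scale;
# idempotent on 2-D (already gray) input.
rgb_to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    if (nc == 1L) return(a[, , 1])
    # ignore an alpha channel if present
    g <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    return(round(g))
  }
  stop("unsupported image array shape", call. = FALSE)
}

read_image_gray <- function(path) {
  lower <- tolower(path)
  a <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (is.matrix(a)) round(a * 255) else rgb_to_gray(a * 255)
}

#' Load a video as a frame sequence
#'
#' Reads a directory of lexicographically ordered PNG/TIFF frames into a
#' [frame_sequence()]. Color frames are converted to grayscale with the
#' Rec.601 luma weighting `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer. The frame rate is taken from `fps_override`, or else
#' from a JSON sidecar `frames.json` (written by [save_frames()])
#' containing `{"fps": <number>}`.
#'
#' Compressed video containers (MP4/AVI) are not decoded by this
#' package; decode them to a lossless frame directory first.
#'
#' @param path directory of image frames.
#' @param fps_override frames per second, overriding any sidecar.
#' @return a `frame_sequence`.
#' @export
load_video <- function(path, fps_override = NULL) {
  if (!file.exists(path))
    stop("cannot read input: ", path, call. = FALSE)
  if (!dir.exists(path)) {
    if (grepl("\\.(mp4|avi|mov|mkv)$", tolower(path)))
      stop("video containers are not decoded by this package; ",
           "extract '", path, "' to a PNG/TIFF frame directory first",
           call. = FALSE)
    stop("cannot read input (expected a frame directory): ", path,
         call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("no image frames found in directory: ", path, call. = FALSE)
  fps <- fps_override
  sidecar <- file.path(path, "frames.json")
  if (is.null(fps) && file.exists(sidecar))
    fps <- jsonlite::read_json(sidecar)$fps
  if (is.null(fps))
    stop("frame directories require an fps (fps_override or frames.json ",
         "sidecar): ", path, call. = FALSE)
  frames <- lapply(files, read_image_gray)
  frame_sequence(frames, fps = as.numeric(fps))
}

#' Save a frame sequence as a lossless PNG directory
#'
#' Writes zero-padded-index PNG files plus a JSON sidecar `frames.json`
#' recording the frame rate, so that [load_video()] on the directory
#' round-trips the sequence bit-exactly.
#'
#' @param seq a `frame_sequence`.
#' @param path output directory (created if needed).
#' @return invisibly, a data frame manifest with columns `frame` and
#'   `file`.
#' @export
save_frames <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop("cannot create output directory: ", path, call. = FALSE)
  n <- length(seq$frames)
  width <- max(6L, nchar(n))
  files <- file.path(path, sprintf(paste0("frame_%0", width, "d.png"),
                                   seq_len(n)))
  for (i in seq_len(n))
    png::writePNG(seq$frames[[i]] / 255, files[i])
  jsonlite::write_json(list(fps = seq$fps, t0 = seq$t0, n_frames = n),
                       file.path(path, "frames.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(data.frame(frame = seq_len(n), file = files,
                       stringsAsFactors = FALSE))
}

# restrict a sequence to frames [from, to] (1-based, clamped)
subset_frames <- function(seq, from, to) {
  from <- max(1L, as.integer(from))
  to <- min(length(seq$frames), as.integer(to))
  frame_sequence(seq$frames[from:to], fps = seq$fps,
                 t0 = seq$t0 + (from - 1) / seq$fps)
}
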