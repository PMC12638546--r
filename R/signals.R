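#' Mean grayscale intensity profile
#'
#' The average pixel intensity of each frame. Because the skin, eyeball
#' and pupil differ in brightness, this profile changes continuously
#' while the lid sweeps over the eye: with bright skin covering a dark
#' eye, each blink appears as a peak.
#'
#' @param seq a [frame_sequence()].
#' @return an object of class `"intensity_profile"`: list with `values`
#'   (one mean per frame) and `fps`.
#' @export
mean_intensity_profile <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  structure(list(values = vapply(seq$frames, mean, numeric(1)),
                 fps = seq$fps),
            class = "intensity_profile")
}

#' Simulated dynamic-vision event profile
#'
#' Emulates an event camera from conventional frames: every pixel keeps
#' a reference brightness, initialized from frame 1; from frame 2 on, a
#' pixel whose current brightness differs from its reference by more
#' than `threshold` fires one (unsigned) event and resets its reference
#' to the current value. The procedure is strictly causal and
#' deterministic. Each blink produces two event bursts -- a taller,
#' narrower one while the lid closes and a flatter one while it opens.
#'
#' @param seq a [frame_sequence()].
#' @param threshold brightness-difference threshold (> 0, intensity
#'   units of 255).
#' @param downsample integer spatial downsampling factor applied before
#'   simulation (default 1, off); pixels are block-subsampled.
#' @param detail if TRUE, attach the per-pixel total event counts as
#'   element `per_pixel` (a matrix of the downsampled frame shape).
#' @return an object of class `"event_profile"`: list with `counts`
#'   (events per frame, `counts[1] == 0`), `threshold`, `fps`, and
#'   optionally `per_pixel`.
#' @export
simulate_events <- function(seq, threshold = 15, downsample = 1L,
                            detail = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single value > 0", call. = FALSE)
  pick <- function(f) {
    if (downsample > 1L)
      f <- f[seq(1, nrow(f), by = downsample),
             seq(1, ncol(f), by = downsample), drop = FALSE]
    f
  }
  ref <- pick(seq$frames[[1]])
  n <- length(seq$frames)
  counts <- integer(n)
  per_pixel <- if (detail) matrix(0L, nrow(ref), ncol(ref)) else NULL
  for (i in seq_len(n)[-1]) {
    cur <- pick(seq$frames[[i]])
    fire <- abs(cur - ref) > threshold
    counts[i] <- sum(fire)
    ref[fire] <- cur[fire]
    if (detail) per_pixel <- per_pixel + fire
  }
  structure(list(counts = counts, threshold = threshold, fps = seq$fps,
                 per_pixel = per_pixel),
            class = "event_profile")
}

#' Write the two signal profiles as CSV
#'
#' @param intensity an `intensity_profile`.
#' @param events an `event_profile` over the same frames.
#' @param path output CSV path; columns frame, time_s, mean_intensity,
#'   event_count.
#' @return invisibly, the written data frame.
#' @export
write_signals_csv <- function(intensity, events, path) {
  stopifnot(length(intensity$values) == length(events$counts))
  df <- data.frame(frame = seq_along(intensity$values),
                   time_s = (seq_along(intensity$values) - 1) /
                     intensity$fps,
                   mean_intensity = intensity$values,
                   event_count = events$counts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# centered moving average with edge shrinkage (window w frames)
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  half <- (w - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (w - 1L - half))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
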