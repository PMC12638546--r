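#' Blink trajectory specification
#'
#' Describes one blink as a sequence of trajectory segments: the eye is
#' held open for `pre_open_ms`, the upper eyelid descends over
#' `close_ms`, holds at `amplitude` of full closure for `closed_ms`,
#' rises over `open_ms`, and is held open for `post_open_ms`.
#'
#' @param pre_open_ms,close_ms,closed_ms,open_ms,post_open_ms segment
#'   durations in milliseconds (>= 0).
#' @param amplitude fraction of the full palpebral aperture traversed,
#'   in (0, 1]; 1 is complete closure (lid reaches the lower lid).
#' @param start_ms optional absolute start time (ms) of the closing
#'   segment; when set the blink is placed at that offset and may
#'   overlap the previous blink's reopening (consecutive blinks), and
#'   `pre_open_ms` is ignored.
#' @return an object of class `"blink_spec"`.
#' @export
blink_spec <- function(pre_open_ms = 500, close_ms = 120, closed_ms = 40,
                       open_ms = 200, post_open_ms = 500, amplitude = 1,
                       start_ms = NULL) {
  durs <- c(pre_open_ms, close_ms, closed_ms, open_ms, post_open_ms)
  if (any(!is.finite(durs)) || any(durs < 0))
    stop("all durations must be finite and >= 0", call. = FALSE)
  if (!is.finite(amplitude) || amplitude <= 0 || amplitude > 1)
    stop("amplitude must lie in (0, 1]: the eyelid cannot travel below ",
         "the lower lid", call. = FALSE)
  structure(list(pre_open_ms = pre_open_ms, close_ms = close_ms,
                 closed_ms = closed_ms, open_ms = open_ms,
                 post_open_ms = post_open_ms, amplitude = amplitude,
                 start_ms = start_ms),
            class = "blink_spec")
}

#' Scene specification for the synthetic eye renderer
#'
#' The renderer draws a bright skin-colored canvas with a single dark
#' eye region (no pupil/iris distinction -- the analysis only needs
#' skin-versus-eye contrast) bounded above by a downward-opening
#' quadratic arch, the upper eyelid. A dark lash line of `lash_px`
#' pixels rides on the arch so the lid margin stays visible at full
#' closure, as real eyelashes do.
#'
#' @param width,height frame dimensions in pixels.
#' @param skin_gray,eye_gray background and eye intensities (0--255,
#'   `eye_gray < skin_gray`).
#' @param aperture_px fully open distance from the arch apex to the
#'   lower lid (px); must be smaller than `height`.
#' @param arch_curvature quadratic coefficient of the eyelid arch
#'   (px per px^2).
#' @param lash_px thickness of the dark lid-margin line (px).
#' @param noise_sd per-pixel Gaussian noise standard deviation
#'   (intensity units).
#' @param flicker_amp,flicker_hz sinusoidal global illumination flicker
#'   amplitude (intensity units) and frequency (Hz).
#' @param seed RNG seed; the same seed yields bit-identical frames.
#' @return an object of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 160, height = 120, skin_gray = 180,
                       eye_gray = 40, aperture_px = 40,
                       arch_curvature = 0.02, lash_px = 3, noise_sd = 2,
                       flicker_amp = 0, flicker_hz = 120, seed = 1L) {
  if (eye_gray >= skin_gray)
    stop("eye_gray must be darker than skin_gray", call. = FALSE)
  if (aperture_px >= height)
    stop("aperture_px must be smaller than the frame height", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 skin_gray = skin_gray, eye_gray = eye_gray,
                 aperture_px = aperture_px, arch_curvature = arch_curvature,
                 lash_px = as.integer(lash_px), noise_sd = noise_sd,
                 flicker_amp = flicker_amp, flicker_hz = flicker_hz,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Normalized closure profiles s(u), u in [0,1], s(0)=0 (open) .. s(1)=1
# (deepest point). "contact" eases out of the open position but meets
# the closure point at full speed, the way a lid stops on contact with
# the lower lid; "cosine" eases at both ends; "linear" does neither.
closure_profile <- function(u, profile) {
  switch(profile,
         contact = 1 - cos(pi * u / 2),
         cosine  = (1 - cos(pi * u)) / 2,
         linear  = u,
         stop("unknown trajectory profile: ", profile, call. = FALSE))
}

# Per-blink closure fraction a(t) = amplitude * s(t) at times t (ms),
# given the absolute start of the closing segment.
blink_closure_at <- function(t_ms, start_ms, spec, profile) {
  c_end <- start_ms + spec$close_ms
  h_end <- c_end + spec$closed_ms
  o_end <- h_end + spec$open_ms
  a <- numeric(length(t_ms))
  i <- t_ms >= start_ms & t_ms < c_end
  if (spec$close_ms > 0)
    a[i] <- closure_profile((t_ms[i] - start_ms) / spec$close_ms, profile)
  a[t_ms >= c_end & t_ms < h_end] <- 1
  i <- t_ms >= h_end & t_ms < o_end
  if (spec$open_ms > 0)
    a[i] <- closure_profile(1 - (t_ms[i] - h_end) / spec$open_ms, profile)
  spec$amplitude * a
}

blink_segment_at <- function(t_ms, start_ms, spec) {
  c_end <- start_ms + spec$close_ms
  h_end <- c_end + spec$closed_ms
  o_end <- h_end + spec$open_ms
  out <- rep("open", length(t_ms))
  out[t_ms >= start_ms & t_ms < c_end] <- "closing"
  out[t_ms >= c_end & t_ms < h_end] <- "closed"
  out[t_ms >= h_end & t_ms < o_end] <- "opening"
  out
}

# lay the blinks out on an absolute timeline; returns per-blink closing
# start times (ms) and the total timeline duration
layout_blinks <- function(blinks) {
  cursor <- 0
  starts <- numeric(length(blinks))
  for (i in seq_along(blinks)) {
    b <- blinks[[i]]
    starts[i] <- if (!is.null(b$start_ms)) b$start_ms else
      cursor + b$pre_open_ms
    cursor <- max(cursor, starts[i] + b$close_ms + b$closed_ms +
                    b$open_ms + b$post_open_ms)
  }
  list(starts = starts, total_ms = cursor)
}

#' Render a synthetic eye-blink video with exact ground truth
#'
#' Renders one frame per `1/fps` seconds: a skin canvas with the dark
#' eye region under a quadratic upper-eyelid arch whose apex row follows
#' the composed blink trajectory (the pointwise-maximum closure over all
#' blinks, so a second blink placed with `start_ms` inside the first
#' blink's reopening produces a consecutive-blink trace). Gaussian
#' sensor noise and sinusoidal illumination flicker are added on top.
#'
#' @param blinks list of [blink_spec()] objects; may be empty when
#'   `duration_ms` is given (static open eye).
#' @param scene a [scene_spec()].
#' @param fps frames per second.
#' @param profile trajectory profile, one of `"contact"` (default),
#'   `"cosine"`, `"linear"`; see [scene_spec()] details.
#' @param duration_ms optional total duration; defaults to the blink
#'   timeline length.
#' @return a list with elements `seq` (a [frame_sequence()]) and
#'   `truth` (a `blink_ground_truth`: per-frame data frame with columns
#'   `frame`, `time_s`, `eyelid_y_px`, `displacement`, `phase`, plus the
#'   displacement-rule phase durations in `$measured`).
#' @export
render_blink_video <- function(blinks, scene = scene_spec(), fps = 240,
                               profile = c("contact", "cosine", "linear"),
                               duration_ms = NULL) {
  profile <- match.arg(profile)
  if (inherits(blinks, "blink_spec")) blinks <- list(blinks)
  if (length(blinks) == 0L && is.null(duration_ms))
    stop("either blinks or duration_ms must be given", call. = FALSE)
  lay <- layout_blinks(blinks)
  total_ms <- max(lay$total_ms, duration_ms %||% 0)
  n <- max(2L, round(total_ms * fps / 1000))
  t_ms <- (seq_len(n) - 1) / fps * 1000

  # composed closure fraction and per-frame phase label
  if (length(blinks)) {
    amat <- vapply(seq_along(blinks), function(i)
      blink_closure_at(t_ms, lay$starts[i], blinks[[i]], profile),
      numeric(n))
    amat <- matrix(amat, nrow = n)
    closure <- do.call(pmax, c(as.data.frame(amat), list(0)))
    dominant <- max.col(amat, ties.method = "first")
    phase <- vapply(seq_len(n), function(i)
      blink_segment_at(t_ms[i], lay$starts[dominant[i]],
                       blinks[[dominant[i]]]), character(1))
    phase[closure == 0 & phase %in% c("closing", "opening")] <- "open"
  } else {
    closure <- numeric(n)
    phase <- rep("open", n)
  }

  # geometry: open apex row and lower lid row, centered vertically
  open_row <- (scene$height - scene$aperture_px) / 2
  lower_lid <- open_row + scene$aperture_px
  cx <- round(scene$width / 2)
  half_w <- floor(sqrt(scene$aperture_px / scene$arch_curvature) - 1e-9)
  cols <- (cx - half_w):(cx + half_w)
  if (min(cols) < 1 || max(cols) > scene$width)
    stop("eye is wider than the frame; reduce aperture_px or increase ",
         "arch_curvature", call. = FALSE)
  arch <- scene$arch_curvature * (cols - cx)^2

  apex_row <- open_row + scene$aperture_px * closure
  displacement <- 0.7 - 0.5 * closure

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(scene$seed)

  rows_mat <- matrix(seq_len(scene$height), scene$height, length(cols))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(scene$skin_gray, scene$height, scene$width)
    edge <- round(pmin(apex_row[i] + arch, lower_lid))
    bottom <- pmax(round(lower_lid), edge + scene$lash_px - 1L)
    dark <- rows_mat >= matrix(edge, scene$height, length(cols),
                               byrow = TRUE) &
      rows_mat <= matrix(bottom, scene$height, length(cols), byrow = TRUE)
    f[, cols][dark] <- scene$eye_gray
    if (scene$flicker_amp > 0)
      f <- f + scene$flicker_amp * sin(2 * pi * scene$flicker_hz *
                                         t_ms[i] / 1000)
    if (scene$noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, scene$noise_sd),
                      nrow(f), ncol(f))
    frames[[i]] <- round(pmin(pmax(f, 0), 255))
  }

  truth_df <- data.frame(frame = seq_len(n), time_s = t_ms / 1000,
                         eyelid_y_px = apex_row,
                         displacement = displacement,
                         phase = phase, stringsAsFactors = FALSE)
  truth <- structure(
    list(df = truth_df, fps = fps,
         measured = truth_phase_durations(displacement, fps),
         scene = scene, blink_starts_ms = lay$starts),
    class = "blink_ground_truth")
  list(seq = frame_sequence(frames, fps = fps), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Displacement-rule phase durations computed directly from the exact
# ground-truth displacement vector (independent of the analysis module):
# the complete-closed phase is the contiguous run below 0.25 around the
# global minimum, closing runs from blink start (first drop below the
# open level) to the closed phase (or the minimum), opening is the rest.
truth_phase_durations <- function(d, fps, closed_thr = 0.25,
                                  incomplete_thr = 0.3, start_eps = 0.01) {
  n <- length(d)
  m <- which.min(d)
  open_ref <- d[1]
  below <- which(d < open_ref - start_eps)
  if (!length(below))
    return(list(closing_frames = 0L, closed_frames = 0L,
                opening_frames = 0L, min_displacement = min(d),
                complete = FALSE))
  start <- min(below)
  end <- max(below)
  if (d[m] < closed_thr) {
    run <- d < closed_thr
    cs <- m; while (cs > 1 && run[cs - 1]) cs <- cs - 1
    ce <- m; while (ce < n && run[ce + 1]) ce <- ce + 1
    complete <- TRUE
  } else {
    cs <- m; ce <- m - 1L  # empty closed interval
    complete <- FALSE
  }
  list(closing_frames = as.integer(cs - start),
       closed_frames = as.integer(ce - cs + 1L),
       opening_frames = as.integer(end - ce),
       min_displacement = d[m],
       complete = complete && d[m] <= incomplete_thr)
}

#' Standard blink fixtures
#'
#' Deterministic synthetic videos, one per blink-pattern class, with
#' exact ground truth: `NORMAL` (complete blink whose displacement-rule
#' phase durations are about 116/30/216 ms, total 362 ms), `INCOMPLETE`
#' (amplitude 0.488 so the minimum displacement is about 0.456, total
#' about 162 ms), `PROLONGED` (phases about 125/208/192 ms, closed phase
#' about 40 percent of the sequence), and `CONSECUTIVE` (a second,
#' complete blink starting before the first, incomplete one has
#' reopened).
#'
#' @param fps frames per second (default 240).
#' @param noise_sd sensor noise of the fixture scenes (default 2).
#' @param seed_base base RNG seed; fixture k uses `seed_base + k`.
#' @return named list; each element is a list with `seq` and `truth` as
#'   returned by [render_blink_video()].
#' @export
standard_fixtures <- function(fps = 240, noise_sd = 2, seed_base = 10L) {
  sc <- function(seed) scene_spec(noise_sd = noise_sd,
                                  seed = as.integer(seed_base - 10L + seed))
  list(
    NORMAL = render_blink_video(
      blink_spec(pre_open_ms = 800, close_ms = 143, closed_ms = 4,
                 open_ms = 267, post_open_ms = 786, amplitude = 1),
      scene = sc(11L), fps = fps),
    INCOMPLETE = render_blink_video(
      blink_spec(pre_open_ms = 900, close_ms = 80.5, closed_ms = 0,
                 open_ms = 106.3, post_open_ms = 913.2, amplitude = 0.488),
      scene = sc(12L), fps = fps),
    PROLONGED = render_blink_video(
      blink_spec(pre_open_ms = 700, close_ms = 155, closed_ms = 183,
                 open_ms = 237, post_open_ms = 725, amplitude = 1),
      scene = sc(13L), fps = fps),
    CONSECUTIVE = render_blink_video(
      list(blink_spec(pre_open_ms = 700, close_ms = 80, closed_ms = 0,
                      open_ms = 140, post_open_ms = 0, amplitude = 0.6),
           blink_spec(start_ms = 810, close_ms = 110, closed_ms = 20,
                      open_ms = 200, post_open_ms = 830, amplitude = 1)),
      scene = sc(14L), fps = fps)
  )
}

#' Write a fixture to disk
#'
#' Writes the frame sequence as a PNG directory with fps sidecar plus a
#' ground-truth CSV (`ground_truth.csv`, columns frame, time_s,
#' eyelid_y_px, displacement, phase).
#'
#' @param fixture a list with `seq` and `truth` (from
#'   [render_blink_video()]).
#' @param path output directory.
#' @return invisibly, `path`.
#' @export
write_fixture <- function(fixture, path) {
  save_frames(fixture$seq, path)
  utils::write.csv(fixture$truth$df, file.path(path, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(path)
}
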