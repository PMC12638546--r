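#' Eyelid displacement trace
#'
#' Collapses the blink matrix to the mid-eyelid position over time: the
#' mean of a band of columns around the matrix center (default 10
#' columns of 500), one value per frame, on the normalized 0.2--0.7
#' scale where larger means more open.
#'
#' @param bm a `"blink_matrix"`.
#' @param config a [blink_config()] (`center_width`).
#' @return an object of class `"displacement_trace"`: list with `d`
#'   (per-frame displacement) and `fps`.
#' @export
displacement_trace <- function(bm, config = blink_config()) {
  stopifnot(inherits(bm, "blink_matrix"))
  W <- ncol(bm$m)
  w <- min(config$center_width, W)
  lo <- floor((W - w) / 2) + 1L
  cols <- lo:(lo + w - 1L)
  structure(list(d = rowMeans(bm$m[, cols, drop = FALSE]), fps = bm$fps),
            class = "displacement_trace")
}

new_displacement_trace <- function(d, fps) {
  structure(list(d = d, fps = fps), class = "displacement_trace")
}

#' Segment a blink into its three phases
#'
#' The Complete Closed phase is the maximal contiguous interval around
#' the global displacement minimum where `d < 0.25` (the lower 10
#' percent of the initial eyelid displacement). The Closing phase runs
#' from blink start -- the last frame before the descent at which the
#' trace still sits within `start_eps` of the open level -- to the
#' start of the closed interval (or to the minimum frame when no closed
#' interval exists), and the Opening phase is the remainder up to the
#' frame where the trace regains the open level. A blink whose minimum
#' displacement exceeds 0.3 has no Complete Closed phase (incomplete
#' blinking); minima in the undefined band \[0.25, 0.3\] are treated as
#' "no closed phase" as well, but do not by themselves make the blink
#' incomplete (the gap rule).
#'
#' @param trace a `"displacement_trace"` (length >= 3).
#' @param config a [blink_config()] (`closed_threshold`,
#'   `incomplete_threshold`, `start_eps`).
#' @return an object of class `"phase_segmentation"`: list with frame
#'   intervals `closing`, `closed` (NULL when absent), `opening`,
#'   logical `complete`, and `span = c(start, end)` of the blink within
#'   the trace.
#' @export
segment_phases <- function(trace, config = blink_config()) {
  stopifnot(inherits(trace, "displacement_trace"))
  d <- trace$d
  n <- length(d)
  stopifnot(n >= 3)
  m <- which.min(d)
  open_ref <- stats::median(d[seq_len(min(5L, n))])
  eps <- config$start_eps
  if (all(d >= open_ref - eps) || m == 1L || m == n ||
      all(diff(d) <= 0) || all(diff(d) >= 0))
    stop("not a blink: trace has no descent-ascent structure",
         call. = FALSE)
  below <- d < open_ref - eps
  start <- m; while (start > 1L && below[start - 1L]) start <- start - 1L
  start <- max(1L, start - 1L)  # last frame still at the open level
  open_end_ref <- stats::median(d[seq(max(1L, n - 4L), n)])
  below_end <- d < open_end_ref - eps
  end <- m; while (end < n && below_end[end + 1L]) end <- end + 1L
  end <- min(n, end + 1L)

  if (d[m] < config$closed_threshold) {
    run <- d < config$closed_threshold
    cs <- m; while (cs > 1L && run[cs - 1L]) cs <- cs - 1L
    ce <- m; while (ce < n && run[ce + 1L]) ce <- ce + 1L
    closed <- c(cs, ce)
    complete <- TRUE
  } else {
    closed <- NULL
    cs <- m; ce <- m
    complete <- FALSE
  }
  closing <- c(start, max(start, cs - 1L))
  opening <- c(min(end, ce + 1L), end)
  structure(list(closing = closing, closed = closed, opening = opening,
                 complete = complete, span = c(start, end),
                 min_displacement = d[m], min_frame = m),
            class = "phase_segmentation")
}

#' Classify the blink pattern
#'
#' `consecutive` when the trace holds two or more blink minima
#' separated by a reopening peak that stays below the "fully reopened"
#' level `d[1] - (1 - reopen_frac) * (d[1] - 0.2)` -- the second blink
#' started before the eyelids had fully opened. Otherwise `incomplete`
#' when the blink has no Complete Closed phase because its minimum
#' stayed above 0.3, else `normal`. Two full blinks separated by a
#' return to the open level do not count as consecutive.
#'
#' @param trace a `"displacement_trace"`.
#' @param phases the matching `"phase_segmentation"`.
#' @param reopen_frac fraction of the open-to-closed span that counts
#'   as fully reopened (default from `config`).
#' @param config a [blink_config()].
#' @return one of `"normal"`, `"incomplete"`, `"consecutive"`.
#' @export
classify_blink <- function(trace, phases, reopen_frac = config$reopen_frac,
                           config = blink_config()) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(phases, "phase_segmentation"))
  d <- trace$d
  span <- phases$span[1]:phases$span[2]
  if (length(span) >= 5) {
    ds <- moving_average(d[span], 3L)
    reopen_level <- d[1] - (1 - reopen_frac) * (d[1] - config$norm_lo)
    pk <- pracma::findpeaks(ds, minpeakheight = -Inf,
                            minpeakdistance = 2L)
    if (!is.null(pk)) {
      interior <- pk[, 2] > 1 & pk[, 2] < length(ds)
      prom <- apply(pk, 1, function(p) {
        lo_l <- min(ds[seq_len(p[2])])
        lo_r <- min(ds[p[2]:length(ds)])
        p[1] - max(lo_l, lo_r)
      })
      if (any(interior & prom >= config$reopen_prominence &
                pk[, 1] < reopen_level))
        return("consecutive")
    }
  }
  if (!phases$complete &&
      phases$min_displacement > config$incomplete_threshold)
    return("incomplete")
  "normal"
}

#' Blink parameters from a segmented displacement trace
#'
#' Durations in milliseconds from the phase frame counts, the
#' closed-phase ratio, the closing and opening speeds (normalized
#' displacement units per second over the moving phases), the total
#' displacement `d[start] - min(d)` and the minimum displacement.
#' Speeds over a zero-length phase are reported as `NA`, not infinite.
#'
#' @param trace a `"displacement_trace"`.
#' @param phases the matching `"phase_segmentation"`.
#' @return a list with `total_duration_ms`, `closing_ms`, `closed_ms`,
#'   `opening_ms`, `closed_ratio_pct`, `closing_speed`,
#'   `opening_speed`, `total_displacement`, `min_displacement`.
#' @export
blink_parameters <- function(trace, phases) {
  d <- trace$d
  per_frame_ms <- 1000 / trace$fps
  closing_f <- diff(phases$closing) ; names(closing_f) <- NULL
  closed_f <- if (is.null(phases$closed)) 0L else
    diff(phases$closed) + 1L
  opening_f <- diff(phases$opening)
  closing_ms <- closing_f * per_frame_ms
  closed_ms <- closed_f * per_frame_ms
  opening_ms <- opening_f * per_frame_ms
  total_ms <- closing_ms + closed_ms + opening_ms
  speed <- function(d0, d1, ms) if (ms > 0) abs(d0 - d1) / (ms / 1000)
    else NA_real_
  list(
    total_duration_ms = total_ms,
    closing_ms = closing_ms,
    closed_ms = closed_ms,
    opening_ms = opening_ms,
    closed_ratio_pct = if (total_ms > 0) closed_ms / total_ms * 100
      else NA_real_,
    closing_speed = speed(d[phases$closing[1]], d[phases$closing[2] + 1L],
                          closing_ms + per_frame_ms),
    opening_speed = speed(d[max(1L, phases$opening[1] - 1L)],
                          d[phases$opening[2]],
                          opening_ms + per_frame_ms),
    total_displacement = d[phases$span[1]] - min(d),
    min_displacement = phases$min_displacement
  )
}

#' Analyze one blink clip end to end
#'
#' Runs the eyelid stage, builds the blink matrix, reduces it to the
#' displacement trace, segments the phases, classifies the pattern and
#' computes the parameters for a single extracted blink clip.
#'
#' @param clip a `"blink_clip"` or [frame_sequence()].
#' @param config a [blink_config()].
#' @return an object of class `"blink_record"`: list with `trace`,
#'   `phases`, `label`, `params`, `matrix`, `roi`, `threshold`,
#'   `source_span`.
#' @export
analyze_clip <- function(clip, config = blink_config()) {
  seq <- if (inherits(clip, "blink_clip")) clip$frames else clip
  est <- estimate_eyelid_curves(clip, config)
  bm <- build_matrix(est$curves, fps = seq$fps, config = config,
                     aperture_px = est$roi$height)
  trace <- displacement_trace(bm, config)
  phases <- segment_phases(trace, config)
  label <- classify_blink(trace, phases, config = config)
  params <- blink_parameters(trace, phases)
  structure(list(trace = trace, phases = phases, label = label,
                 params = params, matrix = bm, roi = est$roi,
                 threshold = est$threshold,
                 source_span = if (inherits(clip, "blink_clip"))
                   clip$source_span else NULL),
            class = "blink_record")
}

#' @export
print.blink_record <- function(x, ...) {
  p <- x$params
  cat(sprintf("blink_record: %s blink, %.1f ms total\n", x$label,
              p$total_duration_ms))
  cat(sprintf("  phases closing/closed/opening: %.1f / %.1f / %.1f ms",
              p$closing_ms, p$closed_ms, p$opening_ms),
      sprintf("(closed ratio %.1f%%)\n", p$closed_ratio_pct))
  cat(sprintf("  displacement: min %.3f, total %.3f\n",
              p$min_displacement, p$total_displacement))
  invisible(x)
}
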