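#' Detect blink candidates on the signal profiles
#'
#' Smooths the mean-intensity profile with a moving average, finds local
#' extrema exceeding a prominence floor (blink peak polarity is
#' auto-detected: whether a blink raises or lowers the mean intensity
#' depends on the skin/eye contrast), and walks outward from each
#' extremum `x2` to the nearest frames where the smoothed profile
#' returns to within a fraction of the peak excursion of baseline,
#' giving the blink span `x1 .. x3`. When an event profile is supplied
#' (the default pipeline), a candidate is kept only if the event signal
#' shows at least two bursts -- lid closing and lid opening -- inside
#' its span.
#'
#' Candidates are returned unfiltered, in temporal order; apply
#' [filter_candidates()] for the duration and symmetry rules.
#'
#' @param intensity an `intensity_profile` from
#'   [mean_intensity_profile()].
#' @param events an `event_profile` from [simulate_events()], or NULL to
#'   detect from intensity alone.
#' @param config a [blink_config()].
#' @return a data frame of class `"blink_candidates"` with columns
#'   `x1, x2, x3` (frame indices, 1-based), `y1, y2, y3` (smoothed
#'   profile values), `status` and `reject_reason`; the frame rate is
#'   attached as attribute `fps`.
#' @export
detect_candidates <- function(intensity, events = NULL,
                              config = blink_config()) {
  stopifnot(inherits(intensity, "intensity_profile"))
  if (!is.null(events)) {
    if (length(events$counts) != length(intensity$values) ||
        events$fps != intensity$fps)
      stop("intensity and event profiles must cover the same frames",
           call. = FALSE)
  }
  v <- intensity$values
  w <- smooth_window_for(config, intensity$fps)
  empty <- data.frame(x1 = integer(0), x2 = integer(0), x3 = integer(0),
                      y1 = numeric(0), y2 = numeric(0), y3 = numeric(0),
                      status = character(0), reject_reason = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "fps") <- intensity$fps
  class(empty) <- c("blink_candidates", "data.frame")
  if (length(v) < 2L * w) {
    warning("profile shorter than twice the smoothing window; ",
            "no candidates")
    return(empty)
  }
  sm <- moving_average(v, w)
  baseline <- stats::median(sm)
  polarity <- if (max(sm) - baseline >= baseline - min(sm)) 1 else -1
  z <- polarity * (sm - baseline)
  floor_ <- max(config$prominence_mad_mult * stats::mad(diff(sm)),
                config$min_prominence)
  pk <- pracma::findpeaks(z, minpeakheight = floor_,
                          minpeakdistance = max(w, 2L))
  if (is.null(pk)) return(empty)
  peaks <- pk[, 2]
  n <- length(z)
  spans <- lapply(peaks, function(p) {
    eps <- config$baseline_return_frac * z[p]
    left <- which(z[seq_len(p - 1)] <= eps)
    x1 <- if (length(left)) max(left) else 1L
    right <- which(z[(p + 1):n] <= eps)
    x3 <- if (length(right)) p + min(right) else n
    c(x1, p, x3)
  })
  spans <- do.call(rbind, spans)
  # peaks with overlapping spans belong to one blink complex (e.g. a
  # consecutive blink whose partial reopening never reaches baseline):
  # merge them into the union span, keeping the tallest peak as x2
  spans <- spans[order(spans[, 1], spans[, 3]), , drop = FALSE]
  merged <- spans[1, , drop = FALSE]
  for (r in seq_len(nrow(spans))[-1]) {
    last <- nrow(merged)
    if (spans[r, 1] <= merged[last, 3]) {
      merged[last, 3] <- max(merged[last, 3], spans[r, 3])
      if (z[spans[r, 2]] > z[merged[last, 2]])
        merged[last, 2] <- spans[r, 2]
    } else merged <- rbind(merged, spans[r, , drop = FALSE])
  }
  spans <- merged

  if (!is.null(events) && config$use_events && nrow(spans)) {
    ok <- apply(spans, 1, function(s)
      event_confirmed(events$counts[s[1]:s[3]]))
    spans <- spans[ok, , drop = FALSE]
  }
  if (!nrow(spans)) return(empty)
  out <- data.frame(x1 = as.integer(spans[, 1]),
                    x2 = as.integer(spans[, 2]),
                    x3 = as.integer(spans[, 3]),
                    y1 = sm[spans[, 1]], y2 = sm[spans[, 2]],
                    y3 = sm[spans[, 3]],
                    status = "candidate", reject_reason = "none",
                    stringsAsFactors = FALSE)
  attr(out, "fps") <- intensity$fps
  class(out) <- c("blink_candidates", "data.frame")
  out
}

# number of event bursts: runs of counts above 25% of the window maximum
event_burst_count <- function(counts) {
  mx <- max(counts)
  if (mx <= 0) return(0L)
  above <- counts > 0.25 * mx
  sum(above & !c(FALSE, above[-length(above)]))
}

# A blink shows two event bursts (closing and opening) separated by the
# closed hold. A blink without a hold -- e.g. an incomplete blink that
# reverses at full speed -- fuses them into one burst of continuous
# motion covering most of the span, which also counts as confirmation;
# sporadic noise events produce neither pattern.
event_confirmed <- function(counts) {
  mx <- max(counts)
  if (mx <= 0) return(FALSE)
  above <- counts > 0.25 * mx
  starts <- above & !c(FALSE, above[-length(above)])
  n_bursts <- sum(starts)
  if (n_bursts >= 2L) return(TRUE)
  runs <- rle(above)
  longest <- max(c(0L, runs$lengths[runs$values]))
  n_bursts == 1L && longest >= 0.5 * length(counts)
}

#' Apply the blink duration and symmetry filters
#'
#' A candidate is rejected as `too_short` when its span is under 50 ms
#' (eyelid flutter), `too_long` when over 1500 ms (micro-sleep), and
#' `asymmetric` when the relative mismatch between its rise `y2 - y1`
#' and fall `y2 - y3` exceeds 20 percent (an environmental intensity
#' change rather than a blink); all other candidates are accepted. The
#' mismatch denominator is the larger of the two excursions.
#'
#' @param cands a `blink_candidates` data frame.
#' @param fps frames per second; defaults to the `fps` attribute of
#'   `cands`.
#' @param config a [blink_config()] (bounds `min_duration_ms`,
#'   `max_duration_ms`, `symmetry_tol`).
#' @return the same data frame with `status` set to `"accepted"` or
#'   `"rejected"` and `reject_reason` filled in.
#' @export
filter_candidates <- function(cands, fps = attr(cands, "fps"),
                              config = blink_config()) {
  if (!nrow(cands)) return(cands)
  duration_ms <- (cands$x3 - cands$x1) / fps * 1000
  rise <- abs(cands$y2 - cands$y1)
  fall <- abs(cands$y2 - cands$y3)
  mismatch <- abs(rise - fall) / pmax(rise, fall)
  reason <- rep("none", nrow(cands))
  reason[mismatch > config$symmetry_tol] <- "asymmetric"
  reason[duration_ms > config$max_duration_ms] <- "too_long"
  reason[duration_ms < config$min_duration_ms] <- "too_short"
  cands$reject_reason <- reason
  cands$status <- ifelse(reason == "none", "accepted", "rejected")
  cands
}

#' Extract per-blink clips
#'
#' Cuts one padded clip per accepted candidate from the source video,
#' clamped to the video bounds; the padding supplies open-eye context on
#' both sides for eyelid estimation and matrix normalization.
#'
#' @param seq the source [frame_sequence()].
#' @param cands a filtered `blink_candidates` data frame.
#' @param pad context frames on each side (default from `config`).
#' @param config a [blink_config()].
#' @return a list of `"blink_clip"` objects: each has `frames` (a
#'   `frame_sequence`), `source_span` (c(x1, x3) in source frames) and
#'   `pad`.
#' @export
extract_clips <- function(seq, cands, pad = config$pad,
                          config = blink_config()) {
  stopifnot(pad >= 0)
  acc <- cands[cands$status == "accepted", , drop = FALSE]
  lapply(seq_len(nrow(acc)), function(i) {
    x1 <- acc$x1[i]; x3 <- acc$x3[i]
    structure(list(frames = subset_frames(seq, x1 - pad, x3 + pad),
                   source_span = c(x1 = x1, x3 = x3),
                   pad = as.integer(pad)),
              class = "blink_clip")
  })
}

#' Summary blink statistics for a video
#'
#' The population-level descriptors: blink rate per minute, mean and
#' (population) standard deviation of blink duration, proportion of
#' closure (summed blink time over total observation time), and the
#' ratio of incomplete blinks when classification labels are supplied.
#'
#' @param cands a filtered `blink_candidates` data frame.
#' @param video_duration_s total observation time (s, > 0).
#' @param durations_ms optional per-blink durations (ms) from the phase
#'   analysis; defaults to the accepted candidates' spans.
#' @param labels optional per-blink classification labels
#'   (`"normal"`, `"incomplete"`, `"consecutive"`).
#' @return a list with `n_blinks`, `rate_per_min`, `mean_duration_ms`,
#'   `sd_duration_ms`, `closure_proportion_pct`,
#'   `incomplete_ratio_pct`.
#' @export
blink_statistics <- function(cands, video_duration_s, durations_ms = NULL,
                             labels = NULL) {
  stopifnot(video_duration_s > 0)
  acc <- cands[cands$status == "accepted", , drop = FALSE]
  if (is.null(durations_ms)) {
    fps <- attr(cands, "fps")
    durations_ms <- (acc$x3 - acc$x1) / fps * 1000
  }
  n <- nrow(acc)
  pop_sd <- function(x) if (length(x)) sqrt(mean((x - mean(x))^2)) else NA_real_
  list(
    n_blinks = n,
    rate_per_min = n / (video_duration_s / 60),
    mean_duration_ms = if (length(durations_ms)) mean(durations_ms)
      else NA_real_,
    sd_duration_ms = pop_sd(durations_ms),
    closure_proportion_pct = sum(durations_ms) / 1000 /
      video_duration_s * 100,
    incomplete_ratio_pct = if (is.null(labels) || !length(labels)) NA_real_
      else mean(labels == "incomplete") * 100
  )
}
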