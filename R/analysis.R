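#' Analyze every blink in a video
#'
#' The single entry point of the pipeline. From a frame sequence (or a
#' frame directory on disk) it computes the mean-intensity and
#' simulated event profiles, detects and filters blink candidates,
#' extracts one padded clip per accepted blink, and runs the eyelid /
#' blink-matrix / phase analysis on each clip.
#'
#' @param x a [frame_sequence()] or a path accepted by [load_video()].
#' @param config a [blink_config()].
#' @param fps_override frame rate override passed to [load_video()]
#'   when `x` is a path.
#' @return an object of class `"blink_analysis"`: list with
#'   `candidates` (all candidates with accept/reject status),
#'   `records` (one `"blink_record"` per accepted blink), `statistics`
#'   (from [blink_statistics()], using the phase-analysis durations and
#'   labels), `intensity`, `events`, `fps`, `n_frames`, `duration_s`,
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' fx <- standard_fixtures()$NORMAL
#' fit <- blink_analysis(fx$seq)
#' fit
#' summary(fit)
#' }
blink_analysis <- function(x, config = blink_config(),
                           fps_override = NULL) {
  seq <- if (inherits(x, "frame_sequence")) x else
    load_video(x, fps_override = fps_override)
  intensity <- mean_intensity_profile(seq)
  events <- if (config$use_events)
    simulate_events(seq, threshold = config$event_threshold,
                    downsample = config$event_downsample) else NULL
  cands <- detect_candidates(intensity, events, config)
  cands <- filter_candidates(cands, fps = seq$fps, config = config)
  clips <- extract_clips(seq, cands, pad = config$pad, config = config)
  records <- lapply(clips, analyze_clip, config = config)
  duration_s <- length(seq$frames) / seq$fps
  stats <- blink_statistics(
    cands, duration_s,
    durations_ms = vapply(records, function(r) r$params$total_duration_ms,
                          numeric(1)),
    labels = vapply(records, function(r) r$label, character(1)))
  structure(list(candidates = cands, records = records,
                 statistics = stats, intensity = intensity,
                 events = events, fps = seq$fps,
                 n_frames = length(seq$frames), duration_s = duration_s,
                 config = config),
            class = "blink_analysis")
}

#' @export
print.blink_analysis <- function(x, ...) {
  cat(sprintf("blink_analysis: %d frames at %.6g fps (%.2f s)\n",
              x$n_frames, x$fps, x$duration_s))
  cat(sprintf("  candidates: %d (%d accepted)\n", nrow(x$candidates),
              sum(x$candidates$status == "accepted")))
  labs <- vapply(x$records, function(r) r$label, character(1))
  if (length(labs)) {
    tab <- table(labs)
    cat("  blinks:", paste(sprintf("%s %d", names(tab), tab),
                           collapse = ", "), "\n")
  } else cat("  blinks: none\n")
  invisible(x)
}

#' @export
summary.blink_analysis <- function(object, ...) {
  s <- object$statistics
  cat("Blink summary\n")
  cat(sprintf("  blinks detected          %d\n", s$n_blinks))
  cat(sprintf("  blink rate               %.2f / min\n", s$rate_per_min))
  cat(sprintf("  mean blink duration      %.1f ms\n", s$mean_duration_ms))
  cat(sprintf("  SD of blink duration     %.2f ms\n", s$sd_duration_ms))
  cat(sprintf("  proportion of closure    %.2f %%\n",
              s$closure_proportion_pct))
  cat(sprintf("  incomplete blink ratio   %.2f %%\n",
              s$incomplete_ratio_pct))
  df <- as.data.frame(object)
  if (nrow(df)) {
    cat("\nPer-blink parameters\n")
    print(df, digits = 4)
  }
  invisible(s)
}

#' Per-blink parameter table
#'
#' @param x a `"blink_analysis"`.
#' @param ... unused.
#' @return data frame with one row per accepted blink: start time,
#'   phase durations, closed ratio, speeds, displacements and the
#'   pattern label.
#' @export
as.data.frame.blink_analysis <- function(x, ...) {
  if (!length(x$records))
    return(data.frame(start_s = numeric(0), duration_ms = numeric(0),
                      closing_ms = numeric(0), closed_ms = numeric(0),
                      opening_ms = numeric(0),
                      closed_ratio_pct = numeric(0),
                      closing_speed = numeric(0),
                      opening_speed = numeric(0),
                      total_displacement = numeric(0),
                      min_displacement = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(x$records, function(r) {
    p <- r$params
    data.frame(
      start_s = if (!is.null(r$source_span))
        (r$source_span[["x1"]] - 1) / x$fps else NA_real_,
      duration_ms = p$total_duration_ms, closing_ms = p$closing_ms,
      closed_ms = p$closed_ms, opening_ms = p$opening_ms,
      closed_ratio_pct = p$closed_ratio_pct,
      closing_speed = p$closing_speed, opening_speed = p$opening_speed,
      total_displacement = p$total_displacement,
      min_displacement = p$min_displacement, label = r$label,
      stringsAsFactors = FALSE)
  }))
}

#' @export
plot.blink_analysis <- function(x, which = c("traces", "profile"), ...) {
  which <- match.arg(which)
  if (which == "profile" || !length(x$records)) {
    t <- (seq_along(x$intensity$values) - 1) / x$fps
    graphics::plot(t, x$intensity$values, type = "l",
                   xlab = "time (s)", ylab = "mean intensity",
                   main = "Intensity profile and accepted blinks", ...)
    acc <- x$candidates[x$candidates$status == "accepted", ,
                        drop = FALSE]
    if (nrow(acc))
      graphics::abline(v = (c(acc$x1, acc$x3) - 1) / x$fps,
                       col = "red", lty = 3)
    return(invisible(x))
  }
  n <- length(x$records)
  old <- graphics::par(mfrow = c(n, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(n)) {
    r <- x$records[[i]]
    t <- (seq_along(r$trace$d) - 1) / r$trace$fps
    graphics::plot(t, r$trace$d, type = "l", ylim = c(0.15, 0.75),
                   xlab = "time (s)", ylab = "displacement",
                   main = sprintf("blink %d: %s", i, r$label))
    graphics::abline(h = c(0.25, 0.3), col = "gray", lty = 2)
    if (!is.null(r$phases$closed))
      graphics::abline(v = (r$phases$closed - 1) / r$trace$fps,
                       col = "red", lty = 3)
  }
  invisible(x)
}

#' Run the pipeline and write a report bundle
#'
#' Executes [blink_analysis()] on a video and writes all artifacts to
#' `out_dir`: the signal profiles (`signals.csv`), all candidates with
#' status and reasons (`blinks.json`), the per-blink parameter table
#' (`parameters.csv`), per-blink records (`blink_<i>.json`), blink
#' matrices (`blink_<i>_matrix.csv`), projection images
#' (`blink_<i>.png`), a summary (`summary.json`), a run manifest with
#' the configuration (`manifest.json`) and a stage log (`run.log`).
#'
#' @param x a [frame_sequence()] or path for [load_video()].
#' @param config a [blink_config()].
#' @param out_dir output directory (created if needed).
#' @param fps_override passed to [load_video()].
#' @return invisibly, the `"blink_analysis"` object.
#' @export
run_pipeline <- function(x, config = blink_config(), out_dir,
                         fps_override = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf("[%s] ", format(Sys.time(),
                                                       "%H:%M:%S")),
                               sprintf(...), "\n", sep = "",
                               file = logfile, append = TRUE)
  cat("", file = logfile)
  t0 <- proc.time()[3]
  fit <- blink_analysis(x, config = config, fps_override = fps_override)
  logline("analysis: %d frames, %d candidates, %d accepted (%.2f s)",
          fit$n_frames, nrow(fit$candidates),
          sum(fit$candidates$status == "accepted"), proc.time()[3] - t0)
  rej <- fit$candidates[fit$candidates$status == "rejected", ,
                        drop = FALSE]
  for (i in seq_len(nrow(rej)))
    logline("rejected candidate %d-%d: %s", rej$x1[i], rej$x3[i],
            rej$reject_reason[i])

  if (!is.null(fit$events))
    write_signals_csv(fit$intensity, fit$events,
                      file.path(out_dir, "signals.csv"))
  cand <- fit$candidates
  cand$x1_s <- (cand$x1 - 1) / fit$fps
  cand$x2_s <- (cand$x2 - 1) / fit$fps
  cand$x3_s <- (cand$x3 - 1) / fit$fps
  jsonlite::write_json(cand, file.path(out_dir, "blinks.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(fit),
                   file.path(out_dir, "parameters.csv"),
                   row.names = FALSE)
  for (i in seq_along(fit$records)) {
    r <- fit$records[[i]]
    jsonlite::write_json(
      list(label = r$label, params = r$params,
           phases = list(closing = r$phases$closing,
                         closed = r$phases$closed,
                         opening = r$phases$opening,
                         complete = r$phases$complete),
           roi = unclass(r$roi), threshold = r$threshold,
           source_span = r$source_span),
      file.path(out_dir, sprintf("blink_%d.json", i)),
      auto_unbox = TRUE, digits = NA)
    write_matrix_csv(r$matrix,
                     file.path(out_dir, sprintf("blink_%d_matrix.csv", i)))
    render_projection(r$matrix,
                      file.path(out_dir, sprintf("blink_%d.png", i)),
                      config = config)
  }
  jsonlite::write_json(fit$statistics, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("blinkscope")),
         r_version = R.version.string,
         config = cfg,
         config_hash = digest_config(cfg)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  logline("report written to %s", out_dir)
  invisible(fit)
}

# stable hash of the configuration (sum of a serialization's bytes --
# enough to detect config drift between runs without extra deps)
digest_config <- function(cfg) {
  raw <- serialize(cfg[order(names(cfg))], NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}
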