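#' Pipeline configuration
#'
#' Builds the full set of tunables for the blink-analysis pipeline,
#' validated and with defaults filled in. Keys in
#' [method_constant_keys()] are fixed by the analysis method itself
#' (duration bounds, symmetry bound, displacement thresholds, matrix
#' geometry); the remainder are implementation choices exposed for
#' tuning.
#'
#' @param ... named overrides of the defaults listed below. Unknown
#'   names are rejected.
#'
#' @details Defaults:
#' \describe{
#'   \item{event_threshold}{brightness-change threshold (intensity units
#'     of 255) that fires a dynamic-vision event; 15.}
#'   \item{smooth_window}{moving-average window (frames) for the
#'     intensity profile; `NA` means `round(fps / 48)` (about 5 frames
#'     at 240 fps).}
#'   \item{prominence_mad_mult}{peak prominence floor as a multiple of
#'     the median absolute deviation of the smoothed profile's first
#'     difference; 4.}
#'   \item{min_prominence}{absolute lower bound (intensity units) on the
#'     peak prominence floor, so sensor noise cannot seed candidates; 2.}
#'   \item{baseline_return_frac}{fraction of a peak's excursion at which
#'     the outward walk declares return to baseline; 0.1.}
#'   \item{use_events}{require the two-burst event-signal confirmation
#'     inside each candidate span; TRUE.}
#'   \item{event_downsample}{spatial downsampling factor applied before
#'     event simulation; 1 (off).}
#'   \item{min_duration_ms, max_duration_ms}{blink duration bounds; 50
#'     and 1500 ms (shorter = eyelid flutter, longer = micro-sleep).}
#'   \item{symmetry_tol}{maximum relative mismatch between the rise
#'     `y2 - y1` and fall `y2 - y3` of a candidate; 0.20.}
#'   \item{pad}{context frames added on each side of a clip; 12.}
#'   \item{poly_degree}{polynomial degree of the eyelid arch fit; 2.}
#'   \item{outlier_tol_px}{absolute residual tolerance (px) of the
#'     iterative outlier removal; 3.}
#'   \item{max_iter}{iteration cap of the outlier removal; 20.}
#'   \item{roi_margin}{margin (px) added around the motion blob; 5.}
#'   \item{acc_threshold_frac}{fraction of the accumulation maximum used
#'     to binarize the dynamic image before blob labeling; 0.25.}
#'   \item{per_frame_threshold}{recompute the binarization threshold on
#'     every frame instead of once from the clip's first frame; FALSE.}
#'   \item{matrix_width}{columns of the blink matrix; 500.}
#'   \item{norm_lo, norm_hi}{normalized displacement range of the first
#'     frame; 0.2 and 0.7.}
#'   \item{norm_mode}{"extent" maps the first frame's vertical extent
#'     onto \[norm_lo, norm_hi\]; "center" maps its center to norm_hi and
#'     one aperture (ROI height) to the span (fallback for flat first
#'     frames).}
#'   \item{center_width}{columns averaged around the matrix center for
#'     the displacement trace; 10.}
#'   \item{closed_threshold}{displacement below which the eye counts as
#'     completely closed; 0.25.}
#'   \item{incomplete_threshold}{minimum displacement above which a
#'     blink has no complete-closed phase and is incomplete; 0.3.}
#'   \item{reopen_frac}{fraction of the open-to-closed span the eyelid
#'     must regain to count as fully reopened (consecutive-blink rule);
#'     0.9.}
#'   \item{reopen_prominence}{minimum prominence (normalized units) of
#'     an interior reopening peak considered by the consecutive rule;
#'     0.05.}
#'   \item{start_eps}{displacement drop (normalized units) below the
#'     open level that marks blink start/end on a trace; 0.01.}
#'   \item{gridline_interval_s}{spacing of the red dotted time
#'     gridlines in the projection image; 0.1 s.}
#'   \item{seed}{seed for stochastic fixture generation; 1.}
#' }
#'
#' @return a named list of class `"blink_config"`.
#' @export
#' @examples
#' cfg <- blink_config(event_threshold = 20)
#' cfg$event_threshold
blink_config <- function(...) {
  defaults <- list(
    event_threshold = 15,
    smooth_window = NA_integer_,
    prominence_mad_mult = 4,
    min_prominence = 2,
    baseline_return_frac = 0.1,
    use_events = TRUE,
    event_downsample = 1L,
    min_duration_ms = 50,
    max_duration_ms = 1500,
    symmetry_tol = 0.20,
    pad = 12L,
    poly_degree = 2L,
    outlier_tol_px = 3,
    max_iter = 20L,
    roi_margin = 5L,
    acc_threshold_frac = 0.25,
    per_frame_threshold = FALSE,
    matrix_width = 500L,
    norm_lo = 0.2,
    norm_hi = 0.7,
    norm_mode = "extent",
    center_width = 10L,
    closed_threshold = 0.25,
    incomplete_threshold = 0.3,
    reopen_frac = 0.9,
    reopen_prominence = 0.05,
    start_eps = 0.01,
    gridline_interval_s = 0.1,
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[nm] <- overrides
  }
  cfg <- structure(defaults, class = "blink_config")
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg,
                                         call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$event_threshold) && cfg$event_threshold > 0,
      "event_threshold must be > 0")
  chk(is.na(cfg$smooth_window) ||
        (num1(cfg$smooth_window) && cfg$smooth_window >= 1),
      "smooth_window must be NA or >= 1")
  chk(num1(cfg$min_duration_ms) && num1(cfg$max_duration_ms) &&
        cfg$min_duration_ms < cfg$max_duration_ms,
      "duration bounds must satisfy min < max")
  chk(num1(cfg$symmetry_tol) && cfg$symmetry_tol > 0 && cfg$symmetry_tol < 1,
      "symmetry_tol must be in (0, 1)")
  chk(num1(cfg$pad) && cfg$pad >= 0, "pad must be >= 0")
  chk(num1(cfg$poly_degree) && cfg$poly_degree >= 1,
      "poly_degree must be >= 1")
  chk(num1(cfg$outlier_tol_px) && cfg$outlier_tol_px > 0,
      "outlier_tol_px must be > 0")
  chk(num1(cfg$max_iter) && cfg$max_iter >= 1, "max_iter must be >= 1")
  chk(num1(cfg$roi_margin) && cfg$roi_margin >= 0, "roi_margin must be >= 0")
  chk(num1(cfg$matrix_width) && cfg$matrix_width >= 2,
      "matrix_width must be >= 2")
  chk(num1(cfg$norm_lo) && num1(cfg$norm_hi) && cfg$norm_lo < cfg$norm_hi,
      "norm_lo must be < norm_hi")
  chk(cfg$norm_mode %in% c("extent", "center"),
      "norm_mode must be 'extent' or 'center'")
  chk(num1(cfg$closed_threshold) && num1(cfg$incomplete_threshold) &&
        cfg$closed_threshold <= cfg$incomplete_threshold,
      "closed_threshold must be <= incomplete_threshold")
  chk(num1(cfg$reopen_frac) && cfg$reopen_frac > 0 && cfg$reopen_frac <= 1,
      "reopen_frac must be in (0, 1]")
  chk(num1(cfg$start_eps) && cfg$start_eps > 0, "start_eps must be > 0")
  chk(num1(cfg$gridline_interval_s) && cfg$gridline_interval_s > 0,
      "gridline_interval_s must be > 0")
  invisible(cfg)
}

#' Keys of `blink_config` fixed by the analysis method
#'
#' These values define the method (blink duration bounds, the 20 percent
#' symmetry bound, the 0.25 / 0.3 displacement thresholds, the 500-column
#' matrix normalized to 0.2--0.7, the 0.1 s gridlines); the remaining
#' keys are implementation tunables.
#'
#' @return character vector of key names.
#' @export
method_constant_keys <- function() {
  c("min_duration_ms", "max_duration_ms", "symmetry_tol",
    "closed_threshold", "incomplete_threshold",
    "matrix_width", "norm_lo", "norm_hi", "gridline_interval_s")
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param cfg a `blink_config` object.
#' @return `read_config` returns a validated `blink_config`;
#'   `write_config` invisibly returns `path`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(blink_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "blink_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.blink_config <- function(x, ...) {
  cat("Blink-analysis pipeline configuration\n")
  const <- method_constant_keys()
  for (k in names(x)) {
    tag <- if (k %in% const) "  [method constant]" else ""
    cat(sprintf("  %-22s %s%s\n", k, format(x[[k]]), tag))
  }
  invisible(x)
}

# effective smoothing window for a given frame rate
smooth_window_for <- function(cfg, fps) {
  w <- cfg$smooth_window
  if (is.na(w)) w <- round(fps / 48)
  max(1L, as.integer(w))
}
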