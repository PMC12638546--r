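#' Histogram-valley binarization threshold
#'
#' Computes a 256-bin intensity histogram of the frame, smooths it with
#' a 5-bin moving average, and returns the deepest local minimum (the
#' valley) between the two highest peaks -- typically the bright skin
#' mode and the dark eye mode. When the histogram has no interior
#' valley (unimodal), Otsu's criterion is used instead.
#'
#' @param frame a 2-D intensity matrix (0--255).
#' @return the threshold intensity; pixels strictly below it are the
#'   dark (eye) class.
#' @export
binarization_threshold <- function(frame) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  if (max(frame) == min(frame))
    stop("degenerate histogram: constant image has no valley",
         call. = FALSE)
  counts <- tabulate(pmin(255, pmax(0, floor(frame))) + 1L, nbins = 256L)
  smoothed <- moving_average(counts, 5L)
  n <- length(smoothed)
  is_peak <- c(FALSE, smoothed[2:(n - 1)] >= smoothed[1:(n - 2)] &
                 smoothed[2:(n - 1)] >= smoothed[3:n], FALSE) &
    smoothed > 0
  pk <- which(is_peak)
  # collapse plateaus of equal smoothed counts to one representative
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) > 1 |
                                   smoothed[pk[-length(pk)]] !=
                                   smoothed[pk[-1]])]
  if (length(pk) >= 2) {
    top2 <- sort(pk[order(smoothed[pk], decreasing = TRUE)][1:2])
    inner <- (top2[1] + 1):(top2[2] - 1)
    if (length(inner)) {
      valley <- inner[which.min(smoothed[inner])]
      if (smoothed[valley] < min(smoothed[top2]))
        return(valley - 1)  # bin b holds intensity b - 1
    }
  }
  # unimodal fallback
  255 * EBImage::otsu(EBImage::Image(frame / 255), range = c(0, 1))
}

#' Accumulated dynamic image of a clip
#'
#' Binarizes every frame at the threshold and counts, per pixel, the
#' frames in which the binary value flips relative to the previous
#' frame. Brighter pixels change more often; during a blink the
#' brightest blob is the eye region swept by the lid.
#'
#' @param clip a [frame_sequence()] with at least 2 frames.
#' @param threshold binarization threshold (from
#'   [binarization_threshold()]).
#' @return an integer matrix of per-pixel change counts.
#' @export
accumulate_dynamic_image <- function(clip, threshold) {
  stopifnot(inherits(clip, "frame_sequence"), length(clip$frames) >= 2L)
  prev <- clip$frames[[1]] < threshold
  acc <- matrix(0L, nrow(prev), ncol(prev))
  for (i in seq_along(clip$frames)[-1]) {
    cur <- clip$frames[[i]] < threshold
    acc <- acc + (cur != prev)
    prev <- cur
  }
  acc
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged afterwards with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Locate the eye ROI from the dynamic image
#'
#' Thresholds the accumulation image at a fraction of its maximum,
#' labels the 8-connected components, picks the component with the
#' largest summed accumulation (the "brightest blob" -- the area that
#' changes most during blinking, i.e. the eye), and returns its
#' bounding rectangle expanded by `margin` and clamped to the frame.
#'
#' @param acc accumulation matrix from [accumulate_dynamic_image()].
#' @param margin expansion margin in pixels.
#' @param threshold_frac fraction of the maximum accumulation used to
#'   binarize (default 0.25).
#' @return an object of class `"roi"`: list with `top`, `left`
#'   (1-based), `height`, `width`.
#' @export
find_roi <- function(acc, margin = 5L, threshold_frac = 0.25) {
  if (all(acc == 0))
    stop("no motion: accumulation image is all zero", call. = FALSE)
  mask <- acc >= threshold_frac * max(acc) & acc > 0
  lab <- label_components8(mask)
  sums <- tapply(acc[lab > 0], lab[lab > 0], sum)
  best <- as.integer(names(sums)[which.max(sums)])
  idx <- which(lab == best, arr.ind = TRUE)
  top <- max(1L, min(idx[, 1]) - margin)
  bottom <- min(nrow(acc), max(idx[, 1]) + margin)
  left <- max(1L, min(idx[, 2]) - margin)
  right <- min(ncol(acc), max(idx[, 2]) + margin)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(bottom - top + 1L),
                 width = as.integer(right - left + 1L)),
            class = "roi")
}

new_eyelid_curve <- function(y, inlier = !is.na(y), coeffs = NULL,
                             interpolated = rep(FALSE, length(y))) {
  structure(list(y = y, inlier = inlier, poly_coeffs = coeffs,
                 interpolated = interpolated),
            class = "eyelid_curve")
}

#' Raw per-column upper-eyelid edge
#'
#' For every column of a binarized ROI, the eyelid row is the smallest
#' row index holding a dark-class pixel; columns with no dark pixel are
#' missing.
#'
#' @param binary_roi logical matrix, TRUE = dark (eye) class.
#' @return an `"eyelid_curve"`: list with per-column `y` (NA where
#'   missing), `inlier` mask (initially the defined columns),
#'   `poly_coeffs` (NULL until [remove_outliers()]), `interpolated`.
#' @export
raw_upper_edge <- function(binary_roi) {
  stopifnot(is.matrix(binary_roi))
  has <- colSums(binary_roi) > 0
  y <- rep(NA_real_, ncol(binary_roi))
  if (any(has))
    y[has] <- apply(binary_roi[, has, drop = FALSE], 2, which.max)
  new_eyelid_curve(y)
}

#' Iterative polynomial outlier removal
#'
#' A deterministic alternative to random-sampling RANSAC: fit a
#' polynomial of the given degree to the current inliers by least
#' squares, mark every column whose residual deviates from the median
#' residual by more than `max(tol, 3 * 1.4826 * MAD)` as an outlier
#' (MAD of the residuals about their median), and repeat until an
#' iteration removes nothing, fewer than `degree + 2` inliers would
#' remain, or `max_iter` is reached. Centering the gate on the median
#' residual keeps grouped outliers from masking themselves by dragging
#' the fit. The inlier set only ever shrinks, and the procedure is
#' idempotent on its own output.
#'
#' @param curve an `"eyelid_curve"`.
#' @param degree polynomial degree (default 2: the eyelid arch is
#'   approximately parabolic).
#' @param tol absolute residual tolerance in pixels (default 3).
#' @param max_iter iteration cap (default 20).
#' @return the curve with the final `inlier` mask and fitted
#'   `poly_coeffs` (highest power first, as [pracma::polyfit()]).
#' @export
remove_outliers <- function(curve, degree = 2L, tol = 3, max_iter = 20L) {
  stopifnot(inherits(curve, "eyelid_curve"))
  inlier <- curve$inlier & !is.na(curve$y)
  if (sum(inlier) < degree + 2)
    stop("under-determined fit: need at least degree + 2 defined columns",
         call. = FALSE)
  x_all <- seq_along(curve$y)

  # Robust pre-clean for gross contamination: a plain least-squares
  # seed has breakdown zero -- a group of grossly displaced points can
  # drag it until their residuals look ordinary (masking). When the
  # initial fit shows deviations far beyond tol, a deterministic
  # least-median-of-squares seed (exact minimal-sample fits scored by
  # median absolute residual) exposes the gross points, and only those
  # are dropped here: anything within 10 * tol is structured data the
  # iterative gate below must judge, not the majority fit, so a merely
  # non-parabolic eyelid (e.g. an arch clamped flat at the lid
  # corners) is never eaten by this step.
  idx <- which(inlier)
  fit0 <- pracma::polyfit(idx, curve$y[idx], degree)
  resls <- curve$y[idx] - pracma::polyval(fit0, idx)
  if (max(abs(resls - stats::median(resls))) > 5 * tol) {
    seed <- lms_seed_fit(idx, curve$y[idx], degree)
    if (!is.null(seed)) {
      res0 <- curve$y[idx] - pracma::polyval(seed$coeffs, idx)
      dev0 <- abs(res0 - stats::median(res0))
      bad0 <- dev0 > max(10 * tol, 3 * stats::mad(res0))
      if (any(bad0) && length(idx) - sum(bad0) >= degree + 2)
        inlier[idx[bad0]] <- FALSE
    }
  }

  coeffs <- NULL
  for (it in seq_len(max_iter)) {
    x <- x_all[inlier]; y <- curve$y[inlier]
    coeffs <- pracma::polyfit(x, y, degree)
    res <- y - pracma::polyval(coeffs, x)
    dev <- abs(res - stats::median(res))
    gate <- max(tol, 3 * stats::mad(res))
    bad <- dev > gate
    if (!any(bad)) break
    if (sum(inlier) - sum(bad) < degree + 2) break
    inlier[inlier] <- !bad
  }
  curve$inlier <- inlier
  curve$poly_coeffs <- coeffs
  curve
}

# Least-median-of-squares seed: exact polynomial fits through minimal
# samples (degree + 1 points), drawn exhaustively when few, otherwise
# from a coarse anchor grid; the fit with the smallest median absolute
# residual wins. Deterministic, bounded work.
lms_seed_fit <- function(x, y, degree) {
  m <- length(x)
  p <- degree + 1L
  if (m < p + 2L) return(NULL)
  pool <- if (choose(m, p) <= 600) seq_len(m)
    else unique(round(seq(1, m, length.out = 14)))
  combs <- utils::combn(pool, p)
  best <- NULL; best_score <- Inf
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    A <- outer(x[i], degree:0, `^`)
    cf <- tryCatch(solve(A, y[i]), error = function(e) NULL)
    if (is.null(cf)) next
    score <- stats::median(abs(y - pracma::polyval(cf, x)))
    if (score < best_score) { best_score <- score; best <- cf }
  }
  if (is.null(best)) NULL else list(coeffs = best, score = best_score)
}

#' Fill missing columns of an eyelid curve
#'
#' Columns interior to the inlier span that are missing or were marked
#' as outliers are filled by evaluating the fitted polynomial; columns
#' outside the span stay missing (the blink-matrix conformance step
#' handles those).
#'
#' @param curve an `"eyelid_curve"`, normally after [remove_outliers()];
#'   if no polynomial has been fitted yet a degree-2 fit of the defined
#'   columns is used.
#' @return the curve with every column in the inlier span defined and
#'   `interpolated` flagging the filled columns.
#' @export
interpolate_eyelid <- function(curve) {
  stopifnot(inherits(curve, "eyelid_curve"))
  ok <- curve$inlier & !is.na(curve$y)
  if (sum(ok) < 2)
    stop("need at least 2 inlier columns to interpolate", call. = FALSE)
  coeffs <- curve$poly_coeffs
  if (is.null(coeffs))
    coeffs <- pracma::polyfit(which(ok), curve$y[ok],
                              min(2L, sum(ok) - 1L))
  span <- range(which(ok))
  fill <- setdiff(span[1]:span[2], which(ok))
  if (length(fill)) {
    curve$y[fill] <- pracma::polyval(coeffs, fill)
    curve$interpolated[fill] <- TRUE
    curve$inlier[fill] <- FALSE
  }
  curve$y[setdiff(seq_along(curve$y), span[1]:span[2])] <- NA_real_
  curve$poly_coeffs <- coeffs
  curve
}

#' Estimate the eyelid curve in every frame of a clip
#'
#' Full eyelid stage for one blink clip: the binarization threshold is
#' taken from the clip's first frame (optionally per frame for
#' flicker-heavy input), the ROI once per clip from the accumulated
#' dynamic image, then each frame is cropped, binarized, edge-extracted,
#' outlier-cleaned and interpolated.
#'
#' @param clip a `"blink_clip"` or [frame_sequence()].
#' @param config a [blink_config()].
#' @return a list with `curves` (one `"eyelid_curve"` per frame, y in
#'   ROI-local rows), `roi`, `threshold`.
#' @export
estimate_eyelid_curves <- function(clip, config = blink_config()) {
  seq <- if (inherits(clip, "blink_clip")) clip$frames else clip
  stopifnot(inherits(seq, "frame_sequence"))
  thr <- binarization_threshold(seq$frames[[1]])
  acc <- accumulate_dynamic_image(seq, thr)
  roi <- find_roi(acc, margin = config$roi_margin,
                  threshold_frac = config$acc_threshold_frac)
  rows <- roi$top:(roi$top + roi$height - 1L)
  cols <- roi$left:(roi$left + roi$width - 1L)
  curves <- vector("list", length(seq$frames))
  for (i in seq_along(seq$frames)) {
    sub <- seq$frames[[i]][rows, cols, drop = FALSE]
    thr_i <- if (config$per_frame_threshold && i > 1L)
      binarization_threshold(seq$frames[[i]]) else thr
    curve <- raw_upper_edge(sub < thr_i)
    n_def <- sum(!is.na(curve$y))
    if (n_def >= config$poly_degree + 2) {
      curve <- remove_outliers(curve, degree = config$poly_degree,
                               tol = config$outlier_tol_px,
                               max_iter = config$max_iter)
      curve <- interpolate_eyelid(curve)
    } else if (i > 1L) {
      curve <- curves[[i - 1L]]  # carry over a degenerate frame
    }
    curves[[i]] <- curve
  }
  list(curves = curves, roi = roi, threshold = thr)
}

#' Write eyelid curves as long-format CSV
#'
#' @param est result of [estimate_eyelid_curves()].
#' @param path output CSV (columns frame, column, y_px, inlier,
#'   interpolated); a `roi.json` with the rectangle and threshold is
#'   written next to it.
#' @return invisibly, the CSV path.
#' @export
write_curves_csv <- function(est, path) {
  rows <- do.call(rbind, lapply(seq_along(est$curves), function(i) {
    cv <- est$curves[[i]]
    data.frame(frame = i, column = seq_along(cv$y), y_px = cv$y,
               inlier = as.integer(cv$inlier),
               interpolated = as.integer(cv$interpolated))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(c(unclass(est$roi), list(threshold = est$threshold)),
                       file.path(dirname(path), "roi.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
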