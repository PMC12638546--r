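#' Common eyelid domain length
#'
#' The horizontal domain shared by all frames of a blink: the mode of
#' the per-frame defined-span lengths of the estimated eyelid curves,
#' with ties broken toward the larger length.
#'
#' @param curves list of `"eyelid_curve"` objects.
#' @return integer length.
#' @export
common_domain_length <- function(curves) {
  stopifnot(length(curves) > 0)
  lens <- vapply(curves, function(cv) {
    def <- which(!is.na(cv$y))
    if (!length(def)) 0L else as.integer(diff(range(def)) + 1L)
  }, integer(1))
  lens <- lens[lens > 0]
  tab <- table(lens)
  cand <- as.integer(names(tab)[tab == max(tab)])
  max(cand)
}

#' Conform an eyelid curve to a fixed domain length
#'
#' Curves longer than the domain are center-trimmed symmetrically (an
#' odd excess removes one extra column from the right); shorter curves
#' are extended on both sides, as evenly as possible, by evaluating the
#' curve's fitted polynomial (extrapolation).
#'
#' @param curve an `"eyelid_curve"` with at least 2 defined columns.
#' @param L target length.
#' @return numeric vector of length `L` of eyelid rows.
#' @export
conform_curve <- function(curve, L) {
  stopifnot(inherits(curve, "eyelid_curve"))
  def <- which(!is.na(curve$y))
  stopifnot(length(def) >= 2)
  span <- min(def):max(def)
  y <- curve$y[span]
  n <- length(y)
  if (n == L) return(y)
  if (n > L) {
    excess <- n - L
    left <- excess %/% 2
    right <- excess - left  # odd excess: one extra from the right
    return(y[(left + 1):(n - right)])
  }
  deficit <- L - n
  left <- ceiling(deficit / 2)
  right <- deficit - left
  coeffs <- curve$poly_coeffs
  if (is.null(coeffs))
    coeffs <- pracma::polyfit(span, y, min(2L, n - 1L))
  xs <- c(seq(min(span) - left, length.out = left),
          span,
          seq(max(span) + 1, length.out = right))
  ext <- pracma::polyval(coeffs, xs)
  ext[(left + 1):(left + n)] <- y
  ext
}

#' Assemble the normalized blink matrix
#'
#' Conforms every frame's eyelid curve to the common domain length,
#' resamples each to 500 columns by linear interpolation, converts
#' image rows (downward) to heights (upward-positive), and affinely
#' maps the values so the first frame's vertical extent spans exactly
#' 0.2 to 0.7. The affine parameters are stored for inverse mapping.
#'
#' When the first frame's curve is flat (zero vertical extent) the
#' fallback mapping puts its center at 0.7 and one full aperture
#' (`aperture_px`, e.g. the ROI height) onto the 0.2--0.7 span.
#'
#' @param curves list of `"eyelid_curve"` objects, one per frame.
#' @param fps frames per second.
#' @param config a [blink_config()] (`matrix_width`, `norm_lo`,
#'   `norm_hi`, `norm_mode`).
#' @param aperture_px aperture used by the `"center"` fallback mapping.
#' @return an object of class `"blink_matrix"`: list with `m` (frames x
#'   500 matrix), `fps`, `norm_params` (list `offset`, `scale` mapping
#'   height-px `h` to `offset + scale * h`).
#' @export
build_matrix <- function(curves, fps, config = blink_config(),
                         aperture_px = NULL) {
  stopifnot(length(curves) > 0)
  L <- common_domain_length(curves)
  W <- config$matrix_width
  rows <- lapply(curves, function(cv) {
    y <- conform_curve(cv, L)
    if (L == W) return(y)
    stats::approx(seq_len(L), y, xout = seq(1, L, length.out = W))$y
  })
  m_px <- do.call(rbind, rows)
  h <- -m_px  # larger = higher in the image = more open
  first <- h[1, ]
  lo <- config$norm_lo; hi <- config$norm_hi
  extent <- max(first) - min(first)
  if (config$norm_mode == "extent" && extent > 0) {
    scale <- (hi - lo) / extent
    offset <- lo - scale * min(first)
  } else {
    if (config$norm_mode == "extent")
      warning("first frame has zero vertical extent; ",
              "falling back to center normalization")
    if (is.null(aperture_px) || aperture_px <= 0)
      stop("center normalization needs a positive aperture_px",
           call. = FALSE)
    scale <- (hi - lo) / aperture_px
    offset <- hi - scale * mean(first)
  }
  structure(list(m = offset + scale * h, fps = fps,
                 norm_params = list(offset = offset, scale = scale)),
            class = "blink_matrix")
}

#' Invert the blink-matrix normalization
#'
#' @param bm a `"blink_matrix"`.
#' @return matrix of eyelid rows in pixels (image coordinates, row 0 at
#'   the top).
#' @export
matrix_to_pixels <- function(bm) {
  -(bm$m - bm$norm_params$offset) / bm$norm_params$scale
}

#' Write a blink matrix as CSV
#'
#' @param bm a `"blink_matrix"`.
#' @param path output path; fps and the normalization parameters are
#'   recorded in a comment line above the header.
#' @return invisibly, `path`.
#' @export
write_matrix_csv <- function(bm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%.10g offset=%.10g scale=%.10g", bm$fps,
                     bm$norm_params$offset, bm$norm_params$scale), con)
  utils::write.table(bm$m, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# the standard jet palette anchors, evaluated as an RGB lookup
jet_colors <- function(n = 256L) {
  grDevices::colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan",
                                "#7FFF7F", "yellow", "#FF7F00", "red",
                                "#7F0000"))(n)
}

#' Render the 2-D projection image of a blink matrix
#'
#' The single-image blink visualization: x is time (one pixel column
#' per frame), y is the eyelid domain (500 rows), and color encodes the
#' normalized eyelid height through the jet palette. Vertical red
#' dotted lines mark every interior multiple of 0.1 s so durations can
#' be compared across images.
#'
#' @param bm a `"blink_matrix"`.
#' @param path output PNG path.
#' @param config a [blink_config()] (`gridline_interval_s`).
#' @param zlim value range mapped onto the palette (default 0.2--0.7).
#' @return invisibly, the RGB array written (rows x frames x 3).
#' @export
render_projection <- function(bm, path, config = blink_config(),
                              zlim = c(config$norm_lo, config$norm_hi)) {
  vals <- t(bm$m)  # rows = eyelid domain, cols = frames
  pal <- jet_colors(256L)
  idx <- pmin(256L, pmax(1L, 1L +
    floor((vals - zlim[1]) / (zlim[2] - zlim[1]) * 255.999)))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, c(nrow(vals), ncol(vals), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(vals))
  img[, , 2] <- matrix(rgb[2, ], nrow(vals))
  img[, , 3] <- matrix(rgb[3, ], nrow(vals))
  for (col in gridline_columns(ncol(vals), bm$fps,
                               config$gridline_interval_s)) {
    dotted <- seq(1, nrow(vals), by = 2)
    img[dotted, col, 1] <- 1
    img[dotted, col, 2] <- 0
    img[dotted, col, 3] <- 0
  }
  png::writePNG(img, path)
  invisible(img)
}

# frame columns of the red gridlines: every multiple of the interval
# strictly inside the clip's time span
gridline_columns <- function(n_frames, fps, interval_s) {
  t_end <- (n_frames - 1) / fps
  k <- seq_len(floor(t_end / interval_s - 1e-9))
  cols <- round(k * interval_s * fps) + 1L
  cols[cols > 1L & cols < n_frames]
}

#' Render the 3-D surface graph of a blink matrix
#'
#' Cosmetic companion of [render_projection()]: a perspective surface
#' with time on x, the eyelid domain on y and normalized height on z,
#' facets colored by the jet palette.
#'
#' @param bm a `"blink_matrix"`.
#' @param path output PNG path.
#' @param downsample keep every k-th domain column for plotting speed
#'   (default 5).
#' @return invisibly, `path`.
#' @export
render_surface <- function(bm, path, downsample = 5L) {
  z <- bm$m[, seq(1, ncol(bm$m), by = downsample), drop = FALSE]
  facet <- (z[-1, -1] + z[-1, -ncol(z)] + z[-nrow(z), -1] +
              z[-nrow(z), -ncol(z)]) / 4
  rng <- range(z)
  pal <- jet_colors(256L)
  col <- if (rng[2] > rng[1])
    pal[1L + floor((facet - rng[1]) / (rng[2] - rng[1]) * 255.999)]
  else pal[128L]
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::persp(x = (seq_len(nrow(z)) - 1) / bm$fps,
                  y = seq_len(ncol(z)), z = z, col = col,
                  theta = 35, phi = 25, expand = 0.6, border = NA,
                  xlab = "time (s)", ylab = "eyelid domain",
                  zlab = "normalized height",
                  zlim = if (rng[2] > rng[1]) rng else rng + c(-0.5, 0.5))
  invisible(path)
}
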