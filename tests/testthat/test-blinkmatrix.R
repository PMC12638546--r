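curve_of_len <- function(n, offset = 0) make_curve(rep(10, n) + offset)

test_that("the common domain length is the modal span, ties to larger", {
  expect_equal(common_domain_length(list(curve_of_len(100),
                                         curve_of_len(100),
                                         curve_of_len(98))), 100)
  expect_equal(common_domain_length(list(curve_of_len(90),
                                         curve_of_len(100))), 100)
  expect_equal(common_domain_length(list(curve_of_len(77))), 77)
})

test_that("conformance trims centrally and extrapolates the polynomial", {
  y104 <- seq_len(104) * 0 + 5
  expect_length(conform_curve(make_curve(y104), 100), 100)
  marked <- seq_len(104)
  out <- conform_curve(make_curve(marked), 100)
  expect_equal(out, 3:102)  # 2 trimmed each side
  out_odd <- conform_curve(make_curve(marked), 99)
  expect_equal(out_odd, 3:101)  # odd excess: extra from the right
  # extension reproduces an exact parabola analytically
  x <- 1:96
  para <- function(x) 0.02 * x^2 - x + 80
  cv <- remove_outliers(make_curve(para(x)), degree = 2, tol = 3)
  ext <- conform_curve(cv, 100)
  expect_equal(ext, para(-1:98), tolerance = 1e-6)
  expect_equal(conform_curve(cv, 96), para(x), tolerance = 1e-9)
})

test_that("the matrix is 500 wide and its first row spans exactly 0.2-0.7", {
  curves <- lapply(1:8, function(i)
    make_curve(0.02 * ((1:91) - 46)^2 + 40 + i))
  bm <- build_matrix(curves, fps = 240)
  expect_equal(dim(bm$m), c(8, 500))
  expect_equal(range(bm$m[1, ]), c(0.2, 0.7), tolerance = 1e-12)
  # identical curves give identical rows
  same <- build_matrix(rep(list(curves[[1]]), 5), fps = 240)
  expect_true(all(apply(same$m, 2, function(col) all(col == col[1]))))
})

test_that("normalization is affine invariant and invertible", {
  base <- lapply(1:6, function(i)
    make_curve(0.015 * ((1:80) - 40)^2 + 30 + 3 * i))
  bm1 <- build_matrix(base, fps = 240)
  scaled <- lapply(base, function(cv) make_curve(2.5 * cv$y + 17))
  bm2 <- build_matrix(scaled, fps = 240)
  expect_equal(bm1$m, bm2$m, tolerance = 1e-9)
  # inverse mapping recovers first-row pixel rows within resampling error
  px <- matrix_to_pixels(bm1)
  y1 <- conform_curve(base[[1]], common_domain_length(base))
  resampled <- stats::approx(seq_along(y1), y1,
                             xout = seq(1, length(y1),
                                        length.out = 500))$y
  expect_lt(max(abs(px[1, ] - resampled)), 0.5)
})

test_that("a flat first frame falls back to center normalization", {
  flat <- c(list(make_curve(rep(55, 60))),
            lapply(1:4, function(i) make_curve(rep(55 - 6 * i, 60))))
  expect_warning(bm <- build_matrix(flat, fps = 240, aperture_px = 40),
                 "zero vertical extent")
  expect_equal(unique(bm$m[1, ]), 0.7, tolerance = 1e-12)
  expect_error(suppressWarnings(build_matrix(flat, fps = 240)),
               "aperture")
})

test_that("gridlines sit at interior multiples of 0.1 s", {
  expect_equal(gridline_columns(240, 240, 0.1), 24 * (1:9) + 1)
  expect_equal(gridline_columns(48, 240, 0.1), 25)
  expect_length(gridline_columns(20, 240, 0.1), 0)
})

test_that("the projection image encodes values in jet with red gridlines", {
  m <- matrix(0.7, 60, 500)
  bm <- structure(list(m = m, fps = 240,
                       norm_params = list(offset = 0, scale = 1)),
                  class = "blink_matrix")
  path <- file.path(withr::local_tempdir(), "proj.png")
  img <- render_projection(bm, path)
  expect_true(file.exists(path))
  expect_equal(dim(img), c(500, 60, 3))
  red <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  red_cols <- which(colSums(red) > 100)
  expect_equal(red_cols, gridline_columns(60, 240, 0.1))
  # away from gridlines the image is the uniform jet color for 0.7
  plain <- img[, -red_cols, ]
  expect_equal(length(unique(as.vector(plain[, , 1]))), 1)
  back <- png::readPNG(path)
  expect_equal(dim(back), c(500, 60, 3))
})

test_that("the 3-D surface renders to a non-empty file", {
  curves <- lapply(1:10, function(i)
    make_curve(0.02 * ((1:91) - 46)^2 + 40 + i))
  bm <- build_matrix(curves, fps = 240)
  path <- file.path(withr::local_tempdir(), "surf.png")
  render_surface(bm, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  flatbm <- structure(list(m = matrix(0.5, 10, 100), fps = 240,
                           norm_params = list(offset = 0, scale = 1)),
                      class = "blink_matrix")
  path2 <- file.path(withr::local_tempdir(), "flat.png")
  render_surface(flatbm, path2)
  expect_true(file.size(path2) > 0)
})

test_that("matrix CSV round-trips values and metadata", {
  curves <- lapply(1:5, function(i)
    make_curve(0.02 * ((1:60) - 30)^2 + 20 + i))
  bm <- build_matrix(curves, fps = 240)
  path <- file.path(withr::local_tempdir(), "m.csv")
  write_matrix_csv(bm, path)
  header <- readLines(path, n = 1)
  expect_match(header, "fps=240")
  vals <- as.matrix(utils::read.csv(path, skip = 1, header = FALSE))
  expect_equal(unname(vals), unname(bm$m), tolerance = 1e-9)
})
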