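test_that("histogram valley separates a bimodal image exactly", {
  set.seed(3)
  vals <- sample(c(rep(60, 50), rep(200, 50)))
  img <- matrix(vals, 10, 10)
  thr <- binarization_threshold(img)
  expect_gt(thr, 60); expect_lt(thr, 200)
  expect_identical(img < thr, img == 60)
  expect_error(binarization_threshold(matrix(128, 5, 5)), "degenerate")
})

test_that("the threshold labels exactly the eye region on a clean scene", {
  r <- render_blink_video(list(), scene = scene_spec(noise_sd = 0),
                          fps = 240, duration_ms = 50)
  f <- r$seq$frames[[1]]
  thr <- binarization_threshold(f)
  expect_identical(f < thr, f == 40)  # eye_gray pixels only
})

test_that("the dynamic image counts binary flips per pixel", {
  static <- frame_sequence(rep(list(matrix(200, 4, 4)), 6), 240)
  expect_true(all(accumulate_dynamic_image(static, 100) == 0))
  n <- 9
  frames <- lapply(seq_len(n), function(i) {
    f <- matrix(200, 4, 4)
    if (i %% 2 == 0) f[2, 3] <- 10
    f
  })
  acc <- accumulate_dynamic_image(frame_sequence(frames, 240), 100)
  expect_equal(acc[2, 3], n - 1)
  expect_equal(sum(acc), n - 1)
})

test_that("find_roi picks the heaviest blob and respects bounds", {
  acc <- matrix(0L, 60, 80)
  acc[21:30, 31:40] <- 5L
  roi <- find_roi(acc, margin = 0)
  expect_equal(unclass(roi)[c("top", "left", "height", "width")],
               list(top = 21L, left = 31L, height = 10L, width = 10L))
  # second blob with larger summed accumulation wins
  acc2 <- acc
  acc2[41:46, 10:15] <- 25L  # sum 900 vs 500
  roi2 <- find_roi(acc2, margin = 0)
  expect_equal(roi2$top, 41L); expect_equal(roi2$left, 10L)
  # margin clamps at the image edge
  acc3 <- matrix(0L, 20, 20); acc3[1:4, 1:4] <- 3L
  roi3 <- find_roi(acc3, margin = 5)
  expect_equal(c(roi3$top, roi3$left), c(1L, 1L))
  expect_equal(c(roi3$height, roi3$width), c(9L, 9L))
  expect_error(find_roi(matrix(0L, 5, 5)), "no motion")
})

test_that("find_roi is translation equivariant", {
  base <- matrix(0L, 50, 50); base[11:18, 21:26] <- 4L
  r1 <- find_roi(base, margin = 2)
  shifted <- matrix(0L, 50, 50); shifted[16:23, 11:16] <- 4L
  r2 <- find_roi(shifted, margin = 2)
  expect_equal(r2$top - r1$top, 5L)
  expect_equal(r2$left - r1$left, -10L)
  expect_equal(c(r2$height, r2$width), c(r1$height, r1$width))
})

test_that("raw upper edge takes the first dark row per column", {
  expect_true(all(is.na(raw_upper_edge(matrix(FALSE, 5, 4))$y)))
  rect <- matrix(FALSE, 30, 6); rect[10:20, ] <- TRUE
  expect_equal(raw_upper_edge(rect)$y, rep(10, 6))
  mixed <- matrix(FALSE, 10, 3)
  mixed[4:9, 1] <- TRUE; mixed[7, 3] <- TRUE
  cv <- raw_upper_edge(mixed)
  expect_equal(cv$y, c(4, NA, 7))
  expect_equal(cv$inlier, c(TRUE, FALSE, TRUE))
})

test_that("iterative removal isolates a planted outlier and recovers the fit", {
  x <- 1:50
  y <- 0.01 * x^2 + 30
  y[23] <- y[23] + 40
  cv <- remove_outliers(make_curve(y), degree = 2, tol = 3)
  expect_equal(which(!cv$inlier), 23)
  expect_equal(cv$poly_coeffs, c(0.01, 0, 30), tolerance = 1e-6)
  # leave-one-out oracle: removing point 23 gives the lowest SSE
  sse <- vapply(x, function(k) {
    cf <- pracma::polyfit(x[-k], y[-k], 2)
    sum((y[-k] - pracma::polyval(cf, x[-k]))^2)
  }, numeric(1))
  expect_equal(which.min(sse), 23)
})

test_that("consistent data keeps every point", {
  y <- 2 * (1:20) + 5
  cv <- remove_outliers(make_curve(y), degree = 2, tol = 3)
  expect_true(all(cv$inlier))
  expect_lt(max(abs(y - pracma::polyval(cv$poly_coeffs, 1:20))), 1e-8)
  expect_error(remove_outliers(make_curve(c(1, 2, 3)), degree = 2),
               "degree \\+ 2")
})

test_that("removal matches exhaustive RANSAC on a scattered instance", {
  set.seed(17)
  x <- 1:10
  y <- 0.5 * x^2 - 3 * x + 40
  bad <- c(2, 5, 6, 9)
  y[bad] <- y[bad] + c(45, -60, 80, 55)  # > 10 * tol
  cv <- remove_outliers(make_curve(y), degree = 2, tol = 3)
  expect_equal(which(cv$inlier), setdiff(1:10, bad))
  expect_equal(which(ransac_consensus(x, y, 3)), setdiff(1:10, bad))
})

test_that("removal shrinks monotonically and is idempotent", {
  set.seed(9)
  for (rep in 1:5) {
    y <- 0.02 * (1:40)^2 + rnorm(40, sd = 1)
    y[sample(40, 3)] <- y[sample(40, 3)] + 50
    cv1 <- remove_outliers(make_curve(y), degree = 2, tol = 3)
    expect_lte(sum(cv1$inlier), 40)
    cv2 <- remove_outliers(cv1, degree = 2, tol = 3)
    expect_identical(cv2$inlier, cv1$inlier)
  }
})

test_that("interpolation fills interior gaps from the fitted polynomial", {
  x <- 1:40
  y <- 0.03 * x^2 - x + 25
  gap <- 18:22
  y_missing <- y; y_missing[gap] <- NA
  cv <- remove_outliers(make_curve(y_missing), degree = 2, tol = 3)
  filled <- interpolate_eyelid(cv)
  expect_lt(max(abs(filled$y[gap] - y[gap])), 0.5)
  expect_true(all(filled$interpolated[gap]))
  # no gaps: identity
  cv2 <- interpolate_eyelid(remove_outliers(make_curve(y), 2, 3))
  expect_equal(cv2$y, y, tolerance = 1e-8)
  # end gaps stay missing
  y_end <- y; y_end[c(1:3, 38:40)] <- NA
  cv3 <- interpolate_eyelid(remove_outliers(make_curve(y_end), 2, 3))
  expect_true(all(is.na(cv3$y[c(1:3, 38:40)])))
  expect_true(all(!is.na(cv3$y[4:37])))
})

test_that("eyelid recovery tracks ground truth through a blink", {
  run_recovery <- function(noise_sd, seed, tol_px) {
    r <- render_single(close_ms = 120, closed_ms = 60, open_ms = 200,
                       noise_sd = noise_sd, seed = seed,
                       pre = 250, post = 250)
    est <- estimate_eyelid_curves(r$seq)
    cx_roi <- round(160 / 2) - est$roi$left + 1
    blink <- which(r$truth$df$phase != "open")
    err <- vapply(blink, function(i) {
      est_row <- est$curves[[i]]$y[cx_roi] + est$roi$top - 1
      abs(est_row - r$truth$df$eyelid_y_px[i])
    }, numeric(1))
    mean(err <= tol_px, na.rm = TRUE)
  }
  expect_gte(run_recovery(0, 51, 1), 0.95)
  expect_gte(run_recovery(5, 52, 2), 0.90)
})
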