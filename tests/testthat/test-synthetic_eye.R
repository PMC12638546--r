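test_that("trajectory phase labels match the segment durations", {
  r <- render_blink_video(
    blink_spec(pre_open_ms = 300, close_ms = 120, closed_ms = 40,
               open_ms = 200, post_open_ms = 300, amplitude = 1),
    scene = scene_spec(noise_sd = 0), fps = 240)
  counts <- table(factor(r$truth$df$phase,
                         levels = c("open", "closing", "closed",
                                    "opening")))
  expect_lte(abs(counts[["closing"]] - round(120 * 0.24)), 1)
  expect_lte(abs(counts[["closed"]] - round(40 * 0.24)), 1)
  expect_lte(abs(counts[["opening"]] - round(200 * 0.24)), 1)
})

test_that("amplitude maps linearly onto the 0.2-0.7 displacement scale", {
  r <- render_blink_video(
    blink_spec(close_ms = 100, closed_ms = 60, open_ms = 100,
               amplitude = 0.5),
    scene = scene_spec(noise_sd = 0), fps = 240)
  expect_equal(min(r$truth$df$displacement), 0.45, tolerance = 1e-9)
  expect_equal(max(r$truth$df$displacement), 0.7, tolerance = 1e-9)
  expect_true(all(r$truth$df$displacement >= 0.2 - 1e-9 &
                    r$truth$df$displacement <= 0.7 + 1e-9))
})

test_that("a blink-free noiseless scene renders identical frames", {
  r <- render_blink_video(list(), scene = scene_spec(noise_sd = 0),
                          fps = 240, duration_ms = 100)
  expect_true(all(vapply(r$seq$frames[-1],
                         function(f) identical(f, r$seq$frames[[1]]),
                         logical(1))))
  expect_true(all(r$truth$df$phase == "open"))
})

test_that("the same seed reproduces frames bit for bit", {
  a <- render_blink_video(blink_spec(), scene = scene_spec(seed = 42),
                          fps = 240)
  b <- render_blink_video(blink_spec(), scene = scene_spec(seed = 42),
                          fps = 240)
  expect_identical(a$seq$frames, b$seq$frames)
  c <- render_blink_video(blink_spec(), scene = scene_spec(seed = 43),
                          fps = 240)
  expect_false(identical(a$seq$frames, c$seq$frames))
})

test_that("the rendered upper edge matches the analytic arch within 1 px", {
  sc <- scene_spec(noise_sd = 0)
  r <- render_blink_video(
    blink_spec(pre_open_ms = 100, close_ms = 200, closed_ms = 50,
               open_ms = 200, post_open_ms = 100),
    scene = sc, fps = 240)
  open_row <- (sc$height - sc$aperture_px) / 2
  lower_lid <- open_row + sc$aperture_px
  cx <- round(sc$width / 2)
  half_w <- floor(sqrt(sc$aperture_px / sc$arch_curvature) - 1e-9)
  cols <- (cx - half_w):(cx + half_w)
  for (i in c(1, 40, 60, 80, 120)) {
    f <- r$seq$frames[[i]]
    apex <- r$truth$df$eyelid_y_px[i]
    analytic <- pmin(apex + sc$arch_curvature * (cols - cx)^2, lower_lid)
    measured <- vapply(cols, function(c)
      which.max(f[, c] < (sc$skin_gray + sc$eye_gray) / 2), numeric(1))
    expect_true(all(abs(measured - analytic) <= 1),
                label = sprintf("frame %d edge within 1 px", i))
  }
})

test_that("invalid blink parameters are rejected", {
  expect_error(blink_spec(amplitude = 1.2), "amplitude")
  expect_error(blink_spec(amplitude = 0), "amplitude")
  expect_error(blink_spec(close_ms = -5), "durations")
  expect_error(render_blink_video(list()), "duration_ms")
  expect_error(scene_spec(eye_gray = 200, skin_gray = 180), "darker")
})

test_that("standard fixtures carry the narrated ground truth", {
  fx <- get_fixtures()
  expect_named(fx, c("NORMAL", "INCOMPLETE", "PROLONGED", "CONSECUTIVE"))
  nm <- fx$NORMAL$truth$measured
  per <- 1000 / 240
  expect_lte(abs(nm$closing_frames * per - 116), per)
  expect_lte(abs(nm$closed_frames * per - 30), per)
  expect_lte(abs(nm$opening_frames * per - 216), per)
  inc <- fx$INCOMPLETE$truth$measured
  expect_lte(abs(inc$min_displacement - 0.456), 0.02)
  expect_false(inc$complete)
  pro <- fx$PROLONGED$truth$measured
  ratio <- pro$closed_frames /
    (pro$closing_frames + pro$closed_frames + pro$opening_frames) * 100
  expect_lte(abs(ratio - 40), 3)
  # consecutive: two descents, reopening peak below the open level
  d <- fx$CONSECUTIVE$truth$df$displacement
  mins <- which(diff(sign(diff(d))) > 0) + 1
  mins <- mins[d[mins] < 0.65]
  expect_gte(length(mins), 2)
  between <- max(d[min(mins):max(mins)])
  expect_lt(between, d[1] - 0.05)
})
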