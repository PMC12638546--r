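make_candidates <- function(x1, x2, x3, y1, y2, y3, fps = 240) {
  df <- data.frame(x1 = x1, x2 = x2, x3 = x3, y1 = y1, y2 = y2, y3 = y3,
                   status = "candidate", reject_reason = "none",
                   stringsAsFactors = FALSE)
  attr(df, "fps") <- fps
  class(df) <- c("blink_candidates", "data.frame")
  df
}

test_that("a flat profile yields no candidates", {
  p <- structure(list(values = rep(130, 200), fps = 240),
                 class = "intensity_profile")
  expect_equal(nrow(detect_candidates(p)), 0)
  short <- structure(list(values = c(1, 2), fps = 240),
                     class = "intensity_profile")
  expect_warning(out <- detect_candidates(short), "smoothing window")
  expect_equal(nrow(out), 0)
})

test_that("detection finds one candidate per blink, in order", {
  fx <- get_fixtures()$NORMAL
  cands <- detect_candidates(mean_intensity_profile(fx$seq),
                             simulate_events(fx$seq))
  expect_equal(nrow(cands), 1)
  expect_true(cands$x1 < cands$x2 & cands$x2 < cands$x3)
  d <- fx$truth$df$displacement
  gt_span <- range(which(d < d[1] - 0.01))
  expect_lte(abs(cands$x1 - gt_span[1]), 10)
  expect_lte(abs(cands$x3 - gt_span[2]), 10)

  b3 <- render_blink_video(
    list(blink_spec(pre_open_ms = 800), blink_spec(pre_open_ms = 1500),
         blink_spec(pre_open_ms = 1500, post_open_ms = 1000)),
    scene = scene_spec(noise_sd = 2, seed = 31), fps = 240)
  c3 <- detect_candidates(mean_intensity_profile(b3$seq),
                          simulate_events(b3$seq))
  expect_equal(nrow(c3), 3)
  expect_true(all(diff(c3$x1) > 0))
})

test_that("duration and symmetry filters set status and reason", {
  fps <- 240
  mk <- function(dur_ms, y1, y2, y3)
    make_candidates(100, 100 + round(dur_ms / 2 * fps / 1000),
                    100 + round(dur_ms * fps / 1000), y1, y2, y3, fps)
  expect_equal(filter_candidates(mk(40, 100, 110, 100))$reject_reason,
               "too_short")
  expect_equal(filter_candidates(mk(1600, 100, 110, 100))$reject_reason,
               "too_long")
  # rise 10, fall 7: mismatch 30% -> asymmetric
  expect_equal(filter_candidates(mk(300, 100, 110, 103))$reject_reason,
               "asymmetric")
  # rise 10, fall 9: mismatch 10% -> accepted
  acc <- filter_candidates(mk(300, 100, 110, 101))
  expect_equal(acc$status, "accepted")
  expect_equal(acc$reject_reason, "none")
})

test_that("clips are padded, clamped, and map back to the source", {
  frames <- rep(list(matrix(100, 4, 4)), 200)
  fs <- frame_sequence(frames, fps = 240)
  cands <- make_candidates(c(100, 3), c(130, 8), c(160, 13),
                           100, 110, 100)
  cands$status <- "accepted"
  clips <- extract_clips(fs, cands, pad = 12)
  expect_length(clips, 2)
  expect_length(clips[[1]]$frames$frames, 160 + 12 - (100 - 12) + 1)
  expect_equal(clips[[1]]$source_span, c(x1 = 100, x3 = 160))
  # clamped at the video start
  expect_length(clips[[2]]$frames$frames, 13 + 12)
  none <- cands; none$status <- "rejected"
  expect_length(extract_clips(fs, none, pad = 12), 0)
})

test_that("summary statistics follow their definitions", {
  cands <- make_candidates(1:5 * 100, 1:5 * 100 + 20, 1:5 * 100 + 50,
                           100, 110, 100)
  cands$status <- "accepted"
  s <- blink_statistics(cands, 60, durations_ms = c(100, 200, 300),
                        labels = c("normal", "incomplete", "normal"))
  expect_equal(s$rate_per_min, 5)
  expect_equal(s$mean_duration_ms, 200)
  expect_equal(s$sd_duration_ms, sqrt(20000 / 3), tolerance = 1e-9)
  expect_equal(s$incomplete_ratio_pct, 100 / 3, tolerance = 1e-9)
  s2 <- blink_statistics(cands, 60, durations_ms = rep(1200, 5))
  expect_equal(s2$closure_proportion_pct, 10)
})

test_that("detection stays sensitive under noise and quiet on static video", {
  hits <- 0L
  for (s in 1:10) {
    v <- render_single(close_ms = 100, closed_ms = 50, noise_sd = 5,
                       seed = 200 + s)
    cc <- filter_candidates(detect_candidates(
      mean_intensity_profile(v$seq), simulate_events(v$seq)), 240)
    hits <- hits + (sum(cc$status == "accepted") == 1L)
  }
  expect_gte(hits, 9)
  for (s in 1:4) {
    bf <- render_blink_video(list(),
                             scene = scene_spec(noise_sd = 5,
                                                seed = 300 + s),
                             fps = 240, duration_ms = 1500)
    c0 <- detect_candidates(mean_intensity_profile(bf$seq),
                            simulate_events(bf$seq))
    expect_equal(nrow(c0), 0)
  }
})
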