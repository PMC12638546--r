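# shared fixtures, rendered once per test session
.fixture_env <- new.env(parent = emptyenv())

get_fixtures <- function() {
  if (is.null(.fixture_env$fx)) .fixture_env$fx <- standard_fixtures()
  .fixture_env$fx
}

get_fixture_fits <- function() {
  if (is.null(.fixture_env$fits))
    .fixture_env$fits <- lapply(get_fixtures(),
                                function(f) blink_analysis(f$seq))
  .fixture_env$fits
}

# one-blink video under configurable conditions
render_single <- function(close_ms, closed_ms, open_ms = 200,
                          amplitude = 1, noise_sd = 2, seed = 1,
                          fps = 240, pre = 400, post = 300) {
  render_blink_video(
    blink_spec(pre_open_ms = pre, close_ms = close_ms,
               closed_ms = closed_ms, open_ms = open_ms,
               post_open_ms = post, amplitude = amplitude),
    scene = scene_spec(noise_sd = noise_sd, seed = seed), fps = fps)
}

# displacement trace whose segmented phase durations are exactly the
# given millisecond values (1 frame per ms): open hold, descent held
# above the closed threshold, closed hold, symmetric ascent
synth_trace <- function(closing_ms, closed_ms, opening_ms, d0 = 0.7,
                        dmin = 0.21, fps = 1000) {
  d <- c(rep(d0, 10),
         seq(d0 - 0.02, 0.251, length.out = closing_ms),
         rep(dmin, closed_ms),
         seq(0.251, d0 - 0.02, length.out = opening_ms),
         rep(d0, 10))
  blinkscope:::new_displacement_trace(d, fps)
}

# an eyelid_curve from a plain numeric vector (NA = missing)
make_curve <- function(y, coeffs = NULL) {
  blinkscope:::new_eyelid_curve(y, coeffs = coeffs)
}

# scalar brute-force oracle for the per-pixel event rule
oracle_events <- function(trace, threshold) {
  ref <- trace[1]
  fires <- logical(length(trace))
  for (i in seq_along(trace)[-1]) {
    if (abs(trace[i] - ref) > threshold) {
      fires[i] <- TRUE
      ref <- trace[i]
    }
  }
  fires
}

# classical RANSAC with exhaustive minimal (3-point) sampling for a
# degree-2 model: consensus = points within tol; ties broken by the
# consensus sum of squared residuals
ransac_consensus <- function(x, y, tol) {
  n <- length(x)
  best <- NULL; best_k <- -1L; best_sse <- Inf
  combs <- utils::combn(n, 3L)
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    A <- cbind(x[i]^2, x[i], 1)
    if (abs(det(A)) < 1e-9) next
    cf <- solve(A, y[i])
    res <- abs(y - (cf[1] * x^2 + cf[2] * x + cf[3]))
    cons <- res <= tol
    k <- sum(cons)
    sse <- sum(res[cons]^2)
    if (k > best_k || (k == best_k && sse < best_sse)) {
      best_k <- k; best <- cons; best_sse <- sse
    }
  }
  best
}
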