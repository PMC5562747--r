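test_that("frame differences match an elementwise oracle", {
  f <- matrix(100, 8, 8)
  seq0 <- frame_sequence(list(f, f), fps = 10)
  expect_equal(frame_difference(seq0), list(matrix(0, 8, 8)))

  g <- f; g[3, 5] <- 150
  d <- frame_difference(frame_sequence(list(f, g), fps = 10))[[1]]
  expect_equal(sum(d != 0), 1)
  expect_equal(d[3, 5], 50)

  set.seed(11)
  a <- matrix(sample(0:255, 64, TRUE), 8, 8)
  b <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_equal(frame_difference(frame_sequence(list(a, b), fps = 10))[[1]],
               oracle_abs_diff(a, b))

  expect_error(frame_difference(frame_sequence(list(f), fps = 10)),
               "at least 2")
})

test_that("automatic threshold follows the pooled mean + k*sd rule", {
  zero <- list(matrix(0, 4, 4))
  expect_equal(auto_threshold(zero), 1.0)
  tr <- threshold_motion(zero, auto_threshold(zero))
  expect_equal(tr$counts, 0)

  vals <- c(0, 0, 0, 10)
  diffs <- list(matrix(vals, 2, 2))
  expect_equal(auto_threshold(diffs, auto_k = 3), mean(vals) + 3 * sd(vals))

  # for symmetric Gaussian difference values, mean + 3 sd cuts off ~0.135 %
  set.seed(5)
  n_px <- 4e5
  gauss <- list(matrix(stats::rnorm(n_px, sd = 4), 500, 800))
  tau <- auto_threshold(gauss, auto_k = 3)
  frac <- sum(gauss[[1]] > tau) / n_px
  p <- stats::pnorm(3, lower.tail = FALSE)
  se <- sqrt(p * (1 - p) / n_px)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("supra-threshold counting is exact and uses strict inequality", {
  set.seed(21)
  for (rep in 1:10) {
    g <- matrix(sample(0:40, 64, TRUE), 8, 8)
    tau <- runif(1, 1, 35)
    tr <- threshold_motion(list(g), tau)
    expect_equal(tr$counts, oracle_count_above(g, tau))
    expect_lte(tr$counts, 64)
  }
  g <- matrix(c(5, 5, 5, 7), 2, 2)
  expect_equal(threshold_motion(list(g), tau = 5)$counts, 1)  # ties excluded
  expect_error(threshold_motion(list(g), tau = 0), "> 0")
})

test_that("motion trace composition behaves on synthetic videos", {
  static <- generate_beating_video(
    video_truth(bpm_trajectory = 60, amplitude_frac = 0, noise_sd = 0,
                duration_s = 3, size_px = 48))$seq
  tr <- compute_motion_trace(static)
  expect_true(all(tr$counts == 0))

  gen <- generate_beating_video(
    video_truth(bpm_trajectory = 60, duration_s = 10, size_px = 64, seed = 9))
  auto <- compute_motion_trace(gen$seq)
  fixed <- compute_motion_trace(
    gen$seq, motion_params(threshold_mode = "fixed", tau = auto$tau_used))
  expect_identical(auto$counts, fixed$counts)   # mode equivalence

  # dominant spectral component of the smoothed trace is the 1 Hz beat
  x <- trace_signal(auto) - mean(trace_signal(auto))
  spec <- Mod(stats::fft(x))[2:(length(x) %/% 2)]
  f_grid <- (seq_along(spec)) * auto$fps / length(x)
  expect_lt(abs(f_grid[which.max(spec)] - 1), 0.15)
})

test_that("counts are invariant to constant offsets and monotone in auto_k", {
  set.seed(31)
  frames <- replicate(6, matrix(sample(0:200, 256, TRUE), 16, 16),
                      simplify = FALSE)
  seq1 <- frame_sequence(frames, fps = 10)
  shifted <- frame_sequence(lapply(frames, function(f) f + 50), fps = 10)
  p <- motion_params(smooth_window_s = 0)
  expect_identical(compute_motion_trace(seq1, p)$counts,
                   compute_motion_trace(shifted, p)$counts)

  diffs <- frame_difference(seq1)
  c1 <- threshold_motion(diffs, auto_threshold(diffs, 3))$counts
  c2 <- threshold_motion(diffs, auto_threshold(diffs, 6))$counts
  expect_true(all(c2 <= c1))
})

test_that("smoothing preserves length and the trace exports cleanly", {
  tr <- compute_motion_trace(generate_beating_video(
    video_truth(bpm_trajectory = 90, duration_s = 5, size_px = 48,
                seed = 2))$seq)
  expect_length(tr$counts_smoothed, length(tr$counts))
  df <- trace_to_df(tr)
  expect_named(df, c("time_s", "count", "count_smoothed"))
  expect_equal(nrow(df), length(tr$counts))
  expect_true(all(diff(df$time_s) > 0))
})
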