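test_that("constant traces yield no beats", {
  tr <- make_trace(rep(5, 100))
  s <- detect_beats(tr)
  expect_length(s$peak_times_s, 0)
  expect_error(detect_beats(make_trace(numeric(0))), "empty")
})

test_that("peak detection matches the exhaustive brute-force definition", {
  set.seed(123)
  bp <- beat_params()
  for (i in 1:60) {
    n <- sample(5:200, 1)
    x <- sample(0:10, n, TRUE)          # integer traces exercise plateaus
    tr <- make_trace(x, fps = 30)
    got <- detect_beats(tr, bp)$indices
    want <- oracle_peaks(x, bp$prominence_frac, bp$refractory_s * 30)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("a clean 1 Hz pulse train gives 30 peaks at 1 s spacing", {
  x <- make_pulse_trace(bpm = 60, duration_s = 30, fps = 30)
  tr <- make_trace(x, fps = 30)
  s <- detect_beats(tr)
  expect_equal(length(s$peak_times_s), 30)
  expect_true(all(abs(diff(s$peak_times_s) - 1) < 2 / 30))
  m <- beat_rate(s, 30)
  expect_equal(m$bpm, 60, tolerance = 0.02)
})

test_that("beat metrics follow the interval-based definition", {
  s <- structure(list(peak_times_s = 0:10, prominences = rep(1, 11),
                      indices = seq(1, 301, by = 30)), class = "beat_series")
  m <- beat_rate(s, duration_s = 11)
  expect_equal(m$bpm, 60)
  expect_equal(m$ibi_cv, 0)
  expect_equal(m$bpm, 60 / m$ibi_mean_s)

  s2 <- structure(list(peak_times_s = c(0, 0.5, 1.5), prominences = rep(1, 3),
                       indices = c(1, 16, 46)), class = "beat_series")
  m2 <- beat_rate(s2, duration_s = 2)
  expect_equal(m2$ibi_mean_s, 0.75)
  expect_equal(m2$bpm, 80)

  s1 <- structure(list(peak_times_s = 3, prominences = 1, indices = 90),
                  class = "beat_series")
  expect_equal(beat_rate(s1, 10)$bpm, 0)
  expect_error(beat_rate(s, duration_s = -1), "> 0")
})

test_that("the peak set is invariant under positive scaling of the trace", {
  set.seed(77)
  x <- make_pulse_trace(45, 20, fps = 30) + rnorm(600, sd = 2)
  x <- pmax(x, 0)
  a <- detect_beats(make_trace(x))$indices
  b <- detect_beats(make_trace(x * 7.3))$indices
  expect_identical(a, b)
})

test_that("cessation combines the trailing-window and noise-floor criteria", {
  set.seed(8)
  noise <- make_trace(pmax(rnorm(450, mean = 20, sd = 3), 0), fps = 30)
  expect_true(detect_cessation(noise))

  steady <- make_trace(make_pulse_trace(60, 30, fps = 30), fps = 30)
  expect_false(detect_cessation(steady))

  # beats for 20 s then flat for 15 s with a 10 s cessation window
  stopped <- make_trace(c(make_pulse_trace(60, 20, fps = 30),
                          pmax(rnorm(450, 5, 1), 0)), fps = 30)
  expect_true(detect_cessation(stopped))
  res <- analyze_trace(stopped)
  expect_true(res$metrics$ceased)
  expect_equal(res$metrics$bpm, 0)   # ceased forces bpm to 0
})

test_that("windowed rates track rate steps and empty windows", {
  steady <- make_trace(make_pulse_trace(60, 30, fps = 30), fps = 30)
  wr <- windowed_rates(steady, window_s = 10)
  expect_equal(nrow(wr), 3)
  expect_true(all(abs(wr$bpm - 60) < 2))

  step <- make_trace(c(make_pulse_trace(60, 15, fps = 30),
                       make_pulse_trace(90, 15, fps = 30)), fps = 30)
  ws <- windowed_rates(step, window_s = 10)
  expect_lt(abs(ws$bpm[1] - 60), 3)
  expect_lt(abs(ws$bpm[nrow(ws)] - 90), 3)

  flat <- make_trace(rep(3, 300), fps = 30)
  wf <- windowed_rates(flat, window_s = 5)
  expect_true(all(wf$bpm == 0))

  long <- windowed_rates(steady, window_s = 60)   # longer than the trace
  expect_equal(nrow(long), 1)
  expect_error(windowed_rates(steady, window_s = 0.1), "refractory")
})

test_that("beat plot export flags exactly the detected peaks", {
  x <- make_pulse_trace(60, 10, fps = 30)
  tr <- make_trace(x, fps = 30)
  s <- detect_beats(tr)
  df <- beat_plot_df(tr, s)
  expect_equal(sum(df$is_peak), length(s$indices))
  expect_equal(df$time_s[df$is_peak], s$peak_times_s)
})
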