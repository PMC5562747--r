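# Independent brute-force oracles. These re-derive each definition with
# naive loops and are kept deliberately separate from the package internals.

# Elementwise |a - b| by explicit double loop.
oracle_abs_diff <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      out[i, j] <- abs(b[i, j] - a[i, j])
  out
}

# Count of entries strictly above tau by explicit loop.
oracle_count_above <- function(g, tau) {
  k <- 0L
  for (v in as.numeric(g)) if (v > tau) k <- k + 1L
  k
}

# Is index i the representative (middle, left-of-centre) of a plateau local
# maximum of x?
oracle_is_peak_rep <- function(x, i) {
  n <- length(x)
  v <- x[i]
  l <- i
  while (l > 1 && x[l - 1] == v) l <- l - 1
  r <- i
  while (r < n && x[r + 1] == v) r <- r + 1
  if (l == 1 || r == n) return(FALSE)
  if (x[l - 1] >= v || x[r + 1] >= v) return(FALSE)
  i == (l + r) %/% 2
}

# Topographic prominence of a peak at i: minimum over the span to the first
# strictly higher sample (or edge) on each side; peak minus the higher base.
oracle_prominence <- function(x, i) {
  n <- length(x)
  left_higher <- which(x[seq_len(i - 1)] > x[i])
  lspan <- if (length(left_higher)) (max(left_higher) + 1):i else 1:i
  right_higher <- if (i < n) which(x[(i + 1):n] > x[i]) + i else integer(0)
  rspan <- if (length(right_higher)) i:(min(right_higher) - 1) else i:n
  x[i] - max(min(x[lspan]), min(x[rspan]))
}

# Exhaustive peak selection: every index is tested against the plateau,
# prominence and spacing definitions; selection repeatedly takes the most
# prominent remaining compatible candidate (ties to the earlier index).
oracle_peaks <- function(x, prominence_frac, min_gap_samples) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng <= 0) return(integer(0))
  cand <- Filter(function(i) oracle_is_peak_rep(x, i), seq_len(n))
  cand <- Filter(function(i)
    oracle_prominence(x, i) >= prominence_frac * rng, cand)
  cand <- unlist(cand)
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) oracle_prominence(x, i), numeric(1))
  selected <- integer(0)
  repeat {
    ok <- vapply(seq_along(cand), function(k) {
      !(cand[k] %in% selected) &&
        (length(selected) == 0L ||
         all(abs(cand[k] - selected) >= min_gap_samples))
    }, logical(1))
    if (!any(ok)) break
    pool <- which(ok)
    pick <- pool[order(-prom[pool], cand[pool])][1]
    selected <- c(selected, cand[pick])
  }
  sort(selected)
}

# Wrap a plain numeric vector as a motion trace for beat-detection tests.
make_trace <- function(counts, fps = 30, t0 = 0) {
  structure(list(counts = counts, sums = counts,
                 times_s = t0 + (seq_along(counts) - 0.5) / fps,
                 fps = fps, tau_used = 1, smoothed = FALSE),
            class = "motion_trace")
}

# A clean spiky pulse-train trace: one triangular burst per beat.
make_pulse_trace <- function(bpm, duration_s, fps = 30, height = 100) {
  n <- round(duration_s * fps)
  x <- numeric(n)
  period <- 60 / bpm * fps
  centers <- round(seq(period / 2, n - 1, by = period))
  for (c in centers) {
    for (d in -2:2) {
      i <- c + d
      if (i >= 1 && i <= n) x[i] <- max(x[i], height * (1 - abs(d) / 3))
    }
  }
  x
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
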