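#' Beat-detection parameters
#'
#' @param prominence_frac minimum peak prominence as a fraction of the trace
#'   dynamic range (0 < x < 1). Range-relative so the same setting works
#'   across magnifications and organoid sizes.
#' @param refractory_s minimum inter-peak spacing in seconds; the default
#'   0.25 s caps the detectable rate at 240 BPM, above any rate these
#'   platforms exhibit.
#' @param cessation_window_s trailing window with no qualifying peak that
#'   triggers the ceased flag.
#' @return an object of class \code{beat_params}.
#' @export
beat_params <- function(prominence_frac = 0.2, refractory_s = 0.25,
                        cessation_window_s = 10) {
  if (!(prominence_frac > 0 && prominence_frac < 1))
    stop("`prominence_frac` must lie in (0, 1)", call. = FALSE)
  if (refractory_s <= 0) stop("`refractory_s` must be > 0", call. = FALSE)
  if (cessation_window_s <= 0)
    stop("`cessation_window_s` must be > 0", call. = FALSE)
  structure(list(prominence_frac = prominence_frac,
                 refractory_s = refractory_s,
                 cessation_window_s = cessation_window_s),
            class = "beat_params")
}

# Local maxima with plateau handling: a maximal run of equal values bounded
# by strictly lower values on both sides is one peak at the middle index
# (left-of-centre for even plateaus). Signal edges never count as peaks.
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Topographic prominence of peaks at indices `idx` in signal `x`:
# extend left/right until a strictly higher sample (or the signal edge),
# take the minimum over each span; prominence = peak - max(left min, right min).
.prominences <- function(x, idx) {
  vapply(idx, function(i) {
    lmin <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- x[i]
    j <- i + 1L
    while (j <= length(x) && x[j] <= x[i]) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    x[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect beat events in a motion trace
#'
#' Local maxima of the (smoothed) trace qualify as beats when their
#' topographic prominence is at least \code{prominence_frac} of the trace
#' dynamic range and their pairwise spacing is at least \code{refractory_s}.
#' When two candidates violate the spacing constraint the one with the higher
#' prominence is kept (ties resolved toward the earlier time). A constant
#' trace has zero dynamic range and yields no beats.
#'
#' @param trace a \code{motion_trace} with known \code{fps}.
#' @param params a \code{\link{beat_params}} object.
#' @return an object of class \code{beat_series}: \code{peak_times_s}
#'   (strictly increasing), \code{prominences}, \code{indices}.
#' @export
detect_beats <- function(trace, params = beat_params()) {
  stopifnot(inherits(trace, "motion_trace"), inherits(params, "beat_params"))
  x <- trace_signal(trace)
  if (length(x) == 0L) stop("trace is empty", call. = FALSE)
  if (is.null(trace$fps)) stop("trace has no fps", call. = FALSE)
  rng <- max(x) - min(x)
  empty <- structure(list(peak_times_s = numeric(0), prominences = numeric(0),
                          indices = integer(0)), class = "beat_series")
  if (rng <= 0) return(empty)
  cand <- .local_maxima(x)
  if (length(cand) == 0L) return(empty)
  prom <- .prominences(x, cand)
  keep <- prom >= params$prominence_frac * rng
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) return(empty)
  # greedy selection: highest prominence first, earlier time breaks ties
  ord <- order(-prom, cand)
  min_gap <- params$refractory_s * trace$fps
  accepted <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - accepted) >= min_gap) || length(accepted) == 0L)
      accepted <- c(accepted, cand[k])
  }
  o <- order(accepted)
  idx <- accepted[o]
  structure(list(peak_times_s = trace$times_s[idx],
                 prominences = .prominences(x, idx),
                 indices = idx),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d peaks\n", length(x$indices)))
  invisible(x)
}

#' Beat metrics from a beat series
#'
#' The primary BPM estimate is interval-based, \code{60 / mean(IBI)}, which is
#' robust to partial beats at the clip edges; the count-based estimate
#' \code{60 * n_peaks / duration_s} is reported alongside. With fewer than two
#' peaks BPM is 0 and cessation assessment is left to
#' \code{\link{detect_cessation}}.
#'
#' @param series a \code{beat_series}.
#' @param duration_s total trace duration in seconds (> 0).
#' @return an object of class \code{beat_metrics}: \code{bpm},
#'   \code{bpm_count}, \code{ibi_mean_s}, \code{ibi_sd_s}, \code{ibi_cv},
#'   \code{n_peaks}, \code{ceased}.
#' @export
beat_rate <- function(series, duration_s) {
  stopifnot(inherits(series, "beat_series"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be > 0", call. = FALSE)
  n <- length(series$peak_times_s)
  if (n >= 2L) {
    ibi <- diff(series$peak_times_s)
    m <- mean(ibi)
    s <- if (n >= 3L) stats::sd(ibi) else 0
    out <- list(bpm = 60 / m, bpm_count = 60 * n / duration_s,
                ibi_mean_s = m, ibi_sd_s = s,
                ibi_cv = if (m > 0) s / m else 0,
                n_peaks = n, ceased = FALSE)
  } else {
    out <- list(bpm = 0, bpm_count = 60 * n / duration_s,
                ibi_mean_s = NA_real_, ibi_sd_s = NA_real_, ibi_cv = NA_real_,
                n_peaks = n, ceased = NA)
  }
  structure(out, class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf("<beat_metrics> bpm = %.2f, n_peaks = %d, ibi_cv = %.3g, ceased = %s\n",
              x$bpm, x$n_peaks, x$ibi_cv, x$ceased))
  invisible(x)
}

#' Detect cessation of beating
#'
#' Dual criterion: beating has ceased when (a) no qualifying beat occurs in
#' the final \code{cessation_window_s} of the trace, or (b) the raw trace
#' dynamic range is below its own noise floor. The noise floor is estimated
#' robustly on the unsmoothed counts -- where genuine beats are sparse
#' excursions above a quiet baseline -- as sub-noise when
#' \code{max - median <= 5 * 1.4826 * MAD}; this catches pure-noise traces
#' whose range-relative peaks would otherwise qualify as beats.
#'
#' @param trace a \code{motion_trace}.
#' @param series the \code{beat_series} detected on it (recomputed when
#'   omitted).
#' @param params a \code{\link{beat_params}} object.
#' @return logical flag.
#' @export
detect_cessation <- function(trace, series = NULL, params = beat_params()) {
  stopifnot(inherits(trace, "motion_trace"))
  x <- trace_signal(trace)
  if (length(x) == 0L) stop("trace is empty", call. = FALSE)
  if (is.null(series)) series <- detect_beats(trace, params)
  raw <- trace$counts                 # noise floor on the unsmoothed counts
  sub_noise <- (max(raw) - stats::median(raw)) <= 5 * stats::mad(raw)
  t_end <- trace$times_s[length(x)]
  window_start <- t_end - params$cessation_window_s
  no_recent_peak <- !any(series$peak_times_s >= window_start)
  isTRUE(sub_noise || no_recent_peak)
}

#' Full beat analysis of a motion trace
#'
#' Runs beat detection, rate estimation and cessation assessment; when the
#' trace is flagged as ceased the reported BPM is forced to 0.
#'
#' @param trace a \code{motion_trace}.
#' @param params a \code{\link{beat_params}} object.
#' @return a list with \code{series} (\code{beat_series}) and \code{metrics}
#'   (\code{beat_metrics}).
#' @export
analyze_trace <- function(trace, params = beat_params()) {
  series <- detect_beats(trace, params)
  duration <- length(trace$counts) / trace$fps
  metrics <- beat_rate(series, duration)
  ceased <- detect_cessation(trace, series, params)
  metrics$ceased <- ceased
  if (ceased) metrics$bpm <- 0
  list(series = series, metrics = metrics)
}

#' Windowed beat rates
#'
#' Splits the trace into non-overlapping windows of \code{window_s} seconds
#' (a window longer than the trace degrades to a single whole-trace window)
#' and reports the interval-based BPM of the peaks falling in each window;
#' windows with fewer than two peaks report 0.
#'
#' @param trace a \code{motion_trace}.
#' @param params a \code{\link{beat_params}} object.
#' @param window_s window length in seconds (>= 2 * refractory_s).
#' @return data frame with columns \code{t_mid_s} and \code{bpm}.
#' @export
windowed_rates <- function(trace, params = beat_params(), window_s) {
  stopifnot(inherits(trace, "motion_trace"))
  if (window_s < 2 * params$refractory_s)
    stop("`window_s` must be at least twice the refractory period", call. = FALSE)
  series <- detect_beats(trace, params)
  t0 <- trace$times_s[1]
  t_end <- trace$times_s[length(trace$times_s)]
  total <- t_end - t0
  if (window_s >= total) {
    starts <- t0
    ends <- t_end + 1e-9
  } else {
    starts <- seq(t0, t_end, by = window_s)
    starts <- starts[starts < t_end]
    ends <- pmin(starts + window_s, t_end + 1e-9)
  }
  bpm <- mapply(function(a, b) {
    pk <- series$peak_times_s[series$peak_times_s >= a & series$peak_times_s < b]
    if (length(pk) >= 2L) 60 / mean(diff(pk)) else 0
  }, starts, ends)
  data.frame(t_mid_s = (starts + ends) / 2, bpm = as.numeric(bpm))
}

#' Beat plot export
#'
#' One row per trace sample with columns \code{time_s}, \code{value},
#' \code{is_peak} -- the layout of a beat peak plot.
#'
#' @param trace a \code{motion_trace}.
#' @param series a \code{beat_series} detected on it.
#' @return a data frame.
#' @export
beat_plot_df <- function(trace, series) {
  x <- trace_signal(trace)
  is_peak <- logical(length(x))
  is_peak[series$indices] <- TRUE
  data.frame(time_s = trace$times_s, value = x, is_peak = is_peak)
}
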