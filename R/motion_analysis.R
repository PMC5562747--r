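#' Motion-analysis parameters
#'
#' Controls the thresholded pixel-movement conversion that turns a video into
#' a contraction signal. In \code{"auto"} mode the threshold is
#' \code{mean + auto_k * sd} of all pooled inter-frame absolute differences;
#' in \code{"fixed"} mode the supplied \code{tau} (intensity units on the
#' 8-bit scale) is applied directly.
#'
#' @param threshold_mode \code{"auto"} or \code{"fixed"}.
#' @param tau fixed intensity-difference threshold (> 0; required when
#'   \code{threshold_mode = "fixed"}).
#' @param auto_k multiplier for the automatic threshold rule (> 0).
#' @param smooth_window_s moving-average window in seconds (>= 0; 0 disables
#'   smoothing). Each beat yields two motion bursts -- contraction and
#'   relaxation -- separated by roughly half the contraction-pulse width; the
#'   default 0.25 s spans that separation for rates down to 30 BPM, merging
#'   the bursts into one hump per beat, while staying below the beat period
#'   of the fastest rates these platforms exhibit (0.4 s at 150 BPM).
#' @return an object of class \code{motion_params}.
#' @export
motion_params <- function(threshold_mode = c("auto", "fixed"), tau = NULL,
                          auto_k = 3, smooth_window_s = 0.25) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed") {
    if (is.null(tau) || !is.numeric(tau) || tau <= 0)
      stop("fixed mode requires `tau` > 0", call. = FALSE)
  }
  if (!is.numeric(auto_k) || auto_k <= 0)
    stop("`auto_k` must be > 0", call. = FALSE)
  if (!is.numeric(smooth_window_s) || smooth_window_s < 0)
    stop("`smooth_window_s` must be >= 0", call. = FALSE)
  structure(list(threshold_mode = threshold_mode, tau = tau,
                 auto_k = auto_k, smooth_window_s = smooth_window_s),
            class = "motion_params")
}

#' Consecutive-frame absolute differences
#'
#' @param seq a \code{\link{frame_sequence}} with at least 2 frames.
#' @return list of \code{n - 1} non-negative matrices; element \code{i} is
#'   \code{|frame[i+1] - frame[i]|}.
#' @export
frame_difference <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  if (n < 2L)
    stop("motion computation requires at least 2 frames", call. = FALSE)
  lapply(seq_len(n - 1L), function(i) abs(seq$frames[[i + 1L]] - seq$frames[[i]]))
}

#' Automatic motion threshold
#'
#' Pools every pixel of every difference grid and returns
#' \code{mean + auto_k * sd} (sample standard deviation). When all differences
#' are exactly zero the positive sentinel 1.0 is returned so that a static
#' clip yields an all-zero motion trace rather than a degenerate threshold.
#'
#' @param diffs list of difference grids (from \code{\link{frame_difference}}).
#' @param auto_k dimensionless multiplier (> 0).
#' @return a single threshold value.
#' @export
auto_threshold <- function(diffs, auto_k = 3) {
  if (length(diffs) == 0L) stop("`diffs` must be non-empty", call. = FALSE)
  if (!is.numeric(auto_k) || auto_k <= 0)
    stop("`auto_k` must be > 0", call. = FALSE)
  v <- unlist(diffs, use.names = FALSE)
  if (all(v == 0)) return(1.0)
  s <- stats::sd(v)
  if (is.na(s)) s <- 0   # single pooled value
  mean(v) + auto_k * s
}

#' Count supra-threshold ("moving") pixels per frame pair
#'
#' The motion statistic is the count of pixels strictly above \code{tau}
#' (ties are excluded). The summed supra-threshold difference intensity is
#' carried along as a secondary statistic.
#'
#' @param diffs list of difference grids.
#' @param tau threshold (> 0).
#' @param fps frames per second of the source video (carried into the trace;
#'   optional here, required downstream for beat detection).
#' @param t0 acquisition start time in seconds.
#' @return an object of class \code{motion_trace} with fields \code{counts}
#'   (one per frame pair), \code{sums}, \code{times_s} (midpoint of each frame
#'   pair), \code{fps}, \code{tau_used} and \code{smoothed}.
#' @export
threshold_motion <- function(diffs, tau, fps = NULL, t0 = 0) {
  if (length(diffs) == 0L) stop("`diffs` must be non-empty", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a single value > 0", call. = FALSE)
  counts <- vapply(diffs, function(d) sum(d > tau), numeric(1))
  sums <- vapply(diffs, function(d) sum(d[d > tau]), numeric(1))
  times <- if (is.null(fps)) rep(NA_real_, length(counts))
           else t0 + (seq_along(counts) - 0.5) / fps
  structure(list(counts = counts, sums = sums, times_s = times,
                 fps = fps, tau_used = tau, smoothed = FALSE),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frame pairs, tau = %.4g, smoothed = %s\n",
              length(x$counts), x$tau_used, x$smoothed))
  invisible(x)
}

# Length-preserving moving average with symmetric edge padding.
.moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L || length(x) <= 1L) return(x)
  half <- window %/% 2L
  padded <- c(rev(x[seq_len(min(half, length(x)))]),
              x,
              rev(x[seq.int(length(x) - min(half, length(x)) + 1L, length(x))]))
  k <- rep(1 / window, window)
  sm <- stats::filter(padded, k, sides = 2)
  out <- as.numeric(sm[(half + 1L):(half + length(x))])
  # filter() leaves NAs where the kernel overhangs; fall back to local means
  na <- which(is.na(out))
  for (i in na) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Compute the contraction motion trace of a video
#'
#' Composition of the full thresholded pixel-movement conversion:
#' grayscale frames -> consecutive absolute differences -> threshold
#' (automatic or fixed) -> per-pair supra-threshold pixel counts -> optional
#' moving-average smoothing over \code{round(smooth_window_s * fps)} samples.
#'
#' @param seq a \code{\link{frame_sequence}} with at least 2 frames.
#' @param params a \code{\link{motion_params}} object.
#' @return a \code{motion_trace}; when smoothing is applied, a
#'   \code{counts_smoothed} field is added and \code{smoothed} is set.
#' @export
compute_motion_trace <- function(seq, params = motion_params()) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(params, "motion_params"))
  diffs <- frame_difference(seq)
  tau <- if (params$threshold_mode == "auto")
    auto_threshold(diffs, params$auto_k) else params$tau
  trace <- threshold_motion(diffs, tau, fps = seq$fps, t0 = seq$t0)
  if (params$smooth_window_s > 0) {
    w <- max(1L, as.integer(round(params$smooth_window_s * seq$fps)))
    trace$counts_smoothed <- .moving_average(trace$counts, w)
    trace$smoothed <- w > 1L
  }
  trace
}

#' Signal column of a motion trace
#'
#' Returns the smoothed counts when present, otherwise the raw counts.
#'
#' @param trace a \code{motion_trace}.
#' @return numeric vector.
#' @export
trace_signal <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  if (!is.null(trace$counts_smoothed)) trace$counts_smoothed else trace$counts
}

#' Export a motion trace as a data frame
#'
#' One row per frame pair with columns \code{time_s}, \code{count} and
#' \code{count_smoothed} (equal to \code{count} when no smoothing was
#' applied), matching the documented CSV layout.
#'
#' @param trace a \code{motion_trace}.
#' @return a data frame.
#' @export
trace_to_df <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  data.frame(time_s = trace$times_s,
             count = trace$counts,
             count_smoothed = trace_signal(trace))
}

#' Render binarized motion frames
#'
#' Writes the thresholded difference grids (moving pixels white, static black)
#' as a multi-page TIFF -- the visual representation of organoid contraction.
#'
#' @param seq a \code{\link{frame_sequence}}.
#' @param tau threshold to apply (> 0).
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_motion_frames <- function(seq, tau, path) {
  diffs <- frame_difference(seq)
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  imgs <- lapply(diffs, function(d) (d > tau) * 1)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}
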