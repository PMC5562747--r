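#' Ground-truth description of a synthetic beating-organoid video
#'
#' The generator renders a roughly circular organoid as a bright soft-edged
#' disk whose radius contracts periodically:
#' \code{r(t) = rest_radius * (1 - amplitude_frac * w(phase))}, where \code{w}
#' is an asymmetric raised-cosine pulse (fast contraction, slower relaxation)
#' active over a 0.3 duty-cycle fraction of each beat and the phase
#' integrates the instantaneous rate \code{bpm_trajectory(t) / 60}. Additive
#' Gaussian pixel noise and a slow linear background drift emulate camera
#' noise and illumination drift. Frames are quantized to 8-bit integers, so
#' written videos round-trip losslessly.
#'
#' @param bpm_trajectory a constant (beats/min) or a function of time in
#'   seconds returning beats/min.
#' @param amplitude_frac radial contraction amplitude as a fraction of the
#'   rest radius (in \code{[0, 0.5)}).
#' @param rest_radius_px organoid rest radius in pixels.
#' @param noise_sd additive Gaussian pixel noise SD (8-bit intensity units).
#' @param drift_per_s linear background intensity drift per second.
#' @param fps frames per second; must be at least \code{4 * max bpm / 60}
#'   (Nyquist with margin).
#' @param duration_s clip duration in seconds.
#' @param size_px frame height and width in pixels.
#' @param background,foreground background and disk intensities (8-bit).
#' @param seed integer seed; all randomness in the render flows from it.
#' @return an object of class \code{video_truth}.
#' @export
video_truth <- function(bpm_trajectory = 60, amplitude_frac = 0.1,
                        rest_radius_px = 30, noise_sd = 2, drift_per_s = 0,
                        fps = 30, duration_s = 30, size_px = 128,
                        background = 30, foreground = 230, seed = 1L) {
  if (amplitude_frac < 0 || amplitude_frac >= 0.5)
    stop("`amplitude_frac` must lie in [0, 0.5)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (fps <= 0 || duration_s <= 0)
    stop("`fps` and `duration_s` must be > 0", call. = FALSE)
  structure(list(bpm_trajectory = bpm_trajectory,
                 amplitude_frac = amplitude_frac,
                 rest_radius_px = rest_radius_px, noise_sd = noise_sd,
                 drift_per_s = drift_per_s, fps = fps,
                 duration_s = duration_s, size_px = size_px,
                 background = background, foreground = foreground,
                 seed = as.integer(seed)),
            class = "video_truth")
}

.bpm_fun <- function(traj) {
  if (is.function(traj)) traj else function(t) rep(traj, length(t))
}

# Asymmetric raised-cosine contraction pulse on pulse phase u in [0, 1):
# active for u < duty; within the pulse, the fast calcium-driven contraction
# occupies the first `contract_frac` of the pulse and the slower relaxation
# the rest.
.pulse_waveform <- function(u, duty = 0.3, contract_frac = 0.12) {
  w <- numeric(length(u))
  act <- u < duty
  s <- u[act] / duty
  w[act] <- ifelse(s < contract_frac,
                   0.5 * (1 - cos(pi * s / contract_frac)),
                   0.5 * (1 + cos(pi * (s - contract_frac) / (1 - contract_frac))))
  w
}

#' Generate a synthetic beating-organoid video
#'
#' @param truth a \code{\link{video_truth}} description.
#' @return a list with \code{seq} (a \code{\link{frame_sequence}}) and
#'   \code{truth} (the input augmented with \code{phase} per frame,
#'   \code{radius_px} per frame, and \code{n_pulses}, the number of
#'   contraction pulses started within the clip).
#' @export
generate_beating_video <- function(truth) {
  stopifnot(inherits(truth, "video_truth"))
  bpm_f <- .bpm_fun(truth$bpm_trajectory)
  n <- round(truth$fps * truth$duration_s)
  t <- (seq_len(n) - 1) / truth$fps
  rate_hz <- bpm_f(t) / 60
  if (any(rate_hz < 0)) stop("bpm trajectory must be >= 0", call. = FALSE)
  if (truth$fps < 4 * max(rate_hz))   # fps >= 4 * max bpm / 60
    stop(sprintf("fps %.3g violates the Nyquist margin for max rate %.3g Hz",
                 truth$fps, max(rate_hz)), call. = FALSE)
  # phase integrates the instantaneous rate
  phase <- cumsum(c(0, (rate_hz[-n] + rate_hz[-1]) / 2 / truth$fps))
  w <- .pulse_waveform(phase %% 1)
  radius <- truth$rest_radius_px * (1 - truth$amplitude_frac * w)
  ctr <- (truth$size_px + 1) / 2
  xs <- seq_len(truth$size_px)
  dist <- sqrt(outer((xs - ctr)^2, (xs - ctr)^2, `+`))
  set.seed(truth$seed)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    disk <- pmin(pmax(radius[i] + 0.5 - dist, 0), 1)   # 1-px soft edge
    f <- truth$background + (truth$foreground - truth$background) * disk +
      truth$drift_per_s * t[i]
    if (truth$noise_sd > 0)
      f <- f + stats::rnorm(length(f), sd = truth$noise_sd)
    frames[[i]] <- matrix(pmin(pmax(round(f), 0), 255),
                          truth$size_px, truth$size_px)
  }
  truth$phase <- phase
  truth$radius_px <- radius
  truth$n_pulses <- floor(phase[n] - 1e-9) + 1L   # onsets at phase 0, 1, 2, ...
  truth$mean_bpm <- mean(bpm_f(t))
  list(seq = frame_sequence(frames, fps = truth$fps,
                            source = sprintf("synthetic(seed=%d)", truth$seed)),
       truth = truth)
}

#' Ground-truth description of a synthetic LIVE/DEAD image
#'
#' Live (green) and dead (red) cells are rendered as soft-edged disks at
#' disjoint positions drawn by rejection sampling; Gaussian blur and additive
#' noise emulate the optics and camera of a macro-confocal projection.
#'
#' @param n_live,n_dead intended object counts (>= 0).
#' @param radius_range_px min/max disk radius in pixels.
#' @param blur_sigma_px Gaussian blur SD in pixels (0 disables).
#' @param noise_sd additive Gaussian noise SD (8-bit intensity units).
#' @param canvas_px canvas height and width in pixels.
#' @param intensity disk peak intensity (8-bit).
#' @param seed integer seed.
#' @return an object of class \code{image_truth}.
#' @export
image_truth <- function(n_live, n_dead, radius_range_px = c(4, 6),
                        blur_sigma_px = 0, noise_sd = 0, canvas_px = 320,
                        intensity = 220, seed = 1L) {
  if (n_live < 0 || n_dead < 0) stop("counts must be >= 0", call. = FALSE)
  if (length(radius_range_px) != 2L || any(radius_range_px <= 0) ||
      radius_range_px[1] > radius_range_px[2])
    stop("`radius_range_px` must be c(min, max) with 0 < min <= max",
         call. = FALSE)
  structure(list(n_live = as.integer(n_live), n_dead = as.integer(n_dead),
                 radius_range_px = radius_range_px,
                 blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
                 canvas_px = as.integer(canvas_px), intensity = intensity,
                 seed = as.integer(seed)),
            class = "image_truth")
}

# Place n disks with radii r (vector) without overlap by rejection sampling.
.place_disks <- function(n, radii, canvas, gap = 2, max_tries = 200L) {
  ys <- xs <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      m <- radii[i] + gap
      y <- stats::runif(1, m, canvas - m)
      x <- stats::runif(1, m, canvas - m)
      if (i == 1L ||
          all(sqrt((ys[seq_len(i - 1)] - y)^2 + (xs[seq_len(i - 1)] - x)^2) >=
              radii[i] + radii[seq_len(i - 1)] + gap)) {
        ys[i] <- y; xs[i] <- x; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("could not place %d non-overlapping objects on a %d px canvas",
                   n, canvas), call. = FALSE)
  }
  data.frame(y = ys, x = xs, r = radii)
}

.render_disks <- function(objs, canvas, intensity) {
  img <- matrix(0, canvas, canvas)
  if (nrow(objs) == 0L) return(img)
  xs <- seq_len(canvas)
  for (i in seq_len(nrow(objs))) {
    yy <- xs - objs$y[i]; xx <- xs - objs$x[i]
    d <- sqrt(outer(yy^2, xx^2, `+`))
    img <- pmax(img, intensity * pmin(pmax(objs$r[i] + 0.5 - d, 0), 1))
  }
  img
}

#' Generate a synthetic LIVE/DEAD two-channel image
#'
#' @param truth an \code{\link{image_truth}} description.
#' @return a list with \code{img} (a \code{\link{two_channel_image}}) and
#'   \code{truth} (augmented with the placed object table).
#' @export
generate_livedead_image <- function(truth) {
  stopifnot(inherits(truth, "image_truth"))
  set.seed(truth$seed)
  n <- truth$n_live + truth$n_dead
  radii <- if (n > 0)
    stats::runif(n, truth$radius_range_px[1], truth$radius_range_px[2])
  else numeric(0)
  objs <- if (n > 0) .place_disks(n, radii, truth$canvas_px)
          else data.frame(y = numeric(0), x = numeric(0), r = numeric(0))
  objs$channel <- rep(c("green", "red"), c(truth$n_live, truth$n_dead))
  g <- .render_disks(objs[objs$channel == "green", , drop = FALSE],
                     truth$canvas_px, truth$intensity)
  r <- .render_disks(objs[objs$channel == "red", , drop = FALSE],
                     truth$canvas_px, truth$intensity)
  if (truth$blur_sigma_px > 0) {
    g <- EBImage::imageData(EBImage::gblur(EBImage::Image(g),
                                           sigma = truth$blur_sigma_px))
    r <- EBImage::imageData(EBImage::gblur(EBImage::Image(r),
                                           sigma = truth$blur_sigma_px))
  }
  if (truth$noise_sd > 0) {
    g <- g + stats::rnorm(length(g), sd = truth$noise_sd)
    r <- r + stats::rnorm(length(r), sd = truth$noise_sd)
  }
  clamp <- function(m) matrix(pmin(pmax(round(m), 0), 255),
                              truth$canvas_px, truth$canvas_px)
  truth$objects <- objs
  list(img = two_channel_image(clamp(g), clamp(r)), truth = truth)
}

#' Generate a ground-truthed video dataset from a simulated experiment
#'
#' Runs the two-tissue simulator, then renders one constant-rate video per
#' observation window: a pre-dose baseline window and one window after each
#' dosing event (the simulated rate sampled \code{post_delay_h} after the
#' event). A JSON manifest records condition labels, per-video seeds, true
#' rates, and the generator configuration, making the dataset bit-exactly
#' reproducible.
#'
#' @param protocol an \code{\link{experiment_protocol}}.
#' @param video_cfg a \code{\link{video_truth}} template; its
#'   \code{bpm_trajectory} is overridden per window.
#' @param out_dir output directory (created if needed).
#' @param pk,pd simulator parameters.
#' @param post_delay_h hours after each event at which the window is taken.
#' @return invisibly, the manifest as a list.
#' @export
generate_experiment_dataset <- function(protocol, video_cfg = video_truth(),
                                        out_dir, pk = pk_params(),
                                        pd = default_pd_params(),
                                        post_delay_h = 1) {
  stopifnot(inherits(protocol, "experiment_protocol"),
            inherits(video_cfg, "video_truth"))
  sim <- simulate_two_tissue_experiment(protocol, pk, pd)
  ts <- sim$timeseries
  bpm_at <- function(t) ts$bpm[which.min(abs(ts$t_h - t))]
  windows <- data.frame(
    label = c("baseline",
              sprintf("post_%s_%g", protocol$events$drug,
                      protocol$events$time_h)),
    t_h = c(0, pmin(protocol$events$time_h + post_delay_h,
                    protocol$duration_h)))
  windows$true_bpm <- vapply(windows$t_h, bpm_at, numeric(1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(windows))
  seeds <- protocol$seed + seq_len(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    vt <- video_cfg
    vt$bpm_trajectory <- windows$true_bpm[i]
    vt$seed <- seeds[i]
    if (windows$true_bpm[i] == 0) vt$amplitude_frac <- 0   # ceased: no motion
    gen <- generate_beating_video(vt)
    files[i] <- file.path(out_dir, sprintf("%02d_%s.tif", i, windows$label[i]))
    write_frames(gen$seq, files[i])
  }
  manifest <- list(
    mode = protocol$mode, seed = protocol$seed,
    events = protocol$events, post_delay_h = post_delay_h,
    video = list(fps = video_cfg$fps, duration_s = video_cfg$duration_s,
                 size_px = video_cfg$size_px,
                 amplitude_frac = video_cfg$amplitude_frac,
                 noise_sd = video_cfg$noise_sd,
                 rest_radius_px = video_cfg$rest_radius_px),
    windows = cbind(windows, seed = seeds, file = basename(files)))
  write_report(manifest, file.path(out_dir, "manifest.json"),
               format = "json", seed = protocol$seed)
  invisible(manifest)
}
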