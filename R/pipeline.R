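#' Analyze a beating-organoid video end to end
#'
#' Runs the full motion-analysis and beat-kinetics pipeline on a video (or an
#' in-memory frame sequence) and, when \code{out_dir} is given, writes the
#' motion trace CSV (\code{trace.csv}), the beat metrics JSON
#' (\code{metrics.json}) and the beat peak plot CSV (\code{beat_plot.csv}),
#' each stamped with the package version and resolved parameters.
#'
#' @param path path to a multi-page TIFF video (alternative to \code{seq}).
#' @param seq a \code{\link{frame_sequence}} (alternative to \code{path}).
#' @param fps frames per second (required with \code{path}).
#' @param roi optional \code{c(y0, y1, x0, x1)} crop.
#' @param motion a \code{\link{motion_params}} object.
#' @param beats a \code{\link{beat_params}} object.
#' @param out_dir optional output directory for report files.
#' @return a list with \code{trace}, \code{series}, \code{metrics}.
#' @export
analyze_video <- function(path = NULL, seq = NULL, fps = NULL, roi = NULL,
                          motion = motion_params(), beats = beat_params(),
                          out_dir = NULL) {
  if (is.null(seq)) {
    if (is.null(path)) stop("supply `path` or `seq`", call. = FALSE)
    seq <- read_frames(path, fps = fps, roi = roi)
  }
  trace <- compute_motion_trace(seq, motion)
  res <- analyze_trace(trace, beats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    resolved <- list(motion = unclass(motion), beats = unclass(beats),
                     fps = seq$fps, tau_used = trace$tau_used)
    utils::write.csv(trace_to_df(trace), file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    write_report(unclass(res$metrics), file.path(out_dir, "metrics.json"),
                 format = "json", params = resolved)
    utils::write.csv(beat_plot_df(trace, res$series),
                     file.path(out_dir, "beat_plot.csv"), row.names = FALSE)
  }
  list(trace = trace, series = res$series, metrics = res$metrics)
}

#' Quantify a LIVE/DEAD image end to end
#'
#' @param path path to a 2-page TIFF (green, red), or the green channel of a
#'   paired-file input (alternative to \code{img}).
#' @param red_path optional red-channel path for paired files.
#' @param img a \code{\link{two_channel_image}} (alternative to \code{path}).
#' @param params a \code{\link{viability_params}} object.
#' @param out_dir optional output directory; writes \code{viability.json}.
#' @return a \code{\link{count_live_dead}} result.
#' @export
analyze_viability <- function(path = NULL, red_path = NULL, img = NULL,
                              params = viability_params(), out_dir = NULL) {
  if (is.null(img)) {
    if (is.null(path)) stop("supply `path` or `img`", call. = FALSE)
    img <- read_two_channel(path, red_path)
  }
  res <- count_live_dead(img, params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(unclass(res), file.path(out_dir, "viability.json"),
                 format = "json", params = unclass(params))
  }
  res
}

#' Simulate an experiment and emit its synthetic dataset
#'
#' Thin orchestration over \code{\link{simulate_two_tissue_experiment}} and
#' \code{\link{generate_experiment_dataset}}: runs the simulator, writes the
#' concentration/beat-rate time series CSV and the ground-truthed video
#' dataset with its manifest.
#'
#' @param protocol an \code{\link{experiment_protocol}}.
#' @param out_dir output directory.
#' @param video_cfg a \code{\link{video_truth}} template.
#' @param pk,pd simulator parameters.
#' @return invisibly, the dataset manifest.
#' @export
simulate_experiment <- function(protocol, out_dir,
                                video_cfg = video_truth(),
                                pk = pk_params(), pd = default_pd_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_tissue_experiment(protocol, pk, pd)
  utils::write.csv(sim$timeseries, file.path(out_dir, "timeseries.csv"),
                   row.names = FALSE)
  generate_experiment_dataset(protocol, video_cfg, out_dir, pk, pd)
}
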