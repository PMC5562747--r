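#' Construct a frame sequence
#'
#' A \code{frame_sequence} is the canonical substrate for motion analysis: an
#' ordered set of single-channel intensity frames (values on the 8-bit scale,
#' \code{[0, 255]}) together with the acquisition frame rate. Frame \code{i}
#' (0-based) is acquired at \code{t0 + i / fps} seconds.
#'
#' @param frames list of numeric matrices, all of identical dimensions, with
#'   intensities in \code{[0, 255]}.
#' @param fps frames per second (> 0).
#' @param t0 acquisition start time in seconds.
#' @param source free-text provenance string.
#' @return an object of class \code{frame_sequence}.
#' @export
frame_sequence <- function(frames, fps, t0 = 0, source = "") {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("all frames must be 2-D matrices (use to_grayscale() first)", call. = FALSE)
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    stop("all frames must share identical height and width", call. = FALSE)
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  structure(
    list(frames = frames, fps = as.numeric(fps), t0 = as.numeric(t0),
         source = as.character(source)),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g fps, %.3g s\n",
              length(x$frames), d[1], d[2], x$fps,
              length(x$frames) / x$fps))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Frame acquisition timestamps
#'
#' @param seq a \code{frame_sequence}.
#' @return numeric vector, \code{t0 + (0:(n-1)) / fps}.
#' @export
frame_times <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  seq$t0 + (seq_along(seq$frames) - 1) / seq$fps
}

#' Convert a frame to single-channel grayscale
#'
#' Three-channel frames are reduced with the standard video luma weights
#' 0.299 R + 0.587 G + 0.114 B; single-channel frames are returned unchanged
#' (the operation is idempotent).
#'
#' @param frame a matrix (1 channel) or an array with \code{dim[3] == 3}.
#' @return a numeric matrix.
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    nc <- dim(frame)[3]
    if (nc == 1L) return(frame[, , 1])
    if (nc == 3L)
      return(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  }
  stop("frame must have 1 or 3 channels", call. = FALSE)
}

# Rescale raw TIFF sample values to the common 8-bit working range.
# 8-bit data is kept as-is; higher bit depths are rescaled linearly by their
# own maximum so downstream thresholds live on a single scale.
.rescale_8bit <- function(m) {
  mx <- max(m)
  if (mx <= 255) return(m)
  m / mx * 255
}

.check_roi <- function(roi, d) {
  if (length(roi) != 4L || any(is.na(roi)))
    stop("`roi` must be c(y0, y1, x0, x1)", call. = FALSE)
  roi <- as.integer(roi)
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > d[1] || roi[4] > d[2] ||
      roi[1] >= roi[2] || roi[3] >= roi[4])
    stop("`roi` must be a non-empty half-open rectangle inside frame bounds",
         call. = FALSE)
  roi
}

#' Read a multi-page TIFF stack as a frame sequence
#'
#' Pages are returned in file order, converted to single-channel 8-bit scale
#' frames. TIFF carries no frame-rate metadata, so \code{fps} is mandatory.
#' ROI coordinates are 0-based, row-major, origin top-left; rectangles are
#' half-open \code{[y0, y1) x [x0, x1)}.
#'
#' @param path path to a multi-page TIFF stack.
#' @param fps frames per second of the recording (required).
#' @param roi optional \code{c(y0, y1, x0, x1)} crop rectangle.
#' @param t0 acquisition start time in seconds.
#' @return a \code{frame_sequence}.
#' @export
read_frames <- function(path, fps, roi = NULL, t0 = 0) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  if (missing(fps) || is.null(fps))
    stop("`fps` is required: the container carries no frame-rate metadata",
         call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("not a readable TIFF stack: %s (%s)",
                                   path, conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L)
    stop("zero readable frames in stack", call. = FALSE)
  frames <- lapply(pages, function(p) .rescale_8bit(to_grayscale(p)))
  if (!is.null(roi)) {
    roi <- .check_roi(roi, dim(frames[[1]]))
    frames <- lapply(frames, function(f)
      f[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4], drop = FALSE])
  }
  frame_sequence(frames, fps = fps, t0 = t0, source = path)
}

#' Write a frame sequence as a multi-page 8-bit TIFF
#'
#' Integer-valued 8-bit frames round-trip losslessly through
#' \code{\link{read_frames}}.
#'
#' @param seq a \code{frame_sequence}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_frames <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  imgs <- lapply(seq$frames, function(f) f / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

#' Construct a two-channel viability image
#'
#' Container for LIVE/DEAD staining data: calcein-AM (green, live cells) and
#' ethidium homodimer (red, dead cells) intensity channels of identical size.
#'
#' @param green,red numeric matrices of identical dimensions, values in
#'   \code{[0, 255]}.
#' @param pixel_size_um optional micrometres per pixel (> 0).
#' @return an object of class \code{two_channel_image}.
#' @export
two_channel_image <- function(green, red, pixel_size_um = NULL) {
  if (!is.matrix(green) || !is.matrix(red))
    stop("`green` and `red` must be matrices", call. = FALSE)
  if (!identical(dim(green), dim(red)))
    stop("green and red channels must have identical dimensions", call. = FALSE)
  rng <- range(green, red)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel intensities must lie in [0, 255]", call. = FALSE)
  if (!is.null(pixel_size_um) && pixel_size_um <= 0)
    stop("`pixel_size_um` must be positive", call. = FALSE)
  structure(list(green = green, red = red, pixel_size_um = pixel_size_um),
            class = "two_channel_image")
}

#' Read a two-channel image from a 2-page TIFF or paired files
#'
#' @param path a 2-page TIFF (page 1 = green, page 2 = red), or the green
#'   channel of a pair.
#' @param red_path optional path to the red channel when using paired files.
#' @param pixel_size_um optional micrometres per pixel.
#' @return a \code{two_channel_image}.
#' @export
read_two_channel <- function(path, red_path = NULL, pixel_size_um = NULL) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  if (is.null(red_path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != 2L)
      stop("expected a 2-page TIFF (green, red); use `red_path` for paired files",
           call. = FALSE)
    g <- pages[[1]]; r <- pages[[2]]
  } else {
    if (!file.exists(red_path))
      stop(sprintf("input file not found: %s", red_path), call. = FALSE)
    g <- tiff::readTIFF(path, as.is = TRUE)
    r <- tiff::readTIFF(red_path, as.is = TRUE)
  }
  two_channel_image(.rescale_8bit(to_grayscale(g)),
                    .rescale_8bit(to_grayscale(r)),
                    pixel_size_um = pixel_size_um)
}

#' Write a two-channel image as a 2-page 8-bit TIFF
#'
#' @param img a \code{two_channel_image}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_two_channel <- function(img, path) {
  stopifnot(inherits(img, "two_channel_image"))
  tiff::writeTIFF(list(img$green / 255, img$red / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

# ---- reports --------------------------------------------------------------

REPORT_SCHEMA_VERSION <- "1.0"

.report_provenance <- function(params = NULL, seed = NULL) {
  list(package = "chipbeat",
       version = as.character(utils::packageVersion("chipbeat")),
       schema_version = REPORT_SCHEMA_VERSION,
       params = params, seed = seed)
}

#' Write an analysis record to CSV or JSON
#'
#' JSON reports carry a versioned schema header with package version and (when
#' supplied) the resolved parameters and seed; numeric fields survive a
#' read/write round trip at full double precision in both formats.
#'
#' @param results a named list (JSON) or data frame (CSV/JSON) of results; an
#'   empty list / zero-row data frame is valid.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param params,seed optional provenance recorded in JSON reports.
#' @return the path, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         params = NULL, seed = NULL) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("cannot write report: directory does not exist: %s", dir),
         call. = FALSE)
  if (format == "json") {
    payload <- list(provenance = .report_provenance(params, seed),
                    results = results)
    # I(17) significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", pretty = TRUE)
  } else {
    df <- as.data.frame(results, stringsAsFactors = FALSE)
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read back a JSON report written by \code{write_report}
#'
#' @param path path to a JSON report.
#' @return list with \code{provenance} and \code{results}.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
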