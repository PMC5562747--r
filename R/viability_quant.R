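#' Viability segmentation parameters
#'
#' @param min_object_px minimum object area in pixels (objects smaller than
#'   this are treated as debris and removed).
#' @param channel_threshold_mode \code{"otsu"} (global Otsu per channel) or
#'   \code{"fixed"}.
#' @param fixed_thresholds named numeric vector \code{c(green =, red =)} of
#'   per-channel intensity cutoffs on the 8-bit scale (required for
#'   \code{"fixed"} mode).
#' @param dual_positive how an object detected in both channels is counted:
#'   \code{"dead"} (default; ethidium entry indicates a compromised membrane)
#'   or \code{"live"}.
#' @return an object of class \code{viability_params}.
#' @export
viability_params <- function(min_object_px = 20,
                             channel_threshold_mode = c("otsu", "fixed"),
                             fixed_thresholds = NULL,
                             dual_positive = c("dead", "live")) {
  channel_threshold_mode <- match.arg(channel_threshold_mode)
  dual_positive <- match.arg(dual_positive)
  if (min_object_px < 1) stop("`min_object_px` must be >= 1", call. = FALSE)
  if (channel_threshold_mode == "fixed" &&
      (is.null(fixed_thresholds) ||
       !all(c("green", "red") %in% names(fixed_thresholds))))
    stop("fixed mode requires `fixed_thresholds = c(green =, red =)`",
         call. = FALSE)
  structure(list(min_object_px = min_object_px,
                 channel_threshold_mode = channel_threshold_mode,
                 fixed_thresholds = fixed_thresholds,
                 dual_positive = dual_positive),
            class = "viability_params")
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so
# diagonally adjacent 4-connected labels are merged with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # \ diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]    # / diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) > 0) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, numeric(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Segment one fluorescence channel into labeled objects
#'
#' Global threshold (Otsu by default), 8-connected component labeling, and
#' removal of objects smaller than \code{min_object_px}. A blank channel
#' (zero variance) yields an empty object set with a warning.
#'
#' @param image 2-D intensity matrix on the 8-bit scale.
#' @param params a \code{\link{viability_params}} object.
#' @param channel \code{"green"} or \code{"red"}; selects the fixed threshold
#'   in fixed mode.
#' @return a list with \code{labels} (label matrix), \code{objects}
#'   (data frame: \code{label}, \code{y}, \code{x} centroids in 0-based pixel
#'   coordinates, \code{area}), and \code{threshold}.
#' @export
segment_channel <- function(image, params = viability_params(),
                            channel = c("green", "red")) {
  channel <- match.arg(channel)
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty matrix", call. = FALSE)
  empty <- list(labels = matrix(0L, nrow(image), ncol(image)),
                objects = data.frame(label = integer(0), y = numeric(0),
                                     x = numeric(0), area = integer(0)),
                threshold = NA_real_)
  if (stats::var(as.numeric(image)) == 0) {
    warning("blank channel (zero variance): no objects segmented",
            call. = FALSE)
    return(empty)
  }
  thr <- if (params$channel_threshold_mode == "otsu") {
    EBImage::otsu(EBImage::Image(image / 255), range = c(0, 1)) * 255
  } else {
    params$fixed_thresholds[[channel]]
  }
  mask <- image > thr
  if (!any(mask)) return(within_threshold(empty, thr))
  lab <- .label8(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_object_px)
  if (length(keep) == 0L) return(within_threshold(empty, thr))
  # relabel survivors 1..k and compute centroids
  newlab <- integer(max(lab))
  newlab[keep] <- seq_along(keep)
  lab[lab > 0] <- newlab[lab[lab > 0]]
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  cy <- tapply(idx[, 1] - 1, lv, mean)
  cx <- tapply(idx[, 2] - 1, lv, mean)
  objects <- data.frame(label = as.integer(names(cy)),
                        y = as.numeric(cy), x = as.numeric(cx),
                        area = as.integer(tabulate(lv)))
  list(labels = lab, objects = objects, threshold = thr)
}

within_threshold <- function(seg, thr) { seg$threshold <- thr; seg }

#' Count live and dead cells in a LIVE/DEAD image
#'
#' Each channel is segmented independently; an object detected in both
#' channels (the centroid of a green object falls inside a red object, or
#' vice versa) represents one physical cell and is counted once, as dead by
#' default (ethidium-homodimer entry indicates a compromised membrane).
#' Viability is \code{100 * live / (live + dead)} by object count; the
#' stained-area ratio is reported as a secondary statistic.
#'
#' @param img a \code{\link{two_channel_image}}.
#' @param params a \code{\link{viability_params}} object.
#' @return an object of class \code{viability_result}: \code{live_count},
#'   \code{dead_count}, \code{viability_pct}, \code{area_viability_pct},
#'   \code{n_dual}.
#' @export
count_live_dead <- function(img, params = viability_params()) {
  stopifnot(inherits(img, "two_channel_image"))
  seg_g <- segment_channel(img$green, params, "green")
  seg_r <- segment_channel(img$red, params, "red")
  ng <- nrow(seg_g$objects); nr <- nrow(seg_r$objects)
  at_label <- function(labels, y, x) {
    i <- pmin(pmax(round(y) + 1, 1), nrow(labels))
    j <- pmin(pmax(round(x) + 1, 1), ncol(labels))
    labels[cbind(i, j)]
  }
  g_in_r <- if (ng > 0) at_label(seg_r$labels, seg_g$objects$y, seg_g$objects$x) > 0
            else logical(0)
  r_in_g <- if (nr > 0) at_label(seg_g$labels, seg_r$objects$y, seg_r$objects$x) > 0
            else logical(0)
  # red objects whose green partner was identified either way
  matched_red <- unique(c(
    if (ng > 0) at_label(seg_r$labels, seg_g$objects$y, seg_g$objects$x)[g_in_r],
    seg_r$objects$label[r_in_g]))
  matched_green <- unique(c(
    seg_g$objects$label[g_in_r],
    if (nr > 0) at_label(seg_g$labels, seg_r$objects$y, seg_r$objects$x)[r_in_g]))
  n_dual <- length(matched_green)
  if (params$dual_positive == "dead") {
    live <- ng - length(matched_green)
    dead <- nr
  } else {
    live <- ng
    dead <- nr - length(matched_red)
  }
  total <- live + dead
  if (total == 0) {
    warning("no objects detected in either channel; viability undefined, reported as 0",
            call. = FALSE)
    pct <- 0
  } else {
    pct <- 100 * live / total
  }
  area_g <- sum(seg_g$objects$area); area_r <- sum(seg_r$objects$area)
  area_pct <- if (area_g + area_r > 0) 100 * area_g / (area_g + area_r) else 0
  structure(list(live_count = as.integer(live), dead_count = as.integer(dead),
                 viability_pct = pct, area_viability_pct = area_pct,
                 n_dual = as.integer(n_dual)),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability_result> live = %d, dead = %d, viability = %.1f%%\n",
              x$live_count, x$dead_count, x$viability_pct))
  invisible(x)
}
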