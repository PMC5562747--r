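#' Percent change in beat rate from baseline
#'
#' @param baseline_bpm baseline beat rate (> 0; a zero baseline is a distinct
#'   condition from cessation and raises an error).
#' @param treated_bpm beat rate under treatment.
#' @return \code{100 * (treated - baseline) / baseline}.
#' @export
percent_change <- function(baseline_bpm, treated_bpm) {
  if (any(baseline_bpm <= 0))
    stop("baseline beat rate must be > 0 (undefined baseline)", call. = FALSE)
  100 * (treated_bpm - baseline_bpm) / baseline_bpm
}

#' Construct a dose-response record
#'
#' @param doses_uM strictly ascending non-negative concentrations (µM).
#' @param responses_pct mean percent change from baseline at each dose.
#' @param replicates optional list of per-dose replicate vectors.
#' @return an object of class \code{dose_response}.
#' @export
dose_response <- function(doses_uM, responses_pct, replicates = NULL) {
  if (length(doses_uM) != length(responses_pct))
    stop("`doses_uM` and `responses_pct` must have equal length", call. = FALSE)
  if (any(doses_uM < 0) || any(diff(doses_uM) <= 0))
    stop("`doses_uM` must be strictly ascending and non-negative", call. = FALSE)
  if (!is.null(replicates) && length(replicates) != length(doses_uM))
    stop("`replicates` must have one entry per dose", call. = FALSE)
  structure(list(doses_uM = as.numeric(doses_uM),
                 responses_pct = as.numeric(responses_pct),
                 replicates = replicates),
            class = "dose_response")
}

#' @export
as.data.frame.dose_response <- function(x, ...) {
  data.frame(dose_uM = x$doses_uM, response_pct = x$responses_pct)
}

.hill <- function(c, Rmax, EC50, n) {
  ifelse(c > 0, Rmax * c^n / (c^n + EC50^n), 0)
}

#' Fit a Hill dose-response model
#'
#' Least-squares fit of \code{response(c) = Rmax * c^n / (c^n + EC50^n)}; the
#' model passes through the origin, so the zero-dose point constrains the fit
#' without an intercept. The Hill coefficient is free; initialization is a
#' multistart grid over \code{n in \{0.5, 1, 2, 4\}} and EC50 over the
#' positive dose range, keeping the best residual sum of squares (ties toward
#' the smallest starting n). Near-zero responses yield \code{Rmax ~ 0} with
#' EC50 flagged unidentifiable.
#'
#' @param dr a \code{\link{dose_response}} with at least 4 doses including 0.
#' @return an object of class \code{hill_fit}: \code{Rmax_pct},
#'   \code{EC50_uM}, \code{hill_n}, \code{rss}, \code{unidentifiable}.
#' @export
fit_dose_response <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  if (length(dr$doses_uM) < 4L || dr$doses_uM[1] != 0)
    stop("need >= 4 doses including dose 0", call. = FALSE)
  d <- dr$doses_uM; y <- dr$responses_pct
  if (max(abs(y)) < 1e-8) {
    return(structure(list(Rmax_pct = 0, EC50_uM = NA_real_, hill_n = NA_real_,
                          rss = sum(y^2), unidentifiable = TRUE),
                     class = "hill_fit"))
  }
  pos <- d[d > 0]
  ec_starts <- unique(exp(seq(log(min(pos)), log(max(pos)), length.out = 4)))
  best <- NULL; best_start_n <- Inf
  for (n0 in c(0.5, 1, 2, 4)) {
    for (ec0 in ec_starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = list(lR = log(max(abs(y))), lE = log(ec0), ln = log(n0)),
          fn = function(p) y - .hill(d, exp(p$lR), exp(p$lE), exp(p$ln)),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 1e-12 ||
          (abs(rss - best$rss) <= 1e-12 && n0 < best_start_n)) {
        p <- fit$par
        best <- list(Rmax_pct = exp(p$lR), EC50_uM = exp(p$lE),
                     hill_n = exp(p$ln), rss = rss, unidentifiable = FALSE)
        best_start_n <- n0
      }
    }
  }
  if (is.null(best)) stop("Hill fit failed to converge from any start", call. = FALSE)
  structure(best, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Rmax = %.3f%%, EC50 = %.4g uM, n = %.3g, rss = %.4g%s\n",
              x$Rmax_pct, x$EC50_uM, x$hill_n, x$rss,
              if (isTRUE(x$unidentifiable)) " (unidentifiable)" else ""))
  invisible(x)
}

#' Blockade (antagonist) analysis
#'
#' Per-dose inhibition fractions \code{1 - response(d) / control} for an
#' antagonist dose series measured against a fixed-agonist control response,
#' plus a monotonicity flag (non-decreasing inhibition with dose, the
#' behaviour expected of a competitive blocker). When blockade of basal tone
#' pushes the response below baseline the fraction can exceed 1.
#'
#' @param control_response_pct agonist-only control percent change (> 0).
#' @param responses_by_antagonist_dose a \code{\link{dose_response}} over
#'   antagonist doses.
#' @return a list with \code{inhibition} data frame (\code{dose_uM},
#'   \code{inhibition_frac}) and \code{monotone_nondecreasing} flag.
#' @export
blockade_analysis <- function(control_response_pct, responses_by_antagonist_dose) {
  if (control_response_pct <= 0)
    stop("`control_response_pct` must be > 0", call. = FALSE)
  dr <- responses_by_antagonist_dose
  stopifnot(inherits(dr, "dose_response"))
  inh <- 1 - dr$responses_pct / control_response_pct
  list(inhibition = data.frame(dose_uM = dr$doses_uM, inhibition_frac = inh),
       monotone_nondecreasing = all(diff(inh) >= -1e-9))
}

#' Fraction of the control response recovered
#'
#' @param treated_pct percent change under the treated condition.
#' @param control_pct percent change of the control condition (> 0).
#' @return \code{treated_pct / control_pct}.
#' @export
fraction_recovered <- function(treated_pct, control_pct) {
  if (control_pct <= 0) stop("`control_pct` must be > 0", call. = FALSE)
  treated_pct / control_pct
}

#' Classify a beat-rate time course
#'
#' Threshold rules over a series of percent changes from baseline. With
#' \code{stable_band} the half-width of the no-effect band (percent points):
#' \itemize{
#'   \item \code{ceased}: any point has \code{bpm == 0};
#'   \item \code{stable}: all \code{|change| < stable_band};
#'   \item \code{increase_then_decrease}: max exceeds the band and the final
#'     point has fallen below \code{-stable_band} or below
#'     \code{max - stable_band};
#'   \item \code{sustained_increase}: max and final point both exceed the band;
#'   \item \code{sustained_decrease}: max below the band, min below
#'     \code{-stable_band}.
#' }
#' Rules are evaluated in that order (the decline rule is more specific than
#' sustained increase, so it takes precedence).
#'
#' @param series data frame with columns \code{time_h} (or \code{time_s}) and
#'   \code{change_pct}; an optional \code{bpm} column enables the ceased rule.
#' @param stable_band no-effect band half-width in percent points. The default
#'   15 places a ~10 percent antagonist-alone effect inside the band.
#' @return one of \code{"stable"}, \code{"sustained_increase"},
#'   \code{"increase_then_decrease"}, \code{"sustained_decrease"},
#'   \code{"ceased"}.
#' @export
classify_timecourse <- function(series, stable_band = 15) {
  if (!is.data.frame(series) || nrow(series) < 3L)
    stop("`series` must be a data frame with >= 3 time points", call. = FALSE)
  if (!"change_pct" %in% names(series))
    stop("`series` must have a `change_pct` column", call. = FALSE)
  ch <- series$change_pct
  if ("bpm" %in% names(series) && any(series$bpm == 0)) return("ceased")
  if (all(abs(ch) < stable_band)) return("stable")
  final <- ch[length(ch)]
  if (max(ch) > stable_band &&
      (final < -stable_band || final < max(ch) - stable_band))
    return("increase_then_decrease")
  if (max(ch) > stable_band && final > stable_band)
    return("sustained_increase")
  if (max(ch) < stable_band && min(ch) < -stable_band)
    return("sustained_decrease")
  "stable"
}
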