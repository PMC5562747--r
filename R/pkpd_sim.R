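#' Pharmacokinetic parameters: first-order hepatic clearance
#'
#' The recirculating chip medium is treated as a single well-mixed
#' compartment, so drug concentration follows \code{C(t) = C0 * exp(-k_h t)}.
#' The default elimination constant \code{k_h = ln(3) / 48} per hour is
#' calibrated so that the concentration falls 3-fold over 48 hours, the
#' fold-change measured by LC-MS for propranolol in the liver-heart platform.
#'
#' @param k_h first-order elimination rate constant (per hour, >= 0).
#' @param C0_uM initial drug concentration (µM, >= 0).
#' @param flow_uL_min recirculation flow rate (µL/min, informational).
#' @return an object of class \code{pk_params}.
#' @export
pk_params <- function(k_h = log(3) / 48, C0_uM = 0, flow_uL_min = 10) {
  if (k_h < 0) stop("`k_h` must be >= 0", call. = FALSE)
  if (C0_uM < 0) stop("`C0_uM` must be >= 0", call. = FALSE)
  structure(list(k_h = k_h, C0_uM = C0_uM, flow_uL_min = flow_uL_min),
            class = "pk_params")
}

#' Simulate first-order clearance
#'
#' @param pk a \code{\link{pk_params}} object.
#' @param t_h time(s) in hours (>= 0); vectorized.
#' @return concentration(s) in µM, \code{C0_uM * exp(-k_h * t_h)}.
#' @export
simulate_clearance <- function(pk, t_h) {
  stopifnot(inherits(pk, "pk_params"))
  if (any(t_h < 0)) stop("`t_h` must be >= 0", call. = FALSE)
  pk$C0_uM * exp(-pk$k_h * t_h)
}

#' Pharmacodynamic parameters: competitive-antagonism beat-rate response
#'
#' Parameters of the Gaddum/Schild response model used by the chip simulator
#' (see \code{\link{beat_rate_response}}). Basal adrenergic tone is expressed
#' as an equivalent agonist concentration \code{E_basal_uM}, which is what
#' lets an antagonist alone depress the beat rate below baseline.
#'
#' @param B0_bpm intrinsic beat rate with zero adrenergic input (> 0).
#' @param Rmax maximal fractional rate increase (dimensionless, > 0).
#' @param EC50_uM agonist half-maximal concentration (µM, > 0).
#' @param Ki_uM antagonist equilibrium constant (µM, > 0).
#' @param hill_n Hill coefficient (> 0).
#' @param E_basal_uM basal adrenergic tone as an equivalent agonist
#'   concentration (µM, >= 0).
#' @return an object of class \code{pd_params}.
#' @export
pd_params <- function(B0_bpm, Rmax, EC50_uM, Ki_uM, hill_n, E_basal_uM) {
  vals <- c(B0_bpm = B0_bpm, Rmax = Rmax, EC50_uM = EC50_uM,
            Ki_uM = Ki_uM, hill_n = hill_n)
  if (any(vals <= 0))
    stop("all pd parameters except E_basal_uM must be > 0", call. = FALSE)
  if (E_basal_uM < 0) stop("`E_basal_uM` must be >= 0", call. = FALSE)
  structure(list(B0_bpm = B0_bpm, Rmax = Rmax, EC50_uM = EC50_uM,
                 Ki_uM = Ki_uM, hill_n = hill_n, E_basal_uM = E_basal_uM),
            class = "pd_params")
}

#' Beat rate under agonist and competitive antagonist
#'
#' Gaddum/Schild competitive shift: the antagonist multiplies the apparent
#' EC50 by \code{1 + P / Ki} without reducing the attainable maximum, so the
#' block is surmountable and the response returns to \code{B0_bpm} in the
#' limit of complete blockade. With \code{A = E + E_basal}:
#' \deqn{bpm = B0 (1 + Rmax \frac{A^n}{A^n + (EC50 (1 + P/Ki))^n})}
#'
#' @param E_uM agonist (epinephrine) concentration in µM (>= 0); vectorized.
#' @param P_uM antagonist (propranolol) concentration in µM (>= 0); vectorized.
#' @param pd a \code{\link{pd_params}} object.
#' @return beat rate(s) in BPM.
#' @export
beat_rate_response <- function(E_uM, P_uM, pd) {
  stopifnot(inherits(pd, "pd_params"))
  if (any(E_uM < 0) || any(P_uM < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  A <- E_uM + pd$E_basal_uM
  K <- pd$EC50_uM * (1 + P_uM / pd$Ki_uM)
  An <- A^pd$hill_n
  h <- An / (An + K^pd$hill_n)
  h[A == 0] <- 0
  pd$B0_bpm * (1 + pd$Rmax * h)
}

#' Percent change from the drug-free baseline of a PD model
#'
#' @param pd a \code{\link{pd_params}} object.
#' @param E_uM,P_uM agonist / antagonist concentrations (µM).
#' @return percent change relative to the response at (0, 0).
#' @export
pd_percent_change <- function(pd, E_uM, P_uM = 0) {
  base <- beat_rate_response(0, 0, pd)
  percent_change(base, beat_rate_response(E_uM, P_uM, pd))
}

#' Default calibration anchors for the PD model
#'
#' Percent-change anchors the shipped defaults are fitted to: +40\% at 0.5 µM
#' epinephrine alone; -10\% at 0.1 µM propranolol alone; +25\% at 0.5 µM
#' epinephrine after 0.1 µM propranolol has been cleared for 18 h by the
#' liver (a factor \code{3^(18/48)} reduction); and a half-weight qualitative
#' anchor of +5\% for the fully blocked heart-only condition.
#'
#' @return data frame with columns \code{condition}, \code{E_uM}, \code{P_uM},
#'   \code{target_pct}, \code{weight}.
#' @export
default_pd_anchors <- function() {
  data.frame(
    condition = c("epinephrine_alone", "propranolol_alone",
                  "liver_cleared_block", "full_block"),
    E_uM = c(0.5, 0, 0.5, 0.5),
    P_uM = c(0, 0.1, 0.1 * 3^(-18 / 48), 0.1),
    target_pct = c(40, -10, 25, 5),
    weight = c(1, 1, 1, 0.5))
}

#' Calibrate PD defaults against percent-change anchors
#'
#' Weighted least-squares fit of \code{(Rmax, EC50, Ki, hill_n, E_basal)} to
#' a set of (condition, target percent change) anchors, by deterministic
#' multistart Nelder-Mead on log-parameters. \code{B0_bpm} cancels out of
#' percent changes and is fixed.
#'
#' @param anchors data frame as returned by \code{\link{default_pd_anchors}}.
#' @param B0_bpm intrinsic beat rate assigned to the fitted parameter set.
#' @param fixed optional named list pinning any of \code{Rmax},
#'   \code{EC50_uM}, \code{Ki_uM}, \code{hill_n}, \code{E_basal_uM} to given
#'   values; only the remaining parameters are optimized.
#' @param max_rss largest acceptable total weighted residual; exceeding it is
#'   treated as non-convergence.
#' @return a list with \code{pd} (a \code{\link{pd_params}}), \code{residuals}
#'   (per-anchor fitted minus target), and \code{rss}.
#' @export
calibrate_pd_defaults <- function(anchors = default_pd_anchors(),
                                  B0_bpm = 54, fixed = list(), max_rss = 1) {
  stopifnot(is.data.frame(anchors),
            all(c("E_uM", "P_uM", "target_pct", "weight") %in% names(anchors)))
  par_names <- c("Rmax", "EC50_uM", "Ki_uM", "hill_n", "E_basal_uM")
  if (!all(names(fixed) %in% par_names))
    stop("`fixed` may only name PD parameters", call. = FALSE)
  free <- setdiff(par_names, names(fixed))
  assemble <- function(th_free) {
    th <- numeric(5); names(th) <- par_names
    th[free] <- th_free
    for (nm in names(fixed)) th[nm] <- fixed[[nm]]
    th
  }
  pct_of <- function(th) {
    pd <- pd_params(B0_bpm, unname(th["Rmax"]), unname(th["EC50_uM"]),
                    unname(th["Ki_uM"]), unname(th["hill_n"]),
                    unname(th["E_basal_uM"]))
    vapply(seq_len(nrow(anchors)), function(i)
      pd_percent_change(pd, anchors$E_uM[i], anchors$P_uM[i]), numeric(1))
  }
  obj <- function(lp) {
    r <- pct_of(assemble(exp(lp))) - anchors$target_pct
    sum(anchors$weight * r^2)
  }
  grid <- expand.grid(Rmax = c(0.5, 1, 2), EC50_uM = c(0.05, 0.2, 1),
                      Ki_uM = c(0.002, 0.01, 0.05), hill_n = c(1, 2, 4),
                      E_basal_uM = c(0.02, 0.1, 0.3))
  grid <- unique(grid[, free, drop = FALSE])
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    start <- log(as.numeric(grid[i, ]))
    o <- tryCatch(
      if (length(free) == 1L)
        stats::optim(start, obj, method = "Brent",
                     lower = start - 12, upper = start + 12)
      else
        stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value > max_rss)
    stop(sprintf("PD calibration did not converge (best rss = %.4g)",
                 if (is.null(best)) Inf else best$value), call. = FALSE)
  th <- assemble(exp(best$par))
  pd <- pd_params(B0_bpm, unname(th["Rmax"]), unname(th["EC50_uM"]),
                  unname(th["Ki_uM"]), unname(th["hill_n"]),
                  unname(th["E_basal_uM"]))
  list(pd = pd, residuals = pct_of(th) - anchors$target_pct, rss = best$value)
}

#' Packaged default PD parameters
#'
#' Loads the shipped parameter file produced by
#' \code{\link{calibrate_pd_defaults}} on the default anchors. These values
#' are calibrated, not measured; the file records the per-anchor residuals.
#'
#' @return a \code{\link{pd_params}} object.
#' @export
default_pd_params <- function() {
  path <- system.file("extdata", "pd_default_params.json",
                      package = "chipbeat", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$parameters
  pd_params(p$B0_bpm, p$Rmax, p$EC50_uM, p$Ki_uM, p$hill_n, p$E_basal_uM)
}

#' Construct an experiment protocol
#'
#' @param mode \code{"cardiac_only"} (no clearance), \code{"liver_cardiac"}
#'   (3-D liver organoids clear the antagonist), \code{"hepatocyte_2d"}
#'   (2-D hepatocytes: no effective clearance) or \code{"three_tissue"}
#'   (lung module present; cytokine scenarios).
#' @param events data frame with columns \code{time_h}, \code{drug},
#'   \code{conc_uM}; event times must lie within \code{[0, duration_h]}.
#' @param duration_h experiment duration in hours.
#' @param liver_cardiac_ratio liver-to-cardiac organoid count ratio
#'   (informational; the platform uses 5:1).
#' @param seed random seed for any stochastic noise downstream.
#' @return an object of class \code{experiment_protocol}.
#' @export
experiment_protocol <- function(mode = c("cardiac_only", "liver_cardiac",
                                         "hepatocyte_2d", "three_tissue"),
                                events, duration_h,
                                liver_cardiac_ratio = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.data.frame(events) ||
      !all(c("time_h", "drug", "conc_uM") %in% names(events)))
    stop("`events` must be a data frame with time_h, drug, conc_uM",
         call. = FALSE)
  if (duration_h <= 0) stop("`duration_h` must be > 0", call. = FALSE)
  if (nrow(events) > 0) {
    if (any(events$time_h < 0 | events$time_h > duration_h))
      stop("event times must lie within [0, duration_h]", call. = FALSE)
    if (any(events$conc_uM < 0))
      stop("event concentrations must be >= 0", call. = FALSE)
  }
  structure(list(mode = mode, events = events[order(events$time_h), ],
                 duration_h = duration_h,
                 liver_cardiac_ratio = liver_cardiac_ratio,
                 seed = as.integer(seed)),
            class = "experiment_protocol")
}

# Concentration of one drug over a time grid given its dosing events.
# Additional doses add to whatever remains of earlier ones.
.drug_conc <- function(times_h, events, drug, k_h) {
  conc <- numeric(length(times_h))
  ev <- events[events$drug == drug, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    dt <- times_h - ev$time_h[i]
    conc <- conc + ifelse(dt >= 0, ev$conc_uM[i] * exp(-k_h * dt), 0)
  }
  conc
}

#' Simulate a two-tissue (liver-heart) drug-interaction experiment
#'
#' The antagonist (propranolol) is cleared between events with first-order
#' kinetics when functional liver tissue is present (\code{liver_cardiac}
#' mode); in \code{cardiac_only} and \code{hepatocyte_2d} modes it is not
#' cleared (\code{k_h = 0}), reflecting the absence of effective hepatic
#' metabolism. The agonist (epinephrine) is treated as uncleared over the
#' short (< 2 h) response window. Beat rate follows
#' \code{\link{beat_rate_response}} at the instantaneous concentrations.
#'
#' @param protocol an \code{\link{experiment_protocol}} whose events dose
#'   \code{"propranolol"} and/or \code{"epinephrine"}.
#' @param pk a \code{\link{pk_params}} providing the hepatic elimination rate.
#' @param pd a \code{\link{pd_params}}; defaults to the shipped calibration.
#' @param dt_h time step of the output grid in hours.
#' @return a list with \code{timeseries} (data frame: \code{t_h}, \code{P_uM},
#'   \code{E_uM}, \code{bpm}) and \code{truth} (parameters, mode, baseline
#'   bpm, and per-event concentrations actually in effect).
#' @export
simulate_two_tissue_experiment <- function(protocol,
                                           pk = pk_params(),
                                           pd = default_pd_params(),
                                           dt_h = 0.05) {
  stopifnot(inherits(protocol, "experiment_protocol"),
            inherits(pk, "pk_params"), inherits(pd, "pd_params"))
  k_h <- if (protocol$mode == "liver_cardiac") pk$k_h else 0
  times <- seq(0, protocol$duration_h, by = dt_h)
  P <- .drug_conc(times, protocol$events, "propranolol", k_h)
  E <- .drug_conc(times, protocol$events, "epinephrine", 0)
  bpm <- beat_rate_response(E, P, pd)
  ts <- data.frame(t_h = times, P_uM = P, E_uM = E, bpm = bpm)
  truth <- list(mode = protocol$mode, k_h_effective = k_h,
                baseline_bpm = beat_rate_response(0, 0, pd),
                pd = unclass(pd), seed = protocol$seed,
                events = protocol$events)
  list(timeseries = ts, truth = truth)
}

#' Cytokine scenario configuration
#'
#' Phenomenological description of the bleomycin -> lung cytokine -> cardiac
#' response cascade. Cytokine production is zero-order after the bleomycin
#' event (lung present only). The IL-1\eqn{\beta} effect curve rises linearly
#' to \code{early_increase_frac} above baseline by \code{rise_h} hours after
#' exposure, holds that plateau through \code{plateau_end_h}, then declines
#' to complete cessation at \code{cessation_h}; IL-8 has no beat-rate effect.
#' Defaults: +60\% by 24 h, plateau through 96 h, cessation at 144 h --
#' matching a day-3 exposure ceasing by day 9.
#'
#' @param il8_rate_pg_ml_h zero-order IL-8 production rate after exposure.
#' @param il1b_rate_pg_ml_h zero-order IL-1\eqn{\beta} production rate.
#' @param early_increase_frac early fractional beat-rate increase (0.6 = 60\%).
#' @param rise_h hours from exposure to the full early increase.
#' @param plateau_end_h hours from exposure at which decline begins.
#' @param cessation_h hours from exposure at which the decline completes:
#'   beating ceases under sustained on-chip exposure, or reaches the late
#'   depressed level in a bolus challenge.
#' @param late_change_frac late fractional change under a bolus challenge
#'   (-0.3 = 30\% below baseline at \code{cessation_h}).
#' @return an object of class \code{cytokine_config}.
#' @export
cytokine_config <- function(il8_rate_pg_ml_h = 2, il1b_rate_pg_ml_h = 0.5,
                            early_increase_frac = 0.6, rise_h = 24,
                            plateau_end_h = 96, cessation_h = 144,
                            late_change_frac = -0.3) {
  if (!(rise_h > 0 && plateau_end_h >= rise_h && cessation_h > plateau_end_h))
    stop("need 0 < rise_h <= plateau_end_h < cessation_h", call. = FALSE)
  if (early_increase_frac < 0)
    stop("`early_increase_frac` must be >= 0", call. = FALSE)
  if (late_change_frac < -1)
    stop("`late_change_frac` must be >= -1", call. = FALSE)
  structure(list(il8_rate_pg_ml_h = il8_rate_pg_ml_h,
                 il1b_rate_pg_ml_h = il1b_rate_pg_ml_h,
                 early_increase_frac = early_increase_frac,
                 rise_h = rise_h, plateau_end_h = plateau_end_h,
                 cessation_h = cessation_h,
                 late_change_frac = late_change_frac),
            class = "cytokine_config")
}

#' IL-1\eqn{\beta} beat-rate effect curve
#'
#' Multiplier applied to the baseline beat rate as a function of time since
#' cytokine exposure: 1 before exposure, a linear rise to the early increase
#' by \code{rise_h}, a plateau through \code{plateau_end_h}, then a linear
#' decline completing at \code{cessation_h}. The decline endpoint depends on
#' the exposure regime: under sustained on-chip production
#' (\code{endpoint = "cessation"}) beating stops entirely (multiplier 0); a
#' single bolus challenge (\code{endpoint = "depression"}) ends at
#' \code{1 + late_change_frac}, depressed below baseline but still beating.
#'
#' @param t_since_h hours since exposure; vectorized.
#' @param cfg a \code{\link{cytokine_config}}.
#' @param endpoint \code{"cessation"} or \code{"depression"}.
#' @return beat-rate multiplier(s).
#' @export
il1b_effect_curve <- function(t_since_h, cfg = cytokine_config(),
                              endpoint = c("cessation", "depression")) {
  stopifnot(inherits(cfg, "cytokine_config"))
  endpoint <- match.arg(endpoint)
  peak <- 1 + cfg$early_increase_frac
  final <- if (endpoint == "cessation") 0 else 1 + cfg$late_change_frac
  m <- ifelse(t_since_h <= 0, 1,
       ifelse(t_since_h <= cfg$rise_h,
              1 + cfg$early_increase_frac * t_since_h / cfg$rise_h,
       ifelse(t_since_h <= cfg$plateau_end_h, peak,
       ifelse(t_since_h < cfg$cessation_h,
              peak + (final - peak) * (t_since_h - cfg$plateau_end_h) /
                     (cfg$cessation_h - cfg$plateau_end_h),
              final))))
  pmax(m, 0)
}

#' Simulate the three-tissue bleomycin / cytokine scenario
#'
#' With the lung module present (\code{three_tissue} mode), IL-8 and
#' IL-1\eqn{\beta} accumulate linearly after the bleomycin event and the
#' cardiac beat rate follows the IL-1\eqn{\beta} effect curve: an early rise,
#' a plateau, then decline to complete cessation. In a \code{cardiac_only}
#' run bleomycin has no effect on beating and no cytokines are produced.
#'
#' @param protocol an \code{\link{experiment_protocol}} including a
#'   \code{"bleomycin"} event.
#' @param cytokine_cfg a \code{\link{cytokine_config}}.
#' @param pd a \code{\link{pd_params}} supplying the baseline beat rate.
#' @param dt_h time step of the output grid in hours.
#' @return a list with \code{timeseries} (data frame: \code{t_h},
#'   \code{il8_pg_ml}, \code{il1b_pg_ml}, \code{bpm}, \code{ceased}) and
#'   \code{truth}.
#' @export
simulate_three_tissue_scenario <- function(protocol,
                                           cytokine_cfg = cytokine_config(),
                                           pd = default_pd_params(),
                                           dt_h = 1) {
  stopifnot(inherits(protocol, "experiment_protocol"),
            inherits(cytokine_cfg, "cytokine_config"))
  bleo <- protocol$events[protocol$events$drug == "bleomycin", , drop = FALSE]
  if (nrow(bleo) == 0L)
    stop("protocol must include a bleomycin event (dose 0 for a no-drug control)",
         call. = FALSE)
  t_b <- bleo$time_h[1]
  # a zero-dose event is the vehicle control: no insult, no cytokines
  lung_present <- protocol$mode == "three_tissue" && bleo$conc_uM[1] > 0
  times <- seq(0, protocol$duration_h, by = dt_h)
  baseline <- beat_rate_response(0, 0, pd)
  dt_since <- times - t_b
  if (lung_present) {
    il8 <- pmax(dt_since, 0) * cytokine_cfg$il8_rate_pg_ml_h
    il1b <- pmax(dt_since, 0) * cytokine_cfg$il1b_rate_pg_ml_h
    bpm <- baseline * il1b_effect_curve(dt_since, cytokine_cfg)
  } else {
    il8 <- il1b <- numeric(length(times))
    bpm <- rep(baseline, length(times))
  }
  ceased <- bpm == 0
  ts <- data.frame(t_h = times, il8_pg_ml = il8, il1b_pg_ml = il1b,
                   bpm = bpm, ceased = ceased)
  truth <- list(mode = protocol$mode, lung_present = lung_present,
                bleomycin_time_h = t_b, baseline_bpm = baseline,
                cytokine_cfg = unclass(cytokine_cfg), seed = protocol$seed)
  list(timeseries = ts, truth = truth)
}

#' Simulate a direct cytokine challenge of cardiac organoids
#'
#' Exposure of cardiac organoids to recombinant IL-1\eqn{\beta}, IL-8, or
#' plain medium at time 0. IL-8 and control arms hold the baseline rate;
#' IL-1\eqn{\beta} follows the effect curve.
#'
#' @param agent \code{"IL-1b"}, \code{"IL-8"} or \code{"control"}.
#' @param times_h observation times in hours (the platform sampled 0, 24, 48,
#'   96 and 144 h).
#' @param cytokine_cfg a \code{\link{cytokine_config}}.
#' @param pd a \code{\link{pd_params}} supplying the baseline beat rate.
#' @return data frame with \code{time_h}, \code{bpm}, \code{change_pct}.
#' @export
simulate_cytokine_challenge <- function(agent = c("IL-1b", "IL-8", "control"),
                                        times_h = c(0, 24, 48, 96, 144),
                                        cytokine_cfg = cytokine_config(),
                                        pd = default_pd_params()) {
  agent <- match.arg(agent)
  baseline <- beat_rate_response(0, 0, pd)
  bpm <- if (agent == "IL-1b")
    baseline * il1b_effect_curve(times_h, cytokine_cfg, endpoint = "depression")
  else rep(baseline, length(times_h))
  data.frame(time_h = times_h, bpm = bpm,
             change_pct = percent_change(baseline, bpm))
}
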