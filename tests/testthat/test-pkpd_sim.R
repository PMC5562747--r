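test_that("clearance is exponential and hits the 48 h three-fold mark", {
  pk <- pk_params(C0_uM = 0.1)
  expect_equal(simulate_clearance(pk, 0), 0.1)
  fold <- simulate_clearance(pk, 0) / simulate_clearance(pk, 48)
  expect_lt(abs(fold - 3) / 3, 0.005)
  expect_true(all(diff(simulate_clearance(pk, 0:100)) < 0))
  expect_error(simulate_clearance(pk, -1), ">= 0")
  expect_error(pk_params(k_h = -0.1), ">= 0")
})

test_that("closed-form clearance matches a numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  pk <- pk_params(k_h = 0.13, C0_uM = 2.5)
  times <- seq(0, 48, by = 1)
  ode <- deSolve::ode(y = c(C = pk$C0_uM), times = times,
                      func = function(t, y, p) list(-p * y),
                      parms = pk$k_h, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  closed <- simulate_clearance(pk, times)
  expect_lt(max(abs(ode[, "C"] - closed) / closed), 1e-6)
})

test_that("the response model honours its null input and blockade limits", {
  pd0 <- pd_params(B0_bpm = 60, Rmax = 0.5, EC50_uM = 0.2, Ki_uM = 0.01,
                   hill_n = 2, E_basal_uM = 0)
  expect_equal(beat_rate_response(0, 0, pd0), 60)
  pd <- default_pd_params()
  expect_gt(beat_rate_response(0, 0, pd), pd$B0_bpm)  # basal tone raises rate
  expect_lt(abs(beat_rate_response(5, 1e9, pd) - pd$B0_bpm), 1e-3)
  expect_error(beat_rate_response(-1, 0, pd), ">= 0")
})

test_that("response is monotone over an agonist/antagonist grid", {
  pd <- default_pd_params()
  E <- seq(0, 10, length.out = 20)
  P <- seq(0, 20, length.out = 20)
  M <- outer(E, P, function(e, p) beat_rate_response(e, p, pd))
  expect_true(all(apply(M, 2, function(col) all(diff(col) >= -1e-12))))
  expect_true(all(apply(M, 1, function(row) all(diff(row) <= 1e-12))))
})

test_that("single-anchor calibration matches the closed-form EC50", {
  cal <- calibrate_pd_defaults(
    anchors = data.frame(condition = "epi", E_uM = 0.5, P_uM = 0,
                         target_pct = 40, weight = 1),
    fixed = list(Rmax = 0.8, Ki_uM = 0.01, hill_n = 2, E_basal_uM = 0))
  # with no basal tone: 1 + Rmax h(0.5) = 1.4  =>  EC50 = 0.5 (Rmax/0.4 - 1)^(1/n)
  ec_closed <- 0.5 * (0.8 / 0.4 - 1)^(1 / 2)
  expect_equal(cal$pd$EC50_uM, ec_closed, tolerance = 1e-6)
})

test_that("the shipped defaults reproduce their calibration file", {
  path <- system.file("extdata", "pd_default_params.json",
                      package = "chipbeat")
  shipped <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_lt(shipped$rss, 1e-6)
  expect_lt(max(abs(shipped$anchors$residual_pct)), 0.01)
  pd <- default_pd_params()
  expect_equal(pd$EC50_uM, shipped$parameters$EC50_uM)
  # re-running the deterministic calibration lands on the same optimum
  cal <- calibrate_pd_defaults()
  expect_equal(cal$pd$EC50_uM, pd$EC50_uM, tolerance = 1e-6)
  expect_equal(cal$pd$Ki_uM, pd$Ki_uM, tolerance = 1e-6)
})

test_that("two-tissue interaction logic reproduces the blocking/recovery pattern", {
  ev <- data.frame(time_h = c(1, 19),
                   drug = c("propranolol", "epinephrine"),
                   conc_uM = c(0.1, 0.5))
  post_pct <- vapply(c("cardiac_only", "liver_cardiac", "hepatocyte_2d"),
                     function(m) {
    sim <- simulate_two_tissue_experiment(
      experiment_protocol(m, ev, duration_h = 21))
    ts <- sim$timeseries
    percent_change(sim$truth$baseline_bpm,
                   ts$bpm[which.min(abs(ts$t_h - 20))])
  }, numeric(1))
  expect_lt(post_pct[["cardiac_only"]], 10)            # blocked
  expect_gt(post_pct[["liver_cardiac"]], post_pct[["cardiac_only"]])
  expect_lt(abs(post_pct[["hepatocyte_2d"]] - post_pct[["cardiac_only"]]), 1)
  # 18 h of hepatic clearance leaves ~25 % of the control response pathway
  expect_equal(post_pct[["liver_cardiac"]], 25, tolerance = 0.05)
})

test_that("propranolol is only cleared when functional liver is present", {
  ev <- data.frame(time_h = 0, drug = "propranolol", conc_uM = 0.1)
  with_liver <- simulate_two_tissue_experiment(
    experiment_protocol("liver_cardiac", ev, duration_h = 48))
  without <- simulate_two_tissue_experiment(
    experiment_protocol("cardiac_only", ev, duration_h = 48))
  end_P <- function(s) tail(s$timeseries$P_uM, 1)
  expect_equal(end_P(without), 0.1)
  expect_equal(0.1 / end_P(with_liver), 3, tolerance = 0.01)
})

test_that("three-tissue bleomycin scenario ceases while cardiac-only does not", {
  ev <- data.frame(time_h = 72, drug = "bleomycin", conc_uM = 10)
  three <- simulate_three_tissue_scenario(
    experiment_protocol("three_tissue", ev, duration_h = 216))
  expect_true(tail(three$timeseries$ceased, 1))
  expect_true(all(diff(three$timeseries$il8_pg_ml) >= 0))

  cardiac <- simulate_three_tissue_scenario(
    experiment_protocol("cardiac_only", ev, duration_h = 216))
  expect_false(any(cardiac$timeseries$ceased))
  expect_true(all(abs(cardiac$timeseries$bpm - cardiac$truth$baseline_bpm) /
                    cardiac$truth$baseline_bpm < 0.05))

  control <- simulate_three_tissue_scenario(
    experiment_protocol("three_tissue",
                        data.frame(time_h = 72, drug = "bleomycin",
                                   conc_uM = 0),
                        duration_h = 216))
  expect_true(all(control$timeseries$il1b_pg_ml == 0))
  expect_true(all(control$timeseries$bpm == control$truth$baseline_bpm))

  expect_error(simulate_three_tissue_scenario(
    experiment_protocol("three_tissue",
                        data.frame(time_h = numeric(0), drug = character(0),
                                   conc_uM = numeric(0)),
                        duration_h = 216)),
    "bleomycin")
})

test_that("cytokine challenges follow the published qualitative pattern", {
  il1b <- simulate_cytokine_challenge("IL-1b")
  expect_equal(il1b$change_pct[il1b$time_h == 24], 60)
  expect_equal(classify_timecourse(il1b), "increase_then_decrease")
  il8 <- simulate_cytokine_challenge("IL-8")
  expect_true(all(il8$change_pct == 0))
  expect_equal(classify_timecourse(il8), "stable")
})

test_that("experiment protocols validate events", {
  expect_error(experiment_protocol("cardiac_only",
    data.frame(time_h = 30, drug = "x", conc_uM = 1), duration_h = 20),
    "within")
  expect_error(experiment_protocol("cardiac_only",
    data.frame(time_h = 1, drug = "x", conc_uM = -1), duration_h = 20),
    ">= 0")
})
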