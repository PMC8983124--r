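test_that("onset detection handles step and ramp starts", {
  # instant exponential decay starting at t = 1.0 s
  t <- seq(0, 3, by = 0.001)
  flow <- ifelse(t >= 1, 150 * exp(-(t - 1) / 0.2), 0)
  tr <- data.frame(time_s = t, flow_ml_s = flow,
                   volume_ml = cumsum(flow) * 0.001)
  expect_lt(abs(detect_exhalation_start(tr) - 1.0), 0.0015)

  # linear ramp starting at 0.5 s back-extrapolates to 0.5 s
  flow2 <- pmax(t - 0.5, 0) * 100
  tr2 <- data.frame(time_s = t, flow_ml_s = flow2,
                    volume_ml = cumsum(flow2) * 0.001)
  expect_lt(abs(detect_exhalation_start(tr2) - 0.5), 0.001)

  tr0 <- data.frame(time_s = t, flow_ml_s = 0 * t, volume_ml = 0 * t)
  expect_error(detect_exhalation_start(tr0), class = "fl_degenerate_error")
})

test_that("spirometry matches the analytic values on noiseless traces", {
  tr <- make_expiration_trace(trace_preset(fvc = 30, tau = 0.2))
  s <- compute_spirometry(tr, 0.4)
  expect_lt(abs(s$fev_ml - 30 * (1 - exp(-2))) / (30 * (1 - exp(-2))), 0.001)
  expect_lt(abs(s$ratio - analytic_ratio(0.4, 1, 0.2)) /
              analytic_ratio(0.4, 1, 0.2), 0.001)
  expect_false(s$truncated)

  bi <- make_expiration_trace(trace_preset(fvc = 30, fractions = c(0.5, 0.5),
                                           tau = c(0.1, 2)))
  s2 <- compute_spirometry(bi, 0.4)
  want <- analytic_ratio(0.4, c(0.5, 0.5), c(0.1, 2))
  expect_lt(abs(s2$ratio - want) / want, 0.001)
  expect_lt(s2$ratio, 0.7)  # the obstructed pattern
})

test_that("FEV_x saturates to FVC when x outruns the trace", {
  tr <- make_expiration_trace(trace_preset(fvc = 30, tau = 0.2))
  s <- compute_spirometry(tr, 1e3)
  expect_equal(s$ratio, 1)
  expect_equal(s$fev_ml, s$fvc_ml)
  expect_error(compute_spirometry(tr, 0), class = "fl_input_error")
})

test_that("length normalization divides through and cancels in ratios", {
  expect_equal(normalize_by_length(40, 40), 1)
  tr <- make_expiration_trace(trace_preset(fvc = 30, tau = 0.2))
  s <- compute_spirometry(tr, 0.4, body_length_cm = 38)
  expect_equal(s$fev_per_cm / s$fvc_per_cm, s$ratio, tolerance = 1e-12)
  expect_error(normalize_by_length(40, 0), class = "fl_input_error")
})

test_that("FEV_x calibration finds the analytic grid point on controls", {
  controls <- lapply(1:5, function(i)
    make_expiration_trace(trace_preset(fvc = 24 + i, tau = 0.2,
                                       noise_sd = 1, seed = i)))
  cal <- calibrate_fev_x(controls, floor = 0.7)
  # analytic crossing of 1 - exp(-x/0.2) = 0.7 is 0.2408 s -> first grid 0.3
  expect_equal(cal$x_star, 0.3)
  expect_equal(nrow(cal$table), 10L)
})

test_that("a floor that is never strictly exceeded raises a no-calibration error", {
  controls <- list(make_expiration_trace(trace_preset(fvc = 30, tau = 0.2)))
  ceiling_ratio <- compute_spirometry(controls[[1]], max(seq(0.1, 1, 0.1)))$ratio
  err <- tryCatch(calibrate_fev_x(controls, floor = ceiling_ratio),
                  error = function(e) e)
  expect_s3_class(err, "fl_no_calibration")
  expect_true(is.data.frame(err$table))
})

test_that("the median summary is driven by the middle control", {
  # three quick controls, two heavily obstructed
  mk <- function(fr, tau) make_expiration_trace(
    trace_preset(fvc = 30, fractions = fr, tau = tau))
  controls <- c(lapply(1:3, function(i) mk(1, 0.2)),
                lapply(1:2, function(i) mk(c(0.4, 0.6), c(0.1, 3))))
  cal <- calibrate_fev_x(controls, floor = 0.7, summary_fn = median)
  # median of the five = 3rd lowest = a healthy control; analytic crossing
  expect_equal(cal$x_star, 0.3)
  # with the all-controls rule the obstructed pair blocks calibration longer
  slow <- tryCatch(calibrate_fev_x(controls, floor = 0.7),
                   error = function(e) e)
  expect_true(inherits(slow, "fl_no_calibration") ||
                slow$x_star > cal$x_star)
})

test_that("calibration responds monotonically to the floor and to healthier controls", {
  controls <- lapply(1:5, function(i)
    make_expiration_trace(trace_preset(fvc = 30, tau = 0.15 + 0.02 * i)))
  xs <- vapply(c(0.8, 0.7, 0.6, 0.5), function(fl)
    calibrate_fev_x(controls, floor = fl)$x_star, numeric(1))
  expect_true(all(diff(xs) <= 0))  # lower floor never raises x*
  healthier <- c(controls,
                 list(make_expiration_trace(trace_preset(fvc = 30, tau = 0.1))))
  expect_lte(calibrate_fev_x(healthier, floor = 0.7)$x_star,
             calibrate_fev_x(controls, floor = 0.7)$x_star)
})

test_that("multistroke IC is a state function and the recruitment correction inverts", {
  # linear lung, C = 2 mL/cmH2O
  expect_equal(ic_multistroke(maneuver_segment(3, 15, 24),
                              maneuver_segment(15, 30, 30)), 54)
  # any monotone PV relation: segment volumes are state differences
  V <- function(p) 60 - 55 * exp(-0.1 * p)
  ic <- ic_multistroke(maneuver_segment(3, 15, V(15) - V(3)),
                       maneuver_segment(15, 30, V(30) - V(15)))
  expect_equal(ic, V(30) - V(3), tolerance = 1e-12)
  # generator applies (1 + delta) to the second stroke; correcting with the
  # same delta restores the single-stroke truth... on the summed volume
  delta <- 0.05
  v1 <- V(15) - V(3); v2 <- V(30) - V(15)
  inflated <- (v1 + v2) * (1 + delta)
  corrected <- ic_multistroke(maneuver_segment(3, 15, v1 * (1 + delta)),
                              maneuver_segment(15, 30, v2 * (1 + delta)),
                              delta = delta)
  expect_equal(corrected, V(30) - V(3), tolerance = 1e-12)
  expect_gt(inflated, V(30) - V(3))
  expect_error(ic_multistroke(maneuver_segment(3, 15, 24),
                              maneuver_segment(14, 30, 30)),
               class = "fl_input_error")
  expect_error(maneuver_segment(15, 3, 10), class = "fl_input_error")
  expect_error(maneuver_segment(3, 15, -1), class = "fl_input_error")
})

test_that("PV compliance fit recovers noise-free parameters exactly", {
  lp <- make_pv_loop(A = 60, B = 55, K = 0.1)
  fit <- fit_pv_compliance(lp, p_ref = 5)
  expect_lt(abs(fit$A - 60) / 60, 1e-6)
  expect_lt(abs(fit$B - 55) / 55, 1e-6)
  expect_lt(abs(fit$K - 0.1) / 0.1, 1e-6)
  expect_equal(fit$cst_ml_cmh2o, 55 * 0.1 * exp(-0.5), tolerance = 1e-6)
  expect_true(fit$accepted)
  expect_false(fit$fallback_linear)
})

test_that("compliance decreases with the reference pressure", {
  lp <- make_pv_loop(A = 60, B = 55, K = 0.12)
  cst <- vapply(c(3, 5, 8, 12), function(p)
    fit_pv_compliance(lp, p_ref = p)$cst_ml_cmh2o, numeric(1))
  expect_true(all(diff(cst) < 0))
  expect_true(all(cst > 0))
})

test_that("poor fits are flagged for exclusion by the R2 gate", {
  lp <- make_pv_loop(A = 60, B = 55, K = 0.1, noise_sd = 10, seed = 3L)
  fit <- fit_pv_compliance(lp)
  expect_lte(fit$r_squared, 0.9)
  expect_false(fit$accepted)
})

test_that("an exactly linear limb takes the fallback path with Cst = slope", {
  lin <- data.frame(pressure_cmh2o = seq(3, 30, 1),
                    volume_ml = 5 + 2 * seq(3, 30, 1), limb = "deflation")
  fit <- fit_pv_compliance(lin)
  expect_true(fit$fallback_linear)
  expect_equal(fit$cst_ml_cmh2o, 2, tolerance = 1e-9)
  expect_true(fit$accepted)
})

test_that("compliance fitting validates its input limb", {
  short <- data.frame(pressure_cmh2o = c(3, 10, 20),
                      volume_ml = c(10, 20, 30), limb = "deflation")
  expect_error(fit_pv_compliance(short), class = "fl_input_error")
  narrow <- data.frame(pressure_cmh2o = c(3, 5, 7, 9),
                       volume_ml = 1:4, limb = "deflation")
  expect_error(fit_pv_compliance(narrow), class = "fl_input_error")
  wobble <- data.frame(pressure_cmh2o = c(3, 10, 7, 20, 30),
                       volume_ml = 1:5, limb = "deflation")
  expect_error(fit_pv_compliance(wobble), class = "fl_input_error")
})
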