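#' Exhalation onset by back-extrapolation
#'
#' Standard spirometric back-extrapolation: a line is fitted to the flow
#' samples between 25% and 75% of peak flow on the rising limb and the
#' onset is its zero-crossing, clamped to the trace range. For traces
#' whose flow steps directly to its peak (no resolvable rising limb) the
#' onset is the first sample at or above 25% of peak.
#'
#' @param trace a `flow_volume_trace` data frame (columns `time_s`,
#'   `flow_ml_s`, `volume_ml`).
#' @return Onset time `t0` in seconds.
#' @export
detect_exhalation_start <- function(trace) {
  t <- trace$time_s; flow <- trace$flow_ml_s
  if (is.null(t) || is.null(flow))
    fl_input_error("trace needs columns time_s and flow_ml_s")
  peak <- max(flow)
  if (!is.finite(peak) || peak <= 0)
    fl_degenerate_error("no exhalation: no flow above the noise floor")
  ipk <- which.max(flow)
  rising <- which(seq_along(flow) < ipk & flow >= 0.25 * peak &
                    flow <= 0.75 * peak)
  t0 <- NA_real_
  if (length(rising) >= 2L) {
    fit <- lm(flow[rising] ~ t[rising])
    if (is.finite(coef(fit)[2]) && coef(fit)[2] > 0)
      t0 <- -coef(fit)[1] / coef(fit)[2]
  }
  if (!is.finite(t0)) t0 <- t[which(flow >= 0.25 * peak)[1]]
  min(max(t0, t[1]), t[length(t)])
}

interp_volume <- function(trace, at) {
  stats::approx(trace$time_s, trace$volume_ml, xout = at, rule = 2)$y
}

#' Spirometry indices from a forced-expiration trace
#'
#' FEV_x is the cumulative exhaled volume `x` seconds after the detected
#' onset (linear interpolation between samples); FVC is the cumulative
#' volume at the end of the trace. The end-of-test rule (flow below
#' `end_flow_frac` of peak, sustained for at least `end_sustain_s`)
#' decides whether exhalation was complete; if it never fires the result
#' carries `truncated = TRUE`.
#'
#' @param trace a `flow_volume_trace` data frame.
#' @param x_seconds timepoint(s) `x` for FEV_x (s, > 0); 0.4 s is the
#'   ferret analogue of the human FEV_1.
#' @param body_length_cm optional nose-to-rump length for size
#'   normalization (mL/cm variants).
#' @param end_flow_frac end-of-test flow criterion as a fraction of peak.
#' @param end_sustain_s how long the flow must stay below the criterion.
#' @return A list of class `spirometry_result`: `t0`, `x_seconds`,
#'   `fev_ml`, `fvc_ml`, `ratio`, `end_of_test_met`, `truncated`, plus
#'   `fev_per_cm` and `fvc_per_cm` when a length is supplied.
#' @export
compute_spirometry <- function(trace, x_seconds = 0.4,
                               body_length_cm = NULL,
                               end_flow_frac = 0.01, end_sustain_s = 0.05) {
  if (any(x_seconds <= 0)) fl_input_error("x_seconds must be > 0")
  t0 <- detect_exhalation_start(trace)
  v0 <- interp_volume(trace, t0)
  fev <- interp_volume(trace, t0 + x_seconds) - v0
  fvc <- trace$volume_ml[nrow(trace)] - v0
  if (fvc <= 0) fl_degenerate_error("FVC is zero; nothing was exhaled")
  flow <- trace$flow_ml_s
  peak <- max(flow)
  dt <- median(diff(trace$time_s))
  need <- max(1L, ceiling(end_sustain_s / dt))
  below <- flow < end_flow_frac * peak
  run <- rle(below)
  met <- any(run$values & run$lengths >= need)
  res <- list(t0 = t0, x_seconds = x_seconds, fev_ml = fev, fvc_ml = fvc,
              ratio = fev / fvc, end_of_test_met = met, truncated = !met)
  if (!is.null(body_length_cm)) {
    res$fev_per_cm <- normalize_by_length(fev, body_length_cm)
    res$fvc_per_cm <- normalize_by_length(fvc, body_length_cm)
    res$body_length_cm <- body_length_cm
  }
  structure(res, class = "spirometry_result")
}

#' @export
print.spirometry_result <- function(x, ...) {
  cat(sprintf("<spirometry> t0=%.3f s  FEV_%.1f=%.2f mL  FVC=%.2f mL  ratio=%.3f%s\n",
              x$t0, x$x_seconds[1], x$fev_ml[1], x$fvc_ml,
              x$ratio[1], if (x$truncated) "  [truncated]" else ""))
  invisible(x)
}

#' Calibrate the FEV timepoint against control animals
#'
#' Finds the smallest `x` on the grid at which the chosen summary of the
#' control FEV_x:FVC ratios stays strictly above the obstruction floor
#' (0.7, the human COPD criterion). With the default summary (`min`) every
#' control must clear the floor, mirroring the calibration that selected
#' 0.4 s for ferrets.
#'
#' @param control_traces list of `flow_volume_trace` data frames from
#'   control animals.
#' @param floor obstruction floor the ratio must exceed (strict).
#' @param grid candidate `x` values in seconds, sorted ascending.
#' @param summary_fn summary applied across control ratios at each `x`
#'   (default [min]; use [median] to require only half the controls).
#' @return A list of class `fev_calibration`: `x_star`, `floor`, `grid`,
#'   and `table` (one row per grid `x`: per-control ratios and their
#'   summary). If no grid point satisfies the criterion an error of class
#'   `fl_no_calibration` is raised carrying the table in its `table`
#'   field.
#' @export
calibrate_fev_x <- function(control_traces, floor = 0.7,
                            grid = seq(0.1, 1.0, by = 0.1),
                            summary_fn = min) {
  if (!length(control_traces)) fl_input_error("no control traces supplied")
  if (!length(grid)) fl_input_error("empty calibration grid")
  grid <- sort(grid)
  ratios <- vapply(control_traces, function(tr) {
    vapply(grid, function(x) compute_spirometry(tr, x)$ratio, numeric(1))
  }, numeric(length(grid)))
  ratios <- matrix(ratios, nrow = length(grid))
  summ <- apply(ratios, 1, summary_fn)
  tab <- data.frame(x_seconds = grid, ratios,
                    summary = summ, check.names = FALSE)
  names(tab)[1 + seq_len(ncol(ratios))] <-
    sprintf("control_%d", seq_len(ncol(ratios)))
  ok <- which(summ > floor)
  if (!length(ok))
    stop(structure(class = c("fl_no_calibration", "fl_degenerate_error",
                             "ferretlung_error", "error", "condition"),
                   list(message = sprintf(
                     "no grid x keeps the control ratio summary above %g",
                     floor), call = sys.call(), table = tab)))
  structure(list(x_star = grid[ok[1]], floor = floor, grid = grid,
                 table = tab), class = "fev_calibration")
}

#' Pressure-controlled maneuver segment
#'
#' One piston stroke delivering `volume_ml` between two airway pressures.
#'
#' @param start_pressure,end_pressure cmH2O, `end > start`.
#' @param volume_ml delivered volume (mL, > 0).
#' @return An object of class `maneuver_segment`.
#' @export
maneuver_segment <- function(start_pressure, end_pressure, volume_ml) {
  if (end_pressure <= start_pressure)
    fl_input_error("end pressure must exceed start pressure")
  if (volume_ml <= 0) fl_input_error("segment volume must be > 0")
  structure(list(start = start_pressure, end = end_pressure,
                 volume = volume_ml), class = "maneuver_segment")
}

#' Multistroke inspiratory capacity
#'
#' When a single piston stroke cannot reach the 30 cmH2O opening
#' pressure, two abutting strokes (PEEP 3 to 15 cmH2O, then 15 to 30
#' cmH2O) are delivered and their volumes summed. Because delivered
#' volume is a state-function difference, the sum equals a single-stroke
#' IC for any monotone pressure-volume relationship; in vivo the second
#' stroke recruits extra volume, which the optional correction `delta`
#' divides back out (`IC = (v1 + v2) / (1 + delta)`).
#'
#' @param seg1,seg2 [maneuver_segment()]s whose pressure ranges abut.
#' @param delta multistroke recruitment correction (0 = raw sum; 0.05
#'   matches the empirically observed 5% overestimate).
#' @return IC in mL.
#' @export
ic_multistroke <- function(seg1, seg2, delta = 0) {
  if (!inherits(seg1, "maneuver_segment") ||
      !inherits(seg2, "maneuver_segment"))
    fl_input_error("ic_multistroke() expects two maneuver_segments")
  if (abs(seg1$end - seg2$start) > 1e-9)
    fl_input_error("segments do not abut: first ends at %g, second starts at %g",
                   seg1$end, seg2$start)
  if (delta <= -1) fl_input_error("delta must be > -1")
  (seg1$volume + seg2$volume) / (1 + delta)
}

#' Quasistatic compliance from a PV-loop deflation limb
#'
#' Fits the single-exponential pressure-volume relation
#' `V(P) = A - B * exp(-K * P)` to the deflation limb by nonlinear least
#' squares and reports the quasistatic compliance as its derivative at a
#' reference pressure, `Cst = B * K * exp(-K * P_ref)`. Fits with a
#' coefficient of determination at or below 0.9 are flagged
#' `accepted = FALSE` and should be excluded from averages. If the
#' exponential degenerates (K collapsing toward 0, i.e. an effectively
#' linear limb) a straight-line fit is used instead and `Cst` is its
#' slope, flagged `fallback_linear`.
#'
#' @param loop a `pv_loop` data frame (columns `pressure_cmh2o`,
#'   `volume_ml`, `limb`) or any data frame with those columns; rows with
#'   `limb == "deflation"` are used (all rows if there is no limb
#'   column).
#' @param p_ref reference pressure for the compliance derivative (cmH2O).
#' @return A list of class `compliance_fit`: `A`, `B`, `K`, `cst_ml_cmh2o`,
#'   `p_ref`, `r_squared`, `accepted`, `fallback_linear`.
#' @export
fit_pv_compliance <- function(loop, p_ref = 5) {
  df <- as.data.frame(loop)
  if (!is.null(df$limb)) df <- df[df$limb == "deflation", , drop = FALSE]
  p <- df$pressure_cmh2o; v <- df$volume_ml
  if (is.null(p) || is.null(v))
    fl_input_error("loop needs columns pressure_cmh2o and volume_ml")
  if (length(p) < 4L)
    fl_input_error("deflation limb has fewer than 4 points")
  if (diff(range(p)) < 10)
    fl_input_error("deflation limb spans less than 10 cmH2O")
  dp <- diff(p)
  if (!(all(dp > 0) || all(dp < 0)))
    fl_input_error("deflation limb pressures are not monotone")
  o <- order(p); p <- p[o]; v <- v[o]

  linear_fit <- function() {
    lf <- lm(v ~ p)
    r2 <- suppressWarnings(summary(lf)$r.squared)
    list(A = NA_real_, B = NA_real_, K = 0,
         cst_ml_cmh2o = unname(coef(lf)[2]), p_ref = p_ref,
         r_squared = r2, accepted = r2 > 0.9, fallback_linear = TRUE)
  }

  # an (essentially) exactly linear limb is the K -> 0 degeneracy: take
  # the straight-line path directly rather than chasing a collapsing K
  if (suppressWarnings(summary(lm(v ~ p))$r.squared) > 1 - 1e-8)
    return(structure(linear_fit(), class = "compliance_fit"))

  # starts from the log-linearized model, guarding the A guess above max(v)
  a0 <- max(v) + 0.05 * max(diff(range(v)), 1)
  ylog <- log(pmax(a0 - v, 1e-8))
  lin <- lm(ylog ~ p)
  k0 <- max(-unname(coef(lin)[2]), 1e-3)
  b0 <- exp(unname(coef(lin)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A - B * exp(-K * p),
      start = list(A = a0, B = b0, K = k0),
      lower = c(A = -Inf, B = 0, K = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(structure(linear_fit(), class = "compliance_fit"))
  cf <- coef(fit)
  if (!is.finite(cf["K"]) || cf["K"] < 1e-4)
    return(structure(linear_fit(), class = "compliance_fit"))
  resid <- v - predict(fit)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(resid^2) / ss_tot
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 K = unname(cf["K"]),
                 cst_ml_cmh2o = unname(cf["B"] * cf["K"] *
                                         exp(-cf["K"] * p_ref)),
                 p_ref = p_ref, r_squared = r2, accepted = r2 > 0.9,
                 fallback_linear = FALSE),
            class = "compliance_fit")
}

#' @export
print.compliance_fit <- function(x, ...) {
  cat(sprintf("<compliance_fit> Cst(%g)=%.3f mL/cmH2O  R2=%.4f  %s%s\n",
              x$p_ref, x$cst_ml_cmh2o, x$r_squared,
              if (x$accepted) "accepted" else "rejected (R2 <= 0.9)",
              if (x$fallback_linear) "  [linear fallback]" else ""))
  invisible(x)
}

#' Normalize a volume by body length
#'
#' @param value volume or capacity (mL).
#' @param length_cm nose-to-rump body length (cm, > 0).
#' @return `value / length_cm` (mL/cm).
#' @export
normalize_by_length <- function(value, length_cm) {
  if (!is.finite(length_cm) || length_cm <= 0)
    fl_input_error("body length must be > 0")
  value / length_cm
}
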