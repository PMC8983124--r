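#' Preset for an analytic forced-expiration trace
#'
#' The exhaled-volume truth is a mono- or multi-exponential emptying
#' curve: `V(t) = FVC * sum_i a_i * (1 - exp(-(t - t_onset)/tau_i))` for
#' `t >= t_onset` and 0 before. Flow is its finite-difference derivative
#' plus optional Gaussian noise; the volume channel is always the
#' noiseless truth (cumulative integral of the noiseless flow), so the
#' analytic FEV_x values attached to the trace are exact.
#'
#' @param fvc forced vital capacity (mL, > 0).
#' @param fractions compartment fractions `a_i`, must sum to 1.
#' @param tau time constants `tau_i` in seconds (> 0), same length as
#'   `fractions`.
#' @param t_onset exhalation onset time (s).
#' @param dt sampling interval (s, > 0); 1 ms default.
#' @param duration trace length (s); default runs to `t_onset + 8 *
#'   max(tau)`, by which point the slowest compartment has emptied to
#'   within 0.04% of FVC.
#' @param noise_sd flow noise SD (mL/s).
#' @param recruitment_delta multistroke recruitment offset `delta`; the
#'   second-stroke delivered volume simulated from this preset is inflated
#'   by `(1 + delta)`.
#' @param seed RNG seed for the flow noise.
#' @return An object of class `trace_preset`.
#' @export
trace_preset <- function(fvc = 30, fractions = 1, tau = 0.2, t_onset = 0,
                         dt = 0.001, duration = NULL, noise_sd = 0,
                         recruitment_delta = 0, seed = 1L) {
  if (!is.finite(fvc) || fvc <= 0) fl_input_error("FVC must be > 0")
  if (length(fractions) != length(tau))
    fl_input_error("fractions and tau must have the same length")
  if (abs(sum(fractions) - 1) > 1e-8)
    fl_input_error("compartment fractions must sum to 1 (got %g)",
                   sum(fractions))
  if (any(tau <= 0)) fl_input_error("all time constants must be > 0")
  if (dt <= 0) fl_input_error("sampling interval dt must be > 0")
  if (noise_sd < 0) fl_input_error("noise SD must be >= 0")
  duration <- duration %||% (t_onset + 8 * max(tau))
  structure(list(fvc = fvc, fractions = fractions, tau = tau,
                 t_onset = t_onset, dt = dt, duration = duration,
                 noise_sd = noise_sd, recruitment_delta = recruitment_delta,
                 seed = as.integer(seed)),
            class = "trace_preset")
}

# analytic exhaled volume of a preset at time t (vectorized)
preset_volume_at <- function(preset, t) {
  tt <- pmax(t - preset$t_onset, 0)
  v <- rep(0, length(tt))
  for (i in seq_along(preset$tau))
    v <- v + preset$fractions[i] * (1 - exp(-tt / preset$tau[i]))
  preset$fvc * v
}

#' Simulate a forced-expiration flow/volume trace
#'
#' @param preset a [trace_preset()].
#' @return A data frame of class `flow_volume_trace` with columns
#'   `time_s`, `flow_ml_s`, `volume_ml`, uniform sampling, and attributes
#'   `truth` (list with `fvc`, `t_onset`, and `fev(x)` closure giving the
#'   analytic FEV_x) and `preset`.
#' @export
make_expiration_trace <- function(preset) {
  if (!inherits(preset, "trace_preset"))
    fl_input_error("make_expiration_trace() expects a trace_preset")
  t <- seq(0, preset$duration, by = preset$dt)
  vol <- preset_volume_at(preset, t)
  # forward difference so the onset step lands on the onset sample itself
  flow <- c(diff(vol) / preset$dt, 0)
  if (preset$noise_sd > 0)
    flow <- withr::with_seed(preset$seed,
                             flow + rnorm(length(flow), 0, preset$noise_sd))
  out <- data.frame(time_s = t, flow_ml_s = flow, volume_ml = vol)
  truth <- list(
    fvc = preset$fvc, t_onset = preset$t_onset,
    fev = function(x) preset_volume_at(preset, preset$t_onset + x)
  )
  structure(out, class = c("flow_volume_trace", "data.frame"),
            truth = truth, preset = preset)
}

#' Simulate a quasistatic pressure-volume loop
#'
#' Both limbs follow the single-exponential (Salazar-Knowles) relation
#' `V(P) = A - B * exp(-K * P)` sampled over `P` in `[3, 30]` cmH2O
#' (pressure-controlled inflation from PEEP to the opening pressure used
#' during maneuvers). The deflation limb is offset upward by `hysteresis`
#' mL at every shared pressure.
#'
#' @param A,B,K model parameters: `A` (mL) asymptotic volume, `B` (mL)
#'   recruitable volume, `K` (1/cmH2O) shape. Requires
#'   `A - B * exp(-K * P_min) >= 0` and `K >= 0`.
#' @param noise_sd volume noise SD (mL).
#' @param hysteresis deflation-limb volume offset (mL).
#' @param pressures pressure sample points for one limb (cmH2O,
#'   increasing).
#' @param seed RNG seed.
#' @return A data frame of class `pv_loop` with columns
#'   `pressure_cmh2o`, `volume_ml`, `limb` (`"inflation"`/`"deflation"`)
#'   and a `truth` attribute carrying `A`, `B`, `K`, `hysteresis`.
#' @export
make_pv_loop <- function(A = 60, B = 55, K = 0.1, noise_sd = 0,
                         hysteresis = 0, pressures = seq(3, 30, by = 1),
                         seed = 1L) {
  if (K < 0) fl_input_error("K must be >= 0")
  if (noise_sd < 0) fl_input_error("noise SD must be >= 0")
  pmin_ <- min(pressures)
  if (A - B * exp(-K * pmin_) < 0)
    fl_input_error("invalid parameters: V(P_min) = %g is negative",
                   A - B * exp(-K * pmin_))
  v <- A - B * exp(-K * pressures)
  out <- data.frame(
    pressure_cmh2o = c(pressures, rev(pressures)),
    volume_ml = c(v, rev(v) + hysteresis),
    limb = rep(c("inflation", "deflation"), each = length(pressures)))
  if (noise_sd > 0)
    out$volume_ml <- withr::with_seed(
      seed, out$volume_ml + rnorm(nrow(out), 0, noise_sd))
  structure(out, class = c("pv_loop", "data.frame"),
            truth = list(A = A, B = B, K = K, hysteresis = hysteresis))
}
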