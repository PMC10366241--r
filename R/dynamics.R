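#' Simulation configuration
#'
#' Bundles membrane, damage and stimulus parameters with the integration
#' controls.  The step size is capped at 1e-4 s as a stability guard: the
#' healthy membrane time constant is 2 ms and explicit Euler needs
#' `dt` well below it, especially near the quadratic spike upstroke.
#'
#' @param mp A [membrane_parameters()] object.
#' @param dp A [damage_parameters()] object.
#' @param stim A [stimulus_spec()] object.
#' @param duration Total simulated time (s), positive; must be an integer
#'   multiple of `dt` after rounding.
#' @param dt Integration step (s), in `(0, 1e-4]`.  Default 1e-5 s.
#' @param seed Integer seed for the synaptic noise.
#' @param record_trace Keep the full membrane-potential trace?  Sweeps turn
#'   this off to save memory; the time grid and stimulus series are always
#'   kept.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(mp, dp, stim, duration, dt = 1e-5, seed = 1L,
                              record_trace = TRUE) {
  stopifnot(inherits(mp, "membrane_parameters"),
            inherits(dp, "damage_parameters"),
            inherits(stim, "stimulus_spec"))
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (dt > 1e-4)
    stop_with("ephapsim_domain_error",
              "dt = %g s exceeds the 1e-4 s stability guard", dt)
  n <- round(duration / dt)
  if (abs(duration / dt - n) > 1e-6)
    stop_with("ephapsim_domain_error",
              "duration (%g s) must be an integer multiple of dt (%g s)",
              duration, dt)
  check_scalar(seed, "seed")
  structure(list(mp = mp, dp = dp, stim = stim, duration = duration,
                 dt = dt, seed = as.integer(seed),
                 record_trace = isTRUE(record_trace), n_steps = n),
            class = "simulation_config")
}

#' Time derivative of the damaged ephaptic QIF membrane potential
#'
#' The right-hand side of the damaged model,
#' \deqn{dV/dt = \frac{(V - V_{rest})(V - V_{thresh})}{R_{dfl} C_{dfl}
#'   (V_{thresh} - V_{rest})} - \frac{\rho_{ext} I_{eph}}{4\pi R_{dfl}
#'   C_{dfl} r} + \frac{I_{syn}}{C_{dfl}},}
#' where `R_dfl = R_m/(1-b)` and `C_dfl = C_m (1-h)`.  With `b = h = 0` this
#' is the healthy ephaptic quadratic integrate-and-fire equation; the damaged
#' form is the same equation with the substituted effective resistance and
#' capacitance, equivalently a rescaling of the quadratic and ephaptic terms
#' by `(1-b)/(1-h)` and of the synaptic term by `1/(1-h)`.
#'
#' @param V Membrane potential (V), scalar or vector.
#' @param I_eph Ephaptic current (A).
#' @param I_syn Synaptic current density (A/m^2).
#' @param mp A [membrane_parameters()] object.
#' @param dp A [damage_parameters()] object.
#' @return Rate of change of the membrane potential (V/s).
#' @examples
#' qif_derivative(-60e-3, 0, 0, membrane_parameters(), damage_parameters())
#' @export
qif_derivative <- function(V, I_eph = 0, I_syn = 0, mp, dp = damage_parameters()) {
  stopifnot(inherits(mp, "membrane_parameters"),
            inherits(dp, "damage_parameters"))
  r_dfl <- dysfunctional_resistance(mp$R_m, dp$b)
  c_dfl <- dysfunctional_capacitance(mp$C_m, dp$h)
  tau <- r_dfl * c_dfl
  (V - mp$V_rest) * (V - mp$V_thresh) / (tau * (mp$V_thresh - mp$V_rest)) -
    mp$rho_ext * I_eph / (4 * pi * tau * mp$r_dist) +
    I_syn / c_dfl
}

#' Integrate the damaged ephaptic QIF model
#'
#' Forward-Euler trajectory from `V_m(0) = V_rest` with hard spike reset:
#' whenever a step carries the potential to `V_peak` or beyond, a spike is
#' recorded at that step's time and the potential is set to `c_reset` before
#' the next step.  The synaptic noise stream is a deterministic function of
#' the config seed, so identical configurations reproduce bitwise-identical
#' results.  If the quadratic term blows past `V_peak` by more than 100 mV
#' in a single step the integration aborts with a stability error naming
#' `dt`.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `simulation_result` with elements `t` (time
#'   grid from 0 to `duration`), `V_m` (potential trace, `NULL` when
#'   `record_trace = FALSE`), `I_eph` (stimulus series on `t`), `spikes`
#'   (a `spike_train`), and `config`.
#' @examples
#' cfg <- simulation_config(membrane_parameters(), damage_parameters(),
#'                          stimulus_spec(f_stim = 5, sigma_noise = 0),
#'                          duration = 1, dt = 1e-4)
#' sim <- simulate_qif(cfg)
#' sim$spikes$n
#' @export
simulate_qif <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  mp <- cfg$mp
  n <- cfg$n_steps
  t <- (0:n) * cfg$dt
  i_eph <- ephaptic_current(t, cfg$stim)
  i_syn <- synaptic_drive(t, cfg$stim, cfg$seed)
  core <- qif_euler_core(mp$V_rest, cfg$dt,
                         i_eph[1:n], i_syn[1:n],
                         mp$V_rest, mp$V_thresh, mp$V_peak, mp$c_reset,
                         dysfunctional_resistance(mp$R_m, cfg$dp$b),
                         dysfunctional_capacitance(mp$C_m, cfg$dp$h),
                         mp$rho_ext, mp$r_dist,
                         cfg$record_trace)
  spikes <- spike_train(core$spike_steps * cfg$dt)
  V_m <- if (cfg$record_trace) c(mp$V_rest, core$V_m) else NULL
  structure(list(t = t, V_m = V_m, I_eph = i_eph, spikes = spikes,
                 config = cfg),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("QIF-E simulation: %g s at dt = %g s, b = %g, h = %g\n",
              cfg$duration, cfg$dt, cfg$dp$b, cfg$dp$h))
  cat(sprintf("  stimulus %g Hz, %d spikes (%.2f /s)\n",
              cfg$stim$f_stim, x$spikes$n, x$spikes$n / cfg$duration))
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  if (is.null(x$V_m))
    stop_with("ephapsim_domain_error",
              "trace was not recorded (record_trace = FALSE)")
  data.frame(t = x$t, V_m = x$V_m, I_eph = x$I_eph)
}

#' Spike train
#'
#' Sorted, de-duplicated spike times with a count.
#'
#' @param times Numeric vector of spike times (s).
#' @return An object of class `spike_train` with elements `times` and `n`.
#' @export
spike_train <- function(times = numeric()) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  times <- sort(unique(as.numeric(times)))
  structure(list(times = times, n = length(times)), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes", x$n))
  if (x$n > 0) cat(sprintf(" in [%.4g, %.4g] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Analytic interspike interval of the unforced model
#'
#' Independent oracle for the noise-free, stimulus-free damaged model: when
#' the tonic drive exceeds rheobase the quadratic has no real roots and the
#' neuron fires periodically with interval
#' \deqn{ISI = \int_{c_{reset}}^{V_{peak}} dV / F(V),}
#' evaluated here by adaptive numeric quadrature of the reciprocal
#' derivative.  This is exact up to quadrature tolerance and independent of
#' the Euler integrator, which must converge to it at rate O(dt).
#'
#' @param mp A [membrane_parameters()] object.
#' @param dp A [damage_parameters()] object.
#' @param I_0 Tonic synaptic current density (A/m^2), above rheobase.
#' @return The interspike interval (s).
#' @examples
#' analytic_isi(membrane_parameters(), damage_parameters(), I_0 = 0.026)
#' @export
analytic_isi <- function(mp, dp = damage_parameters(), I_0) {
  stopifnot(inherits(mp, "membrane_parameters"),
            inherits(dp, "damage_parameters"))
  check_scalar(I_0, "I_0")
  if (I_0 <= rheobase_current(mp, dp))
    stop_with("ephapsim_no_firing",
              "I_0 = %g A/m^2 is at or below rheobase (%g A/m^2): the model does not fire",
              I_0, rheobase_current(mp, dp))
  f <- function(v) 1 / qif_derivative(v, I_eph = 0, I_syn = I_0, mp = mp, dp = dp)
  stats::integrate(f, lower = mp$c_reset, upper = mp$V_peak,
                   rel.tol = 1e-10, subdivisions = 1000L)$value
}

#' Write spike times to a plain-text file
#'
#' One spike time in seconds per line; the format read back by
#' [read_spike_times()], so externally recorded spike/field pairs can be fed
#' to the analysis layer.
#'
#' @param spikes A `spike_train` or numeric vector of times (s).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_times <- function(spikes, path) {
  if (inherits(spikes, "spike_train")) spikes <- spikes$times
  stopifnot(is.numeric(spikes))
  writeLines(format(spikes, digits = 17, scientific = TRUE, trim = TRUE), path)
  invisible(path)
}

#' Read spike times from a plain-text file
#'
#' @param path File with one spike time (seconds) per line.
#' @return A [spike_train()].
#' @export
read_spike_times <- function(path) {
  x <- scan(path, what = double(), quiet = TRUE)
  spike_train(x)
}
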