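#' Stimulus specification
#'
#' Describes the forcing applied to the neuron: a sinusoidal ephaptic current
#' (the local-field-potential surrogate, injected through the point-source
#' extracellular potential) plus a tonic, optionally noisy, synaptic current
#' density.
#'
#' Default amplitudes are the package's calibrated baseline (see
#' [calibrate_baseline()]): `I_0` sits 0.5% above the healthy rheobase of
#' 0.025 A/m^2, giving tonic firing at 5.7 spikes/s, and `A_eph` produces a
#' peak extracellular potential of about 0.1 mV at the default electrode
#' geometry.  Entrainment is selective only when the field modulation is
#' comparable to the suprathreshold drive margin; fields of a millivolt or
#' more overdrive a neuron this close to rheobase, making it burst within
#' slow stimulus cycles and phase-lock far above its tonic rate.
#' `sigma_noise` is a white-noise intensity: the per-step standard deviation
#' of the synaptic drive is `sigma_noise / sqrt(dt)`, so the variance
#' injected per unit time does not depend on the integration step.  The
#' default is perturbative — it shifts the tonic rate by under 5% while
#' breaking the fragile high-order subharmonic locking that would otherwise
#' flatten the frequency preference, and it is the source of the
#' trial-to-trial spread behind sweep error bars.
#'
#' @param f_stim Stimulus frequency (Hz), non-negative.
#' @param A_eph Ephaptic current amplitude (A), non-negative.
#' @param I_0 Tonic synaptic current density (A/m^2).
#' @param sigma_noise Synaptic noise intensity (A s^(1/2) / m^2),
#'   non-negative.
#' @param phase0 Initial phase of the sinusoid (rad).
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(f_stim = 5)
#' @export
stimulus_spec <- function(f_stim = 5, A_eph = 1.795e-8, I_0 = 0.025125,
                          sigma_noise = 2e-5, phase0 = 0) {
  check_scalar(f_stim, "f_stim", nonneg = TRUE)
  check_scalar(A_eph, "A_eph", nonneg = TRUE)
  check_scalar(I_0, "I_0")
  check_scalar(sigma_noise, "sigma_noise", nonneg = TRUE)
  check_scalar(phase0, "phase0")
  structure(list(f_stim = f_stim, A_eph = A_eph, I_0 = I_0,
                 sigma_noise = sigma_noise, phase0 = phase0),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Stimulus: %g Hz sine, A_eph = %g A, I_0 = %g A/m^2, sigma = %g, phase0 = %g rad\n",
              x$f_stim, x$A_eph, x$I_0, x$sigma_noise, x$phase0))
  invisible(x)
}

#' Sinusoidal ephaptic current
#'
#' `A_eph * sin(2 * pi * f_stim * t + phase0)` sampled on the given time
#' grid.  Returns an exactly zero series when the amplitude or the frequency
#' is zero (a zero-frequency "sine" carries no field oscillation to entrain
#' to).
#'
#' @param t Time grid (s), uniformly sampled.
#' @param spec A [stimulus_spec()].
#' @return Current series (A), same length as `t`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' i <- ephaptic_current(t, stimulus_spec(f_stim = 5, A_eph = 1e-7))
#' @export
ephaptic_current <- function(t, spec) {
  stopifnot(inherits(spec, "stimulus_spec"), is.numeric(t))
  if (spec$A_eph == 0 || spec$f_stim == 0) return(numeric(length(t)))
  spec$A_eph * sin(2 * pi * spec$f_stim * t + spec$phase0)
}

#' Point-source extracellular potential
#'
#' Potential generated at distance `r_dist` by a current point source in a
#' homogeneous resistive medium: `rho_ext * I / (4 * pi * r_dist)`.  Linear
#' in the current, so superposition holds.
#'
#' @param I Current (A), scalar or series.
#' @param mp A [membrane_parameters()] object (supplies `rho_ext`, `r_dist`).
#' @return Potential (V), same shape as `I`.
#' @examples
#' extracellular_potential(1.795e-7, membrane_parameters())  # ~1 mV
#' @export
extracellular_potential <- function(I, mp) {
  stopifnot(inherits(mp, "membrane_parameters"), is.numeric(I))
  mp$rho_ext * I / (4 * pi * mp$r_dist)
}

#' Tonic synaptic drive with white noise
#'
#' Synaptic current-density series `I_0 + xi(t)` where `xi` is white
#' Gaussian noise with per-step standard deviation `sigma_noise / sqrt(dt)`
#' (Euler-Maruyama convention: the noise variance delivered per unit time is
#' independent of the step size).  The series is a deterministic function of
#' the seed; the caller's RNG state is left untouched.
#'
#' @param t Uniform time grid (s), length at least 2.
#' @param spec A [stimulus_spec()].
#' @param seed Integer seed.
#' @return Current-density series (A/m^2), same length as `t`.
#' @examples
#' t <- seq(0, 0.1, by = 1e-4)
#' drv <- synaptic_drive(t, stimulus_spec(sigma_noise = 1e-4), seed = 1)
#' @export
synaptic_drive <- function(t, spec, seed) {
  stopifnot(inherits(spec, "stimulus_spec"), is.numeric(t), length(t) >= 2)
  dt <- t[2] - t[1]
  if (dt <= 0 || any(abs(diff(t) - dt) > 1e-9 * dt))
    stop_with("ephapsim_domain_error", "time grid must be uniform")
  if (spec$sigma_noise == 0) return(rep(spec$I_0, length(t)))
  noise <- with_seed(seed, rnorm(length(t), sd = spec$sigma_noise / sqrt(dt)))
  spec$I_0 + noise
}

#' Export a stimulus or drive trace as two-column CSV
#'
#' Writes `time_s, value` rows for any series sampled on a time grid, e.g.
#' the output of [ephaptic_current()] or [synaptic_drive()].
#'
#' @param t Time grid (s).
#' @param value Series on `t`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(t, value, path) {
  stopifnot(is.numeric(t), is.numeric(value), length(t) == length(value))
  utils::write.csv(data.frame(time_s = t, value = value), path,
                   row.names = FALSE)
  invisible(path)
}
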