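# Synthetic phase-locked spike trains for exercising the analysis layer
# without running the neuron model.

#' Synthetic spike train phase-locked to a sinusoid
#'
#' Generates one spike per stimulus cycle at a fixed phase of the cycle,
#' optionally jittered by von Mises-distributed phase noise.  `kappa = Inf`
#' gives perfect locking (spike-field coherence exactly 1 up to rounding);
#' decreasing `kappa` broadens the phase distribution, and `kappa = 0` is
#' uniform phase (coherence near 0 for long trains).  Useful as a controlled
#' fixture for the spike-triggered-average / coherence pipeline.
#'
#' @param f_stim Stimulus frequency (Hz), positive.
#' @param n_spikes Number of cycles / spikes, at least 1.
#' @param phase Preferred phase in radians (0 is the rising zero crossing of
#'   `sin`).
#' @param kappa von Mises concentration; `Inf` for exact locking, 0 for
#'   uniform phases.
#' @param seed Integer seed (required when `kappa < Inf`).
#' @param t_start Time of the start of the first cycle (s).
#' @return A [spike_train()] with `n_spikes` spikes (duplicates after
#'   jitter, if any, are collapsed).
#' @examples
#' locked_spike_train(5, 40)                      # perfect lock
#' locked_spike_train(5, 40, kappa = 4, seed = 1) # jittered
#' @export
locked_spike_train <- function(f_stim, n_spikes, phase = pi / 2,
                               kappa = Inf, seed = NULL, t_start = 0) {
  check_scalar(f_stim, "f_stim", positive = TRUE)
  check_scalar(n_spikes, "n_spikes", positive = TRUE)
  if (is.finite(kappa)) {
    if (is.null(seed))
      stop_with("ephapsim_domain_error", "jittered trains need a seed")
    jit <- with_seed(seed, rvonmises(n_spikes, mu = 0, kappa = kappa))
  } else {
    jit <- numeric(n_spikes)
  }
  ph <- (phase + jit) %% (2 * pi)
  times <- t_start + (seq_len(n_spikes) - 1 + ph / (2 * pi)) / f_stim
  spike_train(times)
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy envelope rejection.
rvonmises <- function(n, mu = 0, kappa) {
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return((runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3] - 0.5) * acos(max(-1, min(1, f)))
    }
  }
  out
}
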