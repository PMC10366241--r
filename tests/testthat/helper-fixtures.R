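# Shared fixtures: default membrane, a fast deterministic drive, and a
# reduced sweep protocol used by the slower experiment-layer tests.

mp_default <- membrane_parameters()
dp_healthy <- damage_parameters()

# noise- and field-free tonic drive, comfortably suprathreshold
stim_tonic <- function(I_0 = 0.026) {
  stimulus_spec(f_stim = 0, A_eph = 0, I_0 = I_0, sigma_noise = 0)
}

# coarse sweep used where an SFC curve is needed quickly
fast_sweep <- function(f_grid = seq(3, 21, by = 3), repeats = 1,
                       duration = 3, dt = 5e-5, seed0 = 7,
                       stim = stimulus_spec()) {
  sweep_config(mp = mp_default, stim = stim, f_grid = f_grid,
               repeats = repeats, duration = duration, warmup = 0.5,
               dt = dt, seed0 = seed0)
}

# sinusoid sampled like a stimulus record, for analysis-layer tests
sine_record <- function(f = 5, dur = 10, dt = 1e-3, A = 1, phase0 = 0) {
  t <- seq(0, dur, by = dt)
  list(t = t, stim = A * sin(2 * pi * f * t + phase0), f = f, dt = dt)
}

# independent SFC oracle: direct sine/cosine projection of each segment onto
# its fundamental, never touching fft()
sfc_oracle <- function(segments) {
  L <- ncol(segments)
  ang <- 2 * pi * (0:(L - 1)) / L
  zr <- numeric(nrow(segments))
  zi <- numeric(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    zr[i] <- sum(segments[i, ] * cos(ang))
    zi[i] <- -sum(segments[i, ] * sin(ang))
  }
  (mean(zr)^2 + mean(zi)^2) / mean(zr^2 + zi^2)
}
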