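#' Spike-triggered average of the stimulus
#'
#' For every spike, extracts the stimulus segment of duration `1 / f_stim`
#' (one stimulus period) centred on the spike time and averages the segments
#' element-wise.  The one-period window puts the stimulus frequency exactly
#' on the first non-zero frequency bin of the segment periodogram, which is
#' what makes the spike-field-coherence ratio a single well-defined number
#' per stimulus frequency.  Spikes whose window would leave the recorded
#' interval are dropped (padding would bias the power spectrum) and counted
#' in `n_dropped`.
#'
#' @param t Uniform time grid of the stimulus record (s).
#' @param stim Stimulus series on `t`.
#' @param spikes A `spike_train` or numeric vector of spike times (s).
#' @param f_stim Stimulus frequency (Hz), positive.
#' @return An object of class `sta_result`: `window` (time offsets, s),
#'   `sta` (averaged segment), `segments` (matrix, one row per used spike),
#'   `n_used`, `n_dropped`, `f_stim`, `dt`.
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' stim <- sin(2 * pi * 5 * t)
#' sta <- spike_triggered_average(t, stim, spike_train(1:40 / 5), 5)
#' sta$n_used
#' @export
spike_triggered_average <- function(t, stim, spikes, f_stim) {
  if (inherits(spikes, "spike_train")) spikes <- spikes$times
  stopifnot(is.numeric(t), is.numeric(stim), length(t) == length(stim),
            is.numeric(spikes))
  check_scalar(f_stim, "f_stim")
  if (f_stim <= 0)
    stop_with("ephapsim_domain_error",
              "f_stim must be > 0 (the STA window is one stimulus period)")
  dt <- t[2] - t[1]
  len <- max(2L, as.integer(round(1 / (f_stim * dt))))
  half <- len %/% 2L
  idx <- round((spikes - t[1]) / dt) + 1L
  starts <- idx - half
  ok <- starts >= 1L & (starts + len - 1L) <= length(stim)
  n_used <- sum(ok)
  if (n_used == 0L)
    stop_with("ephapsim_insufficient_spikes",
              "no spike has a full %g-s STA window inside the record (%d spikes dropped)",
              len * dt, length(spikes))
  segs <- matrix(stim[outer(starts[ok], 0:(len - 1L), "+")],
                 nrow = n_used, ncol = len)
  structure(list(window = (0:(len - 1L) - half) * dt,
                 sta = colMeans(segs),
                 segments = segs,
                 n_used = n_used,
                 n_dropped = length(spikes) - n_used,
                 f_stim = f_stim,
                 dt = dt),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("STA: %d spikes used (%d dropped), window %g s (%d samples) at %g Hz\n",
              x$n_used, x$n_dropped, length(x$window) * x$dt,
              length(x$window), x$f_stim))
  invisible(x)
}

#' @export
as.data.frame.sta_result <- function(x, ...) {
  data.frame(offset_s = x$window, sta = x$sta)
}

#' Periodogram power spectrum
#'
#' Raw periodogram `|DFT|^2` of a segment, one value per frequency bin
#' `k / (N * dt)`, with no tapering and no normalisation, so Parseval's
#' identity reads `sum(power) == N * sum(segment^2)`.  When the segment is
#' one stimulus period long, bin 1 sits exactly at the stimulus frequency.
#'
#' @param segment Numeric series, uniformly sampled.
#' @param dt Sampling step (s).
#' @return A data frame with columns `freq` (Hz) and `power`.
#' @examples
#' ps <- power_spectrum(sin(2 * pi * (0:99) / 100), dt = 1e-3)
#' ps$freq[which.max(ps$power)]
#' @export
power_spectrum <- function(segment, dt) {
  stopifnot(is.numeric(segment), length(segment) >= 2)
  check_scalar(dt, "dt", positive = TRUE)
  n <- length(segment)
  data.frame(freq = (0:(n - 1L)) / (n * dt),
             power = Mod(stats::fft(segment))^2)
}

#' Spike-field coherence at the stimulus frequency
#'
#' Ratio of the power spectrum of the spike-triggered average to the mean
#' power spectrum of the individual spike-centred segments,
#' `SFC = Psi(STA) / mean_i Psi(l_i)`, evaluated at the fundamental bin of
#' the one-period window (the stimulus frequency).  Because the STA is the
#' mean of the segments and the DFT is linear, this equals
#' `|mean_i z_i|^2 / mean_i |z_i|^2` for the segments' fundamental Fourier
#' coefficients `z_i`, which is confined to `[0, 1]` by the
#' Cauchy-Schwarz inequality: 1 for perfectly phase-locked spikes (all
#' segments identical) and approaching 0 for spikes at phases spread
#' uniformly over the stimulus cycle.
#'
#' @param sta_res An `sta_result` from [spike_triggered_average()].
#' @param dt Sampling step (s); defaults to the step recorded in `sta_res`.
#' @return An object of class `sfc_value`: `f_stim` (Hz), `sfc`
#'   (dimensionless, in `[0, 1]`), `n_spikes` (segments used).
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' stim <- sin(2 * pi * 5 * t)
#' sta <- spike_triggered_average(t, stim, spike_train(1:40 / 5), 5)
#' spike_field_coherence(sta)$sfc  # exactly 1: perfect lock
#' @export
spike_field_coherence <- function(sta_res, dt = sta_res$dt) {
  stopifnot(inherits(sta_res, "sta_result"))
  if (sta_res$n_used < 2L)
    stop_with("ephapsim_insufficient_spikes",
              "SFC needs at least 2 usable spikes (a single segment is trivially coherent)")
  # Fundamental (one cycle per window) DFT coefficient of each segment,
  # evaluated directly by projection: for one-period windows only this bin
  # matters, so computing it via BLAS beats a full FFT per segment.
  segs <- sta_res$segments
  w <- 2 * pi * (seq_len(ncol(segs)) - 1L) / ncol(segs)
  re <- drop(segs %*% cos(w))
  im <- -drop(segs %*% sin(w))
  denom <- mean(re^2 + im^2)
  if (denom == 0)
    stop_with("ephapsim_undefined_coherence",
              "stimulus has no power at the fundamental bin (is A_eph zero?)")
  num <- Mod(stats::fft(sta_res$sta))[2L]^2
  # the ratio is <= 1 by Cauchy-Schwarz; rounding can overshoot by an ulp
  structure(list(f_stim = sta_res$f_stim, sfc = min(1, num / denom),
                 n_spikes = sta_res$n_used),
            class = "sfc_value")
}

#' @export
print.sfc_value <- function(x, ...) {
  cat(sprintf("SFC = %.4f at %g Hz (%d spikes)\n", x$sfc, x$f_stim, x$n_spikes))
  invisible(x)
}
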