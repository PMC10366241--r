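#' Frequency-sweep configuration
#'
#' Template for entrainment experiments: which stimulus frequencies to probe,
#' how many noisy repeats per frequency, how long to simulate per point and
#' how seeds are derived.  Each (frequency, repeat, damage) cell gets its own
#' seed from the master seed through a deterministic hash, so any subset of a
#' grid reruns bit-identically.
#'
#' The frequency grid starts at 1 Hz by default: a zero-frequency stimulus is
#' degenerate for the one-period spike-triggered-average window.  `duration`
#' is the analysed time per simulation; an extra `warmup` interval is
#' simulated first and its spikes discarded to remove onset transients.
#'
#' @param mp A [membrane_parameters()] object.
#' @param stim A [stimulus_spec()] template (its `f_stim` is overridden by
#'   the grid).
#' @param f_grid Stimulus frequencies (Hz), strictly increasing, all > 0.
#' @param repeats Trials per frequency, at least 1.
#' @param duration Analysed simulation time per point (s).
#' @param warmup Discarded initial interval (s), non-negative.
#' @param dt Integration step (s).
#' @param seed0 Master seed.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(mp = membrane_parameters(), stim = stimulus_spec(),
                         f_grid = 1:45, repeats = 10, duration = 10,
                         warmup = 0.5, dt = 1e-5, seed0 = 1L) {
  stopifnot(inherits(mp, "membrane_parameters"),
            inherits(stim, "stimulus_spec"))
  if (length(f_grid) < 1 || any(f_grid <= 0) || any(diff(f_grid) <= 0))
    stop_with("ephapsim_domain_error",
              "f_grid must be strictly increasing and positive")
  check_scalar(repeats, "repeats", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(warmup, "warmup", nonneg = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(seed0, "seed0")
  structure(list(mp = mp, stim = stim, f_grid = as.numeric(f_grid),
                 repeats = as.integer(repeats), duration = duration,
                 warmup = warmup, dt = dt, seed0 = as.integer(seed0)),
            class = "sweep_config")
}

#' Spike-field-coherence curve over a frequency sweep
#'
#' For every frequency on the grid and every repeat, simulates the damaged
#' model driven at that frequency, discards the warm-up spikes, computes the
#' spike-triggered average and the spike-field coherence at the stimulus
#' frequency, and aggregates the repeats into a mean and standard deviation.
#' Frequencies at which too few spikes carry a full STA window are recorded
#' as missing (`NA`), never as zero coherence.
#'
#' @param cfg A [sweep_config()].
#' @param dp A [damage_parameters()] object.
#' @return An object of class `sfc_curve`: `f_grid`, `sfc_mean`, `sfc_std`,
#'   `n_spikes_mean`, `damage`, plus the `peak_f` and `band` summary from
#'   [peak_band()].
#' @examples
#' \donttest{
#' cfg <- sweep_config(f_grid = seq(2, 12, by = 2), repeats = 2,
#'                     duration = 2, dt = 1e-4)
#' curve <- sfc_curve(cfg, damage_parameters())
#' curve$peak_f
#' }
#' @export
sfc_curve <- function(cfg, dp = damage_parameters()) {
  stopifnot(inherits(cfg, "sweep_config"), inherits(dp, "damage_parameters"))
  if (cfg$stim$A_eph == 0)
    stop_with("ephapsim_configuration_error",
              "A_eph = 0: coherence with the ephaptic field is undefined at every frequency")
  nf <- length(cfg$f_grid)
  sfc_mat <- matrix(NA_real_, nrow = cfg$repeats, ncol = nf)
  nsp_mat <- matrix(0, nrow = cfg$repeats, ncol = nf)
  total <- cfg$warmup + cfg$duration
  any_spike <- FALSE
  for (i in seq_len(nf)) {
    f <- cfg$f_grid[i]
    stim_f <- cfg$stim
    stim_f$f_stim <- f
    for (r in seq_len(cfg$repeats)) {
      seed <- derive_seed(cfg$seed0, f, r, dp)
      sim <- simulate_qif(simulation_config(cfg$mp, dp, stim_f,
                                            duration = total, dt = cfg$dt,
                                            seed = seed,
                                            record_trace = FALSE))
      spk <- sim$spikes$times
      spk <- spk[spk >= cfg$warmup]
      if (length(spk) > 0) any_spike <- TRUE
      nsp_mat[r, i] <- length(spk)
      sfc_mat[r, i] <- tryCatch({
        sta <- spike_triggered_average(sim$t, sim$I_eph, spk, f)
        spike_field_coherence(sta)$sfc
      }, ephapsim_insufficient_spikes = function(e) NA_real_)
    }
  }
  if (!any_spike)
    stop_with("ephapsim_configuration_error",
              "no spikes at any frequency in any repeat: the drive is subthreshold")
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sd_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(if (length(x) == 1) 0 else NA_real_)
    sd(x)
  }
  out <- structure(list(f_grid = cfg$f_grid,
                        sfc_mean = apply(sfc_mat, 2, mean_na),
                        sfc_std = apply(sfc_mat, 2, sd_na),
                        n_spikes_mean = colMeans(nsp_mat),
                        damage = dp,
                        config = cfg),
                   class = "sfc_curve")
  pb <- peak_band(out)
  out$peak_f <- pb$peak_f
  out$band <- pb$band
  out
}

#' @export
print.sfc_curve <- function(x, ...) {
  cat(sprintf("SFC curve (b = %g, h = %g): %d frequencies in [%g, %g] Hz\n",
              x$damage$b, x$damage$h, length(x$f_grid),
              min(x$f_grid), max(x$f_grid)))
  cat(sprintf("  peak %g Hz (SFC %.3f), band %g-%g Hz\n",
              x$peak_f, max(x$sfc_mean, na.rm = TRUE), x$band[1], x$band[2]))
  invisible(x)
}

#' @export
as.data.frame.sfc_curve <- function(x, ...) {
  data.frame(f_hz = x$f_grid, sfc_mean = x$sfc_mean, sfc_std = x$sfc_std,
             n_spikes_mean = x$n_spikes_mean)
}

#' Peak frequency and preference band of an SFC curve
#'
#' The peak is the grid frequency with maximal mean coherence (ties resolved
#' toward the lowest frequency).  The preference band is the maximal
#' contiguous run of grid points containing the peak whose mean coherence is
#' at least `rel_height` times the maximum.  The 0.9 default is a free
#' summarisation choice; missing frequencies break contiguity.
#'
#' @param curve An `sfc_curve`, or any list with `f_grid` and `sfc_mean`.
#' @param rel_height Fraction of the peak coherence delimiting the band,
#'   in `(0, 1]`.
#' @return A list with `peak_f` (Hz) and `band` (length-2 vector, Hz).
#' @examples
#' peak_band(list(f_grid = 1:5, sfc_mean = c(0.1, 0.9, 1.0, 0.95, 0.2)))
#' @export
peak_band <- function(curve, rel_height = 0.9) {
  check_scalar(rel_height, "rel_height", positive = TRUE)
  if (rel_height > 1)
    stop_with("ephapsim_domain_error", "rel_height must be in (0, 1]")
  m <- curve$sfc_mean
  f <- curve$f_grid
  stopifnot(length(m) == length(f))
  ok <- !is.na(m)
  if (!any(ok))
    stop_with("ephapsim_domain_error", "curve has no non-missing SFC values")
  mx <- max(m[ok])
  peak_i <- which(ok & m == mx)[1]
  good <- ok & m >= rel_height * mx
  lo <- peak_i
  while (lo > 1L && good[lo - 1L]) lo <- lo - 1L
  hi <- peak_i
  while (hi < length(m) && good[hi + 1L]) hi <- hi + 1L
  list(peak_f = f[peak_i], band = c(f[lo], f[hi]))
}

#' Damage-grid experiment
#'
#' Runs one SFC frequency sweep per damage level under one of three designs:
#' combined damage (`b_equals_h`, both fractions set to the level), channel
#' damage only (`b_only`) or bilayer damage only (`h_only`).  All sweeps
#' share the master seed scheme, so the level-0 curve is identical across
#' modes.
#'
#' @param cfg A [sweep_config()].
#' @param mode One of `"b_equals_h"`, `"b_only"`, `"h_only"`.
#' @param levels Damage fractions, each in `[0, 1)`.
#' @return A named list of `sfc_curve` objects, one per level.
#' @export
damage_grid <- function(cfg, mode = c("b_equals_h", "b_only", "h_only"),
                        levels = seq(0, 0.20, by = 0.04)) {
  stopifnot(inherits(cfg, "sweep_config"))
  mode <- match.arg(mode)
  dps <- lapply(levels, function(x) switch(mode,
    b_equals_h = damage_parameters(b = x, h = x),
    b_only     = damage_parameters(b = x, h = 0),
    h_only     = damage_parameters(b = 0, h = x)))
  out <- lapply(dps, function(dp) sfc_curve(cfg, dp))
  names(out) <- sprintf("level_%g", levels)
  out
}

#' Calibrate the unprinted drive amplitudes
#'
#' The model's entrainment predictions depend on two amplitudes with no
#' canonical values: the tonic synaptic density `I_0` and the ephaptic
#' current amplitude `A_eph`.  This routine grid-searches candidate pairs
#' until (i) the stimulus-free, noise-free firing rate (from the exact
#' quadrature oracle [analytic_isi()]) lies in `rate_range` and (ii) the
#' healthy-model SFC peak frequency, measured with the same [peak_band()]
#' rule used everywhere else, does not exceed `healthy_peak_max`.  The
#' template's own amplitudes are tried first, so a spec that already
#' satisfies both targets is returned unchanged.  The returned spec is meant
#' to be frozen and reused unmodified for every damage condition.
#'
#' The healthy-peak check runs a reduced sweep (`peak_f_grid`, and at most
#' `peak_repeats` repeats of `peak_duration` seconds) to keep calibration
#' cheap relative to the experiments it gates.
#'
#' @param cfg A [sweep_config()] holding the template stimulus and membrane.
#' @param rate_range Acceptable tonic firing-rate interval (spikes/s).
#' @param healthy_peak_max Largest admissible healthy peak frequency (Hz).
#' @param I0_candidates Candidate tonic densities (A/m^2); default: the
#'   template value, then rheobase scaled by 1 + {0.002, 0.005, 0.01, 0.02,
#'   0.05, 0.1}.
#' @param A_candidates Candidate ephaptic amplitudes (A); default: the
#'   template value, then amplitudes giving 0.025, 0.05, 0.1 and 0.2 mV peak
#'   extracellular potential (the scale of the suprathreshold drive margin,
#'   where entrainment is frequency-selective).
#' @param peak_f_grid Reduced frequency grid for the healthy-peak check.
#' @param peak_repeats Repeats for the check.
#' @param peak_duration Analysed seconds per point for the check.
#' @return The calibrated [stimulus_spec()] (noise level and phase taken
#'   from the template).
#' @export
calibrate_baseline <- function(cfg,
                               rate_range = c(5, 15),
                               healthy_peak_max = 10,
                               I0_candidates = NULL,
                               A_candidates = NULL,
                               peak_f_grid = seq(1, 45, by = 2),
                               peak_repeats = 2,
                               peak_duration = 3) {
  stopifnot(inherits(cfg, "sweep_config"))
  mp <- cfg$mp
  healthy <- damage_parameters(0, 0)
  if (is.null(I0_candidates)) {
    rh <- rheobase_current(mp, healthy)
    I0_candidates <- unique(c(cfg$stim$I_0,
                              rh * (1 + c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1))))
  }
  if (is.null(A_candidates)) {
    # amplitude producing a given peak extracellular potential
    amp_for_v <- function(v) v * 4 * pi * mp$r_dist / mp$rho_ext
    A_candidates <- unique(c(cfg$stim$A_eph,
                             amp_for_v(c(25e-6, 50e-6, 100e-6, 200e-6))))
  }
  tried <- list()
  for (I0 in I0_candidates) {
    rate <- tryCatch(1 / analytic_isi(mp, healthy, I0),
                     ephapsim_no_firing = function(e) 0)
    rate_ok <- rate >= rate_range[1] && rate <= rate_range[2]
    for (A in A_candidates) {
      if (!rate_ok) {
        tried[[length(tried) + 1L]] <- list(I_0 = I0, A_eph = A, rate = rate,
                                            peak_f = NA_real_)
        next
      }
      spec <- cfg$stim
      spec$I_0 <- I0
      spec$A_eph <- A
      chk <- sweep_config(mp = mp, stim = spec, f_grid = peak_f_grid,
                          repeats = min(cfg$repeats, peak_repeats),
                          duration = min(cfg$duration, peak_duration),
                          warmup = cfg$warmup, dt = cfg$dt,
                          seed0 = cfg$seed0)
      peak <- tryCatch(sfc_curve(chk, healthy)$peak_f,
                       ephapsim_error = function(e) NA_real_)
      tried[[length(tried) + 1L]] <- list(I_0 = I0, A_eph = A, rate = rate,
                                          peak_f = peak)
      if (!is.na(peak) && peak <= healthy_peak_max)
        return(spec)
    }
  }
  front <- do.call(rbind, lapply(tried, as.data.frame))
  stop_with("ephapsim_calibration_failure",
            "no (I_0, A_eph) candidate met rate in [%g, %g] spikes/s and healthy peak <= %g Hz; candidates tried:\n%s",
            rate_range[1], rate_range[2], healthy_peak_max,
            paste(utils::capture.output(print(front)), collapse = "\n"))
}
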