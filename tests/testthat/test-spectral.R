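test_that("STA of perfectly locked spikes is one sine period; a single spike is its own segment", {
  rec <- sine_record(f = 5, dur = 10, dt = 1e-3)
  spk <- locked_spike_train(5, 40)  # one spike per cycle, same phase
  sta <- spike_triggered_average(rec$t, rec$stim, spk, 5)
  expect_identical(sta$n_used + sta$n_dropped, 40L)
  expect_gte(sta$n_used, 38L)
  # all segments identical => sta equals each segment, a full-amplitude period
  expect_equal(max(sta$sta), 1, tolerance = 1e-2)
  expect_equal(min(sta$sta), -1, tolerance = 1e-2)
  expect_equal(sta$sta, sta$segments[1, ], tolerance = 1e-12)

  one <- spike_triggered_average(rec$t, rec$stim, spike_train(2.31), 5)
  expect_identical(one$n_used, 1L)
  expect_identical(one$sta, one$segments[1, ])
})

test_that("STA amplitude of uniform-phase spikes vanishes as O(A/sqrt(n))", {
  rec <- sine_record(f = 5, dur = 200, dt = 1e-3)
  n <- 900
  spk <- locked_spike_train(5, n, kappa = 0, seed = 31)
  sta <- spike_triggered_average(rec$t, rec$stim, spk, 5)
  expect_lt(max(abs(sta$sta)), 5 / sqrt(n))
})

test_that("STA boundary spikes are dropped, never padded", {
  rec <- sine_record(f = 2, dur = 3, dt = 1e-3)  # window 0.5 s
  spk <- spike_train(c(0.1, 1.5, 2.95))          # first and last exit the record
  sta <- spike_triggered_average(rec$t, rec$stim, spk, 2)
  expect_identical(sta$n_used, 1L)
  expect_identical(sta$n_dropped, 2L)
  expect_error(spike_triggered_average(rec$t, rec$stim, spike_train(0.01), 2),
               class = "ephapsim_insufficient_spikes")
  expect_error(spike_triggered_average(rec$t, rec$stim, spk, 0),
               class = "ephapsim_domain_error")
})

test_that("periodogram concentrates a one-period sine in bin 1 and satisfies Parseval", {
  L <- 200; dt <- 1e-3
  x <- sin(2 * pi * (0:(L - 1)) / L)
  ps <- power_spectrum(x, dt)
  expect_equal(which.max(ps$power), 2L)              # bin 1 (0-based)
  expect_equal(ps$freq[2], 1 / (L * dt))
  expect_lt(sum(ps$power[-c(2, L)]) / sum(ps$power), 1e-20)
  const <- power_spectrum(rep(2.5, L), dt)
  expect_equal(which.max(const$power), 1L)           # all power in bin 0
  y <- rnorm(128)
  psy <- power_spectrum(y, dt)
  expect_equal(sum(psy$power), 128 * sum(y^2), tolerance = 1e-10)
})

test_that("SFC is 1 for perfect lock, ~1/n for uniform phases, and bounded in [0, 1]", {
  rec <- sine_record(f = 5, dur = 10, dt = 1e-3)
  sta <- spike_triggered_average(rec$t, rec$stim, locked_spike_train(5, 40), 5)
  expect_equal(spike_field_coherence(sta)$sfc, 1, tolerance = 1e-12)

  long <- sine_record(f = 5, dur = 120, dt = 1e-3)
  for (seed in 1:3) {
    spk <- locked_spike_train(5, 500, kappa = 0, seed = seed)
    s <- spike_field_coherence(spike_triggered_average(long$t, long$stim, spk, 5))
    expect_lt(s$sfc, 0.05)   # expectation ~ 1/500
  }

  # arbitrary random trains never leave [0, 1]
  for (seed in 4:9) {
    set.seed(seed)
    spk <- spike_train(sort(runif(sample(5:80, 1), 1, 9)))
    s <- spike_field_coherence(spike_triggered_average(rec$t, rec$stim, spk, 5))
    expect_gte(s$sfc, 0)
    expect_lte(s$sfc, 1 + 1e-12)
  }
})

test_that("single-segment SFC and zero-power stimulus are rejected", {
  rec <- sine_record(f = 5, dur = 10, dt = 1e-3)
  one <- spike_triggered_average(rec$t, rec$stim, spike_train(2.31), 5)
  expect_error(spike_field_coherence(one),
               class = "ephapsim_insufficient_spikes")
  flat <- spike_triggered_average(rec$t, rep(0, length(rec$t)),
                                  locked_spike_train(5, 10), 5)
  expect_error(spike_field_coherence(flat),
               class = "ephapsim_undefined_coherence")
})

test_that("fundamental-bin SFC matches the direct projection oracle to 1e-10", {
  rec <- sine_record(f = 4, dur = 60, dt = 1e-3, phase0 = 0.4)
  for (kappa in c(8, 1)) {
    spk <- locked_spike_train(4, 150, kappa = kappa, seed = 17)
    sta <- spike_triggered_average(rec$t, rec$stim, spk, 4)
    expect_equal(spike_field_coherence(sta)$sfc, sfc_oracle(sta$segments),
                 tolerance = 1e-10)
  }
})

test_that("SFC is invariant under a common time shift of stimulus and spikes", {
  f <- 5; dt <- 1e-3
  spk0 <- locked_spike_train(f, 60, kappa = 6, seed = 2, t_start = 1)
  t <- seq(0, 30, by = dt)
  base <- sin(2 * pi * f * t)
  s0 <- spike_field_coherence(spike_triggered_average(t, base, spk0, f))$sfc
  shift <- 0.737  # an exact multiple of dt
  shifted <- sin(2 * pi * f * (t - shift))
  spk1 <- spike_train(spk0$times + shift)
  s1 <- spike_field_coherence(spike_triggered_average(t, shifted, spk1, f))$sfc
  expect_equal(s1, s0, tolerance = 1e-9)
})

test_that("SFC decreases monotonically with von Mises phase jitter", {
  rec <- sine_record(f = 5, dur = 90, dt = 1e-3)
  for (seed in c(3, 8)) {
    sfcs <- vapply(c(Inf, 16, 4, 1, 0.25), function(kappa) {
      spk <- locked_spike_train(5, 400, kappa = kappa, seed = seed)
      spike_field_coherence(spike_triggered_average(rec$t, rec$stim, spk, 5))$sfc
    }, double(1))
    expect_true(all(diff(sfcs) < 0))
  }
})
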