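test_that("derivative vanishes at the quadratic roots and matches hand arithmetic", {
  mp <- mp_default
  for (dp in list(dp_healthy, damage_parameters(0.3, 0.1))) {
    expect_equal(qif_derivative(mp$V_rest, 0, 0, mp, dp), 0)
    expect_equal(qif_derivative(mp$V_thresh, 0, 0, mp, dp), 0)
  }
  # (5 mV)(-5 mV) / (2 ms * 10 mV) at the healthy midpoint
  expect_equal(qif_derivative(-60e-3, 0, 0, mp, dp_healthy), -1.25)
})

test_that("subthreshold drive settles at the stable fixed point without spiking", {
  I0 <- 0.02  # below the 0.025 A/m^2 rheobase
  sim <- simulate_qif(simulation_config(mp_default, dp_healthy, stim_tonic(I0),
                                        duration = 1, dt = 1e-4))
  expect_identical(sim$spikes$n, 0L)
  vstar <- uniroot(function(v) qif_derivative(v, 0, I0, mp_default, dp_healthy),
                   c(mp_default$V_rest - 0.05, -60e-3), tol = 1e-12)$root
  expect_lt(vstar, mp_default$V_thresh)
  expect_equal(tail(sim$V_m, 1), vstar, tolerance = 1e-6)
})

test_that("Euler interspike interval converges to the quadrature oracle at rate O(dt)", {
  I0 <- 0.026
  exact <- analytic_isi(mp_default, dp_healthy, I0)
  errs <- vapply(c(1e-4, 5e-5, 1e-5), function(dt) {
    sim <- simulate_qif(simulation_config(mp_default, dp_healthy, stim_tonic(I0),
                                          duration = 2, dt = dt))
    abs(mean(diff(sim$spikes$times)) - exact)
  }, double(1))
  expect_true(all(diff(errs) < 0))
  # first-order constant is ~2.5: each error sits within a few dt
  expect_lt(errs[1], 4 * 1e-4)
  expect_lt(errs[3], 4 * 1e-5)
  # tenfold dt reduction shrinks the error close to tenfold
  expect_gt(errs[1] / errs[3], 5)
})

test_that("reset contract holds: samples capped at V_peak and reset to c_reset", {
  sim <- simulate_qif(simulation_config(mp_default, dp_healthy, stim_tonic(0.03),
                                        duration = 1, dt = 1e-5))
  expect_gt(sim$spikes$n, 2)
  expect_true(all(sim$V_m <= mp_default$V_peak))
  idx <- round(sim$spikes$times / 1e-5) + 1L  # V_m[k+1] is the post-step sample
  expect_true(all(sim$V_m[idx] == mp_default$c_reset))
  expect_true(all(diff(sim$spikes$times) > 0))
  expect_true(all(sim$spikes$times >= 0 & sim$spikes$times <= 1))
})

test_that("damaged equation is trajectory-identical to substituted healthy equation", {
  b <- 0.3; h <- 0.1
  stim <- stimulus_spec(f_stim = 7, A_eph = 1.795e-8, I_0 = 0.03,
                        sigma_noise = 1e-5)
  mp_sub <- membrane_parameters(
    R_m = dysfunctional_resistance(mp_default$R_m, b),
    C_m = dysfunctional_capacitance(mp_default$C_m, h))
  s1 <- simulate_qif(simulation_config(mp_default, damage_parameters(b, h),
                                       stim, duration = 1, dt = 5e-5, seed = 3))
  s2 <- simulate_qif(simulation_config(mp_sub, dp_healthy,
                                       stim, duration = 1, dt = 5e-5, seed = 3))
  expect_identical(s1$V_m, s2$V_m)
  expect_identical(s1$spikes$times, s2$spikes$times)
})

test_that("identical config and seed reproduce the simulation bitwise", {
  cfg <- simulation_config(mp_default, damage_parameters(0.04, 0.04),
                           stimulus_spec(f_stim = 11), duration = 0.5,
                           dt = 5e-5, seed = 21)
  s1 <- simulate_qif(cfg)
  s2 <- simulate_qif(cfg)
  expect_identical(s1$V_m, s2$V_m)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("quadratic blow-up beyond the guard aborts with a stability error naming dt", {
  cfg <- simulation_config(mp_default, dp_healthy, stim_tonic(100),
                           duration = 0.1, dt = 1e-4)
  expect_error(simulate_qif(cfg), "reduce dt")
})

test_that("analytic ISI rejects subthreshold drive and shortens with combined damage", {
  expect_error(analytic_isi(mp_default, dp_healthy, I_0 = 0.02),
               class = "ephapsim_no_firing")
  # b = h = x: tau fixed, synaptic coefficient grows, so the ISI shrinks
  isis <- vapply(c(0, 0.1, 0.2), function(x)
    analytic_isi(mp_default, damage_parameters(x, x), I_0 = 0.026), double(1))
  expect_true(all(diff(isis) < 0))
  # tau-preserving rescale (2 R_m, C_m / 2) changes the synaptic term only,
  # and the stronger I_0/C drive must shorten the interval
  mp2 <- membrane_parameters(R_m = 2 * mp_default$R_m, C_m = mp_default$C_m / 2)
  expect_equal(mp2$R_m * mp2$C_m, mp_default$R_m * mp_default$C_m)
  expect_lt(analytic_isi(mp2, dp_healthy, I_0 = 0.026), isis[1])
})

test_that("simulation config guards duration, step size and grid commensurability", {
  expect_error(simulation_config(mp_default, dp_healthy, stimulus_spec(),
                                 duration = 1, dt = 2e-4),
               class = "ephapsim_domain_error")
  expect_error(simulation_config(mp_default, dp_healthy, stimulus_spec(),
                                 duration = 1.000005, dt = 1e-4),
               class = "ephapsim_domain_error")
})

test_that("spike trains round-trip through the plain-text format", {
  st <- spike_train(c(0.30001, 0.1, 0.2, 0.2))
  expect_identical(st$times, c(0.1, 0.2, 0.30001))
  expect_identical(st$n, 3L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spike_times(st, f)
  expect_equal(read_spike_times(f), st)
})
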