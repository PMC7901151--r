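test_that("passive step solves the RC membrane exactly", {
  cp <- passive_cell()  # 5 MOhm, 5 ms

  # rest stays at rest
  expect_identical(step_passive(0, cp, I = 0, dt = 3.7), 0)

  # steady state is I*R
  expect_equal(step_passive(0, cp, I = 1, dt = 1e9), 5)

  # one membrane time constant: 1 - 1/e of the way, against a fine-step
  # explicit-Euler reference
  v <- step_passive(0, cp, I = 1, dt = 5)
  expect_equal(v, 5 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(v, euler_passive(0, cp, I = 1, t_total = 5), tolerance = 1e-5)

  # semigroup: n substeps compose to one big step at machine precision
  v1 <- step_passive(2, cp, I = -3, dt = 7)
  v2 <- 2
  for (k in 1:7) v2 <- step_passive(v2, cp, I = -3, dt = 1)
  expect_equal(v1, v2, tolerance = 1e-13)

  expect_error(step_passive(NaN, cp, I = 0, dt = 1))
  expect_error(step_passive(0, cp, I = 0, dt = -1))
})

test_that("AHP spike increment follows the geometric recruitment rule", {
  p <- ff_motoneuron()

  st <- apply_spike_reset(neuron_state(V_m = 10, z = 0), p)
  expect_equal(st$z, 0.25)
  expect_equal(st$V_m, p$V_reset)

  # z = 1 is a fixed point for any alpha
  for (a in c(0.1, 0.25, 0.9)) {
    pa <- lif_params(G_in = 0.67, tau_m = 2, alpha = a)
    expect_equal(apply_spike_reset(neuron_state(z = 1), pa)$z, 1)
  }

  # repeated spiking from z = 0 (no decay): z_n = 1 - (1 - alpha)^n
  st <- neuron_state()
  zs <- numeric(3)
  for (n in 1:3) { st <- apply_spike_reset(st, p); zs[n] <- st$z }
  expect_equal(zs, 1 - 0.75^(1:3))  # 0.25, 0.4375, 0.578125
})

test_that("LIF step respects rest, the AHP reversal, and stays bounded", {
  p <- ff_motoneuron()

  # rest with no drive stays at rest, no spike
  out <- step_lif_ahp(neuron_state(V_m = p$V_r, z = 0), p, I = 0, dt = 0.1)
  expect_equal(out$state$V_m, p$V_r)
  expect_false(out$spike)

  # at the AHP reversal the AHP current vanishes: the instantaneous slope
  # equals the leak alone, G_in*(V_r - E_K)/C, independent of z
  dt <- 1e-6
  for (z in c(0.3, 1)) {
    out <- step_lif_ahp(neuron_state(V_m = p$E_K, z = z), p, I = 0, dt = dt)
    slope <- (out$state$V_m - p$E_K) / dt
    expect_equal(slope, p$G_in * (p$V_r - p$E_K) / p$C, tolerance = 1e-4)
  }

  # z decays between spikes and never leaves [0, 1]
  st <- neuron_state(V_m = 0, z = 0)
  z_hist <- numeric(0)
  set.seed(11)
  for (i in 1:200) {
    if (i %% 37 == 0) st <- apply_spike_reset(st, p)
    out <- step_lif_ahp(st, p, I = runif(1, -5, 5), dt = 0.5)
    st <- out$state
    z_hist <- c(z_hist, st$z)
  }
  expect_true(all(z_hist >= 0 & z_hist <= 1))
})

test_that("steady firing rate matches an independent fine-step integrator", {
  p <- s_motoneuron()   # S-type: 0.2 uS, 5 ms
  ref <- euler_lif_spikes(p, I = 5, t_total = 400, dt = 5e-4)
  rec <- record(p, NULL, amplifier_config("bridge"),
                make_square_pulse(5, 400, baseline_ms = 1),
                keep_traces = FALSE)
  # compare steady-state ISIs (discard the adapting onset)
  isi_ref <- diff(ref[ref > 300])
  isi_sim <- diff(rec$spike_times[rec$spike_times > 301])
  expect_gt(length(isi_sim), 2)
  expect_equal(mean(isi_sim), mean(isi_ref), tolerance = 0.01)
})

test_that("exponential-Euler trajectory converges at least first order", {
  p <- ff_motoneuron()
  run <- function(dt) {
    st <- neuron_state(V_m = 0, z = 0.6)   # AHP engaged, subthreshold drive
    for (i in seq_len(round(5 / dt)))
      st <- step_lif_ahp(st, p, I = 3, dt = dt)$state
    st$V_m
  }
  v_ref <- run(1e-4)
  e1 <- abs(run(0.08) - v_ref)
  e2 <- abs(run(0.04) - v_ref)
  expect_lt(e2, e1)
  expect_gt(log2(e1 / e2), 0.9)   # observed order >= ~1
})

test_that("simulations are reproducible: bitwise without noise, seeded with", {
  p <- ff_motoneuron()
  st <- make_square_pulse(8, 150, baseline_ms = 10)
  amp <- amplifier_config("dcc", dcc_rate = 2)
  a <- record(p, NULL, amp, st)
  b <- record(p, NULL, amp, st)
  expect_identical(a$V_m, b$V_m)
  expect_identical(a$spike_times, b$spike_times)

  pn <- ff_motoneuron(sigma = 1)
  n1 <- record(pn, NULL, amp, st, seed = 5, keep_traces = FALSE)
  n2 <- record(pn, NULL, amp, st, seed = 5, keep_traces = FALSE)
  n3 <- record(pn, NULL, amp, st, seed = 6, keep_traces = FALSE)
  expect_identical(n1$spike_times, n2$spike_times)
  expect_false(identical(n1$spike_times, n3$spike_times))
})
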