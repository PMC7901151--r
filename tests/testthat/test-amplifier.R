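test_that("DCC chopping scales by 1/duty and conserves charge", {
  cfg <- amplifier_config("dcc", dcc_rate = 1)  # T = 1 ms, duty 1/3

  expect_equal(chop_current(1, 0.1, cfg), 3)     # on-phase: 3x the command
  expect_equal(chop_current(1, 0.5, cfg), 0)     # off-phase
  expect_equal(chop_current(0, c(0.1, 0.5, 0.9), cfg), c(0, 0, 0))

  # time-average over one full period equals the command
  t <- seq(0, 1, length.out = 6001)[-6001]
  expect_equal(mean(chop_current(2.5, t, cfg)), 2.5, tolerance = 1e-3)

  bad <- amplifier_config("dcc", dcc_rate = 1)
  bad$duty <- 1.2
  expect_error(chop_current(1, 0.1, bad))
  expect_error(chop_current(1, -1, cfg))
})

test_that("sample-and-hold freezes the tip potential between samples", {
  cfg <- amplifier_config("dcc", dcc_rate = 1)
  dt <- 0.01

  # constant input -> constant output
  expect_equal(sample_and_hold(rep(4.2, 501), dt, cfg), rep(4.2, 501))

  # sawtooth synchronized to the period -> constant at the sampled value
  dt2 <- 1 / 128                      # dyadic grid: samples land exactly
  t <- (0:640) * dt2
  saw <- t %% 1
  out <- sample_and_hold(saw, dt2, cfg)
  expect_equal(out[t >= 1], rep(0, sum(t >= 1)))  # sampled at t %% 1 == 0

  # off-grid sampling instants are an error, never interpolated
  expect_error(sample_and_hold(rep(0, 100), dt = 0.013, cfg),
               "grid")
})

test_that("bridge output subtracts the balanced IR drop", {
  cfg <- amplifier_config("bridge", bridge_balance = 1.5)
  expect_equal(bridge_output(7, 0, cfg), 7)            # no current: unchanged
  expect_equal(bridge_output(3 + 1.5 * 2, 2, cfg), 3)  # perfect balance
  cfg0 <- amplifier_config("bridge", bridge_balance = 0)
  expect_equal(bridge_output(9, 2, cfg0), 9)           # unbalanced: raw tip
})

test_that("recording a quiescent cell yields flat traces at rest", {
  cp <- cell_params(R_in = 5, tau_m = 5, V0 = -2)
  st <- stimulus(data.frame(kind = "constant", start = 0, duration = 50,
                            value = 0, slope = 0))
  for (amp in list(amplifier_config("bridge"),
                   amplifier_config("dcc", dcc_rate = 2))) {
    rec <- record(cp, std_electrode(), amp, st)
    expect_equal(rec$V_m, rep(-2, length(rec$V_m)))
    expect_equal(rec$V_amp, rep(-2, length(rec$V_amp)))
  }
})

test_that("simulated steady sampled voltage matches the closed form", {
  # 5 MOhm / 5 ms cell, 1 MOhm / 25 us electrode, 1 nA, 1 kHz
  # (5 cycles per time constant): V_amp/IR = rho(1, 5) ~ 0.934, the
  # electrode residual being ~1e-12 at this rate
  cp <- passive_cell()
  rec <- record(cp, std_electrode(), amplifier_config("dcc", dcc_rate = 1),
                make_square_pulse(1, 150, baseline_ms = 0.5),
                duration_ms = 150)
  expect_equal(rec$V_held / 5, steady_sampled_ratio(1, 5), tolerance = 1e-6)
  expect_equal(rec$V_held / 5, 0.9341226, tolerance = 1e-5)
})

test_that("injected charge equals commanded charge over every DCC period", {
  cp <- passive_cell()
  stim <- make_triangular_ramp(slope = 100, peak = 3, baseline_ms = 10)
  rec <- record(cp, NULL, amplifier_config("dcc", dcc_rate = 1), stim)
  n_per <- rec$n_per
  n_full <- floor((length(rec$I_inj) - 1) / n_per)
  for (p in seq_len(n_full) - 1L) {
    idx <- p * n_per + seq_len(n_per)        # steps of period p
    q_inj <- sum(rec$I_inj[idx + 1L]) * rec$dt
    t_mid <- (p + 0.5) / 1                   # period midpoint, ms
    q_com <- stim_current(stim, t_mid) * 1   # exact for piecewise-linear I
    expect_equal(q_inj, q_com, tolerance = 1e-10)
  }
})

test_that("DCC output is piecewise-constant, changing only at samples", {
  cp <- passive_cell()
  rec <- record(cp, NULL, amplifier_config("dcc", dcc_rate = 1),
                make_square_pulse(2, 30, baseline_ms = 5))
  ch <- which(diff(rec$V_amp) != 0)   # node index before each change
  expect_true(all(ch %% rec$n_per == 0))
})

test_that("DCC converges to Bridge as the rate grows", {
  cp <- passive_cell()
  st <- make_square_pulse(1, 120, baseline_ms = 0.5)
  err <- vapply(c(1, 2, 5, 10, 50), function(r) {
    rec <- record(cp, NULL, amplifier_config("dcc", dcc_rate = r), st,
                  duration_ms = 120, keep_traces = FALSE)
    abs(rec$V_held - 5)   # Bridge steady state = I*R = 5 mV
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[5], 0.01)
})

test_that("entrained firing locks ISIs to multiples of the DCC period", {
  # fast-fatigable motoneuron on a slow ramp at 1 kHz: the interspike
  # intervals concentrate at integer multiples of the DCC period
  rec <- ff_ramp_recording(1)
  nisi <- isi_normalized(rec$spike_times, 1)
  expect_gt(length(nisi), 100)
  expect_gt(entrainment_index(nisi), 0.99)
})
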