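# synthetic stereotyped spike: ~1 ms triangular spike of 80 mV
synth_train <- function(times, t_end = 500, dt = 0.05, width = 1,
                        height = 80) {
  t <- seq(0, t_end, by = dt)
  V <- rep(-70, length(t))
  for (ts in times) {
    up <- t >= ts & t < ts + width / 2
    down <- t >= ts + width / 2 & t < ts + width
    V[up] <- -70 + height * (t[up] - ts) / (width / 2)
    V[down] <- -70 + height * (1 - (t[down] - ts - width / 2) / (width / 2))
  }
  list(t = t, V = V, dt = dt)
}

test_that("spike detection finds stereotyped spikes and LIF spikes", {
  expect_equal(detect_spikes(rep(-70, 1000), 0.05), numeric(0))
  expect_error(detect_spikes(c(1, NA, 3), 0.05))

  times <- c(20, 75.3, 130, 201.1, 290, 350.8, 444)
  tr <- synth_train(times)
  det <- detect_spikes(tr$V, tr$dt)
  expect_length(det, 7)
  expect_true(all(abs(det - times) <= 2 * tr$dt))

  # ramp-driven LIF in Bridge: detected times match the simulator's own
  rec <- record(ff_motoneuron(), NULL, amplifier_config("bridge"),
                make_triangular_ramp(1, 10, baseline_ms = 100))
  det <- detect_spikes(rec$V_m, rec$dt)
  expect_length(det, length(rec$spike_times))
  expect_true(all(abs(det - rec$spike_times) <= 2 * rec$dt))
})

test_that("voltage threshold is read at the 10 V/s foot of the spike", {
  rec <- record(ff_motoneuron(), NULL, amplifier_config("bridge"),
                make_triangular_ramp(1, 10, baseline_ms = 100))
  vt <- voltage_threshold(rec$V_m, rec$dt, rec$spike_times[1])
  expect_equal(vt, 10, tolerance = 0.02)  # model threshold is 10 mV

  expect_error(voltage_threshold(rep(0, 1000), 0.01, 5), "crossing")

  # measured on the held amplifier output at a low DCC rate the apparent
  # threshold differs from the true one (stale samples)
  recd <- record(ff_motoneuron(), NULL,
                 amplifier_config("dcc", dcc_rate = 1),
                 make_triangular_ramp(1, 10, baseline_ms = 100))
  vt_amp <- voltage_threshold(recd$V_amp, recd$dt, recd$spike_times[1])
  expect_gt(abs(vt_amp - 10), 0.25)
})

test_that("F-I curve construction follows the ISI-reciprocal definition", {
  ramp <- make_triangular_ramp(1, 10, baseline_ms = 0.5)

  # two spikes 100 ms apart -> one 10 Hz point at the current of spike 2
  fi <- build_fi(spikes = c(3000, 3100), stim = ramp)
  expect_equal(nrow(fi), 1)
  expect_equal(fi$freq, 10)
  expect_equal(fi$I, stim_current(ramp, 3100))
  expect_equal(fi$phase, "ascending")

  expect_equal(nrow(build_fi(spikes = numeric(0), stim = ramp)), 0)
  expect_equal(nrow(build_fi(spikes = 5, stim = ramp)), 0)

  # ascending/descending split at the apex (t = 10000.5)
  fi2 <- build_fi(spikes = c(9000, 9500, 11000, 12000), stim = ramp)
  expect_equal(fi2$phase, c("ascending", "descending", "descending"))
})

test_that("onset and offset currents follow their ramp-phase definitions", {
  ramp <- make_triangular_ramp(1, 10, baseline_ms = 1000)
  ff <- ff_motoneuron()
  rec <- record(ff, NULL, amplifier_config("bridge"), ramp,
                keep_traces = FALSE)
  oo <- onset_offset(build_fi(rec), rec)
  # rheobase of the model: G_in * V_th = 6.7 nA; the ramp crosses it on the
  # way up, and firing stops near it on the way down
  expect_equal(unname(oo["onset"]),
               stim_current(ramp, min(rec$spike_times)))
  expect_equal(unname(oo["offset"]),
               stim_current(ramp, max(rec$spike_times)))
  expect_gt(oo["onset"], 6.5)           # near the 6.7 nA rheobase
  expect_lt(abs(oo["offset"] - oo["onset"]), 0.5)

  # no descending spikes -> offset reported missing
  fi <- build_fi(spikes = c(5000, 5100), stim = ramp)
  expect_true(is.na(onset_offset(fi)["offset"]))
})

test_that("F-I gain recovers a known slope", {
  mk_fi <- function(I, f, phase = "ascending") {
    structure(data.frame(time = seq_along(I), I = I, freq = f,
                         phase = phase),
              class = c("fi_curve", "data.frame"))
  }
  fi <- mk_fi(seq(4, 10, by = 0.5), 7 * seq(4, 10, by = 0.5) + 3)
  expect_equal(fi_gain(fi, c(4, 10)), 7, tolerance = 1e-10)
  expect_equal(fi_gain(fi, "auto"), 7, tolerance = 1e-10)
  expect_error(fi_gain(fi, c(9.8, 10)), "3 ascending points")

  # descending points are excluded
  fi2 <- mk_fi(c(4:8, 8:4), c(7 * (4:8), 50 * (8:4)),
               rep(c("ascending", "descending"), each = 5))
  expect_equal(fi_gain(fi2, c(4, 8)), 7, tolerance = 1e-10)
})

test_that("input resistance recovers R in Bridge and rho*R under DCC", {
  cp <- passive_cell()
  el <- std_electrode()
  series <- make_resistance_series(duration_ms = 500, baseline_ms = 100)

  # Bridge with perfect balance: exact R
  amp <- amplifier_config("bridge", bridge_balance = el$R_e)
  recs <- lapply(series, function(s) record(cp, el, amp, s))
  expect_equal(apparent_input_resistance(recs), 5, tolerance = 1e-4)

  # DCC with T = tau: rho(tau, tau) * R ~ 0.691 R
  ampd <- amplifier_config("dcc", dcc_rate = 0.2)
  recsd <- lapply(make_resistance_series(c(-3, 3), 500, 100),
                  function(s) record(cp, NULL, ampd, s))
  expect_equal(apparent_input_resistance(recsd),
               5 * steady_sampled_ratio(5, 5), tolerance = 1e-3)

  # 25 cycles per tau: at least 98% of R
  amp25 <- amplifier_config("dcc", dcc_rate = 5)
  recs25 <- lapply(make_resistance_series(c(-3, 3), 500, 100),
                   function(s) record(cp, NULL, amp25, s))
  expect_gte(apparent_input_resistance(recs25), 0.98 * 5)
})

test_that("time-constant fit recovers tau, also on biexponential traces", {
  amp <- amplifier_config("bridge")
  for (tau in c(5, 2)) {
    cp <- cell_params(R_in = 5, tau_m = tau)
    rec <- record(cp, NULL, amp, make_short_pulse(-5, 1))
    expect_equal(estimate_time_constant(rec), tau, tolerance = 0.01)
  }
  # cell + electrode: discard 5*tau_e of the relaxation, recover tau_m
  cp <- passive_cell()
  rec <- record(cp, std_electrode(), amp, make_short_pulse(-5, 1))
  expect_equal(estimate_time_constant(rec, discard_ms = 5 * 0.025), 5,
               tolerance = 0.02)
})

test_that("ripple measurement matches the closed form and is 0 in Bridge", {
  cp <- cell_params(R_in = 2.5, tau_m = 3)
  pulse <- make_square_pulse(10, 100, baseline_ms = 2)
  recb <- record(cp, NULL, amplifier_config("bridge"), pulse,
                 duration_ms = 100)
  expect_lt(ripple_amplitude(recb, c(80, 100)), 1e-9)

  for (r in c(1, 5)) {
    rec <- record(cp, NULL, amplifier_config("dcc", dcc_rate = r), pulse,
                  duration_ms = 100)
    expect_equal(ripple_amplitude(rec, c(80, 100)),
                 steady_ripple(2.5, 3, 10, r), tolerance = 1e-5)
  }
})

test_that("normalized ISIs and the entrainment index behave as defined", {
  # spikes every 11 periods of a 1 kHz clock
  sp <- cumsum(rep(11, 20))
  expect_equal(isi_normalized(sp, 1), rep(11, 19))
  expect_equal(isi_normalized(5, 1), numeric(0))
  expect_equal(entrainment_index(rep(11, 19)), 1)
  expect_error(entrainment_index(numeric(0)))

  # uniform ISIs on [10.5, 11.5]: expected fraction within tol is 2*tol
  set.seed(99)
  u <- runif(2e4, 10.5, 11.5)
  expect_equal(entrainment_index(u, tol = 0.05), 0.1, tolerance = 0.1)
})

test_that("plateau detection flags locked trains, not diffuse ones", {
  # alternating 11- and 12-period ISIs on a 1050 Hz clock: plateaus at
  # 1050/11 = 95.5 Hz and 1050/12 = 87.5 Hz
  isi_p <- rep(c(11, 12), 10)
  spikes <- cumsum(isi_p / 1.050)          # ms
  fi <- build_fi(spikes = spikes,
                 stim = make_square_pulse(5, 400, baseline_ms = 1))
  pl <- detect_plateaus(fi, dcc_rate = 1.050)
  expect_true(attr(pl, "plateau_flag"))
  expect_equal(round(pl$freq_hz, 1), c(95.5, 87.5))

  # Poisson trains: false-positive rate below 5%
  set.seed(7)
  fp <- mean(vapply(1:200, function(i) {
    isi <- stats::rexp(40, rate = 50 / 1000)   # ~50 Hz, ISIs in ms
    attr(detect_plateaus(isi * 1, dcc_rate = 1), "plateau_flag")
  }, logical(1)))
  expect_lt(fp, 0.05)
})

test_that("minimum-rate rule scales inversely with the time constant", {
  expect_equal(recommend_min_rate(4.0), 3.75)
  expect_equal(recommend_min_rate(2.1), 15 / 2.1)
  expect_gte(recommend_min_rate(2.1), 7)
  expect_equal(recommend_min_rate(5, cycles_per_tau = 20), 4)
  expect_error(recommend_min_rate(4, cycles_per_tau = 0))
  expect_error(recommend_min_rate(-1))
})
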