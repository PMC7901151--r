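#' Run a protocol across a set of DCC rates
#'
#' Repeats one full record-and-analyze cycle per switching rate and
#' collects the requested measurement. Seeds are offset per rate
#' (`seed + index`) so stochastic runs are replayable; results are
#' independent of the order in which rates are given and are returned
#' sorted by rate, with each measurement also normalized to its value at
#' the highest rate (the convention used for rate-dependence curves).
#'
#' @param neuron A [cell_params()] or [lif_params()].
#' @param electrode An [electrode_params()] or `NULL`.
#' @param rates DCC switching rates, kHz.
#' @param protocol A [stimulus()] (for `"metrics"`/`"ripple"`) or a list of
#'   stimuli from [make_resistance_series()] (for `"resistance"`).
#' @param measure One of `"metrics"` (F-I excitability metrics from a ramp),
#'   `"resistance"` (apparent input resistance from a pulse series) or
#'   `"ripple"` (steady-state ripple amplitude from a square pulse).
#' @param dt,seed Passed to [record()].
#' @param duty DCC duty cycle.
#' @param gain_window Current window for [fi_gain()] (default `"auto"`).
#' @param keep_traces Passed to [record()] for `"metrics"` runs (traces are
#'   only needed for the voltage threshold; disable to save memory).
#' @return A data frame with one row per rate. Failed runs are reported as
#'   `NA` rows with a warning, and the sweep continues.
#' @export
run_rate_sweep <- function(neuron, electrode = NULL, rates, protocol,
                           measure = c("metrics", "resistance", "ripple"),
                           dt = NULL, seed = NULL, duty = 1 / 3,
                           gain_window = "auto", keep_traces = TRUE) {
  measure <- match.arg(measure)
  ord <- order(rates)
  res <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    rate <- rates[i]
    amp <- amplifier_config("dcc", dcc_rate = rate, duty = duty)
    seed_i <- if (is.null(seed)) NULL else seed + i - 1L
    res[[i]] <- tryCatch({
      if (measure == "resistance") {
        recs <- lapply(protocol, function(st)
          record(neuron, electrode, amp, st, dt = dt, seed = seed_i))
        data.frame(rate = rate, value = apparent_input_resistance(recs))
      } else if (measure == "ripple") {
        rec <- record(neuron, electrode, amp, protocol, dt = dt,
                      seed = seed_i)
        data.frame(rate = rate, value = ripple_amplitude(rec))
      } else {
        rec <- record(neuron, electrode, amp, protocol, dt = dt,
                      seed = seed_i, keep_traces = keep_traces)
        fi <- build_fi(rec)
        oo <- onset_offset(fi, rec)
        nisi <- isi_normalized(rec$spike_times, rate)
        pl <- detect_plateaus(fi, rate)
        vth <- if (keep_traces && length(rec$spike_times) > 0)
          tryCatch(voltage_threshold(rec$V_amp, rec$dt,
                                     rec$spike_times[1]),
                   error = function(e) NA_real_)
        else NA_real_
        data.frame(rate = rate, onset = oo[["onset"]],
                   offset = oo[["offset"]],
                   gain = tryCatch(fi_gain(fi, gain_window),
                                   error = function(e) NA_real_),
                   v_threshold = vth,
                   n_spikes = length(rec$spike_times),
                   min_isi_periods = if (length(nisi)) min(nisi) else NA_real_,
                   entrainment = if (length(nisi))
                     entrainment_index(nisi) else NA_real_,
                   plateau_flag = attr(pl, "plateau_flag"))
      }
    }, error = function(e) {
      warning(sprintf("rate %g kHz failed: %s", rate, conditionMessage(e)))
      NULL
    })
  }
  keep <- !vapply(res, is.null, logical(1))
  out <- do.call(rbind, res[keep])
  out <- out[order(out$rate), , drop = FALSE]
  num <- setdiff(names(out)[vapply(out, is.numeric, logical(1))],
                 c("rate", "n_spikes", "plateau_flag"))
  ref <- out[nrow(out), ]
  for (cn in num) out[[paste0(cn, "_norm")]] <- out[[cn]] / ref[[cn]]
  rownames(out) <- NULL
  out
}

#' Demonstration recipes for the rig's artifact phenomena
#'
#' Self-contained reproductions of the rig's core phenomena, each returning
#' the objects it computed. Available recipes:
#'
#' * `"resistance-vs-rate"`: passive 5 MOhm / 5 ms cell with a 1 MOhm,
#'   25 us electrode, 1 nA pulses; apparent resistance against DCC rate
#'   from both simulation and the closed form, showing low-rate
#'   underestimation and high-rate electrode contamination.
#' * `"ripple"`: 2.5 MOhm / 3 ms passive cell, 10 nA; steady-state ripple
#'   amplitude against rate (simulated and closed form).
#' * `"entrainment"`: fast fatigable LIF (R_in 1.5 MOhm, tau_m 2 ms), 10 nA
#'   triangular ramp at 1 nA/s, DCC at the given rates (default 1, 3 and
#'   8 kHz); F-I curves, normalized-ISI summaries and plateau reports.
#' * `"gain-distortion"`: LIF with R_in 2.5 MOhm, tau_m 2 ms, fast 13 nA
#'   ramp at 5 nA/s; F-I gain measured in a lower and an upper current
#'   window at 3 vs 8 kHz, showing the artifactual steepening.
#' * `"spurious-firing"`: LIF with R_in 2.45 MOhm, tau_m 4.9 ms, 4 nA /
#'   200 ms pulse, subthreshold at steady state in Bridge
#'   (9.8 mV < V_th = 10 mV) yet driven to repetitive firing by the ripple
#'   crests at 1.5 kHz and silent at 8 kHz.
#'
#' @param name Recipe name (see above).
#' @param rates Optional DCC rates (kHz) overriding the recipe default.
#' @param seed RNG seed recorded with the runs (the default models are
#'   noiseless, so results are deterministic).
#' @return A list of results; see each recipe's `$` components.
#' @export
run_recipe <- function(name = c("resistance-vs-rate", "ripple",
                                "entrainment", "gain-distortion",
                                "spurious-firing"),
                       rates = NULL, seed = 1) {
  name <- match.arg(name)
  switch(name,
    "resistance-vs-rate" = {
      if (is.null(rates)) rates <- c(0.5, 1, 2, 3, 5, 8, 15, 25, 40)
      cell <- cell_params(R_in = 5, tau_m = 5)
      el <- electrode_params(R_e = 1, tau_e = 5 / 200)
      series <- make_resistance_series(c(-1, 1), duration_ms = 60,
                                      baseline_ms = 20)
      sim <- run_rate_sweep(cell, el, rates, series,
                            measure = "resistance", seed = seed)
      sim$closed_form <- apparent_resistance_total(
        R_cell = 5, tau_cell = 5, R_e = 1, tau_e = 5 / 200, rate = sim$rate)
      list(cell = cell, electrode = el, table = sim)
    },
    "ripple" = {
      if (is.null(rates)) rates <- c(1, 2, 3, 5, 8, 15)
      cell <- cell_params(R_in = 2.5, tau_m = 3)
      pulse <- make_square_pulse(10, 60, baseline_ms = 5)
      sim <- run_rate_sweep(cell, NULL, rates, pulse, measure = "ripple",
                            seed = seed)
      sim$closed_form <- steady_ripple(2.5, 3, 10, sim$rate)
      list(cell = cell, table = sim)
    },
    "entrainment" = {
      if (is.null(rates)) rates <- c(1, 3, 8)
      ff <- lif_params(G_in = 0.67, tau_m = 2)
      ramp <- make_triangular_ramp(slope = 1, peak = 10)
      sweep <- run_rate_sweep(ff, NULL, rates, ramp, measure = "metrics",
                              seed = seed, keep_traces = FALSE)
      recs <- lapply(rates, function(r)
        record(ff, NULL, amplifier_config("dcc", dcc_rate = r), ramp,
               keep_traces = FALSE))
      fis <- lapply(recs, build_fi)
      names(fis) <- as.character(rates)
      list(neuron = ff, stimulus = ramp, table = sweep, fi = fis)
    },
    "gain-distortion" = {
      if (is.null(rates)) rates <- c(3, 8)
      mn <- lif_params(R_in = 2.5, tau_m = 2)
      ramp <- make_triangular_ramp(slope = 5, peak = 13)
      fis <- lapply(rates, function(r) {
        rec <- record(mn, NULL, amplifier_config("dcc", dcc_rate = r),
                      ramp, keep_traces = FALSE)
        build_fi(rec)
      })
      names(fis) <- as.character(rates)
      gains <- lapply(fis, function(fi) c(
        lower = tryCatch(fi_gain(fi, c(6, 10)), error = function(e) NA_real_),
        upper = tryCatch(fi_gain(fi, c(10.5, 13)),
                         error = function(e) NA_real_)))
      list(neuron = mn, stimulus = ramp, fi = fis, gains = gains)
    },
    "spurious-firing" = {
      if (is.null(rates)) rates <- c(1.5, 8)
      mn <- lif_params(R_in = 2.45, tau_m = 4.9)
      pulse <- make_square_pulse(4, 200, baseline_ms = 50)
      runs <- lapply(c(list(amplifier_config("bridge")),
                       lapply(rates, function(r)
                         amplifier_config("dcc", dcc_rate = r))),
                     function(a) record(mn, NULL, a, pulse))
      names(runs) <- c("bridge", paste0("dcc_", rates))
      list(neuron = mn, stimulus = pulse, recordings = runs,
           n_spikes = vapply(runs, function(r) length(r$spike_times),
                             integer(1)))
    })
}
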