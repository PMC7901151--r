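#' Instantaneous DCC chopping of a commanded current
#'
#' In DCC mode the amplifier injects the commanded current as short pulses:
#' during the on-phase (the first `duty` fraction of each period) the
#' injected current is `I_com / duty` (3x the command for the standard duty
#' cycle of 1/3); during the rest of the period no current flows. The
#' period average therefore equals the command exactly for constant
#' commands.
#'
#' @param I_com Commanded current, nA.
#' @param t Time, ms (vectorized).
#' @param config An [amplifier_config()] in DCC mode.
#' @return Injected current at `t`, nA.
#' @examples
#' cfg <- amplifier_config("dcc", dcc_rate = 1)
#' chop_current(1, 0.1, cfg)  # on-phase: 3 nA
#' chop_current(1, 0.5, cfg)  # off-phase: 0 nA
#' @export
chop_current <- function(I_com, t, config) {
  stopifnot(inherits(config, "amp_config"))
  if (config$mode != "dcc") stop("chop_current requires DCC mode")
  if (config$duty <= 0 || config$duty >= 1) stop("duty must be in (0, 1)")
  if (any(t < 0)) stop("t must be >= 0")
  T_ms <- 1 / config$dcc_rate
  on <- (t %% T_ms) < config$duty * T_ms
  ifelse(on, I_com / config$duty, 0)
}

#' Sample-and-hold of a tip-potential trace
#'
#' Emulates the DCC amplifier's output stage: the continuous tip potential
#' is sampled once per DCC period (at fraction `sample_offset` of the
#' period) and the output held constant at the last sampled value until the
#' next sample. Before the first sample the output is the initial value of
#' the trace.
#'
#' @param V_total Tip-potential trace, mV, on a uniform grid.
#' @param dt Grid step, ms. Every sampling instant must fall on a grid
#'   point (within 1e-9 ms); otherwise an error is raised rather than
#'   silently interpolating.
#' @param config An [amplifier_config()] in DCC mode.
#' @return The held amplifier output, same length as `V_total`.
#' @export
sample_and_hold <- function(V_total, dt, config) {
  stopifnot(inherits(config, "amp_config"))
  if (config$mode != "dcc") stop("sample_and_hold requires DCC mode")
  n <- length(V_total)
  if (n == 0 || anyNA(V_total)) stop("V_total must be non-empty and free of NA")
  T_ms <- 1 / config$dcc_rate
  t_end <- (n - 1) * dt
  k <- seq_len(max(0, floor((t_end - config$sample_offset * T_ms) / T_ms) + 1))
  ts <- (k - 1) * T_ms + config$sample_offset * T_ms
  idx <- ts / dt
  if (any(abs(idx - round(idx)) > 1e-6))
    stop("sampling instants do not fall on the time grid")
  idx <- round(idx) + 1L
  out <- numeric(n)
  bounds <- c(1L, idx, n + 1L)
  vals <- c(V_total[1], V_total[idx])
  for (j in seq_along(vals))
    out[bounds[j]:(bounds[j + 1L] - 1L)] <- vals[j]
  if (length(idx) > 0 && idx[length(idx)] == n) out[n] <- V_total[n]
  out
}

#' Bridge-mode amplifier output
#'
#' Subtracts the estimated electrode IR drop from the tip potential:
#' `V_total - bridge_balance * I_com`. With `bridge_balance` equal to the
#' electrode resistance and a linear electrode this recovers the membrane
#' potential exactly.
#'
#' @param V_total Tip potential, mV.
#' @param I_com Commanded (= injected) current, nA.
#' @param config An [amplifier_config()] in Bridge mode.
#' @return Amplifier output, mV.
#' @export
bridge_output <- function(V_total, I_com, config) {
  stopifnot(inherits(config, "amp_config"))
  if (config$mode != "bridge") stop("bridge_output requires Bridge mode")
  V_total - config$bridge_balance * I_com
}

# internal: choose the integration grid. In DCC mode the period is an
# integer number of steps, the on-phase boundary and the sampling instant
# exact grid points, and the realized duty equals the requested one.
dcc_grid <- function(config, tau_e = NULL, dt = NULL) {
  dt_target <- if (is.null(dt)) {
    min(if (!is.null(tau_e)) tau_e / 5 else Inf, 0.005)
  } else dt
  if (config$mode == "bridge")
    return(list(dt = dt_target, n_per = 0L, on_steps = 0L, sample_step = 0L))
  T_ms <- 1 / config$dcc_rate
  dt_target <- min(dt_target, T_ms / 30)
  n_per <- max(3L, as.integer(ceiling(T_ms / dt_target)))
  ok <- function(n) abs(config$duty * n - round(config$duty * n)) < 1e-9 &&
    round(config$duty * n) >= 1
  n_try <- n_per
  while (!ok(n_try) && n_try < n_per + 1000L) n_try <- n_try + 1L
  if (ok(n_try)) n_per <- n_try   # else: nearest representable duty
  on_steps <- max(1L, as.integer(round(config$duty * n_per)))
  sample_step <- as.integer(round(config$sample_offset * n_per))
  if (sample_step <= on_steps) sample_step <- on_steps + 1L
  if (sample_step > n_per) sample_step <- n_per
  list(dt = T_ms / n_per, n_per = n_per, on_steps = on_steps,
       sample_step = sample_step)
}

#' Simulate a current-clamp recording
#'
#' Co-integrates a neuron model (passive cell or LIF+AHP motoneuron) and,
#' optionally, a series RC electrode, driven by a stimulus through the
#' amplifier: in Bridge mode the command is injected continuously; in DCC
#' mode it is chopped (period-wise charge-conserving on-phase pulses) and
#' the output is sampled-and-held at the configured offset of each period.
#' Spike detection in the LIF model operates on the true membrane
#' potential, never on the amplifier output.
#'
#' Integration uses exact exponential stepping for the linear elements and
#' exponential Euler (AHP conductance frozen within the step) for the LIF,
#' on a grid chosen as `dt = min(tau_e/5, T_dcc/30, 0.005 ms)` and snapped
#' so that DCC phase boundaries and sampling instants are exact grid
#' points.
#'
#' @param neuron A [cell_params()] or [lif_params()] object.
#' @param electrode An [electrode_params()] object, or `NULL` for an ideal
#'   (electrode-free) recording.
#' @param amp An [amplifier_config()].
#' @param stim A [stimulus()].
#' @param dt Optional integration step override, ms.
#' @param seed Optional RNG seed (only relevant when `neuron$sigma > 0`).
#' @param duration_ms Simulated window, ms; defaults to the stimulus
#'   duration.
#' @param keep_traces Keep the full traces (`TRUE`, default) or only spike
#'   times and scalars (`FALSE`, saves memory on long runs).
#' @return An object of class `dcc_recording`: a list with the time base
#'   `time` (ms), traces `I_com`, `I_inj` (nA), `V_m`, `V_total`, `V_amp`
#'   (mV), `spike_times` (ms), the integration step `dt`, and echoes of the
#'   configuration (`neuron`, `electrode`, `amp`, `stim`, `seed`).
#' @examples
#' cp <- cell_params(R_in = 5, tau_m = 5)
#' el <- electrode_params(R_e = 1, tau_e = 0.025)
#' rec <- record(cp, el, amplifier_config("dcc", dcc_rate = 1),
#'               make_square_pulse(1, 40, baseline_ms = 5))
#' print(rec)
#' @export
record <- function(neuron, electrode = NULL, amp, stim, dt = NULL,
                   seed = NULL, duration_ms = NULL, keep_traces = TRUE) {
  stopifnot(inherits(neuron, c("cell_params", "lif_params")),
            inherits(amp, "amp_config"), inherits(stim, "stimulus"))
  if (!is.null(electrode)) {
    stopifnot(inherits(electrode, "electrode_params"))
    if (electrode$tau_e > neuron$tau_m / 10)
      warning("electrode time constant is not much faster than the membrane",
              " (tau_e > tau_m/10); DCC sampling will be contaminated")
  }
  lif <- inherits(neuron, "lif_params")
  grid <- dcc_grid(amp, tau_e = if (!is.null(electrode)) electrode$tau_e,
                   dt = dt)
  if (is.null(duration_ms)) duration_ms <- stim_duration(stim)
  n_steps <- as.integer(ceiling(duration_ms / grid$dt))
  cellp <- if (lif) {
    c(neuron$G_in, neuron$tau_m, neuron$V_r, neuron$V_th, neuron$g_ahp_max,
      neuron$E_K, neuron$tau_ahp, neuron$alpha, neuron$sigma,
      neuron$V_reset, neuron$t_refractory, neuron$spike_peak,
      neuron$spike_width)
  } else {
    c(neuron$G_in, neuron$tau_m, neuron$V0)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- .sim_record(
    neuron_kind = as.integer(lif), cellp = cellp,
    has_electrode = !is.null(electrode),
    Ge = if (is.null(electrode)) 0 else electrode$G_e,
    taue = if (is.null(electrode)) 1 else electrode$tau_e,
    mode = as.integer(amp$mode == "dcc"),
    n_per = grid$n_per, on_steps = grid$on_steps,
    sample_step = grid$sample_step,
    bridge_balance = amp$bridge_balance,
    seg = stim_matrix(stim), dt = grid$dt, n_steps = n_steps,
    keep_traces = keep_traces)
  out <- list(
    time = if (keep_traces) seq(0, by = grid$dt, length.out = n_steps + 1L),
    I_com = res$I_com, I_inj = res$I_inj, V_m = res$V_m,
    V_total = res$V_total, V_amp = res$V_amp,
    spike_times = res$spike_times,
    dt = grid$dt, n_per = grid$n_per, on_steps = grid$on_steps,
    V_end = res$V_end, V_held = res$V_held,
    neuron = neuron, electrode = electrode, amp = amp, stim = stim,
    seed = seed)
  class(out) <- "dcc_recording"
  out
}

#' @export
print.dcc_recording <- function(x, ...) {
  mode <- if (x$amp$mode == "dcc")
    sprintf("DCC %g kHz (duty %.3g)", x$amp$dcc_rate, x$amp$duty)
  else "Bridge"
  dur <- if (is.null(x$time)) NA_real_ else x$time[length(x$time)]
  cat(sprintf("<dcc_recording> %s, dt = %g ms, %s, %d spike(s)\n",
              mode, x$dt,
              if (is.na(dur)) "traces not kept" else sprintf("%g ms", dur),
              length(x$spike_times)))
  cat(sprintf("  neuron: %s; electrode: %s\n",
              if (inherits(x$neuron, "lif_params")) "LIF+AHP" else "passive RC",
              if (is.null(x$electrode)) "none (ideal)"
              else sprintf("%g MOhm / %g ms", x$electrode$R_e,
                           x$electrode$tau_e)))
  invisible(x)
}

#' @export
as.data.frame.dcc_recording <- function(x, ...) {
  if (is.null(x$time) || length(x$I_com) == 0)
    stop("recording was made with keep_traces = FALSE")
  data.frame(t_ms = x$time, I_com_nA = x$I_com, I_inj_nA = x$I_inj,
             V_m_mV = x$V_m, V_total_mV = x$V_total, V_amp_mV = x$V_amp)
}

#' Plot a recording
#'
#' Two stacked panels: injected/commanded current and the voltage traces
#' (true membrane potential, tip potential, amplifier output).
#'
#' @param x A `dcc_recording`.
#' @param xlim Optional time window, ms.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dcc_recording <- function(x, xlim = NULL, ...) {
  if (is.null(x$time)) stop("recording was made with keep_traces = FALSE")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  keep <- if (is.null(xlim)) TRUE else x$time >= xlim[1] & x$time <= xlim[2]
  graphics::plot(x$time[keep], x$V_total[keep], type = "l", col = "grey60",
                 xlab = "time (ms)", ylab = "V (mV)", ...)
  graphics::lines(x$time[keep], x$V_m[keep], col = "forestgreen")
  graphics::lines(x$time[keep], x$V_amp[keep], col = "black", lwd = 1.5)
  graphics::legend("topright", c("V_total", "V_m", "V_amp"), lty = 1,
                   col = c("grey60", "forestgreen", "black"), bty = "n",
                   cex = 0.8)
  graphics::plot(x$time[keep], x$I_inj[keep], type = "l", col = "grey60",
                 xlab = "time (ms)", ylab = "I (nA)")
  graphics::lines(x$time[keep], x$I_com[keep], col = "black")
  invisible(x)
}
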