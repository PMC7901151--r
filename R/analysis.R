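#' Detect spikes on a voltage trace by dV/dt threshold crossing
#'
#' Finds the times at which the centered-difference slope of the voltage
#' crosses `dvdt_threshold` upward (the standard 10 V/s criterion),
#' debounced so that two detections closer than `min_isi` count as one. The
#' crossing time is refined by linear sub-sample interpolation.
#'
#' Note that on raw DCC membrane traces at low switching rates the ripples
#' themselves can exceed 10 V/s, in which case slope-based detection is
#' unreliable (as it is on real recordings, which must then be scanned
#' manually); `min_v` restricts detections to crossings whose voltage
#' subsequently exceeds a floor within 1 ms.
#'
#' @param V Voltage trace, mV, on a uniform grid.
#' @param dt Grid step, ms.
#' @param dvdt_threshold Slope threshold in V/s (= mV/ms).
#' @param min_isi Debounce interval, ms.
#' @param min_v Optional voltage floor, mV: a crossing only counts if `V`
#'   reaches `min_v` within 1 ms after it.
#' @return Spike times, ms.
#' @export
detect_spikes <- function(V, dt, dvdt_threshold = 10, min_isi = 2,
                          min_v = NULL) {
  if (length(V) < 3 || anyNA(V)) stop("V must have >= 3 finite samples")
  n <- length(V)
  dvdt <- c(NA, (V[3:n] - V[1:(n - 2)]) / (2 * dt), NA)
  up <- which(dvdt[-n] < dvdt_threshold & dvdt[-1] >= dvdt_threshold)
  if (length(up) == 0) return(numeric(0))
  frac <- (dvdt_threshold - dvdt[up]) / (dvdt[up + 1] - dvdt[up])
  times <- (up - 1 + frac) * dt
  if (!is.null(min_v)) {
    look <- max(1L, round(1 / dt))
    keep <- vapply(up, function(i) {
      max(V[i:min(n, i + look)]) >= min_v
    }, logical(1))
    times <- times[keep]
  }
  if (length(times) <= 1) return(times)
  out <- times[1]
  for (tt in times[-1]) if (tt - out[length(out)] >= min_isi) out <- c(out, tt)
  out
}

#' Voltage threshold of a spike
#'
#' Returns the membrane potential at the point where the slope of the
#' voltage crosses `dvdt_threshold` (10 V/s by convention) upward,
#' immediately preceding `spike_time` — the "foot" of the spike.
#'
#' @param V Voltage trace, mV, uniform grid.
#' @param dt Grid step, ms.
#' @param spike_time Spike time, ms.
#' @param dvdt_threshold Slope criterion, V/s.
#' @param window_ms How far before `spike_time` to search, ms.
#' @param lookahead_ms How far past `spike_time` the search may extend, ms.
#'   On a sampled-and-held trace the spike upstroke appears only at the
#'   first sample taken on the spike, up to one DCC period late; the
#'   default covers about one action-potential width.
#' @return Voltage threshold, mV.
#' @export
voltage_threshold <- function(V, dt, spike_time, dvdt_threshold = 10,
                              window_ms = 10, lookahead_ms = 1) {
  n <- length(V)
  i_spk <- min(n, max(2L, as.integer(round(spike_time / dt)) + 1L))
  i_lo <- max(2L, i_spk - as.integer(ceiling(window_ms / dt)))
  i_hi <- min(i_spk + as.integer(ceiling(lookahead_ms / dt)), n - 1L)
  idx <- i_lo:i_hi
  dvdt <- (V[idx + 1L] - V[idx - 1L]) / (2 * dt)
  cross <- which(dvdt[-length(dvdt)] < dvdt_threshold &
                   dvdt[-1] >= dvdt_threshold)
  if (length(cross) == 0) {
    # slope already above threshold throughout the window: take its start
    if (all(dvdt >= dvdt_threshold)) return(V[idx[1]])
    stop("no upward dV/dt crossing found before spike_time")
  }
  i <- idx[cross[length(cross)]]
  frac <- (dvdt_threshold - dvdt[cross[length(cross)]]) /
    (dvdt[cross[length(cross)] + 1] - dvdt[cross[length(cross)]])
  V[i] + frac * (V[i + 1L] - V[i])
}

#' Build the frequency-current (F-I) curve of a recording
#'
#' For every spike after the first, the instantaneous firing frequency is
#' the reciprocal of the preceding interspike interval, paired with the
#' commanded current at the spike time and tagged as belonging to the
#' ascending or descending phase of the ramp (split at the stimulus apex;
#' for non-ramp stimuli all points are tagged ascending).
#'
#' @param recording A [record()] result, or `NULL` if `spikes` and `stim`
#'   are given explicitly.
#' @param spikes Spike times, ms (defaults to the recording's).
#' @param stim A [stimulus()] (defaults to the recording's).
#' @return An object of class `fi_curve`: a data frame with columns `time`
#'   (ms), `I` (nA), `freq` (Hz) and `phase` (`"ascending"`/`"descending"`).
#' @export
build_fi <- function(recording = NULL, spikes = NULL, stim = NULL) {
  if (!is.null(recording)) {
    stopifnot(inherits(recording, "dcc_recording"))
    if (is.null(spikes)) spikes <- recording$spike_times
    if (is.null(stim)) stim <- recording$stim
  }
  if (is.null(spikes) || is.null(stim))
    stop("need a recording, or explicit spikes and stim")
  if (length(spikes) < 2) {
    out <- data.frame(time = numeric(0), I = numeric(0), freq = numeric(0),
                      phase = character(0))
    class(out) <- c("fi_curve", "data.frame")
    return(out)
  }
  spikes <- sort(spikes)
  isi <- diff(spikes)
  tt <- spikes[-1]
  seg <- stim$segments
  up <- seg[seg$kind == "ramp" & seg$slope > 0, , drop = FALSE]
  apex <- if (nrow(up) > 0) max(up$start + up$duration) else Inf
  out <- data.frame(time = tt, I = stim_current(stim, tt),
                    freq = 1000 / isi,
                    phase = ifelse(tt <= apex, "ascending", "descending"))
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("<fi_curve> %d point(s)", nrow(x)))
  if (nrow(x) > 0)
    cat(sprintf(", I in [%.3g, %.3g] nA, f in [%.3g, %.3g] Hz",
                min(x$I), max(x$I), min(x$freq), max(x$freq)))
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Plot an F-I curve
#' @param x An `fi_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fi_curve <- function(x, ...) {
  asc <- x$phase == "ascending"
  graphics::plot(x$I[asc], x$freq[asc], pch = 16, col = "black",
                 xlab = "I (nA)", ylab = "instantaneous frequency (Hz)",
                 xlim = range(x$I), ylim = range(x$freq), ...)
  graphics::points(x$I[!asc], x$freq[!asc], pch = 1, col = "grey50")
  invisible(x)
}

#' Onset and offset currents of a triangular-ramp response
#'
#' The onset current is the commanded current at the first spike of the
#' ascending phase; the offset current is the current at the last spike of
#' the descending phase. A missing phase yields `NA` for that value.
#'
#' @param fi An `fi_curve` from [build_fi()], or a recording (in which case
#'   the F-I curve is built first, so the first spike of the train is
#'   included via its own time).
#' @param recording Optionally, the recording, to recover the very first
#'   spike (which has no preceding ISI and hence no F-I point).
#' @return Named numeric vector `c(onset = , offset = )`, nA.
#' @export
onset_offset <- function(fi, recording = NULL) {
  if (inherits(fi, "dcc_recording")) {
    recording <- fi
    fi <- build_fi(recording)
  }
  stopifnot(inherits(fi, "fi_curve"))
  onset <- NA_real_
  if (!is.null(recording) && length(recording$spike_times) > 0) {
    first <- min(recording$spike_times)
    onset <- stim_current(recording$stim, first)
  } else if (any(fi$phase == "ascending")) {
    onset <- fi$I[fi$phase == "ascending"][1]
  }
  offset <- if (any(fi$phase == "descending")) {
    desc <- fi[fi$phase == "descending", ]
    desc$I[which.max(desc$time)]
  } else NA_real_
  c(onset = onset, offset = offset)
}

#' Gain of the F-I relationship
#'
#' Least-squares slope of instantaneous frequency against commanded current
#' over the ascending phase, restricted to a current window. The reported
#' gain should come from a user-chosen window covering the most linear part
#' of the ascending curve (the primary range); `window = "auto"` instead
#' scans contiguous spans covering at least 30% of the ascending points and
#' picks the best-R^2 one — a labelled heuristic, not a measurement
#' definition.
#'
#' @param fi An `fi_curve`.
#' @param window Numeric `c(lo, hi)` current window in nA, or `"auto"`.
#' @return Gain in Hz/nA.
#' @export
fi_gain <- function(fi, window = "auto") {
  stopifnot(inherits(fi, "fi_curve"))
  asc <- fi[fi$phase == "ascending", , drop = FALSE]
  if (identical(window, "auto")) {
    n <- nrow(asc)
    if (n < 5) stop("too few ascending points for auto window")
    asc <- asc[order(asc$I), ]
    span <- max(3L, ceiling(0.3 * n))
    best <- NULL; best_r2 <- -Inf
    for (i in seq_len(n - span + 1L)) {
      sub <- asc[i:(i + span - 1L), ]
      f <- stats::lm(freq ~ I, data = sub)
      ss_tot <- sum((sub$freq - mean(sub$freq))^2)
      r2 <- if (ss_tot > 0) 1 - sum(stats::resid(f)^2) / ss_tot else 1
      if (is.finite(r2) && r2 > best_r2) { best_r2 <- r2; best <- f }
    }
    return(unname(stats::coef(best)[2]))
  }
  stopifnot(is.numeric(window), length(window) == 2)
  sub <- asc[asc$I >= window[1] & asc$I <= window[2], , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 ascending points in the gain window")
  unname(stats::coef(stats::lm(freq ~ I, data = sub))[2])
}

#' Apparent input resistance from a square-pulse series
#'
#' Runs the standard measurement on a list of recordings obtained with
#' [make_resistance_series()] stimuli: for each pulse, the peak response is
#' the extremum deviation of the amplifier output from its pre-pulse
#' baseline within the pulse window; the apparent resistance is the
#' least-squares slope of peak response against pulse amplitude.
#'
#' @param recordings A list of [record()] results, one per pulse amplitude
#'   (each recording's stimulus must be a single square pulse).
#' @return Apparent input resistance, MOhm.
#' @export
apparent_input_resistance <- function(recordings) {
  stopifnot(length(recordings) >= 2)
  pk <- vapply(recordings, function(r) {
    stopifnot(inherits(r, "dcc_recording"))
    seg <- r$stim$segments
    pulse <- seg[seg$value != 0 | seg$slope != 0, , drop = FALSE]
    if (nrow(pulse) != 1) stop("each recording must hold one square pulse")
    t0 <- pulse$start; t1 <- pulse$start + pulse$duration
    base <- mean(r$V_amp[r$time < t0])
    # end-exclusive: at the off-transition node the command is already zero
    # while the electrode IR drop has not yet decayed
    dv <- r$V_amp[r$time >= t0 & r$time < t1] - base
    c(amp = pulse$value, peak = dv[which.max(abs(dv))])
  }, numeric(2))
  unname(stats::coef(stats::lm(pk["peak", ] ~ pk["amp", ]))[2])
}

#' Membrane time constant from the relaxation after a short pulse
#'
#' Fits a single exponential (log-linear regression of `|V - V0|` against
#' time) to the relaxation of the membrane potential after a brief current
#' pulse. The first `discard_ms` of the relaxation can be discarded to let
#' the (much faster) electrode component decay when fitting combined
#' cell-plus-electrode traces.
#'
#' @param recording A [record()] result whose stimulus is a single short
#'   pulse (e.g. [make_short_pulse()]).
#' @param discard_ms Initial portion of the relaxation to discard, ms.
#' @param fit_span_ms Length of relaxation fitted, ms (default `5 * tau`
#'   heuristic: fits until the deviation is small; concretely 4x the
#'   neuron's nominal time constant, falling back to 20 ms for external
#'   traces).
#' @param trace Which trace to fit, `"V_amp"` (default) or `"V_m"`.
#' @return Estimated time constant, ms.
#' @export
estimate_time_constant <- function(recording, discard_ms = 0,
                                   fit_span_ms = NULL, trace = "V_amp") {
  stopifnot(inherits(recording, "dcc_recording"))
  seg <- recording$stim$segments
  pulse <- seg[seg$value != 0 | seg$slope != 0, , drop = FALSE]
  if (nrow(pulse) != 1) stop("stimulus must contain exactly one pulse")
  t1 <- pulse$start + pulse$duration
  V0 <- if (inherits(recording$neuron, "lif_params"))
    recording$neuron$V_r else recording$neuron$V0
  if (is.null(fit_span_ms))
    fit_span_ms <- 4 * (recording$neuron$tau_m %||% 20)
  keep <- recording$time >= t1 + discard_ms &
    recording$time <= t1 + discard_ms + fit_span_ms
  v <- abs(recording[[trace]][keep] - V0)
  tt <- recording$time[keep]
  ok <- v > max(v) * 1e-4
  if (sum(ok) < 10) stop("relaxation too short to fit")
  fit <- stats::lm(log(v[ok]) ~ tt[ok])
  -1 / unname(stats::coef(fit)[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Steady-state ripple amplitude measured on a recording
#'
#' Mean, over the complete DCC periods inside the window, of the
#' peak-to-trough excursion of the true membrane potential within each
#' period. In Bridge mode under constant current this is 0.
#'
#' @param recording A [record()] result.
#' @param window Numeric `c(lo, hi)` time window, ms; defaults to the last
#'   quarter of the recording.
#' @return Ripple amplitude, mV.
#' @export
ripple_amplitude <- function(recording, window = NULL) {
  stopifnot(inherits(recording, "dcc_recording"))
  if (is.null(recording$time)) stop("needs keep_traces = TRUE")
  t_end <- recording$time[length(recording$time)]
  if (is.null(window)) window <- c(0.75 * t_end, t_end)
  if (recording$amp$mode == "bridge") {
    v <- recording$V_m[recording$time >= window[1] &
                         recording$time <= window[2]]
    return(max(v) - min(v))
  }
  T_ms <- 1 / recording$amp$dcc_rate
  k0 <- ceiling(window[1] / T_ms)
  k1 <- floor(window[2] / T_ms) - 1
  if (k1 < k0) stop("window contains no complete DCC period")
  n_per <- recording$n_per
  amp <- vapply(k0:k1, function(k) {
    i <- (k * n_per + 1L):((k + 1L) * n_per + 1L)
    v <- recording$V_m[i]
    max(v) - min(v)
  }, numeric(1))
  mean(amp)
}

#' Interspike intervals normalized by the DCC period
#'
#' @param spikes Spike times, ms.
#' @param dcc_rate DCC switching rate, kHz.
#' @return Numeric vector of ISI / T_DCC (empty when fewer than 2 spikes).
#' @export
isi_normalized <- function(spikes, dcc_rate) {
  stopifnot(dcc_rate > 0)
  if (length(spikes) < 2) return(numeric(0))
  diff(sort(spikes)) * dcc_rate
}

#' Fraction of normalized ISIs locked to the DCC clock
#'
#' The entrainment index is the fraction of normalized interspike intervals
#' lying within `tol` of an integer number of DCC periods. A perfectly
#' entrained train scores 1; intervals uniformly spread over one period
#' score about `2 * tol`.
#'
#' @param nisi Normalized ISIs from [isi_normalized()] (non-empty).
#' @param tol Tolerance around integers, in periods.
#' @return Fraction in `[0, 1]`.
#' @export
entrainment_index <- function(nisi, tol = 0.05) {
  if (length(nisi) == 0) stop("no interspike intervals")
  mean(abs(nisi - round(nisi)) <= tol)
}

#' Detect DCC-entrained plateaus in an F-I curve
#'
#' Plateaus are discrete steps in the instantaneous firing frequency at
#' subharmonics `rate / k` of the DCC switching rate, the signature of
#' firing entrained to the DCC clock. Detection works on the interspike
#' intervals expressed in DCC periods: for each integer `k` up to `k_max`,
#' ISIs within `tol` periods of `k` are pooled, and `k` is reported as a
#' plateau when at least `min_count` ISIs lock to it. Reported plateau
#' frequencies are the subharmonics `rate / k` in Hz.
#'
#' `k_max` encodes resolvability: beyond roughly 20 periods per ISI the
#' spacing between adjacent subharmonics (`~rate/k^2`) is smaller than the
#' natural variability of a discharge, so entrainment — even if present —
#' produces no visible steps; plateaus are a low-`k` phenomenon that
#' appears as the firing rate approaches the DCC rate.
#'
#' @param fi An `fi_curve` (its `freq` column is inverted to ISIs), or a
#'   numeric vector of normalized ISIs.
#' @param dcc_rate DCC switching rate, kHz.
#' @param tol Lock-in tolerance, DCC periods.
#' @param min_count Minimum number of ISIs locked to one subharmonic.
#' @param k_max Largest ISI (in DCC periods) that counts as a resolvable
#'   plateau.
#' @return A data frame with columns `k`, `freq_hz` (`= 1000 * dcc_rate /
#'   k`), `count`, plus attribute `plateau_flag` (any plateau found);
#'   zero rows when none.
#' @export
detect_plateaus <- function(fi, dcc_rate, tol = 0.1, min_count = 4,
                            k_max = 20) {
  stopifnot(dcc_rate > 0)
  nisi <- if (inherits(fi, "fi_curve")) {
    (1000 / fi$freq) * dcc_rate
  } else as.numeric(fi)
  out <- data.frame(k = integer(0), freq_hz = numeric(0), count = integer(0))
  if (length(nisi) > 0) {
    k <- round(nisi)
    locked <- abs(nisi - k) <= tol & k >= 1 & k <= k_max
    if (any(locked)) {
      tab <- table(k[locked])
      keep <- tab >= min_count
      if (any(keep)) {
        kk <- as.integer(names(tab)[keep])
        out <- data.frame(k = kk, freq_hz = 1000 * dcc_rate / kk,
                          count = as.integer(tab[keep]))
        out <- out[order(out$k), ]
        rownames(out) <- NULL
      }
    }
  }
  attr(out, "plateau_flag") <- nrow(out) > 0
  out
}

#' Minimum recommended DCC switching rate for a cell
#'
#' The DCC switching rate must provide at least `cycles_per_tau` cycles per
#' membrane time constant for excitability measurements to match
#' Bridge-mode values; 15-20 cycles per time constant is the recommended
#' range (the older 10-cycle rule of thumb is too permissive). Hence the
#' minimum rate is `cycles_per_tau / tau_m` kHz: a slow motoneuron with
#' `tau_m = 4 ms` can be recorded at 3.75 kHz and above, while a fast
#' fatigable motoneuron with `tau_m = 2.1 ms` needs about 7 kHz or more.
#'
#' @param tau_m Membrane time constant, ms (> 0). Vectorized.
#' @param cycles_per_tau Required DCC cycles per time constant (> 0).
#' @return Minimum DCC rate, kHz.
#' @examples
#' recommend_min_rate(4.0)   # 3.75 kHz
#' recommend_min_rate(2.1)   # ~7.14 kHz
#' @export
recommend_min_rate <- function(tau_m, cycles_per_tau = 15) {
  if (any(!is.finite(tau_m)) || any(tau_m <= 0)) stop("tau_m must be > 0")
  if (!is.finite(cycles_per_tau) || cycles_per_tau <= 0)
    stop("cycles_per_tau must be > 0")
  cycles_per_tau / tau_m
}
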