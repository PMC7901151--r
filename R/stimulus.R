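#' Piecewise stimulus describing the commanded current
#'
#' A stimulus is a contiguous, non-overlapping sequence of segments, each
#' either constant or a linear ramp, describing the commanded current
#' `I_com(t)` (nA) over time (ms). Outside the described window the command
#' is 0 nA.
#'
#' @param segments A data frame with columns `kind` (`"constant"` or
#'   `"ramp"`), `start` (ms), `duration` (ms), `value` (nA at segment start)
#'   and `slope` (nA/ms, 0 for constant segments).
#' @return An object of class `stimulus`.
#' @seealso [make_triangular_ramp()], [make_short_pulse()],
#'   [make_resistance_series()]
#' @export
stimulus <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("kind", "start", "duration", "value", "slope")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  stopifnot(all(segments$duration > 0),
            all(segments$kind %in% c("constant", "ramp")))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1) {
    ends <- segments$start[-1] - utils::head(segments$start + segments$duration, -1)
    if (any(abs(ends) > 1e-9))
      stop("segments must be contiguous and non-overlapping")
  }
  rownames(segments) <- NULL
  structure(list(segments = segments), class = "stimulus")
}

#' Evaluate the commanded current of a stimulus
#'
#' @param stim A [stimulus()].
#' @param t Times in ms (vectorized).
#' @return Commanded current `I_com(t)` in nA.
#' @export
stim_current <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus"))
  seg <- stim$segments
  out <- numeric(length(t))
  for (j in seq_len(nrow(seg))) {
    in_seg <- t >= seg$start[j] & t < seg$start[j] + seg$duration[j]
    if (any(in_seg))
      out[in_seg] <- seg$value[j] + seg$slope[j] * (t[in_seg] - seg$start[j])
  }
  out
}

#' Total duration of a stimulus description, ms
#' @param stim A [stimulus()].
#' @export
stim_duration <- function(stim) {
  seg <- stim$segments
  max(seg$start + seg$duration)
}

#' Analytic charge carried by a stimulus, nA ms
#'
#' Integrates the commanded current over its whole description from the
#' segment geometry (trapezoids), independent of any time grid.
#' @param stim A [stimulus()].
#' @export
stim_charge <- function(stim) {
  seg <- stim$segments
  sum(seg$duration * (seg$value + seg$slope * seg$duration / 2))
}

# internal: matrix form consumed by the compiled integrator
stim_matrix <- function(stim) {
  seg <- stim$segments
  cbind(kind = as.numeric(seg$kind == "ramp"), start = seg$start,
        duration = seg$duration, a = seg$value, b = seg$slope)
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("Stimulus: %d segment(s), %g ms, charge %g nA.ms\n",
              nrow(x$segments), stim_duration(x), stim_charge(x)))
  print(x$segments)
  invisible(x)
}

#' Symmetric triangular current ramp
#'
#' Builds the classic excitability protocol: a slow triangular ramp of
#' current rising at `slope` nA/s to `peak` nA and back down at the same
#' rate, flanked by zero-current baselines. The ramp lasts
#' `2 * peak / slope` seconds.
#'
#' @param slope Ramp speed in nA/s (> 0).
#' @param peak Ramp apex in nA (> 0).
#' @param baseline_ms Quiescent baseline before and after the ramp, ms.
#' @return A [stimulus()].
#' @examples
#' ramp <- make_triangular_ramp(slope = 1, peak = 10)  # 20 s triangle
#' stim_current(ramp, 1000 + 10000)  # apex: 10 nA
#' @export
make_triangular_ramp <- function(slope, peak, baseline_ms = 1000) {
  stopifnot(slope > 0, peak > 0, baseline_ms > 0)
  s <- slope / 1000            # nA/ms
  half <- peak / s             # ms
  segs <- data.frame(
    kind = c("constant", "ramp", "ramp", "constant"),
    start = c(0, baseline_ms, baseline_ms + half, baseline_ms + 2 * half),
    duration = c(baseline_ms, half, half, baseline_ms),
    value = c(0, 0, peak, 0),
    slope = c(0, s, -s, 0))
  stimulus(segs)
}

#' Square current pulse
#'
#' @param amplitude Pulse amplitude, nA (may be negative).
#' @param duration_ms Pulse duration, ms (> 0).
#' @param baseline_ms Baseline before and after the pulse, ms.
#' @return A [stimulus()].
#' @export
make_square_pulse <- function(amplitude, duration_ms, baseline_ms = 1000) {
  stopifnot(duration_ms > 0, baseline_ms >= 0)
  segs <- data.frame(
    kind = "constant",
    start = c(0, baseline_ms, baseline_ms + duration_ms),
    duration = c(baseline_ms, duration_ms, baseline_ms),
    value = c(0, amplitude, 0),
    slope = 0)
  stimulus(segs[segs$duration > 0, , drop = FALSE])
}

#' Series of square pulses for input-resistance measurement
#'
#' One stimulus per amplitude, each a square pulse with common duration and
#' baselines. The defaults reproduce the standard input-resistance protocol:
#' small-amplitude pulses from -3 to +3 nA, 500 ms long.
#'
#' @param amplitudes Pulse amplitudes in nA (non-empty).
#' @param duration_ms Common pulse duration, ms.
#' @param baseline_ms Baseline before and after each pulse, ms.
#' @return A named list of [stimulus()] objects (names = amplitudes).
#' @export
make_resistance_series <- function(amplitudes = c(-3, -2, -1, 1, 2, 3),
                                   duration_ms = 500, baseline_ms = 1000) {
  if (length(amplitudes) == 0) stop("need at least one amplitude")
  out <- lapply(amplitudes, make_square_pulse, duration_ms = duration_ms,
                baseline_ms = baseline_ms)
  names(out) <- as.character(amplitudes)
  out
}

#' Short current pulse for time-constant measurement
#'
#' The membrane time constant is measured on the relaxation of the membrane
#' potential after a brief pulse; the default reproduces the standard
#' -5 nA, 1 ms hyperpolarizing pulse.
#'
#' @param amplitude Pulse amplitude, nA.
#' @param duration_ms Pulse duration, ms.
#' @param baseline_ms Baseline before and after, ms.
#' @return A [stimulus()].
#' @export
make_short_pulse <- function(amplitude = -5, duration_ms = 1,
                             baseline_ms = 100) {
  make_square_pulse(amplitude, duration_ms, baseline_ms)
}
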