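#' Steady-state sampled-voltage ratio of an RC element under chopped current
#'
#' For a linear RC element (resistance `R`, time constant `tau`) driven by a
#' charge-conserving chopped current (period `T`, on-phase `duty * T` at
#' amplitude `I/duty`), the membrane settles into a periodic sawtooth. This
#' returns the ratio `rho` of the voltage sampled at fraction
#' `sample_offset` of the period to the Bridge-mode steady state `I * R`.
#'
#' With `V1` the crest at the end of the on-phase and period-end
#' self-consistency, the sampled ratio is
#' `rho = (1/duty) * (1 - exp(-duty*T/tau)) * exp(-(sample_offset - duty)*T/tau) / (1 - exp(-T/tau))`.
#' For `duty = 1/3` and end-of-period sampling this reduces to
#' `3 (1 - e^{-T/3tau}) e^{-2T/3tau} / (1 - e^{-T/tau})`. `rho -> 1` as
#' `T/tau -> 0` (DCC converges to Bridge) and decreases monotonically with
#' `T/tau`: too-slow switching undersamples the decayed membrane and
#' underestimates the IR drop.
#'
#' @param T_ms DCC period, ms (> 0). Vectorized.
#' @param tau Element time constant, ms (> 0).
#' @param duty On-phase fraction of the period, in (0, 1).
#' @param sample_offset Sampling instant as a fraction of the period, in
#'   (duty, 1].
#' @return The unitless ratio `rho`.
#' @examples
#' steady_sampled_ratio(1, 1)    # T = tau: ~0.691
#' steady_sampled_ratio(0.2, 1)  # 5 cycles per tau: ~0.934
#' @export
steady_sampled_ratio <- function(T_ms, tau, duty = 1 / 3,
                                 sample_offset = 1) {
  stopifnot(all(T_ms > 0), tau > 0, duty > 0, duty < 1,
            sample_offset > duty, sample_offset <= 1)
  x <- T_ms / tau
  (1 / duty) * (1 - exp(-duty * x)) * exp(-(sample_offset - duty) * x) /
    (1 - exp(-x))
}

#' Steady-state ripple amplitude of the membrane potential under DCC
#'
#' Under chopped current the true membrane potential oscillates between a
#' crest at the end of each on-phase and a trough at the end of the period
#' ("ripples", hidden from the experimenter by the sample-and-hold). At
#' steady state the peak-to-trough amplitude is
#' `ripple = V_s * (exp((1 - duty) * T / tau) - 1)` with
#' `V_s = I * R * rho(T, tau, duty)` the end-of-period sampled voltage.
#' Ripples are linear in `I * R`, grow steeply as the rate decreases, and
#' vanish as the rate goes to infinity.
#'
#' @param R Element resistance, MOhm.
#' @param tau Time constant, ms.
#' @param I Commanded current, nA.
#' @param rate DCC switching rate, kHz (> 0). Vectorized.
#' @param duty On-phase fraction.
#' @return Ripple amplitude, mV.
#' @examples
#' steady_ripple(2.5, 3, 10, 1)  # ~5.5 mV at 1 kHz
#' steady_ripple(2.5, 3, 10, 5)  # ~1.1 mV at 5 kHz
#' @export
steady_ripple <- function(R, tau, I, rate, duty = 1 / 3) {
  stopifnot(all(rate > 0))
  T_ms <- 1 / rate
  Vs <- I * R * steady_sampled_ratio(T_ms, tau, duty = duty,
                                     sample_offset = 1)
  Vs * (exp((1 - duty) * T_ms / tau) - 1)
}

#' Apparent input resistance of cell plus electrode under DCC
#'
#' The cell and the electrode are linear RC elements in series sharing the
#' injected current, so the sampled steady-state voltage superposes:
#' `R_app = R_cell * rho(T, tau_cell) + R_e * rho(T, tau_e)`. At low rates
#' the electrode term has fully decayed (rho_e ~ 0) and the cell term makes
#' the apparent resistance fall below `R_cell`; at high rates the electrode
#' IR drop no longer settles before sampling and the apparent resistance
#' rises above `R_cell`, producing the characteristic U-shape against rate.
#'
#' @param R_cell,tau_cell Cell resistance (MOhm) and time constant (ms).
#' @param R_e,tau_e Electrode resistance (MOhm) and time constant (ms).
#'   `R_e = 0` gives the cell-only curve.
#' @param rate DCC rate, kHz. Vectorized.
#' @param duty,sample_offset As in [steady_sampled_ratio()].
#' @return Apparent resistance, MOhm.
#' @export
apparent_resistance_total <- function(R_cell, tau_cell, R_e = 0,
                                      tau_e = tau_cell / 200, rate,
                                      duty = 1 / 3, sample_offset = 1) {
  T_ms <- 1 / rate
  out <- R_cell * steady_sampled_ratio(T_ms, tau_cell, duty, sample_offset)
  if (R_e != 0)
    out <- out + R_e * steady_sampled_ratio(T_ms, tau_e, duty, sample_offset)
  out
}

#' Passive response to a current ramp under continuous injection
#'
#' Closed-form membrane response of a passive cell, from rest, to a linear
#' current ramp of speed `slope` (nA/s) injected continuously (Bridge):
#' `V(t) = R * slope * (t - tau * (1 - exp(-t/tau)))` with `t` in seconds.
#' At `t >> tau` the response parallels the instantaneous `I * R` line with
#' a constant lag `R * slope * tau`.
#'
#' @param R Cell resistance, MOhm.
#' @param tau Time constant, ms.
#' @param slope Ramp speed, nA/s.
#' @param t_s Time since ramp onset, s. Vectorized.
#' @return Membrane depolarization from rest, mV.
#' @export
ramp_response_passive <- function(R, tau, slope, t_s) {
  tau_s <- tau / 1000
  R * slope * (t_s - tau_s * (1 - exp(-t_s / tau_s)))
}
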