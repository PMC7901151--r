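#' Passive cell parameters
#'
#' Describes a neuron's passive membrane as a single RC compartment with
#' input conductance `G_in` (uS), membrane time constant `tau_m` (ms) and
#' resting potential `V0` (mV). The membrane capacitance is derived as
#' `C = G_in * tau_m` (nF) and the input resistance as `R_in = 1/G_in`
#' (MOhm); neither is stored independently.
#'
#' @param G_in Input conductance in uS. Must be positive. Exactly one of
#'   `G_in` and `R_in` may be given.
#' @param tau_m Membrane time constant in ms. Must be positive.
#' @param V0 Resting potential in mV.
#' @param R_in Input resistance in MOhm, as an alternative to `G_in`.
#' @return An object of class `cell_params`.
#' @examples
#' cp <- cell_params(R_in = 5, tau_m = 5)
#' cp$C  # 1 nF: G_in * tau_m = 0.2 uS * 5 ms
#' @export
cell_params <- function(G_in = NULL, tau_m, V0 = 0, R_in = NULL) {
  if (is.null(G_in) == is.null(R_in))
    stop("give exactly one of 'G_in' and 'R_in'")
  if (is.null(G_in)) G_in <- 1 / R_in
  stopifnot(is.finite(G_in), G_in > 0, is.finite(tau_m), tau_m > 0,
            is.finite(V0))
  structure(list(G_in = G_in, tau_m = tau_m, V0 = V0,
                 R_in = 1 / G_in, C = G_in * tau_m),
            class = "cell_params")
}

#' Microelectrode parameters
#'
#' The sharp microelectrode is modelled as a linear RC element in series
#' with the cell: conductance `G_e` (uS, resistance `R_e = 1/G_e` MOhm) and
#' effective time constant `tau_e` (ms). DCC recording relies on `tau_e`
#' being much faster than the membrane time constant so that the electrode's
#' IR drop has vanished by sampling time.
#'
#' @param G_e Electrode conductance in uS (or give `R_e`).
#' @param tau_e Effective electrode time constant in ms.
#' @param R_e Electrode resistance in MOhm, alternative to `G_e`.
#' @return An object of class `electrode_params`.
#' @export
electrode_params <- function(G_e = NULL, tau_e, R_e = NULL) {
  if (is.null(G_e) == is.null(R_e))
    stop("give exactly one of 'G_e' and 'R_e'")
  if (is.null(G_e)) G_e <- 1 / R_e
  stopifnot(is.finite(G_e), G_e > 0, is.finite(tau_e), tau_e > 0)
  structure(list(G_e = G_e, tau_e = tau_e, R_e = 1 / G_e),
            class = "electrode_params")
}

#' Integrate-and-fire motoneuron with AHP conductance
#'
#' Parameters of a leaky integrate-and-fire model with a spike-triggered
#' afterhyperpolarization (AHP) conductance. The membrane obeys
#' `C dV/dt = G_in (V_r - V) + g_ahp_max * z * (E_K - V) + I + noise`, where
#' `z` in `[0, 1]` is the open fraction of the AHP conductance, relaxing as
#' `dz/dt = -z/tau_ahp` between spikes. A spike is elicited when `V` crosses
#' `V_th` from below; at each spike `z` is incremented instantaneously to
#' `(1 - alpha) * z + alpha` (see [apply_spike_reset()]), the membrane is
#' set to `V_reset`, and an absolute refractory period `t_refractory`
#' applies. The AHP dynamics during the spike itself are not modelled.
#'
#' Default conductances follow the motoneuron-type convention used
#' throughout: `G_in` 0.2, 0.4 and 0.67 uS for slow (S), fast
#' fatigue-resistant (FR) and fast fatigable (FF) motoneurons.
#'
#' @param G_in Input conductance, uS (or `R_in`, MOhm).
#' @param tau_m Membrane time constant, ms.
#' @param V_r Resting potential, mV.
#' @param V_th Spike threshold, mV.
#' @param g_ahp_max Maximal AHP conductance, uS.
#' @param E_K AHP reversal potential, mV.
#' @param tau_ahp AHP relaxation time constant, ms.
#' @param alpha Fraction of the AHP recruited by a single spike, in (0, 1].
#' @param sigma Current-noise amplitude, nA (standard deviation scale of a
#'   white-noise current; per-step SD is `sigma/sqrt(dt)`). 0 disables noise.
#' @param V_reset Post-spike membrane potential, mV (default `V_r`).
#' @param t_refractory Absolute refractory period, ms.
#' @param spike_peak Rendering amplitude (mV) of the spike marker drawn
#'   into stored voltage traces; the model itself has no spike shape.
#' @param spike_width Rendered spike duration, ms (about an action-potential
#'   width, so that the sampled amplifier output contains spikes the way
#'   real recordings do). Rendering only; the dynamics are unaffected.
#' @param R_in Input resistance in MOhm, alternative to `G_in`.
#' @return An object of class `lif_params`.
#' @examples
#' ff <- lif_params(G_in = 0.67, tau_m = 2)   # fast fatigable motoneuron
#' s  <- lif_params(G_in = 0.2, tau_m = 5)    # slow motoneuron
#' @export
lif_params <- function(G_in = NULL, tau_m, V_r = 0, V_th = 10,
                       g_ahp_max = 2, E_K = -5, tau_ahp = 10, alpha = 0.25,
                       sigma = 0, V_reset = V_r, t_refractory = 1,
                       spike_peak = 40, spike_width = 1, R_in = NULL) {
  if (is.null(G_in) == is.null(R_in))
    stop("give exactly one of 'G_in' and 'R_in'")
  if (is.null(G_in)) G_in <- 1 / R_in
  stopifnot(is.finite(G_in), G_in > 0, is.finite(tau_m), tau_m > 0,
            tau_ahp > 0, alpha > 0, alpha <= 1, V_th > V_r,
            sigma >= 0, t_refractory >= 0, spike_width >= 0)
  structure(list(G_in = G_in, tau_m = tau_m, V_r = V_r, V_th = V_th,
                 g_ahp_max = g_ahp_max, E_K = E_K, tau_ahp = tau_ahp,
                 alpha = alpha, sigma = sigma, V_reset = V_reset,
                 t_refractory = t_refractory, spike_peak = spike_peak,
                 spike_width = spike_width,
                 R_in = 1 / G_in, C = G_in * tau_m),
            class = "lif_params")
}

#' Amplifier configuration
#'
#' Describes the recording mode of the amplifier. In `"bridge"` mode the
#' commanded current is injected continuously and the output is the tip
#' potential minus `bridge_balance * I_com` (the Bridge circuit subtracting
#' the electrode's IR drop). In `"dcc"` mode the command is chopped into
#' pulses of duration `duty` of the DCC period, scaled by `1/duty` to
#' conserve charge, and the output is the tip potential sampled at fraction
#' `sample_offset` of each period and held until the next sample.
#'
#' @param mode `"bridge"` or `"dcc"`.
#' @param dcc_rate DCC switching rate in kHz (required in DCC mode).
#' @param duty Fraction of the period during which current flows, in (0, 1).
#' @param sample_offset Fraction of the period at which the voltage is
#'   sampled; must satisfy `duty < sample_offset <= 1`. 1 samples at the end
#'   of the period.
#' @param bridge_balance Resistance (MOhm) subtracted in Bridge mode.
#' @return An object of class `amp_config`.
#' @examples
#' amplifier_config("dcc", dcc_rate = 8)
#' amplifier_config("bridge", bridge_balance = 1)
#' @export
amplifier_config <- function(mode = c("bridge", "dcc"), dcc_rate = NULL,
                             duty = 1 / 3, sample_offset = 1,
                             bridge_balance = 0) {
  mode <- match.arg(mode)
  stopifnot(duty > 0, duty < 1, sample_offset > duty, sample_offset <= 1)
  if (mode == "dcc") {
    if (is.null(dcc_rate) || !is.finite(dcc_rate) || dcc_rate <= 0)
      stop("DCC mode requires a positive 'dcc_rate' (kHz)")
  }
  structure(list(mode = mode, dcc_rate = dcc_rate, duty = duty,
                 sample_offset = sample_offset,
                 bridge_balance = bridge_balance),
            class = "amp_config")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("Passive cell: R_in = %g MOhm (G_in = %g uS), tau_m = %g ms, V0 = %g mV\n",
              x$R_in, x$G_in, x$tau_m, x$V0))
  invisible(x)
}

#' @export
print.electrode_params <- function(x, ...) {
  cat(sprintf("Electrode: R_e = %g MOhm, tau_e = %g ms\n", x$R_e, x$tau_e))
  invisible(x)
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF+AHP motoneuron: R_in = %g MOhm, tau_m = %g ms, V_th = %g mV\n",
    x$R_in, x$tau_m, x$V_th))
  cat(sprintf("  AHP: g_max = %g uS, E_K = %g mV, tau = %g ms, alpha = %g\n",
              x$g_ahp_max, x$E_K, x$tau_ahp, x$alpha))
  cat(sprintf("  reset: V_reset = %g mV, refractory = %g ms, sigma = %g nA\n",
              x$V_reset, x$t_refractory, x$sigma))
  invisible(x)
}

#' @export
print.amp_config <- function(x, ...) {
  if (x$mode == "bridge") {
    cat(sprintf("Amplifier: Bridge mode, balance = %g MOhm\n",
                x$bridge_balance))
  } else {
    cat(sprintf(
      "Amplifier: DCC mode, %g kHz, duty = %.3g, sample offset = %g\n",
      x$dcc_rate, x$duty, x$sample_offset))
  }
  invisible(x)
}
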