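#' Exact exponential update of a passive RC membrane
#'
#' Advances the membrane potential of a passive cell by one step of `dt`
#' under a current `I` held constant over the step, using the closed-form
#' solution of the linear ODE `C dV/dt = G (V0 - V) + I`:
#' `V(t + dt) = V_inf + (V - V_inf) exp(-dt/tau)` with
#' `V_inf = V0 + I/G`. There is no discretization error for constant `I`,
#' and composing `n` substeps equals one step of `n*dt` exactly.
#'
#' @param V Membrane potential at the start of the step, mV.
#' @param params A [cell_params()] object.
#' @param I Injected current over the step, nA.
#' @param dt Step duration, ms (> 0).
#' @return Membrane potential at the end of the step, mV.
#' @examples
#' cp <- cell_params(G_in = 0.2, tau_m = 5)
#' step_passive(0, cp, I = 1, dt = 5)  # 5 * (1 - exp(-1)) mV
#' @export
step_passive <- function(V, params, I, dt) {
  stopifnot(inherits(params, "cell_params"))
  if (!all(is.finite(c(V, I, dt))) || dt <= 0)
    stop("step_passive needs finite V, I and dt > 0")
  V_inf <- params$V0 + I / params$G_in
  V_inf + (V - V_inf) * exp(-dt / params$tau_m)
}

#' Neuron state for the integrate-and-fire model
#'
#' @param V_m Membrane potential, mV.
#' @param z Open fraction of the AHP conductance, in `[0, 1]`.
#' @param t_last_spike Time of the last spike, ms, or `-Inf` if none.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V_m = 0, z = 0, t_last_spike = -Inf) {
  stopifnot(z >= 0, z <= 1)
  structure(list(V_m = V_m, z = z, t_last_spike = t_last_spike),
            class = "neuron_state")
}

#' One exponential-Euler step of the LIF+AHP model
#'
#' Advances the integrate-and-fire state by `dt` under a constant current.
#' The AHP open fraction decays as `z * exp(-dt/tau_ahp)`; the membrane is
#' updated by exponential Euler with the total conductance
#' `G_in + g_ahp_max * z` frozen at its start-of-step value. A spike is
#' flagged iff `V` crosses `V_th` from below within the step and the
#' absolute refractory period has elapsed; the spike time is linearly
#' interpolated within the step, and [apply_spike_reset()] is applied.
#'
#' @param state A [neuron_state()].
#' @param params A [lif_params()] object.
#' @param I Injected current over the step, nA. When `params$sigma > 0`,
#'   `noise_draw` adds `sigma/sqrt(dt) * noise_draw` nA.
#' @param dt Step duration, ms (> 0).
#' @param t Time at the start of the step, ms (used for the refractory
#'   bookkeeping and the interpolated spike time).
#' @param noise_draw A standard-normal draw (ignored when `sigma = 0`).
#' @return A list with elements `state` (the new [neuron_state()]),
#'   `spike` (logical) and `spike_time` (ms or `NA`).
#' @export
step_lif_ahp <- function(state, params, I, dt, t = 0, noise_draw = 0) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "lif_params"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  p <- params
  if (p$sigma > 0) I <- I + p$sigma / sqrt(dt) * noise_draw
  G_tot <- p$G_in + p$g_ahp_max * state$z
  V_inf <- (p$G_in * p$V_r + p$g_ahp_max * state$z * p$E_K + I) / G_tot
  V_new <- V_inf + (state$V_m - V_inf) * exp(-dt * G_tot / p$C)
  z_new <- state$z * exp(-dt / p$tau_ahp)
  spike <- FALSE
  spike_time <- NA_real_
  t_last <- state$t_last_spike
  if (state$V_m <= p$V_th && V_new > p$V_th) {
    ts <- t + dt * (p$V_th - state$V_m) / (V_new - state$V_m)
    if (ts - t_last >= p$t_refractory) {
      spike <- TRUE
      spike_time <- ts
      st <- apply_spike_reset(neuron_state(V_new, z_new, t_last), p)
      st$t_last_spike <- ts
      return(list(state = st, spike = TRUE, spike_time = ts))
    }
  }
  list(state = neuron_state(V_new, z_new, t_last),
       spike = spike, spike_time = spike_time)
}

#' Instantaneous AHP increment and membrane reset at a spike
#'
#' At each spike the open fraction of the AHP conductance is incremented
#' instantaneously: `z_after = (1 - alpha) * z_before + alpha`, where
#' `alpha` is the fraction of the AHP recruited by a single spike. This
#' update keeps `z` in `[0, 1]` (with fixed point `z = 1` under sustained
#' firing: after `n` spikes from rest, `z = 1 - (1 - alpha)^n`). The
#' membrane potential is set to `V_reset`.
#'
#' @param state A [neuron_state()] just before the spike.
#' @param params A [lif_params()] object.
#' @return The post-spike [neuron_state()]. `t_last_spike` is not modified
#'   here; [step_lif_ahp()] stamps it with the interpolated spike time.
#' @examples
#' p <- lif_params(G_in = 0.67, tau_m = 2)
#' apply_spike_reset(neuron_state(V_m = 10, z = 0), p)$z  # 0.25
#' @export
apply_spike_reset <- function(state, params) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "lif_params"))
  neuron_state(V_m = params$V_reset,
               z = (1 - params$alpha) * state$z + params$alpha,
               t_last_spike = state$t_last_spike)
}
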