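# Shared fixtures: canonical cells and a plain-R fine-step reference
# integrator, independent of the package's exponential stepping.

passive_cell <- function() cell_params(R_in = 5, tau_m = 5)
std_electrode <- function() electrode_params(R_e = 1, tau_e = 5 / 200)
ff_motoneuron <- function(...) lif_params(G_in = 0.67, tau_m = 2, ...)
s_motoneuron <- function(...) lif_params(G_in = 0.2, tau_m = 5, ...)

# explicit forward-Euler reference for the passive membrane
euler_passive <- function(V, params, I, t_total, dt = 1e-4) {
  n <- round(t_total / dt)
  G <- params$G_in; C <- params$C; V0 <- params$V0
  for (i in seq_len(n)) V <- V + dt * (G * (V0 - V) + I) / C
  V
}

# explicit forward-Euler reference for the LIF+AHP model under constant
# current (no voltage reset, refractory as given); returns spike times
euler_lif_spikes <- function(params, I, t_total, dt = 5e-4) {
  p <- params
  n <- round(t_total / dt)
  V <- p$V_r; z <- 0; t_last <- -Inf
  spikes <- numeric(0)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    dV <- (p$G_in * (p$V_r - V) + p$g_ahp_max * z * (p$E_K - V) + I) / p$C
    Vn <- V + dt * dV
    z <- z * (1 - dt / p$tau_ahp)
    if (V <= p$V_th && Vn > p$V_th && (t - t_last) >= p$t_refractory) {
      spikes <- c(spikes, t)
      z <- (1 - p$alpha) * z + p$alpha
      Vn <- p$V_reset
      t_last <- t
    }
    V <- Vn
  }
  spikes
}

# standard entrainment experiment: FF motoneuron, 10 nA triangular ramp at
# 1 nA/s, recorded in DCC at the given rate
ff_ramp_recording <- function(rate_khz, sigma = 0, seed = NULL) {
  record(ff_motoneuron(sigma = sigma), NULL,
         amplifier_config("dcc", dcc_rate = rate_khz),
         make_triangular_ramp(slope = 1, peak = 10),
         keep_traces = FALSE, seed = seed)
}
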