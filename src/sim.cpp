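#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise stimulus evaluation. seg columns: kind (0 constant, 1 ramp),
// start (ms), duration (ms), a (nA at segment start), b (nA/ms).
static inline double stim_eval(const NumericMatrix& seg, double t) {
  int n = seg.nrow();
  for (int j = 0; j < n; ++j) {
    double t0 = seg(j, 1), dur = seg(j, 2);
    if (t >= t0 && t < t0 + dur) {
      if (seg(j, 0) == 0.0) return seg(j, 3);
      return seg(j, 3) + seg(j, 4) * (t - t0);
    }
  }
  // past the last segment (or before the first): baseline current
  return 0.0;
}

// Co-integrates the cell and (optionally) the electrode driven by the
// amplifier's injected current. Exact exponential stepping for the linear
// elements; exponential Euler with the AHP conductance frozen within each
// step for the LIF. All times in ms, currents in nA, voltages in mV,
// conductances in uS (so R = 1/G is MOhm and C = G*tau is nF).
//
// neuron_kind: 0 passive RC, 1 LIF+AHP
// cellp passive: G, tau, V0
// cellp lif: G, tau, Vr, Vth, gahp, EK, tauahp, alpha, sigma, Vreset, tref,
//            spike_peak, spike_width (trace rendering only)
// mode: 0 Bridge, 1 DCC. In DCC mode the period is n_per grid steps, the
// on-phase the first on_steps of them, and the sample is taken at grid
// point sample_step of each period (sample_step == n_per -> period end).
// [[Rcpp::export(name = ".sim_record")]]
List sim_record(int neuron_kind, NumericVector cellp,
                bool has_electrode, double Ge, double taue,
                int mode, int n_per, int on_steps, int sample_step,
                double bridge_balance,
                NumericMatrix seg, double dt, int n_steps,
                bool keep_traces) {
  const bool lif = neuron_kind == 1;
  const double G    = cellp[0];
  const double tau  = cellp[1];
  const double Vr   = cellp[2];           // V0 for passive
  const double C    = G * tau;
  double Vth = 0, gahp = 0, EK = 0, tauahp = 1, alpha = 0, sigma = 0,
         Vreset = 0, tref = 0, spike_peak = 0, spike_width = 0;
  if (lif) {
    Vth = cellp[3]; gahp = cellp[4]; EK = cellp[5]; tauahp = cellp[6];
    alpha = cellp[7]; sigma = cellp[8]; Vreset = cellp[9]; tref = cellp[10];
    spike_peak = cellp[11]; spike_width = cellp[12];
  }
  const double Re = has_electrode ? 1.0 / Ge : 0.0;
  const double Ee = has_electrode ? std::exp(-dt / taue) : 0.0;
  const double Ez = lif ? std::exp(-dt / tauahp) : 0.0;
  const double Em = std::exp(-dt / tau);          // passive-cell factor
  const double noise_sd = (lif && sigma > 0) ? sigma / std::sqrt(dt) : 0.0;

  int nt = keep_traces ? (n_steps + 1) : 0;
  NumericVector tr_Icom(nt), tr_Iinj(nt), tr_Vm(nt), tr_Vtot(nt), tr_Vamp(nt);
  std::vector<double> spikes;

  double V = Vr, z = 0.0, Ve = 0.0, held = Vr;
  double t_last = R_NegInf, render_until = R_NegInf;
  double Icom0 = stim_eval(seg, 0.0);
  if (keep_traces) {
    tr_Icom[0] = Icom0;
    tr_Iinj[0] = (mode == 1) ? 0.0 : Icom0;  // DCC charge not yet committed
    tr_Vm[0] = Vr; tr_Vtot[0] = Vr;
    tr_Vamp[0] = (mode == 1) ? Vr : Vr - bridge_balance * Icom0;
  }

  double Ion = 0.0;  // current injected during the on-phase of this period
  const double on_time = on_steps * dt;

  if (noise_sd > 0) GetRNGstate();

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    double Icom_mid = stim_eval(seg, t + 0.5 * dt);
    double Iinj;
    if (mode == 1) {
      int phase = i % n_per;
      if (phase == 0) {
        // commit this period's commanded charge to its on-phase
        double Q = 0.0;
        for (int j = 0; j < n_per; ++j)
          Q += stim_eval(seg, t + (j + 0.5) * dt) * dt;
        Ion = Q / on_time;
      }
      Iinj = (phase < on_steps) ? Ion : 0.0;
    } else {
      Iinj = Icom_mid;
    }

    if (has_electrode) {
      double Veinf = Iinj * Re;
      Ve = Veinf + (Ve - Veinf) * Ee;
    }

    double Icell = Iinj;
    if (noise_sd > 0) Icell += noise_sd * norm_rand();

    double Vnew;
    if (!lif) {
      double Vinf = Vr + Icell / G;
      Vnew = Vinf + (V - Vinf) * Em;
    } else {
      double Gtot = G + gahp * z;
      double Vinf = (G * Vr + gahp * z * EK + Icell) / Gtot;
      Vnew = Vinf + (V - Vinf) * std::exp(-dt * Gtot / C);
      double znew = z * Ez;
      if (V <= Vth && Vnew > Vth) {
        double ts = t + dt * (Vth - V) / (Vnew - V);
        if (ts - t_last >= tref) {
          spikes.push_back(ts);
          znew = (1.0 - alpha) * znew + alpha;
          Vnew = Vreset;
          t_last = ts;
          render_until = ts + spike_width;
        }
      }
      z = znew;
    }
    V = Vnew;
    if (!R_finite(V) || (has_electrode && !R_finite(Ve)))
      stop("simulation diverged (non-finite voltage) at t = %f ms", t);

    // spike marker rendered into the stored traces (the model itself has
    // no spike shape); dynamics use V, never the marker
    double Vm_out = (t + dt <= render_until) ? spike_peak : V;
    if (keep_traces) {
      double Vtot = Vm_out + Ve;
      tr_Icom[i + 1] = stim_eval(seg, t + dt);
      tr_Iinj[i + 1] = Iinj;
      tr_Vm[i + 1] = Vm_out;
      tr_Vtot[i + 1] = Vtot;
      if (mode == 1) {
        if ((i + 1) % n_per == sample_step % n_per) held = Vtot;
        tr_Vamp[i + 1] = held;
      } else {
        tr_Vamp[i + 1] = Vtot - bridge_balance * tr_Icom[i + 1];
      }
    } else if (mode == 1 && (i + 1) % n_per == sample_step % n_per) {
      held = Vm_out + Ve;  // keep the held value current even without traces
    }
  }

  if (noise_sd > 0) PutRNGstate();

  return List::create(
    _["I_com"] = tr_Icom, _["I_inj"] = tr_Iinj, _["V_m"] = tr_Vm,
    _["V_total"] = tr_Vtot, _["V_amp"] = tr_Vamp,
    _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
    _["V_end"] = V, _["z_end"] = z, _["Ve_end"] = Ve,
    _["V_held"] = held);
}
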