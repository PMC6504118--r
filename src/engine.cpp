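// Fixed-grid integrator for the adaptive LIF microcircuit with
// conductance-based receptor kinetics.
//
// Receptor conductances are maintained as banks of exponentially decaying
// state variables (four components per receptor, exact per-step decay);
// spike arrivals add jumps so that superposition of single-spike waveforms
// is reproduced exactly on the grid. Within a step the conductances (and
// the NMDA gating factor, evaluated at the step's initial V) are held
// fixed and the membrane potential / adaptation current pair is advanced
// with a classical RK4 step.
//
// Units: mV, ms, nS, pF, pA.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double nmda_gate(double V, double mg) {
  return 1.0 / (1.0 + (mg / 3.57) * std::exp(-0.062 * V));
}

// [[Rcpp::export]]
List engine_run(NumericMatrix npar,      // N x 8: EL Vth Vr gl Cm a b tau_w
                IntegerVector tref_steps,
                IntegerVector class_id,  // 0=E 1=I1 2=I2
                LogicalVector pre_exc,   // polarity of each neuron as a source
                NumericMatrix rec_coef,  // 12 x 4 (class*4+rec), g_bar folded in
                NumericMatrix rec_decay, // 12 x 4, exp(-dt/tau)
                NumericVector rec_erev,  // 12
                LogicalVector rec_nmda,  // 12
                IntegerVector ptr,       // CSR over presynaptic neurons, N+1
                IntegerVector epost,     // 0-based targets
                NumericVector ew,
                IntegerVector edelay,    // in steps, >= 1
                NumericVector bg_lambda, // per-neuron Poisson mean per step
                NumericVector bg_w,
                NumericVector I_const,
                NumericVector u,         // input signal (may be empty)
                double rho_u,
                int u_steps,             // grid steps per input step
                IntegerVector targets,   // 0-based injected-current targets
                IntegerVector ext_step,  // sorted external spike steps
                IntegerVector ext_target,
                NumericVector ext_w,
                LogicalVector ext_exc,
                int n_steps, double dt, double mg,
                NumericVector V0, NumericVector W0,
                int rec_every,
                IntegerVector rec_v_idx, // 0-based; may be empty
                IntegerVector rec_c_idx, // neurons for current/conductance traces
                bool record_currents, bool record_gtot) {
  const int N = npar.nrow();
  int maxd = 1;
  for (int e = 0; e < edelay.size(); ++e)
    if (edelay[e] > maxd) maxd = edelay[e];
  const int D = maxd + 2;

  std::vector<double> x(16 * N, 0.0);          // receptor components
  std::vector<double> pend_exc((size_t)D * N, 0.0), pend_inh((size_t)D * N, 0.0);
  std::vector<double> V(N), W(N);
  std::vector<int> refr(N, 0);
  std::vector<char> is_target(N, 0);
  for (int k = 0; k < targets.size(); ++k) is_target[targets[k]] = 1;

  for (int i = 0; i < N; ++i) { V[i] = V0[i]; W[i] = W0[i]; }

  // recording setup
  const int n_samp = rec_every > 0 ? n_steps / rec_every : 0;
  NumericMatrix Vm(rec_v_idx.size() > 0 ? rec_v_idx.size() : 0, n_samp);
  const int nc = rec_c_idx.size();
  NumericMatrix Iexc(record_currents ? nc : 0, n_samp);
  NumericMatrix Iinh(record_currents ? nc : 0, n_samp);
  NumericMatrix Gtot(record_gtot ? nc : 0, n_samp);
  std::vector<int> cpos(N, -1), vpos(N, -1);
  for (int k = 0; k < nc; ++k) cpos[rec_c_idx[k]] = k;
  for (int k = 0; k < rec_v_idx.size(); ++k) vpos[rec_v_idx[k]] = k;

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> fired;
  fired.reserve(256);

  int ext_ptr = 0;
  const int n_ext = ext_step.size();
  const bool have_u = u.size() > 0 && rho_u != 0.0 && u_steps > 0;

  for (int s = 0; s < n_steps; ++s) {
    const int slot = s % D;
    double *pe = &pend_exc[(size_t)slot * N];
    double *pi = &pend_inh[(size_t)slot * N];

    // external (forced) spikes scheduled for this step
    while (ext_ptr < n_ext && ext_step[ext_ptr] == s) {
      const int tgt = ext_target[ext_ptr];
      if (ext_exc[ext_ptr]) pe[tgt] += ext_w[ext_ptr];
      else pi[tgt] += ext_w[ext_ptr];
      ++ext_ptr;
    }

    // background Poisson bombardment (collapsed K_in sources per neuron)
    for (int i = 0; i < N; ++i) {
      if (bg_lambda[i] > 0.0) {
        const double cnt = R::rpois(bg_lambda[i]);
        if (cnt > 0.0) pe[i] += cnt * bg_w[i];
      }
    }

    const double u_now = have_u ? rho_u * u[std::min((int)(s / u_steps),
                                                     (int)u.size() - 1)] : 0.0;

    fired.clear();
    for (int i = 0; i < N; ++i) {
      double *xi = &x[16 * i];
      const int cls = class_id[i];

      // deliver pending arrivals: jumps on receptor components
      const double ae = pe[i], ai = pi[i];
      if (ae != 0.0) {
        const int rA = cls * 4 + 0, rN = cls * 4 + 1;
        for (int c = 0; c < 4; ++c) {
          xi[0 * 4 + c] += ae * rec_coef(rA, c);
          xi[1 * 4 + c] += ae * rec_coef(rN, c);
        }
      }
      if (ai != 0.0) {
        const int rGa = cls * 4 + 2, rGb = cls * 4 + 3;
        for (int c = 0; c < 4; ++c) {
          xi[2 * 4 + c] += ai * rec_coef(rGa, c);
          xi[3 * 4 + c] += ai * rec_coef(rGb, c);
        }
      }
      pe[i] = 0.0; pi[i] = 0.0;

      // conductances held for this step
      const double gA  = xi[0] + xi[1] + xi[2] + xi[3];
      const double gN  = xi[4] + xi[5] + xi[6] + xi[7];
      const double gGa = xi[8] + xi[9] + xi[10] + xi[11];
      const double gGb = xi[12] + xi[13] + xi[14] + xi[15];

      const double EL = npar(i, 0), Vth = npar(i, 1), Vr = npar(i, 2);
      const double gl = npar(i, 3), Cm = npar(i, 4);
      const double a = npar(i, 5), b = npar(i, 6), tw = npar(i, 7);
      const double eA = rec_erev[cls * 4 + 0], eN = rec_erev[cls * 4 + 1];
      const double eGa = rec_erev[cls * 4 + 2], eGb = rec_erev[cls * 4 + 3];

      const double Iinj = I_const[i] + (is_target[i] ? u_now : 0.0);

      if (refr[i] > 0) {
        // clamped at reset; adaptation relaxes toward a*(Vr - EL) exactly
        V[i] = Vr;
        const double wininf = a * (Vr - EL);
        W[i] = wininf + (W[i] - wininf) * std::exp(-dt / tw);
        --refr[i];
      } else {
        const double gate = nmda_gate(V[i], mg);
        const double gNe = gN * gate;
        // dV/dt = (P - Q V - W)/Cm with conductances fixed
        const double Q = gl + gA + gNe + gGa + gGb;
        const double P = gl * EL + gA * eA + gNe * eN + gGa * eGa +
                         gGb * eGb + Iinj;
        double v = V[i], w = W[i];
        const double h = dt;
        double k1v = (P - Q * v - w) / Cm;
        double k1w = (-w + a * (v - EL)) / tw;
        double v2 = v + 0.5 * h * k1v, w2 = w + 0.5 * h * k1w;
        double k2v = (P - Q * v2 - w2) / Cm;
        double k2w = (-w2 + a * (v2 - EL)) / tw;
        double v3 = v + 0.5 * h * k2v, w3 = w + 0.5 * h * k2w;
        double k3v = (P - Q * v3 - w3) / Cm;
        double k3w = (-w3 + a * (v3 - EL)) / tw;
        double v4 = v + h * k3v, w4 = w + h * k3w;
        double k4v = (P - Q * v4 - w4) / Cm;
        double k4w = (-w4 + a * (v4 - EL)) / tw;
        v += h / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
        w += h / 6.0 * (k1w + 2 * k2w + 2 * k3w + k4w);
        if (!std::isfinite(v) || !std::isfinite(w))
          stop("numerical divergence in membrane state at t = %f ms",
               (s + 1) * dt);
        V[i] = v; W[i] = w;
        if (v >= Vth) {
          spike_t.push_back((s + 1) * dt);
          spike_id.push_back(i + 1);
          fired.push_back(i);
          V[i] = Vr;
          W[i] += b;
          refr[i] = tref_steps[i];
        }
      }

      // exact exponential decay of receptor components (end of step)
      const int base = cls * 4;
      for (int rcp = 0; rcp < 4; ++rcp)
        for (int c = 0; c < 4; ++c)
          xi[rcp * 4 + c] *= rec_decay(base + rcp, c);

      // sampling at the end of the step
      if (rec_every > 0 && (s + 1) % rec_every == 0) {
        const int sc = (s + 1) / rec_every - 1;
        if (vpos[i] >= 0) Vm(vpos[i], sc) = V[i];
        if (cpos[i] >= 0 && (record_currents || record_gtot)) {
          const double gA2  = xi[0] + xi[1] + xi[2] + xi[3];
          const double gN2  = (xi[4] + xi[5] + xi[6] + xi[7]) *
                              nmda_gate(V[i], mg);
          const double gGa2 = xi[8] + xi[9] + xi[10] + xi[11];
          const double gGb2 = xi[12] + xi[13] + xi[14] + xi[15];
          if (record_currents) {
            Iexc(cpos[i], sc) = gA2 * (eA - V[i]) + gN2 * (eN - V[i]);
            Iinh(cpos[i], sc) = gGa2 * (eGa - V[i]) + gGb2 * (eGb - V[i]);
          }
          if (record_gtot)
            Gtot(cpos[i], sc) = gl + gA2 + gN2 + gGa2 + gGb2;
        }
      }
    }

    // propagate this step's spikes through the recurrent connectivity
    for (size_t f = 0; f < fired.size(); ++f) {
      const int j = fired[f];
      const bool exc = pre_exc[j];
      for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
        const int arrive = s + 1 + edelay[e];
        if (arrive >= n_steps + D) continue;  // beyond simulation horizon
        const size_t sl = (size_t)(arrive % D) * N + epost[e];
        if (exc) pend_exc[sl] += ew[e]; else pend_inh[sl] += ew[e];
      }
    }
  }

  return List::create(
    _["spike_times"] = wrap(spike_t),
    _["spike_ids"] = wrap(spike_id),
    _["V"] = Vm, _["I_exc"] = Iexc, _["I_inh"] = Iinh, _["G_total"] = Gtot,
    _["final_V"] = wrap(V), _["final_W"] = wrap(W));
}
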