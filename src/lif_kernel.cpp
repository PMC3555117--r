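#include <Rcpp.h>
using namespace Rcpp;

// Free-running conductance-based leaky integrate-and-fire neuron driven by a
// population of depressing/facilitating synapses.
//
// Synapse dynamics are advanced event-to-event with the exact closed forms of
// the linear three-state resource system; only the active fraction y(t) is
// needed between events and it decays as a single exponential, so the
// per-step cost is one multiply per synapse. The membrane equation
//   C dV/dt = -gL (V - EL) - sum_i w_i y_i(t) (V - Esyn)
// is integrated with exponential Euler on a fixed grid (dt in ms), treating
// the total conductance as constant within a step. Threshold crossing resets
// V, opens an absolute refractory window during which the voltage is clamped
// at the reset value while the synapses keep evolving, and increments a
// spike-triggered adaptation conductance g_a (reversal Ea, decay tau_a) that
// stands in for the after-hyperpolarisation currents of the detailed cell:
//   C dV/dt = -gL (V - EL) - g_syn (V - Esyn) - g_a (V - Ea)
//
// Units: time ms, conductance nS, capacitance pF, voltage mV (pF/nS = ms).

struct SynState {
  double x, y, z, p; // post-event resource fractions and use-variable
  double t_last;     // time of last event, ms
};

static inline void relax_to(SynState &s, double t, double tau_in,
                            double tau_rec, double tau_facil) {
  double dt = t - s.t_last;
  if (dt <= 0) return;
  double e_in = std::exp(-dt / tau_in);
  double z_new;
  if (tau_in != tau_rec) {
    double cc = s.y * tau_rec / (tau_in - tau_rec);
    z_new = (s.z - cc) * std::exp(-dt / tau_rec) + cc * e_in;
  } else {
    z_new = (s.z + s.y * dt / tau_in) * e_in;
  }
  s.y *= e_in;
  s.z = z_new;
  s.x = 1.0 - s.y - s.z;
  s.p *= std::exp(-dt / tau_facil);
  s.t_last = t;
}

// [[Rcpp::export]]
List lif_run_cpp(NumericVector event_times, IntegerVector event_syn,
                 NumericVector weights, double U, double tau_in,
                 double tau_rec, double tau_facil, double C_pF, double gL_nS,
                 double EL, double Vth, double Vreset, double t_ref,
                 double Esyn, double adapt_b, double adapt_tau,
                 double adapt_E, double dt, double duration,
                 bool record_trace) {
  const int n_syn = weights.size();
  const int n_ev = event_times.size();
  const int n_steps = (int)std::ceil(duration / dt);
  const double f_in = std::exp(-dt / tau_in);

  std::vector<SynState> syn(n_syn);
  for (int i = 0; i < n_syn; ++i) syn[i] = SynState{1.0, 0.0, 0.0, 0.0, 0.0};
  // decay factor from each synapse's last event to the current grid time
  std::vector<double> decay(n_syn, 1.0);

  double V = EL;
  double g_a = 0.0;
  const double f_a = std::exp(-dt / adapt_tau);
  double refr_until = -1.0;
  std::vector<double> out_spikes;
  NumericVector trace_v, trace_t;
  if (record_trace) {
    trace_v = NumericVector(n_steps);
    trace_t = NumericVector(n_steps);
  }

  int ev = 0;
  for (int k = 0; k < n_steps; ++k) {
    double t_next = (k + 1) * dt;
    for (int i = 0; i < n_syn; ++i) decay[i] *= f_in;
    // events inside (t, t_next]: exact STP update at the event time
    while (ev < n_ev && event_times[ev] <= t_next) {
      int s = event_syn[ev];
      relax_to(syn[s], event_times[ev], tau_in, tau_rec, tau_facil);
      double p_new = syn[s].p + U * (1.0 - syn[s].p);
      double delta = p_new * syn[s].x;
      syn[s].p = p_new;
      syn[s].x -= delta;
      syn[s].y += delta;
      decay[s] = std::exp(-(t_next - event_times[ev]) / tau_in);
      ++ev;
    }
    double g_syn = 0.0;
    for (int i = 0; i < n_syn; ++i) g_syn += weights[i] * syn[i].y * decay[i];
    g_a *= f_a;

    if (t_next < refr_until) {
      V = Vreset; // clamped during the absolute refractory period
    } else {
      double g_tot = gL_nS + g_syn + g_a;
      double v_inf = (gL_nS * EL + g_syn * Esyn + g_a * adapt_E) / g_tot;
      V = v_inf + (V - v_inf) * std::exp(-dt * g_tot / C_pF);
      if (V >= Vth) {
        out_spikes.push_back(t_next);
        V = Vreset;
        refr_until = t_next + t_ref;
        g_a += adapt_b;
      }
    }
    if (record_trace) {
      trace_t[k] = t_next;
      trace_v[k] = V;
    }
  }

  List out = List::create(_["spikes"] = wrap(out_spikes));
  if (record_trace) {
    out["trace_time"] = trace_t;
    out["trace_v"] = trace_v;
  }
  return out;
}
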