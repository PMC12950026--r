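#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step semi-implicit backward-difference integration of the AdEx model.
//
//   C dV/dt = I - g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T) - w
//   tau_w dw/dt = a (V - E_L) - w
//
// Linear terms are treated implicitly; the exponential spike-initiation term
// is evaluated at the previous step's V with its argument clamped at exp_cap.
// After each update, V > V_T records a spike, resets V to E_L and adds b to w.
//
// Returns spike step indices (1-based, index into the time grid) and, when
// record is true, the full V and w trajectories.
// [[Rcpp::export]]
List cpp_adex(NumericVector I, double dt,
              double C, double g_L, double E_L, double delta_T, double V_T,
              double a, double tau_w, double b,
              double exp_cap, double v_ceiling, bool record) {
  const int n = I.size();
  std::vector<int> spikes;
  NumericVector Vtr, wtr;
  if (record) { Vtr = NumericVector(n); wtr = NumericVector(n); }

  double V = E_L, w = 0.0;
  const double aw = dt / tau_w;
  const double av = dt * g_L / C;
  if (record) { Vtr[0] = V; wtr[0] = w; }

  for (int k = 1; k < n; ++k) {
    w = (w + aw * a * (V - E_L)) / (1.0 + aw);
    double arg = (V - V_T) / delta_T;
    if (arg > exp_cap) arg = exp_cap;
    double ex = g_L * delta_T * std::exp(arg);
    V = (V + (dt / C) * (I[k] + g_L * E_L + ex - w)) / (1.0 + av);
    if (!std::isfinite(V) || V > v_ceiling) {
      stop("membrane potential diverged (V = %f mV at t = %f ms); "
           "check input current scale or raise exp_cap/v_ceiling", V, k * dt);
    }
    if (V > V_T) {
      spikes.push_back(k + 1);  // 1-based grid index
      V = E_L;
      w += b;
    }
    if (record) { Vtr[k] = V; wtr[k] = w; }
  }

  return List::create(_["spike_steps"] = wrap(spikes),
                      _["V"] = Vtr, _["w"] = wtr);
}

// Fixed-step backward-difference integration of the LIF model driven by
// per-step summed synaptic weights (mV). Decay toward E_L is implicit;
// weights arriving in a step are added after the decay update, then the
// threshold V > V_T is tested; a spike resets V to E_L.
// [[Rcpp::export]]
List cpp_lif(NumericVector w_in, double dt,
             double E_L, double V_T, double tau, bool record) {
  const int n = w_in.size();
  std::vector<int> spikes;
  NumericVector Vtr;
  if (record) Vtr = NumericVector(n);

  double V = E_L;
  const double d = 1.0 + dt / tau;
  // events arriving at the first grid point are applied to the initial state
  V += w_in[0];
  if (V > V_T) {
    spikes.push_back(1);
    V = E_L;
  }
  if (record) Vtr[0] = V;

  for (int k = 1; k < n; ++k) {
    V = (V + (dt / tau) * E_L) / d;
    V += w_in[k];
    if (V > V_T) {
      spikes.push_back(k + 1);
      V = E_L;
    }
    if (record) Vtr[k] = V;
  }

  return List::create(_["spike_steps"] = wrap(spikes), _["V"] = Vtr);
}
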