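#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler core for the damaged quadratic integrate-and-fire neuron
// with ephaptic forcing.  Damage enters only through the effective
// resistance/capacitance (r_dfl, c_dfl) so the healthy-with-substitution
// and damaged parameterisations follow bitwise-identical arithmetic.
//
// Stepping: V_{k} = V_{k-1} + dt * F(V_{k-1}, I[k-1]); a spike is recorded
// at the step time k*dt when the post-step value reaches v_peak, and the
// voltage is hard-reset to c_reset before the next step.  Stored samples
// are post-reset, so no stored sample exceeds v_peak.
// [[Rcpp::export]]
List qif_euler_core(double v0, double dt,
                    NumericVector i_eph, NumericVector i_syn,
                    double v_rest, double v_thresh, double v_peak,
                    double c_reset,
                    double r_dfl, double c_dfl,
                    double rho_ext, double r_dist,
                    bool record_trace) {
  const int n = i_eph.size();
  if (i_syn.size() != n) stop("i_eph and i_syn must have equal length");
  const double dv = v_thresh - v_rest;
  const double tau = r_dfl * c_dfl;
  const double quad_coef = 1.0 / (tau * dv);
  const double eph_coef = rho_ext / (4.0 * M_PI * tau * r_dist);
  const double syn_coef = 1.0 / c_dfl;
  const double v_guard = v_peak + 0.1;  // 100 mV past peak: quadratic blow-up

  NumericVector v_out(record_trace ? n : 0);
  std::vector<int> spike_idx;
  double v = v0;
  for (int k = 0; k < n; ++k) {
    const double f = (v - v_rest) * (v - v_thresh) * quad_coef
                   - eph_coef * i_eph[k] + syn_coef * i_syn[k];
    v += dt * f;
    if (!std::isfinite(v) || v > v_guard)
      stop("integration unstable at t = %g s (V_m = %g V): reduce dt (currently %g s)",
           (k + 1) * dt, v, dt);
    if (v >= v_peak) {
      spike_idx.push_back(k + 1);  // spike at time (k+1)*dt
      v = c_reset;
    }
    if (record_trace) v_out[k] = v;
  }
  return List::create(_["V_m"] = v_out, _["spike_steps"] = wrap(spike_idx));
}
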