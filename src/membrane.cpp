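#include <Rcpp.h>
using namespace Rcpp;

// Exponential-Euler integration of the single-compartment membrane equation
//   tau_m dV/dt = -(V - V_rest) - g_exc (V - E_exc) - g_ffi (V - V_rest)
// with leak conductance 1 (g_exc, g_ffi relative to leak). FFI reverses at
// rest, i.e. it is a pure shunt. The optional boost term adds excitatory
// conductance boost_gain * max(0, V - V_rest - boost_threshold), evaluated at
// the current sample (one-step-lagged voltage dependence).
// [[Rcpp::export]]
NumericVector membrane_integrate(NumericVector g_exc, NumericVector g_ffi,
                                 double dt_ms, double tau_m, double v_rest,
                                 double e_exc, bool boost,
                                 double boost_threshold, double boost_gain) {
  R_xlen_t n = g_exc.size();
  if (g_ffi.size() != n)
    stop("conductance series must have equal length");
  NumericVector v(n);
  double V = v_rest;
  for (R_xlen_t i = 0; i < n; ++i) {
    double ge = g_exc[i];
    if (boost) {
      double over = V - v_rest - boost_threshold;
      if (over > 0) ge += boost_gain * over;
    }
    double gi = g_ffi[i];
    double gtot = 1.0 + ge + gi;
    double vinf = (v_rest * (1.0 + gi) + ge * e_exc) / gtot;
    V = vinf + (V - vinf) * std::exp(-dt_ms * gtot / tau_m);
    v[i] = V;
  }
  return v;
}
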