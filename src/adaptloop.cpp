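#include <Rcpp.h>
using namespace Rcpp;

// Cascade of divisive-feedback adaptation loops (Dau-style): each loop
// divides its input by a lowpass-filtered copy of its own output.  Steady
// state for constant input I (with k loops) is I^(1/2^k); five loops give
// the canonical I^(1/32) compression.  A smooth exponential limiter caps
// onset overshoot at `limit` times the steady-state response to a unit
// (full-scale) input.  Inputs are floored at `minlvl` of full scale.
//
// States are initialised to the steady state for the minimum level, so a
// signal rising out of silence produces the characteristic onset overshoot.
//
// x: one column per band (post inner-hair-cell stage, non-negative).
// [[Rcpp::export]]
NumericMatrix adapt_loops_cpp(NumericMatrix x, double fs, NumericVector tau,
                              double minlvl, double limit) {
  const int n = x.nrow(), nb = x.ncol(), nl = tau.size();
  NumericMatrix out(n, nb);

  std::vector<double> a1(nl), b0(nl), state0(nl);
  std::vector<double> factor(nl), expfac(nl), offset(nl);
  double lvl = minlvl;
  for (int j = 0; j < nl; ++j) {
    a1[j] = std::exp(-1.0 / (tau[j] * fs));
    b0[j] = 1.0 - a1[j];
    state0[j] = std::sqrt(lvl);   // steady-state divisor for the minimum level
    lvl = state0[j];
    if (limit > 1.0) {
      // smooth limiter: maps outputs above 1 (the steady state for unit
      // input) onto an exponential saturating at `limit` times that level
      double maxvalue = (1.0 - state0[j] * state0[j]) * limit - 1.0;
      factor[j] = maxvalue * 2.0;
      expfac[j] = -2.0 / maxvalue;
      offset[j] = maxvalue - 1.0;
    }
  }

  std::vector<double> state(nl);
  for (int b = 0; b < nb; ++b) {
    for (int j = 0; j < nl; ++j) state[j] = state0[j];
    for (int i = 0; i < n; ++i) {
      double v = x(i, b);
      if (v < minlvl) v = minlvl;
      for (int j = 0; j < nl; ++j) {
        v /= state[j];
        if (limit > 1.0 && v > 1.0)
          v = factor[j] / (1.0 + std::exp(expfac[j] * (v - 1.0))) - offset[j];
        state[j] = a1[j] * state[j] + b0[j] * v;
      }
      out(i, b) = v;
    }
  }
  return out;
}
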