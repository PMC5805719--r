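#include <Rcpp.h>
using namespace Rcpp;

// Fixed-timestep kinetic Monte Carlo for a linear chain of regulatory
// units with states B(0) <-> C(1) <-> M(2).  Nearest-neighbour coupling:
// the B->C rate of unit i is multiplied by gamma^(active neighbours) and
// the C->B rate divided by the same factor, where a neighbour counts as
// active when it is in C or M.  Neighbour factors are evaluated on the
// state at the start of the step (synchronous update).  a_base supplies
// the uncoupled B->C rate per step, so a time-varying calcium drive is a
// per-step vector.  Uses R's RNG: seeding via set.seed() in the caller.

// [[Rcpp::export]]
List chain_sim_cpp(IntegerVector state0, NumericVector a_base,
                   double b, double f, double g,
                   double gamma, double dt) {
  const int n = state0.size();
  const int n_steps = a_base.size();
  IntegerVector s = clone(state0);
  IntegerVector s_new(n);
  NumericVector pi_b(n_steps), pi_c(n_steps), pi_m(n_steps);

  for (int step = 0; step < n_steps; ++step) {
    const double a0 = a_base[step];
    for (int i = 0; i < n; ++i) {
      int nb = 0;
      if (i > 0 && s[i - 1] != 0) ++nb;
      if (i < n - 1 && s[i + 1] != 0) ++nb;
      const double fac = (nb == 0) ? 1.0 : (nb == 1 ? gamma : gamma * gamma);
      const int st = s[i];
      int nx = st;
      const double u = unif_rand();
      if (st == 0) {                     // blocked
        if (u < a0 * fac * dt) nx = 1;
      } else if (st == 1) {              // closed
        const double pb = (b / fac) * dt;
        if (u < pb) nx = 0;
        else if (u < pb + f * dt) nx = 2;
      } else {                           // myosin-bound
        if (u < g * dt) nx = 1;
      }
      s_new[i] = nx;
    }
    int cb = 0, cc = 0, cm = 0;
    for (int i = 0; i < n; ++i) {
      s[i] = s_new[i];
      if (s[i] == 0) ++cb; else if (s[i] == 1) ++cc; else ++cm;
    }
    pi_b[step] = (double)cb / n;
    pi_c[step] = (double)cc / n;
    pi_m[step] = (double)cm / n;
  }
  return List::create(_["pi_b"] = pi_b, _["pi_c"] = pi_c,
                      _["pi_m"] = pi_m, _["state"] = s);
}
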