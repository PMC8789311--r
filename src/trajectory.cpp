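#include <Rcpp.h>
using namespace Rcpp;

// diploid population size at generation t before present, from an epoch table
// (columns: start, size, growth); growth is the forward-time exponential rate.
static double pop_size_at(const NumericMatrix &epochs, double t) {
  int i = epochs.nrow() - 1;
  while (i > 0 && epochs(i, 0) > t) --i;
  double N = epochs(i, 1) * std::exp(-epochs(i, 2) * (t - epochs(i, 0)));
  return N < 2.0 ? 2.0 : N;
}

// Backward-in-time per-generation Wright-Fisher frequency process, started at
// the present-day frequency f and conditioned on a single-copy origin.
// Selection of strength s (genic) acts between the present and, in soft mode,
// the first backward crossing below f_init; the deterministic backward step
// inverts x' = x(1+s)/(1+sx), after which the frequency one generation older
// is resampled binomially among 2N(t) copies.  Trajectories that jump to zero
// copies without passing through a single copy, exceed max_gen, or drift to
// fixation backwards are rejected.
// mode: 0 neutral, 1 hard sweep, 2 soft (standing-variation) sweep.
// [[Rcpp::export]]
List sim_trajectory_cpp(double s, double f, double f_init, int mode,
                        NumericMatrix epochs, double max_gen, int max_tries) {
  if (f <= 0.0 || f >= 1.0) stop("present-day frequency must lie in (0, 1)");
  if (s < 0.0) stop("selection coefficient must be >= 0");
  for (int attempt = 0; attempt < max_tries; ++attempt) {
    std::vector<double> freqs;
    freqs.reserve(4096);
    freqs.push_back(f);
    double x = f;
    bool sel_active = (mode == 1 || mode == 2) && s > 0.0;
    bool ok = false;
    double g = 0.0;
    while (g < max_gen) {
      g += 1.0;
      double N = pop_size_at(epochs, g);
      double twoN = std::round(2.0 * N);
      if (mode == 2 && sel_active && x < f_init) sel_active = false; // latched
      double y = x;
      if (sel_active) y = x / ((1.0 + s) - s * x);
      double cnt = R::rbinom(twoN, y);
      x = cnt / twoN;
      freqs.push_back(x);
      if (cnt <= 0.5) { ok = false; break; }       // lost without single copy
      if (x >= 1.0)   { ok = false; break; }       // fixed backwards: reject
      if (cnt <= 1.5) { ok = true; break; }        // single founding copy
    }
    if (ok) {
      return List::create(_["freqs"] = wrap(freqs),
                          _["origin"] = (double)(freqs.size() - 1),
                          _["attempts"] = attempt + 1);
    }
  }
  stop("trajectory conditioning failed after %d attempts (s=%g, f=%g); "
       "the requested present-day frequency may be unreachable under this history",
       max_tries, s, f);
}
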