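#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a tabulated potential; +Inf outside the table.
static inline double energy_at(const double *gx, const double *gE, int n,
                               double x) {
  if (x < gx[0] || x > gx[n - 1]) return R_PosInf;
  // uniform grid assumed
  double h = (gx[n - 1] - gx[0]) / (n - 1);
  int j = (int)((x - gx[0]) / h);
  if (j >= n - 1) j = n - 2;
  double t = (x - gx[j]) / h;
  return gE[j] * (1.0 - t) + gE[j + 1] * t;
}

// 1-D Metropolis chain on a tabulated energy surface E(x) (units of kT
// after division by kT here).  Step size is auto-tuned during burn-in to a
// 30-50% acceptance rate.  Uses R's RNG, so set.seed() in R gives
// bit-reproducible chains.
// [[Rcpp::export]]
List metropolis_tabulated(NumericVector grid_x, NumericVector grid_E,
                          double x0, int n_samples, int thin, int burnin,
                          double step0, double kT, bool tune) {
  int n = grid_x.size();
  if (n < 2) stop("energy table needs at least two points");
  if (kT <= 0) stop("kT must be positive");
  const double *gx = grid_x.begin();
  const double *gE = grid_E.begin();

  double x = x0, Ex = energy_at(gx, gE, n, x0) / kT;
  if (!R_FINITE(Ex)) stop("starting point has non-finite energy");
  double step = step0;
  NumericVector out(n_samples);
  long accepted = 0, proposed = 0;
  int tune_win = 0, tune_acc = 0;

  RNGScope scope;
  long total = (long)burnin + (long)n_samples * thin;
  long kept = 0;
  for (long it = 0; it < total; ++it) {
    double xp = x + step * (2.0 * unif_rand() - 1.0);
    double Ep = energy_at(gx, gE, n, xp) / kT;
    ++proposed;
    ++tune_win;
    if (R_FINITE(Ep) && (Ep <= Ex || unif_rand() < std::exp(Ex - Ep))) {
      x = xp;
      Ex = Ep;
      ++accepted;
      ++tune_acc;
    }
    if (tune && it < burnin && tune_win >= 100) {
      double r = (double)tune_acc / tune_win;
      if (r > 0.5) step *= 1.25;
      else if (r < 0.3) step /= 1.25;
      tune_win = 0;
      tune_acc = 0;
    }
    if (it >= burnin && ((it - burnin) % thin) == (thin - 1)) {
      out[kept++] = x;
      if (kept == n_samples) break;
    }
  }
  return List::create(_["samples"] = out,
                      _["acceptance_rate"] = (double)accepted / proposed,
                      _["step"] = step);
}
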