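#include <Rcpp.h>
using namespace Rcpp;

// Analytic model PMF: exponential wall + sum of negative Gaussian wells.
static inline double pmf_energy(double r,
                                const double* wc, const double* wd,
                                const double* ww, int nwells,
                                double wall_pos, double wall_steep) {
  double e = std::exp(-wall_steep * (r - wall_pos));
  for (int k = 0; k < nwells; ++k) {
    double d = r - wc[k];
    e -= wd[k] * std::exp(-0.5 * d * d / (ww[k] * ww[k]));
  }
  return e;
}

// Metropolis random-walk chain on the biased 1-D potential
// U(x) = W(x) + 0.5 * spring * (x - center)^2 (energies kJ/mol).
// Stores every `thin`-th configuration after discarding n_equil stored-sample
// equivalents. Uses R's RNG so set.seed() controls the stream.
// [[Rcpp::export]]
NumericVector metropolis_window(int n_store, int n_equil, int thin,
                                double x0, double step, double beta,
                                double spring_kj, double center,
                                NumericVector well_center,
                                NumericVector well_depth,
                                NumericVector well_width,
                                double wall_pos, double wall_steep) {
  if (n_store <= 0) stop("n_store must be positive");
  if (thin <= 0) stop("thin must be positive");
  if (step <= 0) stop("proposal step must be positive");
  NumericVector out(n_store);
  const double* wc = well_center.begin();
  const double* wd = well_depth.begin();
  const double* ww = well_width.begin();
  const int nw = well_center.size();

  double x = x0;
  double u = pmf_energy(x, wc, wd, ww, nw, wall_pos, wall_steep) +
             0.5 * spring_kj * (x - center) * (x - center);
  const long burn = (long)n_equil * thin;
  const long total = burn + (long)n_store * thin;
  int stored = 0;

  RNGScope scope;
  for (long it = 0; it < total; ++it) {
    double xp = x + R::runif(-step, step);
    if (xp > 1e-3) {  // coordinate must stay positive
      double up = pmf_energy(xp, wc, wd, ww, nw, wall_pos, wall_steep) +
                  0.5 * spring_kj * (xp - center) * (xp - center);
      if (up <= u || R::unif_rand() < std::exp(-beta * (up - u))) {
        x = xp;
        u = up;
      }
    }
    if (it >= burn && ((it - burn + 1) % thin == 0)) out[stored++] = x;
  }
  return out;
}
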