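#include <Rcpp.h>
using namespace Rcpp;

// Potential evaluation shared by the Metropolis samplers.
// form 0: harmonic          params = [k_1..k_d, c_1..c_d]
// form 1: double well       params = [axis(0-based), barrier, a, k_1..k_d, c_1..c_d]
//         quartic barrier*((x_a^2-a^2)/a^2)^2 along `axis` (wells at c_a +- a),
//         harmonic 0.5*k_i*(x_i-c_i)^2 in the remaining dims
// form 2: tabulated 1D/2D   grid passed separately, linear interpolation,
//         +inf (1e30) outside the stated domain
static double pot_energy(int form, int d, const NumericVector &params,
                         const NumericVector &gx, const NumericVector &gy,
                         const NumericMatrix &gv, const double *x) {
  if (form == 0) {
    double u = 0.0;
    for (int i = 0; i < d; ++i) {
      double dx = x[i] - params[d + i];
      u += 0.5 * params[i] * dx * dx;
    }
    return u;
  }
  if (form == 1) {
    int axis = (int)params[0];
    double barrier = params[1], a = params[2];
    double u = 0.0;
    for (int i = 0; i < d; ++i) {
      double c = params[3 + d + i];
      if (i == axis) {
        double q = (x[i] - c) * (x[i] - c) - a * a;
        u += barrier * (q * q) / (a * a * a * a);
      } else {
        double dx = x[i] - c;
        u += 0.5 * params[3 + i] * dx * dx;
      }
    }
    return u;
  }
  // tabulated
  int nx = gx.size();
  if (x[0] < gx[0] || x[0] > gx[nx - 1]) return 1e30;
  int ix = std::upper_bound(gx.begin(), gx.end(), x[0]) - gx.begin() - 1;
  if (ix >= nx - 1) ix = nx - 2;
  double tx = (x[0] - gx[ix]) / (gx[ix + 1] - gx[ix]);
  if (d == 1 || gy.size() == 0) {
    return (1 - tx) * gv(ix, 0) + tx * gv(ix + 1, 0);
  }
  int ny = gy.size();
  if (x[1] < gy[0] || x[1] > gy[ny - 1]) return 1e30;
  int iy = std::upper_bound(gy.begin(), gy.end(), x[1]) - gy.begin() - 1;
  if (iy >= ny - 1) iy = ny - 2;
  double ty = (x[1] - gy[iy]) / (gy[iy + 1] - gy[iy]);
  return (1 - tx) * (1 - ty) * gv(ix, iy) + tx * (1 - ty) * gv(ix + 1, iy) +
         (1 - tx) * ty * gv(ix, iy + 1) + tx * ty * gv(ix + 1, iy + 1);
}

// [[Rcpp::export]]
double potential_energy_cpp(int form, int d, NumericVector params,
                            NumericVector gx, NumericVector gy,
                            NumericMatrix gv, NumericVector x) {
  return pot_energy(form, d, params, gx, gy, gv, REAL(x));
}

// Metropolis random-walk chain targeting exp(-U/RT).  Uses R's RNG, so
// set.seed() on the R side fully determines the output.  Returns the kept
// samples (one row per kept step), the final state/energy and the
// acceptance fraction.
// [[Rcpp::export]]
List mc_chain_cpp(int form, int d, NumericVector params, NumericVector gx,
                  NumericVector gy, NumericMatrix gv, NumericVector x0,
                  int n_steps, double step_size, double RT, int thin) {
  RNGScope scope;
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xp(d);
  double u = pot_energy(form, d, params, gx, gy, gv, x.data());
  if (u >= 1e29 || !R_finite(u)) stop("Non-finite potential at the chain start.");
  int n_keep = n_steps / thin;
  NumericMatrix out(n_keep, d);
  int kept = 0;
  long accepted = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < d; ++i) xp[i] = x[i] + R::runif(-step_size, step_size);
    double up = pot_energy(form, d, params, gx, gy, gv, xp.data());
    double du = up - u;
    if (du <= 0.0 || R::runif(0.0, 1.0) < std::exp(-du / RT)) {
      x = xp;
      u = up;
      ++accepted;
    }
    if (s % thin == 0 && kept < n_keep) {
      for (int i = 0; i < d; ++i) out(kept, i) = x[i];
      ++kept;
    }
  }
  return List::create(_["samples"] = out, _["state"] = NumericVector(x.begin(), x.end()),
                      _["energy"] = u, _["acceptance"] = (double)accepted / n_steps);
}
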