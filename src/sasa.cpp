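#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley point counting: for every atom, place `sphere` unit
// points on the expanded sphere of radius r_i + probe and count the
// points not inside any neighbour's expanded sphere.  Deterministic for a
// fixed point set.  Returns per-atom accessible area in Angstrom^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii, double probe,
                       NumericMatrix sphere) {
  int n = xyz.nrow(), np = sphere.nrow();
  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double lim = ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      double px = xyz(i, 0) + ri * sphere(p, 0);
      double py = xyz(i, 1) + ri * sphere(p, 1);
      double pz = xyz(i, 2) + ri * sphere(p, 2);
      bool free_point = true;
      for (size_t k = 0; k < nbr.size(); ++k) {
        int j = nbr[k];
        double rj = radii[j] + probe;
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        // small tolerance so coincident spheres occlude each other fully
        if (dx * dx + dy * dy + dz * dz < rj * rj + 1e-9) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / np;
  }
  return area;
}

// Per-residue-pair minimum bead-bead distance for one frame, with the
// minimum-image convention in an orthorhombic box.  resA/resB are 0-based
// residue indices for each bead row; returns an nResA x nResB matrix of
// minimum distances.
// [[Rcpp::export]]
NumericMatrix min_res_dist_cpp(NumericMatrix xyzA, IntegerVector resA, int nResA,
                               NumericMatrix xyzB, IntegerVector resB, int nResB,
                               NumericVector box) {
  NumericMatrix out(nResA, nResB);
  std::fill(out.begin(), out.end(), R_PosInf);
  bool pbc = box.size() == 3;
  for (int a = 0; a < xyzA.nrow(); ++a) {
    for (int b = 0; b < xyzB.nrow(); ++b) {
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = xyzA(a, k) - xyzB(b, k);
        if (pbc) d -= box[k] * std::round(d / box[k]);
        d2 += d * d;
      }
      double dd = std::sqrt(d2);
      if (dd < out(resA[a], resB[b])) out(resA[a], resB[b]) = dd;
    }
  }
  return out;
}
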