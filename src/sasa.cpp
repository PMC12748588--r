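#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley numerical SASA. Test points are a golden-spiral lattice on
// each expanded sphere (radius_i + probe); a point is buried if it falls
// inside any neighbour's expanded sphere. Per-atom SASA in A^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int npoints) {
  int n = xyz.nrow();
  NumericVector out(n);
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th); py[k] = r * std::sin(th); pz[k] = z;
  }

  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    // neighbours whose expanded spheres can bury points of atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double cut = ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < npoints; ++k) {
      double x = xyz(i, 0) + ri * px[k], y = xyz(i, 1) + ri * py[k],
             z = xyz(i, 2) + ri * pz[k];
      bool buried = false;
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        double rj = radii[j] + probe;
        double dx = x - xyz(j, 0), dy = y - xyz(j, 1), dz = z - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    out[i] = 4.0 * M_PI * ri * ri * exposed / npoints;
  }
  return out;
}
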