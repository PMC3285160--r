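#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface area.
//
// xyz:    n x 3 atom centres (Angstrom)
// radius: n van-der-Waals radii (Angstrom)
// probe:  probe radius (Angstrom)
// sphere: m x 3 unit-sphere quadrature points (fixed orientation; the caller
//         supplies a deterministic golden-spiral set)
//
// For each atom the probe-centre sphere of radius r_i + probe is sampled at
// the quadrature points; a point is occluded when it lies inside any other
// atom's probe-centre sphere. ASA_i = 4*pi*(r_i+probe)^2 * accessible/m.
// [[Rcpp::export(name = ".sasa_kernel")]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector radius,
                          double probe, NumericMatrix sphere) {
  const int n = xyz.nrow();
  const int m = sphere.nrow();
  NumericVector asa(n);
  if (n == 0) return asa;

  std::vector<double> x(n), y(n), z(n), re(n);  // re = expanded radius
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
    re[i] = radius[i] + probe;
  }

  std::vector<int> nb;  // neighbour scratch
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double lim = re[i] + re[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    const double ri = re[i];
    for (int p = 0; p < m; ++p) {
      const double px = x[i] + ri * sphere(p, 0);
      const double py = y[i] + ri * sphere(p, 1);
      const double pz = z[i] + ri * sphere(p, 2);
      bool free_pt = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        const int j = nb[k];
        const double dx = px - x[j], dy = py - y[j], dz = pz - z[j];
        if (dx * dx + dy * dy + dz * dz < re[j] * re[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    asa[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)m;
  }
  return asa;
}
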