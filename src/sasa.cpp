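#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic golden-angle (Fibonacci) spiral lattice on the unit sphere.
// Quasi-uniform, no RNG: point i sits at z = 1 - (2i+1)/n, azimuth i * phi
// with phi the golden angle.
static void spiral_points(int n, std::vector<double>& px,
                          std::vector<double>& py, std::vector<double>& pz) {
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  px.resize(n); py.resize(n); pz.resize(n);
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * i;
    px[i] = r * std::cos(th);
    py[i] = r * std::sin(th);
    pz[i] = z;
  }
}

// Shrake-Rupley SASA. xyz: n x 3, radius: vdW radius per atom (probe already
// NOT included). Returns accessible area per atom in A^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radius, double probe,
                       int n_points) {
  const int n = xyz.nrow();
  std::vector<double> px, py, pz;
  spiral_points(n_points, px, py, pz);

  std::vector<double> R(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    R[i] = radius[i] + probe;
    if (R[i] > rmax) rmax = R[i];
  }
  NumericVector out(n);

  // neighbour candidates via a coarse O(n^2) distance screen; adequate for
  // the <= ~10^4-atom models this package targets
  std::vector<int> nb;
  nb.reserve(256);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double cut = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    const int m = (int)nb.size();
    for (int p = 0; p < n_points; ++p) {
      double qx = xi + R[i] * px[p];
      double qy = yi + R[i] * py[p];
      double qz = zi + R[i] * pz[p];
      bool free_pt = true;
      for (int k = 0; k < m; ++k) {
        int j = nb[k];
        double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1), dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * R[i] * R[i] * (double)acc / (double)n_points;
  }
  return out;
}
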