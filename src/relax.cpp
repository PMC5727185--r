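#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iterative pairwise shoving of a spherical-particle packing.
// Lateral minimum-image periodicity in x and y, hard floor at z = 0
// (particle centres stay at z >= radius). Each overlapping pair is
// displaced symmetrically along the centre line by half the overlap.
// Neighbour search uses a rebuilt 3-D cell list per sweep (O(N)).
// [[Rcpp::export]]
List relax_cpp(NumericVector x, NumericVector y, NumericVector z,
               NumericVector r, double box_x, double box_y,
               double tol_abs, int max_iters) {
  const int n = x.size();
  std::vector<double> px(x.begin(), x.end());
  std::vector<double> py(y.begin(), y.end());
  std::vector<double> pz(z.begin(), z.end());

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  std::vector<double> sq_hist;
  double max_ov = 0.0;
  int iters = 0;

  if (n > 0 && rmax > 0) {
    const double cell = 2.0 * rmax;
    const int ncx = std::max(1, (int)std::floor(box_x / cell));
    const int ncy = std::max(1, (int)std::floor(box_y / cell));

    auto wrap = [](double v, double box) {
      v -= box * std::floor(v / box);
      if (v >= box) v -= box;
      if (v < 0) v = 0;
      return v;
    };
    auto mic = [](double d, double box) {
      if (d > 0.5 * box) d -= box;
      else if (d < -0.5 * box) d += box;
      return d;
    };

    for (iters = 0; iters < max_iters; ++iters) {
      double zmax = 0.0;
      for (int i = 0; i < n; ++i) {
        px[i] = wrap(px[i], box_x);
        py[i] = wrap(py[i], box_y);
        if (pz[i] < r[i]) pz[i] = r[i];
        zmax = std::max(zmax, pz[i]);
      }
      const int ncz = std::max(1, (int)std::floor((zmax + cell) / cell));
      std::vector<std::vector<int>> head((size_t)ncx * ncy * ncz);
      auto cidx = [&](int cx, int cy, int cz) {
        return (size_t)cx + (size_t)ncx * (cy + (size_t)ncy * cz);
      };
      for (int i = 0; i < n; ++i) {
        int cx = std::min((int)(px[i] / box_x * ncx), ncx - 1);
        int cy = std::min((int)(py[i] / box_y * ncy), ncy - 1);
        int cz = std::min((int)(pz[i] / cell), ncz - 1);
        head[cidx(cx, cy, cz)].push_back(i);
      }
      double sweep_sq = 0.0;
      max_ov = 0.0;
      for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
      for (int cx = 0; cx < ncx; ++cx) {
        const std::vector<int>& cc = head[cidx(cx, cy, cz)];
        if (cc.empty()) continue;
        for (int dcz = -1; dcz <= 1; ++dcz) {
          int oz = cz + dcz;
          if (oz < 0 || oz >= ncz) continue;
          for (int dcy = -1; dcy <= 1; ++dcy) {
            int oy = (cy + dcy + ncy) % ncy;
            for (int dcx = -1; dcx <= 1; ++dcx) {
              int ox = (cx + dcx + ncx) % ncx;
              const std::vector<int>& oc = head[cidx(ox, oy, oz)];
              for (size_t a = 0; a < cc.size(); ++a) {
                int i = cc[a];
                for (size_t b = 0; b < oc.size(); ++b) {
                  int j = oc[b];
                  if (j <= i) continue;
                  double dx = mic(px[j] - px[i], box_x);
                  double dy = mic(py[j] - py[i], box_y);
                  double dz = pz[j] - pz[i];
                  double sum_r = r[i] + r[j];
                  double d2 = dx * dx + dy * dy + dz * dz;
                  if (d2 >= sum_r * sum_r) continue;
                  double d = std::sqrt(d2);
                  double ov, ux, uy, uz;
                  if (d < 1e-12) {           // coincident: deterministic split
                    ov = sum_r;
                    ux = 0.0; uy = 0.0; uz = 1.0;
                  } else {
                    ov = sum_r - d;
                    ux = dx / d; uy = dy / d; uz = dz / d;
                  }
                  sweep_sq += ov * ov;
                  if (ov > max_ov) max_ov = ov;
                  double half = 0.5 * ov;
                  px[i] -= ux * half; py[i] -= uy * half; pz[i] -= uz * half;
                  px[j] += ux * half; py[j] += uy * half; pz[j] += uz * half;
                  if (pz[i] < r[i]) pz[i] = r[i];
                  if (pz[j] < r[j]) pz[j] = r[j];
                }
              }
            }
          }
        }
      }
      sq_hist.push_back(sweep_sq);
      if (max_ov <= tol_abs) { ++iters; break; }
    }
    for (int i = 0; i < n; ++i) {
      px[i] = wrap(px[i], box_x);
      py[i] = wrap(py[i], box_y);
      if (pz[i] < r[i]) pz[i] = r[i];
    }
  }
  return List::create(_["x"] = NumericVector(px.begin(), px.end()),
                      _["y"] = NumericVector(py.begin(), py.end()),
                      _["z"] = NumericVector(pz.begin(), pz.end()),
                      _["iters"] = iters,
                      _["max_overlap"] = max_ov,
                      _["sq_overlap"] = NumericVector(sq_hist.begin(),
                                                      sq_hist.end()));
}
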