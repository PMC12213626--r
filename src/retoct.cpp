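#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact dynamic-programming shortest path across columns of a cost grid.
// Path visits one row per column, |row[j+1] - row[j]| <= max_step, confined
// to rows [rmin, rmax] (1-based, inclusive).  Ties broken toward the smaller
// row index.  Returns 1-based row indices, one per column.
// [[Rcpp::export(name = ".dp_shortest_path")]]
IntegerVector dp_shortest_path_cpp(NumericMatrix cost, int rmin, int rmax,
                                   int max_step) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (rmin < 1 || rmax > nr || rmin > rmax)
    stop("infeasible row band [%d, %d] for %d rows", rmin, rmax, nr);
  if (max_step < 0) stop("max_step must be >= 0");
  const int band = rmax - rmin + 1;
  std::vector<double> prev(band), cur(band);
  std::vector<int> back(static_cast<size_t>(band) * nc);
  for (int r = 0; r < band; ++r) prev[r] = cost(rmin - 1 + r, 0);
  for (int j = 1; j < nc; ++j) {
    for (int r = 0; r < band; ++r) {
      double best = std::numeric_limits<double>::infinity();
      int barg = -1;
      const int lo = std::max(0, r - max_step), hi = std::min(band - 1, r + max_step);
      for (int p = lo; p <= hi; ++p) {
        if (prev[p] < best) { best = prev[p]; barg = p; }  // strict: small row wins ties
      }
      cur[r] = best + cost(rmin - 1 + r, j);
      back[static_cast<size_t>(j) * band + r] = barg;
    }
    std::swap(prev, cur);
  }
  int end = 0;
  for (int r = 1; r < band; ++r) if (prev[r] < prev[end]) end = r;
  IntegerVector path(nc);
  int r = end;
  for (int j = nc - 1; j >= 0; --j) {
    path[j] = rmin + r;
    if (j > 0) r = back[static_cast<size_t>(j) * band + r];
  }
  return path;
}

// Separable Gaussian blur with reflected borders; independent axial
// (vertical, along A-scans) and lateral (horizontal) sigmas.
static std::vector<double> gauss_kernel(double sigma, int& rad) {
  rad = std::max(1, (int)std::ceil(2.5 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export(name = ".gaussian_blur")]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma_axial,
                                double sigma_lateral) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  if (sigma_axial > 0) {
    int rad;
    std::vector<double> k = gauss_kernel(sigma_axial, rad);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int ii = i + d;
          if (ii < 0) ii = -ii - 1;
          if (ii >= nr) ii = 2 * nr - ii - 1;
          acc += k[d + rad] * img(ii, j);
        }
        tmp(i, j) = acc;
      }
  } else {
    tmp = clone(img);
  }
  if (sigma_lateral > 0) {
    int rad;
    std::vector<double> k = gauss_kernel(sigma_lateral, rad);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int jj = j + d;
          if (jj < 0) jj = -jj - 1;
          if (jj >= nc) jj = 2 * nc - jj - 1;
          acc += k[d + rad] * tmp(i, jj);
        }
        out(i, j) = acc;
      }
    return out;
  }
  return tmp;
}

// Connected-component labeling of a binary mask (4- or 8-connectivity).
// Returns an integer matrix of labels (0 = background), labels 1..n in
// scan order of first encounter.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int>> stack;
  int next = 0;
  const int dx4[4] = {1,-1,0,0}, dy4[4] = {0,0,1,-1};
  const int dx8[8] = {1,-1,0,0,1,1,-1,-1}, dy8[8] = {0,0,1,-1,1,-1,1,-1};
  const int *dx = connectivity == 4 ? dx4 : dx8;
  const int *dy = connectivity == 4 ? dy4 : dy8;
  const int nd = connectivity;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int d = 0; d < nd; ++d) {
          const int ni = ci + dy[d], nj = cj + dx[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back({ni, nj});
          }
        }
      }
    }
  return lab;
}

// Row-wise medians (mean of the two central values for even counts).
// [[Rcpp::export(name = ".row_medians")]]
NumericVector row_medians_cpp(NumericMatrix x) {
  const int nr = x.nrow(), k = x.ncol();
  NumericVector out(nr);
  std::vector<double> buf(k);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = x(i, j);
    std::sort(buf.begin(), buf.end());
    out[i] = (k % 2) ? buf[k / 2] : 0.5 * (buf[k / 2 - 1] + buf[k / 2]);
  }
  return out;
}

// Noise-free rendering of a layered medium.  bounds is (K+1) x ncol with
// 0-based boundary depths (bounds[k] = top of band k); refl and mu_m1 have
// length K.  Pixel row r (1-based) covers depth [r-1, r).  Expected
// intensity: area-weighted reflectivity times two-way cumulative
// attenuation, with half of the pixel's own attenuation applied (so a
// uniform layer decays by exactly exp(-2*mu*delta) per pixel).
// [[Rcpp::export(name = ".render_layers")]]
NumericMatrix render_layers_cpp(NumericMatrix bounds, NumericVector refl,
                                NumericVector mu_m1, int nrow_px,
                                double axial_pitch_um) {
  const int nb = bounds.nrow();       // K+1 boundaries
  const int nc = bounds.ncol();
  const int K = nb - 1;
  if (refl.size() != K || mu_m1.size() != K)
    stop("refl/mu length must equal nrow(bounds) - 1");
  const double delta_m = axial_pitch_um * 1e-6;
  NumericMatrix out(nrow_px, nc);
  for (int j = 0; j < nc; ++j) {
    double cum = 0.0;  // one-way optical depth above current pixel
    for (int r = 0; r < nrow_px; ++r) {
      const double z0 = r, z1 = r + 1.0;
      double rf = 0.0, mu_px = 0.0;
      for (int k = 0; k < K; ++k) {
        const double top = bounds(k, j), bot = bounds(k + 1, j);
        if (bot <= z0) continue;
        if (top >= z1) break;
        const double f = std::min(bot, z1) - std::max(top, z0);
        if (f <= 0) continue;
        rf += f * refl[k];
        mu_px += f * mu_m1[k];
      }
      const double od = mu_px * delta_m;  // one-way optical depth of this pixel
      out(r, j) = rf * std::exp(-2.0 * cum - od);
      cum += od;
    }
  }
  return out;
}
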