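#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <cmath>
using namespace Rcpp;

// key for a 3-D spatial hash with cell edge = dmin
static inline long long cell_key(int ix, int iy, int iz) {
  // offsets keep coordinates positive for lenses up to ~1 m
  long long k = (long long)(ix + 1048576);
  k = k * 2097152 + (iy + 1048576);
  k = k * 2097152 + (iz + 1048576);
  return k;
}

// Sequential hard-core (RSA) thinning of candidate points in 3-D.
// The first n_existing rows are taken as already accepted. Returns 1-based
// row indices of all accepted points, in acceptance order.
// [[Rcpp::export]]
IntegerVector cpp_hardcore_thin(NumericMatrix pts, double dmin, int n_target,
                                int n_existing) {
  const int n = pts.nrow();
  const double d2 = dmin * dmin;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<int> accepted;
  accepted.reserve(n_target);

  auto insert_pt = [&](int i) {
    int ix = (int)std::floor(pts(i, 0) / dmin);
    int iy = (int)std::floor(pts(i, 1) / dmin);
    int iz = (int)std::floor(pts(i, 2) / dmin);
    grid[cell_key(ix, iy, iz)].push_back(i);
    accepted.push_back(i);
  };

  for (int i = 0; i < n; ++i) {
    if ((int)accepted.size() >= n_target && i >= n_existing) break;
    if (i < n_existing) { insert_pt(i); continue; }
    int ix = (int)std::floor(pts(i, 0) / dmin);
    int iy = (int)std::floor(pts(i, 1) / dmin);
    int iz = (int)std::floor(pts(i, 2) / dmin);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dz = -1; dz <= 1 && ok; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double a = pts(i, 0) - pts(j, 0);
            double b = pts(i, 1) - pts(j, 1);
            double c = pts(i, 2) - pts(j, 2);
            if (a * a + b * b + c * c < d2) { ok = false; break; }
          }
        }
    if (ok) insert_pt(i);
  }
  IntegerVector out(accepted.size());
  for (size_t k = 0; k < accepted.size(); ++k) out[k] = accepted[k] + 1;
  return out;
}

// Two-pass 8-connected component labeling. mask is an integer matrix of 0/1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // neighbors already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int nb[4] = {0, 0, 0, 0};
      if (i > 0) nb[0] = lab(i - 1, j);
      if (j > 0) {
        if (i > 0) nb[1] = lab(i - 1, j - 1);
        nb[2] = lab(i, j - 1);
        if (i < nr - 1) nb[3] = lab(i + 1, j - 1);
      }
      int m = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (m == 0 || nb[k] < m)) m = nb[k];
      if (m == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        lab(i, j) = m;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0 && nb[k] != m) unite(nb[k], m);
      }
    }
  }
  // flatten and renumber 1..K
  std::vector<int> newid(next + 1, 0);
  int K = 0;
  for (int l = 1; l <= next; ++l) {
    int r = find(l);
    if (newid[r] == 0) newid[r] = ++K;
    newid[l] = newid[r];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) lab(i, j) = newid[lab(i, j)];
  return lab;
}

// Split labeled components by markers: multi-source BFS (8-connected) from
// the marker pixels, constrained to stay inside the originating component.
// Components without a marker keep a single label. Returns a relabeled
// matrix with consecutive labels; marker k seeds output label stored in
// attribute "marker_label".
// [[Rcpp::export]]
IntegerMatrix cpp_split_by_markers(IntegerMatrix labels, IntegerVector mi,
                                   IntegerVector mj) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int maxlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (labels(i, j) > maxlab) maxlab = labels(i, j);
  std::vector<int> nmark(maxlab + 1, 0);
  const int nm = mi.size();
  for (int k = 0; k < nm; ++k) {
    int l = labels(mi[k] - 1, mj[k] - 1);
    if (l > 0) ++nmark[l];
  }
  IntegerMatrix out(nr, nc);
  int K = 0;
  // components without markers get one output label each
  std::vector<int> solo(maxlab + 1, 0);
  for (int l = 1; l <= maxlab; ++l)
    if (nmark[l] == 0) solo[l] = ++K;
  IntegerVector marker_label(nm, 0);
  std::queue<std::pair<int, int> > q;
  for (int k = 0; k < nm; ++k) {
    int i = mi[k] - 1, j = mj[k] - 1;
    int l = labels(i, j);
    if (l == 0) continue;
    if (nmark[l] == 1) {
      marker_label[k] = solo[l] = (solo[l] ? solo[l] : ++K);
      continue;  // whole component takes this label below
    }
    if (out(i, j) == 0) {
      out(i, j) = ++K;
      marker_label[k] = K;
      q.push(std::make_pair(i, j));
    } else {
      marker_label[k] = out(i, j);  // coincident markers share a label
    }
  }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    int i = p.first, j = p.second;
    int l = labels(i, j), o = out(i, j);
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int ii = i + di, jj = j + dj;
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (labels(ii, jj) == l && out(ii, jj) == 0) {
          out(ii, jj) = o;
          q.push(std::make_pair(ii, jj));
        }
      }
  }
  // fill single-marker / no-marker components, and any multi-marker pixels
  // unreachable by BFS (cannot happen for connected components, kept safe)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = labels(i, j);
      if (l > 0 && out(i, j) == 0) out(i, j) = solo[l] ? solo[l] : ++K;
    }
  out.attr("marker_label") = marker_label;
  out.attr("n_labels") = K;
  return out;
}

// Render Gaussian blobs into a 2-D image (pixel units, 1-based centers).
// combine_max = true emulates a maximum-intensity projection; false sums.
// [[Rcpp::export]]
NumericMatrix cpp_render_blobs_2d(int nrow, int ncol, NumericVector ci,
                                  NumericVector cj, NumericVector amp,
                                  double sigma_px, double cutoff,
                                  bool combine_max) {
  NumericMatrix img(nrow, ncol);
  const int w = (int)std::ceil(cutoff * sigma_px);
  const double inv2s2 = 1.0 / (2.0 * sigma_px * sigma_px);
  for (int k = 0; k < ci.size(); ++k) {
    int i0 = std::max(0, (int)std::floor(ci[k]) - 1 - w);
    int i1 = std::min(nrow - 1, (int)std::ceil(ci[k]) - 1 + w);
    int j0 = std::max(0, (int)std::floor(cj[k]) - 1 - w);
    int j1 = std::min(ncol - 1, (int)std::ceil(cj[k]) - 1 + w);
    for (int j = j0; j <= j1; ++j) {
      double dj = (j + 1) - cj[k];
      for (int i = i0; i <= i1; ++i) {
        double di = (i + 1) - ci[k];
        double v = amp[k] * std::exp(-(di * di + dj * dj) * inv2s2);
        if (combine_max) {
          if (v > img(i, j)) img(i, j) = v;
        } else {
          img(i, j) += v;
        }
      }
    }
  }
  return img;
}

// Render Gaussian blobs into a 3-D (z, y, x) array, additive.
// [[Rcpp::export]]
NumericVector cpp_render_blobs_3d(int nz, int ny, int nx, NumericVector cz,
                                  NumericVector cy, NumericVector cx,
                                  NumericVector amp, double sigma_z_px,
                                  double sigma_xy_px, double cutoff) {
  NumericVector arr(nz * ny * nx);
  const int wz = (int)std::ceil(cutoff * sigma_z_px);
  const int wxy = (int)std::ceil(cutoff * sigma_xy_px);
  const double iz2 = 1.0 / (2.0 * sigma_z_px * sigma_z_px);
  const double ixy2 = 1.0 / (2.0 * sigma_xy_px * sigma_xy_px);
  for (int k = 0; k < cz.size(); ++k) {
    int z0 = std::max(0, (int)std::floor(cz[k]) - 1 - wz);
    int z1 = std::min(nz - 1, (int)std::ceil(cz[k]) - 1 + wz);
    int y0 = std::max(0, (int)std::floor(cy[k]) - 1 - wxy);
    int y1 = std::min(ny - 1, (int)std::ceil(cy[k]) - 1 + wxy);
    int x0 = std::max(0, (int)std::floor(cx[k]) - 1 - wxy);
    int x1 = std::min(nx - 1, (int)std::ceil(cx[k]) - 1 + wxy);
    if (z1 < z0 || y1 < y0 || x1 < x0) continue;
    for (int x = x0; x <= x1; ++x) {
      double dx = (x + 1) - cx[k];
      for (int y = y0; y <= y1; ++y) {
        double dy = (y + 1) - cy[k];
        double exy = std::exp(-(dx * dx + dy * dy) * ixy2);
        for (int z = z0; z <= z1; ++z) {
          double dz = (z + 1) - cz[k];
          arr[z + (long long)nz * (y + (long long)ny * x)] +=
            amp[k] * exy * std::exp(-dz * dz * iz2);
        }
      }
    }
  }
  return arr;
}

// Greedy pairing: anterior points (in order) claim the nearest unused
// equatorial point within tol. Returns 1-based index or NA.
// The vertical (latitude) coordinate predicted from an inverted anterior
// centroid is ill-conditioned near the rim (d(colat)/dr ~ 1/cos(colat)), so
// pairing uses an anisotropic metric: dist^2 = dx^2 + (dy / y_scale)^2.
static void greedy_pair(const std::vector<double>& ax,
                        const std::vector<double>& ay,
                        const NumericVector& ex, const NumericVector& ey,
                        double tol, double y_scale, std::vector<int>& match,
                        int& n_in, double& res_sum) {
  const int ne = ex.size();
  std::vector<bool> used(ne, false);
  const double t2 = tol * tol;
  n_in = 0; res_sum = 0.0;
  match.assign(ax.size(), -1);
  for (size_t a = 0; a < ax.size(); ++a) {
    double best = t2; int bi = -1;
    for (int e = 0; e < ne; ++e) {
      if (used[e]) continue;
      double dx = ax[a] - ex[e], dy = (ay[a] - ey[e]) / y_scale;
      double d2 = dx * dx + dy * dy;
      if (d2 <= best) { best = d2; bi = e; }
    }
    if (bi >= 0) {
      used[bi] = true;
      match[a] = bi;
      ++n_in;
      res_sum += std::sqrt(best);
    }
  }
}

// For each candidate view azimuth, forward-project the anterior EdU points
// (given as colatitude/azimuth on a sphere of radius R) into the equatorial
// frame and greedily pair them with the equatorial EdU centroids.
// Returns a matrix with columns (n_inliers, mean_residual).
// [[Rcpp::export]]
NumericMatrix cpp_match_rotation(NumericVector theta, NumericVector az,
                                 NumericVector eq_x, NumericVector eq_y,
                                 double R, double tol, double y_scale,
                                 NumericVector angles) {
  const int na = theta.size(), nv = angles.size();
  NumericMatrix out(nv, 2);
  std::vector<double> px, py;
  std::vector<int> match;
  for (int v = 0; v < nv; ++v) {
    px.clear(); py.clear();
    for (int a = 0; a < na; ++a) {
      double d = az[a] - angles[v];
      if (std::cos(d) < 0) continue;  // back hemisphere not visible
      px.push_back(R * std::sin(theta[a]) * std::sin(d));
      py.push_back(R * std::cos(theta[a]));
    }
    int n_in; double res;
    greedy_pair(px, py, eq_x, eq_y, tol, y_scale, match, n_in, res);
    out(v, 0) = n_in;
    out(v, 1) = n_in > 0 ? res / n_in : NA_REAL;
  }
  return out;
}

// Greedy pairing of two planar point sets (exported for the final match).
// [[Rcpp::export]]
IntegerVector cpp_greedy_pairs(NumericVector ax, NumericVector ay,
                               NumericVector ex, NumericVector ey,
                               double tol, double y_scale) {
  std::vector<double> vx(ax.begin(), ax.end()), vy(ay.begin(), ay.end());
  std::vector<int> match;
  int n_in; double res;
  greedy_pair(vx, vy, ex, ey, tol, y_scale, match, n_in, res);
  IntegerVector out(match.size());
  for (size_t i = 0; i < match.size(); ++i)
    out[i] = match[i] < 0 ? NA_INTEGER : match[i] + 1;
  return out;
}
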