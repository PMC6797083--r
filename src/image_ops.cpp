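#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Separable Gaussian convolution with reflected boundaries.
// Kernel truncated at 4 sigma (standard choice; error < 1e-4 of peak).
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  // along columns (horizontal)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= nc) cc = 2 * nc - cc - 1;
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// 8-connected components of a binary mask, labels in raster-scan discovery
// order (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      // raster order: column-major matches R matrix layout; discovery order
      // is deterministic either way
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int d = 0; d < 8; ++d) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  return lab;
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // Felzenszwalb & Huttenlocher lower envelope of parabolas
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance transform: distance from each foreground
// pixel to the nearest background pixel (background gets 0).
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), buf(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, buf, nr);
    for (int r = 0; r < nr; ++r) d(r, c) = buf[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt1d(f, buf, nc);
    for (int c = 0; c < nc; ++c) d(r, c) = buf[c];
  }
  return d;
}

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker <= mask assumed), 8-connectivity. FIFO-queue algorithm.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(const NumericMatrix& marker,
                                       const NumericMatrix& mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix out(clone(marker));
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // raster scan then anti-raster scan, then queue propagation
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = out(r, c);
      for (int d = 0; d < 4; ++d) { // causal neighbors in column-major scan
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (out(r2, c2) > m) m = out(r2, c2);
      }
      out(r, c) = std::min(m, mask(r, c));
    }
  std::queue<int> q;
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double m = out(r, c);
      for (int d = 4; d < 8; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (out(r2, c2) > m) m = out(r2, c2);
      }
      out(r, c) = std::min(m, mask(r, c));
      for (int d = 4; d < 8; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (out(r2, c2) < out(r, c) && out(r2, c2) < mask(r2, c2))
          q.push(r + c * nr);
      }
    }
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    for (int d = 0; d < 8; ++d) {
      int r2 = r + dr[d], c2 = c + dc[d];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (out(r2, c2) < out(r, c) && out(r2, c2) < mask(r2, c2)) {
        out(r2, c2) = std::min(out(r, c), mask(r2, c2));
        q.push(r2 + c2 * nr);
      }
    }
  }
  return out;
}

// Regional maxima of `img` restricted to `fg`: connected plateaus (8-conn)
// with no strictly higher neighbor inside fg. Returns plateau labels
// (0 = not a maximum), in raster discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(const NumericMatrix& img,
                                  const LogicalMatrix& fg) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<signed char> state(nr * nc, 0); // 0 unvisited, 1 done
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::vector<int> plateau, stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int idx0 = r + c * nr;
      if (!fg(r, c) || state[idx0]) continue;
      double v = img(r, c);
      bool is_max = true;
      plateau.clear();
      stack.clear();
      stack.push_back(idx0);
      state[idx0] = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        plateau.push_back(idx);
        int rr = idx % nr, cc = idx / nr;
        for (int d = 0; d < 8; ++d) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!fg(r2, c2)) continue;
          double v2 = img(r2, c2);
          if (v2 > v) { is_max = false; continue; }
          int idx2 = r2 + c2 * nr;
          if (v2 == v && !state[idx2]) {
            state[idx2] = 1;
            stack.push_back(idx2);
          }
        }
      }
      if (is_max) {
        ++next;
        for (int idx : plateau) lab(idx % nr, idx / nr) = next;
      }
    }
  return lab;
}

// Marker-based watershed by priority flooding on a height map: flooding
// proceeds from markers in order of DECREASING `height` (use the distance
// transform directly). Ties broken by insertion order (raster-deterministic).
// Unlabeled foreground pixels adjacent to the flood take the label of the
// first basin to reach them; no watershed-line pixels are produced.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& height,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& fg) {
  int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(clone(markers));
  struct Node {
    double h;
    long order;
    int idx;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.h != b.h) return a.h < b.h;       // max-heap on height
      return a.order > b.order;               // FIFO among equals
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long counter = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0 && fg(r, c))
        pq.push({height(r, c), counter++, r + c * nr});
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int l = lab(r, c);
    for (int d = 0; d < 8; ++d) {
      int r2 = r + dr[d], c2 = c + dc[d];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!fg(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = l;
      pq.push({height(r2, c2), counter++, r2 + c2 * nr});
    }
  }
  return lab;
}

// Paint a spherocylinder (or an annular DNA halo when mode = 1) into `img`
// IN PLACE, taking the per-pixel maximum with the existing content. Pixel
// (r, c) (0-based here) has its center at ((c + 0.5) px, (r + 0.5) px).
// mode 0: constant `amplitude` where center-to-axis distance d < w/2.
// mode 1: amplitude * profile(d): 1 on [r_in, r_out], Gaussian shoulders of
// sigma `sig` outside the band, floor `core_floor` inside.
// [[Rcpp::export]]
void cpp_paint_cell(NumericMatrix img, double x, double y, double theta,
                    double len, double w, double px, double amplitude,
                    int mode, double r_in, double r_out, double sig,
                    double core_floor, double pad) {
  int nr = img.nrow(), nc = img.ncol();
  double half = len / 2.0 + pad;
  int rr0 = std::max(0, (int)std::floor((y - half) / px) - 1);
  int rr1 = std::min(nr - 1, (int)std::ceil((y + half) / px) + 1);
  int cc0 = std::max(0, (int)std::floor((x - half) / px) - 1);
  int cc1 = std::min(nc - 1, (int)std::ceil((x + half) / px) + 1);
  double hx = (len - w) / 2.0;
  double ux = std::cos(theta), uy = std::sin(theta);
  for (int c = cc0; c <= cc1; ++c) {
    double dx = (c + 0.5) * px - x;
    for (int r = rr0; r <= rr1; ++r) {
      double dy = (r + 0.5) * px - y;
      double t = dx * ux + dy * uy;
      if (t > hx) t = hx;
      if (t < -hx) t = -hx;
      double ex = dx - t * ux, ey = dy - t * uy;
      double d = std::sqrt(ex * ex + ey * ey);
      double v = 0.0;
      if (mode == 0) {
        if (d < w / 2.0) v = amplitude;
      } else {
        double f;
        if (d >= r_in && d <= r_out) f = 1.0;
        else if (d < r_in) {
          double g = std::exp(-(r_in - d) * (r_in - d) / (2 * sig * sig));
          f = std::max(core_floor, g);
        } else {
          f = std::exp(-(d - r_out) * (d - r_out) / (2 * sig * sig));
        }
        v = amplitude * f;
      }
      if (v > img(r, c)) img(r, c) = v;
    }
  }
}
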