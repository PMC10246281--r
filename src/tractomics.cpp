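// Inner loops for texture-matrix construction, the QuickBundles single
// pass, and greedy correlation pruning. Discretized parcels are passed
// as integer 3-D arrays with 0 outside the parcel and levels 1..nlevels
// inside.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 13 unique 3-D directions (one per +/- offset pair, 26-connectivity)
static const int DIRS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

inline int at(const IntegerVector& img, const IntegerVector& d,
              int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= d[0] || y >= d[1] || z >= d[2])
    return -1;                      // outside grid
  return img[x + d[0] * (y + d[1] * z)];
}

// Symmetric gray-level co-occurrence counts, one nlevels x nlevels
// matrix per direction (stacked along the third dimension).
// [[Rcpp::export]]
NumericVector glcm_cpp(IntegerVector img, IntegerVector dims, int nlevels) {
  NumericVector out(nlevels * nlevels * 13);
  out.attr("dim") = IntegerVector::create(nlevels, nlevels, 13);
  for (int dir = 0; dir < 13; ++dir) {
    int dx = DIRS[dir][0], dy = DIRS[dir][1], dz = DIRS[dir][2];
    for (int z = 0; z < dims[2]; ++z)
      for (int y = 0; y < dims[1]; ++y)
        for (int x = 0; x < dims[0]; ++x) {
          int a = at(img, dims, x, y, z);
          if (a <= 0) continue;
          int b = at(img, dims, x + dx, y + dy, z + dz);
          if (b <= 0) continue;
          out[(a - 1) + nlevels * (b - 1) + nlevels * nlevels * dir] += 1.0;
          out[(b - 1) + nlevels * (a - 1) + nlevels * nlevels * dir] += 1.0;
        }
  }
  return out;
}

// Gray-level run-length counts, nlevels x maxrun per direction.
// [[Rcpp::export]]
NumericVector glrlm_cpp(IntegerVector img, IntegerVector dims, int nlevels) {
  int maxrun = std::max(dims[0], std::max(dims[1], dims[2]));
  // diagonal runs can be at most min over the involved axes, <= maxrun
  NumericVector out(nlevels * maxrun * 13);
  out.attr("dim") = IntegerVector::create(nlevels, maxrun, 13);
  for (int dir = 0; dir < 13; ++dir) {
    int dx = DIRS[dir][0], dy = DIRS[dir][1], dz = DIRS[dir][2];
    for (int z = 0; z < dims[2]; ++z)
      for (int y = 0; y < dims[1]; ++y)
        for (int x = 0; x < dims[0]; ++x) {
          // start of a line in this direction?
          if (at(img, dims, x - dx, y - dy, z - dz) != -1) continue;
          int cx = x, cy = y, cz = z;
          int cur = -2, len = 0;
          while (true) {
            int v = at(img, dims, cx, cy, cz);
            if (v == -1) break;
            if (v == cur) {
              ++len;
            } else {
              if (cur > 0)
                out[(cur - 1) + nlevels * (len - 1) +
                    nlevels * maxrun * dir] += 1.0;
              cur = v; len = 1;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (cur > 0)
            out[(cur - 1) + nlevels * (len - 1) + nlevels * maxrun * dir] += 1.0;
        }
  }
  return out;
}

// Gray-level size-zone counts: zones are 26-connected components of
// equal gray level; returns nlevels x maxsize matrix.
// [[Rcpp::export]]
NumericMatrix glszm_cpp(IntegerVector img, IntegerVector dims, int nlevels) {
  int nv = dims[0] * dims[1] * dims[2];
  std::vector<bool> seen(nv, false);
  std::vector<std::pair<int,int> > zones;   // (level, size)
  int maxsize = 1;
  for (int z0 = 0; z0 < dims[2]; ++z0)
    for (int y0 = 0; y0 < dims[1]; ++y0)
      for (int x0 = 0; x0 < dims[0]; ++x0) {
        int i0 = x0 + dims[0] * (y0 + dims[1] * z0);
        int lv = img[i0];
        if (lv <= 0 || seen[i0]) continue;
        int size = 0;
        std::queue<int> q;
        q.push(i0); seen[i0] = true;
        while (!q.empty()) {
          int i = q.front(); q.pop();
          ++size;
          int x = i % dims[0], y = (i / dims[0]) % dims[1],
              zz = i / (dims[0] * dims[1]);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int nx = x + dx, ny = y + dy, nz = zz + dz;
                if (at(img, dims, nx, ny, nz) != lv) continue;
                int j = nx + dims[0] * (ny + dims[1] * nz);
                if (!seen[j]) { seen[j] = true; q.push(j); }
              }
        }
        zones.push_back(std::make_pair(lv, size));
        if (size > maxsize) maxsize = size;
      }
  NumericMatrix out(nlevels, maxsize);
  for (size_t k = 0; k < zones.size(); ++k)
    out(zones[k].first - 1, zones[k].second - 1) += 1.0;
  return out;
}

// Gray-level dependence counts: dependence of a voxel = number of
// 26-neighbors (inside the parcel) whose level differs by <= alpha.
// Returns nlevels x 27 matrix (dependence 0..26 -> column j+1).
// [[Rcpp::export]]
NumericMatrix gldm_cpp(IntegerVector img, IntegerVector dims, int nlevels,
                       int alpha) {
  NumericMatrix out(nlevels, 27);
  for (int z = 0; z < dims[2]; ++z)
    for (int y = 0; y < dims[1]; ++y)
      for (int x = 0; x < dims[0]; ++x) {
        int v = at(img, dims, x, y, z);
        if (v <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int u = at(img, dims, x + dx, y + dy, z + dz);
              if (u > 0 && std::abs(u - v) <= alpha) ++dep;
            }
        out(v - 1, dep) += 1.0;
      }
  return out;
}

// Neighbouring gray-tone difference accumulators: for each level i the
// voxel count n_i and the summed absolute difference s_i between the
// voxel level and the mean of its valid 26-neighbors.
// [[Rcpp::export]]
NumericMatrix ngtdm_cpp(IntegerVector img, IntegerVector dims, int nlevels) {
  NumericMatrix out(nlevels, 2);   // columns: n_i, s_i
  for (int z = 0; z < dims[2]; ++z)
    for (int y = 0; y < dims[1]; ++y)
      for (int x = 0; x < dims[0]; ++x) {
        int v = at(img, dims, x, y, z);
        if (v <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int u = at(img, dims, x + dx, y + dy, z + dz);
              if (u > 0) { sum += u; ++cnt; }
            }
        if (cnt == 0) continue;
        out(v - 1, 0) += 1.0;
        out(v - 1, 1) += std::fabs((double)v - sum / cnt);
      }
  return out;
}

// QuickBundles single pass over streamlines resampled to a common point
// count: pts is n_points x 3 x N. Assigns each streamline to the
// nearest running-mean centroid by MDF if within threshold, else starts
// a new cluster. Flipped streamlines are added reversed.
// [[Rcpp::export]]
List quickbundles_cpp(NumericVector pts, double threshold) {
  IntegerVector dims = pts.attr("dim");
  int np = dims[0], N = dims[2];
  std::vector<std::vector<double> > sums;   // per cluster: np*3 running sum
  std::vector<int> counts;
  IntegerVector assign(N);
  std::vector<double> direct(np), flip(np);
  for (int i = 0; i < N; ++i) {
    double best = R_PosInf; int bestc = -1; bool bestflip = false;
    for (size_t c = 0; c < sums.size(); ++c) {
      double dsum = 0.0, fsum = 0.0;
      double inv = 1.0 / counts[c];
      for (int p = 0; p < np; ++p) {
        double dd = 0.0, ff = 0.0;
        for (int k = 0; k < 3; ++k) {
          double x = pts[p + np * k + np * 3 * i];
          double cd = sums[c][p + np * k] * inv;
          double cf = sums[c][(np - 1 - p) + np * k] * inv;
          dd += (x - cd) * (x - cd);
          ff += (x - cf) * (x - cf);
        }
        dsum += std::sqrt(dd);
        fsum += std::sqrt(ff);
      }
      double d = dsum / np, f = fsum / np;
      double m = d < f ? d : f;
      if (m < best) { best = m; bestc = (int)c; bestflip = f < d; }
    }
    if (bestc >= 0 && best <= threshold) {
      assign[i] = bestc + 1;
      for (int p = 0; p < np; ++p)
        for (int k = 0; k < 3; ++k) {
          int src = bestflip ? (np - 1 - p) : p;
          sums[bestc][p + np * k] += pts[src + np * k + np * 3 * i];
        }
      counts[bestc] += 1;
    } else {
      std::vector<double> s(np * 3);
      for (int p = 0; p < np; ++p)
        for (int k = 0; k < 3; ++k)
          s[p + np * k] = pts[p + np * k + np * 3 * i];
      sums.push_back(s);
      counts.push_back(1);
      assign[i] = (int)sums.size();
    }
  }
  int K = (int)sums.size();
  NumericVector centroids(np * 3 * K);
  centroids.attr("dim") = IntegerVector::create(np, 3, K);
  for (int c = 0; c < K; ++c)
    for (int j = 0; j < np * 3; ++j)
      centroids[j + np * 3 * c] = sums[c][j] / counts[c];
  return List::create(_["assignment"] = assign, _["centroids"] = centroids);
}

// Greedy correlation pruning: keep column j iff no earlier kept column
// has |r| > threshold with it. S is the p x p centered cross-product
// (covariance up to a constant factor), so r^2(j,k) = S(j,k)^2 /
// (S(j,j) S(k,k)).
// [[Rcpp::export]]
LogicalVector prune_correlated_cpp(NumericMatrix S, double threshold) {
  int p = S.ncol();
  double t2 = threshold * threshold;
  LogicalVector keep(p);
  std::vector<int> kept;
  for (int j = 0; j < p; ++j) {
    bool ok = true;
    double vj = S(j, j);
    for (size_t k = 0; k < kept.size(); ++k) {
      int i = kept[k];
      double c = S(i, j);
      if (c * c > t2 * S(i, i) * vj) { ok = false; break; }
    }
    keep[j] = ok;
    if (ok) kept.push_back(j);
  }
  return keep;
}
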