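// Low-level lattice routines for void-phase analysis.
//
// All volumes are stored as R arrays with dim = (nz, ny, nx); the z index
// varies fastest in memory.  Linear index: i = z + nz * (y + ny * x).
// The lattice border is treated as solid throughout (a virtual solid shell
// outside the volume), so no inscribed ball can escape the field of view.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const double BIG = 1e15; // finite stand-in for +inf in the parabola sweep

// ---------------------------------------------------------------------------
// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher squared EDT)
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -BIG;
  zb[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform (center-to-center, voxel units).
// mask: logical, true = void.  Border counts as solid.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int pz = nz + 2, py = ny + 2, px = nx + 2;
  std::vector<double> g((size_t)pz * py * px, 0.0);
  // interior: BIG where void (distance unknown), 0 where solid
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t ip = (size_t)(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1));
        size_t i0 = (size_t)z + (size_t)nz * (y + (size_t)ny * x);
        if (mask[i0]) g[ip] = BIG;
      }

  int nmax = std::max(pz, std::max(py, px));
  std::vector<double> f(nmax), dline(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  for (int x = 0; x < px; ++x)
    for (int y = 0; y < py; ++y) {
      size_t base = (size_t)pz * (y + (size_t)py * x);
      for (int z = 0; z < pz; ++z) f[z] = g[base + z];
      dt1d(f, dline, pz, v, zb);
      for (int z = 0; z < pz; ++z) g[base + z] = dline[z];
    }
  // pass along y
  for (int x = 0; x < px; ++x)
    for (int z = 0; z < pz; ++z) {
      for (int y = 0; y < py; ++y) f[y] = g[(size_t)z + (size_t)pz * (y + (size_t)py * x)];
      dt1d(f, dline, py, v, zb);
      for (int y = 0; y < py; ++y) g[(size_t)z + (size_t)pz * (y + (size_t)py * x)] = dline[y];
    }
  // pass along x
  for (int y = 0; y < py; ++y)
    for (int z = 0; z < pz; ++z) {
      for (int x = 0; x < px; ++x) f[x] = g[(size_t)z + (size_t)pz * (y + (size_t)py * x)];
      dt1d(f, dline, px, v, zb);
      for (int x = 0; x < px; ++x) g[(size_t)z + (size_t)pz * (y + (size_t)py * x)] = dline[x];
    }

  NumericVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t ip = (size_t)(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1));
        size_t i0 = (size_t)z + (size_t)nz * (y + (size_t)ny * x);
        out[i0] = std::sqrt(g[ip]);
      }
  return out;
}

// ---------------------------------------------------------------------------
// Maximal-ball redundancy pruning
// ---------------------------------------------------------------------------
// Ball B(c2, r2) is redundant if some retained B(c1, r1) satisfies
// |c1 - c2| + r2 <= r1 + eps.  Candidates are processed in decreasing radius
// (ties: lexicographic on (z, y, x)), so a ball can only be absorbed by one
// at least as large that was examined earlier.  A uniform grid over centers
// keeps the search local.
// [[Rcpp::export]]
LogicalVector cpp_prune_balls(IntegerMatrix centers, NumericVector radii,
                              double eps) {
  const int n = centers.nrow();
  LogicalVector keep(n);
  if (n == 0) return keep;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (radii[a] != radii[b]) return radii[a] > radii[b];
    if (centers(a, 0) != centers(b, 0)) return centers(a, 0) < centers(b, 0);
    if (centers(a, 1) != centers(b, 1)) return centers(a, 1) < centers(b, 1);
    return centers(a, 2) < centers(b, 2);
  });

  double rmax = radii[ord[0]];
  const double cs = 4.0; // grid cell edge, voxels
  std::unordered_map<long long, std::vector<int> > grid;
  auto key = [](long long cz, long long cy, long long cx) {
    return ((cz + 4096) << 28) ^ ((cy + 4096) << 14) ^ (cx + 4096);
  };

  for (int t = 0; t < n; ++t) {
    int i = ord[t];
    double zi = centers(i, 0), yi = centers(i, 1), xi = centers(i, 2);
    double reach = rmax - radii[i] + eps; // max center distance of an absorber
    if (reach < 0) reach = 0;
    int rc = (int)std::floor(reach / cs) + 1;
    long long cz = (long long)std::floor(zi / cs);
    long long cy = (long long)std::floor(yi / cs);
    long long cx = (long long)std::floor(xi / cs);
    bool contained = false;
    for (long long az = cz - rc; az <= cz + rc && !contained; ++az)
      for (long long ay = cy - rc; ay <= cy + rc && !contained; ++ay)
        for (long long ax = cx - rc; ax <= cx + rc && !contained; ++ax) {
          auto it = grid.find(key(az, ay, ax));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double dz = zi - centers(j, 0), dy = yi - centers(j, 1),
                   dx = xi - centers(j, 2);
            double dist = std::sqrt(dz * dz + dy * dy + dx * dx);
            if (dist + radii[i] <= radii[j] + eps) {
              contained = true;
              break;
            }
          }
        }
    if (!contained) {
      keep[i] = true;
      grid[key(cz, cy, cx)].push_back(i);
    }
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Plateau-collapsed local maxima of the distance field (pore seeds)
// ---------------------------------------------------------------------------
// A plateau is a 26-connected set of void voxels with equal d.  The plateau
// is a maximum iff no member has a 26-neighbour with strictly larger d
// (out-of-bounds and solid count as d = 0).  Each maximum plateau yields one
// seed: its lexicographically smallest (z, y, x) member.
// [[Rcpp::export]]
IntegerMatrix cpp_find_seeds(NumericVector d, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t ntot = (size_t)nz * ny * nx;
  std::vector<char> visited(ntot, 0);
  std::vector<std::array<int, 3> > seeds;
  std::vector<size_t> stack, members;

  auto lin = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * (y + (size_t)ny * x);
  };

  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        size_t i0 = lin(z0, y0, x0);
        if (visited[i0] || d[i0] <= 0) continue;
        double h = d[i0];
        bool is_max = true;
        stack.clear();
        members.clear();
        stack.push_back(i0);
        visited[i0] = 1;
        while (!stack.empty()) {
          size_t i = stack.back();
          stack.pop_back();
          members.push_back(i);
          int z = (int)(i % nz);
          int y = (int)((i / nz) % ny);
          int x = (int)(i / ((size_t)nz * ny));
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dz && !dy && !dx) continue;
                int zz = z + dz, yy = y + dy, xx = x + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                    xx >= nx)
                  continue; // border = solid, d = 0 < h
                size_t j = lin(zz, yy, xx);
                if (d[j] > h) {
                  is_max = false;
                } else if (d[j] == h && !visited[j]) {
                  visited[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        if (is_max) {
          // lexicographically smallest member on (z, y, x)
          std::array<int, 3> best = {nz, ny, nx};
          for (size_t i : members) {
            std::array<int, 3> c = {(int)(i % nz), (int)((i / nz) % ny),
                                    (int)(i / ((size_t)nz * ny))};
            if (c < best) best = c;
          }
          seeds.push_back(best);
        }
      }

  IntegerMatrix out((int)seeds.size(), 3);
  for (size_t k = 0; k < seeds.size(); ++k) {
    out(k, 0) = seeds[k][0];
    out(k, 1) = seeds[k][1];
    out(k, 2) = seeds[k][2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Descending-d region growth from seeds
// ---------------------------------------------------------------------------
// Seeds (rows of `seeds`, 0-based (z, y, x)) get labels 1..P in row order.
// Remaining void voxels are assigned by priority flooding — a watershed of
// -d seeded at the maxima: the frontier voxel with the largest d (ties
// lexicographic on (z, y, x)) is assigned next, to the region of its
// highest-d already-assigned 26-neighbour (ties toward the lower label).
// Flooding, rather than one global decreasing-d sweep, guarantees every
// voxel has an assigned neighbour when its turn comes, including members of
// non-maximum plateaus.
// [[Rcpp::export]]
IntegerVector cpp_grow_regions(NumericVector d, IntegerVector dims,
                               IntegerMatrix seeds) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t ntot = (size_t)nz * ny * nx;
  IntegerVector lab(ntot); // 0 = solid / unassigned
  auto lin = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * (y + (size_t)ny * x);
  };

  struct Item {
    double d;
    int z, y, x;
    size_t i;
  };
  // max-d first; ties: lexicographically smallest (z, y, x) first
  auto cmp = [](const Item& a, const Item& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.z != b.z) return a.z > b.z;
    if (a.y != b.y) return a.y > b.y;
    return a.x > b.x;
  };
  std::priority_queue<Item, std::vector<Item>, decltype(cmp)> pq(cmp);
  std::vector<char> queued(ntot, 0);

  auto push_neighbours = [&](int z, int y, int x) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
              xx >= nx)
            continue;
          size_t j = lin(zz, yy, xx);
          if (d[j] > 0 && !lab[j] && !queued[j]) {
            queued[j] = 1;
            pq.push({d[j], zz, yy, xx, j});
          }
        }
  };

  for (int k = 0; k < seeds.nrow(); ++k) {
    lab[lin(seeds(k, 0), seeds(k, 1), seeds(k, 2))] = k + 1;
  }
  for (int k = 0; k < seeds.nrow(); ++k)
    push_neighbours(seeds(k, 0), seeds(k, 1), seeds(k, 2));

  while (!pq.empty()) {
    Item it = pq.top();
    pq.pop();
    if (lab[it.i]) continue;
    double best_d = -1.0;
    int best_lab = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = it.z + dz, yy = it.y + dy, xx = it.x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
              xx >= nx)
            continue;
          size_t j = lin(zz, yy, xx);
          if (lab[j] > 0 &&
              (d[j] > best_d || (d[j] == best_d && lab[j] < best_lab))) {
            best_d = d[j];
            best_lab = lab[j];
          }
        }
    lab[it.i] = best_lab; // frontier voxels always touch an assigned region
    push_neighbours(it.z, it.y, it.x);
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Inter-region interfaces (throat candidates)
// ---------------------------------------------------------------------------
// For every 26-adjacent pair of void voxels carrying different labels, the
// voxel pair belongs to the (a, b) interface.  A path from pore a to pore b
// crossing at that pair is limited by the smaller of the two inscribed
// radii, so the throat (saddle) radius is the maximum over interface pairs
// of min(d_i, d_j); this keeps the saddle below both peaks.
// Returns a matrix with columns (a, b, radius) and a < b.
// [[Rcpp::export]]
NumericMatrix cpp_find_throats(NumericVector d, IntegerVector lab,
                               IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  auto lin = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * (y + (size_t)ny * x);
  };
  // 13 forward offsets of the 26-neighbourhood
  static const int off[13][3] = {{1, 0, 0},  {0, 1, 0},   {0, 0, 1},
                                 {1, 1, 0},  {1, -1, 0},  {1, 0, 1},
                                 {1, 0, -1}, {0, 1, 1},   {0, 1, -1},
                                 {1, 1, 1},  {1, 1, -1},  {1, -1, 1},
                                 {1, -1, -1}};
  std::unordered_map<long long, double> sad;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = lin(z, y, x);
        int la = lab[i];
        if (la == 0) continue;
        for (int o = 0; o < 13; ++o) {
          int zz = z + off[o][0], yy = y + off[o][1], xx = x + off[o][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          size_t j = lin(zz, yy, xx);
          int lb = lab[j];
          if (lb == 0 || lb == la) continue;
          int a = std::min(la, lb), b = std::max(la, lb);
          long long k = (long long)a * 10000000LL + b;
          double h = std::min(d[i], d[j]);
          auto it = sad.find(k);
          if (it == sad.end())
            sad[k] = h;
          else if (h > it->second)
            it->second = h;
        }
      }
  NumericMatrix out((int)sad.size(), 3);
  int r = 0;
  for (auto& kv : sad) {
    out(r, 0) = (double)(kv.first / 10000000LL);
    out(r, 1) = (double)(kv.first % 10000000LL);
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary mask (6 or 26 connectivity)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t ntot = (size_t)nz * ny * nx;
  IntegerVector lab(ntot);
  auto lin = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * (y + (size_t)ny * x);
  };
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i0 = 0; i0 < ntot; ++i0) {
    if (!mask[i0] || lab[i0]) continue;
    ++next;
    lab[i0] = next;
    stack.clear();
    stack.push_back(i0);
    while (!stack.empty()) {
      size_t i = stack.back();
      stack.pop_back();
      int z = (int)(i % nz), y = (int)((i / nz) % ny),
          x = (int)(i / ((size_t)nz * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
            if (connectivity == 6 && man > 1) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                xx >= nx)
              continue;
            size_t j = lin(zz, yy, xx);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur (truncated at 3 sigma, edge-renormalised)
// ---------------------------------------------------------------------------
static void blur_axis(std::vector<double>& a, int nz, int ny, int nx, int axis,
                      const std::vector<double>& kern) {
  int rad = ((int)kern.size() - 1) / 2;
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::vector<double> line(n), outl(n);
  int n1 = (axis == 0) ? ny : nz;
  int n2 = (axis == 0) ? nx : (axis == 1) ? nx : ny;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int q = 0; q < n; ++q) {
        int z, y, x;
        if (axis == 0) { z = q; y = i1; x = i2; }
        else if (axis == 1) { z = i1; y = q; x = i2; }
        else { z = i1; y = i2; x = q; }
        line[q] = a[(size_t)z + (size_t)nz * (y + (size_t)ny * x)];
      }
      for (int q = 0; q < n; ++q) {
        double s = 0.0, w = 0.0;
        for (int k = -rad; k <= rad; ++k) {
          int qq = q + k;
          if (qq < 0 || qq >= n) continue;
          s += kern[k + rad] * line[qq];
          w += kern[k + rad];
        }
        outl[q] = s / w;
      }
      for (int q = 0; q < n; ++q) {
        int z, y, x;
        if (axis == 0) { z = q; y = i1; x = i2; }
        else if (axis == 1) { z = i1; y = q; x = i2; }
        else { z = i1; y = i2; x = q; }
        a[(size_t)z + (size_t)nz * (y + (size_t)ny * x)] = outl[q];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dims,
                                double sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> a(vol.begin(), vol.end());
  if (sigma > 0) {
    int rad = (int)std::ceil(3.0 * sigma);
    std::vector<double> kern(2 * rad + 1);
    for (int k = -rad; k <= rad; ++k)
      kern[k + rad] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    blur_axis(a, nz, ny, nx, 0, kern);
    blur_axis(a, nz, ny, nx, 1, kern);
    blur_axis(a, nz, ny, nx, 2, kern);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}
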