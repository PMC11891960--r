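// Voxel topology primitives: connected-component labelling, neighbour
// census and topology-preserving curve thinning.
//
// Array convention (shared with the R side): dims = (nz, ny, nx), linear
// index = z + nz*(y + ny*x), i.e. an R array with dim = c(nz, ny, nx).
// Volumes are bounded by 2^31-1 voxels; linear arithmetic uses long.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstdlib>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

struct Dims {
  int nz, ny, nx;
};

inline long lin(int z, int y, int x, const Dims& d) {
  return (long)z + (long)d.nz * ((long)y + (long)d.ny * (long)x);
}

// Neighbourhood offsets (dz, dy, dx) for a 6/18/26 connectivity class.
std::vector<std::array<int, 3>> offsets_for(int connectivity) {
  std::vector<std::array<int, 3>> out;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        out.push_back({dz, dy, dx});
      }
  return out;
}

// Local 3x3x3 cube indexing: loc = (dz+1) + 3*(dy+1) + 9*(dx+1), centre 13.
inline void loc_coord(int i, int& dz, int& dy, int& dx) {
  dz = i % 3 - 1;
  dy = (i / 3) % 3 - 1;
  dx = i / 9 - 1;
}

// Bertrand & Malandain characterization of a 26/6 simple point:
//  (a) the foreground of the 26-neighbourhood forms exactly one
//      26-connected component, and
//  (b) the background restricted to the 18-neighbourhood forms exactly one
//      6-connected component that is 6-adjacent to the centre.
bool is_simple_point(const uint8_t* loc) {
  int lab[27] = {0};
  int st[27];
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !loc[i] || lab[i]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int top = 0;
    st[top++] = i;
    lab[i] = ncomp;
    while (top) {
      int c = st[--top];
      int cz, cy, cx;
      loc_coord(c, cz, cy, cx);
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !loc[j] || lab[j]) continue;
        int jz, jy, jx;
        loc_coord(j, jz, jy, jx);
        if (std::abs(jz - cz) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jx - cx) <= 1) {
          lab[j] = ncomp;
          st[top++] = j;
        }
      }
    }
  }
  if (ncomp != 1) return false;

  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int dz, dy, dx;
    loc_coord(i, dz, dy, dx);
    int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
    in18[i] = (s >= 1 && s <= 2);
  }
  int lab2[27] = {0};
  int nface = 0;  // background 6-components touching a face neighbour
  int ncomp2 = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || loc[i] || lab2[i]) continue;
    ++ncomp2;
    bool touches_face = false;
    int top = 0;
    st[top++] = i;
    lab2[i] = ncomp2;
    while (top) {
      int c = st[--top];
      int cz, cy, cx;
      loc_coord(c, cz, cy, cx);
      if (std::abs(cz) + std::abs(cy) + std::abs(cx) == 1) touches_face = true;
      for (int j = 0; j < 27; ++j) {
        if (!in18[j] || loc[j] || lab2[j]) continue;
        int jz, jy, jx;
        loc_coord(j, jz, jy, jx);
        int diff = std::abs(jz - cz) + std::abs(jy - cy) + std::abs(jx - cx);
        if (diff == 1) {
          lab2[j] = ncomp2;
          st[top++] = j;
        }
      }
    }
    if (touches_face) ++nface;
  }
  return nface == 1;
}

}  // namespace

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(IntegerVector data, IntegerVector dims,
                          int connectivity) {
  Dims d{dims[0], dims[1], dims[2]};
  long n = (long)d.nz * d.ny * d.nx;
  if ((long)data.size() != n) stop("data length does not match dims");
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> offs = offsets_for(connectivity);
  std::vector<long> stack;
  int next = 0;
  for (long i = 0; i < n; ++i) {
    if (!data[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      int cz = (int)(c % d.nz);
      long r = c / d.nz;
      int cy = (int)(r % d.ny);
      int cx = (int)(r / d.ny);
      for (auto& o : offs) {
        int z = cz + o[0], y = cy + o[1], x = cx + o[2];
        if (z < 0 || z >= d.nz || y < 0 || y >= d.ny || x < 0 || x >= d.nx)
          continue;
        long j = lin(z, y, x, d);
        if (data[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".cc_label_2d")]]
IntegerMatrix cc_label_2d(IntegerMatrix m, int connectivity) {
  int ny = m.nrow(), nx = m.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<std::pair<int, int>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy) {
      int s = std::abs(dx) + std::abs(dy);
      if (s == 0) continue;
      if (connectivity == 4 && s > 1) continue;
      offs.push_back({dy, dx});
    }
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!m(y, x) || lab(y, x)) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back({y, x});
      while (!stack.empty()) {
        auto c = stack.back();
        stack.pop_back();
        for (auto& o : offs) {
          int yy = c.first + o.first, xx = c.second + o.second;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (m(yy, xx) && !lab(yy, xx)) {
            lab(yy, xx) = next;
            stack.push_back({yy, xx});
          }
        }
      }
    }
  return lab;
}

// Count of foreground 26-neighbours for every voxel.
// [[Rcpp::export(name = ".neighbor_count_26")]]
IntegerVector neighbor_count_26(IntegerVector data, IntegerVector dims) {
  Dims d{dims[0], dims[1], dims[2]};
  long n = (long)d.nz * d.ny * d.nx;
  if ((long)data.size() != n) stop("data length does not match dims");
  IntegerVector cnt(n);
  std::vector<std::array<int, 3>> offs = offsets_for(26);
  for (long i = 0; i < n; ++i) {
    int cz = (int)(i % d.nz);
    long r = i / d.nz;
    int cy = (int)(r % d.ny);
    int cx = (int)(r / d.ny);
    int c = 0;
    for (auto& o : offs) {
      int z = cz + o[0], y = cy + o[1], x = cx + o[2];
      if (z < 0 || z >= d.nz || y < 0 || y >= d.ny || x < 0 || x >= d.nx)
        continue;
      if (data[lin(z, y, x, d)]) ++c;
    }
    cnt[i] = c;
  }
  return cnt;
}

// Distance-ordered homotopic thinning to a curve skeleton.
// Simple points are removed in increasing chamfer(3,4,5)-distance order;
// curve endpoints (exactly one foreground 26-neighbour) and isolated voxels
// are retained, so components, tunnels and cavities of the object are
// preserved exactly.
// [[Rcpp::export(name = ".thin_3d")]]
IntegerVector thin_3d(IntegerVector data, IntegerVector dims) {
  Dims d{dims[0], dims[1], dims[2]};
  long n = (long)d.nz * d.ny * d.nx;
  if ((long)data.size() != n) stop("data length does not match dims");
  std::vector<uint8_t> img(n);
  for (long i = 0; i < n; ++i) img[i] = data[i] ? 1 : 0;

  std::vector<std::array<int, 3>> offs = offsets_for(26);
  std::vector<int> w(offs.size());
  for (size_t k = 0; k < offs.size(); ++k) {
    int s = std::abs(offs[k][0]) + std::abs(offs[k][1]) + std::abs(offs[k][2]);
    w[k] = (s == 1) ? 3 : (s == 2 ? 4 : 5);
  }

  const int BIG = 1 << 29;
  std::vector<int> dist(n, 0);
  // forward chamfer pass: relax against already-visited (smaller linear
  // index) neighbours; voxels outside the volume count as background.
  for (long i = 0; i < n; ++i) {
    if (!img[i]) continue;
    int cz = (int)(i % d.nz);
    long r = i / d.nz;
    int cy = (int)(r % d.ny);
    int cx = (int)(r / d.ny);
    int best = BIG;
    for (size_t k = 0; k < offs.size(); ++k) {
      int z = cz + offs[k][0], y = cy + offs[k][1], x = cx + offs[k][2];
      if (z < 0 || z >= d.nz || y < 0 || y >= d.ny || x < 0 || x >= d.nx) {
        best = std::min(best, w[k]);
        continue;
      }
      long j = lin(z, y, x, d);
      if (j < i) best = std::min(best, dist[j] + w[k]);
    }
    dist[i] = best;
  }
  for (long i = n - 1; i >= 0; --i) {
    if (!img[i]) continue;
    int cz = (int)(i % d.nz);
    long r = i / d.nz;
    int cy = (int)(r % d.ny);
    int cx = (int)(r / d.ny);
    int best = dist[i];
    for (size_t k = 0; k < offs.size(); ++k) {
      int z = cz + offs[k][0], y = cy + offs[k][1], x = cx + offs[k][2];
      if (z < 0 || z >= d.nz || y < 0 || y >= d.ny || x < 0 || x >= d.nx) {
        best = std::min(best, w[k]);
        continue;
      }
      long j = lin(z, y, x, d);
      if (j > i) best = std::min(best, dist[j] + w[k]);
    }
    dist[i] = best;
  }

  typedef std::pair<int, long> QE;  // (distance, voxel)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (long i = 0; i < n; ++i) {
    if (img[i] && dist[i] <= 5) pq.push({dist[i], i});
  }

  uint8_t loc[27];
  while (!pq.empty()) {
    long i = pq.top().second;
    pq.pop();
    if (!img[i]) continue;
    int cz = (int)(i % d.nz);
    long r = i / d.nz;
    int cy = (int)(r % d.ny);
    int cx = (int)(r / d.ny);
    int nfg = 0;
    for (int k = 0; k < 27; ++k) {
      int dz, dy, dx;
      loc_coord(k, dz, dy, dx);
      int z = cz + dz, y = cy + dy, x = cx + dx;
      if (z < 0 || z >= d.nz || y < 0 || y >= d.ny || x < 0 || x >= d.nx) {
        loc[k] = 0;
        continue;
      }
      loc[k] = img[lin(z, y, x, d)];
      if (k != 13 && loc[k]) ++nfg;
    }
    if (nfg <= 1) continue;  // endpoint or isolated voxel: anchor
    if (!is_simple_point(loc)) continue;
    img[i] = 0;
    for (auto& o : offs) {
      int z = cz + o[0], y = cy + o[1], x = cx + o[2];
      if (z < 0 || z >= d.nz || y < 0 || y >= d.ny || x < 0 || x >= d.nx)
        continue;
      long j = lin(z, y, x, d);
      if (img[j]) pq.push({dist[j], j});
    }
  }

  IntegerVector out(n);
  for (long i = 0; i < n; ++i) out[i] = img[i];
  return out;
}
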