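// Voxel-level kernels for 3D image volumes stored as R arrays with
// dim = c(nz, ny, nx), i.e. linear index = z + nz*(y + ny*x), 0-based here.
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector vol, int kz, int ky, int kx) {
  IntegerVector d = vol.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const int rz = kz / 2, ry = ky / 2, rx = kx / 2;
  NumericVector out(vol.size());
  out.attr("dim") = d;
  std::vector<double> buf;
  buf.reserve((size_t)kz * ky * kx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        // edge replication via index clamping
        for (int dx = -rx; dx <= rx; ++dx) {
          const int xx = clampi(x + dx, 0, nx - 1);
          for (int dy = -ry; dy <= ry; ++dy) {
            const int yy = clampi(y + dy, 0, ny - 1);
            const size_t base = (size_t)nz * (yy + (size_t)ny * xx);
            for (int dz = -rz; dz <= rz; ++dz) {
              const int zz = clampi(z + dz, 0, nz - 1);
              buf.push_back(vol[zz + base]);
            }
          }
        }
        const size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        double med = buf[n / 2];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
          med = 0.5 * (med + lo);
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = med;
      }
    }
  }
  return out;
}

// Splat amp[i] * kernel at integer centres (z, y, x)[i] into a fresh copy
// of vol, clipping kernels at the borders.
// [[Rcpp::export(name = ".add_blobs_cpp")]]
NumericVector add_blobs_cpp(NumericVector vol, IntegerMatrix pos,
                            NumericVector amp, NumericVector kernel) {
  IntegerVector d = vol.attr("dim");
  IntegerVector kd = kernel.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const int kz = kd[0], ky = kd[1], kx = kd[2];
  const int rz = (kz - 1) / 2, ry = (ky - 1) / 2, rx = (kx - 1) / 2;
  NumericVector out = clone(vol);
  for (int i = 0; i < pos.nrow(); ++i) {
    const int cz = pos(i, 0) - 1, cy = pos(i, 1) - 1, cx = pos(i, 2) - 1;
    const double a = amp[i];
    for (int dx = -rx; dx <= rx; ++dx) {
      const int x = cx + dx;
      if (x < 0 || x >= nx) continue;
      for (int dy = -ry; dy <= ry; ++dy) {
        const int y = cy + dy;
        if (y < 0 || y >= ny) continue;
        for (int dz = -rz; dz <= rz; ++dz) {
          const int z = cz + dz;
          if (z < 0 || z >= nz) continue;
          out[z + (size_t)nz * (y + (size_t)ny * x)] +=
            a * kernel[(dz + rz) +
                       (size_t)kz * ((dy + ry) + (size_t)ky * (dx + rx))];
        }
      }
    }
  }
  return out;
}

// Per-(y, x) median across z planes: the robust baseline image used by the
// flat-field estimator.
// [[Rcpp::export(name = ".zmedian_cpp")]]
NumericMatrix zmedian_cpp(NumericVector vol) {
  IntegerVector d = vol.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  NumericMatrix out(ny, nx);
  std::vector<double> buf(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      const size_t base = (size_t)nz * (y + (size_t)ny * x);
      for (int z = 0; z < nz; ++z) buf[z] = vol[base + z];
      std::nth_element(buf.begin(), buf.begin() + nz / 2, buf.end());
      double med = buf[nz / 2];
      if (nz % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + nz / 2);
        med = 0.5 * (med + lo);
      }
      out(y, x) = med;
    }
  return out;
}

// One separable convolution pass along a given axis (0=z,1=y,2=x),
// edge replication at borders.
static void conv1d_axis(const std::vector<double> &in, std::vector<double> &out,
                        int nz, int ny, int nx, int axis,
                        const std::vector<double> &k) {
  const int r = ((int)k.size() - 1) / 2;
  const int n[3] = {nz, ny, nx};
  const size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  const int len = n[axis];
  const size_t st = stride[axis];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const int pos[3] = {z, y, x};
        const size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          const int p = clampi(pos[axis] + t, 0, len - 1);
          acc += k[t + r] * in[idx + (p - pos[axis]) * (long)st];
        }
        out[idx] = acc;
      }
}

// [[Rcpp::export(name = ".gauss3d_cpp")]]
NumericVector gauss3d_cpp(NumericVector vol, double sz, double sy, double sx) {
  IntegerVector d = vol.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const double sig[3] = {sz, sy, sx};
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sig[axis];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) {
      k[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += k[t + r];
    }
    for (double &v : k) v /= sum;
    conv1d_axis(a, b, nz, ny, nx, axis, k);
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = d;
  return out;
}

// Local maxima within an anisotropic box neighborhood; a voxel is reported
// when it attains the window maximum and is the first such voxel in linear
// order within the window (plateau deduplication).
// [[Rcpp::export(name = ".localmax3d_cpp")]]
IntegerVector localmax3d_cpp(NumericVector vol, int rz, int ry, int rx,
                             double thresh) {
  IntegerVector d = vol.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
        const double v = vol[idx];
        if (v <= thresh) continue;
        bool is_max = true;
        long first_arg = -1;
        for (int dx = -rx; dx <= rx && is_max; ++dx) {
          const int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -ry; dy <= ry && is_max; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -rz; dz <= rz; ++dz) {
              const int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              const size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
              if (vol[j] > v) { is_max = false; break; }
              if (vol[j] == v && first_arg < 0) first_arg = (long)j;
            }
          }
        }
        if (is_max && first_arg == (long)idx) hits.push_back((int)idx + 1);
      }
  return wrap(hits); // 1-based linear indices
}

// 6-connected component labelling of a binary mask.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = d;
  int next = 0;
  std::vector<size_t> stack;
  const long off[6] = {-1, 1, -(long)nz, (long)nz,
                       -(long)nz * ny, (long)nz * ny};
  for (size_t i = 0; i < (size_t)mask.size(); ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int z = cur % nz, y = (cur / nz) % ny, x = cur / ((size_t)nz * ny);
      const int pos[3] = {z, y, x};
      const int lim[3] = {nz, ny, nx};
      for (int k = 0; k < 6; ++k) {
        const int axis = k / 2, dir = (k % 2) ? 1 : -1;
        const int p = pos[axis] + dir;
        if (p < 0 || p >= lim[axis]) continue;
        const size_t j = cur + off[k];
        if (mask[j] != 0 && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

struct WsNode {
  double elev;
  long order;
  size_t idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.order > b.order;                     // FIFO on ties
  }
};

// Seeded watershed (Meyer priority flood, 6-connectivity) of an elevation
// volume, restricted to mask; seeds carry positive labels.
// [[Rcpp::export(name = ".watershed3d_cpp")]]
IntegerVector watershed3d_cpp(NumericVector elev, IntegerVector seeds,
                              IntegerVector mask) {
  IntegerVector d = elev.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  IntegerVector lab(elev.size(), 0);
  lab.attr("dim") = d;
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  const long off[6] = {-1, 1, -(long)nz, (long)nz,
                       -(long)nz * ny, (long)nz * ny};
  for (size_t i = 0; i < (size_t)seeds.size(); ++i)
    if (seeds[i] > 0 && mask[i] != 0) {
      lab[i] = seeds[i];
      pq.push({elev[i], order++, i});
    }
  while (!pq.empty()) {
    const WsNode nd = pq.top();
    pq.pop();
    const size_t cur = nd.idx;
    const int z = cur % nz, y = (cur / nz) % ny, x = cur / ((size_t)nz * ny);
    const int pos[3] = {z, y, x};
    const int lim[3] = {nz, ny, nx};
    for (int k = 0; k < 6; ++k) {
      const int axis = k / 2, dir = (k % 2) ? 1 : -1;
      const int p = pos[axis] + dir;
      if (p < 0 || p >= lim[axis]) continue;
      const size_t j = cur + off[k];
      if (mask[j] == 0 || lab[j] != 0) continue;
      lab[j] = lab[cur];
      pq.push({elev[j], order++, j});
    }
  }
  return lab;
}
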