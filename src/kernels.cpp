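// Low-level numeric kernels for fracturekit.
//
// Tensor layout: R arrays with dim = c(D, H, W, C) — axes (z, y, x, channel),
// column-major, so z is the fastest-varying index.  Convolution weights use
// dim = c(kz, ky, kx, Cin, Cout).  Stride-1, zero-padded "same" convolutions
// only; pooling kernels equal their strides and must divide the input.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx4(int z, int y, int x, int c, int D, int H, int W) {
  return z + D * (y + H * (x + (long long)W * c));
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector input, IntegerVector in_dim,
                         NumericVector weight, IntegerVector k_dim,
                         NumericVector bias) {
  const int D = in_dim[0], H = in_dim[1], W = in_dim[2], Ci = in_dim[3];
  const int kz = k_dim[0], ky = k_dim[1], kx = k_dim[2], Co = k_dim[4];
  const int pz = (kz - 1) / 2, py = (ky - 1) / 2, px = (kx - 1) / 2;
  NumericVector out((R_xlen_t)D * H * W * Co);
  const double* in = input.begin();
  const double* w = weight.begin();
  double* o = out.begin();

  for (int co = 0; co < Co; ++co) {
    const double b = bias[co];
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y)
        for (int z = 0; z < D; ++z)
          o[idx4(z, y, x, co, D, H, W)] = b;
    for (int ci = 0; ci < Ci; ++ci) {
      for (int dx = 0; dx < kx; ++dx) {
        for (int dy = 0; dy < ky; ++dy) {
          for (int dz = 0; dz < kz; ++dz) {
            const double wv = w[dz + kz * (dy + ky * (dx + kx * (ci + (long long)Ci * co)))];
            if (wv == 0.0) continue;
            // out[z,y,x] += in[z+dz-pz, y+dy-py, x+dx-px] * wv
            const int z0 = std::max(0, pz - dz), z1 = std::min(D, D + pz - dz);
            const int y0 = std::max(0, py - dy), y1 = std::min(H, H + py - dy);
            const int x0 = std::max(0, px - dx), x1 = std::min(W, W + px - dx);
            for (int x = x0; x < x1; ++x) {
              for (int y = y0; y < y1; ++y) {
                const double* ip = in + idx4(z0 + dz - pz, y + dy - py, x + dx - px, ci, D, H, W);
                double* op = o + idx4(z0, y, x, co, D, H, W);
                for (int z = z0; z < z1; ++z) *op++ += wv * *ip++;
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(D, H, W, Co);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd_input")]]
NumericVector conv3d_bwd_input(NumericVector gout, IntegerVector in_dim,
                               NumericVector weight, IntegerVector k_dim) {
  const int D = in_dim[0], H = in_dim[1], W = in_dim[2], Ci = in_dim[3];
  const int kz = k_dim[0], ky = k_dim[1], kx = k_dim[2], Co = k_dim[4];
  const int pz = (kz - 1) / 2, py = (ky - 1) / 2, px = (kx - 1) / 2;
  NumericVector gin((R_xlen_t)D * H * W * Ci);
  const double* go = gout.begin();
  const double* w = weight.begin();
  double* gi = gin.begin();

  for (int co = 0; co < Co; ++co) {
    for (int ci = 0; ci < Ci; ++ci) {
      for (int dx = 0; dx < kx; ++dx) {
        for (int dy = 0; dy < ky; ++dy) {
          for (int dz = 0; dz < kz; ++dz) {
            const double wv = w[dz + kz * (dy + ky * (dx + kx * (ci + (long long)Ci * co)))];
            if (wv == 0.0) continue;
            // gin[zi,yi,xi] += gout[zi-(dz-pz), ...] * wv  (valid out range)
            const int z0 = std::max(0, dz - pz), z1 = std::min(D, D + dz - pz);
            const int y0 = std::max(0, dy - py), y1 = std::min(H, H + dy - py);
            const int x0 = std::max(0, dx - px), x1 = std::min(W, W + dx - px);
            for (int x = x0; x < x1; ++x) {
              for (int y = y0; y < y1; ++y) {
                const double* gp = go + idx4(z0 - (dz - pz), y - (dy - py), x - (dx - px), co, D, H, W);
                double* ip = gi + idx4(z0, y, x, ci, D, H, W);
                for (int z = z0; z < z1; ++z) *ip++ += wv * *gp++;
              }
            }
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(D, H, W, Ci);
  return gin;
}

// [[Rcpp::export(name = ".conv3d_bwd_weight")]]
List conv3d_bwd_weight(NumericVector input, IntegerVector in_dim,
                       NumericVector gout, IntegerVector k_dim) {
  const int D = in_dim[0], H = in_dim[1], W = in_dim[2], Ci = in_dim[3];
  const int kz = k_dim[0], ky = k_dim[1], kx = k_dim[2], Co = k_dim[4];
  const int pz = (kz - 1) / 2, py = (ky - 1) / 2, px = (kx - 1) / 2;
  NumericVector gw((R_xlen_t)kz * ky * kx * Ci * Co);
  NumericVector gb(Co);
  const double* in = input.begin();
  const double* go = gout.begin();

  for (int co = 0; co < Co; ++co) {
    double bsum = 0.0;
    const double* gbase = go + (R_xlen_t)D * H * W * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)D * H * W; ++i) bsum += gbase[i];
    gb[co] = bsum;
    for (int ci = 0; ci < Ci; ++ci) {
      for (int dx = 0; dx < kx; ++dx) {
        for (int dy = 0; dy < ky; ++dy) {
          for (int dz = 0; dz < kz; ++dz) {
            const int z0 = std::max(0, pz - dz), z1 = std::min(D, D + pz - dz);
            const int y0 = std::max(0, py - dy), y1 = std::min(H, H + py - dy);
            const int x0 = std::max(0, px - dx), x1 = std::min(W, W + px - dx);
            double acc = 0.0;
            for (int x = x0; x < x1; ++x) {
              for (int y = y0; y < y1; ++y) {
                const double* ip = in + idx4(z0 + dz - pz, y + dy - py, x + dx - px, ci, D, H, W);
                const double* gp = go + idx4(z0, y, x, co, D, H, W);
                for (int z = z0; z < z1; ++z) acc += *ip++ * *gp++;
              }
            }
            gw[dz + kz * (dy + ky * (dx + kx * (ci + (long long)Ci * co)))] = acc;
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(kz, ky, kx, Ci, Co);
  return List::create(Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector input, IntegerVector in_dim, IntegerVector factor) {
  const int D = in_dim[0], H = in_dim[1], W = in_dim[2], C = in_dim[3];
  const int fz = factor[0], fy = factor[1], fx = factor[2];
  const int Do = D / fz, Ho = H / fy, Wo = W / fx;
  NumericVector out((R_xlen_t)Do * Ho * Wo * C);
  IntegerVector arg((R_xlen_t)Do * Ho * Wo * C);
  const double* in = input.begin();
  for (int c = 0; c < C; ++c) {
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y)
        for (int z = 0; z < Do; ++z) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int ax = 0; ax < fx; ++ax)
            for (int ay = 0; ay < fy; ++ay)
              for (int az = 0; az < fz; ++az) {
                int ii = idx4(z * fz + az, y * fy + ay, x * fx + ax, c, D, H, W);
                if (in[ii] > best) { best = in[ii]; bi = ii; }
              }
          int oi = idx4(z, y, x, c, Do, Ho, Wo);
          out[oi] = best;
          arg[oi] = bi;
        }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector gout, IntegerVector argmax,
                            IntegerVector in_dim) {
  NumericVector gin((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gin[argmax[i]] += gout[i];
  gin.attr("dim") = in_dim;
  return gin;
}

// [[Rcpp::export(name = ".upsample3d_fwd")]]
NumericVector upsample3d_fwd(NumericVector input, IntegerVector in_dim,
                             IntegerVector factor) {
  const int D = in_dim[0], H = in_dim[1], W = in_dim[2], C = in_dim[3];
  const int fz = factor[0], fy = factor[1], fx = factor[2];
  const int Do = D * fz, Ho = H * fy, Wo = W * fx;
  NumericVector out((R_xlen_t)Do * Ho * Wo * C);
  const double* in = input.begin();
  double* o = out.begin();
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y)
        for (int z = 0; z < Do; ++z)
          o[idx4(z, y, x, c, Do, Ho, Wo)] =
            in[idx4(z / fz, y / fy, x / fx, c, D, H, W)];
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// [[Rcpp::export(name = ".upsample3d_bwd")]]
NumericVector upsample3d_bwd(NumericVector gout, IntegerVector out_dim,
                             IntegerVector factor) {
  const int Do = out_dim[0], Ho = out_dim[1], Wo = out_dim[2], C = out_dim[3];
  const int fz = factor[0], fy = factor[1], fx = factor[2];
  const int D = Do / fz, H = Ho / fy, W = Wo / fx;
  NumericVector gin((R_xlen_t)D * H * W * C);
  const double* go = gout.begin();
  double* gi = gin.begin();
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y)
        for (int z = 0; z < Do; ++z)
          gi[idx4(z / fz, y / fy, x / fx, c, D, H, W)] +=
            go[idx4(z, y, x, c, Do, Ho, Wo)];
  gin.attr("dim") = IntegerVector::create(D, H, W, C);
  return gin;
}

// Resampling of a single-channel volume between voxel grids.  Voxel i sits at
// physical position i * spacing along each axis (shared origin); output voxel
// centres are mapped into the input grid and interpolated.

// [[Rcpp::export(name = ".resample3d")]]
NumericVector resample3d(NumericVector input, IntegerVector in_dim,
                         NumericVector in_spacing, IntegerVector out_dim,
                         NumericVector out_spacing, bool nearest) {
  const int D = in_dim[0], H = in_dim[1], W = in_dim[2];
  const int Do = out_dim[0], Ho = out_dim[1], Wo = out_dim[2];
  NumericVector out((R_xlen_t)Do * Ho * Wo);
  const double* in = input.begin();
  double* o = out.begin();
  const double rz = out_spacing[0] / in_spacing[0];
  const double ry = out_spacing[1] / in_spacing[1];
  const double rx = out_spacing[2] / in_spacing[2];
  for (int x = 0; x < Wo; ++x) {
    double fx = std::min(std::max(x * rx, 0.0), (double)(W - 1));
    for (int y = 0; y < Ho; ++y) {
      double fy = std::min(std::max(y * ry, 0.0), (double)(H - 1));
      for (int z = 0; z < Do; ++z) {
        double fz = std::min(std::max(z * rz, 0.0), (double)(D - 1));
        double v;
        if (nearest) {
          int iz = (int)std::lround(fz), iy = (int)std::lround(fy), ix = (int)std::lround(fx);
          v = in[idx4(iz, iy, ix, 0, D, H, W)];
        } else {
          int z0 = (int)std::floor(fz), y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
          int z1 = std::min(z0 + 1, D - 1), y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
          double wz = fz - z0, wy = fy - y0, wx = fx - x0;
          double c00 = in[idx4(z0, y0, x0, 0, D, H, W)] * (1 - wz) + in[idx4(z1, y0, x0, 0, D, H, W)] * wz;
          double c10 = in[idx4(z0, y1, x0, 0, D, H, W)] * (1 - wz) + in[idx4(z1, y1, x0, 0, D, H, W)] * wz;
          double c01 = in[idx4(z0, y0, x1, 0, D, H, W)] * (1 - wz) + in[idx4(z1, y0, x1, 0, D, H, W)] * wz;
          double c11 = in[idx4(z0, y1, x1, 0, D, H, W)] * (1 - wz) + in[idx4(z1, y1, x1, 0, D, H, W)] * wz;
          double c0 = c00 * (1 - wy) + c10 * wy;
          double c1 = c01 * (1 - wy) + c11 * wy;
          v = c0 * (1 - wx) + c1 * wx;
        }
        o[idx4(z, y, x, 0, Do, Ho, Wo)] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  return out;
}

// Connected-component labelling of a binary volume, 6- or 26-connectivity.
// Returns an integer volume of component ids (0 = background), labelled in
// raster-scan discovery order.

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int D = dim[0], H = dim[1], W = dim[2];
  IntegerVector lab((R_xlen_t)D * H * W);
  const int* m = mask.begin();
  int* L = lab.begin();
  std::vector<std::array<int, 3> > offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manhattan != 1) continue;
        offs.push_back({dz, dy, dx});
      }
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      for (int z = 0; z < D; ++z) {
        int i = idx4(z, y, x, 0, D, H, W);
        if (m[i] == 0 || L[i] != 0) continue;
        L[i] = ++next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int cz = cur % D, cy = (cur / D) % H, cx = cur / (D * H);
          for (size_t k = 0; k < offs.size(); ++k) {
            int nz = cz + offs[k][0], ny = cy + offs[k][1], nx = cx + offs[k][2];
            if (nz < 0 || nz >= D || ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            int ni = idx4(nz, ny, nx, 0, D, H, W);
            if (m[ni] != 0 && L[ni] == 0) { L[ni] = next; stack.push_back(ni); }
          }
        }
      }
  lab.attr("dim") = IntegerVector::create(D, H, W);
  return lab;
}

// Directed nearest-point distances: for each row of A, the minimum Euclidean
// distance to any row of B (both n x 3, physical mm).

// [[Rcpp::export(name = ".min_dists")]]
NumericVector min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
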