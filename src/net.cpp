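// 3D convolutional denoising autoencoder with a Cox survival branch.
// Implemented directly on BLAS sgemm via im2col; single-threaded, deterministic
// under the net's own RNG. All parameters float32, losses accumulated in double.
//
// Activations are kept in channel-plane layout (value of channel c at linear
// voxel v sits at a[c*V + v]), matching R's array layout dim = c(d1,d2,d3,C).
// im2col builds the transposed patch matrix colT [V x K] column-major so both
// the gather and the GEMMs run over contiguous memory.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
#include <cstring>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

extern "C" void sgemm_(const char*, const char*, const int*, const int*, const int*,
                       const float*, const float*, const int*, const float*, const int*,
                       const float*, float*, const int*);

static void gemm(char ta, char tb, int m, int n, int k,
                 float alpha, const float* A, int lda,
                 const float* B, int ldb, float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct Param {
  std::vector<float> w, g, m, v;
  void init(size_t n) { w.assign(n, 0.f); g.assign(n, 0.f); }
  size_t size() const { return w.size(); }
  void zero_grad() { std::fill(g.begin(), g.end(), 0.f); }
  void adam(float lr, float b1, float b2, float eps, long t) {
    if (m.empty()) { m.assign(w.size(), 0.f); v.assign(w.size(), 0.f); }
    const float c1 = 1.f - std::pow(b1, (float)t);
    const float c2 = 1.f - std::pow(b2, (float)t);
    for (size_t i = 0; i < w.size(); ++i) {
      m[i] = b1 * m[i] + (1.f - b1) * g[i];
      v[i] = b2 * v[i] + (1.f - b2) * g[i] * g[i];
      w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
    }
  }
};

struct Conv {
  int Cin = 0, Cout = 0;            // 3x3x3 kernel, pad 1
  Param W;                          // [Cout x Cin*27] column-major
  Param b;                          // [Cout]
};

// ---- im2col / col2im ------------------------------------------------------
// colT: [V x K] column-major; column kk = c*27 + 9*(kz+1) + 3*(ky+1) + (kx+1)
// holds the channel-c image shifted by (-kx,-ky,-kz), zero-padded.

static void im2col(const float* in, int C, int d1, int d2, int d3, float* colT) {
  const size_t V = (size_t)d1 * d2 * d3;
  for (int c = 0; c < C; ++c) {
    const float* plane = in + (size_t)c * V;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int kk = c * 27 + 9 * (kz + 1) + 3 * (ky + 1) + (kx + 1);
          float* dst = colT + (size_t)kk * V;
          const int x0 = std::max(0, -kx), x1 = std::min(d1, d1 - kx);
          for (int z = 0; z < d3; ++z) {
            const int zz = z + kz;
            if (zz < 0 || zz >= d3) {
              std::memset(dst + (size_t)d1 * d2 * z, 0,
                          sizeof(float) * d1 * d2);
              continue;
            }
            for (int y = 0; y < d2; ++y) {
              float* row = dst + (size_t)d1 * (y + (size_t)d2 * z);
              const int yy = y + ky;
              if (yy < 0 || yy >= d2) {
                std::memset(row, 0, sizeof(float) * d1);
                continue;
              }
              const float* src =
                plane + (size_t)d1 * (yy + (size_t)d2 * zz) + kx;
              if (x0 > 0) row[0] = 0.f;
              if (x1 < d1) row[d1 - 1] = 0.f;
              std::memcpy(row + x0, src + x0, sizeof(float) * (x1 - x0));
            }
          }
        }
  }
}

static void col2im(const float* colT, int C, int d1, int d2, int d3, float* din) {
  const size_t V = (size_t)d1 * d2 * d3;
  std::fill(din, din + (size_t)C * V, 0.f);
  for (int c = 0; c < C; ++c) {
    float* plane = din + (size_t)c * V;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int kk = c * 27 + 9 * (kz + 1) + 3 * (ky + 1) + (kx + 1);
          const float* src = colT + (size_t)kk * V;
          const int x0 = std::max(0, -kx), x1 = std::min(d1, d1 - kx);
          for (int z = 0; z < d3; ++z) {
            const int zz = z + kz;
            if (zz < 0 || zz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yy = y + ky;
              if (yy < 0 || yy >= d2) continue;
              float* dstrow = plane + (size_t)d1 * (yy + (size_t)d2 * zz) + kx;
              const float* srow = src + (size_t)d1 * (y + (size_t)d2 * z);
              for (int x = x0; x < x1; ++x) dstrow[x] += srow[x];
            }
          }
        }
  }
}

// out[V x Cout] (plane layout) = colT[V x K] * W^T (+ bias)
static void conv_forward(const Conv& cv, const float* in,
                         int d1, int d2, int d3, float* colT, float* out) {
  const int V = d1 * d2 * d3, K = cv.Cin * 27;
  im2col(in, cv.Cin, d1, d2, d3, colT);
  gemm('N', 'T', V, cv.Cout, K, 1.f, colT, V, cv.W.w.data(), cv.Cout,
       0.f, out, V);
  for (int o = 0; o < cv.Cout; ++o) {
    float* op = out + (size_t)o * V;
    const float b = cv.b.w[o];
    for (int v = 0; v < V; ++v) op[v] += b;
  }
}

static void conv_backward(Conv& cv, const float* in, const float* dout,
                          int d1, int d2, int d3,
                          float* colT, float* dcolT, float* din) {
  const int V = d1 * d2 * d3, K = cv.Cin * 27;
  im2col(in, cv.Cin, d1, d2, d3, colT);
  // dW[Cout x K] += dout^T * colT
  gemm('T', 'N', cv.Cout, K, V, 1.f, dout, V, colT, V,
       1.f, cv.W.g.data(), cv.Cout);
  for (int o = 0; o < cv.Cout; ++o) {
    const float* dp = dout + (size_t)o * V;
    double s = 0.0;
    for (int v = 0; v < V; ++v) s += dp[v];
    cv.b.g[o] += (float)s;
  }
  if (din) {
    // dcolT[V x K] = dout * W
    gemm('N', 'N', V, K, cv.Cout, 1.f, dout, V, cv.W.w.data(), cv.Cout,
         0.f, dcolT, V);
    col2im(dcolT, cv.Cin, d1, d2, d3, din);
  }
}

static void lrelu(float* x, size_t n, float s) {
  for (size_t i = 0; i < n; ++i) if (x[i] < 0.f) x[i] *= s;
}
static void lrelu_back(const float* out, float* g, size_t n, float s) {
  for (size_t i = 0; i < n; ++i) if (out[i] <= 0.f) g[i] *= s;
}

static void maxpool(const float* in, int C, int d1, int d2, int d3,
                    float* out, int32_t* idx) {
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const size_t V = (size_t)d1 * d2 * d3, OV = (size_t)o1 * o2 * o3;
  for (int c = 0; c < C; ++c) {
    const float* plane = in + (size_t)c * V;
    float* op = out + (size_t)c * OV;
    int32_t* ip = idx + (size_t)c * OV;
    for (int z = 0; z < o3; ++z)
      for (int y = 0; y < o2; ++y)
        for (int x = 0; x < o1; ++x) {
          float best = -1e30f; int32_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const size_t iv = (size_t)(2 * x + dx) +
                  (size_t)d1 * ((2 * y + dy) + (size_t)d2 * (2 * z + dz));
                if (plane[iv] > best) { best = plane[iv]; bi = (int32_t)iv; }
              }
          const size_t ov = (size_t)x + (size_t)o1 * (y + (size_t)o2 * z);
          op[ov] = best; ip[ov] = bi;
        }
  }
}

static void maxpool_back(const float* dout, const int32_t* idx, int C,
                         int d1, int d2, int d3, float* din) {
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const size_t V = (size_t)d1 * d2 * d3, OV = (size_t)o1 * o2 * o3;
  std::fill(din, din + (size_t)C * V, 0.f);
  for (int c = 0; c < C; ++c) {
    const float* dp = dout + (size_t)c * OV;
    const int32_t* ip = idx + (size_t)c * OV;
    float* plane = din + (size_t)c * V;
    for (size_t ov = 0; ov < OV; ++ov) plane[ip[ov]] += dp[ov];
  }
}

static void upsample(const float* in, int C, int d1, int d2, int d3, float* out) {
  const int O1 = 2 * d1;
  const size_t V = (size_t)d1 * d2 * d3, OV = 8 * V;
  for (int c = 0; c < C; ++c) {
    const float* plane = in + (size_t)c * V;
    float* op = out + (size_t)c * OV;
    for (int z = 0; z < 2 * d3; ++z)
      for (int y = 0; y < 2 * d2; ++y) {
        const float* srow = plane + (size_t)d1 * ((y / 2) + (size_t)d2 * (z / 2));
        float* drow = op + (size_t)O1 * (y + (size_t)(2 * d2) * z);
        for (int x = 0; x < d1; ++x) {
          drow[2 * x] = srow[x];
          drow[2 * x + 1] = srow[x];
        }
      }
  }
}

static void upsample_back(const float* dout, int C, int d1, int d2, int d3,
                          float* din) {
  const int O1 = 2 * d1;
  const size_t V = (size_t)d1 * d2 * d3, OV = 8 * V;
  std::fill(din, din + (size_t)C * V, 0.f);
  for (int c = 0; c < C; ++c) {
    const float* dp = dout + (size_t)c * OV;
    float* plane = din + (size_t)c * V;
    for (int z = 0; z < 2 * d3; ++z)
      for (int y = 0; y < 2 * d2; ++y) {
        float* drow = plane + (size_t)d1 * ((y / 2) + (size_t)d2 * (z / 2));
        const float* srow = dp + (size_t)O1 * (y + (size_t)(2 * d2) * z);
        for (int x = 0; x < d1; ++x) drow[x] += srow[2 * x] + srow[2 * x + 1];
      }
  }
}

// ---- network --------------------------------------------------------------

struct Cache {
  std::vector<float> x;        // clean input [4*V0]
  std::vector<float> xhat;     // BN-normalized (pre gamma/beta)
  std::vector<float> xin;      // corrupted BN output (encoder input)
  std::vector<uint8_t> cmask;  // corruption keep-mask
  std::vector<float> e_out[3], e_pool[3];
  std::vector<int32_t> p_idx[3];
  std::vector<float> d_out[3], d_up[3];
  std::vector<float> recon;    // sigmoid output [4*V0]
  std::vector<float> f1, f2;
  std::vector<uint8_t> m1, m2;
  double risk = 0.0;
};

struct Net {
  int d0[3];
  int ec[3] = {16, 32, 64};
  int dc[3] = {64, 32, 16};
  int dd[2] = {1024, 128};
  float slope, p_in, p_d1, p_d2;
  int flat = 0;

  Param bn_gamma, bn_beta;
  std::vector<float> bn_rmean, bn_rvar;
  float bn_momentum = 0.9f, bn_eps = 1e-5f;
  std::vector<float> bn_bmean, bn_bvar;

  Conv enc[3], dec[3], outc;
  Param fc1w, fc1b, fc2w, fc2b, fc3w;

  std::mt19937_64 rng;
  long adam_t = 0;

  std::vector<float> col, dcol, buf_a, buf_b;
  std::vector<Cache> caches;

  int dims(int level, int axis) const { return d0[axis] >> level; }
  size_t vox(int level) const {
    return (size_t)dims(level, 0) * dims(level, 1) * dims(level, 2);
  }

  void init(const int* shape, double leaky, double pin, double pd1, double pd2,
            uint64_t seed) {
    for (int i = 0; i < 3; ++i) {
      d0[i] = shape[i];
      if (d0[i] < 8 || d0[i] % 8 != 0)
        stop("VOI shape must have every axis >= 8 and divisible by 8");
    }
    slope = (float)leaky; p_in = (float)pin; p_d1 = (float)pd1; p_d2 = (float)pd2;
    rng.seed(seed);
    flat = (int)(64 * vox(3));

    bn_gamma.init(4); bn_beta.init(4);
    std::fill(bn_gamma.w.begin(), bn_gamma.w.end(), 1.f);
    bn_rmean.assign(4, 0.f); bn_rvar.assign(4, 1.f);

    auto init_conv = [&](Conv& c, int cin, int cout) {
      c.Cin = cin; c.Cout = cout;
      c.W.init((size_t)cout * cin * 27); c.b.init(cout);
      std::normal_distribution<float> nd(0.f, std::sqrt(2.f / (cin * 27)));
      for (auto& w : c.W.w) w = nd(rng);
    };
    init_conv(enc[0], 4, ec[0]);
    init_conv(enc[1], ec[0], ec[1]);
    init_conv(enc[2], ec[1], ec[2]);
    init_conv(dec[0], ec[2], dc[0]);
    init_conv(dec[1], dc[0], dc[1]);
    init_conv(dec[2], dc[1], dc[2]);
    init_conv(outc, dc[2], 4);

    auto init_dense = [&](Param& W, int nin, int nout) {
      W.init((size_t)nout * nin);
      std::normal_distribution<float> nd(0.f, std::sqrt(2.f / nin));
      for (auto& w : W.w) w = nd(rng);
    };
    init_dense(fc1w, flat, dd[0]); fc1b.init(dd[0]);
    init_dense(fc2w, dd[0], dd[1]); fc2b.init(dd[1]);
    init_dense(fc3w, dd[1], 1);

    size_t vmax = 0;
    // col buffer sized over every conv's input (Cin*27 * input voxels)
    const int cins[7] = {4, ec[0], ec[1], dc[0], dc[0], dc[1], dc[2]};
    const int levs[7] = {0, 1, 2, 3, 2, 1, 0};
    for (int i = 0; i < 7; ++i)
      vmax = std::max(vmax, (size_t)cins[i] * 27 * vox(levs[i]));
    col.resize(vmax); dcol.resize(vmax);
    buf_a.resize(64 * vox(0)); buf_b.resize(64 * vox(0));
  }

  std::vector<Param*> params() {
    return { &bn_gamma, &bn_beta,
             &enc[0].W, &enc[0].b, &enc[1].W, &enc[1].b, &enc[2].W, &enc[2].b,
             &dec[0].W, &dec[0].b, &dec[1].W, &dec[1].b, &dec[2].W, &dec[2].b,
             &outc.W, &outc.b, &fc1w, &fc1b, &fc2w, &fc2b, &fc3w };
  }

  void forward_case(Cache& cc, bool training) {
    const size_t V0 = vox(0);
    cc.xhat.resize(4 * V0);
    cc.xin.resize(4 * V0);
    const float* mean = training ? bn_bmean.data() : bn_rmean.data();
    const float* var  = training ? bn_bvar.data()  : bn_rvar.data();
    for (int c = 0; c < 4; ++c) {
      const float inv = 1.f / std::sqrt(var[c] + bn_eps);
      const float ga = bn_gamma.w[c], be = bn_beta.w[c], mu = mean[c];
      for (size_t v = 0; v < V0; ++v) {
        const float xh = (cc.x[c * V0 + v] - mu) * inv;
        cc.xhat[c * V0 + v] = xh;
        cc.xin[c * V0 + v] = ga * xh + be;
      }
    }
    if (training && p_in > 0.f) {
      cc.cmask.resize(4 * V0);
      std::uniform_real_distribution<float> ud(0.f, 1.f);
      for (size_t i = 0; i < 4 * V0; ++i) {
        cc.cmask[i] = ud(rng) >= p_in;
        if (!cc.cmask[i]) cc.xin[i] = 0.f;
      }
    } else cc.cmask.clear();

    // encoder: conv (level s) -> LeakyReLU -> 2x maxpool
    const float* cur = cc.xin.data();
    for (int s = 0; s < 3; ++s) {
      const size_t V = vox(s), Vp = vox(s + 1);
      cc.e_out[s].resize(enc[s].Cout * V);
      cc.e_pool[s].resize(enc[s].Cout * Vp);
      cc.p_idx[s].resize(enc[s].Cout * Vp);
      conv_forward(enc[s], cur, dims(s, 0), dims(s, 1), dims(s, 2),
                   col.data(), cc.e_out[s].data());
      lrelu(cc.e_out[s].data(), cc.e_out[s].size(), slope);
      maxpool(cc.e_out[s].data(), enc[s].Cout, dims(s, 0), dims(s, 1), dims(s, 2),
              cc.e_pool[s].data(), cc.p_idx[s].data());
      cur = cc.e_pool[s].data();
    }

    // survival branch on flattened hidden matrix h
    const float* h = cc.e_pool[2].data();
    cc.f1.assign(dd[0], 0.f);
    gemm('N', 'N', dd[0], 1, flat, 1.f, fc1w.w.data(), dd[0], h, flat,
         0.f, cc.f1.data(), dd[0]);
    for (int i = 0; i < dd[0]; ++i) cc.f1[i] += fc1b.w[i];
    lrelu(cc.f1.data(), dd[0], slope);
    if (training && p_d1 > 0.f) {
      cc.m1.resize(dd[0]);
      std::uniform_real_distribution<float> ud(0.f, 1.f);
      const float sc = 1.f / (1.f - p_d1);
      for (int i = 0; i < dd[0]; ++i) {
        cc.m1[i] = ud(rng) >= p_d1;
        cc.f1[i] = cc.m1[i] ? cc.f1[i] * sc : 0.f;
      }
    } else cc.m1.clear();
    cc.f2.assign(dd[1], 0.f);
    gemm('N', 'N', dd[1], 1, dd[0], 1.f, fc2w.w.data(), dd[1], cc.f1.data(), dd[0],
         0.f, cc.f2.data(), dd[1]);
    for (int i = 0; i < dd[1]; ++i) cc.f2[i] += fc2b.w[i];
    lrelu(cc.f2.data(), dd[1], slope);
    if (training && p_d2 > 0.f) {
      cc.m2.resize(dd[1]);
      std::uniform_real_distribution<float> ud(0.f, 1.f);
      const float sc = 1.f / (1.f - p_d2);
      for (int i = 0; i < dd[1]; ++i) {
        cc.m2[i] = ud(rng) >= p_d2;
        cc.f2[i] = cc.m2[i] ? cc.f2[i] * sc : 0.f;
      }
    } else cc.m2.clear();
    double r = 0.0;
    for (int i = 0; i < dd[1]; ++i) r += (double)fc3w.w[i] * cc.f2[i];
    cc.risk = r;

    // decoder: conv (level 3-s) -> LeakyReLU -> 2x nearest upsample
    cur = h;
    for (int s = 0; s < 3; ++s) {
      const int l = 3 - s;
      cc.d_out[s].resize(dec[s].Cout * vox(l));
      cc.d_up[s].resize(dec[s].Cout * vox(l - 1));
      conv_forward(dec[s], cur, dims(l, 0), dims(l, 1), dims(l, 2),
                   col.data(), cc.d_out[s].data());
      lrelu(cc.d_out[s].data(), cc.d_out[s].size(), slope);
      upsample(cc.d_out[s].data(), dec[s].Cout, dims(l, 0), dims(l, 1), dims(l, 2),
               cc.d_up[s].data());
      cur = cc.d_up[s].data();
    }
    cc.recon.resize(4 * V0);
    conv_forward(outc, cur, dims(0, 0), dims(0, 1), dims(0, 2),
                 col.data(), cc.recon.data());
    for (auto& z : cc.recon) z = 1.f / (1.f + std::exp(-z));
  }

  void backward_case(Cache& cc, std::vector<float>& drecon, double drisk) {
    const size_t V0 = vox(0);
    for (size_t i = 0; i < 4 * V0; ++i) {
      const float s = cc.recon[i];
      drecon[i] *= s * (1.f - s);
    }
    float* da = buf_a.data();
    conv_backward(outc, cc.d_up[2].data(), drecon.data(),
                  dims(0, 0), dims(0, 1), dims(0, 2),
                  col.data(), dcol.data(), da);

    float* db = buf_b.data();
    for (int s = 2; s >= 0; --s) {
      const int l = 3 - s;
      upsample_back(da, dec[s].Cout, dims(l, 0), dims(l, 1), dims(l, 2), db);
      lrelu_back(cc.d_out[s].data(), db, cc.d_out[s].size(), slope);
      const float* in = (s == 0) ? cc.e_pool[2].data() : cc.d_up[s - 1].data();
      conv_backward(dec[s], in, db, dims(l, 0), dims(l, 1), dims(l, 2),
                    col.data(), dcol.data(), da);
    }
    std::vector<float> dh(da, da + flat);

    if (drisk != 0.0) {
      std::vector<float> df2(dd[1]);
      for (int i = 0; i < dd[1]; ++i) {
        fc3w.g[i] += (float)drisk * cc.f2[i];
        df2[i] = (float)drisk * fc3w.w[i];
      }
      if (!cc.m2.empty()) {
        const float sc = 1.f / (1.f - p_d2);
        for (int i = 0; i < dd[1]; ++i) df2[i] = cc.m2[i] ? df2[i] * sc : 0.f;
      }
      // f2 is stored post-dropout; kept units preserve the activation sign, and
      // dropped units already have zero gradient.
      lrelu_back(cc.f2.data(), df2.data(), dd[1], slope);
      std::vector<float> df1(dd[0], 0.f);
      gemm('N', 'T', dd[1], dd[0], 1, 1.f, df2.data(), dd[1],
           cc.f1.data(), dd[0], 1.f, fc2w.g.data(), dd[1]);
      for (int i = 0; i < dd[1]; ++i) fc2b.g[i] += df2[i];
      gemm('T', 'N', dd[0], 1, dd[1], 1.f, fc2w.w.data(), dd[1],
           df2.data(), dd[1], 0.f, df1.data(), dd[0]);
      if (!cc.m1.empty()) {
        const float sc = 1.f / (1.f - p_d1);
        for (int i = 0; i < dd[0]; ++i) df1[i] = cc.m1[i] ? df1[i] * sc : 0.f;
      }
      lrelu_back(cc.f1.data(), df1.data(), dd[0], slope);
      gemm('N', 'T', dd[0], flat, 1, 1.f, df1.data(), dd[0],
           cc.e_pool[2].data(), flat, 1.f, fc1w.g.data(), dd[0]);
      for (int i = 0; i < dd[0]; ++i) fc1b.g[i] += df1[i];
      gemm('T', 'N', flat, 1, dd[0], 1.f, fc1w.w.data(), dd[0],
           df1.data(), dd[0], 1.f, dh.data(), flat);
    }

    std::memcpy(da, dh.data(), sizeof(float) * flat);
    for (int s = 2; s >= 0; --s) {
      maxpool_back(da, cc.p_idx[s].data(), enc[s].Cout,
                   dims(s, 0), dims(s, 1), dims(s, 2), db);
      lrelu_back(cc.e_out[s].data(), db, cc.e_out[s].size(), slope);
      const float* in = (s == 0) ? cc.xin.data() : cc.e_pool[s - 1].data();
      conv_backward(enc[s], in, db, dims(s, 0), dims(s, 1), dims(s, 2),
                    col.data(), dcol.data(), da);
    }
    // da = gradient w.r.t. corrupted BN output
    if (!cc.cmask.empty())
      for (size_t i = 0; i < 4 * V0; ++i) if (!cc.cmask[i]) da[i] = 0.f;
    for (int c = 0; c < 4; ++c) {
      double dg = 0.0, dbta = 0.0;
      for (size_t v = 0; v < V0; ++v) {
        dg += (double)da[c * V0 + v] * cc.xhat[c * V0 + v];
        dbta += da[c * V0 + v];
      }
      bn_gamma.g[c] += (float)dg;
      bn_beta.g[c] += (float)dbta;
    }
  }

  void prepare_bn(const std::vector<Cache>& cs, bool update_running) {
    const size_t V0 = vox(0);
    bn_bmean.assign(4, 0.f); bn_bvar.assign(4, 0.f);
    const double n = (double)cs.size() * V0;
    for (int c = 0; c < 4; ++c) {
      double s = 0.0, s2 = 0.0;
      for (const auto& cc : cs)
        for (size_t v = 0; v < V0; ++v) {
          const double x = cc.x[c * V0 + v];
          s += x; s2 += x * x;
        }
      const double mu = s / n, va = std::max(0.0, s2 / n - mu * mu);
      bn_bmean[c] = (float)mu; bn_bvar[c] = (float)va;
      if (update_running) {
        bn_rmean[c] = bn_momentum * bn_rmean[c] + (1.f - bn_momentum) * (float)mu;
        bn_rvar[c]  = bn_momentum * bn_rvar[c]  + (1.f - bn_momentum) * (float)va;
      }
    }
  }
};

// ---- losses (double precision) --------------------------------------------

static double recon_loss_and_grad(const Cache& cc, double scale,
                                  std::vector<float>& dr) {
  double L = 0.0;
  const size_t n = cc.recon.size();
  dr.resize(n);
  for (size_t i = 0; i < n; ++i) {
    const double e = (double)cc.recon[i] - (double)cc.x[i];
    L += e * e;
    dr[i] = (float)(2.0 * e * scale);
  }
  return L * scale;
}

static double cox_npll(const std::vector<double>& r, const std::vector<double>& t,
                       const std::vector<int>& d, std::vector<double>* grad) {
  const int n = (int)r.size();
  double L = 0.0;
  if (grad) grad->assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!d[i]) continue;
    double mx = -1e300;
    for (int j = 0; j < n; ++j) if (t[j] >= t[i]) mx = std::max(mx, r[j]);
    double S = 0.0;
    for (int j = 0; j < n; ++j) if (t[j] >= t[i]) S += std::exp(r[j] - mx);
    L -= r[i] - (mx + std::log(S));
    if (grad) {
      (*grad)[i] -= 1.0;
      for (int j = 0; j < n; ++j)
        if (t[j] >= t[i]) (*grad)[j] += std::exp(r[j] - mx) / S;
    }
  }
  return L;
}

// ---- R interface -----------------------------------------------------------

static void load_batch(Net& net, const NumericVector& x, int& nb) {
  const size_t percase = 4 * net.vox(0);
  if (x.size() == 0 || x.size() % percase != 0)
    stop("batch array does not match the model's VOI shape");
  nb = (int)(x.size() / percase);
  if ((int)net.caches.size() < nb) net.caches.resize(nb);
  for (int b = 0; b < nb; ++b) {
    net.caches[b].x.resize(percase);
    const double* src = &x[0] + (size_t)b * percase;
    for (size_t i = 0; i < percase; ++i) net.caches[b].x[i] = (float)src[i];
  }
}

// [[Rcpp::export(name = ".cd_net_create")]]
SEXP cd_net_create(IntegerVector voi_shape, double leaky_slope,
                   double input_dropout, double branch_dropout1,
                   double branch_dropout2, int seed) {
  if (voi_shape.size() != 3) stop("voi_shape must have length 3");
  Net* net = new Net();
  int s[3] = {voi_shape[0], voi_shape[1], voi_shape[2]};
  net->init(s, leaky_slope, input_dropout, branch_dropout1, branch_dropout2,
            (uint64_t)seed);
  XPtr<Net> p(net, true);
  return p;
}

// [[Rcpp::export(name = ".cd_net_flat_dim")]]
int cd_net_flat_dim(SEXP ptr) { return XPtr<Net>(ptr)->flat; }

// [[Rcpp::export(name = ".cd_net_n_params")]]
double cd_net_n_params(SEXP ptr) {
  XPtr<Net> net(ptr);
  double n = 0;
  for (auto* p : net->params()) n += (double)p->size();
  return n;
}

// [[Rcpp::export(name = ".cd_net_seed")]]
void cd_net_seed(SEXP ptr, int seed) { XPtr<Net>(ptr)->rng.seed((uint64_t)seed); }

// [[Rcpp::export(name = ".cd_net_get_state")]]
List cd_net_get_state(SEXP ptr) {
  XPtr<Net> net(ptr);
  auto ps = net->params();
  List out(ps.size() + 2);
  CharacterVector nm(ps.size() + 2);
  const char* names[] = { "bn_gamma", "bn_beta",
    "enc1_W", "enc1_b", "enc2_W", "enc2_b", "enc3_W", "enc3_b",
    "dec1_W", "dec1_b", "dec2_W", "dec2_b", "dec3_W", "dec3_b",
    "out_W", "out_b", "fc1_W", "fc1_b", "fc2_W", "fc2_b", "fc3_W" };
  for (size_t i = 0; i < ps.size(); ++i) {
    out[i] = NumericVector(ps[i]->w.begin(), ps[i]->w.end());
    nm[i] = names[i];
  }
  out[ps.size()] = NumericVector(net->bn_rmean.begin(), net->bn_rmean.end());
  nm[ps.size()] = "bn_running_mean";
  out[ps.size() + 1] = NumericVector(net->bn_rvar.begin(), net->bn_rvar.end());
  nm[ps.size() + 1] = "bn_running_var";
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export(name = ".cd_net_set_state")]]
void cd_net_set_state(SEXP ptr, List state) {
  XPtr<Net> net(ptr);
  auto ps = net->params();
  if ((size_t)state.size() != ps.size() + 2)
    stop("checkpoint state has wrong length");
  for (size_t i = 0; i < ps.size(); ++i) {
    NumericVector w = state[i];
    if ((size_t)w.size() != ps[i]->size())
      stop("checkpoint tensor %d has wrong size", (int)i + 1);
    for (size_t j = 0; j < ps[i]->size(); ++j) ps[i]->w[j] = (float)w[j];
  }
  NumericVector rm = state[ps.size()], rv = state[ps.size() + 1];
  for (int c = 0; c < 4; ++c) {
    net->bn_rmean[c] = (float)rm[c];
    net->bn_rvar[c] = (float)rv[c];
  }
}

// [[Rcpp::export(name = ".cd_net_forward")]]
List cd_net_forward(SEXP ptr, NumericVector x, bool training) {
  XPtr<Net> net(ptr);
  int nb = 0;
  load_batch(*net, x, nb);
  if (training) net->prepare_bn(net->caches, false);
  NumericVector recon(x.size());
  NumericVector risk(nb);
  const size_t percase = 4 * net->vox(0);
  for (int b = 0; b < nb; ++b) {
    net->forward_case(net->caches[b], training);
    for (size_t i = 0; i < percase; ++i)
      recon[(size_t)b * percase + i] = net->caches[b].recon[i];
    risk[b] = net->caches[b].risk;
  }
  recon.attr("dim") = x.attr("dim");
  return List::create(_["recon"] = recon, _["risk"] = risk);
}

// [[Rcpp::export(name = ".cd_net_eval_loss")]]
List cd_net_eval_loss(SEXP ptr, NumericVector x, NumericVector times,
                      IntegerVector events, double alpha, double beta,
                      std::string reduction) {
  XPtr<Net> net(ptr);
  int nb = 0;
  load_batch(*net, x, nb);
  const size_t percase = 4 * net->vox(0);
  const double scale = (reduction == "mean")
    ? 1.0 / ((double)nb * percase) : 1.0 / (double)nb;
  double Lr = 0.0;
  std::vector<double> r(nb), t(times.begin(), times.end());
  std::vector<int> d(events.begin(), events.end());
  std::vector<float> tmp;
  for (int b = 0; b < nb; ++b) {
    net->forward_case(net->caches[b], false);
    Lr += recon_loss_and_grad(net->caches[b], scale, tmp);
    r[b] = net->caches[b].risk;
  }
  const double Ls = cox_npll(r, t, d, nullptr);
  return List::create(_["l_r"] = Lr, _["l_s"] = Ls,
                      _["hybrid"] = alpha * Lr + beta * Ls);
}

// [[Rcpp::export(name = ".cd_net_train_batch")]]
List cd_net_train_batch(SEXP ptr, NumericVector x, NumericVector times,
                        IntegerVector events, double alpha, double beta,
                        double lr, std::string reduction) {
  XPtr<Net> net(ptr);
  int nb = 0;
  load_batch(*net, x, nb);
  if ((int)times.size() != nb || (int)events.size() != nb)
    stop("times/events do not match batch size");
  const size_t percase = 4 * net->vox(0);
  const double scale = (reduction == "mean")
    ? 1.0 / ((double)nb * percase) : 1.0 / (double)nb;

  net->prepare_bn(net->caches, true);
  for (auto* p : net->params()) p->zero_grad();

  std::vector<double> r(nb), t(times.begin(), times.end());
  std::vector<int> d(events.begin(), events.end());
  for (int b = 0; b < nb; ++b) {
    net->forward_case(net->caches[b], true);
    r[b] = net->caches[b].risk;
  }
  std::vector<double> gcox;
  const double Ls = cox_npll(r, t, d, &gcox);

  double Lr = 0.0;
  std::vector<float> dr;
  for (int b = 0; b < nb; ++b) {
    Lr += recon_loss_and_grad(net->caches[b], scale, dr);
    for (auto& g : dr) g *= (float)alpha;
    net->backward_case(net->caches[b], dr, beta * gcox[b]);
  }
  const double hybrid = alpha * Lr + beta * Ls;
  if (!std::isfinite(hybrid))
    stop("non-finite training loss (l_r = %g, l_s = %g)", Lr, Ls);

  net->adam_t += 1;
  for (auto* p : net->params())
    p->adam((float)lr, 0.9f, 0.999f, 1e-8f, net->adam_t);
  return List::create(_["l_r"] = Lr, _["l_s"] = Ls, _["hybrid"] = hybrid);
}

// fraction of input voxels zeroed by the denoising corruption in one
// training-mode forward of the given batch
// [[Rcpp::export(name = ".cd_net_corruption_fraction")]]
double cd_net_corruption_fraction(SEXP ptr, NumericVector x) {
  XPtr<Net> net(ptr);
  int nb = 0;
  load_batch(*net, x, nb);
  net->prepare_bn(net->caches, false);
  double dropped = 0.0, total = 0.0;
  for (int b = 0; b < nb; ++b) {
    net->forward_case(net->caches[b], true);
    const auto& m = net->caches[b].cmask;
    for (uint8_t keep : m) dropped += keep ? 0.0 : 1.0;
    total += (double)(4 * net->vox(0));
  }
  return dropped / total;
}

// training-mode loss (batch BN statistics, corruption via the net RNG) with
// no parameter update; used for gradient verification
// [[Rcpp::export(name = ".cd_net_loss_training")]]
List cd_net_loss_training(SEXP ptr, NumericVector x, NumericVector times,
                          IntegerVector events, double alpha, double beta,
                          std::string reduction) {
  XPtr<Net> net(ptr);
  int nb = 0;
  load_batch(*net, x, nb);
  const size_t percase = 4 * net->vox(0);
  const double scale = (reduction == "mean")
    ? 1.0 / ((double)nb * percase) : 1.0 / (double)nb;
  net->prepare_bn(net->caches, false);
  double Lr = 0.0;
  std::vector<double> r(nb), t(times.begin(), times.end());
  std::vector<int> d(events.begin(), events.end());
  std::vector<float> tmp;
  for (int b = 0; b < nb; ++b) {
    net->forward_case(net->caches[b], true);
    Lr += recon_loss_and_grad(net->caches[b], scale, tmp);
    r[b] = net->caches[b].risk;
  }
  const double Ls = cox_npll(r, t, d, nullptr);
  return List::create(_["l_r"] = Lr, _["l_s"] = Ls,
                      _["hybrid"] = alpha * Lr + beta * Ls);
}

// analytic gradients of the hybrid loss for the current weights; no update
// [[Rcpp::export(name = ".cd_net_grads")]]
List cd_net_grads(SEXP ptr, NumericVector x, NumericVector times,
                  IntegerVector events, double alpha, double beta,
                  std::string reduction) {
  XPtr<Net> net(ptr);
  int nb = 0;
  load_batch(*net, x, nb);
  const size_t percase = 4 * net->vox(0);
  const double scale = (reduction == "mean")
    ? 1.0 / ((double)nb * percase) : 1.0 / (double)nb;
  net->prepare_bn(net->caches, false);
  for (auto* p : net->params()) p->zero_grad();
  std::vector<double> r(nb), t(times.begin(), times.end());
  std::vector<int> d(events.begin(), events.end());
  for (int b = 0; b < nb; ++b) {
    net->forward_case(net->caches[b], true);
    r[b] = net->caches[b].risk;
  }
  std::vector<double> gcox;
  cox_npll(r, t, d, &gcox);
  std::vector<float> dr;
  for (int b = 0; b < nb; ++b) {
    recon_loss_and_grad(net->caches[b], scale, dr);
    for (auto& g : dr) g *= (float)alpha;
    net->backward_case(net->caches[b], dr, beta * gcox[b]);
  }
  auto ps = net->params();
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i)
    out[i] = NumericVector(ps[i]->g.begin(), ps[i]->g.end());
  return out;
}

// [[Rcpp::export(name = ".cd_cox_npll")]]
List cd_cox_npll(NumericVector risks, NumericVector times, IntegerVector events,
                 bool want_grad) {
  std::vector<double> r(risks.begin(), risks.end()),
                      t(times.begin(), times.end());
  std::vector<int> d(events.begin(), events.end());
  std::vector<double> g;
  const double L = cox_npll(r, t, d, want_grad ? &g : nullptr);
  if (want_grad)
    return List::create(_["loss"] = L,
                        _["grad"] = NumericVector(g.begin(), g.end()));
  return List::create(_["loss"] = L);
}
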