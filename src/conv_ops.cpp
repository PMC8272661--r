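// Convolution kernels for the deformable U-Net.
//
// Array layout conventions (column-major R arrays):
//   feature maps  x : dim (C, H, W, N)        -> x[c + C*(h + H*(w + W*n))]
//   kernels       w : dim (k, k, Cin, Cout)   -> w[kr + k*(kc + k*(ci + Cin*co))]
//   offset fields   : dim (2*k*k, H, W, N); kernel point m = kr*k + kc (row-major),
//                     channel 2m = vertical (row) displacement, 2m+1 = horizontal.
// Spatial coordinates are 0-based with pixel centers at integers. Samples outside
// the image contribute 0, with a linear taper across the one-pixel border band
// (the same zero-padding semantics as the standard convolution).
//
// Internally each sample is transposed to per-channel (H, W) planes so the
// innermost loops run over contiguous memory and vectorize.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static void dims4(const NumericVector& a, int& d1, int& d2, int& d3, int& d4) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}

// (C,H,W) slab -> per-channel planes
static void to_planes(const double* x, int C, int HW, double* buf) {
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < HW; ++i)
      buf[(std::ptrdiff_t)c * HW + i] = x[(std::ptrdiff_t)i * C + c];
}

static void from_planes(const double* buf, int C, int HW, double* x) {
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < HW; ++i)
      x[(std::ptrdiff_t)i * C + c] = buf[(std::ptrdiff_t)c * HW + i];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int C, H, W, N, k1, k2, Cin, Cout;
  dims4(x, C, H, W, N);
  dims4(w, k1, k2, Cin, Cout);
  if (k1 != k2) stop("kernel must be square");
  if (Cin != C) stop("input has %d channels but kernel expects %d", C, Cin);
  int k = k1, pad = k / 2, HW = H * W;
  NumericVector y((std::ptrdiff_t)Cout * HW * N);
  y.attr("dim") = IntegerVector::create(Cout, H, W, N);
  const double* wp = w.begin();
  std::vector<double> xbuf((std::ptrdiff_t)C * HW), ybuf((std::ptrdiff_t)Cout * HW);
  for (int n = 0; n < N; ++n) {
    to_planes(x.begin() + (std::ptrdiff_t)C * HW * n, C, HW, xbuf.data());
    for (int co = 0; co < Cout; ++co)
      std::fill(ybuf.begin() + (std::ptrdiff_t)co * HW,
                ybuf.begin() + (std::ptrdiff_t)(co + 1) * HW, b[co]);
    for (int co = 0; co < Cout; ++co) {
      double* yplane = ybuf.data() + (std::ptrdiff_t)co * HW;
      for (int ci = 0; ci < C; ++ci) {
        const double* xplane = xbuf.data() + (std::ptrdiff_t)ci * HW;
        for (int kc = 0; kc < k; ++kc) {
          int w0 = std::max(0, pad - kc), w1 = std::min(W, W + pad - kc);
          for (int kr = 0; kr < k; ++kr) {
            double wv = wp[kr + k * (kc + k * (ci + (std::ptrdiff_t)Cin * co))];
            if (wv == 0.0) continue;
            int h0 = std::max(0, pad - kr), h1 = std::min(H, H + pad - kr);
            for (int wc = w0; wc < w1; ++wc) {
              const double* xs = xplane + (h0 + kr - pad) + (std::ptrdiff_t)H * (wc + kc - pad);
              double* yd = yplane + h0 + (std::ptrdiff_t)H * wc;
              for (int h = h0; h < h1; ++h) yd[h - h0] += wv * xs[h - h0];
            }
          }
        }
      }
    }
    from_planes(ybuf.data(), Cout, HW, y.begin() + (std::ptrdiff_t)Cout * HW * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int C, H, W, N, k1, k2, Cin, Cout, Co2, H2, W2, N2;
  dims4(x, C, H, W, N);
  dims4(w, k1, k2, Cin, Cout);
  dims4(dy, Co2, H2, W2, N2);
  if (Co2 != Cout || H2 != H || W2 != W || N2 != N) stop("dy shape mismatch");
  int k = k1, pad = k / 2, HW = H * W;
  NumericVector dx((std::ptrdiff_t)C * HW * N);
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  NumericVector dw((std::ptrdiff_t)k * k * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector db(Cout);
  const double* wp = w.begin();
  double* dwp = dw.begin(); double* dbp = db.begin();
  std::vector<double> xbuf((std::ptrdiff_t)C * HW), dybuf((std::ptrdiff_t)Cout * HW),
      dxbuf((std::ptrdiff_t)C * HW);
  for (int n = 0; n < N; ++n) {
    to_planes(x.begin() + (std::ptrdiff_t)C * HW * n, C, HW, xbuf.data());
    to_planes(dy.begin() + (std::ptrdiff_t)Cout * HW * n, Cout, HW, dybuf.data());
    std::fill(dxbuf.begin(), dxbuf.end(), 0.0);
    for (int co = 0; co < Cout; ++co) {
      const double* gplane = dybuf.data() + (std::ptrdiff_t)co * HW;
      double s = 0.0;
      for (int i = 0; i < HW; ++i) s += gplane[i];
      dbp[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double* xplane = xbuf.data() + (std::ptrdiff_t)ci * HW;
        double* dxplane = dxbuf.data() + (std::ptrdiff_t)ci * HW;
        for (int kc = 0; kc < k; ++kc) {
          int w0 = std::max(0, pad - kc), w1 = std::min(W, W + pad - kc);
          for (int kr = 0; kr < k; ++kr) {
            std::ptrdiff_t wi = kr + k * (kc + k * (ci + (std::ptrdiff_t)Cin * co));
            double wv = wp[wi];
            double acc = 0.0;
            int h0 = std::max(0, pad - kr), h1 = std::min(H, H + pad - kr);
            for (int wc = w0; wc < w1; ++wc) {
              const double* xs = xplane + (h0 + kr - pad) + (std::ptrdiff_t)H * (wc + kc - pad);
              double* dxs = dxbuf.data() + (std::ptrdiff_t)ci * HW +
                            (h0 + kr - pad) + (std::ptrdiff_t)H * (wc + kc - pad);
              const double* gs = gplane + h0 + (std::ptrdiff_t)H * wc;
              int len = h1 - h0;
              for (int h = 0; h < len; ++h) {
                acc += gs[h] * xs[h];
                dxs[h] += wv * gs[h];
              }
            }
            dwp[wi] += acc;
            (void)dxplane;
          }
        }
      }
    }
    from_planes(dxbuf.data(), C, HW, dx.begin() + (std::ptrdiff_t)C * HW * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

struct Corner {
  int i00, i01, i10, i11;       // plane-relative lattice indices (-1 = outside)
  double w00, w01, w10, w11;    // bilinear weights
  double fr, fc;
  bool any;                     // sampling position contributes at all
};

static inline Corner corners(double qr, double qc, int H, int W) {
  Corner c;
  if (qr <= -1.0 || qr >= H || qc <= -1.0 || qc >= W) {
    c.any = false;
    c.i00 = c.i01 = c.i10 = c.i11 = -1;
    c.w00 = c.w01 = c.w10 = c.w11 = c.fr = c.fc = 0.0;
    return c;
  }
  c.any = true;
  int r0 = (int)std::floor(qr), c0 = (int)std::floor(qc);
  c.fr = qr - r0; c.fc = qc - c0;
  bool r0in = r0 >= 0 && r0 < H, r1in = r0 + 1 >= 0 && r0 + 1 < H;
  bool c0in = c0 >= 0 && c0 < W, c1in = c0 + 1 >= 0 && c0 + 1 < W;
  c.i00 = (r0in && c0in) ? r0 + H * c0 : -1;
  c.i01 = (r0in && c1in) ? r0 + H * (c0 + 1) : -1;
  c.i10 = (r1in && c0in) ? r0 + 1 + H * c0 : -1;
  c.i11 = (r1in && c1in) ? r0 + 1 + H * (c0 + 1) : -1;
  c.w00 = (1 - c.fr) * (1 - c.fc); c.w01 = (1 - c.fr) * c.fc;
  c.w10 = c.fr * (1 - c.fc);       c.w11 = c.fr * c.fc;
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_deform_fwd(NumericVector x, NumericVector w, NumericVector b,
                             NumericVector off) {
  int C, H, W, N, k1, k2, Cin, Cout, OC, OH, OW, ON;
  dims4(x, C, H, W, N);
  dims4(w, k1, k2, Cin, Cout);
  dims4(off, OC, OH, OW, ON);
  if (k1 != k2) stop("kernel must be square");
  if (Cin != C) stop("input has %d channels but kernel expects %d", C, Cin);
  int k = k1, pad = k / 2, K2 = k * k, HW = H * W;
  if (OC != 2 * K2) stop("offset field has %d channels but 2*k^2 = %d required", OC, 2 * K2);
  if (OH != H || OW != W || ON != N) stop("offset field spatial dims mismatch");
  NumericVector y((std::ptrdiff_t)Cout * HW * N);
  y.attr("dim") = IntegerVector::create(Cout, H, W, N);
  const double* wp = w.begin();
  std::vector<double> xbuf((std::ptrdiff_t)C * HW), ybuf((std::ptrdiff_t)Cout * HW);
  std::vector<double> sval((std::ptrdiff_t)K2 * C);
  std::vector<Corner> cs(K2);
  for (int n = 0; n < N; ++n) {
    to_planes(x.begin() + (std::ptrdiff_t)C * HW * n, C, HW, xbuf.data());
    const double* op = off.begin() + (std::ptrdiff_t)OC * HW * n;
    for (int wc = 0; wc < W; ++wc)
      for (int h = 0; h < H; ++h) {
        const double* o = op + (std::ptrdiff_t)OC * (h + (std::ptrdiff_t)H * wc);
        for (int kr = 0; kr < k; ++kr)
          for (int kc = 0; kc < k; ++kc) {
            int m = kr * k + kc;          // offset channel pair index
            int m2 = kr + k * kc;         // kernel-weight index within a block
            cs[m2] = corners(h + kr - pad + o[2 * m],
                             wc + kc - pad + o[2 * m + 1], H, W);
          }
        for (int ci = 0; ci < C; ++ci) {
          const double* xplane = xbuf.data() + (std::ptrdiff_t)ci * HW;
          double* sv = sval.data() + (std::ptrdiff_t)K2 * ci;
          for (int m2 = 0; m2 < K2; ++m2) {
            const Corner& cc = cs[m2];
            double v = 0.0;
            if (cc.any) {
              if (cc.i00 >= 0) v += cc.w00 * xplane[cc.i00];
              if (cc.i01 >= 0) v += cc.w01 * xplane[cc.i01];
              if (cc.i10 >= 0) v += cc.w10 * xplane[cc.i10];
              if (cc.i11 >= 0) v += cc.w11 * xplane[cc.i11];
            }
            sv[m2] = v;
          }
        }
        std::ptrdiff_t yi = h + (std::ptrdiff_t)H * wc;
        int len = K2 * C;
        for (int co = 0; co < Cout; ++co) {
          const double* wb = wp + (std::ptrdiff_t)len * co;
          double acc = b[co];
          for (int j = 0; j < len; ++j) acc += wb[j] * sval[j];
          ybuf[(std::ptrdiff_t)co * HW + yi] = acc;
        }
      }
    from_planes(ybuf.data(), Cout, HW, y.begin() + (std::ptrdiff_t)Cout * HW * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_deform_bwd(NumericVector x, NumericVector w, NumericVector off,
                    NumericVector dy) {
  int C, H, W, N, k1, k2, Cin, Cout, OC, OH, OW, ON, Co2, H2, W2, N2;
  dims4(x, C, H, W, N);
  dims4(w, k1, k2, Cin, Cout);
  dims4(off, OC, OH, OW, ON);
  dims4(dy, Co2, H2, W2, N2);
  int k = k1, pad = k / 2, K2 = k * k, HW = H * W;
  if (Co2 != Cout || H2 != H || W2 != W || N2 != N) stop("dy shape mismatch");
  NumericVector dx((std::ptrdiff_t)C * HW * N);
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  NumericVector dw((std::ptrdiff_t)K2 * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector db(Cout);
  NumericVector doff((std::ptrdiff_t)OC * HW * N);
  doff.attr("dim") = IntegerVector::create(OC, H, W, N);
  const double* wp = w.begin();
  double* dwp = dw.begin(); double* dbp = db.begin();
  std::vector<double> xbuf((std::ptrdiff_t)C * HW), dybuf((std::ptrdiff_t)Cout * HW),
      dxbuf((std::ptrdiff_t)C * HW);
  std::vector<double> sval((std::ptrdiff_t)K2 * C), gin((std::ptrdiff_t)K2 * C);
  std::vector<double> dyv(Cout);
  std::vector<Corner> cs(K2);
  int len = K2 * C;
  for (int n = 0; n < N; ++n) {
    to_planes(x.begin() + (std::ptrdiff_t)C * HW * n, C, HW, xbuf.data());
    to_planes(dy.begin() + (std::ptrdiff_t)Cout * HW * n, Cout, HW, dybuf.data());
    std::fill(dxbuf.begin(), dxbuf.end(), 0.0);
    const double* op = off.begin() + (std::ptrdiff_t)OC * HW * n;
    double* dop = doff.begin() + (std::ptrdiff_t)OC * HW * n;
    for (int wc = 0; wc < W; ++wc)
      for (int h = 0; h < H; ++h) {
        std::ptrdiff_t pix = h + (std::ptrdiff_t)H * wc;
        const double* o = op + (std::ptrdiff_t)OC * pix;
        double* dof = dop + (std::ptrdiff_t)OC * pix;
        for (int kr = 0; kr < k; ++kr)
          for (int kc = 0; kc < k; ++kc)
            cs[kr + k * kc] = corners(h + kr - pad + o[2 * (kr * k + kc)],
                                      wc + kc - pad + o[2 * (kr * k + kc) + 1], H, W);
        for (int ci = 0; ci < C; ++ci) {
          const double* xplane = xbuf.data() + (std::ptrdiff_t)ci * HW;
          double* sv = sval.data() + (std::ptrdiff_t)K2 * ci;
          for (int m2 = 0; m2 < K2; ++m2) {
            const Corner& cc = cs[m2];
            double v = 0.0;
            if (cc.any) {
              if (cc.i00 >= 0) v += cc.w00 * xplane[cc.i00];
              if (cc.i01 >= 0) v += cc.w01 * xplane[cc.i01];
              if (cc.i10 >= 0) v += cc.w10 * xplane[cc.i10];
              if (cc.i11 >= 0) v += cc.w11 * xplane[cc.i11];
            }
            sv[m2] = v;
          }
        }
        bool anyg = false;
        for (int co = 0; co < Cout; ++co) {
          dyv[co] = dybuf[(std::ptrdiff_t)co * HW + pix];
          if (dyv[co] != 0.0) anyg = true;
          dbp[co] += dyv[co];
        }
        if (!anyg) continue;
        std::fill(gin.begin(), gin.end(), 0.0);
        for (int co = 0; co < Cout; ++co) {
          double g = dyv[co];
          if (g == 0.0) continue;
          const double* wb = wp + (std::ptrdiff_t)len * co;
          double* dwb = dwp + (std::ptrdiff_t)len * co;
          for (int j = 0; j < len; ++j) {
            dwb[j] += g * sval[j];
            gin[j] += g * wb[j];
          }
        }
        for (int ci = 0; ci < C; ++ci) {
          const double* xplane = xbuf.data() + (std::ptrdiff_t)ci * HW;
          double* dxplane = dxbuf.data() + (std::ptrdiff_t)ci * HW;
          const double* gi = gin.data() + (std::ptrdiff_t)K2 * ci;
          for (int kr = 0; kr < k; ++kr)
            for (int kc = 0; kc < k; ++kc) {
              int m2 = kr + k * kc;
              const Corner& cc = cs[m2];
              if (!cc.any) continue;
              double wg = gi[m2];
              if (wg == 0.0) continue;
              double v00 = cc.i00 >= 0 ? xplane[cc.i00] : 0.0;
              double v01 = cc.i01 >= 0 ? xplane[cc.i01] : 0.0;
              double v10 = cc.i10 >= 0 ? xplane[cc.i10] : 0.0;
              double v11 = cc.i11 >= 0 ? xplane[cc.i11] : 0.0;
              if (cc.i00 >= 0) dxplane[cc.i00] += wg * cc.w00;
              if (cc.i01 >= 0) dxplane[cc.i01] += wg * cc.w01;
              if (cc.i10 >= 0) dxplane[cc.i10] += wg * cc.w10;
              if (cc.i11 >= 0) dxplane[cc.i11] += wg * cc.w11;
              double dval_dr = -(1 - cc.fc) * v00 - cc.fc * v01 +
                               (1 - cc.fc) * v10 + cc.fc * v11;
              double dval_dc = -(1 - cc.fr) * v00 + (1 - cc.fr) * v01 -
                               cc.fr * v10 + cc.fr * v11;
              int m = kr * k + kc;
              dof[2 * m] += wg * dval_dr;
              dof[2 * m + 1] += wg * dval_dc;
            }
        }
      }
    from_planes(dxbuf.data(), C, HW, dx.begin() + (std::ptrdiff_t)C * HW * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db, _["doff"] = doff);
}

// 2x2 max pooling, stride 2. Returns pooled map and flat argmax indices (0-based
// into the input vector) for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int C, H, W, N;
  dims4(x, C, H, W, N);
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::ptrdiff_t)C * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  NumericVector idx((std::ptrdiff_t)C * Ho * Wo * N); // double to hold big indices
  const double* xp = x.begin();
  double* yp = y.begin(); double* ip = idx.begin();
  std::ptrdiff_t o = 0;
  for (int n = 0; n < N; ++n) {
    std::ptrdiff_t nx = (std::ptrdiff_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -1e300; std::ptrdiff_t bi = 0;
          for (int dc = 0; dc < 2; ++dc)
            for (int dr = 0; dr < 2; ++dr) {
              std::ptrdiff_t xi = nx + c + (std::ptrdiff_t)C *
                (2 * ho + dr + (std::ptrdiff_t)H * (2 * wo + dc));
              if (xp[xi] > best) { best = xp[xi]; bi = xi; }
            }
          yp[o] = best; ip[o] = (double)bi; ++o;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, NumericVector idx, IntegerVector xdim) {
  std::ptrdiff_t n = (std::ptrdiff_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin(); const double* ip = idx.begin();
  for (std::ptrdiff_t i = 0; i < dy.size(); ++i)
    dxp[(std::ptrdiff_t)ip[i]] += dyp[i];
  return dx;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping): doubles H and W.
// w: dim (2, 2, Cin, Cout).
// [[Rcpp::export]]
NumericVector cpp_tconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int C, H, W, N, k1, k2, Cin, Cout;
  dims4(x, C, H, W, N);
  dims4(w, k1, k2, Cin, Cout);
  if (k1 != 2 || k2 != 2) stop("transposed conv kernel must be 2x2");
  if (Cin != C) stop("channel mismatch");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((std::ptrdiff_t)Cout * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* yp = y.begin();
  for (std::ptrdiff_t i = 0; i < y.size(); ++i) yp[i] = b[(i % Cout)];
  for (int n = 0; n < N; ++n) {
    std::ptrdiff_t nx = (std::ptrdiff_t)C * H * W * n;
    std::ptrdiff_t ny = (std::ptrdiff_t)Cout * Ho * Wo * n;
    for (int wc = 0; wc < W; ++wc)
      for (int h = 0; h < H; ++h)
        for (int ci = 0; ci < C; ++ci) {
          double xv = xp[nx + ci + (std::ptrdiff_t)C * (h + (std::ptrdiff_t)H * wc)];
          if (xv == 0.0) continue;
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int co = 0; co < Cout; ++co)
                yp[ny + co + (std::ptrdiff_t)Cout *
                   (2 * h + a + (std::ptrdiff_t)Ho * (2 * wc + bb))] +=
                  wp[a + 2 * (bb + 2 * (ci + (std::ptrdiff_t)Cin * co))] * xv;
        }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int C, H, W, N, k1, k2, Cin, Cout, Co2, Ho, Wo, N2;
  dims4(x, C, H, W, N);
  dims4(w, k1, k2, Cin, Cout);
  dims4(dy, Co2, Ho, Wo, N2);
  if (Co2 != Cout || Ho != 2 * H || Wo != 2 * W || N2 != N) stop("dy shape mismatch");
  NumericVector dx((std::ptrdiff_t)C * H * W * N);
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  NumericVector dw((std::ptrdiff_t)4 * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  NumericVector db(Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin(); double* dwp = dw.begin(); double* dbp = db.begin();
  for (int n = 0; n < N; ++n) {
    std::ptrdiff_t nx = (std::ptrdiff_t)C * H * W * n;
    std::ptrdiff_t ny = (std::ptrdiff_t)Cout * Ho * Wo * n;
    for (int wc = 0; wc < W; ++wc)
      for (int h = 0; h < H; ++h)
        for (int a = 0; a < 2; ++a)
          for (int bb = 0; bb < 2; ++bb)
            for (int co = 0; co < Cout; ++co) {
              double g = dyp[ny + co + (std::ptrdiff_t)Cout *
                             (2 * h + a + (std::ptrdiff_t)Ho * (2 * wc + bb))];
              if (g == 0.0) continue;
              for (int ci = 0; ci < C; ++ci) {
                std::ptrdiff_t xi = nx + ci + (std::ptrdiff_t)C * (h + (std::ptrdiff_t)H * wc);
                std::ptrdiff_t wi = a + 2 * (bb + 2 * (ci + (std::ptrdiff_t)Cin * co));
                dxp[xi] += g * wp[wi];
                dwp[wi] += g * xp[xi];
              }
            }
  }
  // bias gradient: plain sum of dy per out channel
  for (std::ptrdiff_t i = 0; i < dy.size(); ++i) dbp[i % Cout] += dyp[i];
  return List::create(_["dx"] = dx, _["db"] = db, _["dw"] = dw);
}
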