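// 3D convolution and max-pooling kernels for the volumetric embedding
// backbones. Tensors follow the R array layout (N, C, D, H, W), column-major,
// so the sample index varies fastest and runs over samples are contiguous.
// Convolution builds a batched im2col matrix with rows indexed by
// (sample, output position) -- filled by contiguous memcpy over samples --
// followed by a single BLAS matrix product per chunk; the backward pass
// reuses the same column geometry to scatter gradients. Chunking over
// samples bounds the im2col buffer at roughly half a gigabyte.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvGeom {
  int N, C, D, H, W;        // input
  int Co, kd, kh, kw;       // kernel
  int sd, sh, sw;           // stride
  int pd, ph, pw;           // zero padding
  int Do, Ho, Wo;           // output
  int K, P;                 // im2col columns (C*kd*kh*kw), positions (Do*Ho*Wo)
};

ConvGeom conv_geom(const IntegerVector& xdim, const IntegerVector& wdim,
                   const IntegerVector& stride, const IntegerVector& pad) {
  ConvGeom g;
  g.N = xdim[0]; g.C = xdim[1]; g.D = xdim[2]; g.H = xdim[3]; g.W = xdim[4];
  g.Co = wdim[0]; g.kd = wdim[2]; g.kh = wdim[3]; g.kw = wdim[4];
  if (wdim[1] != g.C) stop("conv3d: input has %d channels, kernel expects %d", g.C, wdim[1]);
  g.sd = stride[0]; g.sh = stride[1]; g.sw = stride[2];
  g.pd = pad[0]; g.ph = pad[1]; g.pw = pad[2];
  g.Do = (g.D + 2 * g.pd - g.kd) / g.sd + 1;
  g.Ho = (g.H + 2 * g.ph - g.kh) / g.sh + 1;
  g.Wo = (g.W + 2 * g.pw - g.kw) / g.sw + 1;
  if (g.Do < 1 || g.Ho < 1 || g.Wo < 1) stop("conv3d: kernel larger than padded input");
  g.K = g.C * g.kd * g.kh * g.kw;
  g.P = g.Do * g.Ho * g.Wo;
  return g;
}

// weight matrix (K x Co); row k enumerates (ci, a, b, c) with ci fastest
arma::mat weight_matrix_t(const NumericVector& w, const ConvGeom& g) {
  arma::mat Wt(g.K, g.Co);
  const double* wp = w.begin();
  for (int co = 0; co < g.Co; ++co)
    for (int c = 0; c < g.kw; ++c)
      for (int b = 0; b < g.kh; ++b)
        for (int a = 0; a < g.kd; ++a)
          for (int ci = 0; ci < g.C; ++ci)
            Wt(ci + g.C * (a + g.kd * (b + g.kh * c)), co) =
                wp[co + (long)g.Co * (ci + (long)g.C * (a + (long)g.kd * (b + (long)g.kh * c)))];
  return Wt;
}

inline long xoff(const ConvGeom& g, int n, int ci, int d, int h, int w) {
  return n + (long)g.N * (ci + (long)g.C * (d + (long)g.D * (h + (long)g.H * w)));
}

int chunk_samples(const ConvGeom& g) {
  const double cap = 6e7; // doubles in the im2col buffer
  long per_sample = (long)g.P * g.K;
  int nc = (int)std::max(1.0, std::floor(cap / (double)per_sample));
  return std::min(nc, g.N);
}

// Fill col (ncP x K) for samples [n0, n0+nc); row j = (n - n0) + nc * p.
void im2col_chunk(const double* xp, const ConvGeom& g, int n0, int nc,
                  arma::mat& col) {
  col.zeros();
  for (int c = 0; c < g.kw; ++c)
    for (int b = 0; b < g.kh; ++b)
      for (int a = 0; a < g.kd; ++a)
        for (int ci = 0; ci < g.C; ++ci) {
          int k = ci + g.C * (a + g.kd * (b + g.kh * c));
          double* dst0 = col.colptr(k);
          for (int ow = 0; ow < g.Wo; ++ow) {
            int wi = ow * g.sw - g.pw + c;
            if (wi < 0 || wi >= g.W) continue;
            for (int oh = 0; oh < g.Ho; ++oh) {
              int hi = oh * g.sh - g.ph + b;
              if (hi < 0 || hi >= g.H) continue;
              for (int od = 0; od < g.Do; ++od) {
                int di = od * g.sd - g.pd + a;
                if (di < 0 || di >= g.D) continue;
                int p = od + g.Do * (oh + g.Ho * ow);
                std::memcpy(dst0 + (long)nc * p,
                            xp + xoff(g, n0, ci, di, hi, wi),
                            nc * sizeof(double));
              }
            }
          }
        }
}

} // namespace

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         IntegerVector stride, IntegerVector pad) {
  ConvGeom g = conv_geom(x.attr("dim"), w.attr("dim"), stride, pad);
  NumericVector y((long)g.N * g.Co * g.P);
  y.attr("dim") = IntegerVector::create(g.N, g.Co, g.Do, g.Ho, g.Wo);
  arma::mat Wt = weight_matrix_t(w, g);
  const double* xp = x.begin();
  double* yp = y.begin();
  int step = chunk_samples(g);
  arma::mat col((long)step * g.P, g.K);
  for (int n0 = 0; n0 < g.N; n0 += step) {
    int nc = std::min(step, g.N - n0);
    if (nc != step) col.set_size((long)nc * g.P, g.K);
    im2col_chunk(xp, g, n0, nc, col);
    arma::mat out = col * Wt; // (nc*P) x Co
    for (int co = 0; co < g.Co; ++co) {
      const double* src = out.colptr(co);
      double bias = b[co];
      for (int p = 0; p < g.P; ++p) {
        double* dst = yp + n0 + (long)g.N * (co + (long)g.Co * p);
        const double* s = src + (long)nc * p;
        for (int nl = 0; nl < nc; ++nl) dst[nl] = s[nl] + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                IntegerVector stride, IntegerVector pad,
                bool need_gx = true) {
  ConvGeom g = conv_geom(x.attr("dim"), w.attr("dim"), stride, pad);
  arma::mat Wt = weight_matrix_t(w, g);
  NumericVector gx(need_gx ? (long)x.size() : 0L);
  if (need_gx) gx.attr("dim") = x.attr("dim");
  NumericVector gw((long)w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(g.Co);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  arma::mat gWt(g.K, g.Co, arma::fill::zeros);
  int step = chunk_samples(g);
  arma::mat col((long)step * g.P, g.K);
  arma::mat gy2((long)step * g.P, g.Co);
  for (int n0 = 0; n0 < g.N; n0 += step) {
    int nc = std::min(step, g.N - n0);
    if (nc != step) {
      col.set_size((long)nc * g.P, g.K);
      gy2.set_size((long)nc * g.P, g.Co);
    }
    for (int co = 0; co < g.Co; ++co) {
      double* dst = gy2.colptr(co);
      double acc = 0.0;
      for (int p = 0; p < g.P; ++p) {
        const double* src = gyp + n0 + (long)g.N * (co + (long)g.Co * p);
        double* d = dst + (long)nc * p;
        for (int nl = 0; nl < nc; ++nl) { d[nl] = src[nl]; acc += src[nl]; }
      }
      gb[co] += acc;
    }
    im2col_chunk(xp, g, n0, nc, col);
    gWt += col.t() * gy2;
    if (!need_gx) continue;
    arma::mat colg = gy2 * Wt.t(); // (nc*P) x K
    for (int c = 0; c < g.kw; ++c)
      for (int b2 = 0; b2 < g.kh; ++b2)
        for (int a = 0; a < g.kd; ++a)
          for (int ci = 0; ci < g.C; ++ci) {
            int k = ci + g.C * (a + g.kd * (b2 + g.kh * c));
            const double* src0 = colg.colptr(k);
            for (int ow = 0; ow < g.Wo; ++ow) {
              int wi = ow * g.sw - g.pw + c;
              if (wi < 0 || wi >= g.W) continue;
              for (int oh = 0; oh < g.Ho; ++oh) {
                int hi = oh * g.sh - g.ph + b2;
                if (hi < 0 || hi >= g.H) continue;
                for (int od = 0; od < g.Do; ++od) {
                  int di = od * g.sd - g.pd + a;
                  if (di < 0 || di >= g.D) continue;
                  int p = od + g.Do * (oh + g.Ho * ow);
                  const double* s = src0 + (long)nc * p;
                  double* dst = gxp + xoff(g, n0, ci, di, hi, wi);
                  for (int nl = 0; nl < nc; ++nl) dst[nl] += s[nl];
                }
              }
            }
          }
  }
  double* gwp = gw.begin();
  for (int co = 0; co < g.Co; ++co)
    for (int c = 0; c < g.kw; ++c)
      for (int b2 = 0; b2 < g.kh; ++b2)
        for (int a = 0; a < g.kd; ++a)
          for (int ci = 0; ci < g.C; ++ci)
            gwp[co + (long)g.Co * (ci + (long)g.C * (a + (long)g.kd * (b2 + (long)g.kh * c)))] =
                gWt(ci + g.C * (a + g.kd * (b2 + g.kh * c)), co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, IntegerVector size, IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], D = xd[2], H = xd[3], W = xd[4];
  int kd = size[0], kh = size[1], kw = size[2];
  int sd = stride[0], sh = stride[1], sw = stride[2];
  int Do = (D - kd) / sd + 1, Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("maxpool3d: window larger than input");
  long ylen = (long)N * C * Do * Ho * Wo;
  NumericVector y(ylen);
  IntegerVector arg(ylen); // flat (d,h,w) offset of the max, 0-based
  y.attr("dim") = IntegerVector::create(N, C, Do, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od)
        for (int ci = 0; ci < C; ++ci) {
          long o0 = (long)N * (ci + (long)C * (od + (long)Do * (oh + (long)Ho * ow)));
          for (int n = 0; n < N; ++n) { yp[o0 + n] = -HUGE_VAL; }
          for (int c = 0; c < kw; ++c)
            for (int b = 0; b < kh; ++b)
              for (int a = 0; a < kd; ++a) {
                int di = od * sd + a, hi = oh * sh + b, wi = ow * sw + c;
                int flat = di + D * (hi + H * wi);
                const double* src = xp + (long)N * (ci + (long)C * flat);
                for (int n = 0; n < N; ++n) {
                  if (src[n] > yp[o0 + n]) { yp[o0 + n] = src[n]; ap[o0 + n] = flat; }
                }
              }
        }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gy, IntegerVector argmax,
                            IntegerVector xdim) {
  IntegerVector yd = gy.attr("dim");
  int N = yd[0], C = yd[1];
  long xlen = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector gx(xlen);
  gx.attr("dim") = xdim;
  long P = (long)yd[2] * yd[3] * yd[4];
  const double* gp = gy.begin();
  const int* ap = argmax.begin();
  double* gxp = gx.begin();
  for (long p = 0; p < P; ++p)
    for (int ci = 0; ci < C; ++ci) {
      long o0 = (long)N * (ci + (long)C * p);
      for (int n = 0; n < N; ++n) {
        gxp[n + (long)N * (ci + (long)C * (long)ap[o0 + n])] += gp[o0 + n];
      }
    }
  return gx;
}
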