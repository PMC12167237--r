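// Hot numeric kernels: 3x3 reflect-padded mean filtering (and its adjoint)
// for SSIM, im2col for the BLAS-backed convolutions, and bilinear grid
// sampling with zero padding (forward + backward). Arrays are column-major
// H x W x C, matching R.

#include <Rcpp.h>
using namespace Rcpp;

// mirror reflection (edge excluded): -1 -> 1, n -> n-2
static inline int refl(int i, int n) {
  if (i < 0) return 1;
  if (i >= n) return n - 2;
  return i;
}

// [[Rcpp::export]]
NumericVector box3_fwd(NumericVector x, int H, int W, int C) {
  NumericVector out(x.size());
  std::vector<double> tmp((size_t)H * W);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + (size_t)c * H * W;
    double *oc = out.begin() + (size_t)c * H * W;
    // horizontal pass into tmp
    for (int j = 0; j < W; ++j) {
      int jl = refl(j - 1, W), jr = refl(j + 1, W);
      const double *cl = xc + (size_t)jl * H;
      const double *cm = xc + (size_t)j * H;
      const double *cr = xc + (size_t)jr * H;
      double *t = tmp.data() + (size_t)j * H;
      for (int i = 0; i < H; ++i) t[i] = (cl[i] + cm[i] + cr[i]) / 3.0;
    }
    // vertical pass into out
    for (int j = 0; j < W; ++j) {
      const double *t = tmp.data() + (size_t)j * H;
      double *o = oc + (size_t)j * H;
      for (int i = 0; i < H; ++i) {
        int iu = refl(i - 1, H), id = refl(i + 1, H);
        o[i] = (t[iu] + t[i] + t[id]) / 3.0;
      }
    }
  }
  return out;
}

// adjoint of box3_fwd (transpose of the vertical then horizontal pass)
// [[Rcpp::export]]
NumericVector box3_adj(NumericVector g, int H, int W, int C) {
  NumericVector out(g.size());
  std::vector<double> tmp((size_t)H * W);
  for (int c = 0; c < C; ++c) {
    const double *gc = g.begin() + (size_t)c * H * W;
    double *oc = out.begin() + (size_t)c * H * W;
    // adjoint of vertical pass
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int j = 0; j < W; ++j) {
      const double *gj = gc + (size_t)j * H;
      double *t = tmp.data() + (size_t)j * H;
      for (int i = 0; i < H; ++i) {
        double v = gj[i] / 3.0;
        t[refl(i - 1, H)] += v;
        t[i] += v;
        t[refl(i + 1, H)] += v;
      }
    }
    // adjoint of horizontal pass
    for (size_t k = 0; k < (size_t)H * W; ++k) oc[k] = 0.0;
    for (int j = 0; j < W; ++j) {
      const double *t = tmp.data() + (size_t)j * H;
      int jl = refl(j - 1, W), jr = refl(j + 1, W);
      double *cl = oc + (size_t)jl * H;
      double *cm = oc + (size_t)j * H;
      double *cr = oc + (size_t)jr * H;
      for (int i = 0; i < H; ++i) {
        double v = t[i] / 3.0;
        cl[i] += v;
        cm[i] += v;
        cr[i] += v;
      }
    }
  }
  return out;
}

// im2col with implicit zero padding for odd k, stride 1: output is
// (H*W) x (k*k*Cin), column m = di + k*dj + k*k*c
// [[Rcpp::export]]
NumericMatrix im2col_pad(NumericVector x, int H, int W, int Cin, int k) {
  int p = (k - 1) / 2;
  int N = H * W;
  NumericMatrix col(N, k * k * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double *xc = x.begin() + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double *dst = col.begin() + (size_t)(di + k * dj + k * k * c) * N;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - p;
          double *d = dst + (size_t)j * H;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) d[i] = 0.0;
            continue;
          }
          const double *s = xc + (size_t)sj * H;
          int i0 = (p - di > 0) ? (p - di) : 0;            // first valid row
          int i1 = (H + p - di < H) ? (H + p - di) : H;    // one past last
          for (int i = 0; i < i0; ++i) d[i] = 0.0;
          for (int i = i0; i < i1; ++i) d[i] = s[i + di - p];
          for (int i = i1; i < H; ++i) d[i] = 0.0;
        }
      }
    }
  }
  return col;
}

// bilinear sampling with zero padding. u, v: 0-based continuous coords
// (HO x WO), src: H x W x C. Returns out (HO x WO x C) and valid.
// [[Rcpp::export]]
List gridsample_fwd(NumericVector src, int H, int W, int C,
                    NumericVector u, NumericVector v, int HO, int WO,
                    Nullable<NumericVector> extra_valid) {
  int N = HO * WO;
  NumericVector out((size_t)N * C);
  NumericVector valid(N);
  const double *ev = nullptr;
  if (extra_valid.isNotNull()) {
    NumericVector e(extra_valid);
    ev = e.begin();
    // note: e must stay alive; copy instead
  }
  NumericVector evcopy;
  if (extra_valid.isNotNull()) {
    evcopy = NumericVector(extra_valid);
    ev = evcopy.begin();
  }
  for (int n = 0; n < N; ++n) {
    double uu = u[n], vv = v[n];
    bool ok = R_finite(uu) && R_finite(vv) &&
      uu >= 0.0 && uu <= (double)(W - 1) && vv >= 0.0 && vv <= (double)(H - 1);
    if (ok && ev && ev[n] == 0.0) ok = false;
    if (!ok) continue;
    valid[n] = 1.0;
    int x0 = (int)std::floor(uu);
    int y0 = (int)std::floor(vv);
    if (x0 > W - 2) x0 = W - 2;
    if (y0 > H - 2) y0 = H - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    double fx = uu - x0, fy = vv - y0;
    double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
    double w01 = (1 - fx) * fy, w11 = fx * fy;
    size_t i00 = (size_t)y0 + (size_t)H * x0;
    for (int c = 0; c < C; ++c) {
      const double *sc = src.begin() + (size_t)c * H * W;
      out[n + (size_t)c * N] = w00 * sc[i00] + w10 * sc[i00 + H] +
        w01 * sc[i00 + 1] + w11 * sc[i00 + H + 1];
    }
  }
  return List::create(_["out"] = out, _["valid"] = valid);
}

// backward of gridsample_fwd: gradients to src and to (u, v)
// [[Rcpp::export]]
List gridsample_bwd(NumericVector src, int H, int W, int C,
                    NumericVector u, NumericVector v, int HO, int WO,
                    NumericVector valid, NumericVector g,
                    bool need_src, bool need_uv) {
  int N = HO * WO;
  NumericVector gsrc(need_src ? (size_t)H * W * C : 0);
  NumericVector gu(need_uv ? N : 0), gv(need_uv ? N : 0);
  for (int n = 0; n < N; ++n) {
    if (valid[n] == 0.0) continue;
    double uu = u[n], vv = v[n];
    int x0 = (int)std::floor(uu);
    int y0 = (int)std::floor(vv);
    if (x0 > W - 2) x0 = W - 2;
    if (y0 > H - 2) y0 = H - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    double fx = uu - x0, fy = vv - y0;
    double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
    double w01 = (1 - fx) * fy, w11 = fx * fy;
    size_t i00 = (size_t)y0 + (size_t)H * x0;
    double du = 0.0, dv = 0.0;
    for (int c = 0; c < C; ++c) {
      double gc = g[n + (size_t)c * N];
      const double *sc = src.begin() + (size_t)c * H * W;
      double s00 = sc[i00], s10 = sc[i00 + H], s01 = sc[i00 + 1],
             s11 = sc[i00 + H + 1];
      if (need_src) {
        double *gs = gsrc.begin() + (size_t)c * H * W;
        gs[i00] += gc * w00;
        gs[i00 + H] += gc * w10;
        gs[i00 + 1] += gc * w01;
        gs[i00 + H + 1] += gc * w11;
      }
      if (need_uv) {
        du += gc * ((s10 - s00) * (1 - fy) + (s11 - s01) * fy);
        dv += gc * ((s01 - s00) * (1 - fx) + (s11 - s10) * fx);
      }
    }
    if (need_uv) {
      gu[n] = du;
      gv[n] = dv;
    }
  }
  return List::create(_["gsrc"] = gsrc, _["gu"] = gu, _["gv"] = gv);
}
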