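#include <Rcpp.h>
using namespace Rcpp;

// Volumes are column-major arrays with dims (D1, D2, D3, C, B).
// Kernels have dims (K1, K2, K3, Cin, Cout) with odd K; "same" padding.

static inline int dim5(const IntegerVector& d, int i) { return d[i]; }

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], Cin = xd[3], B = xd[4];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Cout = wd[4];
  if (wd[3] != Cin) stop("kernel input channels (%d) do not match input (%d)", (int)wd[3], Cin);
  const int P1 = (K1 - 1) / 2, P2 = (K2 - 1) / 2, P3 = (K3 - 1) / 2;
  NumericVector y(R_xlen_t(D1) * D2 * D3 * Cout * B);
  y.attr("dim") = IntegerVector::create(D1, D2, D3, Cout, B);
  const double* xp = x.begin(); const double* wp = w.begin(); double* yp = y.begin();
  const R_xlen_t xvol = R_xlen_t(D1) * D2 * D3, yvol = xvol;
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      double* ys = yp + (R_xlen_t(b) * Cout + co) * yvol;
      const double bv = bias[co];
      for (R_xlen_t i = 0; i < yvol; ++i) ys[i] = bv;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xs = xp + (R_xlen_t(b) * Cin + ci) * xvol;
        for (int k3 = 0; k3 < K3; ++k3) {
          const int o3 = k3 - P3;
          const int i3lo = std::max(0, -o3), i3hi = std::min(D3, D3 - o3);
          for (int k2 = 0; k2 < K2; ++k2) {
            const int o2 = k2 - P2;
            const int i2lo = std::max(0, -o2), i2hi = std::min(D2, D2 - o2);
            for (int k1 = 0; k1 < K1; ++k1) {
              const int o1 = k1 - P1;
              const int i1lo = std::max(0, -o1), i1hi = std::min(D1, D1 - o1);
              const double wv = wp[k1 + K1 * (k2 + K2 * (k3 + K3 * (ci + Cin * co)))];
              if (wv == 0.0) continue;
              for (int i3 = i3lo; i3 < i3hi; ++i3) {
                for (int i2 = i2lo; i2 < i2hi; ++i2) {
                  double* yrow = ys + R_xlen_t(D1) * (i2 + R_xlen_t(D2) * i3);
                  const double* xrow = xs + (o1 + R_xlen_t(D1) * ((i2 + o2) + R_xlen_t(D2) * (i3 + o3)));
                  for (int i1 = i1lo; i1 < i1hi; ++i1) yrow[i1] += wv * xrow[i1];
                }
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], Cin = xd[3], B = xd[4];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Cout = wd[4];
  const int P1 = (K1 - 1) / 2, P2 = (K2 - 1) / 2, P3 = (K3 - 1) / 2;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  const double* xp = x.begin(); const double* wp = w.begin(); const double* dyp = dy.begin();
  double* dxp = dx.begin(); double* dwp = dw.begin();
  const R_xlen_t vol = R_xlen_t(D1) * D2 * D3;
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      const double* dys = dyp + (R_xlen_t(b) * Cout + co) * vol;
      double acc = 0.0;
      for (R_xlen_t i = 0; i < vol; ++i) acc += dys[i];
      db[co] += acc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xs = xp + (R_xlen_t(b) * Cin + ci) * vol;
        double* dxs = dxp + (R_xlen_t(b) * Cin + ci) * vol;
        for (int k3 = 0; k3 < K3; ++k3) {
          const int o3 = k3 - P3;
          const int i3lo = std::max(0, -o3), i3hi = std::min(D3, D3 - o3);
          for (int k2 = 0; k2 < K2; ++k2) {
            const int o2 = k2 - P2;
            const int i2lo = std::max(0, -o2), i2hi = std::min(D2, D2 - o2);
            for (int k1 = 0; k1 < K1; ++k1) {
              const int o1 = k1 - P1;
              const int i1lo = std::max(0, -o1), i1hi = std::min(D1, D1 - o1);
              const R_xlen_t widx = k1 + K1 * (k2 + K2 * (k3 + K3 * (R_xlen_t(ci) + Cin * co)));
              const double wv = wp[widx];
              double wg = 0.0;
              for (int i3 = i3lo; i3 < i3hi; ++i3) {
                for (int i2 = i2lo; i2 < i2hi; ++i2) {
                  const double* dyrow = dys + R_xlen_t(D1) * (i2 + R_xlen_t(D2) * i3);
                  const R_xlen_t xoff = o1 + R_xlen_t(D1) * ((i2 + o2) + R_xlen_t(D2) * (i3 + o3));
                  const double* xrow = xs + xoff;
                  double* dxrow = dxs + xoff;
                  for (int i1 = i1lo; i1 < i1hi; ++i1) {
                    const double g = dyrow[i1];
                    wg += g * xrow[i1];
                    dxrow[i1] += wv * g;
                  }
                }
              }
              dwp[widx] += wg;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling; input dims must be even on the three spatial axes.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], B = xd[4];
  if (D1 % 2 || D2 % 2 || D3 % 2) stop("max pooling needs even spatial dims");
  const int E1 = D1 / 2, E2 = D2 / 2, E3 = D3 / 2;
  NumericVector y(R_xlen_t(E1) * E2 * E3 * C * B);
  y.attr("dim") = IntegerVector::create(E1, E2, E3, C, B);
  NumericVector idx(y.size()); // 1-based flat index into x of the max element
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin(); double* ip = idx.begin();
  R_xlen_t n = 0;
  for (int b = 0; b < B; ++b) for (int c = 0; c < C; ++c) {
    const R_xlen_t base = (R_xlen_t(b) * C + c) * R_xlen_t(D1) * D2 * D3;
    for (int e3 = 0; e3 < E3; ++e3) for (int e2 = 0; e2 < E2; ++e2) for (int e1 = 0; e1 < E1; ++e1) {
      double best = R_NegInf; R_xlen_t bi = 0;
      for (int d3 = 0; d3 < 2; ++d3) for (int d2 = 0; d2 < 2; ++d2) for (int d1 = 0; d1 < 2; ++d1) {
        const R_xlen_t xi = base + (2 * e1 + d1) +
          R_xlen_t(D1) * ((2 * e2 + d2) + R_xlen_t(D2) * (2 * e3 + d3));
        if (xp[xi] > best) { best = xp[xi]; bi = xi; }
      }
      yp[n] = best; ip[n] = double(bi + 1); ++n;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector dy, NumericVector idx, IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n); dx.attr("dim") = xdim;
  double* dxp = dx.begin(); const double* dyp = dy.begin(); const double* ip = idx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[R_xlen_t(ip[i]) - 1] += dyp[i];
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".upsample3d_fwd")]]
NumericVector upsample3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], B = xd[4];
  const int E1 = 2 * D1, E2 = 2 * D2, E3 = 2 * D3;
  NumericVector y(R_xlen_t(E1) * E2 * E3 * C * B);
  y.attr("dim") = IntegerVector::create(E1, E2, E3, C, B);
  const double* xp = x.begin(); double* yp = y.begin();
  R_xlen_t n = 0;
  for (int b = 0; b < B; ++b) for (int c = 0; c < C; ++c) {
    const R_xlen_t base = (R_xlen_t(b) * C + c) * R_xlen_t(D1) * D2 * D3;
    for (int e3 = 0; e3 < E3; ++e3) for (int e2 = 0; e2 < E2; ++e2) {
      const R_xlen_t row = base + R_xlen_t(D1) * ((e2 / 2) + R_xlen_t(D2) * (e3 / 2));
      for (int e1 = 0; e1 < E1; ++e1) yp[n++] = xp[row + e1 / 2];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample3d_bwd")]]
NumericVector upsample3d_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int E1 = yd[0], E2 = yd[1], E3 = yd[2], C = yd[3], B = yd[4];
  const int D1 = E1 / 2, D2 = E2 / 2, D3 = E3 / 2;
  NumericVector dx(R_xlen_t(D1) * D2 * D3 * C * B);
  dx.attr("dim") = IntegerVector::create(D1, D2, D3, C, B);
  const double* dyp = dy.begin(); double* dxp = dx.begin();
  R_xlen_t n = 0;
  for (int b = 0; b < B; ++b) for (int c = 0; c < C; ++c) {
    const R_xlen_t base = (R_xlen_t(b) * C + c) * R_xlen_t(D1) * D2 * D3;
    for (int e3 = 0; e3 < E3; ++e3) for (int e2 = 0; e2 < E2; ++e2) {
      const R_xlen_t row = base + R_xlen_t(D1) * ((e2 / 2) + R_xlen_t(D2) * (e3 / 2));
      for (int e1 = 0; e1 < E1; ++e1) dxp[row + e1 / 2] += dyp[n++];
    }
  }
  return dx;
}
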