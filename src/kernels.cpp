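// Compiled hot loops for the CNN + peephole-LSTM classifier.
//
// Layout conventions (column-major, matching R arrays):
//   feature maps: one column per sample, flat index i + H*(j + W*c)
//   conv weights: (kh*kw*Cin) x F, patch index di + kh*(dj + kw*c)
//   LSTM input:   cube (D, B, T); gate rows ordered [i; f; o; g]
// Convolutions are stride-1 with "same" zero padding (pad = floor((k-1)/2)
// on the top/left, remainder on the bottom/right).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col_same(const double* x, int H, int W, int C,
                        int kh, int kw, int sh, int sw,
                        int Ho, int Wo, mat& P) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  // P: (Ho*Wo) x (kh*kw*C); output (io, jo) reads input (io*sh+di-pt, ...)
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int q = di + kh * (dj + kw * c);
        double* pcol = P.colptr(q);
        for (int jo = 0; jo < Wo; ++jo) {
          const int sj = jo * sw + dj - pl;
          if (sj < 0 || sj >= W) {
            for (int io = 0; io < Ho; ++io) pcol[io + Ho * jo] = 0.0;
            continue;
          }
          const double* xcol = x + H * (sj + (long)W * c);
          for (int io = 0; io < Ho; ++io) {
            const int si = io * sh + di - pt;
            pcol[io + Ho * jo] = (si < 0 || si >= H) ? 0.0 : xcol[si];
          }
        }
      }
    }
  }
}

// scatter-add the patch gradient back onto the input gradient
static void col2im_same(const mat& dP, int H, int W, int C,
                        int kh, int kw, int sh, int sw,
                        int Ho, int Wo, double* dx) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int q = di + kh * (dj + kw * c);
        const double* pcol = dP.colptr(q);
        for (int jo = 0; jo < Wo; ++jo) {
          const int sj = jo * sw + dj - pl;
          if (sj < 0 || sj >= W) continue;
          double* xcol = dx + H * (sj + (long)W * c);
          for (int io = 0; io < Ho; ++io) {
            const int si = io * sh + di - pt;
            if (si >= 0 && si < H) xcol[si] += pcol[io + Ho * jo];
          }
        }
      }
    }
  }
}

static inline int out_dim(int n, int s) { return (n + s - 1) / s; }

// [[Rcpp::export]]
arma::mat nn_conv_fw(const arma::mat& X, int H, int W, int C,
                     const arma::mat& Wk, const arma::vec& bias,
                     int kh, int kw, int sh, int sw) {
  const int B = X.n_cols, F = Wk.n_cols;
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  mat Y(Ho * Wo * F, B);
  mat P(Ho * Wo, kh * kw * C);
  for (int b = 0; b < B; ++b) {
    im2col_same(X.colptr(b), H, W, C, kh, kw, sh, sw, Ho, Wo, P);
    mat Yb = P * Wk;                      // (Ho*Wo) x F
    Yb.each_row() += bias.t();
    std::copy(Yb.begin(), Yb.end(), Y.colptr(b));
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bw(const arma::mat& X, const arma::mat& dY,
                      int H, int W, int C,
                      const arma::mat& Wk, int kh, int kw, int sh, int sw) {
  const int B = X.n_cols, F = Wk.n_cols;
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  mat dX(size(X), fill::zeros);
  mat dW(size(Wk), fill::zeros);
  vec db(F, fill::zeros);
  mat P(Ho * Wo, kh * kw * C);
  for (int b = 0; b < B; ++b) {
    im2col_same(X.colptr(b), H, W, C, kh, kw, sh, sw, Ho, Wo, P);
    const mat dYb(const_cast<double*>(dY.colptr(b)), Ho * Wo, F, false, true);
    dW += P.t() * dYb;
    db += sum(dYb, 0).t();
    mat dP = dYb * Wk.t();
    col2im_same(dP, H, W, C, kh, kw, sh, sw, Ho, Wo, dX.colptr(b));
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List nn_pool_fw(const arma::mat& X, int H, int W, int C,
                      int ph, int pw) {
  const int B = X.n_cols, Ho = H / ph, Wo = W / pw;
  mat Y(Ho * Wo * C, B);
  imat idx(Ho * Wo * C, B);
  for (int b = 0; b < B; ++b) {
    const double* x = X.colptr(b);
    double* y = Y.colptr(b);
    sword* id = idx.colptr(b);
    for (int c = 0; c < C; ++c) {
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -datum::inf; long besti = 0;
          for (int dj = 0; dj < pw; ++dj) {
            for (int di = 0; di < ph; ++di) {
              const long f = (io * ph + di) + (long)H * ((jo * pw + dj) + (long)W * c);
              if (x[f] > best) { best = x[f]; besti = f; }
            }
          }
          const long o = io + (long)Ho * (jo + (long)Wo * c);
          y[o] = best; id[o] = besti;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat nn_pool_bw(const arma::mat& dY, const arma::imat& idx,
                     long in_len) {
  const int B = dY.n_cols;
  mat dX(in_len, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* dy = dY.colptr(b);
    const sword* id = idx.colptr(b);
    double* dx = dX.colptr(b);
    for (uword o = 0; o < dY.n_rows; ++o) dx[id[o]] += dy[o];
  }
  return dX;
}

static inline mat sigm(const mat& a) { return 1.0 / (1.0 + exp(-a)); }

// Peephole LSTM over a full sequence; returns the last hidden state plus
// the caches the backward pass needs. Gates: i, f see C_{t-1}; o sees C_t.
// [[Rcpp::export]]
Rcpp::List nn_lstm_fw(const arma::cube& X, const arma::mat& Wx,
                      const arma::mat& Wh, const arma::vec& b,
                      const arma::vec& pi, const arma::vec& pf,
                      const arma::vec& po) {
  const int D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const int Hn = Wh.n_cols;
  if ((int)Wx.n_rows != 4 * Hn || (int)Wx.n_cols != D) {
    Rcpp::stop("LSTM weight shapes inconsistent with input");
  }
  cube Gates(4 * Hn, B, T), Cs(Hn, B, T), Hs(Hn, B, T);
  mat h(Hn, B, fill::zeros), Cprev(Hn, B, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat A = Wx * X.slice(t) + Wh * h;
    A.each_col() += b;
    mat ai = A.rows(0, Hn - 1);
    mat af = A.rows(Hn, 2 * Hn - 1);
    mat ao = A.rows(2 * Hn, 3 * Hn - 1);
    mat ag = A.rows(3 * Hn, 4 * Hn - 1);
    mat tmp = Cprev; tmp.each_col() %= pi; ai += tmp;
    tmp = Cprev; tmp.each_col() %= pf; af += tmp;
    mat i = sigm(ai), f = sigm(af), g = tanh(ag);
    mat Ct = f % Cprev + i % g;
    tmp = Ct; tmp.each_col() %= po; ao += tmp;
    mat o = sigm(ao);
    h = o % tanh(Ct);
    Gates.slice(t).rows(0, Hn - 1) = i;
    Gates.slice(t).rows(Hn, 2 * Hn - 1) = f;
    Gates.slice(t).rows(2 * Hn, 3 * Hn - 1) = o;
    Gates.slice(t).rows(3 * Hn, 4 * Hn - 1) = g;
    Cs.slice(t) = Ct;
    Hs.slice(t) = h;
    Cprev = Ct;
  }
  return Rcpp::List::create(Rcpp::Named("h_last") = h,
                            Rcpp::Named("gates") = Gates,
                            Rcpp::Named("cells") = Cs,
                            Rcpp::Named("hidden") = Hs);
}

// [[Rcpp::export]]
Rcpp::List nn_lstm_bw(const arma::cube& X, const arma::cube& Gates,
                      const arma::cube& Cs, const arma::cube& Hs,
                      const arma::mat& Wx, const arma::mat& Wh,
                      const arma::vec& pi, const arma::vec& pf,
                      const arma::vec& po, const arma::mat& dh_last) {
  const int B = X.n_cols, T = X.n_slices;
  const int Hn = Wh.n_cols;
  cube dX(size(X), fill::zeros);
  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  vec db(4 * Hn, fill::zeros), dpi(Hn, fill::zeros), dpf(Hn, fill::zeros),
      dpo(Hn, fill::zeros);
  mat dh = dh_last, dC(Hn, B, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const mat i = Gates.slice(t).rows(0, Hn - 1);
    const mat f = Gates.slice(t).rows(Hn, 2 * Hn - 1);
    const mat o = Gates.slice(t).rows(2 * Hn, 3 * Hn - 1);
    const mat g = Gates.slice(t).rows(3 * Hn, 4 * Hn - 1);
    const mat Ct = Cs.slice(t);
    const mat Cprev = (t > 0) ? Cs.slice(t - 1) : mat(Hn, B, fill::zeros);
    const mat hprev = (t > 0) ? Hs.slice(t - 1) : mat(Hn, B, fill::zeros);
    const mat tC = tanh(Ct);
    mat dao = (dh % tC) % o % (1.0 - o);
    mat dCt = dC + dh % o % (1.0 - tC % tC);
    mat tmp = dao; tmp.each_col() %= po; dCt += tmp;
    mat dai = (dCt % g) % i % (1.0 - i);
    mat daf = (dCt % Cprev) % f % (1.0 - f);
    mat dag = (dCt % i) % (1.0 - g % g);
    dC = dCt % f;
    tmp = dai; tmp.each_col() %= pi; dC += tmp;
    tmp = daf; tmp.each_col() %= pf; dC += tmp;
    mat dA = join_cols(dai, daf, dao, dag);
    dWx += dA * X.slice(t).t();
    dWh += dA * hprev.t();
    db += sum(dA, 1);
    dpi += sum(dai % Cprev, 1);
    dpf += sum(daf % Cprev, 1);
    dpo += sum(dao % Ct, 1);
    dX.slice(t) = Wx.t() * dA;
    dh = Wh.t() * dA;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dpi") = dpi,
                            Rcpp::Named("dpf") = dpf,
                            Rcpp::Named("dpo") = dpo);
}
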