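// SPS weight generation: valid 2-D cross-correlation of a global template
// (p slices of r x c) with per-module kernels (p, p0, kh, kw), plus the
// adjoints needed for training. FFTW half-spectrum path for dense kernels,
// direct path (zero-skipping, hence bit-exact for one-hot kernels) for
// sparse/small ones.
//
// Index conventions (0-based, matching R column-major arrays):
//   template E: dim (p, r, c)        E[s,i,j]   -> s + p*(i + r*j)
//   kernel   M: dim (p, p0, kh, kw)  M[s,q,a,b] -> s + p*(q + p0*(a + kh*b))
//   output   W: dim (p0, r0, c0)     W[q,i,j]   -> q + p0*(i + r0*j)
// with r0 = r - kh + 1, c0 = c - kw + 1.
//
// Frequency-domain identities used (all at pad size r x c, real transforms):
//   forward:  W_q = ifft( sum_s FE_s .* conj(FM_sq) )[0:r0, 0:c0]
//   dM_sq    = ifft( FE_s .* conj(FdO_q) )[0:kh, 0:kw]
//   dE_s     = ifft( sum over bindings, q of FdO_q .* FM_sq )   (exact:
//              the linear extent r0 + kh - 1 equals r, so nothing wraps)

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <map>
#include <vector>
using namespace Rcpp;
typedef std::complex<double> cplx;

struct FftPlan {
  int r, c, nc;
  double* rbuf;
  fftw_complex* cbuf;
  fftw_plan fwd, bwd;
  FftPlan(int r_, int c_) : r(r_), c(c_), nc(c_ * (r_ / 2 + 1)) {
    rbuf = fftw_alloc_real(r * c);
    cbuf = fftw_alloc_complex(nc);
    // R matrices are column-major; hand FFTW the transposed (c x r) view
    fwd = fftw_plan_dft_r2c_2d(c, r, rbuf, cbuf, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_c2r_2d(c, r, cbuf, rbuf, FFTW_ESTIMATE);
  }
};

static FftPlan* get_plan(int r, int c) {
  static std::map<std::pair<int, int>, FftPlan*> cache;
  auto key = std::make_pair(r, c);
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  FftPlan* p = new FftPlan(r, c);
  cache[key] = p;
  return p;
}

// r2c of a zero-padded (hr x wc) block laid out with stride `stride0`
static void fft_block(FftPlan* P, const double* src, int hr, int wc,
                      int sstep, int scol, std::vector<cplx>& out) {
  std::fill(P->rbuf, P->rbuf + P->r * P->c, 0.0);
  for (int j = 0; j < wc; ++j)
    for (int i = 0; i < hr; ++i)
      P->rbuf[i + P->r * j] = src[sstep * i + scol * j];
  fftw_execute(P->fwd);
  out.resize(P->nc);
  std::copy(reinterpret_cast<cplx*>(P->cbuf),
            reinterpret_cast<cplx*>(P->cbuf) + P->nc, out.begin());
}

// c2r inverse (normalized); result left in P->rbuf, column-major (r x c)
static void ifft_to_rbuf(FftPlan* P, const std::vector<cplx>& spec) {
  std::copy(spec.begin(), spec.end(), reinterpret_cast<cplx*>(P->cbuf));
  fftw_execute(P->bwd);
  double inv = 1.0 / (double(P->r) * double(P->c));
  for (int t = 0; t < P->r * P->c; ++t) P->rbuf[t] *= inv;
}

struct KernDims {
  int p, p0, kh, kw, r0, c0;
};

static KernDims kern_dims(const NumericVector& M, int r, int c) {
  IntegerVector d = M.attr("dim");
  if (d.size() != 4) stop("kernel must be a 4-d array (p, p0, kh, kw)");
  KernDims k;
  k.p = d[0];
  k.p0 = d[1];
  k.kh = d[2];
  k.kw = d[3];
  k.r0 = r - k.kh + 1;
  k.c0 = c - k.kw + 1;
  if (k.r0 < 1 || k.c0 < 1) stop("kernel larger than template extent");
  return k;
}

typedef std::vector<std::vector<cplx>> SpecSet;

// half-spectra of all template slices, reused across every binding in a
// batch; opaque to the R side (dim attr carries r, c)
// [[Rcpp::export]]
ComplexVector cpp_fft_slices(NumericVector E) {
  IntegerVector d = E.attr("dim");
  int p = d[0], r = d[1], c = d[2];
  FftPlan* P = get_plan(r, c);
  ComplexVector out(P->nc * p);
  std::vector<cplx> spec;
  std::vector<double> slice(r * c);
  for (int s = 0; s < p; ++s) {
    for (int j = 0; j < c; ++j)
      for (int i = 0; i < r; ++i) slice[i + r * j] = E[s + p * (i + r * j)];
    fft_block(P, slice.data(), r, c, 1, r, spec);
    std::copy(spec.begin(), spec.end(),
              reinterpret_cast<cplx*>(out.begin()) + s * P->nc);
  }
  out.attr("r") = r;
  out.attr("c") = c;
  out.attr("p") = p;
  return out;
}

static void kernel_spectra(const NumericVector& M, const KernDims& k,
                           FftPlan* P, SpecSet& FM) {
  FM.resize(k.p * (size_t)k.p0);
  std::vector<double> plane(k.kh * k.kw);
  for (int q = 0; q < k.p0; ++q)
    for (int s = 0; s < k.p; ++s) {
      for (int b = 0; b < k.kw; ++b)
        for (int a = 0; a < k.kh; ++a)
          plane[a + k.kh * b] = M[s + k.p * (q + k.p0 * (a + k.kh * b))];
      fft_block(P, plane.data(), k.kh, k.kw, 1, k.kh, FM[s + k.p * q]);
    }
}

// forward for a set of bindings sharing one template; returns generated
// (pre-activation, pre-bias) weights plus cached kernel spectra (external
// pointer) for the backward pass
// [[Rcpp::export]]
List cpp_sps_forward_multi(ComplexVector FEv, List kernels) {
  int r = FEv.attr("r"), c = FEv.attr("c"), p = FEv.attr("p");
  FftPlan* P = get_plan(r, c);
  const cplx* FE = reinterpret_cast<const cplx*>(FEv.begin());
  int nb = kernels.size();
  List weights(nb);
  XPtr<std::vector<SpecSet>> kcache(new std::vector<SpecSet>(nb), true);
  std::vector<cplx> acc(P->nc);
  for (int m = 0; m < nb; ++m) {
    NumericVector M = kernels[m];
    KernDims k = kern_dims(M, r, c);
    if (k.p != p) stop("kernel slice count does not match template");
    SpecSet& FM = (*kcache)[m];
    kernel_spectra(M, k, P, FM);
    NumericVector W(k.p0 * (size_t)k.r0 * k.c0);
    W.attr("dim") = IntegerVector::create(k.p0, k.r0, k.c0);
    for (int q = 0; q < k.p0; ++q) {
      std::fill(acc.begin(), acc.end(), cplx(0, 0));
      for (int s = 0; s < p; ++s) {
        const cplx* fe = FE + s * P->nc;
        const cplx* fm = FM[s + p * q].data();
        for (int t = 0; t < P->nc; ++t) acc[t] += fe[t] * std::conj(fm[t]);
      }
      ifft_to_rbuf(P, acc);
      for (int j = 0; j < k.c0; ++j)
        for (int i = 0; i < k.r0; ++i)
          W[q + k.p0 * (i + (size_t)k.r0 * j)] = P->rbuf[i + r * j];
    }
    weights[m] = W;
  }
  return List::create(_["weights"] = weights, _["kfft"] = kcache);
}

// adjoints: gradient w.r.t. template (summed over bindings) and each kernel
// [[Rcpp::export]]
List cpp_sps_backward_multi(ComplexVector FEv, List kernels, SEXP kfft,
                            List gouts) {
  int r = FEv.attr("r"), c = FEv.attr("c"), p = FEv.attr("p");
  FftPlan* P = get_plan(r, c);
  const cplx* FE = reinterpret_cast<const cplx*>(FEv.begin());
  XPtr<std::vector<SpecSet>> kcache(kfft);
  int nb = kernels.size();
  std::vector<std::vector<cplx>> accE(p, std::vector<cplx>(P->nc, cplx(0, 0)));
  std::vector<cplx> spec(P->nc), mix(P->nc);
  std::vector<double> gplane;
  List dMs(nb);
  for (int m = 0; m < nb; ++m) {
    NumericVector M = kernels[m];
    KernDims k = kern_dims(M, r, c);
    NumericVector dM(M.size());
    dM.attr("dim") = M.attr("dim");
    if (!Rf_isNull(gouts[m])) {
      NumericVector dO = gouts[m];
      const SpecSet& FM = (*kcache)[m];
      gplane.resize((size_t)k.r0 * k.c0);
      for (int q = 0; q < k.p0; ++q) {
        for (int j = 0; j < k.c0; ++j)
          for (int i = 0; i < k.r0; ++i)
            gplane[i + (size_t)k.r0 * j] = dO[q + k.p0 * (i + (size_t)k.r0 * j)];
        fft_block(P, gplane.data(), k.r0, k.c0, 1, k.r0, spec);
        for (int s = 0; s < p; ++s) {
          const cplx* fm = FM[s + p * q].data();
          const cplx* fe = FE + s * P->nc;
          cplx* ae = accE[s].data();
          for (int t = 0; t < P->nc; ++t) {
            ae[t] += spec[t] * fm[t];
            mix[t] = fe[t] * std::conj(spec[t]);
          }
          ifft_to_rbuf(P, mix);
          for (int b = 0; b < k.kw; ++b)
            for (int a = 0; a < k.kh; ++a)
              dM[s + p * (q + k.p0 * (a + k.kh * b))] = P->rbuf[a + r * b];
        }
      }
    }
    dMs[m] = dM;
  }
  NumericVector dE(p * (size_t)r * c);
  dE.attr("dim") = IntegerVector::create(p, r, c);
  for (int s = 0; s < p; ++s) {
    ifft_to_rbuf(P, accE[s]);
    for (int j = 0; j < c; ++j)
      for (int i = 0; i < r; ++i)
        dE[s + p * (i + (size_t)r * j)] = P->rbuf[i + r * j];
  }
  return List::create(_["dE"] = dE, _["dM"] = dMs);
}

// direct path: skips zero kernel entries, so one-hot kernels reproduce
// template windows bit-for-bit
// [[Rcpp::export]]
NumericVector cpp_sps_xcorr_direct(NumericVector E, NumericVector M) {
  IntegerVector de = E.attr("dim");
  int p = de[0], r = de[1], c = de[2];
  KernDims k = kern_dims(M, r, c);
  if (k.p != p) stop("kernel slice count does not match template");
  NumericVector W(k.p0 * (size_t)k.r0 * k.c0);
  W.attr("dim") = IntegerVector::create(k.p0, k.r0, k.c0);
  for (int b = 0; b < k.kw; ++b)
    for (int a = 0; a < k.kh; ++a)
      for (int q = 0; q < k.p0; ++q)
        for (int s = 0; s < p; ++s) {
          double w = M[s + p * (q + k.p0 * (a + k.kh * b))];
          if (w == 0.0) continue;
          for (int j = 0; j < k.c0; ++j)
            for (int i = 0; i < k.r0; ++i)
              W[q + k.p0 * (i + (size_t)k.r0 * j)] +=
                  w * E[s + p * ((i + a) + (size_t)r * (j + b))];
        }
  return W;
}

// single-binding FFT path (used by sps_generate for dense kernels)
// [[Rcpp::export]]
NumericVector cpp_sps_xcorr_fft(NumericVector E, NumericVector M) {
  ComplexVector FE = cpp_fft_slices(E);
  List res = cpp_sps_forward_multi(FE, List::create(M));
  return List(res["weights"])[0];
}

// fused mean token-level cross-entropy over masked rows: returns the loss
// and the ready-scaled gradient matrix in one pass
// [[Rcpp::export]]
List cpp_ce_loss(NumericMatrix logits, IntegerVector targets,
                 LogicalVector mask) {
  int R = logits.nrow(), V = logits.ncol();
  NumericMatrix G(R, V);
  double total = 0.0;
  int nm = 0;
  for (int i = 0; i < R; ++i) if (mask[i]) ++nm;
  if (nm == 0) stop("empty target mask");
  double inv = 1.0 / nm;
  for (int i = 0; i < R; ++i) {
    if (!mask[i]) continue;
    double mx = logits(i, 0);
    for (int j = 1; j < V; ++j) if (logits(i, j) > mx) mx = logits(i, j);
    double Z = 0.0;
    for (int j = 0; j < V; ++j) {
      double e = std::exp(logits(i, j) - mx);
      G(i, j) = e;
      Z += e;
    }
    int tgt = targets[i] - 1;
    total += logits(i, tgt) - mx - std::log(Z);
    double s = inv / Z;
    for (int j = 0; j < V; ++j) G(i, j) *= s;
    G(i, tgt) -= inv;
  }
  return List::create(_["loss"] = -total * inv, _["grad"] = G);
}

// ---- fused scaled dot-product attention core (single head) ----------------
// Batch layout: row of (t, b) in a (B*T) x n matrix is (t-1)*B + (b-1).

#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

static void dgemm_(char ta, char tb, int m, int n, int k, double alpha,
                   const double* A, int lda, const double* B, int ldb,
                   double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

struct AttnCtx {
  int B, Tq, Tk, n;
  std::vector<std::vector<double>> P;   // per-item Tq x Tk softmax weights
  std::vector<double> Qg, Kg, Vg;       // gathered per-item inputs, reused
};

static void gather_item(const NumericMatrix& X, int b, int B, int T, int n,
                        std::vector<double>& out) {
  out.resize((size_t)T * n);
  int R = X.nrow();
  const double* x = &X(0, 0);
  for (int c = 0; c < n; ++c)
    for (int t = 0; t < T; ++t)
      out[t + (size_t)T * c] = x[t * B + b + (size_t)R * c];
}

// [[Rcpp::export]]
List cpp_attn_forward(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                      int B, int Tq, int Tk, bool causal,
                      Nullable<LogicalVector> key_mask_) {
  int n = Q.ncol();
  double sc = 1.0 / std::sqrt((double)n);
  NumericMatrix out(B * Tq, n);
  XPtr<AttnCtx> ctx(new AttnCtx(), true);
  ctx->B = B; ctx->Tq = Tq; ctx->Tk = Tk; ctx->n = n;
  ctx->P.resize(B);
  std::vector<double> S((size_t)Tq * Tk);
  bool has_mask = key_mask_.isNotNull();
  LogicalVector km;
  if (has_mask) km = key_mask_.get();
  for (int b = 0; b < B; ++b) {
    gather_item(Q, b, B, Tq, n, ctx->Qg);
    gather_item(K, b, B, Tk, n, ctx->Kg);
    gather_item(V, b, B, Tk, n, ctx->Vg);
    // S = Q K^T * sc  (Tq x Tk)
    dgemm_('N', 'T', Tq, Tk, n, sc, ctx->Qg.data(), Tq, ctx->Kg.data(), Tk,
           0.0, S.data(), Tq);
    const double NEG = -std::numeric_limits<double>::infinity();
    if (has_mask) {
      for (int j = 0; j < Tk; ++j)
        if (!km[j * B + b])
          for (int i = 0; i < Tq; ++i) S[i + (size_t)Tq * j] = NEG;
    }
    if (causal) {
      for (int j = 0; j < Tk; ++j)
        for (int i = 0; i < std::min(j, Tq); ++i) S[i + (size_t)Tq * j] = NEG;
    }
    std::vector<double>& P = ctx->P[b];
    P.assign((size_t)Tq * Tk, 0.0);
    for (int i = 0; i < Tq; ++i) {
      double mx = NEG;
      for (int j = 0; j < Tk; ++j) mx = std::max(mx, S[i + (size_t)Tq * j]);
      double Z = 0.0;
      for (int j = 0; j < Tk; ++j) {
        double e = std::exp(S[i + (size_t)Tq * j] - mx);
        P[i + (size_t)Tq * j] = e;
        Z += e;
      }
      double inv = 1.0 / Z;
      for (int j = 0; j < Tk; ++j) P[i + (size_t)Tq * j] *= inv;
    }
    // Ob = P V (Tq x n), scattered back into batch layout
    std::vector<double> Ob((size_t)Tq * n);
    dgemm_('N', 'N', Tq, n, Tk, 1.0, P.data(), Tq, ctx->Vg.data(), Tk, 0.0,
           Ob.data(), Tq);
    double* o = &out(0, 0);
    int R = B * Tq;
    for (int c = 0; c < n; ++c)
      for (int t = 0; t < Tq; ++t)
        o[t * B + b + (size_t)R * c] = Ob[t + (size_t)Tq * c];
  }
  return List::create(_["out"] = out, _["ctx"] = ctx);
}

// [[Rcpp::export]]
List cpp_attn_backward(NumericMatrix g, NumericMatrix Q, NumericMatrix K,
                       NumericMatrix V, SEXP ctx_) {
  XPtr<AttnCtx> ctx(ctx_);
  int B = ctx->B, Tq = ctx->Tq, Tk = ctx->Tk, n = ctx->n;
  double sc = 1.0 / std::sqrt((double)n);
  NumericMatrix gQ(B * Tq, n), gK(B * Tk, n), gV(B * Tk, n);
  std::vector<double> gO, gP((size_t)Tq * Tk), gS((size_t)Tq * Tk);
  std::vector<double> gQb((size_t)Tq * n), gKb((size_t)Tk * n),
      gVb((size_t)Tk * n);
  for (int b = 0; b < B; ++b) {
    gather_item(g, b, B, Tq, n, gO);
    gather_item(Q, b, B, Tq, n, ctx->Qg);
    gather_item(K, b, B, Tk, n, ctx->Kg);
    gather_item(V, b, B, Tk, n, ctx->Vg);
    const std::vector<double>& P = ctx->P[b];
    // gP = gO V^T ; gV = P^T gO
    dgemm_('N', 'T', Tq, Tk, n, 1.0, gO.data(), Tq, ctx->Vg.data(), Tk, 0.0,
           gP.data(), Tq);
    dgemm_('T', 'N', Tk, n, Tq, 1.0, P.data(), Tq, gO.data(), Tq, 0.0,
           gVb.data(), Tk);
    // gS = (gP - rowSums(gP * P)) * P * sc
    for (int i = 0; i < Tq; ++i) {
      double dot = 0.0;
      for (int j = 0; j < Tk; ++j)
        dot += gP[i + (size_t)Tq * j] * P[i + (size_t)Tq * j];
      for (int j = 0; j < Tk; ++j)
        gS[i + (size_t)Tq * j] =
            (gP[i + (size_t)Tq * j] - dot) * P[i + (size_t)Tq * j] * sc;
    }
    dgemm_('N', 'N', Tq, n, Tk, 1.0, gS.data(), Tq, ctx->Kg.data(), Tk, 0.0,
           gQb.data(), Tq);
    dgemm_('T', 'N', Tk, n, Tq, 1.0, gS.data(), Tq, ctx->Qg.data(), Tq, 0.0,
           gKb.data(), Tk);
    int Rq = B * Tq, Rk = B * Tk;
    double* pq = &gQ(0, 0);
    double* pk = &gK(0, 0);
    double* pv = &gV(0, 0);
    for (int c = 0; c < n; ++c) {
      for (int t = 0; t < Tq; ++t)
        pq[t * B + b + (size_t)Rq * c] = gQb[t + (size_t)Tq * c];
      for (int t = 0; t < Tk; ++t) {
        pk[t * B + b + (size_t)Rk * c] = gKb[t + (size_t)Tk * c];
        pv[t * B + b + (size_t)Rk * c] = gVb[t + (size_t)Tk * c];
      }
    }
  }
  return List::create(_["gQ"] = gQ, _["gK"] = gK, _["gV"] = gV);
}

// ---- fused LSTM sequence (forward + BPTT) --------------------------------
// Gate order in the 4n dimension: f, d, i, o. Layout as above (time-major
// row blocks). Stores activated gates and cell traces for the backward pass.

struct LstmCtx {
  int B, T, n;
  std::vector<double> G;      // (B*T) x 4n activated gates
  std::vector<double> Cprev;  // (B*T) x n cell state entering each step
  std::vector<double> tC;     // (B*T) x n tanh(c_t)
  std::vector<double> h0;     // B x n initial hidden state
};

// [[Rcpp::export]]
List cpp_lstm_forward(NumericMatrix X, NumericMatrix W, NumericMatrix U,
                      NumericVector b, Nullable<NumericMatrix> h0_, int B,
                      int T) {
  int n = W.nrow(), n4 = 4 * n, R = B * T;
  NumericMatrix H(R, n);
  XPtr<LstmCtx> ctx(new LstmCtx(), true);
  ctx->B = B; ctx->T = T; ctx->n = n;
  ctx->G.resize((size_t)R * n4);
  ctx->Cprev.assign((size_t)R * n, 0.0);
  ctx->tC.resize((size_t)R * n);
  ctx->h0.assign((size_t)B * n, 0.0);
  if (h0_.isNotNull()) {
    NumericMatrix h0(h0_.get());
    std::copy(h0.begin(), h0.end(), ctx->h0.begin());
  }
  std::vector<double> Hc(ctx->h0), Cc((size_t)B * n, 0.0),
      Gp((size_t)B * n4);
  const double* x = &X(0, 0);
  double* h = &H(0, 0);
  for (int t = 0; t < T; ++t) {
    int off = t * B;
    // Gp = X_t W + H U + b
    for (int c = 0; c < n4; ++c)
      for (int i = 0; i < B; ++i) Gp[i + (size_t)B * c] = b[c];
    // X_t is rows off..off+B-1 of X (lda R)
    dgemm_('N', 'N', B, n4, n, 1.0, x + off, R, &W(0, 0), n, 1.0, Gp.data(),
           B);
    dgemm_('N', 'N', B, n4, n, 1.0, Hc.data(), B, &U(0, 0), n, 1.0,
           Gp.data(), B);
    for (int c = 0; c < n; ++c) {
      for (int i = 0; i < B; ++i) {
        size_t k = i + (size_t)B * c;
        double f = 1.0 / (1.0 + std::exp(-Gp[i + (size_t)B * c]));
        double d = std::tanh(Gp[i + (size_t)B * (n + c)]);
        double gi = 1.0 / (1.0 + std::exp(-Gp[i + (size_t)B * (2 * n + c)]));
        double o = 1.0 / (1.0 + std::exp(-Gp[i + (size_t)B * (3 * n + c)]));
        size_t rg = (size_t)(off + i);
        ctx->G[rg + (size_t)R * c] = f;
        ctx->G[rg + (size_t)R * (n + c)] = d;
        ctx->G[rg + (size_t)R * (2 * n + c)] = gi;
        ctx->G[rg + (size_t)R * (3 * n + c)] = o;
        ctx->Cprev[rg + (size_t)R * c] = Cc[k];
        double cn = Cc[k] * f + d * gi;
        Cc[k] = cn;
        double tc = std::tanh(cn);
        ctx->tC[rg + (size_t)R * c] = tc;
        double hn = o * tc;
        Hc[k] = hn;
        h[off + i + (size_t)R * c] = hn;
      }
    }
  }
  return List::create(_["H"] = H, _["ctx"] = ctx);
}

// [[Rcpp::export]]
List cpp_lstm_backward(NumericMatrix gH, NumericMatrix X, NumericMatrix W,
                       NumericMatrix U, NumericMatrix H, SEXP ctx_) {
  XPtr<LstmCtx> ctx(ctx_);
  int B = ctx->B, T = ctx->T, n = ctx->n, n4 = 4 * n, R = B * T;
  NumericMatrix gX(R, n), gW(n, n4), gU(n, n4), gh0(B, n);
  NumericVector gb(n4);
  std::vector<double> carry((size_t)B * n, 0.0), gC((size_t)B * n, 0.0),
      gGp((size_t)B * n4);
  const double* g = &gH(0, 0);
  const double* h = &H(0, 0);
  const double* x = &X(0, 0);
  for (int t = T - 1; t >= 0; --t) {
    int off = t * B;
    for (int c = 0; c < n; ++c) {
      for (int i = 0; i < B; ++i) {
        size_t rg = (size_t)(off + i);
        size_t k = i + (size_t)B * c;
        double f = ctx->G[rg + (size_t)R * c];
        double d = ctx->G[rg + (size_t)R * (n + c)];
        double gi = ctx->G[rg + (size_t)R * (2 * n + c)];
        double o = ctx->G[rg + (size_t)R * (3 * n + c)];
        double tc = ctx->tC[rg + (size_t)R * c];
        double gh = g[off + i + (size_t)R * c] + carry[k];
        double go = gh * tc;
        double gc = gC[k] + gh * o * (1.0 - tc * tc);
        double gf = gc * ctx->Cprev[rg + (size_t)R * c];
        double gd = gc * gi;
        double ggi = gc * d;
        gGp[i + (size_t)B * c] = gf * f * (1.0 - f);
        gGp[i + (size_t)B * (n + c)] = gd * (1.0 - d * d);
        gGp[i + (size_t)B * (2 * n + c)] = ggi * gi * (1.0 - gi);
        gGp[i + (size_t)B * (3 * n + c)] = go * o * (1.0 - o);
        gC[k] = gc * f;
      }
    }
    // gW += X_t^T gGp ; gU += Hprev^T gGp ; gb += colSums(gGp)
    dgemm_('T', 'N', n, n4, B, 1.0, x + off, R, gGp.data(), B, 1.0,
           &gW(0, 0), n);
    const double* hprev;
    std::vector<double> hp0;
    if (t == 0) {
      hprev = ctx->h0.data();
      dgemm_('T', 'N', n, n4, B, 1.0, hprev, B, gGp.data(), B, 1.0,
             &gU(0, 0), n);
    } else {
      // rows (t-1)*B .. of H, lda R
      dgemm_('T', 'N', n, n4, B, 1.0, h + (t - 1) * B, R, gGp.data(), B,
             1.0, &gU(0, 0), n);
    }
    for (int c = 0; c < n4; ++c) {
      double s = 0.0;
      for (int i = 0; i < B; ++i) s += gGp[i + (size_t)B * c];
      gb[c] += s;
    }
    // gX_t = gGp W^T (write into rows off..) ; carry = gGp U^T
    dgemm_('N', 'T', B, n, n4, 1.0, gGp.data(), B, &W(0, 0), n, 0.0,
           &gX(off, 0), R);
    dgemm_('N', 'T', B, n, n4, 1.0, gGp.data(), B, &U(0, 0), n, 0.0,
           carry.data(), B);
  }
  std::copy(carry.begin(), carry.end(), gh0.begin());
  return List::create(_["gX"] = gX, _["gW"] = gW, _["gU"] = gU,
                      _["gb"] = gb, _["gh0"] = gh0);
}

// ---- in-place Adam update -------------------------------------------------
// value, m, v are modified in place (the caller owns every alias).

// [[Rcpp::export]]
void cpp_adam_update(NumericVector value, NumericVector grad,
                     NumericVector m, NumericVector v, double lr,
                     double beta1, double beta2, double eps, double bc1,
                     double bc2, double gscale) {
  R_xlen_t N = value.size();
  for (R_xlen_t i = 0; i < N; ++i) {
    double g = grad[i] * gscale;
    double mi = beta1 * m[i] + (1.0 - beta1) * g;
    double vi = beta2 * v[i] + (1.0 - beta2) * g * g;
    m[i] = mi;
    v[i] = vi;
    value[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
}

// in-place helpers for freshly allocated intermediates (caller owns them)
// [[Rcpp::export]]
void cpp_add_bias_rows(NumericMatrix M, NumericVector b) {
  int R = M.nrow(), C = M.ncol();
  double* m = &M(0, 0);
  for (int c = 0; c < C; ++c) {
    double bc = b[c];
    for (int i = 0; i < R; ++i) m[i + (size_t)R * c] += bc;
  }
}

// [[Rcpp::export]]
void cpp_add_inplace(NumericMatrix A, NumericMatrix B) {
  R_xlen_t N = (R_xlen_t)A.nrow() * A.ncol();
  double* a = &A(0, 0);
  const double* b = &B(0, 0);
  for (R_xlen_t i = 0; i < N; ++i) a[i] += b[i];
}
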