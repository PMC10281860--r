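// Batched LSTM time-step loop (forward and backpropagation through
// time) with sequence-length masking.  Designed for zero-copy exchange
// with R: sequences and caches are flat R numeric vectors in
// [N, T, feature] column-major layout (row (i, t) of the corresponding
// (N*T) x feature matrix), so R-side reshapes are free and nothing
// large is copied across the interface.  The input projection X_t W + b
// is hoisted out of the loop (one large GEMM done R-side); the compiled
// loop performs the recurrent GEMM and one fused elementwise pass per
// step.  Rows shorter than T are padded; the mask holds hidden and cell
// state constant past each row's length, so the final state equals the
// state at the last valid position.  Gate order is i, f, g, o.

#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;

static inline double fsigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}
static inline double ftanh(double x) { return std::tanh(x); }

// Inner elementwise pass of one forward step, specialised at compile
// time on caching and masking so the hot loop carries no branches.
template <bool WC, bool MASK>
static inline void fwd_step(const double* zx, const double* z,
                            double* hp, double* cp, double* Hp,
                            double* CI, double* CF, double* CG,
                            double* CO, double* CT, double* CC,
                            const sword* lens, uword N, uword H,
                            uword NT, uword t) {
  for (uword hh = 0; hh < H; ++hh) {
    const double* zxi = zx + (hh)*NT + t * N;
    const double* zxf = zx + (H + hh) * NT + t * N;
    const double* zxg = zx + (2 * H + hh) * NT + t * N;
    const double* zxo = zx + (3 * H + hh) * NT + t * N;
    const double* zri = z + (hh)*N;
    const double* zrf = z + (H + hh) * N;
    const double* zrg = z + (2 * H + hh) * N;
    const double* zro = z + (3 * H + hh) * N;
    double* hcol = hp + hh * N;
    double* ccol = cp + hh * N;
    const uword cidx = hh * NT + t * N;
    for (uword i = 0; i < N; ++i) {
      const double igv = fsigmoid(zxi[i] + zri[i]);
      const double fgv = fsigmoid(zxf[i] + zrf[i]);
      const double ggv = ftanh(zxg[i] + zrg[i]);
      const double ogv = fsigmoid(zxo[i] + zro[i]);
      const double ch = fgv * ccol[i] + igv * ggv;
      const double tcv = ftanh(ch);
      if (WC) {
        CI[cidx + i] = igv; CF[cidx + i] = fgv; CG[cidx + i] = ggv;
        CO[cidx + i] = ogv; CT[cidx + i] = tcv;
      }
      if (!MASK || (uword)lens[i] > t) {
        hcol[i] = ogv * tcv;
        ccol[i] = ch;
      }
      Hp[cidx + i] = hcol[i];
      if (WC) CC[cidx + i] = ccol[i];
    }
  }
}

// cache layout: 6 consecutive blocks of N*T*H doubles (I, F, G, O, TC, C)
// [[Rcpp::export]]
List lstm_forward_cpp(const NumericMatrix& ZX, const arma::mat& U,
                      const arma::vec& b, const arma::ivec& lens,
                      int n_rows, bool want_cache) {
  const uword N = (uword)n_rows;
  const uword H4 = ZX.ncol();
  const uword H = H4 / 4;
  const uword T = ZX.nrow() / N;
  const uword NT = N * T;
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  NumericVector Hout(NT * H);
  NumericVector cache(want_cache ? 6 * NT * H : 0);
  const double* zx = ZX.begin();
  double* Hp = Hout.begin();
  double* CI = want_cache ? cache.begin() : nullptr;
  double* CF = CI ? CI + NT * H : nullptr;
  double* CG = CF ? CF + NT * H : nullptr;
  double* CO = CG ? CG + NT * H : nullptr;
  double* CT = CO ? CO + NT * H : nullptr;
  double* CC = CT ? CT + NT * H : nullptr;
  bool mask_needed = false;
  for (uword i = 0; i < N; ++i)
    if ((uword)lens[i] < T) { mask_needed = true; break; }
  mat zr(N, H4);
  double* hp = h.memptr();
  double* cp = c.memptr();
  const sword* lp = lens.memptr();
  const rowvec bt = b.t();
  for (uword t = 0; t < T; ++t) {
    zr = h * U;                       // recurrent pre-activation + bias
    zr.each_row() += bt;
    const double* z = zr.memptr();
    if (want_cache) {
      if (mask_needed)
        fwd_step<true, true>(zx, z, hp, cp, Hp, CI, CF, CG, CO, CT, CC,
                             lp, N, H, NT, t);
      else
        fwd_step<true, false>(zx, z, hp, cp, Hp, CI, CF, CG, CO, CT, CC,
                              lp, N, H, NT, t);
    } else {
      if (mask_needed)
        fwd_step<false, true>(zx, z, hp, cp, Hp, CI, CF, CG, CO, CT, CC,
                              lp, N, H, NT, t);
      else
        fwd_step<false, false>(zx, z, hp, cp, Hp, CI, CF, CG, CO, CT, CC,
                               lp, N, H, NT, t);
    }
  }
  return List::create(Named("H") = Hout, Named("h_final") = h,
                      Named("cache") = cache,
                      Named("mask_needed") = mask_needed);
}

// Returns the pre-activation gradients dZ as a flat [N, T, 4H] vector
// plus the recurrent-weight gradient dU; input-side gradients (dW, db,
// dA) are recovered R-side from dZ with large GEMMs.
// [[Rcpp::export]]
List lstm_backward_cpp(const NumericVector& Hout,
                       const NumericVector& cache, bool mask_needed,
                       const arma::mat& U, const arma::ivec& lens,
                       int n_rows,
                       Rcpp::Nullable<NumericVector> dH_,
                       Rcpp::Nullable<NumericMatrix> dh_final_) {
  const uword N = (uword)n_rows;
  const uword H = U.n_rows;
  const uword NT = cache.size() / (6 * H);
  const uword T = NT / N;
  const double* CI = cache.begin();
  const double* CF = CI + NT * H;
  const double* CG = CF + NT * H;
  const double* CO = CG + NT * H;
  const double* CT = CO + NT * H;
  const double* CC = CT + NT * H;
  const double* Hp = Hout.begin();
  const bool has_dH = dH_.isNotNull();
  const double* dHp = nullptr;
  NumericVector dHv;
  if (has_dH) { dHv = NumericVector(dH_); dHp = dHv.begin(); }
  mat dh_carry(N, H, fill::zeros), dc_carry(N, H, fill::zeros);
  if (dh_final_.isNotNull()) {
    NumericMatrix dhf(dh_final_);
    std::copy(dhf.begin(), dhf.end(), dh_carry.memptr());
  }
  mat dU(H, 4 * H, fill::zeros);
  NumericVector dZ(NT * 4 * H);
  double* dZp = dZ.begin();
  const mat Ut = U.t();
  mat dz(N, 4 * H), dh_pass(N, H);
  double* dcc = dc_carry.memptr();
  double* dps = dh_pass.memptr();
  double* dzp = dz.memptr();
  double* dUp = dU.memptr();
  for (uword tt = T; tt-- > 0;) {
    const uword o = tt * N;
    const double* dhc = dh_carry.memptr();
    for (uword hh = 0; hh < H; ++hh) {
      const uword cidx = hh * NT + o;
      const uword hN = hh * N;
      for (uword i = 0; i < N; ++i) {
        double dht = dhc[hN + i];
        if (has_dH) dht += dHp[cidx + i];
        const bool valid = !mask_needed || (uword)lens[i] > tt;
        const double dhh = valid ? dht : 0.0;
        dps[hN + i] = valid ? 0.0 : dht;
        const double dci = valid ? dcc[hN + i] : 0.0;
        const double dcp = valid ? 0.0 : dcc[hN + i];
        const double tc = CT[cidx + i];
        const double og = CO[cidx + i];
        const double ig = CI[cidx + i];
        const double fg = CF[cidx + i];
        const double gg = CG[cidx + i];
        const double dch = dci + dhh * og * (1.0 - tc * tc);
        const double cpv = (tt > 0) ? CC[cidx + i - N] : 0.0;
        dzp[(hh)*N + i] = (dch * gg) * ig * (1.0 - ig);
        dzp[(H + hh) * N + i] = (dch * cpv) * fg * (1.0 - fg);
        dzp[(2 * H + hh) * N + i] = (dch * ig) * (1.0 - gg * gg);
        dzp[(3 * H + hh) * N + i] = (dhh * tc) * og * (1.0 - og);
        dcc[hN + i] = dch * fg + dcp;
      }
    }
    // dU += h_{t-1}^T dz  (h_{t-1} read from the flat Hout layout)
    if (tt > 0) {
      for (uword g = 0; g < 4 * H; ++g) {
        const double* dzg = dzp + g * N;
        for (uword hh = 0; hh < H; ++hh) {
          const double* hprev = Hp + hh * NT + (tt - 1) * N;
          double acc = 0.0;
          for (uword i = 0; i < N; ++i) acc += hprev[i] * dzg[i];
          dUp[g * H + hh] += acc;
        }
      }
    }
    // store dz into the flat [N, T, 4H] output
    for (uword g = 0; g < 4 * H; ++g)
      std::copy(dzp + g * N, dzp + (g + 1) * N,
                dZp + g * NT + o);
    dh_carry = dz * Ut + dh_pass;
  }
  return List::create(Named("dZ") = dZ, Named("dU") = dU);
}
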