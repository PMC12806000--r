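// LSTM / bidirectional-LSTM kernels.  Sequence tensors are time-major:
// row t*B + b holds sample b at position t (0-based).  The R level owns
// parameter storage, gate layout (i, f, g, o) and the model wiring; these
// kernels run the recurrence and backward-through-time.
//
// The bidirectional "flatten" path keeps its caches on the C++ side
// (returned to R as an external pointer) so a forward/backward pair does
// not round-trip the per-position gate tensors through R memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid_mat(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache {
  mat X, Y, I, F, G, O, C, TC;
};

static void run_forward(const mat& X, const mat& Wx, const mat& Wh,
                        const vec& b, int B, int L, DirCache& cc) {
  const int H = Wh.n_rows;
  mat XW = X * Wx;
  XW.each_row() += b.t();
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  cc.X = X;
  cc.Y.set_size(L * B, H);
  cc.I.set_size(L * B, H);
  cc.F.set_size(L * B, H);
  cc.G.set_size(L * B, H);
  cc.O.set_size(L * B, H);
  cc.C.set_size(L * B, H);
  cc.TC.set_size(L * B, H);
  for (int t = 0; t < L; ++t) {
    const span rs(t * B, (t + 1) * B - 1);
    mat A = XW.rows(rs) + h * Wh;
    mat ig = sigmoid_mat(A.cols(0, H - 1));
    mat fg = sigmoid_mat(A.cols(H, 2 * H - 1));
    mat gg = tanh(A.cols(2 * H, 3 * H - 1));
    mat og = sigmoid_mat(A.cols(3 * H, 4 * H - 1));
    c = fg % c + ig % gg;
    mat tc = tanh(c);
    h = og % tc;
    cc.Y.rows(rs) = h;
    cc.I.rows(rs) = ig;
    cc.F.rows(rs) = fg;
    cc.G.rows(rs) = gg;
    cc.O.rows(rs) = og;
    cc.C.rows(rs) = c;
    cc.TC.rows(rs) = tc;
  }
}

static void run_backward(const DirCache& cc, const mat& Wx, const mat& Wh,
                         const mat& dY, int B, int L, mat& dX, mat& dWx,
                         mat& dWh, rowvec& db) {
  const int H = Wh.n_rows;
  const int E = cc.X.n_cols;
  dWx.zeros(E, 4 * H);
  dWh.zeros(H, 4 * H);
  db.zeros(4 * H);
  dX.set_size(L * B, E);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  const mat WxT = Wx.t();
  const mat WhT = Wh.t();
  for (int t = L - 1; t >= 0; --t) {
    const span rs(t * B, (t + 1) * B - 1);
    const mat ig = cc.I.rows(rs), fg = cc.F.rows(rs), gg = cc.G.rows(rs),
              og = cc.O.rows(rs), tc = cc.TC.rows(rs);
    mat dh = dY.rows(rs) + dh_next;
    mat do_ = dh % tc;
    mat dc = dc_next + dh % og % (1.0 - tc % tc);
    mat c_prev(B, H, fill::zeros), h_prev(B, H, fill::zeros);
    if (t > 0) {
      const span ps((t - 1) * B, t * B - 1);
      c_prev = cc.C.rows(ps);
      h_prev = cc.TC.rows(ps) % cc.O.rows(ps);
    }
    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = (dc % gg) % ig % (1.0 - ig);
    dA.cols(H, 2 * H - 1) = (dc % c_prev) % fg % (1.0 - fg);
    dA.cols(2 * H, 3 * H - 1) = (dc % ig) % (1.0 - gg % gg);
    dA.cols(3 * H, 4 * H - 1) = do_ % og % (1.0 - og);
    dc_next = dc % fg;
    dWx += cc.X.rows(rs).t() * dA;
    dWh += h_prev.t() * dA;
    db += sum(dA, 0);
    dX.rows(rs) = dA * WxT;
    dh_next = dA * WhT;
  }
}

static mat reverse_tm(const mat& X, int B, int L) {
  mat out(X.n_rows, X.n_cols);
  for (int t = 0; t < L; ++t) {
    out.rows(span(t * B, (t + 1) * B - 1)) =
        X.rows(span((L - 1 - t) * B, (L - t) * B - 1));
  }
  return out;
}

// ---- single-direction interface (last-hidden mode) ---------------------

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b,
                            int B, int L) {
  DirCache cc;
  run_forward(X, Wx, Wh, b, B, L, cc);
  return Rcpp::List::create(
      Rcpp::Named("Y") = cc.Y, Rcpp::Named("I") = cc.I,
      Rcpp::Named("F") = cc.F, Rcpp::Named("G") = cc.G,
      Rcpp::Named("O") = cc.O, Rcpp::Named("C") = cc.C,
      Rcpp::Named("TC") = cc.TC);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::mat& I,
                             const arma::mat& F, const arma::mat& G,
                             const arma::mat& O, const arma::mat& C,
                             const arma::mat& TC, const arma::mat& dY,
                             int B, int L) {
  DirCache cc;
  cc.X = X;
  cc.I = I;
  cc.F = F;
  cc.G = G;
  cc.O = O;
  cc.C = C;
  cc.TC = TC;
  mat dX, dWx, dWh;
  rowvec db;
  run_backward(cc, Wx, Wh, dY, B, L, dX, dWx, dWh, db);
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
      Rcpp::Named("dWh") = dWh,
      Rcpp::Named("db") = Rcpp::wrap(conv_to<std::vector<double>>::from(db)));
}

// ---- fused bidirectional flatten path ----------------------------------

struct BilstmCache {
  DirCache fwd, bwd;
  int B, L, H;
};

// Forward direction on X, backward direction on the position-reversed X;
// output is the flattened per-position concatenation, shape
// B x (2H * L) with columns ordered position-major: position t occupies
// columns [t*2H, (t+1)*2H) as [h_fwd_t, h_bwd_t].
// [[Rcpp::export]]
Rcpp::List bilstm_flat_forward_cpp(const arma::mat& X, const arma::mat& fWx,
                                   const arma::mat& fWh, const arma::vec& fb,
                                   const arma::mat& bWx, const arma::mat& bWh,
                                   const arma::vec& bb, int B, int L) {
  auto* cc = new BilstmCache();
  cc->B = B;
  cc->L = L;
  cc->H = fWh.n_rows;
  run_forward(X, fWx, fWh, fb, B, L, cc->fwd);
  run_forward(reverse_tm(X, B, L), bWx, bWh, bb, B, L, cc->bwd);
  const int H = cc->H;
  mat Yflat(B, 2 * H * L);
  for (int t = 0; t < L; ++t) {
    Yflat.cols(t * 2 * H, t * 2 * H + H - 1) =
        cc->fwd.Y.rows(span(t * B, (t + 1) * B - 1));
    Yflat.cols(t * 2 * H + H, (t + 1) * 2 * H - 1) =
        cc->bwd.Y.rows(span((L - 1 - t) * B, (L - t) * B - 1));
  }
  Rcpp::XPtr<BilstmCache> ptr(cc, true);
  return Rcpp::List::create(Rcpp::Named("Y") = Yflat, Rcpp::Named("ptr") = ptr);
}

// [[Rcpp::export]]
Rcpp::List bilstm_flat_backward_cpp(SEXP ptr_, const arma::mat& fWx,
                                    const arma::mat& fWh, const arma::mat& bWx,
                                    const arma::mat& bWh,
                                    const arma::mat& dYflat) {
  Rcpp::XPtr<BilstmCache> ptr(ptr_);
  const int B = ptr->B, L = ptr->L, H = ptr->H;
  mat dYf(L * B, H), dYb(L * B, H);
  for (int t = 0; t < L; ++t) {
    dYf.rows(span(t * B, (t + 1) * B - 1)) =
        dYflat.cols(t * 2 * H, t * 2 * H + H - 1);
    dYb.rows(span((L - 1 - t) * B, (L - t) * B - 1)) =
        dYflat.cols(t * 2 * H + H, (t + 1) * 2 * H - 1);
  }
  mat fdX, fdWx, fdWh, bdX, bdWx, bdWh;
  rowvec fdb, bdb;
  run_backward(ptr->fwd, fWx, fWh, dYf, B, L, fdX, fdWx, fdWh, fdb);
  run_backward(ptr->bwd, bWx, bWh, dYb, B, L, bdX, bdWx, bdWh, bdb);
  mat dX = fdX + reverse_tm(bdX, B, L);
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("fwd.dWx") = fdWx,
      Rcpp::Named("fwd.dWh") = fdWh,
      Rcpp::Named("fwd.db") = Rcpp::wrap(conv_to<std::vector<double>>::from(fdb)),
      Rcpp::Named("bwd.dWx") = bdWx, Rcpp::Named("bwd.dWh") = bdWh,
      Rcpp::Named("bwd.db") = Rcpp::wrap(conv_to<std::vector<double>>::from(bdb)));
}
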