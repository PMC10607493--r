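// Numeric core: recurrent cells with backprop-through-time, multi-head
// self-attention, the sliding-window beamforming correlation, and the
// normalized cross-correlation feature.
//
// Sequence activations are "flat" matrices of shape (B * T, feat) with row
// index b + t * B (0-based): the B parallel sequences are interleaved, so
// time step t occupies the contiguous row block [t*B, (t+1)*B). Input and
// output projections are then single large GEMMs; only the recurrences and
// attention scores touch per-step blocks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------- GRU ----
// r = s(x Wr + h Ur + br); z = s(x Wz + h Uz + bz)
// n = tanh(x Wn + r % (h Un) + bn); h' = (1-z) % n + z % h
// Wx: (I, 3H) blocks [r|z|n]; Uh: (H, 3H); b: vec 3H.

// [[Rcpp::export(rng = false)]]
Rcpp::List gru_fwd(const arma::mat& X, const int B, const arma::mat& Wx,
                   const arma::mat& Uh, const arma::vec& b) {
  const uword nv = X.n_rows, T = nv / B, H = Uh.n_rows;
  mat XW = X * Wx;
  XW.each_row() += b.t();
  mat Hm(nv, H), R(nv, H), Z(nv, H), N(nv, H), HUN(nv, H);
  mat h(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const uword r0 = t * B, r1 = r0 + B - 1;
    mat hU = h * Uh;                                    // B x 3H
    mat r = sigm(XW.submat(r0, 0, r1, H - 1) + hU.cols(0, H - 1));
    mat z = sigm(XW.submat(r0, H, r1, 2 * H - 1) + hU.cols(H, 2 * H - 1));
    mat hun = hU.cols(2 * H, 3 * H - 1);
    mat n = tanh(XW.submat(r0, 2 * H, r1, 3 * H - 1) + r % hun);
    h = (1.0 - z) % n + z % h;
    R.rows(r0, r1) = r; Z.rows(r0, r1) = z; N.rows(r0, r1) = n;
    HUN.rows(r0, r1) = hun; Hm.rows(r0, r1) = h;
  }
  return List::create(Named("h") = Hm, Named("r") = R, Named("z") = Z,
                      Named("n") = N, Named("hun") = HUN);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List gru_bwd(const arma::mat& X, const int B, const arma::mat& Wx,
                   const arma::mat& Uh, const Rcpp::List& cache,
                   const arma::mat& dH) {
  const mat Hm = cache["h"], R = cache["r"], Z = cache["z"], N = cache["n"],
            HUN = cache["hun"];
  const uword nv = X.n_rows, T = nv / B, H = Uh.n_rows;
  const mat Ur = Uh.cols(0, H - 1), Uz = Uh.cols(H, 2 * H - 1),
            Un = Uh.cols(2 * H, 3 * H - 1);
  mat dA(nv, 3 * H);                // pre-activation grads, all steps
  mat dUh(H, 3 * H, fill::zeros);
  mat dh(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const uword r0 = tt * B, r1 = r0 + B - 1;
    dh += dH.rows(r0, r1);
    const mat hprev = (tt == 0) ? mat(B, H, fill::zeros)
                                : Hm.rows(r0 - B, r0 - 1);
    const mat r = R.rows(r0, r1), z = Z.rows(r0, r1), n = N.rows(r0, r1),
              hun = HUN.rows(r0, r1);
    mat da_n = (dh % (1.0 - z)) % (1.0 - n % n);
    mat dhun = da_n % r;
    mat da_r = (da_n % hun) % r % (1.0 - r);
    mat da_z = (dh % (hprev - n)) % z % (1.0 - z);
    dA.submat(r0, 0, r1, H - 1) = da_r;
    dA.submat(r0, H, r1, 2 * H - 1) = da_z;
    dA.submat(r0, 2 * H, r1, 3 * H - 1) = da_n;
    dUh.cols(0, H - 1) += hprev.t() * da_r;
    dUh.cols(H, 2 * H - 1) += hprev.t() * da_z;
    dUh.cols(2 * H, 3 * H - 1) += hprev.t() * dhun;
    dh = dh % z + da_r * Ur.t() + da_z * Uz.t() + dhun * Un.t();
  }
  mat dX = dA * Wx.t();
  mat dWx = X.t() * dA;
  vec db = sum(dA, 0).t();
  return List::create(Named("dx") = dX, Named("dWx") = dWx,
                      Named("dUh") = dUh, Named("db") = db);
}

// --------------------------------------------------------------- LSTM ----
// gate order [i|f|g|o]; c' = f%c + i%g; h' = o % tanh(c')

// [[Rcpp::export(rng = false)]]
Rcpp::List lstm_fwd(const arma::mat& X, const int B, const arma::mat& Wx,
                    const arma::mat& Uh, const arma::vec& b) {
  const uword nv = X.n_rows, T = nv / B, H = Uh.n_rows;
  mat XW = X * Wx;
  XW.each_row() += b.t();
  mat Hm(nv, H), C(nv, H), Gi(nv, H), Gf(nv, H), Gg(nv, H), Go(nv, H);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const uword r0 = t * B, r1 = r0 + B - 1;
    mat a = XW.rows(r0, r1) + h * Uh;
    mat gi = sigm(a.cols(0, H - 1));
    mat gf = sigm(a.cols(H, 2 * H - 1));
    mat gg = tanh(a.cols(2 * H, 3 * H - 1));
    mat go = sigm(a.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    Gi.rows(r0, r1) = gi; Gf.rows(r0, r1) = gf; Gg.rows(r0, r1) = gg;
    Go.rows(r0, r1) = go; C.rows(r0, r1) = c; Hm.rows(r0, r1) = h;
  }
  return List::create(Named("h") = Hm, Named("c") = C, Named("i") = Gi,
                      Named("f") = Gf, Named("g") = Gg, Named("o") = Go);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List lstm_bwd(const arma::mat& X, const int B, const arma::mat& Wx,
                    const arma::mat& Uh, const Rcpp::List& cache,
                    const arma::mat& dH) {
  const mat Hm = cache["h"], C = cache["c"], Gi = cache["i"], Gf = cache["f"],
            Gg = cache["g"], Go = cache["o"];
  const uword nv = X.n_rows, T = nv / B, H = Uh.n_rows;
  mat dA(nv, 4 * H);
  mat dUh(H, 4 * H, fill::zeros);
  mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const uword r0 = tt * B, r1 = r0 + B - 1;
    dh += dH.rows(r0, r1);
    const mat gi = Gi.rows(r0, r1), gf = Gf.rows(r0, r1),
              gg = Gg.rows(r0, r1), go = Go.rows(r0, r1);
    const mat tc = tanh(C.rows(r0, r1));
    const mat cprev = (tt == 0) ? mat(B, H, fill::zeros)
                                : C.rows(r0 - B, r0 - 1);
    const mat hprev = (tt == 0) ? mat(B, H, fill::zeros)
                                : Hm.rows(r0 - B, r0 - 1);
    mat d_o = dh % tc;
    dc += dh % go % (1.0 - tc % tc);
    mat da(B, 4 * H);
    da.cols(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    da.cols(H, 2 * H - 1) = (dc % cprev) % gf % (1.0 - gf);
    da.cols(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    da.cols(3 * H, 4 * H - 1) = d_o % go % (1.0 - go);
    dA.rows(r0, r1) = da;
    dUh += hprev.t() * da;
    dh = da * Uh.t();
    dc = dc % gf;
  }
  mat dX = dA * Wx.t();
  mat dWx = X.t() * dA;
  vec db = sum(dA, 0).t();
  return List::create(Named("dx") = dX, Named("dWx") = dWx,
                      Named("dUh") = dUh, Named("db") = db);
}

// ---------------------------------------------------------- vanilla RNN ----
// h' = tanh(x W + h U + b)

// [[Rcpp::export(rng = false)]]
Rcpp::List rnn_fwd(const arma::mat& X, const int B, const arma::mat& Wx,
                   const arma::mat& Uh, const arma::vec& b) {
  const uword nv = X.n_rows, T = nv / B, H = Uh.n_rows;
  mat XW = X * Wx;
  XW.each_row() += b.t();
  mat Hm(nv, H);
  mat h(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const uword r0 = t * B, r1 = r0 + B - 1;
    h = tanh(XW.rows(r0, r1) + h * Uh);
    Hm.rows(r0, r1) = h;
  }
  return List::create(Named("h") = Hm);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List rnn_bwd(const arma::mat& X, const int B, const arma::mat& Wx,
                   const arma::mat& Uh, const Rcpp::List& cache,
                   const arma::mat& dH) {
  const mat Hm = cache["h"];
  const uword nv = X.n_rows, T = nv / B, H = Uh.n_rows;
  mat dA(nv, H);
  mat dUh(H, H, fill::zeros);
  mat dh(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const uword r0 = tt * B, r1 = r0 + B - 1;
    dh += dH.rows(r0, r1);
    const mat h = Hm.rows(r0, r1);
    const mat hprev = (tt == 0) ? mat(B, H, fill::zeros)
                                : Hm.rows(r0 - B, r0 - 1);
    mat da = dh % (1.0 - h % h);
    dA.rows(r0, r1) = da;
    dUh += hprev.t() * da;
    dh = da * Uh.t();
  }
  mat dX = dA * Wx.t();
  mat dWx = X.t() * dA;
  vec db = sum(dA, 0).t();
  return List::create(Named("dx") = dX, Named("dWx") = dWx,
                      Named("dUh") = dUh, Named("db") = db);
}

// ---------------------------------------------------- multi-head attention ----
// X: flat (B*T, D); Wq/Wk/Wv/Wo: (D, D); nh heads, dk = D / nh.
// Q/K/V and the output projection are single GEMMs; only the (B * nh)
// score matrices of size T x T are formed per sequence.

static mat softmax_rows(const mat& s) {
  mat m = s.each_col() - max(s, 1);
  mat e = exp(m);
  return e.each_col() / sum(e, 1);
}

// permute rows of a flat (B*T, D) matrix between batch-major
// (row = b + t*B) and sequence-major (row = t + b*T) layouts; column-wise
// passes keep the working set inside one column, so the reorder is a
// single sweep instead of B scattered gathers
static mat to_seq_major(const mat& X, const uword B) {
  const uword nv = X.n_rows, T = nv / B, D = X.n_cols;
  mat out(nv, D);
  for (uword d = 0; d < D; ++d) {
    const double* src = X.colptr(d);
    double* dst = out.colptr(d);
    for (uword i = 0; i < nv; ++i) {
      const uword b = i % B, t = i / B;
      dst[t + b * T] = src[i];
    }
  }
  return out;
}

static mat to_batch_major(const mat& X, const uword B) {
  const uword nv = X.n_rows, T = nv / B, D = X.n_cols;
  mat out(nv, D);
  for (uword d = 0; d < D; ++d) {
    const double* src = X.colptr(d);
    double* dst = out.colptr(d);
    for (uword i = 0; i < nv; ++i) {
      const uword b = i % B, t = i / B;
      dst[i] = src[t + b * T];
    }
  }
  return out;
}

// For short sequences the per-sequence score GEMMs are overhead-bound, so
// scores are instead vectorized across the batch: S[, t1*T + t2] holds
// <q_t1, k_t2> for every sequence at once (batch-major layout throughout).
static const uword MHA_SMALL_T = 20;

// per-head time blocks, materialized once: blocks[t] = M[t*B .. , c0:c1]
static std::vector<mat> head_blocks(const mat& M, const uword B,
                                    const uword T, const uword c0,
                                    const uword c1) {
  std::vector<mat> out(T);
  for (uword t = 0; t < T; ++t) {
    out[t] = M.submat(t * B, c0, (t + 1) * B - 1, c1);
  }
  return out;
}

static mat small_t_scores(const std::vector<mat>& Qb,
                          const std::vector<mat>& Kb, const uword B,
                          const uword T, const double sc) {
  mat S(B, T * T);
  for (uword t1 = 0; t1 < T; ++t1) {
    for (uword t2 = 0; t2 < T; ++t2) {
      S.col(t1 * T + t2) = sum(Qb[t1] % Kb[t2], 1) * sc;
    }
  }
  // softmax over t2 within each t1 block
  for (uword t1 = 0; t1 < T; ++t1) {
    mat blk = S.cols(t1 * T, (t1 + 1) * T - 1);
    blk.each_col() -= max(blk, 1);
    blk = exp(blk);
    blk.each_col() /= sum(blk, 1);
    S.cols(t1 * T, (t1 + 1) * T - 1) = blk;
  }
  return S;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List mha_fwd(const arma::mat& X, const int B, const arma::mat& Wq,
                   const arma::mat& Wk, const arma::mat& Wv,
                   const arma::mat& Wo, const int nh) {
  const uword nv = X.n_rows, D = X.n_cols, T = nv / B;
  const uword dk = D / nh;
  const double sc = 1.0 / std::sqrt((double)dk);
  mat Hcat(nv, D);
  mat Q, K, V;
  if (T <= MHA_SMALL_T) {
    Q = X * Wq; K = X * Wk; V = X * Wv;       // batch-major
    for (int h = 0; h < nh; ++h) {
      const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      const std::vector<mat> Qb = head_blocks(Q, B, T, c0, c1);
      const std::vector<mat> Kb = head_blocks(K, B, T, c0, c1);
      const std::vector<mat> Vb = head_blocks(V, B, T, c0, c1);
      const mat A = small_t_scores(Qb, Kb, B, T, sc);
      for (uword t1 = 0; t1 < T; ++t1) {
        mat O(B, dk, fill::zeros);
        for (uword t2 = 0; t2 < T; ++t2) {
          O += Vb[t2].each_col() % A.col(t1 * T + t2);
        }
        Hcat.submat(t1 * B, c0, (t1 + 1) * B - 1, c1) = O;
      }
    }
  } else {
    // sequence-major layout: each sequence is a contiguous row block, so
    // every per-head operand is a BLAS-strided view
    Q = to_seq_major(X * Wq, B);
    K = to_seq_major(X * Wk, B);
    V = to_seq_major(X * Wv, B);
    mat Hs(nv, D);
    for (uword b = 0; b < (uword)B; ++b) {
      const uword r0 = b * T, r1 = r0 + T - 1;
      for (int h = 0; h < nh; ++h) {
        const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
        mat Ah = softmax_rows(Q.submat(r0, c0, r1, c1) *
                              K.submat(r0, c0, r1, c1).t() * sc);
        Hs.submat(r0, c0, r1, c1) = Ah * V.submat(r0, c0, r1, c1);
      }
    }
    Hcat = to_batch_major(Hs, B);
  }
  mat out = Hcat * Wo;
  // attention weights are cheap to recompute from Q and K; the backward
  // pass rebuilds them rather than caching B * nh score matrices
  return List::create(Named("out") = out, Named("q") = Q, Named("k") = K,
                      Named("v") = V, Named("hcat") = Hcat);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List mha_bwd(const arma::mat& X, const int B, const arma::mat& Wq,
                   const arma::mat& Wk, const arma::mat& Wv,
                   const arma::mat& Wo, const int nh, const Rcpp::List& cache,
                   const arma::mat& dOut) {
  const mat Q = cache["q"], K = cache["k"], V = cache["v"],
            Hcat = cache["hcat"];
  const uword nv = X.n_rows, D = X.n_cols, T = nv / B;
  const uword dk = D / nh;
  const double sc = 1.0 / std::sqrt((double)dk);
  mat dWo = Hcat.t() * dOut;
  mat dQ(nv, D), dK(nv, D), dV(nv, D);
  if (T <= MHA_SMALL_T) {
    const mat dHb = dOut * Wo.t();              // batch-major like Q/K/V
    for (int h = 0; h < nh; ++h) {
      const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      const std::vector<mat> Qb = head_blocks(Q, B, T, c0, c1);
      const std::vector<mat> Kb = head_blocks(K, B, T, c0, c1);
      const std::vector<mat> Vb = head_blocks(V, B, T, c0, c1);
      const std::vector<mat> dOb = head_blocks(dHb, B, T, c0, c1);
      const mat A = small_t_scores(Qb, Kb, B, T, sc);
      // dA, then the softmax Jacobian applied per t1 block
      mat dA(B, T * T);
      std::vector<mat> dVa(T, mat(B, dk, fill::zeros));
      for (uword t1 = 0; t1 < T; ++t1) {
        for (uword t2 = 0; t2 < T; ++t2) {
          dA.col(t1 * T + t2) = sum(dOb[t1] % Vb[t2], 1);
          dVa[t2] += dOb[t1].each_col() % A.col(t1 * T + t2);
        }
      }
      mat dS(B, T * T);
      for (uword t1 = 0; t1 < T; ++t1) {
        const mat Ab = A.cols(t1 * T, (t1 + 1) * T - 1);
        const mat dAb = dA.cols(t1 * T, (t1 + 1) * T - 1);
        dS.cols(t1 * T, (t1 + 1) * T - 1) =
          Ab % (dAb.each_col() - sum(dAb % Ab, 1));
      }
      std::vector<mat> dQa(T, mat(B, dk, fill::zeros));
      std::vector<mat> dKa(T, mat(B, dk, fill::zeros));
      for (uword t1 = 0; t1 < T; ++t1) {
        for (uword t2 = 0; t2 < T; ++t2) {
          const vec s = dS.col(t1 * T + t2) * sc;
          dQa[t1] += Kb[t2].each_col() % s;
          dKa[t2] += Qb[t1].each_col() % s;
        }
      }
      for (uword t = 0; t < T; ++t) {
        dQ.submat(t * B, c0, (t + 1) * B - 1, c1) = dQa[t];
        dK.submat(t * B, c0, (t + 1) * B - 1, c1) = dKa[t];
        dV.submat(t * B, c0, (t + 1) * B - 1, c1) = dVa[t];
      }
    }
  } else {
    const mat dHs = to_seq_major(dOut * Wo.t(), B);
    for (uword b = 0; b < (uword)B; ++b) {
      const uword r0 = b * T, r1 = r0 + T - 1;
      for (int h = 0; h < nh; ++h) {
        const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
        const mat Qh = Q.submat(r0, c0, r1, c1);
        const mat Kh = K.submat(r0, c0, r1, c1);
        const mat Ah = softmax_rows(Qh * Kh.t() * sc);
        const mat dOh = dHs.submat(r0, c0, r1, c1);
        mat dAh = dOh * V.submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = Ah.t() * dOh;
        mat dS = Ah % (dAh.each_col() - sum(dAh % Ah, 1));
        dQ.submat(r0, c0, r1, c1) = dS * Kh * sc;
        dK.submat(r0, c0, r1, c1) = dS.t() * Qh * sc;
      }
    }
    dQ = to_batch_major(dQ, B);
    dK = to_batch_major(dK, B);
    dV = to_batch_major(dV, B);
  }
  mat dX = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  mat dWq = X.t() * dQ, dWk = X.t() * dK, dWv = X.t() * dV;
  return List::create(Named("dx") = dX, Named("dWq") = dWq,
                      Named("dWk") = dWk, Named("dWv") = dWv,
                      Named("dWo") = dWo);
}

// ----------------------------------------------- beamforming correlation ----
// Y(t, j) = sum_g F(t, g) * CTX(t, g + j); F: (Tf, G), CTX: (Tf, G + L - 1).

// [[Rcpp::export(rng = false)]]
arma::mat frame_corr_fwd(const arma::mat& F, const arma::mat& CTX,
                         const int L) {
  const uword G = F.n_cols;
  mat Y(F.n_rows, L);
  for (int j = 0; j < L; ++j)
    Y.col(j) = sum(F % CTX.cols(j, j + G - 1), 1);
  return Y;
}

// [[Rcpp::export(rng = false)]]
arma::mat frame_corr_bwd(const arma::mat& dY, const arma::mat& CTX,
                         const int G) {
  const uword L = dY.n_cols;
  mat dF(dY.n_rows, G);
  for (int g = 0; g < G; ++g)
    dF.col(g) = sum(dY % CTX.cols(g, g + L - 1), 1);
  return dF;
}

// ---------------------------------------------------------- NCC feature ----
// Row-wise cosine similarity between every length-L slice of CTX and FR.
// Zero-norm slices (either side) contribute 0, the "no correlation" value.

// [[Rcpp::export(rng = false)]]
arma::mat ncc_all_lags(const arma::mat& CTX, const arma::mat& FR) {
  const uword L = FR.n_cols, nlag = CTX.n_cols - L + 1;
  mat out(FR.n_rows, nlag);
  const vec fn = sqrt(sum(FR % FR, 1));
  for (uword g = 0; g < nlag; ++g) {
    const mat seg = CTX.cols(g, g + L - 1);
    vec num = sum(seg % FR, 1);
    vec den = sqrt(sum(seg % seg, 1)) % fn;
    vec v(FR.n_rows, fill::zeros);
    uvec ok = find(den > 0);
    v(ok) = num(ok) / den(ok);
    out.col(g) = v;
  }
  return out;
}
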