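// Compiled kernels for the hot paths of the network: row gather/scatter
// (im2col convolution, patchify, upsampling) and the fused multi-head
// attention with low-rank positional and Gaussian-locality score biases.
// Backward passes mirror the hand-derived gradients; the R test suite
// checks them against central finite differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// out[i, (k-1)*C + .] = x[idx[i,k], .], idx == 0 contributing a zero row.
// [[Rcpp::export]]
arma::mat cpp_gather(const arma::mat& x, const arma::imat& idx) {
  const int K = idx.n_cols, N = idx.n_rows, C = x.n_cols;
  arma::mat out(N, K * C);
  for (int k = 0; k < K; ++k) {
    const int* id = idx.colptr(k);
    for (int c = 0; c < C; ++c) {
      double* o = out.colptr(k * C + c);
      const double* xc = x.colptr(c);
      for (int i = 0; i < N; ++i) o[i] = id[i] > 0 ? xc[id[i] - 1] : 0.0;
    }
  }
  return out;
}

// Adjoint of cpp_gather: scatter-add chunks of g back to their source rows.
// [[Rcpp::export]]
arma::mat cpp_scatter(const arma::mat& g, const arma::imat& idx, int n_rows) {
  const int K = idx.n_cols, N = idx.n_rows, C = g.n_cols / K;
  arma::mat out(n_rows, C, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int* id = idx.colptr(k);
    for (int c = 0; c < C; ++c) {
      const double* gc = g.colptr(k * C + c);
      double* o = out.colptr(c);
      for (int i = 0; i < N; ++i) if (id[i] > 0) o[id[i] - 1] += gc[i];
    }
  }
  return out;
}

// Inverse of cpp_gather for a partition index: write chunk k of x to rows
// idx[, k] of an (n_rows x C) matrix.
// [[Rcpp::export]]
arma::mat cpp_ungroup_fwd(const arma::mat& x, const arma::imat& idx, int n_rows, int C) {
  const int K = idx.n_cols, N = idx.n_rows;
  arma::mat out(n_rows, C, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int* id = idx.colptr(k);
    for (int c = 0; c < C; ++c) {
      const double* xc = x.colptr(k * C + c);
      double* o = out.colptr(c);
      for (int i = 0; i < N; ++i) if (id[i] > 0) o[id[i] - 1] = xc[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_ungroup_bwd(const arma::mat& g, const arma::imat& idx, int x_rows, int x_cols) {
  const int K = idx.n_cols, N = idx.n_rows;
  const int C = x_cols / K;
  arma::mat out(x_rows, x_cols, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int* id = idx.colptr(k);
    for (int c = 0; c < C; ++c) {
      double* o = out.colptr(k * C + c);
      const double* gc = g.colptr(c);
      for (int i = 0; i < N; ++i) if (id[i] > 0) o[i] = gc[id[i] - 1];
    }
  }
  return out;
}

static std::vector<arma::mat> pos_matrices(const arma::mat& U, const arma::mat& Vp, int heads) {
  std::vector<arma::mat> P;
  const int r = U.n_cols / heads;
  for (int h = 0; h < heads; ++h) {
    P.push_back(U.cols(h * r, (h + 1) * r - 1) * Vp.cols(h * r, (h + 1) * r - 1).t());
  }
  return P;
}

static std::vector<arma::mat> gauss_matrices(const arma::mat& sigx, const arma::mat& sigy,
                                             const arma::mat& dx2, const arma::mat& dy2,
                                             int heads, bool per_patch) {
  std::vector<arma::mat> G;
  const int Nq = dx2.n_rows;
  for (int h = 0; h < heads; ++h) {
    if (per_patch) {
      arma::mat Gh(dx2.n_rows, dx2.n_cols);
      for (int i = 0; i < Nq; ++i) {
        Gh.row(i) = -(dx2.row(i) / sigx(h, i) + dy2.row(i) / sigy(h, i));
      }
      G.push_back(Gh);
    } else {
      G.push_back(-(dx2 / sigx(h, 0) + dy2 / sigy(h, 0)));
    }
  }
  return G;
}

// [[Rcpp::export]]
List cpp_mha_fwd(const arma::mat& xq, const arma::mat& xkv,
                 const arma::mat& Wq, const arma::mat& Wk,
                 const arma::mat& Wv, const arma::mat& Wo,
                 int heads, int B, int Nq, int Nk,
                 const arma::mat& U, const arma::mat& Vp, bool use_pos,
                 const arma::mat& sigx, const arma::mat& sigy,
                 const arma::mat& dx2, const arma::mat& dy2,
                 bool use_gauss, bool per_patch, bool need_abs) {
  const int D = xq.n_cols, dh = D / heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  arma::mat Q = xq * Wq, K = xkv * Wk, V = xkv * Wv;
  arma::cube A(Nq, Nk, B * heads);
  arma::mat out(B * Nq, D);
  double abs_sum = 0.0;
  std::vector<arma::mat> P, G;
  if (use_pos) P = pos_matrices(U, Vp, heads);
  if (use_gauss) G = gauss_matrices(sigx, sigy, dx2, dy2, heads, per_patch);
  for (int b = 0; b < B; ++b) {
    arma::mat Ob(Nq, D);
    for (int h = 0; h < heads; ++h) {
      arma::mat S = Q.submat(b * Nq, h * dh, (b + 1) * Nq - 1, (h + 1) * dh - 1) *
                    K.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1).t() * scl;
      if (need_abs) abs_sum += arma::accu(arma::abs(S));
      if (use_pos) S += P[h];
      if (use_gauss) S += G[h];
      S.each_col() -= arma::max(S, 1);
      arma::mat E = arma::exp(S);
      E.each_col() /= arma::sum(E, 1);
      A.slice(b * heads + h) = E;
      Ob.cols(h * dh, (h + 1) * dh - 1) =
        E * V.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1);
    }
    out.rows(b * Nq, (b + 1) * Nq - 1) = Ob * Wo;
  }
  return List::create(_["out"] = out, _["A"] = A, _["Q"] = Q, _["K"] = K,
                      _["V"] = V, _["abs_sum"] = abs_sum);
}

// [[Rcpp::export]]
List cpp_mha_bwd(const arma::mat& g, const arma::cube& A,
                 const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                 const arma::mat& xq, const arma::mat& xkv,
                 const arma::mat& Wq, const arma::mat& Wk,
                 const arma::mat& Wv, const arma::mat& Wo,
                 int heads, int B, int Nq, int Nk,
                 const arma::mat& U, const arma::mat& Vp, bool use_pos,
                 const arma::mat& rhox, const arma::mat& rhoy,
                 const arma::mat& sigx, const arma::mat& sigy,
                 const arma::mat& dx2, const arma::mat& dy2,
                 bool use_gauss, bool per_patch, double lambda_attn) {
  const int D = xq.n_cols, dh = D / heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  const double n_scores = (double)B * heads * Nq * Nk;
  arma::mat dQ(Q.n_rows, D, arma::fill::zeros), dK(K.n_rows, D, arma::fill::zeros),
            dV(V.n_rows, D, arma::fill::zeros), dWo(D, D, arma::fill::zeros);
  arma::mat dU, dVp, drx, dry;
  int r = 0;
  if (use_pos) {
    r = U.n_cols / heads;
    dU.zeros(U.n_rows, U.n_cols);
    dVp.zeros(Vp.n_rows, Vp.n_cols);
  }
  if (use_gauss) {
    drx.zeros(rhox.n_rows, rhox.n_cols);
    dry.zeros(rhoy.n_rows, rhoy.n_cols);
  }
  for (int b = 0; b < B; ++b) {
    arma::mat Gb = g.rows(b * Nq, (b + 1) * Nq - 1);
    arma::mat dOb = Gb * Wo.t();
    for (int h = 0; h < heads; ++h) {
      const arma::mat& Ah = A.slice(b * heads + h);
      arma::mat Qh = Q.submat(b * Nq, h * dh, (b + 1) * Nq - 1, (h + 1) * dh - 1);
      arma::mat Kh = K.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1);
      arma::mat Vh = V.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1);
      dWo.rows(h * dh, (h + 1) * dh - 1) += (Ah * Vh).t() * Gb;
      arma::mat dOh = dOb.cols(h * dh, (h + 1) * dh - 1);
      arma::mat dA = dOh * Vh.t();
      dV.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1) += Ah.t() * dOh;
      arma::mat dS = Ah % (dA.each_col() - arma::sum(dA % Ah, 1));
      arma::mat dSc = dS;
      if (lambda_attn > 0) {
        arma::mat Sc = Qh * Kh.t() * scl;
        dSc += (lambda_attn / n_scores) * arma::sign(Sc);
      }
      dQ.submat(b * Nq, h * dh, (b + 1) * Nq - 1, (h + 1) * dh - 1) += dSc * Kh * scl;
      dK.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1) += dSc.t() * Qh * scl;
      if (use_pos) {
        dU.cols(h * r, (h + 1) * r - 1) += dS * Vp.cols(h * r, (h + 1) * r - 1);
        dVp.cols(h * r, (h + 1) * r - 1) += dS.t() * U.cols(h * r, (h + 1) * r - 1);
      }
      if (use_gauss) {
        if (per_patch) {
          for (int i = 0; i < Nq; ++i) {
            double sx = sigx(h, i), sy = sigy(h, i);
            drx(h, i) += arma::dot(dS.row(i), dx2.row(i)) / (sx * sx) /
                         (1.0 + std::exp(-rhox(h, i)));
            dry(h, i) += arma::dot(dS.row(i), dy2.row(i)) / (sy * sy) /
                         (1.0 + std::exp(-rhoy(h, i)));
          }
        } else {
          double sx = sigx(h, 0), sy = sigy(h, 0);
          drx(h, 0) += arma::accu(dS % dx2) / (sx * sx) / (1.0 + std::exp(-rhox(h, 0)));
          dry(h, 0) += arma::accu(dS % dy2) / (sy * sy) / (1.0 + std::exp(-rhoy(h, 0)));
        }
      }
    }
  }
  List res = List::create(
    _["dxq"] = dQ * Wq.t(), _["dxkv"] = dK * Wk.t() + dV * Wv.t(),
    _["dWq"] = xq.t() * dQ, _["dWk"] = xkv.t() * dK,
    _["dWv"] = xkv.t() * dV, _["dWo"] = dWo);
  if (use_pos) { res["dU"] = dU; res["dV"] = dVp; }
  if (use_gauss) { res["drx"] = drx; res["dry"] = dry; }
  return res;
}
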