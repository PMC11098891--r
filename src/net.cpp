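// Forward/backward pass of the skeleton-graph attention network.
//
// The network operates frame-wise on feature matrices X of shape
// (rows = windows * frames_per_window) x (J joints * C channels), with
// joint-major column blocks: columns (j*C)..(j*C + C - 1) hold joint j.
//
// Layer stack: LCN (per-pair weights) -> BN -> LeakyReLU -> dropout, twice;
// then the pyramidal channel-squeezing-fusion block, global average pooling
// over frames and joints, and a fully connected classifier head.

#include <RcppArmadillo.h>
using namespace Rcpp;

struct BNCache {
  arma::rowvec invsd;
  arma::mat xhat;
};

static arma::mat bn_forward(const arma::mat& Z, const arma::vec& g, const arma::vec& b,
                            arma::vec& rm, arma::vec& rv, bool training, double mom,
                            double eps, BNCache& cache) {
  arma::rowvec mu, var;
  if (training) {
    mu = arma::mean(Z, 0);
    var = arma::var(Z, 1, 0); // biased, as is conventional for batch statistics
    rm = (1.0 - mom) * rm + mom * mu.t();
    rv = (1.0 - mom) * rv + mom * var.t();
  } else {
    mu = rm.t();
    var = rv.t();
  }
  cache.invsd = 1.0 / arma::sqrt(var + eps);
  cache.xhat = Z.each_row() - mu;
  cache.xhat.each_row() %= cache.invsd;
  arma::mat out = cache.xhat;
  out.each_row() %= g.t();
  out.each_row() += b.t();
  return out;
}

static arma::mat bn_backward(const arma::mat& dout, const arma::vec& g, const BNCache& c,
                             bool training, arma::vec& dg, arma::vec& db) {
  dg = arma::sum(dout % c.xhat, 0).t();
  db = arma::sum(dout, 0).t();
  arma::mat dxhat = dout;
  dxhat.each_row() %= g.t();
  if (!training) {
    dxhat.each_row() %= c.invsd;
    return dxhat;
  }
  const double N = (double) dout.n_rows;
  arma::rowvec s1 = arma::sum(dxhat, 0) / N;
  arma::rowvec s2 = arma::sum(dxhat % c.xhat, 0) / N;
  arma::mat dx = dxhat;
  dx.each_row() -= s1;
  arma::mat tmp = c.xhat;
  tmp.each_row() %= s2;
  dx -= tmp;
  dx.each_row() %= c.invsd;
  return dx;
}

static inline arma::span jspan(int j, int C) { return arma::span(j * C, (j + 1) * C - 1); }

// h_i = sum_{j in N(i)} a_ij * W_j^i x_j ; per-pair weights when `shared` is false.
static arma::mat lcn_forward(const arma::mat& X, int C_in, int C_out,
                             const std::vector<arma::uvec>& nb,
                             const std::vector<arma::vec>& av,
                             const std::vector<arma::mat>& W,
                             bool shared, const arma::mat& Wsh) {
  const int J = (int) nb.size();
  arma::mat Z(X.n_rows, J * C_out, arma::fill::zeros);
  for (int i = 0; i < J; ++i) {
    arma::mat acc(X.n_rows, C_out, arma::fill::zeros);
    for (arma::uword s = 0; s < nb[i].n_elem; ++s) {
      const int j = (int) nb[i](s);
      if (shared) {
        acc += av[i](s) * (X.cols(jspan(j, C_in)) * Wsh);
      } else {
        acc += av[i](s) * (X.cols(jspan(j, C_in)) *
                           W[i].rows(s * C_in, (s + 1) * C_in - 1));
      }
    }
    Z.cols(jspan(i, C_out)) = acc;
  }
  return Z;
}

static arma::mat lcn_backward(const arma::mat& X, const arma::mat& dZ, int C_in, int C_out,
                              const std::vector<arma::uvec>& nb,
                              const std::vector<arma::vec>& av,
                              const std::vector<arma::mat>& W,
                              bool shared, const arma::mat& Wsh,
                              std::vector<arma::mat>& dW, arma::mat& dWsh) {
  const int J = (int) nb.size();
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  if (shared) dWsh.zeros(C_in, C_out);
  for (int i = 0; i < J; ++i) {
    arma::mat dZi = dZ.cols(jspan(i, C_out));
    if (!shared) dW[i].zeros(nb[i].n_elem * C_in, C_out);
    for (arma::uword s = 0; s < nb[i].n_elem; ++s) {
      const int j = (int) nb[i](s);
      const double a = av[i](s);
      arma::mat Xj = X.cols(jspan(j, C_in));
      if (shared) {
        dWsh += a * (Xj.t() * dZi);
        dX.cols(jspan(j, C_in)) += a * (dZi * Wsh.t());
      } else {
        arma::mat Wb = W[i].rows(s * C_in, (s + 1) * C_in - 1);
        dW[i].rows(s * C_in, (s + 1) * C_in - 1) = a * (Xj.t() * dZi);
        dX.cols(jspan(j, C_in)) += a * (dZi * Wb.t());
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat cpp_lcn_layer(const arma::mat& X, List W, List nb, List av,
                        int C_in, int C_out, bool shared) {
  const int J = nb.size();
  std::vector<arma::uvec> nbv(J);
  std::vector<arma::vec> avv(J);
  std::vector<arma::mat> Wv;
  arma::mat Wsh;
  for (int i = 0; i < J; ++i) {
    nbv[i] = as<arma::uvec>(nb[i]);
    avv[i] = as<arma::vec>(av[i]);
  }
  if (shared) {
    Wsh = as<arma::mat>(W[0]);
  } else {
    for (int i = 0; i < J; ++i) Wv.push_back(as<arma::mat>(W[i]));
  }
  return lcn_forward(X, C_in, C_out, nbv, avv, Wv, shared, Wsh);
}

// Pyramidal channel-squeezing-fusion: for each target i, every node j is
// squeezed to its hop-dependent width, contributions are concatenated in slot
// order (self, short-range, long-range) and fused by the target's weight F_i.
// [[Rcpp::export]]
arma::mat cpp_pcsf_layer(const arma::mat& X, List S, List Fm, List slot_src, int C_in) {
  const int J = slot_src.size();
  arma::mat F0 = as<arma::mat>(Fm[0]);
  const int C_out = (int) F0.n_cols;
  arma::mat Y(X.n_rows, J * C_out);
  for (int i = 0; i < J; ++i) {
    List Si = S[i];
    arma::uvec src = as<arma::uvec>(slot_src[i]);
    arma::mat Fi = as<arma::mat>(Fm[i]);
    arma::mat Ysq(X.n_rows, Fi.n_rows);
    arma::uword col = 0;
    for (arma::uword s = 0; s < src.n_elem; ++s) {
      arma::mat Ss = as<arma::mat>(Si[s]);
      Ysq.cols(col, col + Ss.n_cols - 1) = X.cols(jspan((int) src(s), C_in)) * Ss;
      col += Ss.n_cols;
    }
    Y.cols(jspan(i, C_out)) = Ysq * Fi;
  }
  return Y;
}

static void softmax_rows(arma::mat& P) {
  P.each_col() -= arma::max(P, 1);
  P = arma::exp(P);
  P.each_col() /= arma::sum(P, 1);
}

// [[Rcpp::export]]
List net_run(const arma::mat& X, const arma::ivec& y, List arch, List params,
             List state, List hyper) {
  const int J  = as<int>(arch["J"]);
  const int C0 = as<int>(arch["C0"]);
  const int C1 = as<int>(arch["C1"]);
  const int C2 = as<int>(arch["C2"]);
  const int K  = as<int>(arch["K"]);
  const int Fw = as<int>(arch["Fw"]);
  const bool use_att  = as<bool>(arch["use_attention"]);
  const bool use_pcsf = as<bool>(arch["use_pcsf"]);

  List nbL = arch["nb"], avL = arch["av"];
  std::vector<arma::uvec> nb(J);
  std::vector<arma::vec> av(J);
  for (int i = 0; i < J; ++i) {
    nb[i] = as<arma::uvec>(nbL[i]);
    av[i] = as<arma::vec>(avL[i]);
  }

  std::vector<arma::mat> W1, W2;
  arma::mat W1sh, W2sh;
  if (use_att) {
    List W1L = params["W1"], W2L = params["W2"];
    for (int i = 0; i < J; ++i) {
      W1.push_back(as<arma::mat>(W1L[i]));
      W2.push_back(as<arma::mat>(W2L[i]));
    }
  } else {
    W1sh = as<arma::mat>(params["W1"]);
    W2sh = as<arma::mat>(params["W2"]);
  }
  arma::vec g1 = as<arma::vec>(params["g1"]), b1 = as<arma::vec>(params["b1"]);
  arma::vec g2 = as<arma::vec>(params["g2"]), b2 = as<arma::vec>(params["b2"]);
  arma::mat Wfc = as<arma::mat>(params["Wfc"]);
  arma::vec bfc = as<arma::vec>(params["bfc"]);

  std::vector<std::vector<arma::mat> > S;
  std::vector<arma::mat> Fm;
  std::vector<arma::uvec> slot_src;
  if (use_pcsf) {
    List SL = params["S"], FL = params["Fm"], slotL = arch["slot_src"];
    S.resize(J); Fm.resize(J); slot_src.resize(J);
    for (int i = 0; i < J; ++i) {
      List Si = SL[i];
      for (int s = 0; s < Si.size(); ++s) S[i].push_back(as<arma::mat>(Si[s]));
      Fm[i] = as<arma::mat>(FL[i]);
      slot_src[i] = as<arma::uvec>(slotL[i]);
    }
  }

  arma::vec rm1 = as<arma::vec>(state["rm1"]), rv1 = as<arma::vec>(state["rv1"]);
  arma::vec rm2 = as<arma::vec>(state["rm2"]), rv2 = as<arma::vec>(state["rv2"]);

  const bool training  = as<bool>(hyper["training"]);
  const bool backward  = as<bool>(hyper["backward"]);
  const bool want_att  = as<bool>(hyper["attention"]);
  const double p_drop  = as<double>(hyper["dropout"]);
  const double leak    = as<double>(hyper["leaky"]);
  const double mom     = as<double>(hyper["bn_momentum"]);
  const double eps     = as<double>(hyper["bn_eps"]);
  const int loss_type  = as<int>(hyper["loss_type"]); // 0 = cross-entropy, 1 = focal
  const double gamma   = as<double>(hyper["focal_gamma"]);
  arma::vec alpha      = as<arma::vec>(hyper["alpha"]);

  if ((int) X.n_cols != J * C0) stop("feature matrix has %d columns, expected %d",
                                     (int) X.n_cols, J * C0);
  if (X.n_rows % Fw != 0) stop("row count is not a multiple of the window length");
  if (!X.is_finite()) stop("non-finite values in input features");
  const int R = (int) X.n_rows;
  const int B = R / Fw;

  // ---- forward ----
  arma::mat Z1 = lcn_forward(X, C0, C1, nb, av, W1, !use_att, W1sh);
  BNCache bc1;
  arma::mat A1 = bn_forward(Z1, g1, b1, rm1, rv1, training, mom, eps, bc1);
  arma::mat H1 = A1 % (leak + (1.0 - leak) * arma::conv_to<arma::mat>::from(A1 > 0));
  arma::mat M1;
  if (training && p_drop > 0) {
    M1.set_size(H1.n_rows, H1.n_cols);
    for (arma::uword k = 0; k < M1.n_elem; ++k)
      M1(k) = (unif_rand() < p_drop) ? 0.0 : 1.0 / (1.0 - p_drop);
    H1 %= M1;
  }

  arma::mat Z2 = lcn_forward(H1, C1, C2, nb, av, W2, !use_att, W2sh);
  BNCache bc2;
  arma::mat A2 = bn_forward(Z2, g2, b2, rm2, rv2, training, mom, eps, bc2);
  arma::mat H2 = A2 % (leak + (1.0 - leak) * arma::conv_to<arma::mat>::from(A2 > 0));
  arma::mat M2;
  if (training && p_drop > 0) {
    M2.set_size(H2.n_rows, H2.n_cols);
    for (arma::uword k = 0; k < M2.n_elem; ++k)
      M2(k) = (unif_rand() < p_drop) ? 0.0 : 1.0 / (1.0 - p_drop);
    H2 %= M2;
  }

  // PCSF
  std::vector<arma::mat> Ysq(J);
  arma::mat Yf;
  if (use_pcsf) {
    Yf.set_size(R, J * C2);
    for (int i = 0; i < J; ++i) {
      arma::mat Yi(R, Fm[i].n_rows);
      arma::uword col = 0;
      for (arma::uword s = 0; s < slot_src[i].n_elem; ++s) {
        const arma::mat& Ss = S[i][s];
        Yi.cols(col, col + Ss.n_cols - 1) = H2.cols(jspan((int) slot_src[i](s), C2)) * Ss;
        col += Ss.n_cols;
      }
      Ysq[i] = Yi;
      Yf.cols(jspan(i, C2)) = Yi * Fm[i];
    }
  } else {
    Yf = H2;
  }

  // global average pooling over frames; joint identity is preserved so the
  // classifier head can weight joints (the wrists carry the signal)
  arma::mat G(B, J * C2);
  for (int b = 0; b < B; ++b)
    G.row(b) = arma::mean(Yf.rows(b * Fw, (b + 1) * Fw - 1), 0);

  arma::mat logits = G * Wfc;
  logits.each_row() += bfc.t();

  List out;
  out["logits"] = logits;

  // per-frame attention: a_ij-weighted norm of each source joint's transformed
  // contribution in the second (deepest) attention layer
  if (want_att) {
    if (!use_att) stop("attention maps are undefined for the shared-weight variant");
    arma::mat att(R, J, arma::fill::zeros);
    for (int i = 0; i < J; ++i) {
      for (arma::uword s = 0; s < nb[i].n_elem; ++s) {
        const int j = (int) nb[i](s);
        arma::mat contrib = av[i](s) *
          (H1.cols(jspan(j, C1)) * W2[i].rows(s * C1, (s + 1) * C1 - 1));
        att.col(j) += arma::sqrt(arma::sum(arma::square(contrib), 1));
      }
    }
    out["attention"] = att;
  }

  double loss = NA_REAL;
  arma::mat P = logits, dlogits(B, K, arma::fill::zeros);
  if (y.n_elem > 0) {
    softmax_rows(P);
    loss = 0.0;
    for (int b = 0; b < B; ++b) {
      const int yc = (int) y(b); // 0-based
      const double pb = std::max(P(b, yc), 1e-12);
      double dLdp;
      if (loss_type == 0) {
        loss += -std::log(pb);
        dLdp = -1.0 / pb;
      } else {
        const double a = alpha(yc);
        const double om = 1.0 - pb;
        loss += -a * std::pow(om, gamma) * std::log(pb);
        dLdp = a * (gamma * std::pow(std::max(om, 1e-12), gamma - 1.0) * std::log(pb)
                    - std::pow(om, gamma) / pb);
      }
      // dp/dz_k = p * (delta_ky - P_k)
      for (int k = 0; k < K; ++k)
        dlogits(b, k) = dLdp * pb * ((k == yc ? 1.0 : 0.0) - P(b, k)) / B;
    }
    loss /= B;
    out["loss"] = loss;
    out["prob"] = P;
  }

  if (training) {
    out["rm1"] = rm1; out["rv1"] = rv1; out["rm2"] = rm2; out["rv2"] = rv2;
  }

  if (!backward) return out;
  if (y.n_elem == 0) stop("backward pass requires labels");

  // ---- backward ----
  arma::mat dG = dlogits * Wfc.t();
  arma::mat dWfc = G.t() * dlogits;
  arma::vec dbfc = arma::sum(dlogits, 0).t();

  arma::mat dYf(R, J * C2);
  for (int b = 0; b < B; ++b)
    dYf.rows(b * Fw, (b + 1) * Fw - 1) = arma::repmat(dG.row(b) / Fw, Fw, 1);

  arma::mat dH2(R, J * C2, arma::fill::zeros);
  List dS(J), dFm(J);
  if (use_pcsf) {
    for (int i = 0; i < J; ++i) {
      arma::mat dYp = dYf.cols(jspan(i, C2));
      arma::mat dYi = dYp * Fm[i].t();           // R x T_i
      dFm[i] = wrap(arma::mat(Ysq[i].t() * dYp)); // T_i x C2
      List dSi(slot_src[i].n_elem);
      arma::uword col = 0;
      for (arma::uword s = 0; s < slot_src[i].n_elem; ++s) {
        const arma::mat& Ss = S[i][s];
        const int j = (int) slot_src[i](s);
        arma::mat dYis = dYi.cols(col, col + Ss.n_cols - 1);
        dSi[s] = wrap(arma::mat(H2.cols(jspan(j, C2)).t() * dYis));
        dH2.cols(jspan(j, C2)) += dYis * Ss.t();
        col += Ss.n_cols;
      }
      dS[i] = dSi;
    }
  } else {
    dH2 = dYf;
  }

  if (training && p_drop > 0) dH2 %= M2;
  arma::mat dA2 = dH2 % (leak + (1.0 - leak) * arma::conv_to<arma::mat>::from(A2 > 0));
  arma::vec dg2, db2;
  arma::mat dZ2 = bn_backward(dA2, g2, bc2, training, dg2, db2);

  std::vector<arma::mat> dW2(J);
  arma::mat dW2sh;
  arma::mat dH1 = lcn_backward(H1, dZ2, C1, C2, nb, av, W2, !use_att, W2sh, dW2, dW2sh);

  if (training && p_drop > 0) dH1 %= M1;
  arma::mat dA1 = dH1 % (leak + (1.0 - leak) * arma::conv_to<arma::mat>::from(A1 > 0));
  arma::vec dg1, db1;
  arma::mat dZ1 = bn_backward(dA1, g1, bc1, training, dg1, db1);

  std::vector<arma::mat> dW1(J);
  arma::mat dW1sh;
  lcn_backward(X, dZ1, C0, C1, nb, av, W1, !use_att, W1sh, dW1, dW1sh);

  List grads;
  if (use_att) {
    List gW1(J), gW2(J);
    for (int i = 0; i < J; ++i) { gW1[i] = wrap(dW1[i]); gW2[i] = wrap(dW2[i]); }
    grads["W1"] = gW1; grads["W2"] = gW2;
  } else {
    grads["W1"] = wrap(dW1sh); grads["W2"] = wrap(dW2sh);
  }
  grads["g1"] = dg1; grads["b1"] = db1;
  grads["g2"] = dg2; grads["b2"] = db2;
  if (use_pcsf) { grads["S"] = dS; grads["Fm"] = dFm; }
  grads["Wfc"] = wrap(dWfc); grads["bfc"] = dbfc;
  out["grads"] = grads;
  return out;
}
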