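// Pruning engine for reversible 20-state substitution models.
//
// Likelihoods are computed by Felsenstein's post-order pruning with per-node
// column rescaling (log accumulators) so alignments of any size are safe from
// underflow.  Transition matrices come from the symmetric eigendecomposition
// of the reversible generator, supplied from R as Q = A diag(lam) Ainv with
// A = Pi^{-1/2} U and Ainv = U' Pi^{1/2}.
//
// The same machinery yields analytic derivatives: a pre-order (root-to-tip)
// pass produces, for every edge, the outer-product matrix G_e of flank
// partials, from which
//   dlnL/dt_e      = <G_e, rho Q P_e>                    (per gamma category)
//   dlnL/dQ        = s * Ainv' ((A' G_e Ainv') o Phi) A'  with s = t_e rho
// where Phi is the Daleckii-Krein divided-difference matrix of exp on the
// eigenvalues.  These power the branch-length and exchangeability optimizers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat pmat(const mat& A, const vec& lam, const mat& Ainv, double s) {
  mat P = A * diagmat(exp(lam * s)) * Ainv;
  // eigendecomposition round-off can leave tiny negative entries
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// divided differences (e^{xi} - e^{xj}) / (xi - xj), xi = lam_i * s
static mat phimat(const vec& lam, double s) {
  const uword n = lam.n_elem;
  vec x = lam * s;
  mat Phi(n, n);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      double dx = x(i) - x(j);
      double ax = std::abs(dx);
      if (ax < 1e-12) {
        Phi(i, j) = std::exp(0.5 * (x(i) + x(j)));
      } else {
        // (e^{xi}-e^{xj})/dx = e^{max} (1 - e^{-|dx|}) / |dx|, overflow-safe
        Phi(i, j) = std::exp(std::max(x(i), x(j))) * (-std::expm1(-ax)) / ax;
      }
    }
  }
  return Phi;
}

static void rescale_cols(mat& M, vec& lsc) {
  rowvec mx = max(M, 0);
  for (uword j = 0; j < M.n_cols; ++j) {
    if (mx(j) > 0.0 && mx(j) != 1.0) {
      M.col(j) /= mx(j);
      lsc(j) += std::log(mx(j));
    }
  }
}

// Mixture log-likelihood of one alignment under +I+G, with optional analytic
// gradients with respect to the (normalized or not) generator entries and the
// branch lengths.
//
// tip     : 20 x npat x ntip cube of tip partial indicators
// edge    : nedge x 2 (parent, child), 1-based, post-order (children first)
// el      : branch lengths, one per edge row
// A, lam, Ainv : eigensystem of the generator actually used (Q = A L Ainv)
// pi      : equilibrium frequencies (root distribution)
// rates   : gamma category rates (length C)
// v       : proportion of invariant sites
// invlik  : per-pattern invariant-class likelihood (sum of pi over the
//           residues compatible with a constant column; 0 if none)
// weights : per-pattern multiplicities
// [[Rcpp::export]]
Rcpp::List cpp_mix_loglik(const arma::cube& tip,
                          const arma::imat& edge,
                          const arma::vec& el,
                          const arma::mat& A,
                          const arma::vec& lam,
                          const arma::mat& Ainv,
                          const arma::vec& pi,
                          const arma::vec& rates,
                          double v,
                          const arma::vec& invlik,
                          const arma::vec& weights,
                          bool grad_q,
                          bool grad_t) {
  const uword npat = tip.n_cols;
  const uword ntip = tip.n_slices;
  const uword nedge = edge.n_rows;
  const uword C = rates.n_elem;
  const uword nnode = static_cast<uword>(edge.max());
  const uword root = static_cast<uword>(edge(nedge - 1, 0)) - 1;

  // children edge lists per internal node
  std::vector<std::vector<uword>> kids(nnode);
  for (uword e = 0; e < nedge; ++e)
    kids[static_cast<uword>(edge(e, 0)) - 1].push_back(e);

  mat catlog(C, npat);
  // per-category state kept for the gradient pass
  std::vector<cube> dn_all;
  std::vector<mat> lsc_all;

  for (uword c = 0; c < C; ++c) {
    const double rho = rates(c);
    cube dn(20, npat, nnode);
    mat lsc(npat, nnode, fill::zeros);
    std::vector<char> touched(nnode, 0);
    for (uword i = 0; i < ntip; ++i) {
      dn.slice(i) = tip.slice(i);
      touched[i] = 1;
    }
    for (uword e = 0; e < nedge; ++e) {
      const uword p = static_cast<uword>(edge(e, 0)) - 1;
      const uword ch = static_cast<uword>(edge(e, 1)) - 1;
      mat P = pmat(A, lam, Ainv, el(e) * rho);
      mat M = P * dn.slice(ch);
      if (!touched[p]) {
        dn.slice(p) = M;
        lsc.col(p) = lsc.col(ch);
        touched[p] = 1;
      } else {
        dn.slice(p) %= M;
        lsc.col(p) += lsc.col(ch);
      }
      vec lp = lsc.col(p);
      rescale_cols(dn.slice(p), lp);
      lsc.col(p) = lp;
    }
    vec rootlin = (pi.t() * dn.slice(root)).t();
    for (uword j = 0; j < npat; ++j)
      catlog(c, j) = (rootlin(j) > 0.0)
                         ? std::log(rootlin(j)) + lsc(j, root)
                         : -datum::inf;
    if (grad_q || grad_t) {
      dn_all.push_back(std::move(dn));
      lsc_all.push_back(std::move(lsc));
    }
  }

  // per-site mixture via log-sum-exp
  vec sitelog(npat);
  const double lgc = std::log1p(-v) - std::log(static_cast<double>(C));
  for (uword j = 0; j < npat; ++j) {
    double mxv = -datum::inf;
    for (uword c = 0; c < C; ++c)
      mxv = std::max(mxv, lgc + catlog(c, j));
    double linv = -datum::inf;
    if (v > 0.0 && invlik(j) > 0.0) {
      linv = std::log(v) + std::log(invlik(j));
      mxv = std::max(mxv, linv);
    }
    if (!std::isfinite(mxv)) {
      sitelog(j) = -datum::inf;
      continue;
    }
    double acc = 0.0;
    for (uword c = 0; c < C; ++c)
      acc += std::exp(lgc + catlog(c, j) - mxv);
    if (std::isfinite(linv)) acc += std::exp(linv - mxv);
    sitelog(j) = mxv + std::log(acc);
  }
  const double total = dot(weights, sitelog);

  mat gQ(20, 20, fill::zeros);
  vec gT(nedge, fill::zeros);

  if ((grad_q || grad_t) && std::isfinite(total)) {
    const mat Qgen = A * diagmat(lam) * Ainv;
    for (uword c = 0; c < C; ++c) {
      const double rho = rates(c);
      const cube& dn = dn_all[c];
      const mat& lsc = lsc_all[c];
      // cache transition matrices for this category
      std::vector<mat> Pc(nedge);
      std::vector<mat> Mc(nedge);
      for (uword e = 0; e < nedge; ++e) {
        const uword ch = static_cast<uword>(edge(e, 1)) - 1;
        Pc[e] = pmat(A, lam, Ainv, el(e) * rho);
        Mc[e] = Pc[e] * dn.slice(ch);
      }
      cube up(20, npat, nnode, fill::zeros);
      mat usc(npat, nnode, fill::zeros);
      up.slice(root) = repmat(pi, 1, npat);
      for (uword ee = nedge; ee-- > 0;) {
        const uword p = static_cast<uword>(edge(ee, 0)) - 1;
        const uword ch = static_cast<uword>(edge(ee, 1)) - 1;
        mat E = up.slice(p);
        vec Esc = usc.col(p);
        for (uword e2 : kids[p]) {
          if (e2 == ee) continue;
          E %= Mc[e2];
          Esc += lsc.col(static_cast<uword>(edge(e2, 1)) - 1);
        }
        // per-pattern weight of this category in d(total)/d(site likelihood)
        vec coef(npat);
        for (uword j = 0; j < npat; ++j) {
          if (!std::isfinite(sitelog(j))) {
            coef(j) = 0.0;
            continue;
          }
          double lc = Esc(j) + lsc(j, ch) - sitelog(j);
          coef(j) = weights(j) * std::exp(lgc + lc);
        }
        mat G = (E.each_row() % coef.t()) * dn.slice(ch).t();
        if (grad_t) gT(ee) += accu(G % (Qgen * Pc[ee])) * rho;
        if (grad_q) {
          const double s = el(ee) * rho;
          gQ += s * Ainv.t() *
                ((A.t() * G * Ainv.t()) % phimat(lam, s)) * A.t();
        }
        if (ch >= ntip) {
          mat Uch = Pc[ee].t() * E;
          vec us = Esc;
          rescale_cols(Uch, us);
          up.slice(ch) = Uch;
          usc.col(ch) = us;
        }
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("loglik") = total,
      Rcpp::Named("sitelog") = sitelog,
      Rcpp::Named("catlog") = catlog,
      Rcpp::Named("grad_q") = gQ,
      Rcpp::Named("grad_t") = gT);
}
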