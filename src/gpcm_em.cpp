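// Marginal maximum likelihood estimation of the generalized partial
// credit model by EM over a fixed quadrature grid, optionally with a
// latent-regression conditioning model N(mu + beta'c, sigma^2) as the
// person-specific prior. The E-step accumulates expected node x category
// count tables per item; the M-step runs a damped Fisher-scoring Newton
// per item and (when conditioning) a weighted least-squares update of the
// regression, followed by a standardization of the latent metric that
// resolves the location/scale indeterminacy of the joint model.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// category log-probabilities of one item at all nodes: Q x C
static mat item_logprob(double a, const rowvec& bcum, const vec& nodes,
                        int C) {
  const int Q = nodes.n_elem;
  mat eta(Q, C);
  for (int c = 0; c < C; ++c) eta.col(c) = a * (c * nodes - bcum[c]);
  vec mx = max(eta, 1);
  eta.each_col() -= mx;
  vec lz = log(sum(exp(eta), 1));
  eta.each_col() -= lz;
  return eta;
}

static rowvec cumulate(const rowvec& b, int C) {
  rowvec bcum(C, fill::zeros);
  for (int c = 1; c < C; ++c) bcum[c] = bcum[c - 1] + b[c - 1];
  return bcum;
}

// one M-step for a single item: damped Fisher-scoring on (a, b_1..b_{C-1})
// maximizing sum_qc R(q,c) log P_c(theta_q). The expected-information
// Hessian is negative semidefinite, so the step with halving ascends.
static void mstep_item(double& a, rowvec& b, const mat& R, const vec& nodes,
                       int C) {
  const int Q = nodes.n_elem;
  const int np = C;  // a plus C-1 step parameters
  vec nq = sum(R, 1);
  for (int it = 0; it < 25; ++it) {
    rowvec bcum = cumulate(b, C);
    mat logP = item_logprob(a, bcum, nodes, C);
    mat P = exp(logP);
    double f0 = accu(R % logP);
    vec g(np, fill::zeros);
    mat H(np, np, fill::zeros);
    mat F(C, np);
    for (int q = 0; q < Q; ++q) {
      for (int c = 0; c < C; ++c) {
        F(c, 0) = c * nodes[q] - bcum[c];
        for (int t = 1; t < C; ++t) F(c, t) = (c >= t) ? -a : 0.0;
      }
      rowvec p = P.row(q);
      rowvec pbar = p * F;
      g += ((R.row(q) - nq[q] * p) * F).t();
      H += nq[q] * (F.t() * diagmat(p) * F - pbar.t() * pbar);
    }
    vec delta;
    if (!solve(delta, H + 1e-10 * eye(np, np), g)) break;
    double step = 1.0, a_new = a;
    rowvec b_new = b;
    for (int h = 0; h < 25; ++h) {
      a_new = a + step * delta[0];
      if (a_new < 0.01) a_new = 0.01;
      b_new = b + step * delta.subvec(1, np - 1).t();
      double f1 = accu(R % item_logprob(a_new, cumulate(b_new, C), nodes, C));
      if (f1 >= f0 - 1e-12) break;
      step *= 0.5;
    }
    double chg = std::abs(a_new - a);
    for (int t = 0; t < C - 1; ++t)
      chg = std::max(chg, std::abs(b_new[t] - b[t]));
    a = a_new;
    b = b_new;
    if (chg < 1e-9) break;
  }
}

// [[Rcpp::export]]
Rcpp::List gpcm_em_cpp(const arma::imat& x, const arma::ivec& ncat,
                       const arma::vec& nodes, const arma::vec& base_wt,
                       arma::vec a, arma::mat b, const arma::mat& Cmat,
                       bool latreg, int max_iter, double tol) {
  const int n = x.n_rows, k = x.n_cols, Q = nodes.n_elem;
  const int p = latreg ? Cmat.n_cols : 0;

  vec reg_coef(std::max(p, 1), fill::zeros);
  double sigma2 = 1.0;
  vec fitted(n, fill::zeros);
  mat XtX;
  if (latreg) XtX = Cmat.t() * Cmat;

  mat post(n, Q);
  std::vector<mat> P(k);
  std::vector<double> llhist;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    vec a_old = a;
    mat b_old = b;
    vec reg_old = reg_coef;
    double sig_old = sigma2;

    for (int j = 0; j < k; ++j) {
      int C = ncat[j];
      P[j] = exp(item_logprob(a[j], cumulate(b.row(j).head(C - 1), C), nodes, C));
    }

    // person x node likelihoods
    mat L(n, Q, fill::ones);
    for (int j = 0; j < k; ++j) {
      const mat& Pj = P[j];
      for (int q = 0; q < Q; ++q) {
        double* Lq = L.colptr(q);
        const double* Pq = Pj.memptr() + q;  // row q, stride Q
        const int* xj = x.colptr(j);
        for (int i = 0; i < n; ++i) Lq[i] *= Pq[(size_t)(xj[i] - 1) * Q];
      }
    }

    // prior weights
    if (latreg) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int q = 0; q < Q; ++q) {
          double z = nodes[q] - fitted[i];
          double w = std::exp(-0.5 * z * z / sigma2);
          post(i, q) = L(i, q) * w;
          s += w;
        }
        post.row(i) /= s;  // normalize the prior, likelihood carried along
      }
    } else {
      for (int q = 0; q < Q; ++q) post.col(q) = L.col(q) * base_wt[q];
    }

    vec li = sum(post, 1);
    double ll = accu(log(li));
    llhist.push_back(ll);
    post.each_col() /= li;

    // expected count tables and item updates
    for (int j = 0; j < k; ++j) {
      int C = ncat[j];
      mat R(Q, C, fill::zeros);
      const int* xj = x.colptr(j);
      for (int q = 0; q < Q; ++q) {
        const double* pq = post.colptr(q);
        for (int i = 0; i < n; ++i) R(q, xj[i] - 1) += pq[i];
      }
      double aj = a[j];
      rowvec bj = b.row(j).head(C - 1);
      mstep_item(aj, bj, R, nodes, C);
      a[j] = aj;
      b.row(j).head(C - 1) = bj;
    }

    if (latreg) {
      vec m1 = post * nodes;
      vec m2 = post * square(nodes);
      reg_coef = solve(XtX, Cmat.t() * m1);
      fitted = Cmat * reg_coef;
      sigma2 = mean(m2 - 2.0 * fitted % m1 + square(fitted));
      if (sigma2 < 1e-6) sigma2 = 1e-6;
      // standardize the latent marginal to mean 0, variance 1
      double m = mean(fitted);
      double v = mean(square(fitted - m)) + sigma2;
      double s = std::sqrt(v);
      a *= s;
      b = (b - m) / s;
      reg_coef /= s;
      reg_coef[0] -= m / s;  // first column of Cmat is the intercept
      fitted = (fitted - m) / s;
      sigma2 /= v;
    }

    double chg = std::max(abs(a - a_old).max(), abs(vectorise(b - b_old)).max());
    if (latreg) {
      chg = std::max(chg, abs(reg_coef - reg_old).max());
      chg = std::max(chg, std::abs(sigma2 - sig_old));
    }
    if (chg < tol) {
      converged = true;
      break;
    }
  }

  // final E-step so the returned posterior matches the returned parameters
  for (int j = 0; j < k; ++j) {
    int C = ncat[j];
    P[j] = exp(item_logprob(a[j], cumulate(b.row(j).head(C - 1), C), nodes, C));
  }
  mat L(n, Q, fill::ones);
  for (int j = 0; j < k; ++j) {
    const mat& Pj = P[j];
    for (int q = 0; q < Q; ++q) {
      double* Lq = L.colptr(q);
      const double* Pq = Pj.memptr() + q;
      const int* xj = x.colptr(j);
      for (int i = 0; i < n; ++i) Lq[i] *= Pq[(size_t)(xj[i] - 1) * Q];
    }
  }
  if (latreg) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int q = 0; q < Q; ++q) {
        double z = nodes[q] - fitted[i];
        double w = std::exp(-0.5 * z * z / sigma2);
        post(i, q) = L(i, q) * w;
        s += w;
      }
      post.row(i) /= s;
    }
  } else {
    for (int q = 0; q < Q; ++q) post.col(q) = L.col(q) * base_wt[q];
  }
  vec li = sum(post, 1);
  double ll = accu(log(li));
  post.each_col() /= li;

  return Rcpp::List::create(
      Rcpp::Named("a") = a, Rcpp::Named("b") = b,
      Rcpp::Named("posterior") = post, Rcpp::Named("loglik") = ll,
      Rcpp::Named("loglik_history") = llhist,
      Rcpp::Named("iterations") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("reg_coef") = reg_coef, Rcpp::Named("sigma2") = sigma2);
}

// per-person continuous argmax scoring: WLE (type 1) maximizes
// loglik + 0.5 log(test information), EBM (type 2) maximizes
// loglik + log N(theta; pm, pv). Grid scan over the quadrature nodes to
// bracket, then golden-section refinement.
static double score_obj(const irowvec& xi, const vec& a, const mat& bcum,
                        const ivec& ncat, double th, int type, double pm,
                        double pv) {
  const int k = xi.n_elem;
  double ll = 0.0, info = 0.0;
  for (int j = 0; j < k; ++j) {
    const int C = ncat[j];
    double mx = -datum::inf;
    double eta[8];
    for (int c = 0; c < C; ++c) {
      eta[c] = a[j] * (c * th - bcum(j, c));
      if (eta[c] > mx) mx = eta[c];
    }
    double z = 0.0, e1 = 0.0, e2 = 0.0;
    for (int c = 0; c < C; ++c) {
      double w = std::exp(eta[c] - mx);
      z += w;
      e1 += c * w;
      e2 += double(c) * c * w;
    }
    ll += eta[xi[j] - 1] - mx - std::log(z);
    if (type == 1) {
      e1 /= z;
      e2 /= z;
      info += a[j] * a[j] * (e2 - e1 * e1);
    }
  }
  if (type == 1) return ll + 0.5 * std::log(info);
  double d = th - pm;
  return ll - 0.5 * d * d / pv;
}

// [[Rcpp::export]]
arma::vec gpcm_score_cpp(const arma::imat& x, const arma::ivec& ncat,
                         const arma::vec& a, const arma::mat& b,
                         const arma::vec& nodes, int type, double prior_mean,
                         double prior_var) {
  const int n = x.n_rows, k = x.n_cols, Q = nodes.n_elem;
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  mat bcum(k, 8, fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int c = 1; c < ncat[j]; ++c) bcum(j, c) = bcum(j, c - 1) + b(j, c - 1);
  vec out(n);
  for (int i = 0; i < n; ++i) {
    irowvec xi = x.row(i);
    int best = 0;
    double fbest = -datum::inf;
    for (int q = 0; q < Q; ++q) {
      double f = score_obj(xi, a, bcum, ncat, nodes[q], type, prior_mean,
                           prior_var);
      if (f > fbest) {
        fbest = f;
        best = q;
      }
    }
    double lo = nodes[std::max(best - 1, 0)];
    double hi = nodes[std::min(best + 1, Q - 1)];
    double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
    double f1 = score_obj(xi, a, bcum, ncat, x1, type, prior_mean, prior_var);
    double f2 = score_obj(xi, a, bcum, ncat, x2, type, prior_mean, prior_var);
    for (int it = 0; it < 40; ++it) {
      if (f1 >= f2) {
        hi = x2;
        x2 = x1;
        f2 = f1;
        x1 = hi - gr * (hi - lo);
        f1 = score_obj(xi, a, bcum, ncat, x1, type, prior_mean, prior_var);
      } else {
        lo = x1;
        x1 = x2;
        f1 = f2;
        x2 = lo + gr * (hi - lo);
        f2 = score_obj(xi, a, bcum, ncat, x2, type, prior_mean, prior_var);
      }
    }
    out[i] = (lo + hi) / 2.0;
  }
  return out;
}
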