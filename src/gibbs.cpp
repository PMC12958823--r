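// Gibbs sampler for the multitrait individual-tree mixed model (MTM) and the
// recursive structural equation model (SEM).
//
// Model (tree i = 1..n, traits t-vector):
//   (I - Lambda) y_i = beta' x_i + a_i + e_i
//   a ~ N(0, Sigma_a kron K),  e_i ~ iid N(0, R0)
// with Lambda = 0 for the MTM. K enters through its eigendecomposition
// K = U diag(d) U': rotating rows by U' leaves the residual covariance
// R0 kron I intact while making the rows of the rotated breeding values
// independent with covariance d_i * Sigma_a, so the a-update is n small
// t-dimensional draws per sweep.
//
// Updates per sweep: beta (matrix normal, flat prior), a (per-tree normal in
// the rotated basis), Sigma_a and R0 (inverse-Wishart), free entries of
// Lambda (joint normal, prior N(0, v_lambda)), and data augmentation of
// missing phenotypes from their conditional given the observed traits.
// The deviance of the observed data given (beta, a, Lambda, R0) is traced on
// retained iterations. All randomness comes from R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat rnorm_mat(int r, int c) {
  arma::mat out(r, c);
  for (arma::uword i = 0; i < out.n_elem; ++i) out(i) = R::norm_rand();
  return out;
}

// Draw from Wishart(df, V) via the Bartlett decomposition.
static arma::mat rwish(double df, const arma::mat& V) {
  const int p = V.n_rows;
  arma::mat Lv = arma::chol(V, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = Lv * A;
  return LA * LA.t();
}

// Inverse-Wishart(df, S) draw: X^{-1} with X ~ Wishart(df, S^{-1}).
static arma::mat riwish(double df, const arma::mat& S) {
  return arma::inv_sympd(rwish(df, arma::inv_sympd(S)));
}

// -2 log N(y_obs; mu_obs, V_obs) contribution of one tree.
static double tree_deviance(const arma::rowvec& y, const arma::rowvec& mu,
                            const arma::mat& V, const arma::uvec& obs) {
  if (obs.n_elem == 0) return 0.0;
  arma::vec r = (y.cols(obs) - mu.cols(obs)).t();
  arma::mat Vo = V.submat(obs, obs);
  arma::mat L = arma::chol(Vo, "lower");
  arma::vec z = arma::solve(arma::trimatl(L), r);
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  return obs.n_elem * std::log(2.0 * M_PI) + logdet + arma::dot(z, z);
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(arma::mat Y,              // n x t, missing entries = NaN
                const arma::mat& X,       // n x p
                const arma::mat& U,       // n x n eigenvectors of K
                const arma::vec& d,       // eigenvalues of K (all > 0)
                const arma::imat& lambda_to_from, // m x 2, 0-based (to, from)
                double nu_a, const arma::mat& S_a,
                double nu_r, const arma::mat& S_r,
                double v_lambda,
                int n_iter, int burn, int thin,
                bool trace_deviance, bool residual_diag) {
  const int n = Y.n_rows, t = Y.n_cols, p = X.n_cols;
  const int m = lambda_to_from.n_rows;

  // missingness bookkeeping
  std::vector<arma::uvec> obs_idx(n), mis_idx(n);
  std::vector<int> miss_trees;
  for (int i = 0; i < n; ++i) {
    std::vector<arma::uword> o, mi;
    for (int j = 0; j < t; ++j) {
      if (std::isnan(Y(i, j))) mi.push_back(j); else o.push_back(j);
    }
    obs_idx[i] = arma::uvec(o);
    mis_idx[i] = arma::uvec(mi);
    if (!mi.empty()) miss_trees.push_back(i);
  }
  // initialize missing entries at the observed trait means
  arma::rowvec ymean(t, arma::fill::zeros);
  for (int j = 0; j < t; ++j) {
    arma::vec col = Y.col(j);
    arma::uvec ok = arma::find_finite(col);
    ymean(j) = ok.n_elem ? arma::mean(col(ok)) : 0.0;
  }
  for (size_t k = 0; k < miss_trees.size(); ++k) {
    int i = miss_trees[k];
    for (arma::uword q = 0; q < mis_idx[i].n_elem; ++q)
      Y(i, mis_idx[i](q)) = ymean(mis_idx[i](q));
  }

  const arma::mat XtX = X.t() * X;
  const arma::mat Ax = arma::chol(XtX);          // upper
  const arma::mat Ut = U.t();
  const arma::mat Xt_rot = Ut * X;               // rotated design

  // state
  arma::mat beta(p, t, arma::fill::zeros);
  arma::mat a(n, t, arma::fill::zeros);
  arma::mat Sigma_a = arma::eye(t, t) * 0.5;
  arma::mat R0 = arma::eye(t, t) * 0.5;
  arma::vec lambda(m, arma::fill::zeros);
  arma::mat Lambda(t, t, arma::fill::zeros);

  const int n_keep = (n_iter - burn) / thin;
  arma::mat keep_Sa(n_keep, t * t), keep_R0(n_keep, t * t);
  arma::mat keep_beta(n_keep, p * t);
  arma::mat keep_lambda(n_keep, std::max(m, 1));
  arma::vec keep_dev(n_keep, arma::fill::zeros);
  arma::mat a_sum(n, t, arma::fill::zeros), a_sum2(n, t, arma::fill::zeros);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // structural transform w_i = y_i - Lambda y_i (current Lambda)
    arma::mat W = (m > 0) ? arma::mat(Y - Y * Lambda.t()) : Y;

    // --- beta | a, Lambda, R0 (flat prior): matrix normal around GLS
    arma::mat Bhat = arma::solve(XtX, X.t() * (W - a));
    arma::mat Cr = arma::chol(R0);               // upper
    beta = Bhat + arma::solve(arma::trimatu(Ax), rnorm_mat(p, t)) * Cr;

    // --- (lambda, a) block. First lambda | beta, Sigma_a, R0 with the
    // breeding values integrated out: in the rotated basis the rows of
    // (I - Lambda) Y~ are independent N(X~ beta, d_i Sigma_a + R0), so the
    // free entries have a joint normal conditional; collapsing a removes
    // the lambda / genetic-covariance random walk that cripples mixing.
    arma::mat Yrot = Ut * Y;
    if (m > 0) {
      arma::mat Resid0 = Yrot - Xt_rot * beta;   // c~_i = y~_i - x~_i' beta
      arma::mat Q(m, m, arma::fill::zeros);
      arma::vec rhs(m, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        arma::mat Vinv = arma::inv_sympd(d(i) * Sigma_a + R0);
        arma::vec vc = Vinv * Resid0.row(i).t();
        for (int u = 0; u < m; ++u) {
          int ru = lambda_to_from(u, 0), ju = lambda_to_from(u, 1);
          double yu = Yrot(i, ju);
          rhs(u) += yu * vc(ru);
          for (int v = 0; v <= u; ++v) {
            int rv = lambda_to_from(v, 0), jv = lambda_to_from(v, 1);
            Q(u, v) += Vinv(ru, rv) * yu * Yrot(i, jv);
          }
        }
      }
      Q = arma::symmatl(Q);
      Q.diag() += 1.0 / v_lambda;
      arma::mat Lq = arma::chol(Q, "lower");
      arma::vec mu = arma::solve(arma::trimatu(Lq.t()),
                                 arma::solve(arma::trimatl(Lq), rhs));
      lambda = mu + arma::solve(arma::trimatu(Lq.t()), rnorm_mat(m, 1).col(0));
      Lambda.zeros();
      for (int u = 0; u < m; ++u)
        Lambda(lambda_to_from(u, 0), lambda_to_from(u, 1)) = lambda(u);
      W = Y - Y * Lambda.t();
    }

    // --- a | lambda, beta, Sigma_a, R0 in the rotated basis
    arma::mat R0inv = arma::inv_sympd(R0);
    arma::mat Sainv = arma::inv_sympd(Sigma_a);
    arma::mat Crot = (m > 0) ? arma::mat(Yrot - Yrot * Lambda.t() - Xt_rot * beta)
                             : arma::mat(Yrot - Xt_rot * beta);
    arma::mat atil(n, t);
    for (int i = 0; i < n; ++i) {
      arma::mat P = R0inv + Sainv / d(i);
      arma::mat Lp = arma::chol(P, "lower");
      arma::vec rhs = R0inv * Crot.row(i).t();
      arma::vec mu = arma::solve(arma::trimatu(Lp.t()),
                                 arma::solve(arma::trimatl(Lp), rhs));
      arma::vec z = rnorm_mat(t, 1).col(0);
      atil.row(i) = (mu + arma::solve(arma::trimatu(Lp.t()), z)).t();
    }
    a = U * atil;

    // --- Sigma_a | a
    arma::mat Sq = S_a;
    for (int i = 0; i < n; ++i)
      Sq += atil.row(i).t() * atil.row(i) / d(i);
    Sigma_a = riwish(nu_a + n, Sq);

    // --- R0 | rest (optionally restricted to a diagonal matrix, under
    // which the sparse recursive system is fully identified)
    arma::mat E = W - X * beta - a;
    if (residual_diag) {
      R0.zeros();
      for (int j = 0; j < t; ++j) {
        double s = S_r(j, j) + arma::dot(E.col(j), E.col(j));
        R0(j, j) = s / R::rchisq(nu_r + n);
      }
    } else {
      R0 = riwish(nu_r + n, S_r + E.t() * E);
    }

    if (!Sigma_a.is_finite() || !R0.is_finite())
      stop("divergent covariance draw at iteration %d", it);

    // --- missing phenotypes | rest, from the reduced-form conditional
    bool keep_now = (it > burn) && ((it - burn) % thin == 0);
    if (!miss_trees.empty() || (keep_now && trace_deviance)) {
      arma::mat ImL_inv = (m > 0)
        ? arma::mat(arma::inv(arma::eye(t, t) - Lambda)) : arma::eye(t, t);
      arma::mat Mu = (X * beta + a) * ImL_inv.t();
      arma::mat V = ImL_inv * R0 * ImL_inv.t();
      for (size_t k2 = 0; k2 < miss_trees.size(); ++k2) {
        int i = miss_trees[k2];
        const arma::uvec& mi = mis_idx[i];
        const arma::uvec& oi = obs_idx[i];
        arma::vec mm = Mu.row(i).t();
        if (oi.n_elem == 0) {
          arma::mat Lv = arma::chol(V, "lower");
          arma::vec draw = mm + Lv * rnorm_mat(t, 1).col(0);
          for (int j = 0; j < t; ++j) Y(i, j) = draw(j);
        } else {
          arma::mat Voo = V.submat(oi, oi);
          arma::mat Vmo = V.submat(mi, oi);
          arma::vec yo = Y.row(i).t();
          arma::vec resid = yo(oi) - mm(oi);
          arma::mat Sol = arma::solve(Voo, Vmo.t());      // |o| x |m|
          arma::vec cmu = mm(mi) + Sol.t() * resid;
          arma::mat cV = V.submat(mi, mi) - Vmo * Sol;
          cV = 0.5 * (cV + cV.t());
          arma::mat Lc = arma::chol(cV, "lower");
          arma::vec draw = cmu + Lc * rnorm_mat(mi.n_elem, 1).col(0);
          for (arma::uword q = 0; q < mi.n_elem; ++q) Y(i, mi(q)) = draw(q);
        }
      }
      if (keep_now && trace_deviance) {
        double dev = 0.0;
        for (int i = 0; i < n; ++i)
          dev += tree_deviance(Y.row(i), Mu.row(i), V, obs_idx[i]);
        keep_dev(kept) = dev;
      }
    }

    if (keep_now) {
      keep_Sa.row(kept) = arma::vectorise(Sigma_a).t();
      keep_R0.row(kept) = arma::vectorise(R0).t();
      keep_beta.row(kept) = arma::vectorise(beta).t();
      if (m > 0) keep_lambda.row(kept) = lambda.t();
      a_sum += a;
      a_sum2 += arma::square(a);
      ++kept;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  arma::mat a_mean = a_sum / n_keep;
  arma::mat a_var = a_sum2 / n_keep - arma::square(a_mean);
  a_var.transform([](double x) { return x > 0 ? x : 0.0; });

  return List::create(
    _["Sigma_a"] = keep_Sa, _["R0"] = keep_R0, _["beta"] = keep_beta,
    _["lambda"] = keep_lambda, _["deviance"] = keep_dev,
    _["a_mean"] = a_mean, _["a_sd"] = arma::sqrt(a_var),
    _["n_keep"] = n_keep);
}
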