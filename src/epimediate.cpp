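// Compiled kernels for the per-CpG association scan and the MCP-penalized
// outcome model. Both are called only through the R wrappers, which validate
// inputs and handle naming.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Batched logistic Wald scan: for each column j of M, fit
//   y ~ X0 + M[, j]   (X0 must already contain an intercept column)
// by IRLS and return estimate / SE of the M coefficient. Columns that fail
// (non-convergence, separation, singular information) come back as NaN.
// [[Rcpp::export]]
Rcpp::List cpp_logistic_scan(const arma::mat& X0, const arma::mat& M,
                             const arma::vec& y, const int max_iter = 30,
                             const double tol = 1e-8) {
  const uword n = X0.n_rows, k = X0.n_cols, m = M.n_cols;
  vec est(m), se(m);
  est.fill(datum::nan);
  se.fill(datum::nan);
  mat X(n, k + 1);
  X.cols(0, k - 1) = X0;

  for (uword j = 0; j < m; ++j) {
    X.col(k) = M.col(j);
    vec beta(k + 1, fill::zeros);
    bool ok = false;
    double dev_old = datum::inf;
    for (int it = 0; it < max_iter; ++it) {
      vec eta = X * beta;
      eta = clamp(eta, -30.0, 30.0);
      vec p = 1.0 / (1.0 + exp(-eta));
      vec w = p % (1.0 - p);
      // guard against degenerate weights from quasi-separation
      w = clamp(w, 1e-10, 0.25);
      const double dev =
          -2.0 * sum(y % log(p + 1e-12) + (1.0 - y) % log(1.0 - p + 1e-12));
      mat XtW = X.each_col() % w;
      mat info = X.t() * XtW;
      vec score = X.t() * (y - p);
      vec delta;
      const bool solved = solve(delta, info, score, solve_opts::no_approx);
      if (!solved) break;
      // converge on coefficients, or on the deviance as glm does — on a
      // separation boundary the deviance stabilises while a coefficient
      // keeps drifting, and the fit is still usable (huge SE)
      const bool conv = abs(delta).max() < tol ||
                        std::fabs(dev - dev_old) /
                                (std::fabs(dev) + 0.1) < 1e-8;
      if (conv) {
        mat cov;
        if (inv_sympd(cov, info)) {
          est(j) = beta(k);
          se(j) = std::sqrt(cov(k, k));
          ok = true;
        }
        break;
      }
      dev_old = dev;
      beta += delta;
      if (beta.has_nan()) break;
    }
    if (!ok) {
      est(j) = datum::nan;
      se(j) = datum::nan;
    }
  }
  return Rcpp::List::create(Rcpp::Named("estimate") = est,
                            Rcpp::Named("se") = se);
}

// firm (MCP) coordinate update with adaptive rescaling: minimise
//   (d/2) b^2 - z b + rho(b; lambda, gamma / d)
// so the penalty's concavity scale adapts to the coordinate curvature d
// (Breheny & Huang's device for penalized GLMs). On a standardized
// least-squares design d = 1 and this is the plain firm threshold; for any
// d > 0 and gamma > 1 the coordinate objective stays convex.
static inline double mcp_update(const double z, const double d,
                                const double lambda, const double gamma) {
  const double az = std::fabs(z);
  if (az <= lambda) return 0.0;
  if (az <= gamma * lambda) {
    return std::copysign(az - lambda, z) / (d * (1.0 - 1.0 / gamma));
  }
  return z / d;
}

// MCP-penalized regression over a descending lambda grid with warm starts.
// Xp: penalized columns (caller standardizes), Xu: unpenalized columns
// (including the intercept). family: 0 = gaussian, 1 = binomial.
// The binomial path uses the majorize-minimize quadratic bound with fixed
// weight 0.25, refreshing the working residual once per coordinate cycle.
// Returns (p_pen + p_unpen) x nlambda coefficients (penalized block first)
// and a convergence flag per lambda.
// [[Rcpp::export]]
Rcpp::List cpp_mcp_path(const arma::mat& Xp, const arma::mat& Xu,
                        const arma::vec& y, const arma::vec& lambdas,
                        const double gamma = 3.0, const int family = 0,
                        const int max_iter = 5000, const double tol = 1e-4,
                        const int dfmax = -1) {
  const uword n = Xp.n_rows, p = Xp.n_cols, q = Xu.n_cols,
              nl = lambdas.n_elem;
  mat coefs(p + q, nl, fill::zeros);
  ivec converged(nl, fill::zeros);
  const uword df_cap = (dfmax < 0) ? p : (uword)dfmax;
  uword n_used = 0;
  const double w0 = (family == 1) ? 0.25 : 1.0;

  vec bp(p, fill::zeros), bu(q, fill::zeros);
  if (family == 1) {
    const double ybar = mean(y);
    bu(0) = std::log((ybar + 1e-6) / (1.0 - ybar + 1e-6));
  } else {
    bu(0) = mean(y);
  }

  // curvature terms are constant because the weights are fixed
  vec d_pen(p), d_un(q);
  for (uword j = 0; j < p; ++j) d_pen(j) = w0 * dot(Xp.col(j), Xp.col(j)) / n;
  for (uword j = 0; j < q; ++j) d_un(j) = w0 * dot(Xu.col(j), Xu.col(j)) / n;

  vec eta = Xp * bp + Xu * bu;

  for (uword l = 0; l < nl; ++l) {
    const double lambda = lambdas(l);
    bool conv = false;
    for (int it = 0; it < max_iter; ++it) {
      // refresh the working residual at the current coefficients
      vec r(n);
      if (family == 1) {
        vec mu = 1.0 / (1.0 + exp(-clamp(eta, -30.0, 30.0)));
        r = (y - mu) / w0;
      } else {
        r = y - eta;
      }
      double maxdiff = 0.0;
      for (uword j = 0; j < p; ++j) {
        const double bj = bp(j);
        const double z = w0 * dot(Xp.col(j), r) / n + d_pen(j) * bj;
        const double bnew = mcp_update(z, d_pen(j), lambda, gamma);
        const double delta = bnew - bj;
        if (delta != 0.0) {
          r -= Xp.col(j) * delta;
          eta += Xp.col(j) * delta;
          bp(j) = bnew;
          maxdiff = std::max(maxdiff, std::fabs(delta));
        }
      }
      for (uword j = 0; j < q; ++j) {
        const double bj = bu(j);
        if (d_un(j) < 1e-12) continue;
        const double z = w0 * dot(Xu.col(j), r) / n + d_un(j) * bj;
        const double delta = z / d_un(j) - bj;
        if (delta != 0.0) {
          r -= Xu.col(j) * delta;
          eta += Xu.col(j) * delta;
          bu(j) = z / d_un(j);
          maxdiff = std::max(maxdiff, std::fabs(delta));
        }
      }
      if (maxdiff < tol) {
        conv = true;
        break;
      }
      if (!bp.is_finite() || !bu.is_finite()) break;
    }
    coefs.col(l) = join_cols(bp, bu);
    converged(l) = conv ? 1 : 0;
    n_used = l + 1;
    // stop the path once the model saturates: deeper penalties head into
    // (quasi-)separation for logistic fits and are never selected anyway
    uword df = 0;
    for (uword j = 0; j < p; ++j)
      if (bp(j) != 0.0) ++df;
    if (df > df_cap) break;
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = coefs,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("n_used") = (int)n_used);
}
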