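#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Negative log marginal likelihood of a zero-mean GP with squared-exponential
// kernel, plus its gradient in (log sigma_f, log l, log sigma, dt_2, ..., dt_G).
// theta: (log sigma_f, log l, log sigma [, dt for each non-reference group]).
// group: 1-based group index per observation; ref: 1-based reference group.
// blockDiag: zero out cross-group covariance (independence model).
// withShift: whether theta carries per-group offsets.
// Returns list(value, grad); value = 1e10 signals a failed factorization.
// [[Rcpp::export(name = ".gpNegLogLik")]]
Rcpp::List gpNegLogLik(const arma::vec& theta, const arma::vec& x, const arma::vec& y,
                       const arma::ivec& group, int ngroups, int ref,
                       bool blockDiag, bool withShift, double jitterScale) {
  const uword n = x.n_elem;
  const double sf = std::exp(theta(0));
  const double l  = std::exp(theta(1));
  const double s  = std::exp(theta(2));

  vec dt(ngroups, fill::zeros);
  if (withShift) {
    uword k = 3;
    for (int i = 0; i < ngroups; ++i)
      if (i + 1 != ref) dt(i) = theta(k++);
  }
  vec u = x;
  if (withShift)
    for (uword j = 0; j < n; ++j) u(j) -= dt(group(j) - 1);

  mat D(n, n), E(n, n);
  const double inv2l2 = 1.0 / (2.0 * l * l);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j <= i; ++j) {
      double d = u(i) - u(j);
      double e = std::exp(-d * d * inv2l2);
      if (blockDiag && group(i) != group(j)) e = 0.0;
      D(i, j) = d; D(j, i) = -d;
      E(i, j) = e; E(j, i) = e;
    }

  const double sf2 = sf * sf;
  const double jit = jitterScale * sf2;
  mat K = sf2 * E;
  K.diag() += s * s + jit;

  mat C;
  vec grad(theta.n_elem, fill::zeros);
  if (!chol(C, K, "lower"))
    return Rcpp::List::create(Rcpp::Named("value") = 1e10,
                              Rcpp::Named("grad")  = Rcpp::wrap(grad));

  vec a = solve(trimatu(C.t()), solve(trimatl(C), y));
  double nll = 0.5 * dot(y, a) + accu(log(C.diag())) +
               0.5 * n * std::log(2.0 * M_PI);

  // W = alpha alpha' - K^{-1}; dlogL/dtheta_k = 0.5 * accu(W % dK/dtheta_k)
  mat Kinv = inv_sympd(K);
  mat W = a * a.t() - Kinv;

  double gsf = 0.5 * (2.0 * sf2 * accu(W % E) + 2.0 * jit * trace(W));
  mat EDsq = E % square(D);
  double gl = 0.5 * sf2 * accu(W % EDsq) / (l * l);
  double gs = s * s * trace(W);
  grad(0) = -gsf; grad(1) = -gl; grad(2) = -gs;

  if (withShift) {
    // dK_jk/d dt_i = k_se(j,k) * (u_j - u_k)/l^2 * ([g_j==i] - [g_k==i])
    mat G = (sf2 / (l * l)) * (E % D);
    vec r = sum(W % G, 1);
    uword k = 3;
    for (int i = 0; i < ngroups; ++i) {
      if (i + 1 == ref) continue;
      double gi = 0.0;
      for (uword j = 0; j < n; ++j)
        if (group(j) == i + 1) gi += r(j);
      grad(k++) = -gi;
    }
  }
  return Rcpp::List::create(Rcpp::Named("value") = nll,
                            Rcpp::Named("grad")  = Rcpp::wrap(grad));
}

// Profile log likelihood (up to a constant) of a pairwise shift-model
// covariance over a grid of offsets d: observations in `shiftable` are
// evaluated at x - d. Returns one value per grid point; -inf on failure.
// [[Rcpp::export(name = ".pairProfileGrid")]]
arma::vec pairProfileGrid(const arma::vec& x, const arma::vec& y,
                          const arma::uvec& shiftable, const arma::vec& grid,
                          double sf, double l, double s, double jitter) {
  const uword n = x.n_elem;
  const double sf2 = sf * sf;
  const double inv2l2 = 1.0 / (2.0 * l * l);
  const double diagAdd = s * s + jitter * sf2;
  vec out(grid.n_elem);
  mat K(n, n);
  mat C;
  for (uword g = 0; g < grid.n_elem; ++g) {
    const double d = grid(g);
    for (uword i = 0; i < n; ++i) {
      const double ui = x(i) - (shiftable(i) ? d : 0.0);
      for (uword j = 0; j <= i; ++j) {
        const double uj = x(j) - (shiftable(j) ? d : 0.0);
        const double dd = ui - uj;
        const double v = sf2 * std::exp(-dd * dd * inv2l2);
        K(i, j) = v; K(j, i) = v;
      }
      K(i, i) += diagAdd;
    }
    if (!chol(C, K, "lower")) { out(g) = -datum::inf; continue; }
    vec a = solve(trimatu(C.t()), solve(trimatl(C), y));
    out(g) = -0.5 * dot(y, a) - accu(log(C.diag()));
  }
  return out;
}
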