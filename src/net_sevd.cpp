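// Core alternating solver for the network-constrained sparse
// eigendecomposition (Net-sEVD) of a normalized graph Laplacian.
//
// The objective, for a p x p normalized Laplacian L and rank q,
//
//   min_{A,B} ||L - L B A'||_F^2 + g1 * sum_r ||b_r||_1
//             + g2 * sum_r b_r' P_r b_r ,   A'A = I_q,
//
// is solved by alternating a per-component penalized regression in B
// (coordinate descent on the Gram form) with an orthogonal Procrustes
// update of A from the thin SVD of L'L B.  P_r is the penalty matrix:
// L itself (network penalty), I (ridge), absent, or the sign-adjusted
// S_r L S_r with S_r = diag(sgn(b_r)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// penalty kinds, kept in sync with R-level penalty_config()
enum PenaltyKind { NETWORK = 0, RIDGE = 1, NONE = 2, SIGN_ADJUSTED = 3, DENSE = 4 };

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Minimize b'Qb - 2 c'b + g1*||b||_1 by cyclic coordinate descent.
// Sweeps until the largest coordinate change falls below sweep_tol,
// then verifies the KKT subgradient conditions to kkt_tol and keeps
// sweeping if they are violated.
static vec cd_gram(const mat& Q, const vec& c, double g1, vec beta,
                   double sweep_tol, int max_sweeps, double kkt_tol) {
  const int p = c.n_elem;
  const double thr = g1 / 2.0;
  for (int it = 0; it < max_sweeps; ++it) {
    double del = 0.0;
    for (int j = 0; j < p; ++j) {
      const double qjj = Q(j, j);
      const double old = beta(j);
      if (qjj <= 1e-14) {          // coordinate absent from the quadratic: L1 pins it to 0
        if (old != 0.0) { del = std::max(del, std::fabs(old)); beta(j) = 0.0; }
        continue;
      }
      const double r = c(j) - dot(Q.col(j), beta) + qjj * old;
      const double nb = soft_threshold(r, thr) / qjj;
      if (nb != old) { del = std::max(del, std::fabs(nb - old)); beta(j) = nb; }
    }
    if (del < sweep_tol) {
      // KKT: grad_j = 2(Qb - c)_j; need |grad_j + g1*sgn| small on the
      // active set and |grad_j| <= g1 + tol on the zero set.
      vec grad = 2.0 * (Q * beta - c);
      double viol = 0.0;
      for (int j = 0; j < p; ++j) {
        if (Q(j, j) <= 1e-14) continue;
        if (beta(j) != 0.0)
          viol = std::max(viol, std::fabs(grad(j) + g1 * (beta(j) > 0 ? 1.0 : -1.0)));
        else
          viol = std::max(viol, std::max(0.0, std::fabs(grad(j)) - g1));
      }
      if (viol <= kkt_tol) break;
    }
  }
  return beta;
}

// Unpenalized limit (g1 = 0): minimum-norm least-squares through the
// symmetric eigendecomposition of Q, dropping eigenvalues below a
// relative rank cutoff (LU-based solves are unreliable on the exactly
// singular Gram matrices that Laplacians with zero eigenvalues produce).
static vec solve_quadratic(const mat& Q, const vec& c, bool* deficient = nullptr) {
  vec eval; mat evec;
  eig_sym(eval, evec, symmatu(Q));
  const double cutoff = std::max(eval.max(), 0.0) * 1e-10;
  vec proj = evec.t() * c;
  int rank = 0;
  for (uword i = 0; i < eval.n_elem; ++i) {
    if (eval(i) > cutoff) { proj(i) /= eval(i); ++rank; }
    else proj(i) = 0.0;
  }
  if (deficient) *deficient = rank < static_cast<int>(eval.n_elem);
  return evec * proj;
}

static mat penalty_matrix(int kind, const mat& L, const vec& beta_r) {
  const int p = L.n_rows;
  switch (kind) {
  case NETWORK: return L;
  case RIDGE:   return eye(p, p);
  case SIGN_ADJUSTED: {
    vec s(p);
    for (int i = 0; i < p; ++i) s(i) = beta_r(i) < 0 ? -1.0 : 1.0;  // sgn(0) := +1
    return L % (s * s.t());
  }
  default: return zeros(p, p);
  }
}

// [[Rcpp::export]]
List cpp_penalized_solve(const arma::mat& L, const arma::vec& z,
                         double gamma1, double gamma2, const arma::mat& P,
                         double kkt_tol, int max_sweeps) {
  const mat Q = L.t() * L + gamma2 * P;
  const vec c = L.t() * z;
  vec beta;
  bool fallback = false;
  if (gamma1 == 0.0) {
    beta = solve_quadratic(Q, c, &fallback);
  } else {
    beta = cd_gram(Q, c, gamma1, zeros<vec>(c.n_elem), 1e-12, max_sweeps, kkt_tol);
  }
  const double obj = dot(beta, Q * beta) - 2.0 * dot(c, beta) + dot(z, z)
    + gamma1 * accu(abs(beta));
  return List::create(_["beta"] = beta, _["objective"] = obj,
                      _["pinv_fallback"] = fallback);
}

// [[Rcpp::export]]
List cpp_net_sevd(const arma::mat& L, int q, double gamma1, double gamma2,
                  int penalty_kind, double tol, int max_iter,
                  double cd_tol, int cd_max_sweeps) {
  const int p = L.n_rows;
  const mat Ls = symmatu(L);
  const mat G = Ls.t() * Ls;

  // Step 1: initialize A (and B, used only for initial signs in the
  // sign-adjusted variant) at the dense eigenvectors, eigenvalues
  // descending, each vector's largest-magnitude entry made positive.
  vec eval; mat evec;
  eig_sym(eval, evec, Ls);
  mat A(p, q);
  for (int r = 0; r < q; ++r) {
    vec v = evec.col(p - 1 - r);
    if (v(abs(v).index_max()) < 0) v = -v;
    A.col(r) = v;
  }
  mat B = A;

  const bool unpenalized = (gamma1 == 0.0);
  std::vector<double> obj_trace;
  bool converged = false;
  int iter = 0;
  vec pen_term(q, fill::zeros);

  for (iter = 1; iter <= max_iter; ++iter) {
    // Step 2: per-component penalized regression with target z_r = L a_r,
    // in Gram form: c_r = L'L a_r, Q_r = L'L + g2 P_r.
    mat Bnew(p, q);
    for (int r = 0; r < q; ++r) {
      const vec c = G * A.col(r);
      mat Q = G;
      if (gamma2 > 0.0 && penalty_kind != NONE && penalty_kind != DENSE)
        Q += gamma2 * penalty_matrix(penalty_kind, Ls, B.col(r));
      vec beta;
      if (unpenalized) beta = solve_quadratic(Q, c);
      else beta = cd_gram(Q, c, gamma1, B.col(r), cd_tol, cd_max_sweeps, 1e-7);
      Bnew.col(r) = beta;
      pen_term(r) = (penalty_kind == NONE || penalty_kind == DENSE) ? 0.0
        : dot(beta, penalty_matrix(penalty_kind, Ls, beta) * beta);
    }
    const double delta = abs(Bnew - B).max();
    B = Bnew;

    // Step 3: Procrustes update, A = U V' from the thin SVD of L'L B.
    mat U, V; vec s;
    svd_econ(U, s, V, G * B);
    A = U.cols(0, q - 1) * V.t();

    obj_trace.push_back(accu(square(Ls - Ls * B * A.t()))
                        + gamma1 * accu(abs(B)) + gamma2 * accu(pen_term));
    if (delta < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  // Steps 5-6: normalize loadings, eigenvalues from diag(V'LV); an
  // all-zero component contributes v_r = 0, lambda_r = 0.
  mat Vn(p, q, fill::zeros);
  for (int r = 0; r < q; ++r) {
    const double nb = norm(B.col(r));
    // loadings at numerical-noise scale are the all-zero component
    if (nb > 1e-8) Vn.col(r) = B.col(r) / nb;
  }
  const mat Lam = Vn.t() * Ls * Vn;
  vec lam = Lam.diag();
  const double offdiag = norm(Lam - diagmat(lam), "fro");

  const uvec ord = sort_index(lam, "descend");
  lam = vec(lam(ord));
  const mat A_ord = A.cols(ord), B_ord = B.cols(ord), V_ord = Vn.cols(ord);

  return List::create(
    _["rotation"] = A_ord, _["loadings"] = B_ord,
    _["vectors"] = V_ord, _["eigenvalues"] = lam,
    _["working_targets"] = mat(Ls * A_ord),
    _["n_iterations"] = iter, _["converged"] = converged,
    _["objective_trace"] = obj_trace, _["offdiagonal_mass"] = offdiag);
}
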