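#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Bounded-variable two-phase primal simplex:
//   min c'x   s.t.  A x = b,  lb <= x <= ub
// lb must be finite; ub may be +Inf. Bland's rule throughout (smallest
// entering index, smallest leaving basis index), so the method terminates
// under degeneracy and is fully deterministic.
//
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

static const double TOL_RC = 1e-9;    // reduced-cost threshold
static const double TOL_PIV = 1e-9;   // minimum pivot magnitude
static const double TOL_FEAS = 1e-7;  // phase-1 feasibility threshold

namespace {

struct SimplexState {
  arma::mat T;                 // m x N tableau, B^{-1} * A_all
  arma::vec beta;              // current basic values (length m)
  std::vector<int> basis;      // column in basis for each row
  std::vector<bool> in_basis;  // length N
  std::vector<int> stat;       // nonbasic at lower (0) or upper (1)
  arma::vec U;                 // variable upper widths (z in [0, U])
  int m, N;
};

// One simplex phase with cost vector d. Returns 0 optimal, 2 unbounded,
// 3 iteration limit.
int run_phase(SimplexState &S, const arma::vec &d, int max_iter) {
  const int m = S.m, N = S.N;
  arma::vec dB(m);
  for (int it = 0; it < max_iter; ++it) {
    for (int i = 0; i < m; ++i) dB[i] = d[S.basis[i]];
    // entering: Bland — smallest eligible index
    int jin = -1, dir = 0;
    for (int j = 0; j < N; ++j) {
      if (S.in_basis[j] || S.U[j] <= TOL_PIV) continue;
      double rj = d[j] - arma::dot(dB, S.T.col(j));
      if (S.stat[j] == 0 && rj < -TOL_RC) { jin = j; dir = +1; break; }
      if (S.stat[j] == 1 && rj > TOL_RC)  { jin = j; dir = -1; break; }
    }
    if (jin < 0) return 0;  // optimal
    // ratio test: entering moves by t >= 0 in direction dir
    double tmax = S.U[jin];           // bound-flip limit (may be Inf)
    int rleave = -1, leave_to = 0;    // 0 -> lower, 1 -> upper
    double tbest = tmax;
    for (int i = 0; i < m; ++i) {
      double a = dir * S.T(i, jin);
      double lim = arma::datum::inf;
      int to = 0;
      if (a > TOL_PIV) {
        lim = S.beta[i] / a; to = 0;
      } else if (a < -TOL_PIV && std::isfinite(S.U[S.basis[i]])) {
        lim = (S.U[S.basis[i]] - S.beta[i]) / (-a); to = 1;
      } else {
        continue;
      }
      if (lim < 0) lim = 0;  // numerical guard on degenerate rows
      if (lim < tbest - 1e-12 ||
          (lim < tbest + 1e-12 && rleave >= 0 &&
           S.basis[i] < S.basis[rleave])) {
        tbest = lim; rleave = i; leave_to = to;
      }
    }
    if (!std::isfinite(tbest)) return 2;  // unbounded
    if (rleave < 0 || S.U[jin] < tbest + 1e-12) {
      // bound flip, no basis change
      double t = S.U[jin];
      if (!std::isfinite(t)) return 2;
      for (int i = 0; i < m; ++i) S.beta[i] -= dir * S.T(i, jin) * t;
      S.stat[jin] = 1 - S.stat[jin];
      continue;
    }
    // pivot: jin enters, basis[rleave] leaves
    double t = tbest;
    int lcol = S.basis[rleave];
    for (int i = 0; i < m; ++i) S.beta[i] -= dir * S.T(i, jin) * t;
    double z_enter = (S.stat[jin] == 0) ? t : S.U[jin] - t;
    double piv = S.T(rleave, jin);
    S.T.row(rleave) /= piv;
    double br = z_enter;
    for (int i = 0; i < m; ++i) {
      if (i == rleave) continue;
      double f = S.T(i, jin);
      if (f != 0.0) S.T.row(i) -= f * S.T.row(rleave);
    }
    S.beta[rleave] = br;
    S.in_basis[lcol] = false;
    S.stat[lcol] = leave_to;
    S.in_basis[jin] = true;
    S.basis[rleave] = jin;
  }
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_cpp")]]
Rcpp::List simplex_cpp(const arma::mat &A, const arma::vec &b,
                       const arma::vec &c, const arma::vec &lb,
                       const arma::vec &ub, int max_iter = 0) {
  const int m = A.n_rows, n = A.n_cols;
  if (m < 1 || n < 1) Rcpp::stop("simplex: need at least one row and column");
  if (max_iter <= 0) max_iter = 20000 + 200 * (m + n);
  for (int j = 0; j < n; ++j) {
    if (!std::isfinite(lb[j]))
      Rcpp::stop("simplex: lower bounds must be finite");
    if (ub[j] < lb[j] - 1e-12)
      return Rcpp::List::create(Rcpp::Named("status") = 1);
  }
  // shift z = x - lb in [0, U]
  arma::vec U0 = ub - lb;
  arma::vec b2 = b - A * lb;
  SimplexState S;
  S.m = m; S.N = n + m;
  S.T.set_size(m, S.N);
  S.T.cols(0, n - 1) = A;
  S.T.cols(n, S.N - 1) = arma::eye(m, m);
  S.beta = b2;
  S.U.set_size(S.N);
  for (int j = 0; j < n; ++j) S.U[j] = std::max(U0[j], 0.0);
  for (int j = n; j < S.N; ++j) S.U[j] = arma::datum::inf;
  // flip rows so beta >= 0 (artificial columns stay +1 on the diagonal)
  for (int i = 0; i < m; ++i) {
    if (S.beta[i] < 0) {
      S.T.row(i) = -S.T.row(i);
      S.T(i, n + i) = 1.0;
      S.beta[i] = -S.beta[i];
    }
  }
  S.basis.resize(m);
  S.in_basis.assign(S.N, false);
  S.stat.assign(S.N, 0);
  for (int i = 0; i < m; ++i) { S.basis[i] = n + i; S.in_basis[n + i] = true; }

  // phase 1
  arma::vec d1 = arma::zeros(S.N);
  for (int j = n; j < S.N; ++j) d1[j] = 1.0;
  int st = run_phase(S, d1, max_iter);
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
  double art = 0.0;
  for (int i = 0; i < m; ++i)
    if (S.basis[i] >= n) art += S.beta[i];
  if (art > TOL_FEAS)
    return Rcpp::List::create(Rcpp::Named("status") = 1);
  for (int j = n; j < S.N; ++j) S.U[j] = 0.0;  // freeze artificials

  // phase 2
  arma::vec d2 = arma::zeros(S.N);
  for (int j = 0; j < n; ++j) d2[j] = c[j];
  st = run_phase(S, d2, max_iter);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = st);

  // recover solution
  arma::vec z = arma::zeros(n);
  for (int j = 0; j < n; ++j)
    if (!S.in_basis[j] && S.stat[j] == 1) z[j] = S.U[j];
  for (int i = 0; i < m; ++i)
    if (S.basis[i] < n) z[S.basis[i]] = S.beta[i];
  arma::vec x = z + lb;
  for (int j = 0; j < n; ++j) {  // clamp tiny violations
    if (x[j] < lb[j]) x[j] = lb[j];
    if (std::isfinite(ub[j]) && x[j] > ub[j]) x[j] = ub[j];
  }
  double obj = arma::dot(c, x);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = obj);
}
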