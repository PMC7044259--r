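// Bounded-variable two-phase primal simplex for flux balance problems:
//   min c'x  s.t.  A x = b,  l <= x <= u
// Dense arithmetic; problem sizes here are tiny (tens of reactions), so a
// fresh basis factorization per iteration is cheap and numerically safe.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

const int NB_LB = 0, NB_UB = 1, NB_FREE = 2, BASIC = 3;

struct SimplexState {
  mat A;            // m x (n + m), structural + artificial columns
  vec b, c, l, u;   // length n + m
  int m, n;
  std::vector<int> status;    // per column
  std::vector<int> basis;     // length m, column index basic in row i
  vec x;                      // current point, length n + m
};

// value a nonbasic column sits at
double nbValue(const SimplexState& st, int j) {
  if (st.status[j] == NB_LB) return st.l[j];
  if (st.status[j] == NB_UB) return st.u[j];
  return 0.0;
}

// recompute basic values from the nonbasic ones; returns false on a
// numerically singular basis
bool recomputeBasics(SimplexState& st) {
  vec rhs = st.b;
  for (int j = 0; j < st.m + st.n; ++j) {
    if (st.status[j] != BASIC) {
      double v = nbValue(st, j);
      st.x[j] = v;
      if (v != 0.0) rhs -= st.A.col(j) * v;
    }
  }
  mat B(st.m, st.m);
  for (int i = 0; i < st.m; ++i) B.col(i) = st.A.col(st.basis[i]);
  vec xB;
  if (!solve(xB, B, rhs, solve_opts::no_approx)) return false;
  for (int i = 0; i < st.m; ++i) st.x[st.basis[i]] = xB[i];
  return true;
}

// one simplex phase on the current state; cost vector taken from st.c.
// returns 0 optimal, 2 unbounded, 3 iteration trouble, 4 singular basis
int runPhase(SimplexState& st, int maxIter, double tol) {
  const int ncol = st.n + st.m;
  int blandAfter = std::max(200, 20 * ncol);
  for (int iter = 0; iter < maxIter; ++iter) {
    bool bland = iter > blandAfter;
    mat B(st.m, st.m);
    for (int i = 0; i < st.m; ++i) B.col(i) = st.A.col(st.basis[i]);
    vec cB(st.m);
    for (int i = 0; i < st.m; ++i) cB[i] = st.c[st.basis[i]];
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 4;

    // pricing
    int enter = -1;
    double bestViol = tol;
    int dir = 0;  // +1 increase, -1 decrease
    for (int j = 0; j < ncol; ++j) {
      if (st.status[j] == BASIC) continue;
      if (st.l[j] == st.u[j]) continue;  // fixed, cannot move
      double dj = st.c[j] - dot(y, st.A.col(j));
      double viol = 0.0;
      int d = 0;
      if (st.status[j] == NB_LB && dj < -tol) { viol = -dj; d = 1; }
      else if (st.status[j] == NB_UB && dj > tol) { viol = dj; d = -1; }
      else if (st.status[j] == NB_FREE && std::fabs(dj) > tol) {
        viol = std::fabs(dj); d = dj < 0 ? 1 : -1;
      }
      if (d != 0) {
        if (bland) { enter = j; dir = d; break; }
        if (viol > bestViol) { bestViol = viol; enter = j; dir = d; }
      }
    }
    if (enter < 0) return 0;  // optimal

    vec w;
    if (!solve(w, B, st.A.col(enter), solve_opts::no_approx)) return 4;

    // ratio test: step t >= 0 along x_enter += dir * t, x_basic -= dir * t * w
    double tEnter = datum::inf;
    if (std::isfinite(st.u[enter]) && std::isfinite(st.l[enter]))
      tEnter = st.u[enter] - st.l[enter];
    double tMax = tEnter;
    int leave = -1;      // row index of leaving basic variable
    int leaveTo = NB_LB;
    for (int i = 0; i < st.m; ++i) {
      double delta = -dir * w[i];   // d x_basis[i] / d t
      if (std::fabs(delta) < 1e-11) continue;
      int jb = st.basis[i];
      double lim;
      int to;
      if (delta > 0) { lim = (st.u[jb] - st.x[jb]) / delta; to = NB_UB; }
      else           { lim = (st.l[jb] - st.x[jb]) / delta; to = NB_LB; }
      if (lim < -1e-9) lim = 0.0;   // numerical guard on slight infeasibility
      if (lim < tMax - 1e-12 ||
          (bland && leave >= 0 && std::fabs(lim - tMax) <= 1e-12 &&
           jb < st.basis[leave])) {
        tMax = lim; leave = i; leaveTo = to;
      }
    }
    if (!std::isfinite(tMax)) return 2;  // unbounded
    if (tMax < 0) tMax = 0;

    // apply the step
    double xe = st.x[enter] + dir * tMax;
    for (int i = 0; i < st.m; ++i) st.x[st.basis[i]] -= dir * tMax * w[i];
    st.x[enter] = xe;

    if (leave < 0) {
      // bound flip of the entering variable
      st.status[enter] = (dir > 0) ? NB_UB : NB_LB;
    } else {
      int jb = st.basis[leave];
      st.status[jb] = leaveTo;
      st.x[jb] = (leaveTo == NB_UB) ? st.u[jb] : st.l[jb];
      st.status[enter] = BASIC;
      st.basis[leave] = enter;
    }
  }
  return 3;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".simplexSolve")]]
Rcpp::List simplexSolve(const arma::mat& A, const arma::vec& b,
                        const arma::vec& cost, const arma::vec& lower,
                        const arma::vec& upper, bool maximize,
                        double tol = 1e-9, int maxIter = 50000) {
  const int m = A.n_rows, n = A.n_cols;
  SimplexState st;
  st.m = m; st.n = n;
  st.A = join_rows(A, eye(m, m));
  st.b = b;
  st.c = vec(n + m, fill::zeros);
  st.l = vec(n + m, fill::zeros);
  st.u = vec(n + m, fill::zeros);
  st.x = vec(n + m, fill::zeros);
  st.status.assign(n + m, NB_LB);
  st.basis.assign(m, 0);

  for (int j = 0; j < n; ++j) {
    st.l[j] = lower[j];
    st.u[j] = upper[j];
    if (lower[j] > upper[j] + 1e-12)
      return Rcpp::List::create(Rcpp::Named("status") = "infeasible");
    if (std::isfinite(lower[j])) {
      // start at the bound closer to zero to keep phase-1 residuals small
      bool atL = !std::isfinite(upper[j]) ||
                 std::fabs(lower[j]) <= std::fabs(upper[j]);
      st.status[j] = atL ? NB_LB : NB_UB;
    } else if (std::isfinite(upper[j])) {
      st.status[j] = NB_UB;
    } else {
      st.status[j] = NB_FREE;
    }
    st.x[j] = nbValue(st, j);
  }

  // artificial columns: signed identity, bounds [0, inf), phase-1 cost 1
  vec resid = b;
  for (int j = 0; j < n; ++j)
    if (st.x[j] != 0.0) resid -= A.col(j) * st.x[j];
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    if (resid[i] < 0) st.A.col(j) = -st.A.col(j);
    st.l[j] = 0.0; st.u[j] = datum::inf;
    st.c[j] = 1.0;
    st.status[j] = BASIC;
    st.basis[i] = j;
    st.x[j] = std::fabs(resid[i]);
  }

  int ret = runPhase(st, maxIter, tol);
  if (ret == 4 || ret == 3)
    return Rcpp::List::create(Rcpp::Named("status") = "numerical");
  double phase1 = 0.0;
  for (int i = 0; i < m; ++i) phase1 += st.x[n + i] > 0 ? st.x[n + i] : 0.0;
  for (int j = n; j < n + m; ++j)
    if (st.status[j] != BASIC) phase1 += st.x[j];
  double feasTol = std::max(1e-7, tol * 100);
  if (phase1 > feasTol)
    return Rcpp::List::create(Rcpp::Named("status") = "infeasible");

  // phase 2: freeze artificials at zero, switch to the real objective
  for (int j = n; j < n + m; ++j) { st.l[j] = 0.0; st.u[j] = 0.0; st.c[j] = 0.0; }
  for (int j = 0; j < n; ++j) st.c[j] = maximize ? -cost[j] : cost[j];
  if (!recomputeBasics(st))
    return Rcpp::List::create(Rcpp::Named("status") = "numerical");
  ret = runPhase(st, maxIter, tol);
  if (ret == 2)
    return Rcpp::List::create(Rcpp::Named("status") = "unbounded");
  if (ret != 0)
    return Rcpp::List::create(Rcpp::Named("status") = "numerical");

  if (!recomputeBasics(st))
    return Rcpp::List::create(Rcpp::Named("status") = "numerical");
  vec xs = st.x.subvec(0, n - 1);
  double obj = dot(cost.subvec(0, n - 1), xs);
  return Rcpp::List::create(
      Rcpp::Named("status") = "optimal",
      Rcpp::Named("x") = xs,
      Rcpp::Named("objective") = obj);
}
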