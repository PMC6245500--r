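// Bounded-variable two-phase primal simplex, dense tableau.
//
// Solves   maximize c'x  subject to  A x = b,  lb <= x <= ub
// with possibly infinite bounds. Written for the flux balance problems this
// package generates: a few hundred well-scaled rows/columns, b mostly zero.
// Phase I starts from the bound of each variable closest to zero and uses one
// signed artificial per row; Phase II locks artificials at zero. Degeneracy is
// handled by switching to Bland's rule after a run of zero-step pivots.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double PINF = std::numeric_limits<double>::infinity();

struct Tab {
  int m, n, N;                 // rows, structural cols, total cols (n + m artificials)
  std::vector<double> D;       // m x N tableau, row-major: B^{-1} * [A | Art]
  std::vector<double> lb, ub;  // per-column bounds (length N)
  std::vector<double> val;     // current value of each NONBASIC column
  std::vector<int> stat;       // 0 at-lower (free vars sit at 0), 1 at-upper, 2 basic
  std::vector<int> basis;      // length m, column index of basic var per row
  std::vector<double> xB;      // basic values per row

  double &at(int i, int j) { return D[(size_t)i * N + j]; }
};

// One simplex phase. cvec has length N. Columns j with enterable[j]==0 never
// enter the basis. Returns 0 optimal, 2 unbounded, 3 iteration limit.
static int run_phase(Tab &T, const std::vector<double> &cvec,
                     const std::vector<char> &enterable,
                     double tol, int maxit) {
  const int m = T.m, N = T.N;
  bool bland = false;
  int degen_run = 0;

  std::vector<double> d(N);      // reduced costs, updated incrementally
  std::vector<double> cB(m);
  auto recompute_d = [&]() {
    for (int j = 0; j < N; ++j) d[j] = cvec[j];
    for (int i = 0; i < m; ++i) {
      const double ci = cvec[T.basis[i]];
      if (ci == 0.0) continue;
      const double *row = &T.D[(size_t)i * N];
      for (int j = 0; j < N; ++j) d[j] -= ci * row[j];
    }
  };
  recompute_d();

  for (int iter = 0; iter < maxit; ++iter) {
    if (iter > 0 && iter % 500 == 0) recompute_d();  // numerical hygiene

    // entering column
    int jin = -1, dir = 0;
    double best = tol;
    for (int j = 0; j < N; ++j) {
      if (T.stat[j] == 2 || !enterable[j]) continue;
      const bool lo_fin = std::isfinite(T.lb[j]);
      const bool up_fin = std::isfinite(T.ub[j]);
      const bool freev = !lo_fin && !up_fin;
      int dj = 0;
      if (T.stat[j] == 0) {                 // at lower bound (or free at 0)
        if (d[j] > tol) dj = +1;
        else if (freev && d[j] < -tol) dj = -1;
      } else {                              // at upper bound
        if (d[j] < -tol) dj = -1;
      }
      if (dj == 0) continue;
      if (bland) { jin = j; dir = dj; break; }
      const double mag = std::fabs(d[j]);
      if (mag > best) { best = mag; jin = j; dir = dj; }
    }
    if (jin < 0) return 0;  // optimal

    // ratio test: entering moves by t in direction dir, basic i changes by
    // -dir * D(i,jin) * t
    double t_own = PINF;     // step at which entering hits its opposite bound
    if (std::isfinite(T.lb[jin]) && std::isfinite(T.ub[jin]))
      t_own = T.ub[jin] - T.lb[jin];
    double t_row = PINF;     // tightest limit imposed by a basic variable
    int leave = -1;          // row index of leaving variable
    int leave_to = 0;        // 0 -> leaves at its lower bound, 1 -> upper
    double piv_mag = 0.0;

    for (int i = 0; i < m; ++i) {
      const double w = dir * T.at(i, jin);
      double lim; int to;
      if (w > tol) {
        const double lo = T.lb[T.basis[i]];
        if (!std::isfinite(lo)) continue;
        lim = (T.xB[i] - lo) / w; to = 0;
      } else if (w < -tol) {
        const double up = T.ub[T.basis[i]];
        if (!std::isfinite(up)) continue;
        lim = (T.xB[i] - up) / w; to = 1;   // both factors <= 0
      } else continue;
      if (lim < 0.0) lim = 0.0;             // round-off guard
      if (lim < t_row - tol) {
        t_row = lim; leave = i; leave_to = to; piv_mag = std::fabs(w);
      } else if (lim <= t_row + tol) {      // tie within tolerance
        const bool take = bland ? (leave < 0 || T.basis[i] < T.basis[leave])
                                : (std::fabs(w) > piv_mag);
        if (take) {
          if (lim < t_row) t_row = lim;
          leave = i; leave_to = to; piv_mag = std::fabs(w);
        }
      }
    }

    if (!std::isfinite(t_own) && !std::isfinite(t_row))
      return 2;  // unbounded ray

    const bool flip = t_own < t_row - tol;   // own bound strictly tightest
    const double tstep = flip ? t_own : t_row;

    if (tstep <= tol) { if (++degen_run > 200) bland = true; }
    else degen_run = 0;

    // update basic values
    for (int i = 0; i < m; ++i) T.xB[i] -= dir * T.at(i, jin) * tstep;

    if (flip) {
      T.val[jin] = (T.stat[jin] == 0) ? T.ub[jin] : T.lb[jin];
      T.stat[jin] = 1 - T.stat[jin];
      continue;
    }

    const double enter_val = T.val[jin] + dir * tstep;
    const int jout = T.basis[leave];
    T.val[jout] = leave_to == 0 ? T.lb[jout] : T.ub[jout];
    T.stat[jout] = leave_to;

    // pivot on (leave, jin)
    const double piv = T.at(leave, jin);
    double *prow = &T.D[(size_t)leave * N];
    const double inv = 1.0 / piv;
    for (int j = 0; j < N; ++j) prow[j] *= inv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      const double f = T.at(i, jin);
      if (f == 0.0) continue;
      double *row = &T.D[(size_t)i * N];
      for (int j = 0; j < N; ++j) row[j] -= f * prow[j];
      T.at(i, jin) = 0.0;   // kill round-off in the pivot column
    }
    prow[jin] = 1.0;
    T.basis[leave] = jin;
    T.stat[jin] = 2;
    T.xB[leave] = enter_val;

    // incremental reduced-cost update: d <- d - d[jin] * (pivoted row)
    const double dpiv = d[jin];
    if (dpiv != 0.0)
      for (int j = 0; j < N; ++j) d[j] -= dpiv * prow[j];
    d[jin] = 0.0;
  }
  return 3;
}

// [[Rcpp::export(name = ".cpp_simplex")]]
List cpp_simplex(NumericVector obj, NumericMatrix A, NumericVector rhs,
                 NumericVector lower, NumericVector upper,
                 double tol = 1e-9, int maxit = 0) {
  const int m = A.nrow(), n = A.ncol();
  if (obj.size() != n || lower.size() != n || upper.size() != n ||
      rhs.size() != m)
    stop("inconsistent LP dimensions");
  if (maxit <= 0) maxit = 200 * (m + n) + 5000;

  Tab T;
  T.m = m; T.n = n; T.N = n + m;
  T.D.assign((size_t)m * T.N, 0.0);
  T.lb.resize(T.N); T.ub.resize(T.N);
  T.val.assign(T.N, 0.0);
  T.stat.assign(T.N, 0);
  T.basis.resize(m);
  T.xB.assign(m, 0.0);

  for (int j = 0; j < n; ++j) {
    T.lb[j] = lower[j]; T.ub[j] = upper[j];
    if (T.lb[j] > T.ub[j] + 1e-12)
      stop("lower bound exceeds upper bound at column %d", j + 1);
    double v;
    const bool fl = std::isfinite(T.lb[j]), fu = std::isfinite(T.ub[j]);
    if (fl && fu) v = (std::fabs(T.lb[j]) <= std::fabs(T.ub[j])) ? T.lb[j] : T.ub[j];
    else if (fl) v = T.lb[j];
    else if (fu) v = T.ub[j];
    else v = 0.0;
    T.val[j] = v;
    T.stat[j] = (fu && v == T.ub[j] && !(fl && T.lb[j] == T.ub[j])) ? 1 : 0;
    for (int i = 0; i < m; ++i) T.at(i, j) = A(i, j);
  }

  // residuals and signed artificial columns; initial basis = artificials
  for (int i = 0; i < m; ++i) {
    double r = rhs[i];
    for (int j = 0; j < n; ++j) r -= A(i, j) * T.val[j];
    const double sg = (r < 0.0) ? -1.0 : 1.0;
    const int ja = n + i;
    T.at(i, ja) = sg;
    T.lb[ja] = 0.0; T.ub[ja] = PINF;
    T.basis[i] = ja; T.stat[ja] = 2;
    T.xB[i] = std::fabs(r);
    if (sg < 0) {  // scale row so that B^{-1} is applied (B = diag(sg))
      double *row = &T.D[(size_t)i * T.N];
      for (int j = 0; j < T.N; ++j) row[j] = -row[j];
      T.at(i, ja) = 1.0;
    }
  }

  std::vector<char> enterable(T.N, 1);
  std::vector<double> c1(T.N, 0.0);
  for (int i = 0; i < m; ++i) c1[n + i] = -1.0;  // maximize -sum(artificials)

  int st = run_phase(T, c1, enterable, tol, maxit);
  if (st == 3) return List::create(_["status"] = 3);

  double infeas = 0.0;
  for (int i = 0; i < m; ++i)
    if (T.basis[i] >= n) infeas += T.xB[i];
  for (int j = n; j < T.N; ++j)
    if (T.stat[j] != 2) infeas += T.val[j];
  if (infeas > 1e-7 * (1.0 + std::fabs(infeas)))
    return List::create(_["status"] = 1);

  // Phase II: artificials frozen at zero and barred from entering
  for (int j = n; j < T.N; ++j) { T.ub[j] = 0.0; enterable[j] = 0; }
  std::vector<double> c2(T.N, 0.0);
  for (int j = 0; j < n; ++j) c2[j] = obj[j];

  st = run_phase(T, c2, enterable, tol, maxit);
  if (st == 2) return List::create(_["status"] = 2);
  if (st == 3) return List::create(_["status"] = 3);

  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = T.val[j];
  for (int i = 0; i < m; ++i)
    if (T.basis[i] < n) x[T.basis[i]] = T.xB[i];
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(lower[j]) && x[j] < lower[j]) x[j] = lower[j];
    if (std::isfinite(upper[j]) && x[j] > upper[j]) x[j] = upper[j];
  }
  double z = 0.0, resid = 0.0;
  for (int j = 0; j < n; ++j) z += obj[j] * x[j];
  for (int i = 0; i < m; ++i) {
    double s = rhs[i];
    for (int j = 0; j < n; ++j) s -= A(i, j) * x[j];
    resid = std::max(resid, std::fabs(s));
  }
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = z,
                      _["residual"] = resid);
}
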