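// Sparse EM-REML engine for the animal model with maternal genetic effects.
//
// Henderson's mixed-model equations C* theta = W'y / s2e with
//   C* = W'W / s2e + blockdiag(0_p, Ainv / s2a, Ainv / s2m)
// are refactorized each EM iteration by a sparse LDL' decomposition on a
// fixed fill-reducing permutation.  The EM expectation step needs the
// elements of (C*)^-1 on the sparsity pattern of A-inverse only; these are
// obtained exactly by the Takahashi selected-inverse recursion on the
// pattern of L.  The restricted log-likelihood comes from the standard
// identity  log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C*|.
//
// LDL symbolic/numeric factorization follows the classic up-looking
// elimination-tree algorithm (Davis, "Direct Methods for Sparse Linear
// Systems").

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- sparse LDL on upper-triangular CSC input ------------------------------

struct LDL {
  int n;
  std::vector<int> parent, Lp, Lnz, Li, flag, pattern;
  std::vector<double> Lx, D, Y;

  void symbolic(const int *Ap, const int *Ai) {
    parent.assign(n, -1);
    Lnz.assign(n, 0);
    flag.assign(n, -1);
    for (int k = 0; k < n; k++) {
      parent[k] = -1;
      flag[k] = k;
      for (int p = Ap[k]; p < Ap[k + 1]; p++) {
        int i = Ai[p];
        if (i >= k) continue;
        for (; flag[i] != k; i = parent[i]) {
          if (parent[i] == -1) parent[i] = k;
          Lnz[i]++;
          flag[i] = k;
        }
      }
    }
    Lp.assign(n + 1, 0);
    for (int k = 0; k < n; k++) Lp[k + 1] = Lp[k] + Lnz[k];
    Li.assign(Lp[n], 0);
    Lx.assign(Lp[n], 0.0);
    D.assign(n, 0.0);
    Y.assign(n, 0.0);
    pattern.assign(n, 0);
  }

  // returns false on a zero pivot
  bool numeric(const int *Ap, const int *Ai, const double *Ax) {
    std::vector<int> stack(n);
    std::fill(flag.begin(), flag.end(), -1);
    std::fill(Lnz.begin(), Lnz.end(), 0);
    for (int k = 0; k < n; k++) {
      Y[k] = 0.0;
      int top = n;
      flag[k] = k;
      for (int p = Ap[k]; p < Ap[k + 1]; p++) {
        int i = Ai[p];
        if (i > k) continue;
        Y[i] += Ax[p];
        int len = 0;
        for (; flag[i] != k; i = parent[i]) {
          pattern[len++] = i;
          flag[i] = k;
        }
        while (len > 0) stack[--top] = pattern[--len];
      }
      D[k] = Y[k];
      Y[k] = 0.0;
      for (int s = top; s < n; s++) {
        int i = stack[s];
        double yi = Y[i];
        Y[i] = 0.0;
        int p2 = Lp[i] + Lnz[i];
        for (int p = Lp[i]; p < p2; p++) Y[Li[p]] -= Lx[p] * yi;
        double lki = yi / D[i];
        D[k] -= lki * yi;
        Li[p2] = k;
        Lx[p2] = lki;
        Lnz[i]++;
      }
      if (D[k] == 0.0) return false;
    }
    return true;
  }

  // solve (LDL') x = b in place (permuted space)
  void solve(std::vector<double> &x) const {
    for (int j = 0; j < n; j++) {
      double xj = x[j];
      if (xj != 0.0)
        for (int p = Lp[j]; p < Lp[j] + Lnz[j]; p++) x[Li[p]] -= Lx[p] * xj;
    }
    for (int j = 0; j < n; j++) x[j] /= D[j];
    for (int j = n - 1; j >= 0; j--) {
      double xj = x[j];
      for (int p = Lp[j]; p < Lp[j] + Lnz[j]; p++) xj -= Lx[p] * x[Li[p]];
      x[j] = xj;
    }
  }

  double logdet() const {
    double s = 0.0;
    for (int k = 0; k < n; k++) s += std::log(D[k]);
    return s;
  }
};

// Takahashi selected inverse on the pattern of L: fills Zx (aligned with
// Li/Lp) and Zdiag.  Entries (i, j), i > j, of the inverse of the permuted
// matrix; all lookups fall inside the pattern by the fill lemma.
static double zlookup(const LDL &F, const std::vector<double> &Zx,
                      const std::vector<double> &Zd, int a, int b) {
  if (a == b) return Zd[a];
  int row = a > b ? a : b, col = a > b ? b : a;
  int lo = F.Lp[col], hi = F.Lp[col] + F.Lnz[col] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (F.Li[mid] == row) return Zx[mid];
    if (F.Li[mid] < row) lo = mid + 1; else hi = mid - 1;
  }
  return 0.0;  // structurally absent => unreachable for valid patterns
}

static void takahashi(const LDL &F, std::vector<double> &Zx,
                      std::vector<double> &Zd) {
  int n = F.n;
  Zx.assign(F.Lp[n], 0.0);
  Zd.assign(n, 0.0);
  for (int j = n - 1; j >= 0; j--) {
    int p0 = F.Lp[j], m = F.Lnz[j];
    for (int s = m - 1; s >= 0; s--) {
      int i = F.Li[p0 + s];
      double acc = 0.0;
      for (int t = 0; t < m; t++)
        acc += F.Lx[p0 + t] * zlookup(F, Zx, Zd, F.Li[p0 + t], i);
      Zx[p0 + s] = -acc;
    }
    double acc = 1.0 / F.D[j];
    for (int t = 0; t < m; t++) acc -= F.Lx[p0 + t] * Zx[p0 + t];
    Zd[j] = acc;
  }
}

// ---- EM-REML driver --------------------------------------------------------

struct Workspace {
  LDL F;
  int nobs, p, q, nblocks;
  double yty, logdetA, pin;
  const int *Cp, *Ci;
  const double *vww, *va, *vm;
  int nnz;
  NumericVector Wy;         // original coordinates
  IntegerVector perm;       // permuted row i <- original perm[i] (0-based)
  std::vector<int> iperm;
  // trace machinery per block: position in L pattern (-(j+1) for diagonal j)
  std::vector<std::vector<int> > tr_pos;
  std::vector<std::vector<double> > tr_w;
  // quadratic-form machinery per block (original theta indices)
  std::vector<IntegerVector> qf_i, qf_j;
  std::vector<NumericVector> qf_w;
  std::vector<double> Zx, Zd, vals;
};

// assemble permuted upper-CSC values for sigma2 = (e, a, [m])
static void assemble(Workspace &W, const std::vector<double> &sig) {
  double ie = 1.0 / sig[0], ia = 1.0 / sig[1];
  double im = W.nblocks > 1 ? 1.0 / sig[2] : 0.0;
  for (int k = 0; k < W.nnz; k++) {
    double v = W.vww[k] * ie + W.va[k] * ia;
    if (W.nblocks > 1) v += W.vm[k] * im;
    W.vals[k] = v;
  }
}

struct StepResult {
  double loglik;
  std::vector<double> theta;     // original coordinates
  std::vector<double> next;      // next EM iterate of sigma2
  bool ok;
};

// one EM step: factorize at sig, compute loglik(sig), solution and updates
static StepResult em_step(Workspace &W, const std::vector<double> &sig) {
  StepResult R;
  R.ok = false;
  assemble(W, sig);
  if (!W.F.numeric(W.Cp, W.Ci, W.vals.data())) return R;
  int dim = W.F.n;
  // solve for theta
  std::vector<double> x(dim);
  for (int i = 0; i < dim; i++) x[i] = W.Wy[W.perm[i]] / sig[0];
  W.F.solve(x);
  R.theta.assign(dim, 0.0);
  for (int i = 0; i < dim; i++) R.theta[W.perm[i]] = x[i];
  double dot = 0.0;
  for (int i = 0; i < dim; i++) dot += R.theta[i] * W.Wy[i];
  double yPy = (W.yty - dot) / sig[0];
  // restricted log-likelihood
  double ll = (W.nobs - W.p) * std::log(2.0 * M_PI) +
    W.nobs * std::log(sig[0]) + W.q * std::log(sig[1]) + W.logdetA +
    W.F.logdet() + yPy;
  if (W.nblocks > 1) ll += W.q * std::log(sig[2]) + W.logdetA;
  R.loglik = -0.5 * ll;
  // selected inverse for the EM traces
  takahashi(W.F, W.Zx, W.Zd);
  R.next = sig;
  for (int b = 0; b < W.nblocks; b++) {
    double trace = 0.0;
    const std::vector<int> &pos = W.tr_pos[b];
    const std::vector<double> &w = W.tr_w[b];
    for (size_t k = 0; k < pos.size(); k++) {
      double z = pos[k] < 0 ? W.Zd[-pos[k] - 1] : W.Zx[pos[k]];
      trace += w[k] * z;
    }
    double uAu = 0.0;
    const IntegerVector &qi = W.qf_i[b], &qj = W.qf_j[b];
    const NumericVector &qw = W.qf_w[b];
    for (int k = 0; k < qi.size(); k++)
      uAu += qw[k] * R.theta[qi[k]] * R.theta[qj[k]];
    R.next[b + 1] = (uAu + trace) / W.q;
  }
  R.next[0] = (W.yty - dot) / (W.nobs - W.p);
  for (size_t k = 0; k < R.next.size(); k++)
    if (R.next[k] < W.pin) R.next[k] = W.pin;
  R.ok = true;
  return R;
}

// [[Rcpp::export(name = ".em_reml_cpp")]]
List em_reml_cpp(IntegerVector Cp, IntegerVector Ci, NumericVector vww,
                 NumericVector va, NumericVector vm, IntegerVector perm,
                 NumericVector Wy, double yty, int nobs, int p, int q,
                 int nblocks, double logdetA,
                 IntegerVector tra_r, IntegerVector tra_c, NumericVector tra_w,
                 IntegerVector trm_r, IntegerVector trm_c, NumericVector trm_w,
                 IntegerVector qfa_i, IntegerVector qfa_j, NumericVector qfa_w,
                 IntegerVector qfm_i, IntegerVector qfm_j, NumericVector qfm_w,
                 NumericVector start, double tol, double ll_tol, int max_iter,
                 bool accelerate, double pin) {
  Workspace W;
  int dim = Cp.size() - 1;
  W.F.n = dim;
  W.Cp = Cp.begin(); W.Ci = Ci.begin();
  W.vww = vww.begin(); W.va = va.begin();
  W.vm = vm.size() ? vm.begin() : NULL;
  W.nnz = vww.size();
  W.vals.assign(W.nnz, 0.0);
  W.nobs = nobs; W.p = p; W.q = q; W.nblocks = nblocks;
  W.yty = yty; W.logdetA = logdetA; W.pin = pin;
  W.Wy = Wy; W.perm = perm;
  W.F.symbolic(W.Cp, W.Ci);
  // one numeric factorization at start values to freeze the L row layout,
  // then resolve trace entry positions by binary search
  std::vector<double> sig(start.begin(), start.end());
  assemble(W, sig);
  if (!W.F.numeric(W.Cp, W.Ci, W.vals.data()))
    stop("mixed-model equations singular at starting values");
  W.tr_pos.resize(nblocks); W.tr_w.resize(nblocks);
  for (int b = 0; b < nblocks; b++) {
    const IntegerVector &rr = b == 0 ? tra_r : trm_r;
    const IntegerVector &cc = b == 0 ? tra_c : trm_c;
    const NumericVector &ww = b == 0 ? tra_w : trm_w;
    for (int k = 0; k < rr.size(); k++) {
      int i = rr[k], j = cc[k];
      if (i == j) { W.tr_pos[b].push_back(-(i + 1)); }
      else {
        int row = i > j ? i : j, col = i > j ? j : i;
        int lo = W.F.Lp[col], hi = W.F.Lp[col] + W.F.Lnz[col] - 1, found = -1;
        while (lo <= hi) {
          int mid = (lo + hi) / 2;
          if (W.F.Li[mid] == row) { found = mid; break; }
          if (W.F.Li[mid] < row) lo = mid + 1; else hi = mid - 1;
        }
        if (found < 0) stop("internal error: trace entry outside L pattern");
        W.tr_pos[b].push_back(found);
      }
      W.tr_w[b].push_back(ww[k]);
    }
  }
  W.qf_i.push_back(qfa_i); W.qf_j.push_back(qfa_j); W.qf_w.push_back(qfa_w);
  if (nblocks > 1) {
    W.qf_i.push_back(qfm_i); W.qf_j.push_back(qfm_j); W.qf_w.push_back(qfm_w);
  }

  std::vector<double> ll_trace;
  StepResult cur = em_step(W, sig);
  if (!cur.ok) stop("factorization failed at starting values");
  ll_trace.push_back(cur.loglik);
  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    std::vector<double> sig_old = sig;
    double ll_old = cur.loglik;
    if (accelerate) {
      std::vector<double> s1 = cur.next;
      StepResult r1 = em_step(W, s1);
      if (!r1.ok) stop("factorization failed during EM");
      std::vector<double> s2 = r1.next;
      StepResult r2 = em_step(W, s2);
      if (!r2.ok) stop("factorization failed during EM");
      // squared extrapolation through (sig, s1, s2), monotonicity-guarded
      double rn = 0.0, vn = 0.0;
      std::vector<double> rv(sig.size()), vv(sig.size());
      for (size_t k = 0; k < sig.size(); k++) {
        rv[k] = s1[k] - sig[k];
        vv[k] = s2[k] - s1[k] - rv[k];
        rn += rv[k] * rv[k];
        vn += vv[k] * vv[k];
      }
      ll_trace.push_back(r1.loglik);
      ll_trace.push_back(r2.loglik);
      sig = s2; cur = r2;
      if (vn > 0.0) {
        double alpha = -std::sqrt(rn / vn);
        std::vector<double> cand(sig.size());
        for (size_t k = 0; k < sig.size(); k++) {
          cand[k] = sig_old[k] - 2.0 * alpha * rv[k] + alpha * alpha * vv[k];
          if (cand[k] < W.pin) cand[k] = W.pin;
        }
        StepResult rc = em_step(W, cand);
        if (rc.ok && rc.loglik >= r2.loglik) {
          sig = cand; cur = rc;
          ll_trace.push_back(rc.loglik);
        }
      }
      iter += 2;
    } else {
      sig = cur.next;
      cur = em_step(W, sig);
      if (!cur.ok) stop("factorization failed during EM");
      ll_trace.push_back(cur.loglik);
      iter += 1;
    }
    double rel = 0.0;
    for (size_t k = 0; k < sig.size(); k++) {
      double d = std::fabs(sig[k] - sig_old[k]) /
        std::max(std::fabs(sig_old[k]), W.pin);
      if (d > rel) rel = d;
    }
    if (rel < tol && std::fabs(cur.loglik - ll_old) < ll_tol) {
      converged = true;
      break;
    }
  }
  return List::create(
    _["sigma2"] = NumericVector(sig.begin(), sig.end()),
    _["theta"] = NumericVector(cur.theta.begin(), cur.theta.end()),
    _["loglik"] = cur.loglik,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["converged"] = converged,
    _["n_iterations"] = iter);
}
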