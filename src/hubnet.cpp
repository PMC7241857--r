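#include <Rcpp.h>
using namespace Rcpp;

// sign with configurable zero handling: variant 0 -> sign(0) = 0,
// variant 1 -> sign(0) = +1 (source nodes act as a constant drive)
static inline int sgn(double x, int variant) {
  if (x > 0) return 1;
  if (x < 0) return -1;
  return variant == 1 ? 1 : 0;
}

// Asynchronous threshold dynamics s_i <- sign(sum_j W_ij s_j + b_i) on a
// sparse weight matrix (dgCMatrix slots). At each step a fresh uniform
// subset of n_update distinct nodes is updated simultaneously (based on the
// state at the start of the step). The field x = W s + b is maintained
// incrementally via column walks: column j of W holds the out-edges of j.
//
// Frozen-core bookkeeping: after `burn_in` steps the state is snapshotted;
// a node counts as frozen iff its value never changes during the following
// `window` steps. Optionally the window states are recorded (n x (window+1),
// column 0 = state at the end of burn-in).
//
// Uses R's RNG stream: results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_run_dynamics(IntegerVector dim, IntegerVector p, IntegerVector i,
                      NumericVector xval, NumericVector bias,
                      IntegerVector s0, int burn_in, int window,
                      int n_update, int sign_variant, bool record) {
  const int n = dim[0];
  std::vector<int> s(s0.begin(), s0.end());
  std::vector<double> x(bias.begin(), bias.end());
  for (int j = 0; j < n; ++j) {
    if (s[j] != 0) {
      for (int k = p[j]; k < p[j + 1]; ++k) x[i[k]] += xval[k] * s[j];
    }
  }

  std::vector<int> perm(n), chosen(n_update), newv(n_update);
  for (int j = 0; j < n; ++j) perm[j] = j;
  std::vector<int> sref(n, 0);
  std::vector<unsigned char> changed(n, 0);

  IntegerMatrix traj = record ? IntegerMatrix(n, window + 1)
                              : IntegerMatrix(0, 0);

  const int total = burn_in + window;
  for (int t = 0; t < total; ++t) {
    if (t == burn_in) {
      sref = s;
      if (record) for (int j = 0; j < n; ++j) traj(j, 0) = s[j];
    }
    // partial Fisher-Yates draw of n_update distinct nodes
    for (int u = 0; u < n_update; ++u) {
      int r = u + (int)(unif_rand() * (n - u));
      if (r >= n) r = n - 1;
      std::swap(perm[u], perm[r]);
      chosen[u] = perm[u];
    }
    // synchronous update of the chosen subset
    for (int u = 0; u < n_update; ++u)
      newv[u] = sgn(x[chosen[u]], sign_variant);
    for (int u = 0; u < n_update; ++u) {
      int node = chosen[u];
      int delta = newv[u] - s[node];
      if (delta != 0) {
        s[node] = newv[u];
        for (int k = p[node]; k < p[node + 1]; ++k)
          x[i[k]] += xval[k] * delta;
        if (t >= burn_in) changed[node] = 1;
      }
    }
    if (record && t >= burn_in) {
      int col = t - burn_in + 1;
      for (int j = 0; j < n; ++j) traj(j, col) = s[j];
    }
  }

  int n_frozen = 0;
  LogicalVector frozen(n);
  for (int j = 0; j < n; ++j) {
    frozen[j] = changed[j] == 0;
    if (!changed[j]) ++n_frozen;
  }

  List out = List::create(
      _["state"] = IntegerVector(s.begin(), s.end()),
      _["frozen"] = frozen,
      _["frozen_fraction"] = (double)n_frozen / n);
  if (record) out["trajectory"] = traj;
  return out;
}

// One-step damage spreading on a sparse system: for each trial the caller
// supplies nothing; here we take the network once and run n_trials of
// (random state, single-bit flip, one synchronous step, count differing
// bits). Counting is restricted to rows touched by the flipped column plus
// an exact recomputation of the sign of the perturbed field.
// [[Rcpp::export]]
IntegerVector cpp_damage_trials(IntegerVector dim, IntegerVector p,
                                IntegerVector i, NumericVector xval,
                                NumericVector bias, int n_trials,
                                int sign_variant) {
  const int n = dim[0];
  IntegerVector out(n_trials);
  std::vector<int> s(n);
  std::vector<double> x(n);
  for (int trial = 0; trial < n_trials; ++trial) {
    for (int j = 0; j < n; ++j) s[j] = unif_rand() < 0.5 ? -1 : 1;
    for (int j = 0; j < n; ++j) x[j] = bias[j];
    for (int j = 0; j < n; ++j)
      for (int k = p[j]; k < p[j + 1]; ++k) x[i[k]] += xval[k] * s[j];
    int flip = (int)(unif_rand() * n);
    if (flip >= n) flip = n - 1;
    // perturbed field differs only on rows with W[row, flip] != 0
    int diff = 0;
    double delta = -2.0 * s[flip];
    for (int k = p[flip]; k < p[flip + 1]; ++k) {
      int row = i[k];
      int s1 = sgn(x[row], sign_variant);
      int s2 = sgn(x[row] + xval[k] * delta, sign_variant);
      if (s1 != s2) ++diff;
    }
    out[trial] = diff;
  }
  return out;
}

// Exhaustive fixed-point enumeration over all 2^n states in {-1,+1}^n by
// Gray-code traversal: successive states differ in one bit, so the field
// x = W s + drive is updated with a single column of W per state. A state
// is fixed iff s_i * x_i > 0 for every i (sign(0) = 0 can never equal +-1).
// [[Rcpp::export]]
List cpp_enumerate_fixed_points(NumericMatrix W, NumericVector drive,
                                bool return_states) {
  const int n = W.ncol();
  if (n > 24) stop("exhaustive enumeration limited to n <= 24");
  std::vector<double> x(n);
  std::vector<int> s(n, 1);
  for (int r = 0; r < n; ++r) {
    double acc = drive[r];
    for (int j = 0; j < n; ++j) acc += W(r, j);
    x[r] = acc;
  }
  std::vector<unsigned int> codes;
  const unsigned long total = 1UL << n;
  int count = 0;
  unsigned int gray = 0;  // bit b set  <=>  s[b] == -1
  for (unsigned long t = 0;; ++t) {
    bool fixed = true;
    for (int r = 0; r < n; ++r) {
      if (s[r] * x[r] <= 0) { fixed = false; break; }
    }
    if (fixed) {
      ++count;
      if (return_states) codes.push_back(gray);
    }
    if (t + 1 == total) break;
    int j = __builtin_ctzl(t + 1);
    s[j] = -s[j];
    gray ^= (1U << j);
    const double twos = 2.0 * s[j];
    for (int r = 0; r < n; ++r) x[r] += twos * W(r, j);
  }
  List out = List::create(_["count"] = count);
  if (return_states) {
    IntegerVector cv(codes.size());
    for (size_t q = 0; q < codes.size(); ++q) cv[q] = (int)codes[q];
    out["codes"] = cv;
  }
  return out;
}
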