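// Metropolis-Monte-Carlo inner loops for log-linear panel scoring functions.
// The objective of a weight vector is the mean held-out sensitivity over a
// fixed set of stratified subsampling splits, with the decision threshold
// re-calibrated on each split's training controls so that training
// specificity is at or above the target.
//
// Hot-path layout: control scores are sorted (descending) once per objective
// evaluation; each split then only scans that order for its first
// `allowed + 1` training-control members, so per-split work is proportional
// to the handful of scores near the specificity quantile, not to the number
// of training controls.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// shared "just above" convention (matches the R calibrate_threshold)
static inline double just_above(double v) {
  return v + std::max(std::fabs(v), 1.0) * 1e-9;
}

struct Split {
  std::vector<int> test_case, test_ctrl;   // subject indices
  std::vector<char> is_train;              // over control positions
  int n_train, allowed;                    // controls allowed at/above t
  mutable std::vector<double> top;         // scratch: allowed+1 top train scores
};

struct Ctx {
  std::vector<int> ctrl_subject;           // subject index of control position
  std::vector<Split> splits;
  // per-evaluation scratch
  mutable std::vector<double> cscore;      // control scores
  mutable std::vector<int> order;          // control positions, score-descending
};

static Ctx parse_splits(const List& splits, const IntegerVector& ctrl_subject,
                        double sp_target) {
  Ctx ctx;
  ctx.ctrl_subject = as<std::vector<int>>(ctrl_subject);
  const int nc = (int)ctx.ctrl_subject.size();
  // map subject index -> control position
  int max_subj = 0;
  for (int s : ctx.ctrl_subject) max_subj = std::max(max_subj, s);
  std::vector<int> pos_of(max_subj + 1, -1);
  for (int p = 0; p < nc; p++) pos_of[ctx.ctrl_subject[p]] = p;

  ctx.splits.resize(splits.size());
  for (R_xlen_t i = 0; i < splits.size(); i++) {
    List s = splits[i];
    Split& sp = ctx.splits[i];
    sp.test_case = as<std::vector<int>>(s["test_case"]);
    sp.test_ctrl = as<std::vector<int>>(s["test_ctrl"]);
    std::vector<int> train_ctrl = as<std::vector<int>>(s["train_ctrl"]);
    sp.is_train.assign(nc, 0);
    for (int subj : train_ctrl) {
      if (subj > max_subj || pos_of[subj] < 0)
        stop("train_ctrl index is not a control");
      sp.is_train[pos_of[subj]] = 1;
    }
    sp.n_train = (int)train_ctrl.size();
    sp.allowed = (int)std::floor(sp.n_train * (1.0 - sp_target / 100.0));
    sp.top.resize(std::max(sp.allowed + 1, 1));
  }
  ctx.cscore.resize(nc);
  ctx.order.resize(nc);
  return ctx;
}

// Smallest threshold t with (#train-control scores >= t) <= allowed among
// observed values; ties among control scores push the threshold upward
// (specificity-protective). Rule elsewhere: call case if score >= t.
static double split_threshold(const Ctx& ctx, const Split& sp) {
  const int allowed = sp.allowed;
  if (allowed >= sp.n_train) { // every control may sit at/above t
    double mn = INF;
    for (size_t p = 0; p < sp.is_train.size(); p++)
      if (sp.is_train[p]) mn = std::min(mn, ctx.cscore[p]);
    return mn;
  }
  if (allowed < 1) { // only 100% specificity attainable: just above the max
    for (int p : ctx.order)
      if (sp.is_train[p]) return just_above(ctx.cscore[p]);
    return INF; // unreachable: n_train >= 1
  }
  // first allowed+1 training controls in global descending score order
  const int m = allowed + 1;
  double* top = sp.top.data();
  int cnt = 0;
  for (int p : ctx.order) {
    if (sp.is_train[p]) {
      top[cnt++] = ctx.cscore[p];
      if (cnt == m) break;
    }
  }
  const double v1 = top[allowed - 1]; // allowed-th largest train score
  const double v2 = top[m - 1];      // (allowed+1)-th largest
  if (v1 > v2) return v1;            // exactly `allowed` scores at/above v1
  // tie spill: smallest train score strictly above v1 (sorted descending)
  for (int j = allowed - 2; j >= 0; j--)
    if (top[j] > v1) return top[j];
  return just_above(v1);
}

// mean held-out SN (%) over splits; mean held-out SP (%) via sp_out
static double objective(const std::vector<double>& s, const Ctx& ctx,
                        double* sp_out = 0) {
  const int nc = (int)ctx.ctrl_subject.size();
  for (int p = 0; p < nc; p++) ctx.cscore[p] = s[ctx.ctrl_subject[p]];
  std::iota(ctx.order.begin(), ctx.order.end(), 0);
  const std::vector<double>& cs = ctx.cscore;
  std::sort(ctx.order.begin(), ctx.order.end(),
            [&cs](int a, int b) { return cs[a] > cs[b]; });
  double sn_sum = 0.0, sp_sum = 0.0;
  for (const Split& sp : ctx.splits) {
    const double t = split_threshold(ctx, sp);
    int pos = 0;
    for (int i : sp.test_case) if (s[i] >= t) pos++;
    sn_sum += (double)pos / (double)sp.test_case.size();
    if (sp_out) {
      int neg = 0;
      for (int i : sp.test_ctrl) if (s[i] < t) neg++;
      sp_sum += (double)neg / (double)sp.test_ctrl.size();
    }
  }
  if (sp_out) *sp_out = 100.0 * sp_sum / (double)ctx.splits.size();
  return 100.0 * sn_sum / (double)ctx.splits.size();
}

static void compute_scores(const NumericMatrix& X, const std::vector<int>& cols,
                           const std::vector<double>& w, std::vector<double>& s) {
  const int n = X.nrow();
  std::fill(s.begin(), s.end(), 0.0);
  for (size_t j = 0; j < cols.size(); j++) {
    const double* col = &X(0, cols[j]);
    const double wj = w[j];
    for (int i = 0; i < n; i++) s[i] += wj * col[i];
  }
}

struct FitResult {
  std::vector<double> w;
  double obj, sp;
};

// Metropolis random walk over one coefficient at a time; geometric cooling;
// returns the best-seen state (monotone incumbent).
static FitResult mmc_fit_one(const NumericMatrix& X, const std::vector<int>& cols,
                             const Ctx& ctx, int n_iter, double prop_sd,
                             double temp0, double cooling,
                             const std::vector<double>& w0) {
  const int n = X.nrow();
  const size_t k = cols.size();
  std::vector<double> s(n);
  std::vector<double> w_cur = w0, w_new = w0, w_best = w0;
  compute_scores(X, cols, w_cur, s);
  double obj_cur = objective(s, ctx);
  double obj_best = obj_cur;
  double temp = temp0;
  for (int it = 0; it < n_iter; it++) {
    int j = (int)(unif_rand() * (double)k);
    if (j >= (int)k) j = (int)k - 1;
    w_new = w_cur;
    w_new[j] += norm_rand() * prop_sd;
    compute_scores(X, cols, w_new, s);
    const double obj_new = objective(s, ctx);
    const double delta = obj_new - obj_cur;
    if (delta >= 0.0 || unif_rand() < std::exp(delta / temp)) {
      w_cur = w_new;
      obj_cur = obj_new;
      if (obj_new > obj_best) {
        obj_best = obj_new;
        w_best = w_new;
      }
    }
    temp *= cooling;
  }
  FitResult res;
  res.w = w_best;
  compute_scores(X, cols, w_best, s);
  res.obj = objective(s, ctx, &res.sp);
  return res;
}

// [[Rcpp::export(name = ".mmc_fit_cpp")]]
List mmc_fit_cpp(NumericMatrix X, List splits, IntegerVector ctrl_subject,
                 double sp_target, int n_iter, double prop_sd, double temp0,
                 double cooling, NumericVector w0) {
  std::vector<int> cols(X.ncol());
  for (int j = 0; j < X.ncol(); j++) cols[j] = j;
  Ctx ctx = parse_splits(splits, ctrl_subject, sp_target);
  FitResult res = mmc_fit_one(X, cols, ctx, n_iter, prop_sd, temp0, cooling,
                              as<std::vector<double>>(w0));
  return List::create(_["weights"] = wrap(res.w), _["objective"] = res.obj,
                      _["cv_sp"] = res.sp);
}

// [[Rcpp::export(name = ".mmc_search_cpp")]]
List mmc_search_cpp(NumericMatrix X, IntegerMatrix panels, List splits,
                    IntegerVector ctrl_subject, double sp_target, int n_iter,
                    double prop_sd, double temp0, double cooling) {
  const int P = panels.ncol(), k = panels.nrow();
  Ctx ctx = parse_splits(splits, ctrl_subject, sp_target);
  NumericVector obj(P), spv(P);
  NumericMatrix W(k, P);
  std::vector<double> w0(k, 1.0);
  for (int p = 0; p < P; p++) {
    std::vector<int> cols(k);
    for (int j = 0; j < k; j++) cols[j] = panels(j, p);
    FitResult res = mmc_fit_one(X, cols, ctx, n_iter, prop_sd, temp0, cooling, w0);
    obj[p] = res.obj;
    spv[p] = res.sp;
    for (int j = 0; j < k; j++) W(j, p) = res.w[j];
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["objective"] = obj, _["cv_sp"] = spv,
                      _["weights"] = W);
}

// [[Rcpp::export(name = ".panel_objective_cpp")]]
List panel_objective_cpp(NumericMatrix X, List splits,
                         IntegerVector ctrl_subject, double sp_target,
                         NumericVector w) {
  std::vector<int> cols(X.ncol());
  for (int j = 0; j < X.ncol(); j++) cols[j] = j;
  Ctx ctx = parse_splits(splits, ctrl_subject, sp_target);
  std::vector<double> s(X.nrow());
  compute_scores(X, cols, as<std::vector<double>>(w), s);
  double spo = 0.0;
  double sn = objective(s, ctx, &spo);
  return List::create(_["sn"] = sn, _["sp"] = spo);
}

// [[Rcpp::export(name = ".threshold_at_sp_cpp")]]
double threshold_at_sp_cpp(NumericVector scores, double sp_target) {
  const int n = scores.size();
  IntegerVector ctrl = seq_len(n) - 1;
  List one = List::create(_["train_ctrl"] = ctrl,
                          _["test_case"] = IntegerVector::create(0),
                          _["test_ctrl"] = IntegerVector::create(0));
  Ctx ctx = parse_splits(List::create(one), ctrl, sp_target);
  std::vector<double> s = as<std::vector<double>>(scores);
  for (int p = 0; p < n; p++) ctx.cscore[p] = s[p];
  std::iota(ctx.order.begin(), ctx.order.end(), 0);
  const std::vector<double>& cs = ctx.cscore;
  std::sort(ctx.order.begin(), ctx.order.end(),
            [&cs](int a, int b) { return cs[a] > cs[b]; });
  return split_threshold(ctx, ctx.splits[0]);
}
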