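#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Breslow risk sets: subjects with Y_k >= Y_i, tied times share one risk set.
// Computes the log partial likelihood and the per-subject martingale-style
// residual r_i = status_i - exp(eta_i) * B_i, where B_i sums 1/S0(e) over
// events e with Y_e <= Y_i; the gradient is then Z' r.
// `time` must be sorted ascending; `gstart(i)` is the first index of i's tie
// group. eta is shifted by its max before exponentiation (overflow guard).
static void cox_core(const arma::vec& eta, const arma::uvec& gstart,
                     const arma::ivec& status, double& loglik, arma::vec& resid) {
  const int n = eta.n_elem;
  const double m = eta.max();
  arma::vec w = arma::exp(eta - m);
  arma::vec suf(n);
  double acc = 0.0;
  for (int i = n - 1; i >= 0; --i) { acc += w(i); suf(i) = acc; }
  loglik = 0.0;
  arma::vec B(n, arma::fill::zeros);
  double bacc = 0.0;
  int i = 0;
  while (i < n) {
    const int gs = i;
    const double S0 = suf(gs);
    int ge = gs;
    double add = 0.0;
    while (ge < n && (int) gstart(ge) == gs) {
      if (status(ge) == 1) {
        loglik += eta(ge) - m - std::log(S0);
        add += 1.0 / S0;
      }
      ++ge;
    }
    bacc += add;
    for (int k = gs; k < ge; ++k) B(k) = bacc;
    i = ge;
  }
  resid = arma::conv_to<arma::vec>::from(status) - w % B;
}

static arma::uvec group_starts(const arma::vec& time_sorted) {
  const int n = time_sorted.n_elem;
  arma::uvec gstart(n);
  gstart(0) = 0;
  for (int i = 1; i < n; ++i)
    gstart(i) = (time_sorted(i) == time_sorted(i - 1)) ? gstart(i - 1) : (unsigned) i;
  return gstart;
}

// [[Rcpp::export]]
double cox_loglik_cpp(const arma::mat& Z, const arma::vec& beta,
                      const arma::vec& time, const arma::ivec& status) {
  arma::uvec ord = arma::stable_sort_index(time);
  arma::vec ts = time(ord);
  arma::ivec ss(status.n_elem);
  for (arma::uword i = 0; i < ord.n_elem; ++i) ss(i) = status(ord(i));
  arma::vec eta = Z * beta;
  eta = eta(ord);
  double ll; arma::vec r;
  cox_core(eta, group_starts(ts), ss, ll, r);
  return ll;
}

// [[Rcpp::export]]
arma::vec cox_gradient_cpp(const arma::mat& Z, const arma::vec& beta,
                           const arma::vec& time, const arma::ivec& status) {
  arma::uvec ord = arma::stable_sort_index(time);
  arma::vec ts = time(ord);
  arma::ivec ss(status.n_elem);
  for (arma::uword i = 0; i < ord.n_elem; ++i) ss(i) = status(ord(i));
  arma::mat Zs = Z.rows(ord);
  arma::vec eta = Zs * beta;
  double ll; arma::vec r;
  cox_core(eta, group_starts(ts), ss, ll, r);
  return Zs.t() * r;
}

// Threshold vector at the current gradient. Plain rule: f_j = |g_j| >= tau*max|g|.
// Modified (heredity) rule: second-order features (par1_j >= 0) by the plain
// rule; a first-order feature passes by its own gradient OR because a selected
// second-order feature has it as a parent.
static void threshold_f(const arma::vec& g, double tau, bool heredity,
                        const arma::ivec& par1, const arma::ivec& par2,
                        arma::uvec& f) {
  const int p = g.n_elem;
  const double thr = tau * arma::abs(g).max();
  f.zeros(p);
  for (int j = 0; j < p; ++j)
    if (std::abs(g(j)) >= thr) f(j) = 1;
  if (heredity) {
    for (int j = 0; j < p; ++j) {
      if (par1(j) >= 0 && f(j)) {
        f(par1(j)) = 1;
        f(par2(j)) = 1;
      }
    }
  }
}

// TGDR path: beta starts at 0; each of K iterations recomputes the gradient
// and threshold vector at the current beta and takes the step
// beta_j += dnu * g_j * f_j. Records the training log partial likelihood at
// every beta_k (k = 0..K) and, if an evaluation set is supplied, the
// cross-validation criterion contribution R_eval(beta_k) - R_train(beta_k).
// Stops early if the gradient vanishes.
// [[Rcpp::export]]
List tgdr_engine(const arma::mat& Z, const arma::vec& time, const arma::ivec& status,
                 double tau, int K, double dnu, bool heredity,
                 const arma::ivec& par1, const arma::ivec& par2,
                 bool do_eval, const arma::mat& Zev,
                 const arma::vec& time_ev, const arma::ivec& status_ev) {
  const int p = Z.n_cols;
  arma::uvec ord = arma::stable_sort_index(time);
  arma::vec ts = time(ord);
  arma::ivec ss(status.n_elem);
  for (arma::uword i = 0; i < ord.n_elem; ++i) ss(i) = status(ord(i));
  arma::mat Zs = Z.rows(ord);
  arma::uvec gs = group_starts(ts);

  arma::uvec ord_ev; arma::vec ts_ev; arma::ivec ss_ev; arma::mat Zs_ev; arma::uvec gs_ev;
  if (do_eval) {
    ord_ev = arma::stable_sort_index(time_ev);
    ts_ev = time_ev(ord_ev);
    ss_ev.set_size(status_ev.n_elem);
    for (arma::uword i = 0; i < ord_ev.n_elem; ++i) ss_ev(i) = status_ev(ord_ev(i));
    Zs_ev = Zev.rows(ord_ev);
    gs_ev = group_starts(ts_ev);
  }

  arma::vec beta(p, arma::fill::zeros);
  arma::vec loglik_trace(K + 1);
  arma::vec cvl_trace(do_eval ? K + 1 : 0);
  bool heredity_ok = true;
  int iters = 0;
  arma::uvec f(p);

  for (int k = 0; k <= K; ++k) {
    arma::vec eta = Zs * beta;
    double ll; arma::vec r;
    cox_core(eta, gs, ss, ll, r);
    loglik_trace(k) = ll;
    if (do_eval) {
      arma::vec eta_ev = Zs_ev * beta;
      double ll_ev; arma::vec r_ev;
      cox_core(eta_ev, gs_ev, ss_ev, ll_ev, r_ev);
      cvl_trace(k) = ll_ev - ll;
    }
    if (k == K) break;
    arma::vec g = Zs.t() * r;
    const double gmax = arma::abs(g).max();
    if (gmax <= 0.0) {
      // converged: remaining trace entries repeat the current value
      for (int kk = k + 1; kk <= K; ++kk) {
        loglik_trace(kk) = loglik_trace(k);
        if (do_eval) cvl_trace(kk) = cvl_trace(k);
      }
      break;
    }
    threshold_f(g, tau, heredity, par1, par2, f);
    for (int j = 0; j < p; ++j)
      if (f(j)) beta(j) += dnu * g(j);
    ++iters;
    if (heredity) {
      for (int j = 0; j < p; ++j) {
        if (par1(j) >= 0 && beta(j) != 0.0 &&
            (beta(par1(j)) == 0.0 || beta(par2(j)) == 0.0)) {
          heredity_ok = false;
        }
      }
    }
    if (!beta.is_finite())
      stop("TGDR update produced non-finite coefficients (step size too large for this instance)");
  }

  return List::create(_["beta"] = beta,
                      _["loglik_trace"] = loglik_trace,
                      _["cvl_trace"] = cvl_trace,
                      _["iterations"] = iters,
                      _["heredity_ok"] = heredity_ok);
}
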