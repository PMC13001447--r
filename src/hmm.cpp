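#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM with binomial emissions.
// Sequences (chromosomes) are delimited by `ends`: 1-based cumulative end
// indices; each sequence starts from the stationary distribution of A.
// Sites with total = 0 have emission likelihood 1 in both states: they pass
// through the chain without evidence (callers report them as missing).

static inline double emis(int m, int n, double theta) {
  if (n == 0) return 1.0;
  return R::dbinom(m, n, theta, 0);
}

static void stationary(const NumericMatrix& A, double* pi0) {
  // stationary distribution of a 2x2 row-stochastic matrix
  double a = A(0, 1), b = A(1, 0);
  if (a + b <= 0) { pi0[0] = 0.5; pi0[1] = 0.5; return; }
  pi0[0] = b / (a + b);
  pi0[1] = a / (a + b);
}

// [[Rcpp::export]]
List hmm_forward_backward(IntegerVector meth, IntegerVector total,
                          IntegerVector ends, NumericVector theta,
                          NumericMatrix A) {
  int n = meth.size();
  NumericMatrix gamma(n, 2);
  NumericMatrix alpha(n, 2), beta_m(n, 2);
  NumericVector scale(n);
  // xi sums for EM (summed over all transitions)
  NumericMatrix xisum(2, 2);
  double loglik = 0.0;
  double pi0[2];
  stationary(A, pi0);

  int s0 = 0;
  for (int seq = 0; seq < ends.size(); ++seq) {
    int s1 = ends[seq]; // exclusive end (passed as C-style end)
    // forward
    for (int i = s0; i < s1; ++i) {
      double e0 = emis(meth[i], total[i], theta[0]);
      double e1 = emis(meth[i], total[i], theta[1]);
      double a0, a1;
      if (i == s0) {
        a0 = pi0[0] * e0; a1 = pi0[1] * e1;
      } else {
        a0 = (alpha(i - 1, 0) * A(0, 0) + alpha(i - 1, 1) * A(1, 0)) * e0;
        a1 = (alpha(i - 1, 0) * A(0, 1) + alpha(i - 1, 1) * A(1, 1)) * e1;
      }
      double c = a0 + a1;
      if (c <= 0) { c = DBL_MIN; a0 = 0.5 * c; a1 = 0.5 * c; }
      alpha(i, 0) = a0 / c; alpha(i, 1) = a1 / c;
      scale[i] = c;
      loglik += std::log(c);
    }
    // backward
    beta_m(s1 - 1, 0) = 1.0; beta_m(s1 - 1, 1) = 1.0;
    for (int i = s1 - 2; i >= s0; --i) {
      double e0 = emis(meth[i + 1], total[i + 1], theta[0]);
      double e1 = emis(meth[i + 1], total[i + 1], theta[1]);
      double b0 = A(0, 0) * e0 * beta_m(i + 1, 0) +
                  A(0, 1) * e1 * beta_m(i + 1, 1);
      double b1 = A(1, 0) * e0 * beta_m(i + 1, 0) +
                  A(1, 1) * e1 * beta_m(i + 1, 1);
      beta_m(i, 0) = b0 / scale[i + 1];
      beta_m(i, 1) = b1 / scale[i + 1];
    }
    // gamma and xi
    for (int i = s0; i < s1; ++i) {
      double g0 = alpha(i, 0) * beta_m(i, 0);
      double g1 = alpha(i, 1) * beta_m(i, 1);
      double s = g0 + g1;
      if (s <= 0) { g0 = 0.5; g1 = 0.5; s = 1.0; }
      gamma(i, 0) = g0 / s; gamma(i, 1) = g1 / s;
    }
    for (int i = s0; i < s1 - 1; ++i) {
      double e0 = emis(meth[i + 1], total[i + 1], theta[0]);
      double e1 = emis(meth[i + 1], total[i + 1], theta[1]);
      double denom = scale[i + 1];
      for (int u = 0; u < 2; ++u) {
        double eu[2] = {e0, e1};
        for (int v = 0; v < 2; ++v) {
          xisum(u, v) += alpha(i, u) * A(u, v) * eu[v] *
                         beta_m(i + 1, v) / denom;
        }
      }
    }
    s0 = s1;
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["xisum"] = xisum);
}

// [[Rcpp::export]]
List hmm_em_binom(IntegerVector meth, IntegerVector total,
                  IntegerVector ends, NumericVector theta0,
                  NumericMatrix A0, int max_iter, double tol) {
  NumericVector theta = clone(theta0);
  NumericMatrix A = clone(A0);
  double prev = R_NegInf, loglik = R_NegInf;
  int iter = 0;
  bool converged = false;
  List fb;
  for (iter = 1; iter <= max_iter; ++iter) {
    fb = hmm_forward_backward(meth, total, ends, theta, A);
    loglik = as<double>(fb["loglik"]);
    NumericMatrix gamma = fb["gamma"];
    NumericMatrix xisum = fb["xisum"];
    // M-step: binomial emission levels
    for (int k = 0; k < 2; ++k) {
      double num = 0, den = 0;
      for (int i = 0; i < meth.size(); ++i) {
        num += gamma(i, k) * meth[i];
        den += gamma(i, k) * total[i];
      }
      if (den > 0) {
        double th = num / den;
        // keep levels in the open interval for well-defined likelihoods
        theta[k] = std::min(1.0 - 1e-6, std::max(1e-6, th));
      }
    }
    // M-step: transitions
    for (int u = 0; u < 2; ++u) {
      double rowsum = xisum(u, 0) + xisum(u, 1);
      if (rowsum > 0) {
        for (int v = 0; v < 2; ++v) {
          double a = xisum(u, v) / rowsum;
          A(u, v) = std::min(1.0 - 1e-6, std::max(1e-6, a));
        }
        double rs = A(u, 0) + A(u, 1);
        A(u, 0) /= rs; A(u, 1) /= rs;
      }
    }
    if (iter > 1 && std::fabs(loglik - prev) < tol) { converged = true; break; }
    prev = loglik;
  }
  // order states: state 0 = unmethylated (lower emission level)
  if (theta[0] > theta[1]) {
    std::swap(theta[0], theta[1]);
    NumericMatrix A2(2, 2);
    A2(0, 0) = A(1, 1); A2(0, 1) = A(1, 0);
    A2(1, 0) = A(0, 1); A2(1, 1) = A(0, 0);
    A = A2;
  }
  List fb2 = hmm_forward_backward(meth, total, ends, theta, A);
  return List::create(_["theta"] = theta, _["A"] = A,
                      _["loglik"] = as<double>(fb2["loglik"]),
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
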