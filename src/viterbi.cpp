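#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Viterbi decoding for the heterogeneous truncated-Gaussian shifting-level
// model.  States are a fixed grid of candidate mean levels on [-1, 1].
//
// Initial distribution: w_k  proportional to N(level_k; 0, sigmaMu^2).
// Transition at step i (distance d):
//   stay: 1 - eta(d)
//   jump j -> k (k != j): eta(d) * N(level_k - level_j; 0, sigmaMu^2),
//   renormalised over k != j.
// Emission: Gaussian N(level_k, sigmaEps^2) truncated to [-1, 1].
//
// Ties (exact log-score equality) are broken toward the lower state index,
// both in the per-step argmax and in the final state, so the decoded path is
// deterministic.

static inline double eta_jump(double d, double theta, double dNorm) {
    return 0.5 * theta + (0.5 - theta) * std::exp(std::log(theta) / (d / dNorm));
}

// [[Rcpp::export(name = "viterbi_path_cpp")]]
IntegerVector viterbi_path_cpp(NumericVector x, NumericVector d,
                               NumericVector levels, double sigmaEps,
                               double sigmaMu, double theta, double dNorm) {
    const int n = x.size();
    const int K = levels.size();
    if (n == 0) stop("empty profile");
    if (d.size() != n - 1) stop("'d' must have length(x) - 1 elements");

    // per-state truncation log-normaliser for the emission density
    std::vector<double> logZ(K);
    for (int k = 0; k < K; ++k) {
        double Z = R::pnorm(1.0, levels[k], sigmaEps, 1, 0) -
                   R::pnorm(-1.0, levels[k], sigmaEps, 1, 0);
        logZ[k] = std::log(Z);
    }

    // jump-target log-probabilities, row j -> column k (k != j)
    std::vector<double> logJ(K * K, R_NegInf);
    for (int j = 0; j < K; ++j) {
        double rowsum = 0.0;
        for (int k = 0; k < K; ++k)
            if (k != j)
                rowsum += R::dnorm(levels[k] - levels[j], 0.0, sigmaMu, 0);
        for (int k = 0; k < K; ++k)
            if (k != j)
                logJ[j * K + k] =
                    R::dnorm(levels[k] - levels[j], 0.0, sigmaMu, 1) -
                    std::log(rowsum);
    }

    std::vector<double> dp(K), ndp(K);
    IntegerMatrix bp(n, K);

    // initial distribution: stationary level weights
    double w0 = 0.0;
    for (int k = 0; k < K; ++k)
        w0 += R::dnorm(levels[k], 0.0, sigmaMu, 0);
    for (int k = 0; k < K; ++k)
        dp[k] = R::dnorm(levels[k], 0.0, sigmaMu, 1) - std::log(w0) +
                R::dnorm(x[0], levels[k], sigmaEps, 1) - logZ[k];

    for (int i = 1; i < n; ++i) {
        const double eta = eta_jump(d[i - 1], theta, dNorm);
        const double logStay = std::log1p(-eta);
        const double logJump = std::log(eta);
        for (int k = 0; k < K; ++k) {
            double best = R_NegInf;
            int arg = 0;
            for (int j = 0; j < K; ++j) {
                const double trans = (j == k) ? logStay
                                              : logJump + logJ[j * K + k];
                const double cand = dp[j] + trans;
                if (cand > best) { best = cand; arg = j; }
            }
            ndp[k] = best + R::dnorm(x[i], levels[k], sigmaEps, 1) - logZ[k];
            bp(i, k) = arg;
        }
        dp.swap(ndp);
    }

    int last = 0;
    double best = dp[0];
    for (int k = 1; k < K; ++k)
        if (dp[k] > best) { best = dp[k]; last = k; }

    IntegerVector path(n);
    path[n - 1] = last;
    for (int i = n - 1; i > 0; --i)
        path[i - 1] = bp(i, path[i]);
    for (int i = 0; i < n; ++i) path[i] += 1;  // 1-based for R
    return path;
}
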