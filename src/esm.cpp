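#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gini coefficient of a non-negative vector via the sorted-vector identity
// G = (2 * sum_i i*x_(i) - (n+1) * sum_i x_i) / (n * sum_i x_i), with G = 0
// for an all-zero vector (degenerate equal state).
static double gini_sorted(std::vector<double> &x) {
    const int n = (int)x.size();
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i];
    if (s <= 0.0) return 0.0;
    std::sort(x.begin(), x.end());
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += (double)(i + 1) * x[i];
    double g = (2.0 * acc - (double)(n + 1) * s) / ((double)n * s);
    if (g < 0.0) g = 0.0;
    return g;
}

struct Logistic {
    double slope, mid, s0, s1, denom;
    Logistic(double slope_, double mid_) : slope(slope_), mid(mid_) {
        s0 = 1.0 / (1.0 + std::exp(slope * mid));
        s1 = 1.0 / (1.0 + std::exp(-slope * (1.0 - mid)));
        denom = s1 - s0;
    }
    // normalized logistic: L(0)=0, L(1)=1, strictly increasing
    double operator()(double p) const {
        double s = 1.0 / (1.0 + std::exp(-slope * (p - mid)));
        return (s - s0) / denom;
    }
};

// [[Rcpp::export]]
NumericMatrix esm_simulate_cpp(NumericMatrix acp, IntegerMatrix delay,
                               NumericVector p0, int n_steps, double dt,
                               double beta0, double delta0, double mu,
                               double sigma, double slope, double mid,
                               double decay, Nullable<NumericMatrix> noise_) {
    const int n = acp.nrow();
    if (acp.ncol() != n || delay.nrow() != n || delay.ncol() != n)
        stop("acp and delay must be square matrices of equal size");
    if (p0.size() != n) stop("p0 length must match matrix size");

    const double b0 = std::min(beta0, 1.0);
    const double d0 = std::min(delta0, 1.0);
    const Logistic L(slope, mid);
    const double sq = sigma * std::sqrt(dt);

    bool has_noise = noise_.isNotNull();
    NumericMatrix noise;
    if (has_noise) {
        noise = NumericMatrix(noise_);
        if (noise.nrow() < n_steps || noise.ncol() != n)
            stop("noise matrix must be n_steps x n");
    }

    NumericMatrix P(n_steps + 1, n);
    // beta_total(P_j(t)) cached once per (t, j); reception reads it at the
    // delayed index so the sigmoid is evaluated once per region-step.
    NumericMatrix btot(n_steps + 1, n);
    for (int j = 0; j < n; ++j) {
        P(0, j) = p0[j];
        btot(0, j) = b0 * L(p0[j]);
    }

    std::vector<double> cur(n), work(n), deltav(n);
    for (int t = 0; t < n_steps; ++t) {
        for (int j = 0; j < n; ++j) cur[j] = P(t, j);
        work = cur;
        const double g = gini_sorted(work);
        for (int j = 0; j < n; ++j) {
            deltav[j] = d0 * std::exp(-decay * cur[j]);
        }
        for (int i = 0; i < n; ++i) {
            double prod = 1.0;
            for (int j = 0; j < n; ++j) {
                if (j == i) continue; // self-transmission handled by beta_int
                const double a = acp(j, i);
                if (a <= 0.0) continue;
                // outbreak starts at t=0: the delayed history before then is
                // the clean (zero-deposition) state, whose production is 0
                const int td = t - delay(j, i);
                if (td < 0) continue;
                const double bj = btot(td, j);
                prod *= (1.0 - a * g * bj);
            }
            const double bint = (1.0 - g) * btot(t, i);
            const double R = 1.0 - (1.0 - bint) * prod;
            double np = cur[i] +
                dt * ((1.0 - cur[i]) * R - cur[i] * deltav[i]) + mu * dt;
            if (has_noise) np += sq * noise(t, i);
            if (np < 0.0) np = 0.0;
            else if (np > 1.0) np = 1.0;
            if (!std::isfinite(np)) stop("non-finite state at step %d", t);
            P(t + 1, i) = np;
            btot(t + 1, i) = b0 * L(np);
        }
    }
    return P;
}

// Earliest day index (0-based) minimizing the Euclidean distance between a
// trajectory row and a target pattern; strict '<' keeps the earliest tie.
// [[Rcpp::export]]
List traj_best_match_cpp(NumericMatrix P, NumericVector pattern) {
    const int T = P.nrow(), n = P.ncol();
    if (pattern.size() != n) stop("pattern length must match trajectory width");
    int best = 0;
    double bestd = R_PosInf;
    for (int t = 0; t < T; ++t) {
        double d = 0.0;
        for (int j = 0; j < n; ++j) {
            const double e = P(t, j) - pattern[j];
            d += e * e;
        }
        if (d < bestd) { bestd = d; best = t; }
    }
    return List::create(_["t_index"] = best + 1, // 1-based row index
                        _["distance"] = std::sqrt(bestd));
}
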