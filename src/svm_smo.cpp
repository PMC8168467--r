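#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// C-SVC dual solved by SMO with maximal-violating-pair working-set selection:
//   min 1/2 a'Qa - e'a,  0 <= a_i <= C,  sum(a_i y_i) = 0,  Q_ij = y_i y_j K_ij.
// Operates on a precomputed kernel (Gram) matrix so cross-validation folds and
// label permutations reuse the same kernel. Labels are +1/-1; a decision value
// of exactly 0 is assigned to the -1 class (documented tie rule).

struct SmoFit {
    std::vector<double> alpha;  // aligned with training indices
    double rho;
    int iterations;
};

static SmoFit smo_train(const double *K, const int n_full,
                        const std::vector<int> &tr,
                        const std::vector<int> &y,
                        const double C, const double eps, const int max_iter)
{
    const int n = static_cast<int>(tr.size());
    const double TAU = 1e-12;
    std::vector<double> alpha(n, 0.0), G(n, -1.0);

    int iter = 0;
    while (iter < max_iter) {
        // maximal violating pair
        double m = -std::numeric_limits<double>::infinity();
        double M = std::numeric_limits<double>::infinity();
        int i = -1, j = -1;
        for (int t = 0; t < n; ++t) {
            const double v = -y[t] * G[t];
            const bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
            const bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
            if (up && v > m) { m = v; i = t; }
            if (low && v < M) { M = v; j = t; }
        }
        if (i < 0 || j < 0 || m - M < eps) break;
        ++iter;

        const double Kii = K[tr[i] + (size_t)n_full * tr[i]];
        const double Kjj = K[tr[j] + (size_t)n_full * tr[j]];
        const double Kij = K[tr[i] + (size_t)n_full * tr[j]];
        double quad = Kii + Kjj - 2.0 * Kij;
        if (quad <= 0) quad = TAU;

        const double old_ai = alpha[i], old_aj = alpha[j];
        if (y[i] != y[j]) {
            const double delta = (-G[i] - G[j]) / quad;
            const double diff = alpha[i] - alpha[j];
            alpha[i] += delta; alpha[j] += delta;
            if (diff > 0) {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
            }
            if (diff > 0) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
            } else {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
            }
        } else {
            const double delta = (G[i] - G[j]) / quad;
            const double sum = alpha[i] + alpha[j];
            alpha[i] -= delta; alpha[j] += delta;
            if (sum > C) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
            } else {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
            }
            if (sum > C) {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
            }
        }

        const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
        for (int t = 0; t < n; ++t) {
            const double Kti = K[tr[t] + (size_t)n_full * tr[i]];
            const double Ktj = K[tr[t] + (size_t)n_full * tr[j]];
            G[t] += y[t] * (y[i] * Kti * dai + y[j] * Ktj * daj);
        }
    }

    // intercept (libsvm's rho): average -y*G over free support vectors,
    // otherwise midpoint of the feasibility bounds
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    double sum_free = 0.0;
    int n_free = 0;
    for (int t = 0; t < n; ++t) {
        const double yG = y[t] * G[t];
        if (alpha[t] >= C) {               // upper bound
            if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
        } else if (alpha[t] <= 0) {        // lower bound
            if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
        } else {
            ++n_free; sum_free += yG;
        }
    }
    SmoFit fit;
    fit.alpha = alpha;
    fit.rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;
    if (!std::isfinite(fit.rho)) fit.rho = 0.0;
    fit.iterations = iter;
    return fit;
}

// [[Rcpp::export]]
List svm_kernel_fit_cpp(NumericMatrix K, IntegerVector y, double C,
                        double eps = 1e-8, int max_iter = 100000)
{
    const int n = K.nrow();
    std::vector<int> tr(n), yy(n);
    for (int t = 0; t < n; ++t) { tr[t] = t; yy[t] = y[t]; }
    SmoFit fit = smo_train(REAL(K), n, tr, yy, C, eps, max_iter);
    return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                        _["rho"] = fit.rho,
                        _["iterations"] = fit.iterations);
}

// accuracy of grouped cross-validation on a precomputed kernel:
// every unique value of `fold` is held out once (labels y in +1/-1)
static double cv_accuracy_kernel(const double *K, const int n,
                                 const int *y, const int *fold,
                                 const double C, const double eps,
                                 const int max_iter)
{
    // collect unique folds preserving first appearance
    std::vector<int> folds;
    for (int t = 0; t < n; ++t) {
        bool seen = false;
        for (size_t u = 0; u < folds.size(); ++u)
            if (folds[u] == fold[t]) { seen = true; break; }
        if (!seen) folds.push_back(fold[t]);
    }

    int correct = 0;
    for (size_t f = 0; f < folds.size(); ++f) {
        std::vector<int> tr, te, ytr;
        tr.reserve(n); ytr.reserve(n);
        for (int t = 0; t < n; ++t) {
            if (fold[t] == folds[f]) te.push_back(t);
            else { tr.push_back(t); ytr.push_back(y[t]); }
        }
        SmoFit fit = smo_train(K, n, tr, ytr, C, eps, max_iter);
        for (size_t s = 0; s < te.size(); ++s) {
            double dec = -fit.rho;
            for (size_t t = 0; t < tr.size(); ++t)
                dec += fit.alpha[t] * ytr[t] * K[te[s] + (size_t)n * tr[t]];
            const int pred = (dec > 0) ? 1 : -1;
            if (pred == y[te[s]]) ++correct;
        }
    }
    return static_cast<double>(correct) / n;
}

// [[Rcpp::export]]
double cv_accuracy_cpp(NumericMatrix K, IntegerVector y, IntegerVector fold,
                       double C, double eps = 1e-8, int max_iter = 100000)
{
    return cv_accuracy_kernel(REAL(K), K.nrow(), INTEGER(y), INTEGER(fold),
                              C, eps, max_iter);
}

// Batch version for permutation nulls: one kernel per region, one label row
// per permutation. Returns an n_perm x n_region accuracy matrix.
// [[Rcpp::export]]
NumericMatrix cv_accuracy_perms_cpp(List Ks, IntegerMatrix Y, IntegerVector fold,
                                    double C, double eps = 1e-8,
                                    int max_iter = 100000)
{
    const int n_perm = Y.nrow();
    const int n_reg = Ks.size();
    const int n = Y.ncol();
    NumericMatrix out(n_perm, n_reg);
    std::vector<int> yy(n);
    for (int r = 0; r < n_reg; ++r) {
        NumericMatrix K = Ks[r];
        if (K.nrow() != n)
            stop("kernel %d has %d rows; expected %d", r + 1, K.nrow(), n);
        const double *Kp = REAL(K);
        for (int p = 0; p < n_perm; ++p) {
            for (int t = 0; t < n; ++t) yy[t] = Y(p, t);
            out(p, r) = cv_accuracy_kernel(Kp, n, yy.data(), INTEGER(fold),
                                           C, eps, max_iter);
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}
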