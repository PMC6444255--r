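// Path solvers for sparse logistic regression on a standardized design
// matrix: cyclic coordinate descent with soft-threshold updates (LASSO
// penalty) and threshold gradient descent regularization (TGDR).
// Columns of X are assumed centered and scaled by the caller (zero-variance
// columns passed as all-zero); the intercept is unpenalized.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft(double x, double y) {
    if (x > 0.0 && y < x) return x - y;
    if (x < 0.0 && y < -x) return x + y;
    return 0.0;
}

// One cyclic pass of weighted-least-squares coordinate updates over the
// coordinates listed in `idx`; returns the largest coefficient change.
static double cd_sweep(const arma::mat& X, const arma::vec& w,
                       arma::vec& r, arma::vec& beta, double& b0,
                       const arma::vec& wxx, double sw, double lam,
                       const arma::uvec& idx) {
    const int n = X.n_rows;
    double change = 0.0;
    for (arma::uword m = 0; m < idx.n_elem; ++m) {
        const arma::uword j = idx[m];
        if (wxx[j] <= 0.0) continue;
        const double* xj = X.colptr(j);
        double num = 0.0;
        for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
        num = num / n + wxx[j] * beta[j];
        double bnew = soft(num, lam) / wxx[j];
        double d = bnew - beta[j];
        if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
            beta[j] = bnew;
            if (std::fabs(d) > change) change = std::fabs(d);
        }
    }
    double num0 = arma::dot(w, r);
    double d0 = num0 / sw;
    if (d0 != 0.0) {
        r -= d0;
        b0 += d0;
        if (std::fabs(d0) > change) change = std::fabs(d0);
    }
    return change;
}

// Coordinate-descent LASSO logistic path.
// Minimizes (1/n) * negative Bernoulli log-likelihood + lambda * ||beta||_1
// by iteratively reweighted least squares with cyclic coordinate
// soft-threshold updates, warm-started along the (descending) lambda path.
// After each full pass, iteration is confined to the active (nonzero) set
// until convergence, then re-checked with a full pass.
// [[Rcpp::export]]
List cd_lasso_path_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::vec& lambdas, double tol,
                       int max_sweeps, int max_irls) {
    const int n = X.n_rows, p = X.n_cols, L = lambdas.n_elem;
    arma::vec beta(p, arma::fill::zeros);
    const double ybar = arma::mean(y);
    double b0 = std::log(ybar / (1.0 - ybar));
    arma::vec eta(n, arma::fill::value(b0));
    arma::mat betas(p, L);
    arma::vec a0(L);
    arma::uvec all_idx = arma::regspace<arma::uvec>(0, p - 1);

    for (int l = 0; l < L; ++l) {
        const double lam = lambdas[l];
        for (int it = 0; it < max_irls; ++it) {
            // quadratic approximation at current eta
            arma::vec pr = 1.0 / (1.0 + arma::exp(-eta));
            arma::vec w = arma::clamp(pr % (1.0 - pr), 1e-5, arma::datum::inf);
            double sw = arma::accu(w);
            arma::vec z = eta + (y - pr) / w;
            arma::vec r = z - eta;
            // wxx_j = (1/n) sum_i w_i x_ij^2
            arma::vec wxx(p);
            for (int j = 0; j < p; ++j) {
                const double* xj = X.colptr(j);
                double s = 0.0;
                for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
                wxx[j] = s / n;
            }
            double outer_change = 0.0;
            int sweeps = 0;
            while (sweeps < max_sweeps) {
                double change = cd_sweep(X, w, r, beta, b0, wxx, sw, lam,
                                         all_idx);
                ++sweeps;
                if (change > outer_change) outer_change = change;
                if (change < tol) break;
                arma::uvec act = arma::find(beta != 0.0);
                while (sweeps < max_sweeps) {
                    double ch = cd_sweep(X, w, r, beta, b0, wxx, sw, lam, act);
                    ++sweeps;
                    if (ch > outer_change) outer_change = ch;
                    if (ch < tol) break;
                }
            }
            eta = z - r;
            if (outer_change < tol) break;
        }
        a0[l] = b0;
        betas.col(l) = beta;
    }
    return List::create(_["a0"] = NumericVector(a0.begin(), a0.end()),
                        _["beta"] = wrap(betas));
}

// TGDR path: gradient ascent on the (1/n-scaled) Bernoulli log-likelihood
// where only coefficients whose gradient magnitude is within a factor tau of
// the largest (ties included) are updated; the unpenalized intercept moves by
// its full gradient every step. Coefficients start at zero; snapshots are
// recorded after the step counts in `ks` (sorted ascending).
// [[Rcpp::export]]
List tgdr_path_cpp(const arma::mat& X, const arma::vec& y,
                   double tau, double dnu, const IntegerVector& ks) {
    const int n = X.n_rows, p = X.n_cols, S = ks.size();
    const int kmax = ks[S - 1];
    arma::vec beta(p, arma::fill::zeros), eta(n, arma::fill::zeros);
    double b0 = 0.0;
    arma::mat betas(p, S);
    arma::vec a0(S);
    int snap = 0;

    for (int step = 0; step <= kmax; ++step) {
        while (snap < S && ks[snap] == step) {
            a0[snap] = b0;
            betas.col(snap) = beta;
            ++snap;
        }
        if (step == kmax) break;
        arma::vec res = y - 1.0 / (1.0 + arma::exp(-eta));
        double g0 = arma::mean(res);
        arma::vec g = X.t() * res / n;
        double gmax = g.n_elem ? arma::abs(g).max() : 0.0;
        b0 += dnu * g0;
        eta += dnu * g0;
        if (gmax > 0.0) {
            const double cut = tau * gmax;
            arma::uvec upd = arma::find(arma::abs(g) >= cut);
            for (arma::uword m = 0; m < upd.n_elem; ++m) {
                const arma::uword j = upd[m];
                const double d = dnu * g[j];
                beta[j] += d;
                eta += d * X.col(j);
            }
        }
    }
    return List::create(_["a0"] = NumericVector(a0.begin(), a0.end()),
                        _["beta"] = wrap(betas));
}
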