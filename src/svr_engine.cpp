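// Linear epsilon-SVR engine for leave-one-out connectome prediction.
//
// The dual problem depends on the feature matrix only through the Gram
// matrix X X', so the full LOOCV x permutation sweep precomputes one
// n x n Gram and solves every fold / permutation / threshold with a
// sequential-minimal-optimization (SMO) solver on Gram submatrices.
// Weight-based feature ranking then needs a single p x m matrix product
// per fold, batched over all permutations at once.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <algorithm>
#include <numeric>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

static const double SMO_TAU = 1e-12;

struct SmoWorkspace {
    std::vector<double> alpha, grad, qd;
    void resize(int l) {
        alpha.assign(2 * l, 0.0);
        grad.resize(2 * l);
        qd.resize(2 * l);
    }
};

// SMO for epsilon-SVR on a precomputed Gram matrix (2l-variable dual,
// second-order working-set selection, standard stopping rule).
// Returns beta (length l, = alpha - alpha*) and intercept b such that
// f(x) = sum_t beta[t] K(x_t, x) + b.
static int smo_epsilon_svr(const arma::mat& K, const double* y,
                           double C, double eps, double tol,
                           arma::vec& beta, double& b, SmoWorkspace& ws)
{
    const int l  = static_cast<int>(K.n_rows);
    const int n2 = 2 * l;
    const double INF = std::numeric_limits<double>::infinity();

    ws.resize(l);
    double* alpha = ws.alpha.data();
    double* grad  = ws.grad.data();
    double* qd    = ws.qd.data();
    for (int t = 0; t < l; ++t) {
        grad[t]     = eps - y[t];
        grad[l + t] = eps + y[t];
        qd[t] = qd[l + t] = K(t, t);
    }
    // sign of variable t: +1 for t < l (alpha), -1 for t >= l (alpha*)

    const int max_iter = std::max(200000, 100 * l);
    int iter = 0;
    for (; iter < max_iter; ++iter) {
        // first index: maximal violation over I_up
        double gmax = -INF;
        int i = -1;
        for (int t = 0; t < l; ++t)
            if (alpha[t] < C && -grad[t] > gmax) { gmax = -grad[t]; i = t; }
        for (int t = l; t < n2; ++t)
            if (alpha[t] > 0.0 && grad[t] > gmax) { gmax = grad[t]; i = t; }
        if (i < 0) break;

        const double* Ki = K.colptr(i % l);
        const double qdi = qd[i];

        // second index: best second-order gain over I_low
        double gmax2 = -INF, obj_min = INF;
        int j = -1;
        for (int t = 0; t < l; ++t) {
            if (alpha[t] > 0.0) {
                const double grad_diff = gmax + grad[t];
                if (grad[t] > gmax2) gmax2 = grad[t];
                if (grad_diff > 0.0) {
                    double quad = qdi + qd[t] - 2.0 * Ki[t];
                    if (quad <= 0.0) quad = SMO_TAU;
                    const double od = -(grad_diff * grad_diff) / quad;
                    if (od <= obj_min) { j = t; obj_min = od; }
                }
            }
        }
        for (int t = l; t < n2; ++t) {
            if (alpha[t] < C) {
                const double grad_diff = gmax - grad[t];
                if (-grad[t] > gmax2) gmax2 = -grad[t];
                if (grad_diff > 0.0) {
                    double quad = qdi + qd[t] - 2.0 * Ki[t - l];
                    if (quad <= 0.0) quad = SMO_TAU;
                    const double od = -(grad_diff * grad_diff) / quad;
                    if (od <= obj_min) { j = t; obj_min = od; }
                }
            }
        }
        if (gmax + gmax2 < tol || j < 0) break;

        const double* Kj = K.colptr(j % l);
        const int si = (i < l) ? 1 : -1;
        const int sj = (j < l) ? 1 : -1;
        const double old_ai = alpha[i], old_aj = alpha[j];

        double quad = qdi + qd[j] - 2.0 * Ki[j % l];
        if (quad <= 0.0) quad = SMO_TAU;

        if (si != sj) {
            const double delta = (-grad[i] - grad[j]) / quad;
            const double diff  = alpha[i] - alpha[j];
            alpha[i] += delta;
            alpha[j] += delta;
            if (diff > 0.0) {
                if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = diff; }
            } else {
                if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = -diff; }
            }
            if (diff > 0.0) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
            } else {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
            }
        } else {
            const double delta = (grad[i] - grad[j]) / quad;
            const double sum   = alpha[i] + alpha[j];
            alpha[i] -= delta;
            alpha[j] += delta;
            if (sum > C) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
            } else {
                if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = sum; }
            }
            if (sum > C) {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
            } else {
                if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = sum; }
            }
        }

        const double dai = si * (alpha[i] - old_ai);
        const double daj = sj * (alpha[j] - old_aj);
        for (int t = 0; t < l; ++t) {
            const double v = Ki[t] * dai + Kj[t] * daj;
            grad[t]     += v;
            grad[l + t] -= v;
        }
    }

    // intercept from KKT conditions
    double ub = INF, lb = -INF, sum_free = 0.0;
    int nfree = 0;
    for (int t = 0; t < n2; ++t) {
        const int s = (t < l) ? 1 : -1;
        const double yg = s * grad[t];
        if (alpha[t] >= C) {
            if (s == -1) ub = std::min(ub, yg); else lb = std::max(lb, yg);
        } else if (alpha[t] <= 0.0) {
            if (s == 1)  ub = std::min(ub, yg); else lb = std::max(lb, yg);
        } else {
            ++nfree;
            sum_free += yg;
        }
    }
    const double rho = (nfree > 0) ? sum_free / nfree : 0.5 * (ub + lb);
    b = -rho;

    beta.set_size(l);
    for (int t = 0; t < l; ++t) beta[t] = alpha[t] - alpha[l + t];
    return iter;
}

static double pearson_r(const arma::vec& a, const arma::vec& b)
{
    const arma::vec ac = a - arma::mean(a);
    const arma::vec bc = b - arma::mean(b);
    const double den = std::sqrt(arma::dot(ac, ac) * arma::dot(bc, bc));
    if (den <= 0.0) return NA_REAL;
    return arma::dot(ac, bc) / den;
}

// Top-k indices of |w| with ties broken by lower index, sorted so that
// every prefix is itself a top-k' set under the same ordering.
// Value-based selection avoids an O(p log p) indexed sort.
static void top_k_abs(const double* w, arma::uword p, arma::uword k,
                      std::vector<double>& absw, std::vector<double>& buf,
                      std::vector<arma::uword>& out)
{
    absw.resize(p);
    for (arma::uword t = 0; t < p; ++t) absw[t] = std::fabs(w[t]);
    buf.resize(p);
    std::memcpy(buf.data(), absw.data(), p * sizeof(double));
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end(),
                     std::greater<double>());
    const double kth = buf[k - 1];

    out.clear();
    out.reserve(k + 16);
    for (arma::uword t = 0; t < p; ++t)
        if (absw[t] > kth) out.push_back(t);
    const arma::uword n_above = out.size();
    for (arma::uword t = 0; t < p && out.size() < k; ++t)
        if (absw[t] == kth) out.push_back(t);
    // entries above the k-th value still need (|w| desc, index asc) order;
    // boundary ties are already in ascending index order
    const double* aw = absw.data();
    std::sort(out.begin(), out.begin() + n_above,
              [aw](arma::uword a, arma::uword b) {
                  if (aw[a] != aw[b]) return aw[a] > aw[b];
                  return a < b;
              });
}

// copy the (valid) upper triangle onto the lower one, in place
static void symmetrize_upper(arma::mat& C)
{
    const arma::uword n = C.n_rows;
    for (arma::uword c = 0; c < n; ++c) {
        const double* col = C.colptr(c);
        for (arma::uword r = 0; r < c; ++r)
            C(c, r) = col[r];
    }
}

// Gtr := G with row and column i removed (contiguous block copies)
static void drop_index(const arma::mat& G, arma::uword i, arma::mat& Gtr)
{
    const arma::uword n = G.n_rows;
    arma::uword cc = 0;
    for (arma::uword c = 0; c < n; ++c) {
        if (c == i) continue;
        const double* src = G.colptr(c);
        double* dst = Gtr.colptr(cc);
        if (i > 0) std::memcpy(dst, src, i * sizeof(double));
        if (i + 1 < n)
            std::memcpy(dst + i, src + i + 1, (n - 1 - i) * sizeof(double));
        ++cc;
    }
}

// C := C + A A' (upper triangle), then symmetrized by the caller
static void syrk_update(arma::mat& C, const arma::mat& A)
{
    const int n = static_cast<int>(A.n_rows);
    const int k = static_cast<int>(A.n_cols);
    const double one = 1.0;
    F77_CALL(dsyrk)("U", "N", &n, &k, &one, A.memptr(), &n, &one,
                    C.memptr(), &n FCONE FCONE);
}

// Single SVR fit on a precomputed Gram matrix.
// [[Rcpp::export]]
Rcpp::List cpp_svr_fit(const arma::mat& K, const arma::vec& y,
                       double cost, double epsilon, double tol)
{
    arma::vec beta;
    double b = 0.0;
    SmoWorkspace ws;
    const int iters = smo_epsilon_svr(K, y.memptr(), cost, epsilon, tol,
                                      beta, b, ws);
    return Rcpp::List::create(Rcpp::Named("beta") = beta,
                              Rcpp::Named("b") = b,
                              Rcpp::Named("iterations") = iters);
}

// Full LOOCV sweep: for every column of Y (column 1 = observed scores,
// the rest = permuted scores) and every fold, fit a ranking SVR on all
// features of the training subjects, keep the top-k columns by |weight|
// (ties broken by lower column index) for each requested feature count,
// refit on the selected columns and predict the held-out subject.
// Feature counts must be ascending; selections are nested by
// construction, so selected-column Gram matrices grow incrementally.
// [[Rcpp::export]]
Rcpp::List cpp_loocv_engine(const arma::mat& X, const arma::mat& Y,
                            const arma::uvec& kcounts,
                            double cost, double epsilon, double tol,
                            bool standardize, bool details)
{
    const arma::uword n = X.n_rows, p = X.n_cols;
    const arma::uword m = Y.n_cols, nT = kcounts.n_elem;
    const arma::uword kmax = kcounts[nT - 1];

    arma::mat K;
    if (!standardize) {
        K.zeros(n, n);
        syrk_update(K, X);
        symmetrize_upper(K);
    }

    arma::cube pred(n, m, nT, arma::fill::zeros);
    std::vector<arma::umat> sel(nT);
    std::vector<arma::mat>  selw(nT);
    if (details) {
        for (arma::uword t = 0; t < nT; ++t) {
            sel[t].set_size(kcounts[t], n);
            selw[t].set_size(kcounts[t], n);
        }
    }

    arma::mat B(n, m), W, Xf;
    arma::mat Gsel(n, n), Gtr(n - 1, n - 1);
    arma::vec beta, beta2;
    std::vector<double> absw, abuf;
    std::vector<arma::uword> idx;
    SmoWorkspace ws;

    for (arma::uword i = 0; i < n; ++i) {
        Rcpp::checkUserInterrupt();
        arma::uvec tr(n - 1);
        arma::uword c = 0;
        for (arma::uword t = 0; t < n; ++t) if (t != i) tr[c++] = t;

        // with standardization on, features are rescaled per fold using
        // training-subject statistics only (the held-out row is transformed
        // with the training mean/sd), so the Gram is fold-specific
        const arma::mat* Xp = &X;
        arma::mat Ktr(n - 1, n - 1);
        if (standardize) {
            Xf.set_size(n, p);
            for (arma::uword cc = 0; cc < p; ++cc) {
                const double* xc = X.colptr(cc);
                double s1 = 0.0, s2 = 0.0;
                for (arma::uword t = 0; t < n; ++t) {
                    if (t == i) continue;
                    s1 += xc[t];
                    s2 += xc[t] * xc[t];
                }
                const double mu = s1 / (n - 1);
                double var = (s2 - (n - 1) * mu * mu) / (n - 2.0);
                double sd = (var > 0.0) ? std::sqrt(var) : 1.0;
                double* fc = Xf.colptr(cc);
                for (arma::uword t = 0; t < n; ++t) fc[t] = (xc[t] - mu) / sd;
            }
            arma::mat Kf(n, n, arma::fill::zeros);
            syrk_update(Kf, Xf);
            symmetrize_upper(Kf);
            drop_index(Kf, i, Ktr);
            Xp = &Xf;
        } else {
            drop_index(K, i, Ktr);
        }
        B.zeros();
        double bfit;
        arma::vec ytr(n - 1);
        for (arma::uword j = 0; j < m; ++j) {
            for (arma::uword q = 0; q < n - 1; ++q) ytr[q] = Y(tr[q], j);
            smo_epsilon_svr(Ktr, ytr.memptr(), cost, epsilon, tol,
                            beta, bfit, ws);
            B.submat(tr, arma::uvec{j}) = beta;
        }
        W = Xp->t() * B;  // p x m ranking weights, one column per permutation

        for (arma::uword j = 0; j < m; ++j) {
            top_k_abs(W.colptr(j), p, kmax, absw, abuf, idx);
            for (arma::uword q = 0; q < n - 1; ++q) ytr[q] = Y(tr[q], j);

            Gsel.zeros();
            arma::uword done = 0;
            for (arma::uword t = 0; t < nT; ++t) {
                const arma::uword kt = kcounts[t];
                if (kt > done) {
                    arma::uvec cols(kt - done);
                    for (arma::uword q = done; q < kt; ++q)
                        cols[q - done] = idx[q];
                    syrk_update(Gsel, Xp->cols(cols));
                    symmetrize_upper(Gsel);
                    done = kt;
                }
                drop_index(Gsel, i, Gtr);
                double b2;
                smo_epsilon_svr(Gtr, ytr.memptr(), cost, epsilon, tol,
                                beta2, b2, ws);
                const double* ki = Gsel.colptr(i);  // symmetric: row i
                double f = b2;
                for (arma::uword q = 0; q < n - 1; ++q)
                    f += ki[tr[q]] * beta2[q];
                pred(i, j, t) = f;

                if (details && j == 0) {
                    arma::uvec scols(kt);
                    for (arma::uword q = 0; q < kt; ++q) scols[q] = idx[q];
                    sel[t].col(i) = scols + 1;  // 1-based for R
                    const arma::mat Xts = Xp->submat(tr, scols);
                    selw[t].col(i) = Xts.t() * beta2;
                }
            }
        }
    }

    arma::mat r(m, nT);
    for (arma::uword j = 0; j < m; ++j)
        for (arma::uword t = 0; t < nT; ++t)
            r(j, t) = pearson_r(pred.slice(t).col(j), Y.col(j));

    arma::mat pred_obs(n, nT);  // observed-scores predictions per threshold
    for (arma::uword t = 0; t < nT; ++t) pred_obs.col(t) = pred.slice(t).col(0);
    Rcpp::List out = Rcpp::List::create(
        Rcpp::Named("r") = r,
        Rcpp::Named("pred") = pred_obs);
    if (details) {
        Rcpp::List sl(nT), wl(nT);
        for (arma::uword t = 0; t < nT; ++t) {
            sl[t] = sel[t];
            wl[t] = selw[t];
        }
        out["selected"] = sl;
        out["fold_weights"] = wl;
    }
    return out;
}
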