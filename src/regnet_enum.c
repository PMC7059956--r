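/* Exact solver for the shared-regulator L1 selection problem.
 *
 * The selection MIP separates by target gene once the TF subset S is fixed:
 *   F(S) = sum_i  min_beta  sum_k | z[i,k] - beta0 - sum_{t in S∩R_i} C_i[k,t] beta_t |
 * with R_i the gene's candidate regulators (edge score > 0). Each inner
 * problem is a tiny L1 regression whose optimum is attained at a vertex
 * interpolating p = 1+|A| points, so it is solved exactly by enumerating
 * point subsets and linear solves. Per-gene values are memoized over the
 * local regulator mask, and F is minimized by exhaustive enumeration of all
 * TF subsets of size <= cap (ties: smaller objective, then smaller subset,
 * then lexicographic order).
 *
 * Returns ok = FALSE when the instance is out of the supported range
 * (callers then fall back to the generic MIP backend).
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

#define MAX_P 16     /* max parameters (intercept + regulators) per gene fit */
#define MAX_N 24     /* max samples */
#define EPS_SING 1e-9
#define EPS_TIE 1e-9

/* solve A x = b (p x p) in place; returns 0 on success, 1 if singular */
static int solve_dense(int p, double *A, double *b, double *x)
{
    int piv[MAX_P];
    int i, j, k;
    for (i = 0; i < p; i++) piv[i] = i;
    for (k = 0; k < p; k++) {
        int best = k;
        double bestv = fabs(A[k * p + k]);
        for (i = k + 1; i < p; i++) {
            double v = fabs(A[k * p + i]);
            if (v > bestv) { bestv = v; best = i; }
        }
        if (bestv < EPS_SING) return 1;
        if (best != k) {
            for (j = 0; j < p; j++) {
                double tmp = A[j * p + k];
                A[j * p + k] = A[j * p + best];
                A[j * p + best] = tmp;
            }
            double tb = b[k]; b[k] = b[best]; b[best] = tb;
        }
        for (i = k + 1; i < p; i++) {
            double f = A[k * p + i] / A[k * p + k];
            if (f == 0.0) continue;
            for (j = k; j < p; j++) A[j * p + i] -= f * A[j * p + k];
            b[i] -= f * b[k];
        }
    }
    for (i = p - 1; i >= 0; i--) {
        double s = b[i];
        for (j = i + 1; j < p; j++) s -= A[j * p + i] * x[j];
        x[i] = s / A[i * p + i];
    }
    (void) piv;
    return 0;
}

/* column ranks of X (n x p, column major): marks independent columns.
 * Gaussian elimination on a copy, returns number of independent columns. */
static int indep_cols(int n, int p, const double *X, int *keep)
{
    double W[MAX_N * MAX_P];
    int i, j, k, r = 0;
    memcpy(W, X, sizeof(double) * n * p);
    int rowused[MAX_N];
    for (i = 0; i < n; i++) rowused[i] = 0;
    for (j = 0; j < p; j++) {
        int piv = -1;
        double bestv = EPS_SING;
        for (i = 0; i < n; i++) {
            if (!rowused[i] && fabs(W[j * n + i]) > bestv) {
                bestv = fabs(W[j * n + i]); piv = i;
            }
        }
        if (piv < 0) { keep[j] = 0; continue; }
        keep[j] = 1; r++;
        rowused[piv] = 1;
        for (i = 0; i < n; i++) {
            if (i == piv || fabs(W[j * n + i]) == 0.0) continue;
            double f = W[j * n + i] / W[j * n + piv];
            for (k = j; k < p; k++) W[k * n + i] -= f * W[k * n + piv];
        }
    }
    return r;
}

/* objective sum_k |z_k - X_k beta| */
static double l1_obj(int n, int p, const double *X, const double *z,
                     const double *beta)
{
    double s = 0.0;
    int i, j;
    for (i = 0; i < n; i++) {
        double r = z[i];
        for (j = 0; j < p; j++) r -= X[j * n + i] * beta[j];
        s += fabs(r);
    }
    return s;
}

/* exact L1 fit with full-column-rank X (n x p, p <= n): enumerate point
 * subsets of size p; returns best objective, fills beta (length p).
 * Returns -1 on failure (should not happen for full-rank X). */
static double l1_fit_rank(int n, int p, const double *X, const double *z,
                          double *beta)
{
    int idx[MAX_P];
    double best = -1.0;
    double A[MAX_P * MAX_P], b[MAX_P], x[MAX_P];
    int i, j;

    if (p == 0) return -1.0;
    for (i = 0; i < p; i++) idx[i] = i;
    for (;;) {
        /* build subsystem from points idx[0..p-1] */
        for (j = 0; j < p; j++)
            for (i = 0; i < p; i++)
                A[j * p + i] = X[j * n + idx[i]];
        for (i = 0; i < p; i++) b[i] = z[idx[i]];
        if (!solve_dense(p, A, b, x)) {
            double obj = l1_obj(n, p, X, z, x);
            if (best < 0 || obj < best - 1e-15) {
                best = obj;
                memcpy(beta, x, sizeof(double) * p);
            }
        }
        /* next combination */
        for (i = p - 1; i >= 0; i--) {
            if (idx[i] < n - p + i) {
                idx[i]++;
                for (j = i + 1; j < p; j++) idx[j] = idx[j - 1] + 1;
                break;
            }
        }
        if (i < 0) break;
    }
    return best;
}

/* general exact L1 fit: reduces to independent columns; beta entries of
 * dependent columns are 0. X n x p (p can exceed n). */
static double l1_fit(int n, int p, const double *X, const double *z,
                     double *beta)
{
    int keep[MAX_P];
    int i, j, r;
    double Xr[MAX_N * MAX_P], br[MAX_P];

    if (p > MAX_P || n > MAX_N) return -1.0;
    r = indep_cols(n, p, X, keep);
    if (r == 0) {
        for (j = 0; j < p; j++) beta[j] = 0.0;
        double s = 0.0;
        for (i = 0; i < n; i++) s += fabs(z[i]);
        return s;
    }
    int cols[MAX_P], rr = 0;
    for (j = 0; j < p; j++)
        if (keep[j]) cols[rr++] = j;
    int pr = rr > n ? n : rr; /* at most n independent columns anyway */
    for (j = 0; j < pr; j++)
        memcpy(Xr + j * n, X + cols[j] * n, sizeof(double) * n);
    double obj = l1_fit_rank(n, pr, Xr, z, br);
    if (obj < 0) return -1.0;
    for (j = 0; j < p; j++) beta[j] = 0.0;
    for (j = 0; j < pr; j++) beta[cols[j]] = br[j];
    return obj;
}

typedef struct {
    int n_reg;          /* regulators of this gene */
    const int *regs;    /* global TF index per local position (0-based) */
    const double *C;    /* n x n_reg coefficient matrix */
    const double *z;    /* n observations */
    double *memo;       /* 2^n_reg values, NA when not yet computed */
    int *pos_of_tf;     /* nT: local position or -1 */
    int mask;           /* current local mask during enumeration */
} gene_t;

static double gene_value(gene_t *g, int n, int mask)
{
    if (!ISNA(g->memo[mask])) return g->memo[mask];
    int p = 1, j;
    double X[MAX_N * MAX_P], beta[MAX_P];
    int i;
    for (i = 0; i < n; i++) X[i] = 1.0; /* intercept */
    for (j = 0; j < g->n_reg; j++) {
        if (mask & (1 << j)) {
            memcpy(X + p * n, g->C + j * n, sizeof(double) * n);
            p++;
        }
    }
    double obj = l1_fit(n, p, X, g->z, beta);
    if (obj < 0) return R_NaReal; /* signal failure upward */
    g->memo[mask] = obj;
    return obj;
}

typedef struct {
    int nT, nG, n, cap;
    gene_t *genes;
    int has_best;
    double bestF;
    int best_sel[32];
    int best_size;
    int cur_sel[32];
    double curF;
    int failed;
} enum_state_t;

static int lex_less(const int *a, int na, const int *b, int nb)
{
    int m = na < nb ? na : nb;
    int i;
    for (i = 0; i < m; i++) {
        if (a[i] != b[i]) return a[i] < b[i];
    }
    return na < nb;
}

static void consider(enum_state_t *st, int size)
{
    if (!st->has_best || st->curF < st->bestF - EPS_TIE) {
        st->has_best = 1;
        st->bestF = st->curF;
        st->best_size = size;
        memcpy(st->best_sel, st->cur_sel, sizeof(int) * size);
    } else if (fabs(st->curF - st->bestF) <= EPS_TIE) {
        if (size < st->best_size ||
            (size == st->best_size &&
             lex_less(st->cur_sel, size, st->best_sel, st->best_size))) {
            st->bestF = st->curF < st->bestF ? st->curF : st->bestF;
            st->best_size = size;
            memcpy(st->best_sel, st->cur_sel, sizeof(int) * size);
        }
    }
}

static void enum_subsets(enum_state_t *st, int start, int depth)
{
    if (st->failed) return;
    consider(st, depth);
    if (depth == st->cap) return;
    int t, i;
    for (t = start; t < st->nT; t++) {
        double saveF = st->curF;
        /* add TF t: update affected genes */
        for (i = 0; i < st->nG; i++) {
            gene_t *g = &st->genes[i];
            int pos = g->pos_of_tf[t];
            if (pos < 0) continue;
            double oldv = gene_value(g, st->n, g->mask);
            int nm = g->mask | (1 << pos);
            double newv = gene_value(g, st->n, nm);
            if (ISNA(oldv) || ISNA(newv)) { st->failed = 1; return; }
            st->curF += newv - oldv;
            g->mask = nm;
        }
        st->cur_sel[depth] = t;
        enum_subsets(st, t + 1, depth + 1);
        /* remove TF t */
        for (i = 0; i < st->nG; i++) {
            gene_t *g = &st->genes[i];
            int pos = g->pos_of_tf[t];
            if (pos < 0) continue;
            g->mask &= ~(1 << pos);
        }
        st->curF = saveF;
        if (st->failed) return;
    }
}

/* regs_list: list of integer vectors (1-based TF indices per gene)
 * C_list: list of n x n_reg coefficient matrices
 * z: n x nG matrix of observations */
SEXP C_regnet_enum(SEXP nT_sexp, SEXP cap_sexp, SEXP z_sexp, SEXP regs_list,
                   SEXP C_list, SEXP want_beta)
{
    int nT = INTEGER(nT_sexp)[0];
    int cap = INTEGER(cap_sexp)[0];
    int nG = LENGTH(regs_list);
    int n = nrows(z_sexp);
    int i, j;
    SEXP fail_res;

    if (cap > MAX_P - 1 || cap > 31 || nT > 10000 || n > MAX_N) goto fail;

    enum_state_t st;
    st.nT = nT; st.nG = nG; st.n = n;
    st.cap = cap < nT ? cap : nT;
    st.has_best = 0; st.bestF = 0.0; st.best_size = 0; st.curF = 0.0;
    st.failed = 0;
    st.genes = (gene_t *) R_alloc(nG, sizeof(gene_t));

    for (i = 0; i < nG; i++) {
        gene_t *g = &st.genes[i];
        SEXP ri = VECTOR_ELT(regs_list, i);
        g->n_reg = LENGTH(ri);
        if (g->n_reg > 20) goto fail; /* memo table would get too large */
        g->regs = INTEGER(ri);
        g->C = REAL(VECTOR_ELT(C_list, i));
        g->z = REAL(z_sexp) + (size_t) i * n;
        size_t nmask = (size_t) 1 << g->n_reg;
        g->memo = (double *) R_alloc(nmask, sizeof(double));
        for (size_t m = 0; m < nmask; m++) g->memo[m] = R_NaReal;
        g->pos_of_tf = (int *) R_alloc(nT, sizeof(int));
        for (j = 0; j < nT; j++) g->pos_of_tf[j] = -1;
        for (j = 0; j < g->n_reg; j++) g->pos_of_tf[g->regs[j] - 1] = j;
        g->mask = 0;
        double v0 = gene_value(g, n, 0);
        if (ISNA(v0)) goto fail;
        st.curF += v0;
    }

    enum_subsets(&st, 0, 0);
    if (st.failed || !st.has_best) goto fail;
    if (st.bestF < 0) st.bestF = 0.0; /* roundoff from incremental updates */

    /* recover coefficients for the winning subset */
    SEXP beta_list = R_NilValue;
    if (asLogical(want_beta)) {
        PROTECT(beta_list = allocVector(VECSXP, nG));
        for (i = 0; i < nG; i++) {
            gene_t *g = &st.genes[i];
            int mask = 0, t;
            for (t = 0; t < st.best_size; t++) {
                int pos = g->pos_of_tf[st.best_sel[t]];
                if (pos >= 0) mask |= (1 << pos);
            }
            int p = 1;
            double X[MAX_N * MAX_P], beta[MAX_P];
            int kk;
            for (kk = 0; kk < n; kk++) X[kk] = 1.0;
            int local_of_col[MAX_P];
            local_of_col[0] = -1;
            for (j = 0; j < g->n_reg; j++) {
                if (mask & (1 << j)) {
                    memcpy(X + p * n, g->C + j * n, sizeof(double) * n);
                    local_of_col[p] = j;
                    p++;
                }
            }
            double obj = l1_fit(n, p, X, g->z, beta);
            if (obj < 0) { if (asLogical(want_beta)) UNPROTECT(1); goto fail; }
            SEXP bi = allocVector(REALSXP, g->n_reg + 1);
            SET_VECTOR_ELT(beta_list, i, bi);
            for (j = 0; j <= g->n_reg; j++) REAL(bi)[j] = 0.0;
            REAL(bi)[0] = beta[0];
            for (j = 1; j < p; j++) REAL(bi)[local_of_col[j] + 1] = beta[j];
        }
    }

    SEXP res = PROTECT(allocVector(VECSXP, 4));
    SEXP nms = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(nms, 0, mkChar("ok"));
    SET_STRING_ELT(nms, 1, mkChar("objective"));
    SET_STRING_ELT(nms, 2, mkChar("selected"));
    SET_STRING_ELT(nms, 3, mkChar("beta"));
    setAttrib(res, R_NamesSymbol, nms);
    SET_VECTOR_ELT(res, 0, ScalarLogical(1));
    SET_VECTOR_ELT(res, 1, ScalarReal(st.bestF));
    SEXP sel = allocVector(INTSXP, st.best_size);
    SET_VECTOR_ELT(res, 2, sel);
    for (i = 0; i < st.best_size; i++)
        INTEGER(sel)[i] = st.best_sel[i] + 1;
    SET_VECTOR_ELT(res, 3, beta_list);
    UNPROTECT(asLogical(want_beta) ? 3 : 2);
    return res;

fail:
    fail_res = PROTECT(allocVector(VECSXP, 1));
    SEXP fnms = PROTECT(allocVector(STRSXP, 1));
    SET_STRING_ELT(fnms, 0, mkChar("ok"));
    setAttrib(fail_res, R_NamesSymbol, fnms);
    SET_VECTOR_ELT(fail_res, 0, ScalarLogical(0));
    UNPROTECT(2);
    return fail_res;
}
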