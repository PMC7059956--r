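/* Bridge between the R-level program container and the GLPK C API.
 *
 * One entry point builds a glp_prob from vectorized pieces (column bounds,
 * kinds, objective, a constraint matrix in triplet form, row senses and
 * right-hand sides), solves it with glp_simplex (pure LP) or glp_intopt
 * (any integer columns), and returns status / objective / primal values.
 * A second entry point writes the same problem in CPLEX LP format for
 * debugging.
 */

#include <glpk.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <string.h>

/* row/col bound type from finite-ness of lo/up */
static void set_bnds(glp_prob *lp, int is_row, int idx, double lo, double up)
{
    int type;
    if (lo == up)
        type = GLP_FX;
    else if (R_FINITE(lo) && R_FINITE(up))
        type = GLP_DB;
    else if (R_FINITE(lo))
        type = GLP_LO;
    else if (R_FINITE(up))
        type = GLP_UP;
    else
        type = GLP_FR;
    if (is_row)
        glp_set_row_bnds(lp, idx, type, lo, up);
    else
        glp_set_col_bnds(lp, idx, type, lo, up);
}

static glp_prob *build_prob(SEXP sense, SEXP obj, SEXP lb, SEXP ub, SEXP kind,
                            SEXP ia, SEXP ja, SEXP ar, SEXP rdir, SEXP rhs)
{
    int ncol = LENGTH(obj), nrow = LENGTH(rhs), nz = LENGTH(ar);
    int j, i, k;
    glp_prob *lp = glp_create_prob();

    glp_set_obj_dir(lp, INTEGER(sense)[0] > 0 ? GLP_MIN : GLP_MAX);
    if (ncol > 0) glp_add_cols(lp, ncol);
    for (j = 0; j < ncol; j++) {
        set_bnds(lp, 0, j + 1, REAL(lb)[j], REAL(ub)[j]);
        glp_set_obj_coef(lp, j + 1, REAL(obj)[j]);
        if (INTEGER(kind)[j] != 0)
            glp_set_col_kind(lp, j + 1, GLP_IV); /* bounds already set */
    }
    if (nrow > 0) glp_add_rows(lp, nrow);
    for (i = 0; i < nrow; i++) {
        double b = REAL(rhs)[i];
        int d = INTEGER(rdir)[i]; /* 1: <=, 2: ==, 3: >= */
        if (d == 1)
            glp_set_row_bnds(lp, i + 1, GLP_UP, 0.0, b);
        else if (d == 2)
            glp_set_row_bnds(lp, i + 1, GLP_FX, b, b);
        else
            glp_set_row_bnds(lp, i + 1, GLP_LO, b, 0.0);
    }
    if (nz > 0) {
        /* glp_load_matrix uses 1-based arrays with a dummy element 0 */
        int *mi = (int *) R_alloc(nz + 1, sizeof(int));
        int *mj = (int *) R_alloc(nz + 1, sizeof(int));
        double *mv = (double *) R_alloc(nz + 1, sizeof(double));
        for (k = 0; k < nz; k++) {
            mi[k + 1] = INTEGER(ia)[k];
            mj[k + 1] = INTEGER(ja)[k];
            mv[k + 1] = REAL(ar)[k];
        }
        glp_load_matrix(lp, nz, mi, mj, mv);
    }
    return lp;
}

static SEXP mk_result(const char *status, double objval, SEXP sol)
{
    SEXP res = PROTECT(allocVector(VECSXP, 3));
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("status"));
    SET_STRING_ELT(nms, 1, mkChar("objective"));
    SET_STRING_ELT(nms, 2, mkChar("solution"));
    setAttrib(res, R_NamesSymbol, nms);
    SET_VECTOR_ELT(res, 0, mkString(status));
    SET_VECTOR_ELT(res, 1, ScalarReal(objval));
    SET_VECTOR_ELT(res, 2, sol);
    UNPROTECT(2);
    return res;
}

SEXP C_glpk_solve(SEXP sense, SEXP obj, SEXP lb, SEXP ub, SEXP kind,
                  SEXP ia, SEXP ja, SEXP ar, SEXP rdir, SEXP rhs,
                  SEXP tol, SEXP time_limit_ms)
{
    int ncol = LENGTH(obj);
    int j, has_int = 0, ret;
    SEXP sol, res;
    glp_prob *lp;

    for (j = 0; j < ncol; j++)
        if (INTEGER(kind)[j] != 0) { has_int = 1; break; }

    glp_term_out(GLP_OFF);
    lp = build_prob(sense, obj, lb, ub, kind, ia, ja, ar, rdir, rhs);

    if (!has_int) {
        glp_smcp parm;
        glp_init_smcp(&parm);
        parm.msg_lev = GLP_MSG_OFF;
        parm.tol_bnd = REAL(tol)[0];
        parm.tol_dj  = REAL(tol)[0];
        if (R_FINITE(REAL(time_limit_ms)[0]))
            parm.tm_lim = (int) REAL(time_limit_ms)[0];
        ret = glp_simplex(lp, &parm);
        if (ret != 0) {
            glp_delete_prob(lp);
            return mk_result("error", NA_REAL, R_NilValue);
        }
        switch (glp_get_status(lp)) {
        case GLP_OPT:
            sol = PROTECT(allocVector(REALSXP, ncol));
            for (j = 0; j < ncol; j++)
                REAL(sol)[j] = glp_get_col_prim(lp, j + 1);
            res = mk_result("optimal", glp_get_obj_val(lp), sol);
            UNPROTECT(1);
            break;
        case GLP_INFEAS:
        case GLP_NOFEAS:
            res = mk_result("infeasible", NA_REAL, R_NilValue);
            break;
        case GLP_UNBND:
            res = mk_result("unbounded", NA_REAL, R_NilValue);
            break;
        default:
            res = mk_result("error", NA_REAL, R_NilValue);
        }
        glp_delete_prob(lp);
        return res;
    }

    {
        glp_iocp parm;
        glp_init_iocp(&parm);
        parm.msg_lev = GLP_MSG_OFF;
        parm.presolve = GLP_ON;
        parm.gmi_cuts = GLP_ON;
        parm.mir_cuts = GLP_ON;
        parm.tol_int = REAL(tol)[0];
        if (R_FINITE(REAL(time_limit_ms)[0]))
            parm.tm_lim = (int) REAL(time_limit_ms)[0];
        ret = glp_intopt(lp, &parm);
        if (ret == GLP_ENOPFS) {
            res = mk_result("infeasible", NA_REAL, R_NilValue);
        } else if (ret == GLP_ENODFS) {
            res = mk_result("unbounded", NA_REAL, R_NilValue);
        } else if (ret == 0 || ret == GLP_ETMLIM || ret == GLP_EMIPGAP) {
            int st = glp_mip_status(lp);
            if (st == GLP_OPT || st == GLP_FEAS) {
                sol = PROTECT(allocVector(REALSXP, ncol));
                for (j = 0; j < ncol; j++)
                    REAL(sol)[j] = glp_mip_col_val(lp, j + 1);
                res = mk_result(st == GLP_OPT ? "optimal" : "feasible",
                                glp_mip_obj_val(lp), sol);
                UNPROTECT(1);
            } else if (st == GLP_NOFEAS) {
                res = mk_result("infeasible", NA_REAL, R_NilValue);
            } else {
                res = mk_result("error", NA_REAL, R_NilValue);
            }
        } else {
            res = mk_result("error", NA_REAL, R_NilValue);
        }
        glp_delete_prob(lp);
        return res;
    }
}

SEXP C_glpk_write_lp(SEXP sense, SEXP obj, SEXP lb, SEXP ub, SEXP kind,
                     SEXP ia, SEXP ja, SEXP ar, SEXP rdir, SEXP rhs,
                     SEXP names, SEXP path)
{
    glp_prob *lp;
    int j, ok;
    glp_term_out(GLP_OFF);
    lp = build_prob(sense, obj, lb, ub, kind, ia, ja, ar, rdir, rhs);
    for (j = 0; j < LENGTH(names); j++)
        glp_set_col_name(lp, j + 1, CHAR(STRING_ELT(names, j)));
    ok = glp_write_lp(lp, NULL, CHAR(STRING_ELT(path, 0)));
    glp_delete_prob(lp);
    return ScalarLogical(ok == 0);
}

SEXP C_regnet_enum(SEXP nT_sexp, SEXP cap_sexp, SEXP z_sexp, SEXP regs_list,
                   SEXP C_list, SEXP want_beta);

static const R_CallMethodDef call_methods[] = {
    {"C_glpk_solve",    (DL_FUNC) &C_glpk_solve,    12},
    {"C_glpk_write_lp", (DL_FUNC) &C_glpk_write_lp, 12},
    {"C_regnet_enum",   (DL_FUNC) &C_regnet_enum,    6},
    {NULL, NULL, 0}
};

void R_init_macrep(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
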