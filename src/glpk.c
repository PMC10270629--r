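/* Thin .Call interface to the GLPK simplex solver for flux balance and
 * flux variability analysis.  Problems are steady-state LPs
 *   max/min c'v  s.t.  S v = 0,  lb <= v <= ub
 * passed as the stoichiometric matrix in triplet form.  All bounds are
 * expected finite (capped upstream). */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <glpk.h>
#include <string.h>

#define FC_OPTIMAL    0
#define FC_INFEASIBLE 1
#define FC_UNBOUNDED  2
#define FC_FAILED     3

static glp_prob *fc_build(int m, int n,
                          const int *ti, const int *tj, const double *tx,
                          int nnz, const double *lb, const double *ub)
{
    glp_prob *lp = glp_create_prob();
    glp_add_rows(lp, m);
    glp_add_cols(lp, n);
    for (int i = 1; i <= m; i++)
        glp_set_row_bnds(lp, i, GLP_FX, 0.0, 0.0);
    for (int j = 1; j <= n; j++) {
        if (lb[j - 1] == ub[j - 1])
            glp_set_col_bnds(lp, j, GLP_FX, lb[j - 1], ub[j - 1]);
        else
            glp_set_col_bnds(lp, j, GLP_DB, lb[j - 1], ub[j - 1]);
    }
    /* glp_load_matrix wants 1-based arrays with a dummy 0 element */
    int    *ia = (int *)    R_alloc(nnz + 1, sizeof(int));
    int    *ja = (int *)    R_alloc(nnz + 1, sizeof(int));
    double *ar = (double *) R_alloc(nnz + 1, sizeof(double));
    for (int k = 0; k < nnz; k++) {
        ia[k + 1] = ti[k];
        ja[k + 1] = tj[k];
        ar[k + 1] = tx[k];
    }
    glp_load_matrix(lp, nnz, ia, ja, ar);
    return lp;
}

static int fc_solve(glp_prob *lp, int warm)
{
    glp_smcp parm;
    glp_init_smcp(&parm);
    parm.msg_lev = GLP_MSG_OFF;
    parm.meth = GLP_DUALP;          /* dual simplex, primal fallback */
    int ret = glp_simplex(lp, &parm);
    if (ret != 0 || glp_get_status(lp) == GLP_UNDEF) {
        /* cold restart with the presolver if the warm basis failed */
        glp_init_smcp(&parm);
        parm.msg_lev = GLP_MSG_OFF;
        parm.presolve = GLP_ON;
        ret = glp_simplex(lp, &parm);
        if (ret == GLP_ENOPFS) return FC_INFEASIBLE;
        if (ret == GLP_ENODFS) return FC_UNBOUNDED;
        if (ret != 0) return FC_FAILED;
    }
    (void) warm;
    switch (glp_get_status(lp)) {
    case GLP_OPT:    return FC_OPTIMAL;
    case GLP_NOFEAS: return FC_INFEASIBLE;
    case GLP_INFEAS: return FC_INFEASIBLE;
    case GLP_UNBND:  return FC_UNBOUNDED;
    default:         return FC_FAILED;
    }
}

/* Single LP: returns list(status, objval, flux) */
SEXP fc_glpk_fba(SEXP sI, SEXP sJ, SEXP sX, SEXP sM, SEXP sN,
                 SEXP sLb, SEXP sUb, SEXP sObj, SEXP sMax)
{
    int m = asInteger(sM), n = asInteger(sN), nnz = length(sX);
    glp_prob *lp = fc_build(m, n, INTEGER(sI), INTEGER(sJ), REAL(sX),
                            nnz, REAL(sLb), REAL(sUb));
    const double *obj = REAL(sObj);
    for (int j = 1; j <= n; j++)
        if (obj[j - 1] != 0.0) glp_set_obj_coef(lp, j, obj[j - 1]);
    glp_set_obj_dir(lp, asLogical(sMax) ? GLP_MAX : GLP_MIN);

    int status = fc_solve(lp, 0);

    SEXP ans = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(ans, 0, ScalarInteger(status));
    SET_VECTOR_ELT(ans, 1, ScalarReal(status == FC_OPTIMAL ?
                                      glp_get_obj_val(lp) : NA_REAL));
    SEXP flux = PROTECT(allocVector(REALSXP, n));
    for (int j = 1; j <= n; j++)
        REAL(flux)[j - 1] = (status == FC_OPTIMAL) ?
            glp_get_col_prim(lp, j) : NA_REAL;
    SET_VECTOR_ELT(ans, 2, flux);
    glp_delete_prob(lp);
    UNPROTECT(2);
    return ans;
}

/* FVA over a set of columns, reusing one problem and warm bases.
 * Returns list(status[k], min[k], max[k]) for the requested columns. */
SEXP fc_glpk_fva(SEXP sI, SEXP sJ, SEXP sX, SEXP sM, SEXP sN,
                 SEXP sLb, SEXP sUb, SEXP sCols)
{
    int m = asInteger(sM), n = asInteger(sN), nnz = length(sX);
    int k = length(sCols);
    const int *cols = INTEGER(sCols);
    glp_prob *lp = fc_build(m, n, INTEGER(sI), INTEGER(sJ), REAL(sX),
                            nnz, REAL(sLb), REAL(sUb));

    SEXP ans  = PROTECT(allocVector(VECSXP, 3));
    SEXP stat = PROTECT(allocVector(INTSXP,  k));
    SEXP vmin = PROTECT(allocVector(REALSXP, k));
    SEXP vmax = PROTECT(allocVector(REALSXP, k));

    int prev = 0;
    for (int t = 0; t < k; t++) {
        int j = cols[t];
        if (prev > 0) glp_set_obj_coef(lp, prev, 0.0);
        glp_set_obj_coef(lp, j, 1.0);
        prev = j;

        glp_set_obj_dir(lp, GLP_MIN);
        int s1 = fc_solve(lp, t > 0);
        double lo = (s1 == FC_OPTIMAL) ? glp_get_obj_val(lp) : NA_REAL;
        glp_set_obj_dir(lp, GLP_MAX);
        int s2 = fc_solve(lp, 1);
        double hi = (s2 == FC_OPTIMAL) ? glp_get_obj_val(lp) : NA_REAL;

        int s = (s1 == FC_OPTIMAL && s2 == FC_OPTIMAL) ? FC_OPTIMAL :
                (s1 == FC_INFEASIBLE || s2 == FC_INFEASIBLE) ? FC_INFEASIBLE :
                (s1 == FC_UNBOUNDED  || s2 == FC_UNBOUNDED)  ? FC_UNBOUNDED :
                FC_FAILED;
        INTEGER(stat)[t] = s;
        REAL(vmin)[t] = lo;
        REAL(vmax)[t] = hi;
    }
    SET_VECTOR_ELT(ans, 0, stat);
    SET_VECTOR_ELT(ans, 1, vmin);
    SET_VECTOR_ELT(ans, 2, vmax);
    glp_delete_prob(lp);
    UNPROTECT(4);
    return ans;
}

static const R_CallMethodDef callMethods[] = {
    {"fc_glpk_fba", (DL_FUNC) &fc_glpk_fba, 9},
    {"fc_glpk_fva", (DL_FUNC) &fc_glpk_fva, 8},
    {NULL, NULL, 0}
};

void R_init_FluxCohort(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    glp_term_out(GLP_OFF);
}
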