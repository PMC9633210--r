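#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* Fused in-place Adam update: m, v and the parameter vector are updated in
 * one pass, avoiding the temporary allocations an R-level update needs.
 * The bias correction is folded into lr_t by the caller. All four vectors
 * are private to the training loop, so in-place mutation is safe. */
SEXP C_adam_update(SEXP p, SEXP m, SEXP v, SEXP g,
                   SEXP b1_, SEXP b2_, SEXP lrt_, SEXP eps_)
{
    const double b1 = Rf_asReal(b1_), b2 = Rf_asReal(b2_);
    const double lrt = Rf_asReal(lrt_), eps = Rf_asReal(eps_);
    const R_xlen_t n = XLENGTH(p);
    double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v);
    const double *pg = REAL(g);
    for (R_xlen_t i = 0; i < n; i++) {
        const double gi = pg[i];
        const double mi = b1 * pm[i] + (1.0 - b1) * gi;
        const double vi = b2 * pv[i] + (1.0 - b2) * gi * gi;
        pm[i] = mi;
        pv[i] = vi;
        pp[i] -= lrt * mi / (sqrt(vi) + eps);
    }
    return R_NilValue;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_adam_update", (DL_FUNC) &C_adam_update, 8},
    {NULL, NULL, 0}
};

void R_init_survomics(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
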