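#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void mnm_initmod(void (*odeparms)(int *, double *));
void mnm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
SEXP mnm_net_rk4(SEXP s_par, SEXP s_tbreak, SEXP s_ibreak,
                 SEXP s_dt, SEXP s_nstep, SEXP s_thin, SEXP s_y0);

static const R_CallMethodDef call_entries[] = {
    {"mnm_net_rk4", (DL_FUNC) &mnm_net_rk4, 7},
    {NULL, NULL, 0}
};

/* registered so that deSolve can look them up by name */
static const R_CMethodDef c_entries[] = {
    {"mnm_initmod", (DL_FUNC) &mnm_initmod, 1},
    {"mnm_derivs",  (DL_FUNC) &mnm_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_mnm(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
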