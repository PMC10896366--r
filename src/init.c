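#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* qif_net.cpp */
extern SEXP pingmf_simulate_qif(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                SEXP, SEXP, SEXP, SEXP, SEXP);

/* mf_ode.c: deSolve compiled-model entry points */
extern void mf_initmod(void (*odeparms)(int *, double *));
extern void mf_derivs(int *, double *, double *, double *, double *, int *);
extern void mf_jac(int *, double *, double *, int *, int *, double *, int *,
                   double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"pingmf_simulate_qif", (DL_FUNC) &pingmf_simulate_qif, 19},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"mf_initmod", (DL_FUNC) &mf_initmod, 1},
    {"mf_derivs", (DL_FUNC) &mf_derivs, 6},
    {"mf_jac", (DL_FUNC) &mf_jac, 9},
    {NULL, NULL, 0}
};

void R_init_pingmf(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
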