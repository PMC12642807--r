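#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_rk4_full(SEXP, SEXP, SEXP, SEXP);
extern SEXP C_rk4_reduced(SEXP, SEXP, SEXP, SEXP);

extern void sv_init_full(void *);
extern void sv_derivs_full(int *, double *, double *, double *, double *, int *);
extern void sv_root_full(int *, double *, double *, int *, double *, double *, int *);
extern void sv_init_reduced(void *);
extern void sv_derivs_reduced(int *, double *, double *, double *, double *, int *);
extern void sv_root_reduced(int *, double *, double *, int *, double *, double *, int *);

static const R_CallMethodDef call_entries[] = {
    {"C_rk4_full", (DL_FUNC) &C_rk4_full, 4},
    {"C_rk4_reduced", (DL_FUNC) &C_rk4_reduced, 4},
    {NULL, NULL, 0}
};

void R_init_symbiovade(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* deSolve looks the derivative/root symbols up by name */
    R_useDynamicSymbols(dll, TRUE);
}
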