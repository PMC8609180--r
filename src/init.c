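#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP c_h5_write_recording(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP c_h5_read_recording(SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"c_h5_write_recording", (DL_FUNC) &c_h5_write_recording, 6},
    {"c_h5_read_recording",  (DL_FUNC) &c_h5_read_recording,  1},
    {NULL, NULL, 0}
};

void R_init_slicephys(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
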