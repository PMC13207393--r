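#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_sha256(SEXP data);
SEXP C_hmac_sha256(SEXP key, SEXP msg);
SEXP C_pbkdf2_sha256(SEXP pass, SEXP salt, SEXP iter, SEXP dklen);
SEXP C_logistic(SEXP r_, SEXP x0_, SEXP burn_, SEXP n_);
SEXP C_chain_apply(SEXP x_, SEXP sbox_, SEXP k1_, SEXP k2_, SEXP k3_,
                   SEXP iv_, SEXP backward_, SEXP inverse_);
SEXP C_hairpin(SEXP x_, SEXP stem_, SEXP loop_, SEXP window_);
SEXP C_rs_encode(SEXP data_, SEXP nsym_);
SEXP C_rs_decode(SEXP coded_, SEXP nsym_);

static const R_CallMethodDef callMethods[] = {
    {"C_sha256",        (DL_FUNC) &C_sha256,        1},
    {"C_hmac_sha256",   (DL_FUNC) &C_hmac_sha256,   2},
    {"C_pbkdf2_sha256", (DL_FUNC) &C_pbkdf2_sha256, 4},
    {"C_logistic",      (DL_FUNC) &C_logistic,      4},
    {"C_chain_apply",   (DL_FUNC) &C_chain_apply,   8},
    {"C_hairpin",       (DL_FUNC) &C_hairpin,       4},
    {"C_rs_encode",     (DL_FUNC) &C_rs_encode,     2},
    {"C_rs_decode",     (DL_FUNC) &C_rs_decode,     2},
    {NULL, NULL, 0}
};

void R_init_helixcrypt(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
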