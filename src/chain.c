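/* Sequential layers that cannot be vectorized in R: the chaotic logistic
 * iteration, the context-chained substitution passes of the transcription
 * layer, and the hairpin (reverse-complement stem) screen. Symbols are
 * integers 0..3 in the canonical base order A,C,G,T/U; the Watson-Crick
 * complement is 3 - x. */

#include <R.h>
#include <Rinternals.h>

SEXP C_logistic(SEXP r_, SEXP x0_, SEXP burn_, SEXP n_)
{
    double r = asReal(r_), x = asReal(x0_);
    R_xlen_t burn = (R_xlen_t) asReal(burn_), n = (R_xlen_t) asReal(n_);
    if (!(x > 0.0 && x < 1.0)) error("x0 must lie strictly in (0, 1)");
    for (R_xlen_t i = 0; i < burn; i++) x = r * x * (1.0 - x);
    SEXP ans = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(ans);
    for (R_xlen_t i = 0; i < n; i++) {
        x = r * x * (1.0 - x);
        y[i] = x;
    }
    UNPROTECT(1);
    return ans;
}

/* One chained-substitution pass.
 *
 * Context register holds the previous 12 output symbols (24 bits, newest in
 * the low bits); its three bytes are looked up in the keyed tables k1,k2,k3
 * and xored to select a 2-bit context class c.  The symbol substitution is
 * the coset box B_c(x) = sbox[x] ^ c, a bijection on {0..3} for every c.
 * Inversion reads the register from the pass's own output symbols, so a
 * corrupted symbol perturbs at most the following 12 positions.
 */
SEXP C_chain_apply(SEXP x_, SEXP sbox_, SEXP k1_, SEXP k2_, SEXP k3_,
                   SEXP iv_, SEXP backward_, SEXP inverse_)
{
    R_xlen_t n = XLENGTH(x_);
    int *x = INTEGER(x_);
    int sbox[4], sinv[4];
    for (int i = 0; i < 4; i++) sbox[i] = INTEGER(sbox_)[i];
    for (int i = 0; i < 4; i++) sinv[sbox[i]] = i;
    unsigned char *k1 = RAW(k1_), *k2 = RAW(k2_), *k3 = RAW(k3_);
    unsigned int reg = (unsigned int) asInteger(iv_) & 0xFFFFFFu;
    int backward = asLogical(backward_), inverse = asLogical(inverse_);

    SEXP ans = PROTECT(allocVector(INTSXP, n));
    int *y = INTEGER(ans);
    for (R_xlen_t step = 0; step < n; step++) {
        R_xlen_t i = backward ? (n - 1 - step) : step;
        int c = (k1[reg & 0xFF] ^ k2[(reg >> 8) & 0xFF] ^ k3[(reg >> 16) & 0xFF]) & 3;
        int out, fed;
        if (!inverse) {
            out = sbox[x[i]] ^ c;
            fed = out;          /* encryption feeds its own output */
        } else {
            out = sinv[x[i] ^ c];
            fed = x[i];         /* decryption feeds the ciphertext symbol */
        }
        y[i] = out;
        reg = ((reg << 2) | (unsigned int) fed) & 0xFFFFFFu;
    }
    UNPROTECT(1);
    return ans;
}

/* Count (i, j) stem placements where the stem_min-mer starting at i is the
 * reverse complement of the stem_min-mer starting at j, with a loop of at
 * least loop_min symbols between the stem halves and the whole placement
 * inside a window of `window` symbols. */
SEXP C_hairpin(SEXP x_, SEXP stem_, SEXP loop_, SEXP window_)
{
    R_xlen_t n = XLENGTH(x_);
    int *x = INTEGER(x_);
    int stem = asInteger(stem_), loop = asInteger(loop_), window = asInteger(window_);
    double count = 0;
    for (R_xlen_t i = 0; i + 2 * stem + loop <= n; i++) {
        R_xlen_t jmax = i + window - stem;      /* stem end j+stem-1 <= i+window-1 */
        if (jmax > n - stem) jmax = n - stem;
        for (R_xlen_t j = i + stem + loop; j <= jmax; j++) {
            int hit = 1;
            for (int t = 0; t < stem; t++) {
                if (x[i + t] != 3 - x[j + stem - 1 - t]) { hit = 0; break; }
            }
            count += hit;
        }
    }
    return ScalarReal(count);
}
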