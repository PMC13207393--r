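/* Systematic Reed-Solomon codec over GF(2^8), primitive polynomial 0x11d,
 * generator element alpha = 2, first consecutive root alpha^0.  Decoding is
 * Berlekamp-Massey + Chien search + Forney.  Shortened codewords are
 * supported implicitly: leading zero data bytes change neither the parity
 * nor the syndromes. */

#include <R.h>
#include <Rinternals.h>
#include <string.h>

static unsigned char gf_exp[512];
static unsigned char gf_log[256];
static int tables_ready = 0;

static void gf_init(void)
{
    if (tables_ready) return;
    int x = 1;
    for (int i = 0; i < 255; i++) {
        gf_exp[i] = (unsigned char) x;
        gf_log[x] = (unsigned char) i;
        x <<= 1;
        if (x & 0x100) x ^= 0x11d;
    }
    for (int i = 255; i < 512; i++) gf_exp[i] = gf_exp[i - 255];
    tables_ready = 1;
}

static unsigned char gmul(unsigned char a, unsigned char b)
{
    if (a == 0 || b == 0) return 0;
    return gf_exp[gf_log[a] + gf_log[b]];
}

static unsigned char ginv(unsigned char a)
{
    return gf_exp[255 - gf_log[a]];
}

/* generator polynomial, highest-degree coefficient first, length nsym+1 */
static void gen_poly(int nsym, unsigned char *g)
{
    g[0] = 1;
    int glen = 1;
    for (int i = 0; i < nsym; i++) {
        /* multiply by (x + alpha^i): new[j] = g[j] ^ alpha^i * g[j-1] */
        unsigned char a = gf_exp[i];
        g[glen] = 0;
        for (int j = glen; j >= 1; j--)
            g[j] ^= gmul(a, g[j - 1]);
        glen++;
    }
}

SEXP C_rs_encode(SEXP data_, SEXP nsym_)
{
    gf_init();
    int nsym = asInteger(nsym_);
    R_xlen_t k = XLENGTH(data_);
    if (nsym < 1 || nsym > 254 || k + nsym > 255)
        error("invalid Reed-Solomon parameters");
    unsigned char g[256];
    gen_poly(nsym, g);
    unsigned char *d = RAW(data_);
    unsigned char rem[256];
    memset(rem, 0, (size_t) nsym);
    for (R_xlen_t i = 0; i < k; i++) {
        unsigned char f = d[i] ^ rem[0];
        memmove(rem, rem + 1, (size_t) (nsym - 1));
        rem[nsym - 1] = 0;
        if (f)
            for (int j = 0; j < nsym; j++)
                rem[j] ^= gmul(f, g[j + 1]);
    }
    SEXP ans = PROTECT(allocVector(RAWSXP, nsym));
    memcpy(RAW(ans), rem, (size_t) nsym);
    UNPROTECT(1);
    return ans;
}

/* evaluate polynomial given highest-degree-first coefficients */
static unsigned char poly_eval_high(const unsigned char *p, int len, unsigned char xv)
{
    unsigned char y = 0;
    for (int i = 0; i < len; i++) y = gmul(y, xv) ^ p[i];
    return y;
}

/* evaluate polynomial given lowest-degree-first coefficients */
static unsigned char poly_eval_low(const unsigned char *p, int len, unsigned char xv)
{
    unsigned char y = 0;
    for (int i = len - 1; i >= 0; i--) y = gmul(y, xv) ^ p[i];
    return y;
}

/* Returns list(data raw, status int, nerr int); status 0 = ok, 1 = uncorrectable */
SEXP C_rs_decode(SEXP coded_, SEXP nsym_)
{
    gf_init();
    int nsym = asInteger(nsym_);
    int L = (int) XLENGTH(coded_);
    if (nsym < 1 || L <= nsym || L > 255) error("invalid codeword framing");
    unsigned char r[255];
    memcpy(r, RAW(coded_), (size_t) L);

    int status = 0, nerr = 0;

    unsigned char synd[256];
    int all_zero = 1;
    for (int i = 0; i < nsym; i++) {
        synd[i] = poly_eval_high(r, L, gf_exp[i]);
        if (synd[i]) all_zero = 0;
    }

    if (!all_zero) {
        /* Berlekamp-Massey, lowest-degree-first locator C(x) */
        unsigned char C[256], B[256], T[256];
        memset(C, 0, sizeof C); memset(B, 0, sizeof B);
        C[0] = 1; B[0] = 1;
        int LL = 0, m = 1;
        unsigned char b = 1;
        for (int nn = 0; nn < nsym; nn++) {
            unsigned char d = synd[nn];
            for (int i = 1; i <= LL; i++) d ^= gmul(C[i], synd[nn - i]);
            if (d == 0) {
                m++;
            } else if (2 * LL <= nn) {
                memcpy(T, C, sizeof T);
                unsigned char coef = gmul(d, ginv(b));
                for (int i = 0; i + m < 256; i++)
                    C[i + m] ^= gmul(coef, B[i]);
                LL = nn + 1 - LL;
                memcpy(B, T, sizeof B);
                b = d;
                m = 1;
            } else {
                unsigned char coef = gmul(d, ginv(b));
                for (int i = 0; i + m < 256; i++)
                    C[i + m] ^= gmul(coef, B[i]);
                m++;
            }
        }
        nerr = LL;
        if (2 * LL > nsym) {
            status = 1;
        } else {
            /* Chien search over the L received positions */
            int pos[128], nroots = 0;
            for (int p = 0; p < L && nroots <= LL; p++) {
                unsigned char xinv = gf_exp[(255 - ((L - 1 - p) % 255)) % 255];
                if (poly_eval_low(C, LL + 1, xinv) == 0) {
                    if (nroots < 128) pos[nroots] = p;
                    nroots++;
                }
            }
            if (nroots != LL) {
                status = 1;
            } else {
                /* Omega(x) = S(x) C(x) mod x^nsym, lowest-first */
                unsigned char omega[256];
                memset(omega, 0, sizeof omega);
                for (int i = 0; i < nsym; i++) {
                    unsigned char acc = 0;
                    for (int j = 0; j <= i && j <= LL; j++)
                        acc ^= gmul(C[j], synd[i - j]);
                    omega[i] = acc;
                }
                /* formal derivative C'(x): odd-power terms */
                unsigned char dC[256];
                memset(dC, 0, sizeof dC);
                for (int i = 1; i <= LL; i += 2) dC[i - 1] = C[i];
                for (int e = 0; e < LL; e++) {
                    int p = pos[e];
                    unsigned char X = gf_exp[(L - 1 - p) % 255];
                    unsigned char Xinv = ginv(X);
                    unsigned char den = poly_eval_low(dC, LL, Xinv);
                    if (den == 0) { status = 1; break; }
                    unsigned char num = poly_eval_low(omega, nsym, Xinv);
                    unsigned char mag = gmul(X, gmul(num, ginv(den)));
                    r[p] ^= mag;
                }
                if (status == 0) {
                    for (int i = 0; i < nsym && status == 0; i++)
                        if (poly_eval_high(r, L, gf_exp[i])) status = 1;
                }
            }
        }
    }

    SEXP data = PROTECT(allocVector(RAWSXP, L - nsym));
    memcpy(RAW(data), r, (size_t) (L - nsym));
    SEXP ans = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(ans, 0, data);
    SET_VECTOR_ELT(ans, 1, ScalarInteger(status));
    SET_VECTOR_ELT(ans, 2, ScalarInteger(nerr));
    SEXP nm = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nm, 0, mkChar("data"));
    SET_STRING_ELT(nm, 1, mkChar("status"));
    SET_STRING_ELT(nm, 2, mkChar("nerr"));
    setAttrib(ans, R_NamesSymbol, nm);
    UNPROTECT(3);
    return ans;
}
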