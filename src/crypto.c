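/* Hash/KDF primitives backed by the system OpenSSL libcrypto. */

#include <R.h>
#include <Rinternals.h>
#include <openssl/evp.h>
#include <openssl/hmac.h>
#include <openssl/sha.h>

SEXP C_sha256(SEXP data)
{
    unsigned char out[SHA256_DIGEST_LENGTH];
    SHA256(RAW(data), (size_t) XLENGTH(data), out);
    SEXP ans = PROTECT(allocVector(RAWSXP, SHA256_DIGEST_LENGTH));
    memcpy(RAW(ans), out, SHA256_DIGEST_LENGTH);
    UNPROTECT(1);
    return ans;
}

SEXP C_hmac_sha256(SEXP key, SEXP msg)
{
    unsigned char out[SHA256_DIGEST_LENGTH];
    unsigned int len = SHA256_DIGEST_LENGTH;
    if (!HMAC(EVP_sha256(), RAW(key), (int) XLENGTH(key),
              RAW(msg), (size_t) XLENGTH(msg), out, &len))
        error("HMAC-SHA256 failed");
    SEXP ans = PROTECT(allocVector(RAWSXP, len));
    memcpy(RAW(ans), out, len);
    UNPROTECT(1);
    return ans;
}

SEXP C_pbkdf2_sha256(SEXP pass, SEXP salt, SEXP iter, SEXP dklen)
{
    int it = asInteger(iter), dk = asInteger(dklen);
    if (it < 1 || dk < 1) error("invalid PBKDF2 parameters");
    SEXP ans = PROTECT(allocVector(RAWSXP, dk));
    if (!PKCS5_PBKDF2_HMAC((const char *) RAW(pass), (int) XLENGTH(pass),
                           RAW(salt), (int) XLENGTH(salt),
                           it, EVP_sha256(), dk, RAW(ans)))
        error("PBKDF2 failed");
    UNPROTECT(1);
    return ans;
}
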