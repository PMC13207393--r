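#' Derive all key material from a passphrase
#'
#' The passphrase is stretched with PBKDF2-HMAC-SHA256 to a 512-bit (64-byte)
#' master key.  Everything key-dependent in the pipeline is derived from the
#' master key deterministically: the encoding-table index is the SHA-256
#' digest of the master key reduced mod 24, the one-time-pad keystream is
#' HMAC-SHA256 in counter mode, and the chaotic permutation seed is a
#' key-derived initial condition for the logistic map.  The salt is public
#' (stored in the ciphertext header); the iteration count is the usual
#' work-factor dial against dictionary attacks.
#'
#' @param passphrase Non-empty character scalar (UTF-8) or raw vector.
#' @param salt 16-byte raw vector; freshly drawn from the session RNG when
#'   omitted.
#' @param iterations PBKDF2 iteration count (>= 1); default 600000.
#' @return A `key_material` object with fields `master_key` (64 raw bytes),
#'   `salt`, `kdf_iterations`, `table_index` (0..23) and `stream_nonce`
#'   (counter, starts at 0).
#' @examples
#' key <- derive_master_key("correct horse", salt = as.raw(1:16),
#'                          iterations = 1000)
#' key$table_index
#' @export
derive_master_key <- function(passphrase, salt = NULL, iterations = 600000L) {
  pw <- if (is.raw(passphrase)) passphrase else {
    if (!is.character(passphrase) || length(passphrase) != 1L || is.na(passphrase))
      stop("passphrase must be a single character string or raw vector", call. = FALSE)
    charToRaw(enc2utf8(passphrase))
  }
  if (length(pw) == 0L) stop("passphrase must be non-empty", call. = FALSE)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("iterations must be a positive integer", call. = FALSE)
  if (is.null(salt)) salt <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  if (!is.raw(salt) || length(salt) != 16L)
    stop("salt must be exactly 16 raw bytes", call. = FALSE)
  mk <- .Call(C_pbkdf2_sha256, pw, salt, iterations, 64L)
  structure(
    list(master_key = mk,
         salt = salt,
         kdf_iterations = iterations,
         table_index = table_index_from_key(mk),
         stream_nonce = 0L),
    class = "key_material")
}

#' @export
print.key_material <- function(x, ...) {
  cat(sprintf("<key_material: 512-bit master key, table %d, %d KDF iterations>\n",
              x$table_index, x$kdf_iterations))
  invisible(x)
}

table_index_from_key <- function(master_key) {
  digest <- .Call(C_sha256, master_key)
  # big integer mod 24, folded byte by byte
  acc <- 0L
  for (b in as.integer(digest)) acc <- (acc * 256L + b) %% 24L
  acc
}

sha256_raw <- function(data) .Call(C_sha256, data)
hmac_sha256 <- function(key, msg) .Call(C_hmac_sha256, key, msg)

uint64_be <- function(x) {
  out <- raw(8)
  x <- as.numeric(x)
  for (i in 8:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' Key-derived one-time-pad keystream
#'
#' HMAC-SHA256 in counter mode: block `i` is
#' `HMAC-SHA256(master_key, nonce || i)` with 64-bit big-endian encodings of
#' nonce and block counter; the concatenated blocks are chopped into 2-bit
#' symbols (most significant bit pair of each byte first).  The construction
#' is a deterministic PRF of `(master_key, nonce)`, so a stream is
#' reproducible and streams under distinct nonces are independent, which is
#' what the nonce-counter constraint-enforcement loop relies on.
#'
#' @param key A `key_material` object.
#' @param nonce Non-negative integer counter.
#' @param n_symbols Number of 2-bit symbols to produce (>= 1).
#' @return Integer vector of `n_symbols` values in 0..3.
#' @export
keystream <- function(key, nonce, n_symbols) {
  n_symbols <- as.integer(n_symbols)
  if (is.na(n_symbols) || n_symbols < 1L)
    stop("n_symbols must be a positive integer", call. = FALSE)
  nbytes <- ceiling(n_symbols / 4)
  nblocks <- ceiling(nbytes / 32)
  nhead <- uint64_be(nonce)
  blocks <- vapply(seq_len(nblocks) - 1L, function(i)
    hmac_sha256(key$master_key, c(nhead, uint64_be(i))), raw(32))
  bytes <- as.integer(as.vector(blocks))[seq_len(nbytes)]
  syms <- rbind(bytes %/% 64L,
                (bytes %/% 16L) %% 4L,
                (bytes %/% 4L) %% 4L,
                bytes %% 4L)
  as.integer(syms)[seq_len(n_symbols)]
}

#' Logistic-map parameters
#'
#' The chaotic recurrence `x_{n+1} = r x_n (1 - x_n)` is used in its chaotic
#' regime; the default `r = 3.99`.  A burn-in discards the transient before
#' any values are consumed.
#'
#' @param r Map parameter in `(3.57, 4]`.
#' @param x0 Initial condition strictly inside `(0, 1)`, not the fixed point
#'   `1 - 1/r`.
#' @param burn_in Number of initial iterates to discard (default 1000).
#' @return A `logistic_params` object.
#' @export
logistic_params <- function(r = 3.99, x0 = 0.5, burn_in = 1000L) {
  if (!(r > 3.57 && r <= 4)) stop("r must lie in (3.57, 4]", call. = FALSE)
  if (!(x0 > 0 && x0 < 1)) stop("x0 must lie strictly in (0, 1)", call. = FALSE)
  if (x0 == 1 - 1 / r) stop("x0 must not be the fixed point 1 - 1/r", call. = FALSE)
  burn_in <- as.integer(burn_in)
  if (is.na(burn_in) || burn_in < 0L) stop("burn_in must be >= 0", call. = FALSE)
  structure(list(r = r, x0 = x0, burn_in = burn_in), class = "logistic_params")
}

#' Iterate the logistic map
#'
#' @param params A [logistic_params()] object.
#' @param n Number of values to return after the burn-in.
#' @return Numeric vector of `n` values, all strictly in `(0, 1)`.
#' @examples
#' logistic_sequence(logistic_params(x0 = 0.5, burn_in = 0), 3)
#' @export
logistic_sequence <- function(params, n) {
  stopifnot(inherits(params, "logistic_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  .Call(C_logistic, params$r, params$x0, params$burn_in, n)
}

# key-derived initial condition: first 8 bytes of SHA-256(master_key||"perm")
# read as an unsigned big-endian integer scaled to (0,1), clamped away from
# the interval ends so the iteration cannot collapse onto 0.
chaos_x0 <- function(key) {
  d <- as.integer(sha256_raw(c(key$master_key, charToRaw("perm"))))[1:8]
  x <- sum(d * 256^(7:0)) / 2^64
  min(max(x, 2^-20), 1 - 2^-20)
}

#' Key-dependent chaotic permutation
#'
#' The permutation of `{1..n}` given by ranking `n` logistic-map iterates:
#' position `i` of the result holds the index of the i-th smallest chaotic
#' value (gather form), with ties broken by original index.  The initial
#' condition is derived from the master key, so the shuffle is part of the
#' keyed diffusion.
#'
#' @param key A `key_material` object.
#' @param n Permutation size (>= 1).
#' @param params Optional [logistic_params()]; `x0` is always overridden by
#'   the key-derived initial condition.
#' @return Integer vector: a permutation of `1:n`.
#' @export
permutation_from_chaos <- function(key, n, params = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (is.null(params)) params <- logistic_params()
  params <- logistic_params(r = params$r, x0 = chaos_x0(key),
                            burn_in = params$burn_in)
  order(logistic_sequence(params, n))
}

#' Keyed substitution-box family for the transcription layer
#'
#' Derives from the master key the material for the two chained substitution
#' passes of [transcribe()]: a base substitution `S` (one of the 24
#' bijections of `{A,C,G,U}`) per direction, three 256-entry context tables
#' per direction hashing the preceding 12-nucleotide window to one of four
#' coset boxes `B_c(x) = S(x) xor c`, and a keyed initial register standing
#' in for the out-of-sequence context at the chain start.
#'
#' @param key A `key_material` object.
#' @return An `sbox_family` object.
#' @seealso [identity_sboxes()] for the degenerate family under which
#'   [transcribe()] reduces to the plain T-to-U alphabet shift.
#' @export
sbox_family <- function(key) {
  expand <- function(label, nbytes) {
    nblocks <- ceiling(nbytes / 32)
    blocks <- vapply(seq_len(nblocks) - 1L, function(i)
      hmac_sha256(key$master_key, c(charToRaw(label), uint64_be(i))), raw(32))
    as.vector(blocks)[seq_len(nbytes)]
  }
  direction <- function(tag) {
    ctx <- expand(paste0("sbox-ctx-", tag), 768L)
    ivb <- as.integer(expand(paste0("sbox-iv-", tag), 3L))
    sel <- as.integer(expand(paste0("sbox-base-", tag), 1L)) %% 24L
    perms <- base_permutations(0:3)
    list(sbox = as.integer(perms[[sel + 1L]]),
         k1 = ctx[1:256], k2 = ctx[257:512], k3 = ctx[513:768],
         iv = ivb[1] + 256L * ivb[2] + 65536L * ivb[3])
  }
  structure(list(forward = direction("fwd"), backward = direction("bwd")),
            class = "sbox_family")
}

#' Identity substitution-box family
#'
#' All boxes are the identity and all context material is zero; under this
#' family [transcribe()] is exactly the textbook T-to-U transcription rule.
#'
#' @return An `sbox_family` object.
#' @export
identity_sboxes <- function() {
  d <- list(sbox = 0:3, k1 = raw(256), k2 = raw(256), k3 = raw(256), iv = 0L)
  structure(list(forward = d, backward = d), class = "sbox_family")
}
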