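#' Watson-Crick complement
#'
#' Positionwise `A <-> T`, `C <-> G` on a DNA sequence; an involution, and the
#' first keyless layer of the cipher.
#'
#' @param seq A DNA [nuc_seq()].
#' @return The complementary DNA [nuc_seq()].
#' @examples
#' complement(nuc_seq("TAAG"))  # ATTC
#' @export
complement <- function(seq) {
  assert_alphabet(seq, "DNA")
  nuc_seq(chartr("ACGT", "TGCA", as.character(seq)), "DNA")
}

#' One-time-pad XOR at the DNA level
#'
#' Each base is mapped to its 2-bit value under the encoding table, xored
#' with the corresponding keystream symbol, and mapped back.  Applying the
#' same stream twice is the identity.
#'
#' @param seq A DNA [nuc_seq()].
#' @param stream Integer vector of 2-bit symbols (0..3), same length as the
#'   sequence.
#' @param table The [encoding_table()] in force.
#' @return The masked DNA [nuc_seq()].
#' @export
dna_xor <- function(seq, stream, table) {
  assert_alphabet(seq, "DNA")
  n <- seq_length(seq)
  if (length(stream) != n)
    stop("keystream length must equal sequence length", call. = FALSE)
  if (n == 0L) return(seq)
  inv <- integer(4)
  inv[.seq_codes[utf8ToInt(paste(table$assignment, collapse = "")) + 1L] + 1L] <- 0:3
  vals <- bitwXor(inv[seq_ints(seq) + 1L], as.integer(stream))
  nuc_seq(paste(table$assignment[vals + 1L], collapse = ""), "DNA")
}

#' Apply / invert a gather permutation
#'
#' Gather semantics: output position `i` takes input position `p[i]`.
#' `invert_permutation()` undoes `apply_permutation()` with the same key.
#'
#' @param seq A [nuc_seq()] (either alphabet).
#' @param p Integer permutation of `1:n` where `n` is the sequence length.
#' @return The rearranged [nuc_seq()].
#' @examples
#' apply_permutation(nuc_seq("AATT"), c(4, 1, 3, 2))  # TATA
#' @export
apply_permutation <- function(seq, p) {
  ints <- seq_ints(seq)
  check_permutation(p, length(ints))
  ints_to_seq(ints[p], seq_alphabet(seq))
}

#' @rdname apply_permutation
#' @export
invert_permutation <- function(seq, p) {
  ints <- seq_ints(seq)
  check_permutation(p, length(ints))
  out <- integer(length(ints))
  out[p] <- ints
  ints_to_seq(out, seq_alphabet(seq))
}

check_permutation <- function(p, n) {
  if (length(p) != n)
    stop("permutation length must equal sequence length", call. = FALSE)
  if (n > 0L && !identical(sort(as.integer(p)), seq_len(n)))
    stop("p is not a permutation of 1..n", call. = FALSE)
  invisible(TRUE)
}

#' Transcription-inspired keyed substitution layer
#'
#' Step 1 replaces every T by U (the alphabet shift of biological
#' transcription).  Step 2 runs two chained substitution passes, forward then
#' backward: each output symbol is a keyed bijection of the input symbol,
#' selected by a keyed hash of the preceding (resp. following) 12 already
#' substituted nucleotides.  Chaining in both directions makes a change at
#' any plaintext position propagate through the entire payload, giving the
#' cipher its avalanche behaviour; because each pass's context is read from
#' its own output, inversion is local and sequential.
#'
#' @param seq A DNA [nuc_seq()].
#' @param sboxes An [sbox_family()]; with [identity_sboxes()] the layer
#'   reduces to the plain T-to-U rule.
#' @return An RNA [nuc_seq()].
#' @export
transcribe <- function(seq, sboxes) {
  assert_alphabet(seq, "DNA")
  x <- seq_ints(seq)
  x <- chain_pass(x, sboxes$forward, backward = FALSE, inverse = FALSE)
  x <- chain_pass(x, sboxes$backward, backward = TRUE, inverse = FALSE)
  ints_to_seq(x, "RNA")
}

#' @rdname transcribe
#' @export
untranscribe <- function(seq, sboxes) {
  assert_alphabet(seq, "RNA")
  x <- seq_ints(seq)
  x <- chain_pass(x, sboxes$backward, backward = TRUE, inverse = TRUE)
  x <- chain_pass(x, sboxes$forward, backward = FALSE, inverse = TRUE)
  ints_to_seq(x, "DNA")
}

chain_pass <- function(x, d, backward, inverse) {
  if (length(x) == 0L) return(x)
  .Call(C_chain_apply, x, d$sbox, d$k1, d$k2, d$k3, d$iv, backward, inverse)
}

#' Pipeline configuration
#'
#' @param kdf_iterations PBKDF2 iteration count used when deriving keys.
#' @param use_ecc Enable the Reed-Solomon outer code.
#' @param ecc A [code_config()] used when `use_ecc` is `TRUE`.
#' @param logistic [logistic_params()] controlling the chaotic permutation
#'   (`x0` is always key-derived).
#' @return A `helix_config` list.
#' @export
helix_config <- function(kdf_iterations = 600000L,
                         use_ecc = FALSE,
                         ecc = code_config(),
                         logistic = logistic_params()) {
  structure(list(kdf_iterations = as.integer(kdf_iterations),
                 use_ecc = isTRUE(use_ecc),
                 ecc = ecc,
                 logistic = logistic),
            class = "helix_config")
}

#' Encrypt bytes into an RNA ciphertext
#'
#' Pipeline: bits -> key-selected base encoding -> Watson-Crick complement ->
#' DNA one-time-pad XOR -> chaotic permutation -> transcription with chained
#' keyed substitution; optionally wrapped in the Reed-Solomon outer code.
#' The result carries a header (salt, nonce, KDF iterations, plaintext bit
#' length, code parameters) sufficient for [decrypt()] given the passphrase.
#'
#' @param plaintext Raw vector or character scalar (UTF-8 encoded).
#' @param passphrase Non-empty character scalar or raw vector.
#' @param config A [helix_config()].
#' @param nbits Plaintext length in bits when the message is not a whole
#'   number of bytes; defaults to `8 * nbytes`.  Trailing bits of the last
#'   byte beyond `nbits` must be zero.
#' @param salt,nonce Header overrides, used by the constraint-enforcement
#'   loop; fresh salt and nonce 0 by default.
#' @return A `ciphertext` object.
#' @examples
#' cfg <- helix_config(kdf_iterations = 1000)
#' ct <- encrypt("CRYPTO", "pass", cfg)
#' rawToChar(decrypt(ct, "pass"))
#' @export
encrypt <- function(plaintext, passphrase, config = helix_config(),
                    nbits = NULL, salt = NULL, nonce = 0L) {
  msg <- as_message_raw(plaintext)
  if (is.null(nbits)) nbits <- 8L * length(msg)
  nbits <- as.integer(nbits)
  if (nbits < 0L || nbits > 8L * length(msg) || length(msg) != ceiling(nbits / 8))
    stop("nbits inconsistent with message length", call. = FALSE)

  key <- derive_master_key(passphrase, salt = salt,
                           iterations = config$kdf_iterations)
  ct_core <- encrypt_core(msg, nbits, key, nonce, config)

  payload <- ct_core
  if (config$use_ecc) {
    coded <- rs_encode(pack_rna(payload), config$ecc)
    payload <- unpack_rna(coded)
  }
  structure(list(payload = payload,
                 salt = key$salt,
                 stream_nonce = as.integer(nonce),
                 kdf_iterations = key$kdf_iterations,
                 plaintext_bit_length = nbits,
                 ecc = if (config$use_ecc)
                   list(n = config$ecc$n, k = config$ecc$k,
                        interleave = config$ecc$interleave_depth) else NULL,
                 constrained = FALSE,
                 version = "helixcrypt-1"),
            class = "ciphertext")
}

# cipher core: everything inside the (optional) outer code
encrypt_core <- function(msg, nbits, key, nonce, config) {
  bits <- bytes_to_bits(msg)[seq_len(nbits)]
  table <- encoding_table(key$table_index)
  dna <- bits_to_dna(bits, table, pad = TRUE)
  n <- seq_length(dna)
  if (n > 0L) {
    dna <- complement(dna)
    dna <- dna_xor(dna, keystream(key, nonce, n), table)
    dna <- apply_permutation(dna, permutation_from_chaos(key, n, config$logistic))
  }
  transcribe(dna, sbox_family(key))
}

decrypt_core <- function(rna, nbits, key, nonce, config) {
  dna <- untranscribe(rna, sbox_family(key))
  n <- seq_length(dna)
  if (n > 0L) {
    dna <- invert_permutation(dna, permutation_from_chaos(key, n, config$logistic))
    dna <- dna_xor(dna, keystream(key, nonce, n), encoding_table(key$table_index))
    dna <- complement(dna)
  }
  bits <- dna_to_bits(dna, encoding_table(key$table_index))
  bits <- bits[seq_len(nbits)]
  out <- bits_to_bytes(bits)
  attr(out, "nbits") <- nbits
  out
}

#' Decrypt an RNA ciphertext
#'
#' Exact inverse chain of [encrypt()], driven by the ciphertext header and
#' the passphrase.  A wrong passphrase yields noise (or an explicit
#' Reed-Solomon failure when the outer code is enabled); the scheme carries
#' no authentication tag.
#'
#' @param ct A `ciphertext` object.
#' @param passphrase The passphrase used at encryption.
#' @param config Optional [helix_config()]; logistic-map parameters must
#'   match those used at encryption (defaults).
#' @return Raw plaintext with an `nbits` attribute.
#' @export
decrypt <- function(ct, passphrase, config = helix_config()) {
  if (!inherits(ct, "ciphertext")) stop("not a ciphertext object", call. = FALSE)
  if (!identical(ct$version, "helixcrypt-1"))
    stop("unsupported ciphertext version: ", ct$version, call. = FALSE)
  key <- derive_master_key(passphrase, salt = ct$salt,
                           iterations = ct$kdf_iterations)
  payload <- ct$payload
  core_bases <- as.integer(ceiling(ct$plaintext_bit_length / 2))
  bytes <- if (isTRUE(ct$constrained)) demodulate_payload(payload) else NULL
  if (!is.null(ct$ecc)) {
    cfg <- code_config(ct$ecc$n, ct$ecc$k, ct$ecc$interleave)
    core_bytes <- as.integer(ceiling(core_bases / 4))
    coded <- if (is.null(bytes)) pack_rna(payload) else bytes
    expected <- rs_coded_length(core_bytes, cfg)
    if (length(coded) != expected)
      stop_helix("format", sprintf(
        "payload length %d inconsistent with code framing (expected %d bytes)",
        length(coded), expected))
    payload <- unpack_rna(rs_decode(coded, cfg), n_bases = core_bases)
  } else if (!is.null(bytes)) {
    if (length(bytes) != ceiling(core_bases / 4))
      stop_helix("format", "constrained payload length disagrees with header")
    payload <- unpack_rna(bytes, n_bases = core_bases)
  } else {
    if (seq_length(payload) != core_bases)
      stop_helix("format", sprintf(
        "payload has %d bases but header declares %d",
        seq_length(payload), core_bases))
  }
  decrypt_core(payload, ct$plaintext_bit_length, key, ct$stream_nonce,
               helix_config(kdf_iterations = ct$kdf_iterations,
                            logistic = config$logistic))
}

#' @export
print.ciphertext <- function(x, ...) {
  cat(sprintf("<ciphertext v%s: %d RNA bases, %d plaintext bits, nonce %d%s%s>\n",
              sub("helixcrypt-", "", x$version), seq_length(x$payload),
              x$plaintext_bit_length, x$stream_nonce,
              if (!is.null(x$ecc))
                sprintf(", RS(%d,%d)x%d", x$ecc$n, x$ecc$k, x$ecc$interleave) else "",
              if (isTRUE(x$constrained)) ", constrained" else ""))
  invisible(x)
}

# classed conditions so the CLI can map failures to exit codes
stop_helix <- function(kind, msg) {
  cond <- structure(
    class = c(paste0("helixcrypt_", kind, "_error"), "helixcrypt_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

# RNA <-> packed bytes under the canonical A=0, C=1, G=2, U=3 coding,
# 4 bases per byte, first base in the high bit pair.
pack_rna <- function(seq) {
  ints <- seq_ints(seq)
  pad <- (-length(ints)) %% 4L
  ints <- c(ints, integer(pad))
  if (length(ints) == 0L) return(raw(0))
  m <- matrix(ints, nrow = 4L)
  as.raw(m[1, ] * 64L + m[2, ] * 16L + m[3, ] * 4L + m[4, ])
}

unpack_rna <- function(bytes, n_bases = 4L * length(bytes)) {
  v <- as.integer(bytes)
  ints <- as.integer(rbind(v %/% 64L, (v %/% 16L) %% 4L, (v %/% 4L) %% 4L, v %% 4L))
  ints_to_seq(ints[seq_len(n_bases)], "RNA")
}
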