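#' Write a ciphertext to FASTA with a JSON sidecar
#'
#' The RNA payload goes into a standard FASTA record (60-column wrapping,
#' written through Biostrings, so any FASTA-aware tool can read it); the
#' header metadata lives in a JSON sidecar at `<path>.json` and is mirrored
#' compactly in the FASTA description line.
#'
#' @param ct A `ciphertext` object.
#' @param path Output FASTA path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_ciphertext <- function(ct, path) {
  if (!inherits(ct, "ciphertext")) stop_helix("input", "not a ciphertext object")
  desc <- paste0("helixcrypt ", meta_string(ct))
  set <- Biostrings::RNAStringSet(stats::setNames(as.character(ct$payload), desc))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  sidecar <- list(version = ct$version,
                  salt = paste(format(ct$salt), collapse = ""),
                  stream_nonce = ct$stream_nonce,
                  kdf_iterations = ct$kdf_iterations,
                  plaintext_bit_length = ct$plaintext_bit_length,
                  ecc = ct$ecc,
                  constrained = isTRUE(ct$constrained))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

meta_string <- function(ct) {
  paste0("version=", ct$version,
         ";nonce=", ct$stream_nonce,
         ";bits=", ct$plaintext_bit_length,
         ";ecc=", if (is.null(ct$ecc)) "none"
                  else sprintf("%d/%d/%d", ct$ecc$n, ct$ecc$k, ct$ecc$interleave),
         ";constrained=", if (isTRUE(ct$constrained)) "1" else "0")
}

#' Read a ciphertext written by [write_ciphertext()]
#'
#' Validates the RNA alphabet, checks that the FASTA description metadata
#' and the JSON sidecar agree, and reconstructs the `ciphertext` object
#' field-exactly.
#'
#' @param path FASTA path (the `<path>.json` sidecar must exist).
#' @return A `ciphertext` object.
#' @export
read_ciphertext <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side_path))
    stop_helix("format", sprintf("missing ciphertext file or sidecar at %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_helix("format", conditionMessage(e)))
  if (length(set) != 1L)
    stop_helix("format", sprintf("expected 1 FASTA record, found %d", length(set)))
  seq_chr <- as.character(set[[1L]])
  if (grepl("[^ACGU]", seq_chr))
    stop_helix("format", "payload contains symbols outside the RNA alphabet")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(side$version, "helixcrypt-1"))
    stop_helix("format", paste("unsupported ciphertext version:", side$version))
  salt_hex <- as.character(side$salt)
  if (!grepl("^[0-9a-fA-F]{32}$", salt_hex))
    stop_helix("format", "sidecar salt must be 16 bytes of hex")
  ct <- structure(list(
    payload = nuc_seq(seq_chr, "RNA"),
    salt = as.raw(strtoi(substring(salt_hex, seq(1, 31, 2), seq(2, 32, 2)), 16L)),
    stream_nonce = as.integer(side$stream_nonce),
    kdf_iterations = as.integer(side$kdf_iterations),
    plaintext_bit_length = as.integer(side$plaintext_bit_length),
    ecc = if (is.null(side$ecc) || length(side$ecc) == 0L) NULL else
      list(n = as.integer(side$ecc$n), k = as.integer(side$ecc$k),
           interleave = as.integer(side$ecc$interleave)),
    constrained = isTRUE(side$constrained),
    version = side$version), class = "ciphertext")
  desc <- sub("^\\S*\\s*", "", names(set)[1L])
  if (nzchar(desc) && !identical(desc, meta_string(ct)))
    stop_helix("format", "FASTA description metadata disagrees with sidecar")
  ct
}

#' Seeded plaintext fixture generator
#'
#' Reproduces the evaluation corpus: `n_messages` uniformly random bit
#' strings with bit lengths uniform over `bit_range`, plus the literal
#' benchmark string `"CRYPTO"`.  Each message is a raw vector with an
#' `nbits` attribute; unused trailing bits of the final byte are zero.
#'
#' @param n_messages Number of random messages.
#' @param bit_range Inclusive integer range of message bit lengths.
#' @param seed RNG seed; the corpus is a pure function of the arguments.
#' @param include_benchmark Append the `"CRYPTO"` benchmark message.
#' @return List of raw vectors (the benchmark element is named `"CRYPTO"`).
#' @export
generate_fixtures <- function(n_messages, bit_range = c(128L, 192L), seed = 1L,
                              include_benchmark = TRUE) {
  n_messages <- as.integer(n_messages)
  if (is.na(n_messages) || n_messages < 0L)
    stop_helix("input", "n_messages must be a non-negative integer")
  if (length(bit_range) != 2L || bit_range[1] > bit_range[2] || bit_range[1] < 1)
    stop_helix("input", "bit_range must be a valid inclusive range")
  msgs <- with_seed(seed, {
    lens <- sample(bit_range[1]:bit_range[2], n_messages, replace = TRUE)
    lapply(lens, function(nb) {
      nbytes <- ceiling(nb / 8)
      r <- as.raw(sample.int(256L, nbytes, replace = TRUE) - 1L)
      extra <- 8L * nbytes - nb
      if (extra > 0L)  # zero the unused low-order bits of the last byte
        r[nbytes] <- as.raw(bitwAnd(as.integer(r[nbytes]),
                                    bitwShiftL(255L, extra) %% 256L))
      attr(r, "nbits") <- as.integer(nb)
      r
    })
  })
  if (include_benchmark) {
    bench <- charToRaw("CRYPTO")
    attr(bench, "nbits") <- 48L
    msgs <- c(msgs, list(CRYPTO = bench))
  }
  msgs
}
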