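#' Base frequencies of a sequence
#'
#' @param seq A non-empty [nuc_seq()].
#' @return Named numeric vector of the four base fractions (in alphabet
#'   order A, C, G, T/U), summing to 1.
#' @export
base_frequencies <- function(seq) {
  ints <- seq_ints(seq)
  if (length(ints) == 0L)
    stop_helix("input", "base frequencies of an empty sequence are undefined")
  f <- tabulate(ints + 1L, 4L) / length(ints)
  names(f) <- if (seq_alphabet(seq) == "DNA") c("A", "C", "G", "T")
              else c("A", "C", "G", "U")
  f
}

#' Shannon entropy of a base-frequency vector
#'
#' `H = -sum(p * log2(p))` over the positive frequencies; at most 2 bits per
#' base for a 4-letter alphabet, attained only by the uniform distribution.
#'
#' @param freqs Numeric vector of 4 non-negative fractions summing to 1
#'   (within 1e-6).
#' @return Entropy in bits per base.
#' @examples
#' shannon_entropy(c(0.25, 0.25, 0.25, 0.25))  # 2
#' @export
shannon_entropy <- function(freqs) {
  if (length(freqs) != 4L || any(is.na(freqs)) || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 1e-6)
    stop_helix("input", "freqs must be 4 non-negative fractions summing to 1")
  p <- freqs[freqs > 0]
  -sum(p * log2(p))
}

#' Avalanche statistics of the cipher
#'
#' For each trial a random message is encrypted twice under the same key and
#' nonce, once verbatim and once with a single uniformly chosen bit flipped,
#' and the two payloads are compared.  A fully diffusing pipeline
#' re-randomizes every output symbol, so the expected change fraction is 1/2
#' at the bit level and 3/4 at the nucleotide level (a changed 2-bit symbol
#' is uniform over the three other values).
#'
#' @param passphrase Passphrase for the single key used across trials.
#' @param config A [helix_config()]; the core pipeline is measured, without
#'   the outer code or constrained modulation.
#' @param n_trials Number of message pairs.
#' @param msg_bytes Message size in bytes (default 1024).
#' @param seed RNG seed for messages and flip positions.
#' @return List with `bit_fraction`, `nuc_fraction`, `n_trials`, `seed`.
#' @export
avalanche <- function(passphrase, config = helix_config(), n_trials = 100L,
                      msg_bytes = 1024L, seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L)
    stop_helix("input", "n_trials must be >= 1")
  key <- derive_master_key(passphrase, salt = as.raw(rep(7L, 16L)),
                           iterations = config$kdf_iterations)
  with_seed(seed, {
    bitf <- nucf <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      msg <- as.raw(sample.int(256L, msg_bytes, replace = TRUE) - 1L)
      pos <- sample.int(8L * msg_bytes, 1L)
      flipped <- msg
      byte <- (pos - 1L) %/% 8L + 1L
      bit <- (pos - 1L) %% 8L
      flipped[byte] <- as.raw(bitwXor(as.integer(flipped[byte]),
                                      bitwShiftL(1L, 7L - bit)))
      a <- seq_ints(encrypt_core(msg, 8L * msg_bytes, key, 0L, config))
      b <- seq_ints(encrypt_core(flipped, 8L * msg_bytes, key, 0L, config))
      nucf[i] <- mean(a != b)
      d <- bitwXor(a, b)
      bitf[i] <- mean(c(d %/% 2L, d %% 2L))
    }
    list(bit_fraction = mean(bitf), nuc_fraction = mean(nucf),
         n_trials = n_trials, seed = seed)
  })
}

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

check_bits <- function(bits, min_n) {
  if (!is.numeric(bits) || length(bits) < min_n || any(!(bits %in% c(0, 1))))
    stop_helix("input", sprintf("need a 0/1 bit vector of length >= %d", min_n))
  as.integer(bits)
}

#' SP 800-22 randomness subset
#'
#' The three tests of the public SP 800-22 specification that the evaluation
#' protocol uses: the monobit frequency test, the runs test, and the
#' discrete-Fourier-transform (spectral) test.  Each returns a p-value in
#' `[0, 1]`; the conventional pass criterion is `p > 0.01`.  Recommended
#' minimum lengths are 100 bits (frequency, runs) and 1000 bits (DFT);
#' inputs of at least 10 bits are accepted for didactic worked examples.
#'
#' @param bits Integer 0/1 vector.
#' @return p-value.
#' @examples
#' nist_frequency(rep(c(0, 1), 64))  # balanced: p = 1
#' @export
nist_frequency <- function(bits) {
  b <- check_bits(bits, 10L)
  n <- length(b)
  s <- abs(sum(2L * b - 1L))
  erfc(s / sqrt(2 * n))
}

#' @rdname nist_frequency
#' @export
nist_runs <- function(bits) {
  b <- check_bits(bits, 10L)
  n <- length(b)
  pi <- mean(b)
  if (abs(pi - 0.5) >= 2 / sqrt(n)) return(0)
  v <- 1L + sum(b[-1L] != b[-n])
  erfc(abs(v - 2 * n * pi * (1 - pi)) / (2 * sqrt(2 * n) * pi * (1 - pi)))
}

#' @rdname nist_frequency
#' @export
nist_dft <- function(bits) {
  b <- check_bits(bits, 1000L)
  n <- length(b)
  x <- 2 * b - 1
  mods <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  threshold <- sqrt(n * log(1 / 0.05))
  n0 <- 0.95 * n / 2
  n1 <- sum(mods < threshold)
  d <- (n1 - n0) / sqrt(n * 0.95 * 0.05 / 4)
  erfc(abs(d) / sqrt(2))
}

#' Key-space accounting
#'
#' The searchable key space is set by the master-key size: `8 * key_bytes`
#' bits, i.e. `4 * key_bytes` nucleotide-equivalents (2 bits per base).  The
#' 24 encoding tables and the stream nonce are *derived* from the master key
#' and are therefore reported as structure, not multiplied into the key
#' space.
#'
#' @param key_bytes Master-key size in bytes (default 64, i.e. 512 bits).
#' @return List with `keyspace_log2`, `nucleotide_equivalents`,
#'   `derived_table_bits` (log2 of 24) and a `note`.
#' @export
keyspace_accounting <- function(key_bytes = 64L) {
  key_bytes <- as.integer(key_bytes)
  if (is.na(key_bytes) || key_bytes < 1L)
    stop_helix("input", "key_bytes must be a positive integer")
  list(keyspace_log2 = 8 * key_bytes,
       nucleotide_equivalents = 4 * key_bytes,
       derived_table_bits = log2(24),
       note = paste("table choice and nonce are key-derived structure,",
                    "not independent secret bits"))
}

#' Security-evaluation report for a ciphertext
#'
#' Base frequencies, per-base Shannon entropy, the SP 800-22 subset on the
#' payload bits, and key-space accounting, in one structure.
#'
#' @param ct A `ciphertext` object (or a [nuc_seq()]).
#' @return An `eval_report` list.
#' @export
eval_report <- function(ct) {
  seq <- if (inherits(ct, "ciphertext")) ct$payload else ct
  freqs <- base_frequencies(seq)
  ints <- seq_ints(seq)
  bits <- as.integer(rbind(ints %/% 2L, ints %% 2L))
  pv <- list(frequency = nist_frequency(bits), runs = nist_runs(bits))
  if (length(bits) >= 1000L) pv$dft <- nist_dft(bits)
  ks <- keyspace_accounting()
  structure(list(base_freqs = freqs,
                 entropy_bits_per_base = shannon_entropy(freqs),
                 test_pvalues = pv,
                 keyspace_log2 = ks$keyspace_log2,
                 n_bases = length(ints)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d bases>\n", x$n_bases))
  cat("  base freqs:", paste(sprintf("%s=%.4f", names(x$base_freqs),
                                     x$base_freqs), collapse = " "), "\n")
  cat(sprintf("  entropy: %.5f bits/base\n", x$entropy_bits_per_base))
  for (nm in names(x$test_pvalues))
    cat(sprintf("  %s test p = %.4f\n", nm, x$test_pvalues[[nm]]))
  cat(sprintf("  key space: 2^%d (%d nucleotide-equivalents)\n",
              x$keyspace_log2, x$keyspace_log2 / 2))
  invisible(x)
}
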