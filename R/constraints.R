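#' Biochemical sequence constraint limits
#'
#' Limits a payload must satisfy before it could plausibly be synthesized:
#' balanced GC content (45-55% by default, globally and over every sliding
#' window), homopolymer runs capped at 3, and no reverse-complement stem of
#' `stem_min` or more bases that could fold back into a hairpin within a
#' window.  The stem length default of 11 reflects typical inverted-repeat
#' screening in synthesis QC; short stems (~6 bp) occur by chance every few
#' hundred bases in any random-looking sequence and are not actionable.
#'
#' @param gc_min,gc_max GC fraction band (defaults 0.45, 0.55).
#' @param max_homopolymer Longest allowed run of one base (default 3).
#' @param stem_min Minimum screened hairpin stem length in bases (default 11).
#' @param loop_min Minimum loop separating the stem halves (default 3).
#' @param window Sliding-window width in bases for the windowed GC check and
#'   the hairpin screen (default 100).
#' @param max_attempts Re-randomization budget of [enforce_constraints()]
#'   (default 1000).
#' @return A `constraint_limits` object.
#' @export
constraint_limits <- function(gc_min = 0.45, gc_max = 0.55,
                              max_homopolymer = 3L, stem_min = 11L,
                              loop_min = 3L, window = 100L,
                              max_attempts = 1000L) {
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1))
    stop_helix("config", "need 0 <= gc_min < gc_max <= 1")
  max_homopolymer <- as.integer(max_homopolymer)
  if (is.na(max_homopolymer) || max_homopolymer < 1L)
    stop_helix("config", "max_homopolymer must be >= 1")
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = max_homopolymer,
                 stem_min = as.integer(stem_min),
                 loop_min = as.integer(loop_min),
                 window = as.integer(window),
                 max_attempts = as.integer(max_attempts)),
            class = "constraint_limits")
}

#' GC content of a sequence
#'
#' @param seq A non-empty [nuc_seq()].
#' @return Fraction of G and C bases.
#' @examples
#' gc_content(nuc_seq("ACGT"))  # 0.5
#' @export
gc_content <- function(seq) {
  ints <- seq_ints(seq)
  if (length(ints) == 0L)
    stop_helix("input", "GC content of an empty sequence is undefined")
  mean(ints == 1L | ints == 2L)
}

#' Longest homopolymer run
#'
#' @param seq A [nuc_seq()].
#' @return Length of the longest run of identical consecutive bases (0 for
#'   an empty sequence).
#' @examples
#' max_homopolymer(nuc_seq("AAAT"))  # 3
#' @export
max_homopolymer <- function(seq) {
  ints <- seq_ints(seq)
  if (length(ints) == 0L) return(0L)
  max(rle(ints)$lengths)
}

#' Hairpin stem screen
#'
#' Counts stem placements `(i, j)` where the `stem_min`-mer starting at `i`
#' is the reverse complement of the `stem_min`-mer starting at `j`, with at
#' least `loop_min` bases between the stem halves and the whole placement
#' inside a `window`-base window.  This reverse-complement counting is the
#' standard light-weight proxy for secondary-structure propensity; a
#' nearest-neighbour free-energy model would slot in behind the same
#' interface.
#'
#' @param seq A [nuc_seq()] over either alphabet.
#' @param limits A [constraint_limits()].
#' @return Number of stem hits (0 means no screened hairpin).
#' @export
hairpin_screen <- function(seq, limits = constraint_limits()) {
  ints <- seq_ints(seq)
  if (length(ints) < 2L * limits$stem_min + limits$loop_min) return(0)
  .Call(C_hairpin, ints, limits$stem_min, limits$loop_min, limits$window)
}

# windowed + global GC band check, vectorized over all sliding windows
gc_windows_ok <- function(ints, limits) {
  n <- length(ints)
  gcvec <- as.integer(ints == 1L | ints == 2L)
  gc_all <- mean(gcvec)
  if (gc_all < limits$gc_min || gc_all > limits$gc_max) return(FALSE)
  w <- limits$window
  if (n > w) {
    cs <- cumsum(gcvec)
    wsum <- cs[w:n] - c(0L, cs[seq_len(n - w)])
    if (any(wsum < limits$gc_min * w - 1e-9) ||
        any(wsum > limits$gc_max * w + 1e-9)) return(FALSE)
  }
  TRUE
}

#' Check a payload against the constraint limits
#'
#' @param seq A [nuc_seq()].
#' @param limits A [constraint_limits()].
#' @return List with `ok` plus the measured `gc`, `max_run`, `hairpin_hits`
#'   and a character vector of violations.
#' @export
check_constraints <- function(seq, limits = constraint_limits()) {
  ints <- seq_ints(seq)
  gc <- if (length(ints)) mean(ints == 1L | ints == 2L) else NA_real_
  run <- max_homopolymer(seq)
  hits <- hairpin_screen(seq, limits)
  viol <- character(0)
  if (length(ints) == 0L || !gc_windows_ok(ints, limits))
    viol <- c(viol, sprintf("GC outside [%g, %g] (global %.3f or a %d-base window)",
                            limits$gc_min, limits$gc_max, gc, limits$window))
  if (run > limits$max_homopolymer)
    viol <- c(viol, sprintf("homopolymer run %d exceeds %d", run,
                            limits$max_homopolymer))
  if (hits > 0)
    viol <- c(viol, sprintf("%d hairpin stem hit(s) of length >= %d", hits,
                            limits$stem_min))
  list(ok = length(viol) == 0L, gc = gc, max_run = run, hairpin_hits = hits,
       violations = viol)
}

# ---- constrained modulation ------------------------------------------------
#
# Byte -> 6-base codebook.  Every codeword has GC content exactly 3/6, no
# run longer than 3, and distinct first and last base pairs, so any
# concatenation of codewords has max homopolymer run 3, global GC exactly
# 50%, and every sliding window within about 2 bases of 50% GC (only the
# partial codewords at the window edges can deviate).  The 256 codewords are
# the first qualifying 6-mers in lexicographic order.  One channel
# substitution corrupts one codeword, i.e. one byte of the inner code.

modulation_codebook <- function() {
  if (!is.null(.pkg_cache$codebook)) return(.pkg_cache$codebook)
  idx <- 0:4095
  d <- sapply(5:0, function(s) (idx %/% 4L^s) %% 4L)  # 4096 x 6, lex order
  gc <- rowSums(d == 1L | d == 2L)
  run_ok <- apply(d, 1L, function(v) max(rle(v)$lengths) <= 3L)
  ends_ok <- d[, 1L] != d[, 2L] & d[, 5L] != d[, 6L]
  code <- which(gc == 3L & run_ok & ends_ok)[1:256] - 1L
  decode <- rep(NA_integer_, 4096L)
  decode[code + 1L] <- 0:255
  cb <- list(code = code, decode = decode)
  .pkg_cache$codebook <- cb
  cb
}

# bytes -> RNA (6 bases per byte)
modulate_payload <- function(bytes) {
  cb <- modulation_codebook()
  if (length(bytes) == 0L) return(nuc_seq("", "RNA"))
  vals <- cb$code[as.integer(bytes) + 1L]
  d <- sapply(5:0, function(s) (vals %/% 4L^s) %% 4L)
  ints <- as.integer(t(matrix(d, ncol = 6L)))
  ints_to_seq(ints, "RNA")
}

# RNA -> bytes; 6-mers not in the codebook (possible only under channel
# noise) decode to 0x00 and are left for the outer Reed-Solomon layer
demodulate_payload <- function(seq) {
  n <- seq_length(seq)
  if (n %% 6L != 0L)
    stop_helix("format", "constrained payload length is not a multiple of 6")
  if (n == 0L) return(raw(0))
  cb <- modulation_codebook()
  ints <- seq_ints(seq)
  m <- matrix(ints, nrow = 6L)
  vals <- as.integer(4L^(5:0) %*% m)
  bytes <- cb$decode[vals + 1L]
  bytes[is.na(bytes)] <- 0L
  as.raw(bytes)
}

#' Enforce biochemical constraints on a ciphertext
#'
#' Re-encodes the payload through the constrained modulation (byte to 5-base
#' codewords), which structurally guarantees the homopolymer cap and keeps
#' GC tightly centred at 50%; residual violations (a GC window outside the
#' band, or a screened hairpin stem) are cleared by re-encrypting under
#' successive stream nonces until the payload passes, the classical
#' rejection-sampling route.  The successful nonce is part of the header, so
#' [decrypt()] is unchanged.
#'
#' @param ct A `ciphertext` from [encrypt()].
#' @param passphrase The passphrase that produced `ct`.
#' @param limits A [constraint_limits()].
#' @param config A [helix_config()]; KDF iterations and code parameters are
#'   taken from the ciphertext header.
#' @return A compliant `ciphertext` with `constrained = TRUE`.
#' @export
enforce_constraints <- function(ct, passphrase, limits = constraint_limits(),
                                config = helix_config()) {
  if (!inherits(ct, "ciphertext")) stop_helix("input", "not a ciphertext object")
  cfg <- helix_config(
    kdf_iterations = ct$kdf_iterations,
    use_ecc = !is.null(ct$ecc),
    ecc = if (!is.null(ct$ecc))
      code_config(ct$ecc$n, ct$ecc$k, ct$ecc$interleave) else code_config(),
    logistic = config$logistic)
  plain <- decrypt(ct, passphrase, cfg)
  best <- NULL
  for (a in seq_len(limits$max_attempts) - 1L) {
    nonce <- ct$stream_nonce + a
    cand <- encrypt(plain, passphrase, cfg,
                    nbits = attr(plain, "nbits"),
                    salt = ct$salt, nonce = nonce)
    mseq <- modulate_payload(pack_rna(cand$payload))
    res <- check_constraints(mseq, limits)
    if (res$ok) {
      cand$payload <- mseq
      cand$constrained <- TRUE
      return(cand)
    }
    if (is.null(best) || length(res$violations) < length(best$violations))
      best <- c(res, list(nonce = nonce))
  }
  stop_helix("constraint", sprintf(
    "no compliant payload within %d attempts; best attempt (nonce %d): %s",
    limits$max_attempts, best$nonce, paste(best$violations, collapse = "; ")))
}
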