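#' Reed-Solomon code configuration
#'
#' Systematic Reed-Solomon over GF(2^8) with block interleaving.  The default
#' heavy-parity profile RS(255, 51) corrects up to t = 102 byte errors per
#' codeword, sized for a DNA substitution channel: a per-base substitution
#' rate e induces a per-byte symbol error rate 1 - (1 - e)^4 (4 bases per
#' byte), about 28.4% at e = 8%, well inside t/n = 40%.  A lighter archival
#' profile such as RS(255, 223) can be selected instead.
#'
#' @param n Codeword length in bytes (2..255).
#' @param k Data bytes per codeword (1 <= k < n).
#' @param interleave_depth Codewords per interleaving group (>= 1); byte
#'   bursts of length up to `interleave_depth * t` are spread across
#'   codewords.
#' @return A `code_config` object with fields `n`, `k`, `t`,
#'   `interleave_depth`.
#' @export
code_config <- function(n = 255L, k = 51L, interleave_depth = 8L) {
  n <- as.integer(n); k <- as.integer(k)
  interleave_depth <- as.integer(interleave_depth)
  if (is.na(n) || is.na(k) || k < 1L || k >= n || n > 255L)
    stop_helix("config", "Reed-Solomon parameters must satisfy 1 <= k < n <= 255")
  t <- (n - k) %/% 2L
  if (t < 1L)
    stop_helix("config", "code must correct at least one symbol error (n - k >= 2)")
  if (is.na(interleave_depth) || interleave_depth < 1L)
    stop_helix("config", "interleave_depth must be a positive integer")
  structure(list(n = n, k = k, t = t, interleave_depth = interleave_depth),
            class = "code_config")
}

#' Reed-Solomon encode with interleaving
#'
#' Data is chunked into k-byte blocks (the final block shortened with
#' implicit leading zeros), each block extended with n - k parity bytes, and
#' codewords are emitted column-major within groups of `interleave_depth`.
#' The framing is fully determined by the data length and the configuration,
#' so no length fields are embedded.
#'
#' @param data Raw vector (possibly empty).
#' @param cfg A [code_config()].
#' @return Raw vector of coded bytes.
#' @export
rs_encode <- function(data, cfg) {
  stopifnot(inherits(cfg, "code_config"))
  if (!is.raw(data)) stop_helix("input", "rs_encode expects a raw vector")
  if (length(data) == 0L) return(raw(0))
  nsym <- cfg$n - cfg$k
  starts <- seq(1L, length(data), by = cfg$k)
  cws <- lapply(starts, function(s) {
    blk <- data[s:min(s + cfg$k - 1L, length(data))]
    c(blk, .Call(C_rs_encode, blk, nsym))
  })
  interleave_bytes(cws, cfg$interleave_depth)
}

#' Reed-Solomon decode with de-interleaving
#'
#' Inverse of [rs_encode()]: framing is inferred from the coded length, each
#' codeword is corrected by Berlekamp-Massey decoding (up to t byte errors),
#' and the data bytes are reassembled.  Uncorrectable codewords raise an
#' explicit classed error rather than returning silently corrupted data.
#'
#' @param coded Raw vector produced by [rs_encode()] (possibly corrupted).
#' @param cfg The same [code_config()].
#' @return Raw vector of recovered data bytes.
#' @export
rs_decode <- function(coded, cfg) {
  stopifnot(inherits(cfg, "code_config"))
  if (!is.raw(coded)) stop_helix("input", "rs_decode expects a raw vector")
  if (length(coded) == 0L) return(raw(0))
  nsym <- cfg$n - cfg$k
  lens <- rs_frame_lengths(length(coded), cfg)
  cws <- deinterleave_bytes(coded, lens, cfg$interleave_depth)
  out <- vector("list", length(cws))
  for (i in seq_along(cws)) {
    res <- .Call(C_rs_decode, cws[[i]], nsym)
    if (res$status != 0L)
      stop_helix("decode", sprintf(
        "codeword %d of %d is uncorrectable (locator degree %d, capacity %d)",
        i, length(cws), res$nerr, cfg$t))
    out[[i]] <- res$data
  }
  unlist(out)
}

# codeword lengths implied by a coded stream length; the only shortened
# codeword is the last one
rs_frame_lengths <- function(L, cfg) {
  nsym <- cfg$n - cfg$k
  full <- L %/% cfg$n
  rem <- L %% cfg$n
  if (rem == 0L) return(rep.int(cfg$n, full))
  if (rem <= nsym)
    stop_helix("format", "coded length inconsistent with code framing")
  c(rep.int(cfg$n, full), rem)
}

rs_coded_length <- function(msg_len, cfg) {
  if (msg_len == 0L) return(0L)
  full <- msg_len %/% cfg$k
  rem <- msg_len %% cfg$k
  full * cfg$n + if (rem > 0L) rem + (cfg$n - cfg$k) else 0L
}

# column-major interleaving within groups of `depth` codewords; ragged final
# codewords are simply exhausted early, which keeps the permutation a pure
# function of the length vector
interleave_perm <- function(lens, depth) {
  groups <- split(seq_along(lens), (seq_along(lens) - 1L) %/% depth)
  unlist(lapply(groups, function(g) {
    ls <- lens[g]
    offs <- cumsum(c(0L, ls[-length(ls)]))
    cwid <- rep(seq_along(g), ls)
    pos <- sequence(ls)
    (offs[cwid] + pos)[order(pos, cwid)] + sum(lens[seq_len(g[1] - 1L)])
  }), use.names = FALSE)
}

interleave_bytes <- function(cws, depth) {
  lens <- lengths(cws)
  unlist(cws)[interleave_perm(lens, depth)]
}

deinterleave_bytes <- function(coded, lens, depth) {
  perm <- interleave_perm(lens, depth)
  orig <- raw(length(coded))
  orig[perm] <- coded
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  lapply(seq_along(lens), function(i) orig[starts[i]:ends[i]])
}
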