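#' Binary-to-base encoding tables
#'
#' The codec maps consecutive bit pairs to nucleotide bases through one of 24
#' encoding tables, the bijections from the four 2-bit values `00,01,10,11`
#' to the four DNA bases.  Which table is in force is selected by the master
#' key (see [derive_master_key()]), so the very first encoding step is
#' already key-dependent.
#'
#' Table order: the 24 assignments are sorted lexicographically by the base
#' string assigned to `(00, 01, 10, 11)` and then re-indexed so that the
#' classical scheme `00→A, 01→T, 10→C, 11→G` is table 0.
#'
#' @param index Integer in `[0, 23]`.
#' @return An `encoding_table` with fields `index` and `assignment`
#'   (character vector of 4 bases, positions correspond to 2-bit values
#'   0, 1, 2, 3).
#' @examples
#' encoding_table(0)$assignment  # A T C G
#' @export
encoding_table <- function(index) {
  index <- as.integer(index)
  if (is.na(index) || index < 0L || index > 23L)
    stop("encoding table index must lie in [0, 23]", call. = FALSE)
  enumerate_tables()[[index + 1L]]
}

#' Enumerate all 24 encoding tables
#'
#' @return List of 24 `encoding_table` objects, all distinct, with table 0
#'   the classical `00→A, 01→T, 10→C, 11→G` assignment.
#' @export
enumerate_tables <- function() {
  if (!is.null(.pkg_cache$tables)) return(.pkg_cache$tables)
  perms <- base_permutations(c("A", "C", "G", "T"))
  strs <- vapply(perms, paste, "", collapse = "")
  perms <- perms[order(strs)]
  anchor <- which(vapply(perms, function(p) identical(p, c("A", "T", "C", "G")), TRUE))
  idx <- (seq_along(perms) - anchor) %% 24L
  tabs <- vector("list", 24L)
  for (i in seq_along(perms)) {
    tabs[[idx[i] + 1L]] <- structure(
      list(index = idx[i], assignment = perms[[i]]),
      class = "encoding_table")
  }
  .pkg_cache$tables <- tabs
  tabs
}

# all permutations of a length-4 vector, recursively, in input order
base_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(base_permutations(v[-i]), function(p) c(v[i], p)))
  out
}

.pkg_cache <- new.env(parent = emptyenv())

#' Convert bytes or text to a bit sequence
#'
#' Text is UTF-8 encoded first; each byte expands to its 8-bit big-endian
#' representation (most significant bit first), matching the usual printed
#' ASCII-to-binary tables.
#'
#' @param message Character scalar or raw vector.
#' @return Integer vector of 0/1 bits, length `8 * nbytes`.
#' @examples
#' paste(text_to_bits("C"), collapse = "")  # 01000011
#' @export
text_to_bits <- function(message) {
  bytes_to_bits(as_message_raw(message))
}

as_message_raw <- function(message) {
  if (is.raw(message)) return(message)
  if (is.character(message) && length(message) == 1L)
    return(charToRaw(enc2utf8(message)))
  stop("message must be a raw vector or a single character string", call. = FALSE)
}

bytes_to_bits <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0))
  v <- as.integer(bytes)
  as.integer(t(outer(v, 7:0, function(x, s) bitwAnd(bitwShiftR(x, s), 1L))))
}

bits_to_bytes <- function(bits) {
  if (length(bits) == 0L) return(raw(0))
  pad <- (-length(bits)) %% 8L
  bits <- c(bits, integer(pad))
  m <- matrix(bits, nrow = 8L)
  as.raw(colSums(m * 2L^(7:0)))
}

#' Encode a bit sequence as DNA
#'
#' Consecutive bit pairs are mapped through the table's assignment; the
#' encoded length in bases is half the bit length.
#'
#' @param bits Integer 0/1 vector.
#' @param table An [encoding_table()].
#' @param pad If `TRUE`, an odd-length bit input is padded with a single 0
#'   bit (the caller is responsible for recording the original bit length);
#'   if `FALSE` (default) odd input is an error.
#' @return A DNA [nuc_seq()].
#' @examples
#' bits_to_dna(text_to_bits("C"), encoding_table(0))  # TAAG
#' @export
bits_to_dna <- function(bits, table, pad = FALSE) {
  if (length(bits) %% 2L == 1L) {
    if (!pad) stop("bit sequence has odd length; enable pad to append a 0 bit",
                   call. = FALSE)
    bits <- c(bits, 0L)
  }
  if (length(bits) == 0L) return(nuc_seq("", "DNA"))
  vals <- bits[c(TRUE, FALSE)] * 2L + bits[c(FALSE, TRUE)]
  nuc_seq(paste(table$assignment[vals + 1L], collapse = ""), "DNA")
}

#' Decode a DNA sequence back to bits
#'
#' Exact inverse of [bits_to_dna()] under the same table.
#'
#' @param seq A DNA [nuc_seq()].
#' @param table An [encoding_table()].
#' @return Integer 0/1 vector of length `2 * bases`.
#' @examples
#' paste(dna_to_bits(nuc_seq("TAAG"), encoding_table(0)), collapse = "")
#' @export
dna_to_bits <- function(seq, table) {
  assert_alphabet(seq, "DNA")
  s <- as.character(seq)
  if (!nzchar(s)) return(integer(0))
  inv <- integer(4)
  inv[.seq_codes[utf8ToInt(paste(table$assignment, collapse = "")) + 1L] + 1L] <-
    0:3
  vals <- inv[seq_ints(seq) + 1L]
  as.integer(rbind(vals %/% 2L, vals %% 2L))
}
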