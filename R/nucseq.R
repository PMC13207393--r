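#' Validated nucleotide sequence
#'
#' A `nuc_seq` is a single sequence over a declared alphabet, either DNA
#' (`A`, `C`, `G`, `T`) or RNA (`A`, `C`, `G`, `U`).  It is stored as a plain
#' character scalar with an `alphabet` attribute; all cipher layers validate
#' the alphabet at their boundaries.
#'
#' @param x Character scalar (possibly empty) over the declared alphabet.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return A `nuc_seq` object.
#' @examples
#' nuc_seq("TAAG", "DNA")
#' nuc_seq("UUAA", "RNA")
#' @export
nuc_seq <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("a nuc_seq is a single character string", call. = FALSE)
  bad <- if (alphabet == "DNA") grepl("[^ACGT]", x) else grepl("[^ACGU]", x)
  if (bad)
    stop(sprintf("sequence contains symbols outside the %s alphabet", alphabet),
         call. = FALSE)
  structure(x, alphabet = alphabet, class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(unclass(x))
  shown <- if (n > 60) paste0(substr(unclass(x), 1, 60), "...") else unclass(x)
  cat(sprintf("<nuc_seq %s, %d bases> %s\n", attr(x, "alphabet"), n, shown))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) as.vector(unclass(x))

#' Number of bases in a sequence
#' @param seq A [nuc_seq()].
#' @return Integer base count.
#' @export
seq_length <- function(seq) nchar(as.character(seq))

seq_alphabet <- function(seq) attr(seq, "alphabet") %||% stop("not a nuc_seq")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_alphabet <- function(seq, alphabet) {
  if (!inherits(seq, "nuc_seq"))
    stop("expected a nuc_seq object", call. = FALSE)
  if (seq_alphabet(seq) != alphabet)
    stop(sprintf("expected a %s-alphabet sequence, got %s",
                 alphabet, seq_alphabet(seq)), call. = FALSE)
  invisible(seq)
}

# Canonical integer symbol coding used internally by all compiled layers:
# A=0, C=1, G=2, T/U=3.  The Watson-Crick complement is 3 - x in this order.
.seq_codes <- local({
  z <- integer(256)
  z[utf8ToInt("A") + 1L] <- 0L
  z[utf8ToInt("C") + 1L] <- 1L
  z[utf8ToInt("G") + 1L] <- 2L
  z[utf8ToInt("T") + 1L] <- 3L
  z[utf8ToInt("U") + 1L] <- 3L
  z
})

seq_ints <- function(seq) {
  s <- as.character(seq)
  if (!nzchar(s)) return(integer(0))
  .seq_codes[utf8ToInt(s) + 1L]
}

ints_to_seq <- function(ints, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  letters4 <- if (alphabet == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  s <- if (length(ints)) paste(letters4[ints + 1L], collapse = "") else ""
  structure(s, alphabet = alphabet, class = "nuc_seq")
}
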