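# 2-bit packed mers and elementary operations on the DNA alphabet.

#' Pack a DNA string into a 2-bit-per-symbol representation
#'
#' Symbols are encoded A=0, C=1, G=2, T=3 (so that comparison of the packed
#' words equals lexicographic comparison of the strings) and packed 32
#' symbols per 64-bit word, most-significant symbol first. Input is
#' case-insensitive; symbols outside A/C/G/T are rejected.
#'
#' @param s a single string over A/C/G/T (either case).
#' @return an object of class `packed_mer`: the mer length `j` and the packed
#'   words (`ceiling(j/32)` of them, as raw bytes).
#' @examples
#' x <- pack_mer("CTAAGAT")
#' unpack_mer(x)
#' @export
pack_mer <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  structure(list(j = nchar(s), words = cpp_pack_mer(s)), class = "packed_mer")
}

#' Decode a packed mer back to its string form
#' @param x a `packed_mer`.
#' @return the DNA string (upper case).
#' @export
unpack_mer <- function(x) {
  stopifnot(inherits(x, "packed_mer"))
  cpp_unpack_mer(x$words, x$j)
}

#' Number of machine words of a packed mer
#' @param x a `packed_mer`.
#' @return `ceiling(j/32)`.
#' @export
n_words <- function(x) {
  stopifnot(inherits(x, "packed_mer"))
  length(x$words) %/% 8L
}

#' @export
print.packed_mer <- function(x, ...) {
  cat("<packed_mer> j =", x$j, " words =", n_words(x), "\n")
  cat(" ", unpack_mer(x), "\n")
  invisible(x)
}

#' Reverse complement
#'
#' Reverses the symbol order and complements each symbol (A<->T, C<->G).
#' An involution: `reverse_complement(reverse_complement(x))` equals `x`.
#'
#' @param x a character vector of DNA strings, or a `packed_mer`.
#' @return an object of the same kind as the input.
#' @examples
#' reverse_complement("CTAA") # "TTAG"
#' @export
reverse_complement <- function(x) {
  if (inherits(x, "packed_mer")) return(pack_mer(cpp_revcomp(unpack_mer(x))))
  cpp_revcomp(x)
}

#' Canonical form of a mer
#'
#' The lexicographic minimum (A < C < G < T) of a mer and its reverse
#' complement. The orientation records whether the input itself was already
#' canonical (`"forward"`) or not (`"backward"`).
#'
#' @param x a character vector of DNA strings.
#' @return a data frame with columns `mer` and `orientation`.
#' @examples
#' canonical_mer(c("GAT", "CGA"))
#' @export
canonical_mer <- function(x) {
  if (inherits(x, "packed_mer")) x <- unpack_mer(x)
  r <- cpp_canonical(x)
  data.frame(mer = r$mer,
             orientation = ifelse(r$forward, "forward", "backward"),
             stringsAsFactors = FALSE)
}

#' Glue two overlapping strings
#'
#' The l-length glue `x %glue_l% y`: requires the length-l suffix of `x` to
#' equal the length-l prefix of `y`, and returns `x` followed by the
#' remainder of `y`.
#'
#' @param x,y strings.
#' @param l overlap length, `0 < l <= min(nchar(x), nchar(y))`.
#' @return the glued string.
#' @examples
#' glue_mers("CGA", "GAT", 2) # "CGAT"
#' @export
glue_mers <- function(x, y, l) {
  stopifnot(is.character(x), is.character(y), length(x) == 1L,
            length(y) == 1L)
  l <- as.integer(l)
  if (l <= 0L || l > min(nchar(x), nchar(y)))
    stop("overlap length must be in (0, min(|x|, |y|)]")
  if (substring(x, nchar(x) - l + 1L, nchar(x)) != substring(y, 1L, l))
    stop("overlap violation: suffix of x does not match prefix of y")
  paste0(x, substring(y, l + 1L, nchar(y)))
}

#' Enumerate the valid j-mer windows of a sequence
#'
#' Yields every length-j window composed solely of A/C/G/T (case folded to
#' upper case). Any other symbol (N, IUPAC ambiguity codes, ...) splits the
#' sequence: no window spans it. Positions are 1-based.
#'
#' @param seq a single sequence string.
#' @param j window length.
#' @return a data frame with columns `position` and `mer`; zero rows if no
#'   valid window exists.
#' @examples
#' valid_jmers("CTAAGAT", 4)
#' @export
valid_jmers <- function(seq, j) {
  stopifnot(is.character(seq), length(seq) == 1L)
  j <- as.integer(j)
  if (j <= 0L) stop("j must be > 0")
  r <- cpp_valid_jmers(seq, j)
  data.frame(position = r$position, mer = r$mer, stringsAsFactors = FALSE)
}
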