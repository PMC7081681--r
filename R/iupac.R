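## IUPAC nucleotide codes as 4-bit masks: A=1, C=2, G=4, T=8.
## A degenerate code is the union of its concrete bases; two codes are
## compatible iff their base sets intersect (bitwAnd > 0).
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L,
  `-` = 0L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

.CONCRETE_BASES <- c("A", "C", "G", "T")

## popcount over the 4-bit masks: number of concrete bases a code denotes
.BITS_CARD <- vapply(0:15, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L),
                     integer(1))

## Concrete expansions per code, in fixed A < C < G < T order.
.IUPAC_EXPANSION <- lapply(.IUPAC_BITS, function(bits) {
  .CONCRETE_BASES[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
})

#' Split an IUPAC string into validated single-character codes
#'
#' @param s character scalar over the IUPAC alphabet (optionally with `-`
#'   when `allow_gap = TRUE`); lower case accepted, `U` treated as `T`.
#' @param allow_gap permit the alignment gap character `-`.
#' @return character vector of single upper-case codes.
#' @keywords internal
iupac_chars <- function(s, allow_gap = FALSE) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  ok <- ch %in% names(.IUPAC_BITS)
  if (!allow_gap) ok <- ok & ch != "-"
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("invalid IUPAC character '%s' at position %d", ch[bad], bad),
         call. = FALSE)
  }
  ch[ch == "U"] <- "T"
  ch
}

#' Encode an IUPAC string as 4-bit base masks
#' @inheritParams iupac_chars
#' @return integer vector of bit masks (A=1, C=2, G=4, T=8; unions for
#'   degenerate codes, 0 for gaps).
#' @keywords internal
iupac_bits <- function(s, allow_gap = FALSE) {
  unname(.IUPAC_BITS[iupac_chars(s, allow_gap = allow_gap)])
}

#' Do two IUPAC codes match?
#'
#' Two codes match when the sets of concrete bases they denote intersect,
#' e.g. `Y` (C/T) matches `C` but not `R` (A/G). The relation is symmetric.
#'
#' @param a,b single IUPAC codes.
#' @return logical scalar.
#' @examples
#' iupac_match("Y", "C")  # TRUE
#' iupac_match("Y", "R")  # FALSE
#' @export
iupac_match <- function(a, b) {
  bitwAnd(iupac_bits(a), iupac_bits(b)) > 0L
}

#' Reverse-complement an IUPAC string
#'
#' Degenerate codes map to the complement of their base set (Y <-> R,
#' K <-> M, S and W are self-complementary, N stays N). The operation is an
#' involution: `revcomp(revcomp(x)) == x`.
#'
#' @param s IUPAC string (may be empty); gaps are preserved if present.
#' @return the reverse complement, upper case.
#' @examples
#' revcomp("AGCT")   # "AGCT" (palindrome)
#' revcomp("GGAY")   # "RTCC"
#' @export
revcomp <- function(s) {
  ch <- iupac_chars(s, allow_gap = TRUE)
  if (length(ch) == 0L) return("")
  paste(rev(unname(.IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' Degeneracy of an IUPAC string
#'
#' Product over positions of the number of concrete bases each code denotes;
#' equals the number of concrete sequences the string expands to.
#'
#' @param s IUPAC string (no gaps).
#' @return integer >= 1 (1 for the empty string).
#' @export
degeneracy <- function(s) {
  ch <- iupac_chars(s)
  if (length(ch) == 0L) return(1L)
  prod(vapply(.IUPAC_EXPANSION[ch], length, integer(1)))
}

#' A named degenerate oligonucleotide primer
#'
#' @param name primer name (used in panel definitions and reports).
#' @param seq 5'->3' IUPAC sequence, length >= 10, no gaps.
#' @return object of class `primer` with fields `name`, `seq`, `degeneracy`.
#' @examples
#' primer("marR", "GGTTYTAGTATGTAGTTTTCAAA")
#' @export
primer <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ch <- iupac_chars(seq)
  if (length(ch) < 10L)
    stop(sprintf("primer '%s' is shorter than 10 nt", name), call. = FALSE)
  structure(
    list(name = name, seq = paste(ch, collapse = ""),
         degeneracy = degeneracy(seq)),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s-3'  (%d nt, degeneracy %d)\n",
              x$name, x$seq, nchar(x$seq), x$degeneracy))
  invisible(x)
}

#' Expand a degenerate primer into its concrete sequences
#'
#' All concrete expansions in lexicographic order. Refuses to expand past
#' `cap` so pathological primers fail loudly instead of exploding.
#'
#' @param p a [primer] or an IUPAC string.
#' @param cap maximum permitted degeneracy (default 64).
#' @return character vector of length `degeneracy(p)`.
#' @export
expand_degenerate <- function(p, cap = 64L) {
  if (inherits(p, "primer")) {
    nm <- p$name; s <- p$seq
  } else {
    nm <- "<unnamed>"; s <- p
  }
  stopifnot(cap >= 1L)
  d <- degeneracy(s)
  if (d > cap)
    stop(sprintf("degeneracy cap exceeded for primer '%s': %d > %d",
                 nm, d, cap), call. = FALSE)
  ch <- iupac_chars(s)
  if (length(ch) == 0L) return("")
  ## expand_grid-style cartesian product, leftmost position varying slowest
  ## so the result is in lexicographic order
  out <- ""
  for (i in seq_along(ch)) {
    bases <- .IUPAC_EXPANSION[[ch[i]]]
    out <- as.vector(t(outer(out, bases, paste0)))
  }
  out
}
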