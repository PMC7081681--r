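## Melting temperature and primer-primer interaction scoring.

## Unified nearest-neighbor parameters (SantaLucia's unified set):
## dH kcal/mol, dS cal/(mol K) per stacked dinucleotide step.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

.tm_wallace <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

.tm_nn <- function(seq, monovalent_m = 0.05, primer_m = 0.25e-6) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  steps <- paste0(ch[-n], ch[-1])
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  ## duplex initiation with terminal penalties
  for (term in ch[c(1, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ## monovalent-salt entropy correction
  ds <- ds + 0.368 * (n - 1) * log(monovalent_m)
  1000 * dh / (ds + 1.9872 * log(primer_m / 4)) - 273.15
}

#' Melting temperature interval of a (possibly degenerate) primer
#'
#' Computed for every concrete expansion; the interval is the min/max over
#' expansions, so a concrete primer gets a zero-width interval. `wallace`
#' is the 2(A+T) + 4(G+C) rule; `nearest_neighbor` uses the unified
#' nearest-neighbor enthalpy/entropy table with a monovalent-salt entropy
#' correction, at 50 mM monovalent cation and 0.25 uM primer by default.
#'
#' @param p a [primer] or IUPAC string.
#' @param method `"wallace"` or `"nearest_neighbor"`.
#' @param monovalent_m monovalent cation concentration (mol/L).
#' @param primer_m primer concentration (mol/L).
#' @param cap degeneracy cap for expansion.
#' @return numeric `c(tm_min, tm_max)` in degrees C, with attribute
#'   `conditions` documenting the assumptions for `nearest_neighbor`.
#' @export
tm_estimate <- function(p, method = c("wallace", "nearest_neighbor"),
                        monovalent_m = 0.05, primer_m = 0.25e-6, cap = 64L) {
  method <- match.arg(method)
  seqs <- expand_degenerate(p, cap = cap)
  tms <- switch(method,
    wallace = vapply(seqs, .tm_wallace, numeric(1)),
    nearest_neighbor = vapply(seqs, .tm_nn, numeric(1),
                              monovalent_m = monovalent_m,
                              primer_m = primer_m))
  out <- c(tm_min = min(tms), tm_max = max(tms))
  if (method == "nearest_neighbor")
    attr(out, "conditions") <- sprintf(
      "unified NN table, %g mM monovalent, %g uM primer",
      monovalent_m * 1000, primer_m * 1e6)
  out
}

## Can codes a and b (one from each strand, read 5'->3' on their own
## strands) base-pair? True iff some expansion of a is the Watson-Crick
## complement of some expansion of b.
.pairs_with <- function(bits_a, comp_bits_b) bitwAnd(bits_a, comp_bits_b) > 0L

#' 3'-anchored cross-dimer score of two primers
#'
#' Length of the longest run of consecutive complementary base pairs, over
#' all antiparallel annealing offsets of the two primers, that terminates
#' at the 3' end of either primer -- the geometry that lets a polymerase
#' extend a primer dimer. Degenerate positions count as complementary if
#' any concrete expansion pairs (worst case). Symmetric in its arguments;
#' a primer against its own reverse complement scores its full length.
#'
#' @param p1,p2 [primer]s or IUPAC strings.
#' @return integer >= 0.
#' @export
cross_dimer_score <- function(p1, p2) {
  s1 <- if (inherits(p1, "primer")) p1$seq else p1
  s2 <- if (inherits(p2, "primer")) p2$seq else p2
  max(.anchored_run(s1, s2), .anchored_run(s2, s1))
}

## Longest complementary run ending at a's 3'-terminal base, over all
## positions of b it can pair with. Antiparallel: a read 3'->5' from its
## end pairs with b read 5'->3'.
.anchored_run <- function(a, b) {
  abits <- rev(iupac_bits(a))                      # a from 3' end inward
  bcomp <- iupac_bits(revcomp(b))                  # complement of b, 3'->5'
  bcomp <- rev(bcomp)                              # complement of b, 5'->3'
  m <- length(abits); n <- length(bcomp)
  best <- 0L
  for (j in seq_len(n)) {
    k <- 0L
    while (k < m && j + k <= n &&
             .pairs_with(abits[k + 1L], bcomp[j + k])) k <- k + 1L
    if (k > best) best <- k
  }
  best
}
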