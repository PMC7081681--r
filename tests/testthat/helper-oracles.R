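## Independent brute-force oracles for property tests. These derive IUPAC
## semantics from explicit base sets and scan templates position by
## position -- deliberately a different algorithmic route from the
## package's vectorised bit-mask engine.

oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

## pairwise code-compatibility table from set intersections
oracle_match_table <- local({
  nm <- names(oracle_sets)
  m <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in nm) for (b in nm)
    m[a, b] <- length(intersect(oracle_sets[[a]], oracle_sets[[b]])) > 0
  m
})

oracle_revcomp <- function(s) {
  if (nchar(s) == 0) return("")
  paste(rev(unname(oracle_comp[strsplit(s, "")[[1]]])), collapse = "")
}

## exhaustive O(n*m) binding-site scan; returns data.frame(strand, start,
## end, mismatches) in (start, strand) order, 0-based half-open
oracle_sites <- function(pseq, tmpl, circular, policy) {
  tch <- strsplit(tmpl, "")[[1]]
  n <- length(tch)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pseq else oracle_revcomp(pseq)
    pch <- strsplit(pat, "")[[1]]
    m <- length(pch)
    scan_t <- tch
    if (circular) {
      ext <- min(n - 1, policy$max_product_len + m - 1)
      if (ext > 0) scan_t <- c(tch, tch[seq_len(ext)])
    }
    w <- min(policy$three_prime_window, m)
    wpos <- if (w == 0) integer(0)
            else if (strand == "+") (m - w + 1):m else 1:w
    for (s0 in 0:(length(scan_t) - m)) {
      if (s0 >= n) next
      mm <- 0; mmw <- 0
      for (i in 1:m) {
        if (!oracle_match_table[pch[i], scan_t[s0 + i]]) {
          mm <- mm + 1
          if (i %in% wpos) mmw <- mmw + 1
        }
      }
      if (mm <= policy$max_mismatches_total &&
            mmw <= policy$max_mismatches_in_window)
        out[[length(out) + 1]] <- data.frame(
          strand = strand, start = s0, end = s0 + m, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## naive amplicon enumeration from oracle sites: every (+ fwd, - rev) pair
## with the rev end downstream (wrapping once on circular templates),
## product within policy, each physical pair once at its shortest extent
oracle_amplicons <- function(fseq, rseq, tmpl, circular, policy) {
  fs <- oracle_sites(fseq, tmpl, circular, policy)
  fs <- fs[fs$strand == "+", , drop = FALSE]
  rs <- oracle_sites(rseq, tmpl, circular, policy)
  rs <- rs[rs$strand == "-", , drop = FALSE]
  n <- nchar(tmpl)
  out <- list()
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    lens <- c(if (rs$start[j] >= fs$start[i]) rs$end[j] - fs$start[i],
              if (circular) rs$end[j] + n - fs$start[i])
    lens <- lens[lens >= max(nchar(fseq), nchar(rseq)) &
                   lens <= policy$max_product_len]
    if (length(lens))
      out[[length(out) + 1]] <- data.frame(
        fwd_start = fs$start[i], rev_phys = rs$start[j],
        length = min(lens), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(fwd_start = integer(0), rev_phys = integer(0),
                      length = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$fwd_start, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## exhaustive 3'-anchored cross-dimer score over all concrete expansions
## and all antiparallel offsets
oracle_dimer <- function(s1, s2) {
  run_for <- function(a, b) {
    ## longest complementary run ending at a's 3' end, some offset of b
    ach <- strsplit(a, "")[[1]]
    bch <- strsplit(b, "")[[1]]
    best <- 0
    for (j in seq_along(bch)) {
      k <- 0
      while (k < length(ach) && j + k <= length(bch) &&
               oracle_comp[[ach[length(ach) - k]]] == bch[j + k])
        k <- k + 1
      best <- max(best, k)
    }
    best
  }
  best <- 0
  for (e1 in multipcr::expand_degenerate(s1))
    for (e2 in multipcr::expand_degenerate(s2))
      best <- max(best, run_for(e1, e2), run_for(e2, e1))
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac <- function(n, codes = names(oracle_sets)) {
  paste(sample(codes, n, replace = TRUE), collapse = "")
}

## a quick concrete resolution of a degenerate string (first expansion)
concrete1 <- function(s) multipcr::expand_degenerate(s)[1]
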