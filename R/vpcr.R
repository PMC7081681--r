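#' Primer-binding match policy
#'
#' Parameterises what counts as "specific amplification": how many
#' mismatches a primer may tolerate overall, how many inside the
#' 3'-terminal window (where mismatches block extension in real PCR), and
#' the longest product the polymerase is assumed to make.
#'
#' @param max_mismatches_total mismatches allowed anywhere in the primer.
#' @param three_prime_window length (nt) of the 3'-terminal window.
#' @param max_mismatches_in_window mismatches allowed in that window.
#' @param max_product_len longest reported product (bp).
#' @return object of class `match_policy`.
#' @export
match_policy <- function(max_mismatches_total = 2L,
                         three_prime_window = 5L,
                         max_mismatches_in_window = 0L,
                         max_product_len = 1500L) {
  stopifnot(max_mismatches_total >= 0L, three_prime_window >= 0L,
            max_mismatches_in_window >= 0L, max_product_len >= 0L)
  structure(list(max_mismatches_total = as.integer(max_mismatches_total),
                 three_prime_window = as.integer(three_prime_window),
                 max_mismatches_in_window = as.integer(max_mismatches_in_window),
                 max_product_len = as.integer(max_product_len)),
            class = "match_policy")
}

#' @export
print.match_policy <- function(x, ...) {
  cat(sprintf(
    "<match_policy> <=%d mismatches total, <=%d in 3' %d nt, products <=%d bp\n",
    x$max_mismatches_total, x$max_mismatches_in_window, x$three_prime_window,
    x$max_product_len))
  invisible(x)
}

## Vectorised mismatch profile: for a pattern (bit codes) slid along a
## template (bit codes), returns per-offset total mismatches and mismatches
## within the given pattern positions. Degenerate codes on either side match
## on base-set intersection, so N in a draft template never counts as a
## mismatch (conservative, avoids false negatives).
.slide_mismatches <- function(tmpl_bits, pat_bits, window_positions) {
  n <- length(tmpl_bits)
  m <- length(pat_bits)
  k <- n - m + 1L
  if (k < 1L) return(list(total = integer(0), window = integer(0)))
  total <- integer(k)
  window <- integer(k)
  for (i in seq_len(m)) {
    miss <- bitwAnd(tmpl_bits[i:(i + k - 1L)], pat_bits[i]) == 0L
    total <- total + miss
    if (i %in% window_positions) window <- window + miss
  }
  list(total = total, window = window)
}

.sites_df <- function(template_id = character(0)) {
  data.frame(template_id = template_id, primer = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             mismatches = integer(0), mismatches_3prime = integer(0),
             stringsAsFactors = FALSE)
}

#' Find primer binding sites on a template
#'
#' Exhaustive degenerate-aware scan for every position where the primer can
#' prime synthesis, on both strands. Coordinates are 0-based half-open on
#' the forward strand of the stored template; `end - start` equals the
#' primer length. Strand `+` means the primer matches the forward strand as
#' written (priming rightward synthesis); strand `-` means the primer
#' matches the reverse strand, i.e. `revcomp(primer)` occurs on the forward
#' strand (priming leftward). On circular templates the scan is extended
#' past the origin by `max_product_len` plus one primer length so
#' origin-spanning sites are found exactly once; their coordinates may have
#' `end > length(template)`.
#'
#' @param p a [primer].
#' @param t a [nuc_sequence].
#' @param policy a [match_policy].
#' @return data.frame with columns `template_id`, `primer`, `strand`,
#'   `start`, `end`, `mismatches`, `mismatches_3prime`, sorted by `start`.
#' @export
find_binding_sites <- function(p, t, policy = match_policy()) {
  stopifnot(inherits(p, "primer"), inherits(t, "nuc_sequence"),
            inherits(policy, "match_policy"))
  if (nchar(p$seq) > nchar(t$residues))
    stop("primer longer than template", call. = FALSE)
  enc <- .encode_template(t, policy, nchar(p$seq))
  .sites_for_primer(p, enc, policy, t$id)
}

## Encode a template once as bit codes, extended past the origin for
## circular topology (by max_product_len plus the longest primer, so
## origin-spanning sites and products are visible exactly once).
.encode_template <- function(t, policy, max_primer_len) {
  bits <- iupac_bits(t$residues)
  n <- length(bits)
  if (t$topology == "circular") {
    ext_len <- min(n - 1L, policy$max_product_len + max_primer_len - 1L)
    if (ext_len > 0L) bits <- c(bits, bits[seq_len(ext_len)])
  }
  list(bits = bits, n = n, circular = t$topology == "circular")
}

.sites_for_primer <- function(p, enc, policy, template_id) {
  m <- nchar(p$seq)
  w <- min(policy$three_prime_window, m)
  fwd_bits <- iupac_bits(p$seq)
  rev_bits <- iupac_bits(revcomp(p$seq))
  ## + strand: primer 3' end = last pattern position.
  ## - strand: pattern is revcomp(primer); primer 3' end = first position.
  hits <- list(
    .scan_one(enc$bits, fwd_bits, if (w > 0L) (m - w + 1L):m else integer(0),
              "+", policy),
    .scan_one(enc$bits, rev_bits, if (w > 0L) 1L:w else integer(0), "-",
              policy)
  )
  out <- do.call(rbind, hits)
  if (nrow(out)) {
    ## keep each physical site once: starts within the original sequence
    out <- out[out$start < enc$n, , drop = FALSE]
    out$template_id <- template_id
    out$primer <- p$name
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- .sites_df()
  }
  out
}

.scan_one <- function(tmpl_bits, pat_bits, window_positions, strand, policy) {
  mm <- .slide_mismatches(tmpl_bits, pat_bits, window_positions)
  keep <- which(mm$total <= policy$max_mismatches_total &
                  mm$window <= policy$max_mismatches_in_window)
  m <- length(pat_bits)
  data.frame(template_id = rep(NA_character_, length(keep)),
             primer = rep(NA_character_, length(keep)),
             strand = rep(strand, length(keep)),
             start = keep - 1L, end = keep - 1L + m,
             mismatches = mm$total[keep], mismatches_3prime = mm$window[keep],
             stringsAsFactors = FALSE)
}

.amplicons_df <- function() {
  data.frame(template_id = character(0), fwd = character(0),
             rev = character(0), fwd_start = integer(0),
             fwd_end = integer(0), rev_start = integer(0),
             rev_end = integer(0), length = integer(0),
             mismatches = integer(0), wraps_origin = logical(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Predict PCR products of one primer pair on a template
#'
#' Pairs every forward-strand site of `fwd` with every downstream
#' reverse-strand site of `rev` whose product is no longer than
#' `policy$max_product_len`. Product length is primer-inclusive: the 5' end
#' of the forward site through the 3' end of the reverse site on the
#' forward strand, matching how product sizes are read off a gel. On
#' circular templates, products spanning the origin are reported exactly
#' once with `wraps_origin = TRUE` (their `rev_end` exceeds the template
#' length; subtract the length to wrap). The amplicon sequence is the
#' template substring, i.e. primer-region bases as written on the template.
#'
#' @param fwd,rev [primer]s (forward and reverse).
#' @param t a [nuc_sequence].
#' @param policy a [match_policy].
#' @param with_sequence include the product sequence column (default TRUE).
#' @return data.frame of class `amplicon_table`; zero rows means
#'   PCR-negative.
#' @export
predict_amplicons <- function(fwd, rev, t, policy = match_policy(),
                              with_sequence = TRUE) {
  enc <- .encode_template(t, policy, max(nchar(fwd$seq), nchar(rev$seq)))
  fsites <- .sites_for_primer(fwd, enc, policy, t$id)
  fsites <- fsites[fsites$strand == "+", , drop = FALSE]
  rsites <- .rev_sites_extended(.sites_for_primer(rev, enc, policy, t$id),
                                enc)
  out <- .pair_sites(fsites, rsites, fwd$name, rev$name, t, policy,
                     with_sequence)
  class(out) <- c("amplicon_table", class(out))
  out
}

## Reverse-strand sites including, on circular templates, images shifted
## one template length rightward so a forward site near the end can pair
## across the origin. Coordinates beyond the template length denote wrap.
.rev_sites_extended <- function(sites, enc) {
  sites <- sites[sites$strand == "-", , drop = FALSE]
  if (enc$circular && nrow(sites)) {
    wrapped <- sites
    wrapped$start <- wrapped$start + enc$n
    wrapped$end <- wrapped$end + enc$n
    sites <- rbind(sites, wrapped)
  }
  sites
}

.pair_sites <- function(fsites, rsites, fwd_name, rev_name, t, policy,
                        with_sequence) {
  n <- nchar(t$residues)
  out <- .amplicons_df()
  if (!nrow(fsites) || !nrow(rsites)) return(out)
  ext <- if (!with_sequence) NULL
         else if (t$topology == "circular") paste0(t$residues, t$residues)
         else t$residues
  for (i in seq_len(nrow(fsites))) {
    fs <- fsites[i, ]
    len <- rsites$end - fs$start
    ok <- len <= policy$max_product_len &
      len >= pmax(fs$end - fs$start, rsites$end - rsites$start) &
      rsites$start >= fs$start
    ## each physical (fwd site, rev site) pair once, at its shortest
    ## rightward extent (relevant when max_product_len >= template length)
    seen <- character(0)
    for (j in which(ok)[order(len[ok])]) {
      rs <- rsites[j, ]
      key <- paste(fs$start, rs$start %% n)
      if (key %in% seen) next
      seen <- c(seen, key)
      wraps <- rs$end > n
      out <- rbind(out, data.frame(
        template_id = t$id, fwd = fwd_name, rev = rev_name,
        fwd_start = fs$start, fwd_end = fs$end,
        rev_start = rs$start %% n, rev_end = rs$end,
        length = rs$end - fs$start,
        mismatches = fs$mismatches + rs$mismatches,
        wraps_origin = wraps,
        sequence = if (with_sequence)
          substr(ext, fs$start + 1L, rs$end) else NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(out)) {
    out <- out[order(out$fwd_start, out$length), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' @export
print.amplicon_table <- function(x, ...) {
  if (!nrow(x)) {
    cat("<amplicons> no products (PCR-negative)\n")
    return(invisible(x))
  }
  cat(sprintf("<amplicons> %d product(s)\n", nrow(x)))
  show <- x[, setdiff(names(x), "sequence"), drop = FALSE]
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Run a multiplex panel against a template
#'
#' Takes the union of [predict_amplicons] over *all* forward x reverse
#' primer combinations in the panel -- not only the intended pairs -- so
#' shared reverse primers and unintended cross-pair products are visible.
#' Products are deduplicated by (template, start, end).
#'
#' @param panel a [panel_design].
#' @param t a [nuc_sequence].
#' @param policy a [match_policy].
#' @param with_sequence include product sequences.
#' @return an `amplicon_table` data.frame (possibly zero rows).
#' @export
run_multiplex <- function(panel, t, policy = match_policy(),
                          with_sequence = FALSE) {
  stopifnot(inherits(panel, "panel_design"))
  if (!length(panel$members)) stop("empty panel", call. = FALSE)
  fwds <- panel_primers(panel, "fwd")
  revs <- panel_primers(panel, "rev")
  max_m <- max(vapply(c(fwds, revs), function(p) nchar(p$seq), integer(1)))
  enc <- .encode_template(t, policy, max_m)
  fsites <- lapply(fwds, function(p) {
    s <- .sites_for_primer(p, enc, policy, t$id)
    s[s$strand == "+", , drop = FALSE]
  })
  rsites <- lapply(revs, function(p)
    .rev_sites_extended(.sites_for_primer(p, enc, policy, t$id), enc))
  pieces <- list()
  for (f in names(fsites)) for (r in names(rsites)) {
    pieces[[length(pieces) + 1L]] <-
      .pair_sites(fsites[[f]], rsites[[r]], f, r, t, policy, with_sequence)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out) || !nrow(out)) {
    out <- .amplicons_df()
  } else {
    key <- paste(out$template_id, out$fwd_start, out$rev_end)
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$fwd_start, out$length), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("amplicon_table", class(out))
  out
}
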