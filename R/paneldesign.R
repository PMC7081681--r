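#' Constraints governing panel design
#'
#' Defaults encode the stated design goal: specific products under 500 bp
#' whose sizes differ enough to be resolved side by side on a 1.5% agarose
#' gel. The minimum size gap defaults to 30 bp with a warning below 40:
#' 40-50 bp spacing is the stated aim, but the published panels themselves
#' realise minimum gaps of 39 and 36 bp, so a hard 40 would reject working
#' designs.
#'
#' @param max_product_len longest admissible product (bp).
#' @param min_size_gap minimum pairwise difference of expected sizes (bp).
#' @param warn_size_gap gap below which a warning is emitted (bp).
#' @param primer_len `c(min, max)` primer length (nt).
#' @param tm_method `"wallace"` or `"nearest_neighbor"`.
#' @param tm_range admissible primer Tm interval (degrees C).
#' @param max_tm_spread largest admissible distance between the Tm
#'   intervals of any two panel primers (degrees C).
#' @param gc_range admissible GC fraction.
#' @param max_degeneracy largest admissible primer degeneracy.
#' @param three_prime_clamp require a concrete (non-degenerate) 3' base.
#' @param max_dimer_run largest admissible 3'-anchored complementary run
#'   between any two panel primers (nt).
#' @param min_flank_len shortest conserved flank accepted around a
#'   variable core (alignment columns).
#' @param conservation_threshold within-species conservation above which a
#'   column's species consensus is its majority code (below it, the
#'   degenerate union).
#' @param binding_policy the [match_policy] species-specific candidates
#'   must defeat on non-target species: a candidate is kept only if, for
#'   every other species, it carries more mismatches than the policy
#'   tolerates or a mismatch inside the 3'-terminal window.
#' @return object of class `design_constraints`.
#' @export
design_constraints <- function(max_product_len = 500L, min_size_gap = 30L,
                               warn_size_gap = 40L, primer_len = c(18L, 25L),
                               tm_method = c("wallace", "nearest_neighbor"),
                               tm_range = c(50, 68), max_tm_spread = 5,
                               gc_range = c(0.30, 0.70), max_degeneracy = 8L,
                               three_prime_clamp = TRUE, max_dimer_run = 8L,
                               min_flank_len = 20L,
                               conservation_threshold = 0.95,
                               binding_policy = match_policy()) {
  tm_method <- match.arg(tm_method)
  stopifnot(primer_len[1] < primer_len[2], tm_range[1] < tm_range[2],
            gc_range[1] < gc_range[2],
            max_product_len > 2 * primer_len[1],
            min_size_gap >= 0, max_degeneracy >= 1)
  structure(as.list(environment()), class = "design_constraints")
}

#' Per-column conservation and discrimination profiles of an alignment
#'
#' For every alignment column: the within-species conservation (fraction
#' of that species' rows carrying the species-majority code), the gap
#' fraction, the per-species consensus code (majority code at conserved
#' columns, degenerate union below `conservation_threshold`), and
#' discrimination flags -- a column discriminates species `s` when the
#' consensus base set of `s` is disjoint from every other species' set.
#'
#' @param a an [alignment] with at least two species.
#' @param constraints a [design_constraints] (only the conservation
#'   threshold is used here).
#' @return object of class `column_profiles`: list with `species`, `width`,
#'   matrices `conservation` and `disc_species` (species x column),
#'   `consensus_bits` (species x column), vectors `gap_fraction` and
#'   `discrimination` (1 when all species sets are pairwise disjoint).
#' @export
column_profiles <- function(a, constraints = design_constraints()) {
  stopifnot(inherits(a, "alignment"))
  sp <- unique(a$species)
  if (length(sp) < 2L)
    stop("alignment must contain at least two species", call. = FALSE)
  w <- a$width
  mat <- do.call(rbind, strsplit(a$rows, ""))   # rows x columns
  ns <- length(sp)
  conservation <- matrix(NA_real_, ns, w, dimnames = list(sp, NULL))
  consensus_bits <- matrix(NA_integer_, ns, w, dimnames = list(sp, NULL))
  gap_fraction <- colMeans(mat == "-")
  thr <- constraints$conservation_threshold
  for (si in seq_along(sp)) {
    rows <- mat[a$species == sp[si], , drop = FALSE]
    chars <- sort(unique(as.vector(rows)))
    counts <- vapply(chars, function(ch) colSums(rows == ch),
                     numeric(w))             # w x length(chars)
    if (w == 1L) counts <- matrix(counts, nrow = 1L)
    maj_idx <- max.col(counts, ties.method = "first")  # ties: alphabetical
    cons <- counts[cbind(seq_len(w), maj_idx)] / nrow(rows)
    conservation[si, ] <- cons
    maj_bits <- unname(.IUPAC_BITS[chars[maj_idx]])
    union_bits <- integer(w)
    for (ci in seq_along(chars)) {
      present <- counts[, ci] > 0
      union_bits[present] <- bitwOr(union_bits[present],
                                    .IUPAC_BITS[[chars[ci]]])
    }
    consensus_bits[si, ] <- ifelse(cons >= thr, maj_bits, union_bits)
  }
  disc_species <- matrix(0L, ns, w, dimnames = list(sp, NULL))
  for (si in seq_along(sp)) {
    others <- consensus_bits[-si, , drop = FALSE]
    overlap <- bitwAnd(others,
                       matrix(consensus_bits[si, ], nrow(others), w,
                              byrow = TRUE)) > 0L
    dim(overlap) <- dim(others)
    disc_species[si, ] <- as.integer(colSums(overlap) == 0L &
                                       consensus_bits[si, ] > 0L)
  }
  discrimination <- as.integer(colSums(disc_species) == ns)
  structure(list(species = sp, width = w, conservation = conservation,
                 consensus_bits = consensus_bits, gap_fraction = gap_fraction,
                 disc_species = disc_species, discrimination = discrimination),
            class = "column_profiles")
}

#' @export
print.column_profiles <- function(x, ...) {
  cat(sprintf(
    "<column_profiles> %d columns, %d species; %d fully discriminating column(s)\n",
    x$width, length(x$species), sum(x$discrimination)))
  invisible(x)
}

## Columns conserved across all species: high within-species conservation,
## no gaps, identical consensus in every species.
.conserved_columns <- function(profiles, constraints) {
  thr <- constraints$conservation_threshold
  all_cons <- apply(profiles$conservation >= thr, 2, all)
  same <- apply(profiles$consensus_bits, 2,
                function(b) length(unique(b)) == 1L)
  all_cons & same & profiles$gap_fraction == 0
}

#' Find diagnostic windows: variable cores between conserved flanks
#'
#' Scans the column profiles for maximal runs of cross-species conserved
#' columns of at least `min_flank_len`; every ordered pair of such runs
#' whose flank-to-flank span fits within `max_product_len` brackets a
#' variable core. A window is reported for species `s` when the core
#' contains at least one column discriminating `s`. Pairing all runs (not
#' only adjacent ones) keeps the window set monotone: weakening the flank
#' requirement can only add windows.
#'
#' @param profiles a [column_profiles].
#' @param constraints a [design_constraints].
#' @return data.frame with one row per (species, window): `species`,
#'   `flank_left_start`, `flank_left_end`, `core_start`, `core_end`,
#'   `flank_right_start`, `flank_right_end` (1-based inclusive alignment
#'   columns), `n_disc` (discriminating columns in the core for that
#'   species), sorted by position. Zero rows when nothing qualifies.
#' @export
find_diagnostic_windows <- function(profiles, constraints = design_constraints()) {
  stopifnot(inherits(profiles, "column_profiles"))
  cons <- .conserved_columns(profiles, constraints)
  r <- rle(cons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends)[r$values, , drop = FALSE]
  runs <- runs[runs$end - runs$start + 1L >= constraints$min_flank_len, ,
               drop = FALSE]
  out <- list()
  if (nrow(runs) >= 2L) {
    for (k in seq_len(nrow(runs) - 1L)) {
     for (l in (k + 1L):nrow(runs)) {
      L <- runs[k, ]; R <- runs[l, ]
      core <- c(L$end + 1L, R$start - 1L)
      if (core[2] < core[1]) next
      if (R$end - L$start + 1L > constraints$max_product_len) break
      for (sp in profiles$species) {
        nd <- sum(profiles$disc_species[sp, core[1]:core[2]])
        if (nd >= 1L)
          out[[length(out) + 1L]] <- data.frame(
            species = sp,
            flank_left_start = L$start, flank_left_end = L$end,
            core_start = core[1], core_end = core[2],
            flank_right_start = R$start, flank_right_end = R$end,
            n_disc = nd, stringsAsFactors = FALSE)
      }
     }
    }
  }
  if (!length(out)) {
    return(data.frame(species = character(0), flank_left_start = integer(0),
                      flank_left_end = integer(0), core_start = integer(0),
                      core_end = integer(0), flank_right_start = integer(0),
                      flank_right_end = integer(0), n_disc = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$flank_left_start, res$species), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.bits_to_code <- function(bits) {
  names(.IUPAC_BITS)[match(bits, .IUPAC_BITS)]
}

## Map an alignment column to the 0-based template position for a species
## (counting that species' consensus non-gap columns). Returns a vector
## over all columns; NA where the species consensus is a gap.
.species_template_pos <- function(profiles, sp) {
  present <- profiles$consensus_bits[sp, ] > 0L
  pos <- cumsum(present) - 1L
  pos[!present] <- NA_integer_
  pos
}

#' Enumerate primer candidates within a diagnostic window
#'
#' Slides every admissible start/length over the window span and builds,
#' for each species (and for the cross-species consensus, yielding
#' "shared" candidates), the degenerate consensus primer over that span.
#' Degenerate codes appear only where within-species variation pushes a
#' column below the conservation threshold. A candidate is kept if it
#' satisfies the per-primer constraints (length, degeneracy, GC, Tm range,
#' concrete 3' base); species-specific candidates must additionally be
#' unable to prime any other species' consensus under the constraints'
#' `binding_policy` -- more total mismatches than the policy tolerates, or
#' a mismatch inside the 3'-terminal window where mismatches block
#' extension (the minimum mismatch counts against other species are
#' reported per candidate).
#' Forward candidates are enumerated over the left flank plus core and
#' reverse candidates (reverse-complemented) over the core plus right
#' flank.
#'
#' @param window one row of [find_diagnostic_windows] output.
#' @param profiles the [column_profiles] the window came from.
#' @param constraints a [design_constraints].
#' @param species species to enumerate for (default: the window's).
#' @return data.frame of class `primer_candidates`: `name`, `species`
#'   (`"shared"` for cross-species conserved candidates), `orientation`,
#'   `seq`, `aln_start`, `aln_end` (1-based inclusive columns),
#'   `tpl_start`, `tpl_end` (0-based half-open on the species template;
#'   for shared candidates, on the first species), `degeneracy`, `gc`,
#'   `tm_min`, `tm_max`, `min_mismatch_vs_others`, `min_mismatch_3p`.
#' @export
enumerate_candidates <- function(window, profiles,
                                 constraints = design_constraints(),
                                 species = window$species) {
  stopifnot(inherits(profiles, "column_profiles"))
  lens <- constraints$primer_len[1]:constraints$primer_len[2]
  spans <- list(
    fwd = c(window$flank_left_start, window$core_end),
    rev = c(window$core_start, window$flank_right_end))
  conserved <- .conserved_columns(profiles, constraints)
  rows <- list()
  for (orient in names(spans)) {
    span <- spans[[orient]]
    for (start in span[1]:span[2]) {
      for (len in lens) {
        end <- start + len - 1L
        if (end > span[2]) next
        cand <- .build_candidate(start, end, orient, species, profiles,
                                 constraints, conserved)
        if (!is.null(cand)) rows[[length(rows) + 1L]] <- cand
      }
    }
  }
  if (length(rows)) {
    out <- data.frame(
      name = vapply(rows, `[[`, character(1), "name"),
      species = vapply(rows, `[[`, character(1), "species"),
      orientation = vapply(rows, `[[`, character(1), "orientation"),
      seq = vapply(rows, `[[`, character(1), "seq"),
      aln_start = vapply(rows, `[[`, integer(1), "aln_start"),
      aln_end = vapply(rows, `[[`, integer(1), "aln_end"),
      degeneracy = vapply(rows, `[[`, numeric(1), "degeneracy"),
      gc = vapply(rows, `[[`, numeric(1), "gc"),
      tm_min = vapply(rows, `[[`, numeric(1), "tm_min"),
      tm_max = vapply(rows, `[[`, numeric(1), "tm_max"),
      min_mismatch_vs_others = vapply(rows, `[[`, integer(1),
                                      "min_mismatch_vs_others"),
      min_mismatch_3p = vapply(rows, `[[`, integer(1), "min_mismatch_3p"),
      stringsAsFactors = FALSE)
    ## template coordinates of the spanned columns (0-based half-open),
    ## projected onto each candidate's own species (first species for
    ## shared candidates)
    out$tpl_start <- NA_integer_
    out$tpl_end <- NA_integer_
    for (sp_i in unique(out$species)) {
      pos <- .species_template_pos(
        profiles, if (sp_i == "shared") profiles$species[1] else sp_i)
      sel <- out$species == sp_i
      out$tpl_start[sel] <- pos[out$aln_start[sel]]
      out$tpl_end[sel] <- pos[out$aln_end[sel]] + 1L
    }
  } else {
    out <- data.frame(name = character(0), species = character(0),
                      orientation = character(0), seq = character(0),
                      aln_start = integer(0), aln_end = integer(0),
                      degeneracy = numeric(0), gc = numeric(0),
                      tm_min = numeric(0), tm_max = numeric(0),
                      min_mismatch_vs_others = integer(0),
                      min_mismatch_3p = integer(0), tpl_start = integer(0),
                      tpl_end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("primer_candidates", class(out))
  out
}

.build_candidate <- function(start, end, orient, sp, profiles, constraints,
                             conserved) {
  cols <- start:end
  bits <- profiles$consensus_bits[sp, cols]
  if (any(bits == 0L)) return(NULL)            # gap in consensus
  shared <- all(conserved[cols])
  deg <- prod(.BITS_CARD[bits + 1L])
  if (deg > constraints$max_degeneracy) return(NULL)
  ## primer 3' base: last column for fwd, first column (complemented) for rev
  if (constraints$three_prime_clamp) {
    b3 <- if (orient == "fwd") bits[length(bits)] else bits[1]
    if (.BITS_CARD[b3 + 1L] != 1L) return(NULL)
  }
  ## GC fraction over expansions (midpoint must sit in range); unchanged
  ## under reverse complement
  can_gc <- bitwAnd(bits, 6L) > 0L    # code contains G or C
  can_at <- bitwAnd(bits, 9L) > 0L    # code contains A or T
  gc_mid <- (sum(can_gc & !can_at) + sum(can_gc & can_at) / 2) / length(cols)
  if (gc_mid < constraints$gc_range[1] || gc_mid > constraints$gc_range[2])
    return(NULL)
  codes <- .bits_to_code(bits)
  seq <- if (orient == "fwd") paste(codes, collapse = "")
         else paste(rev(unname(.IUPAC_COMPLEMENT[codes])), collapse = "")
  if (constraints$tm_method == "wallace") {
    ## Wallace contributions per position: 2 for A/T, 4 for G/C; a
    ## degenerate code spans both when it mixes the classes
    tm <- c(sum(ifelse(can_at, 2, 4)), sum(ifelse(can_gc, 4, 2)))
  } else {
    tm <- tm_estimate(seq, method = constraints$tm_method)
  }
  if (tm[1] < constraints$tm_range[1] || tm[2] > constraints$tm_range[2])
    return(NULL)

  mm_min <- NA_integer_; mm3_min <- NA_integer_
  if (!shared) {
    ## specificity against every non-target species consensus: the
    ## candidate must not be able to prime the other species under the
    ## binding policy, i.e. per species either more total mismatches than
    ## the policy tolerates or at least one mismatch in the 3'-terminal
    ## window (where any mismatch blocks extension under the default)
    pol <- constraints$binding_policy
    w3 <- min(pol$three_prime_window, length(cols))
    others <- setdiff(profiles$species, sp)
    mm <- integer(0); mm3 <- integer(0)
    for (o in others) {
      obits <- profiles$consensus_bits[o, cols]
      miss <- bitwAnd(bits, obits) == 0L | obits == 0L
      ## 3'-terminal window of the primer as oriented
      idx3 <- if (orient == "fwd") tail(seq_along(cols), w3)
              else head(seq_along(cols), w3)
      mm <- c(mm, sum(miss)); mm3 <- c(mm3, sum(miss[idx3]))
    }
    mm_min <- min(mm); mm3_min <- min(mm3)
    blocked <- mm > pol$max_mismatches_total |
      mm3 > pol$max_mismatches_in_window
    if (!all(blocked)) return(NULL)
  }
  name <- sprintf("%s_%s_%d_%d",
                  if (shared) "shared" else gsub("[^A-Za-z0-9]+", ".", sp),
                  orient, start, end)
  list(
    name = name, species = if (shared) "shared" else sp,
    orientation = orient, seq = seq, aln_start = start, aln_end = end,
    degeneracy = deg, gc = gc_mid, tm_min = tm[[1]], tm_max = tm[[2]],
    min_mismatch_vs_others = mm_min, min_mismatch_3p = mm3_min)
}
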