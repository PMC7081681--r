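## Panel selection: one primer pair per species, sizes spaced for gel
## resolution, Tm-compatible, dimer-clean. Deterministic given input order.

## All admissible (fwd, rev) pairs for one species, with the
## primer-inclusive product size projected onto that species' template.
.species_pairs <- function(cands, profiles, sp, constraints) {
  pos <- .species_template_pos(profiles, sp)
  own <- cands[cands$species %in% c(sp, "shared"), , drop = FALSE]
  fwd <- own[own$orientation == "fwd", , drop = FALSE]
  rev <- own[own$orientation == "rev", , drop = FALSE]
  if (!nrow(fwd) || !nrow(rev)) return(NULL)
  rev_end_pos <- pos[rev$aln_end] + 1L
  rev_len <- nchar(rev$seq)
  is <- list(); js <- list()
  for (i in seq_len(nrow(fwd))) {
    size <- rev_end_pos - pos[fwd$aln_start[i]]
    ok <- which(!is.na(size) & size <= constraints$max_product_len &
                  size >= nchar(fwd$seq[i]) + rev_len)
    if (length(ok)) {
      is[[length(is) + 1L]] <- rep.int(i, length(ok))
      js[[length(js) + 1L]] <- ok
    }
  }
  if (!length(is)) return(NULL)
  i <- unlist(is); j <- unlist(js)
  out <- data.frame(
    species = sp, fwd_name = fwd$name[i], fwd_seq = fwd$seq[i],
    rev_name = rev$name[j], rev_seq = rev$seq[j],
    size = rev_end_pos[j] - pos[fwd$aln_start[i]],
    fwd_shared = fwd$species[i] == "shared",
    rev_shared = rev$species[j] == "shared",
    f_tm_min = fwd$tm_min[i], f_tm_max = fwd$tm_max[i],
    r_tm_min = rev$tm_min[j], r_tm_max = rev$tm_max[j],
    stringsAsFactors = FALSE)
  ## the two primers of a pair must themselves be Tm-compatible, and at
  ## least one must be species-specific: a fully shared pair amplifies
  ## every species and can never be diagnostic
  gap <- pmax(0, out$r_tm_min - out$f_tm_max, out$f_tm_min - out$r_tm_max)
  out <- out[gap <= constraints$max_tm_spread &
               !(out$fwd_shared & out$rev_shared), , drop = FALSE]
  if (!nrow(out)) return(NULL)
  out
}

## Keep a deterministic, size-diverse subset: one pair per distinct size,
## preferring pairs whose Tm midpoints sit near the centre of the
## admissible Tm range (so the retained pairs are mutually compatible),
## then shared primers, then lexicographic names; finally at most `cap`
## sizes spread evenly across the size range.
.prune_pairs <- function(pairs, cap, constraints) {
  tm_target <- mean(constraints$tm_range)
  tm_mid <- (pmin(pairs$f_tm_min, pairs$r_tm_min) +
               pmax(pairs$f_tm_max, pairs$r_tm_max)) / 2
  ord <- order(pairs$size, abs(tm_mid - tm_target),
               !(pairs$fwd_shared | pairs$rev_shared),
               pairs$fwd_name, pairs$rev_name)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$size), , drop = FALSE]
  if (nrow(pairs) > cap) {
    keep <- unique(round(seq(1, nrow(pairs), length.out = cap)))
    pairs <- pairs[keep, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

.interval_distance <- function(a_min, a_max, b_min, b_max) {
  max(0, b_min - a_max, a_min - b_max)
}

#' Select a size-spaced multiplex panel
#'
#' Chooses one (forward, reverse) candidate pair per species maximising the
#' minimum pairwise expected-size gap, subject to: all sizes at most
#' `max_product_len`, minimum gap at least `min_size_gap`, every pair of
#' panel primers Tm-compatible (interval distance at most `max_tm_spread`)
#' and dimer-clean ([cross_dimer_score] at most `max_dimer_run`). Shared
#' primers are preferred when otherwise tied (fewer oligos to synthesise),
#' then smaller total amplicon length, then lexicographic primer names, so
#' the selection is deterministic given input order. The search is a
#' branch-and-bound on the size-gap objective, exact because the partial
#' minimum gap can only shrink as members are added; it reduces to
#' exhaustive search on small candidate sets. A warning is emitted when the
#' selected minimum gap falls below `warn_size_gap`.
#'
#' @param candidates a `primer_candidates` data.frame (rows for all target
#'   species, including `"shared"` candidates), e.g. rbind-ed output of
#'   [enumerate_candidates] over windows.
#' @param profiles the [column_profiles] the candidates came from.
#' @param constraints a [design_constraints].
#' @param species species to cover (default: all non-shared species in
#'   `candidates`).
#' @param panel_name name of the resulting panel.
#' @param max_pairs_per_species deterministic cap on candidate pairs
#'   considered per species (size-diverse subset).
#' @param verify_templates optional named list of [nuc_sequence], one per
#'   species (e.g. the species consensus genomes): each complete
#'   assignment is additionally checked by in-silico multiplex -- every
#'   template must yield exactly its intended band across *all* forward x
#'   reverse combinations under `verify_policy`. This rejects assignments
#'   whose per-primer specificity margins (one mismatch against another
#'   species) are still tolerated by the binding policy, and shared-primer
#'   combinations that amplify more than one locus.
#' @param verify_policy [match_policy] for the verification multiplex; the
#'   default is the classification layer's default policy, so cross-pair
#'   products longer than the design's own size budget are still caught.
#' @return a [panel_design]; on infeasibility an error of class
#'   `panel_infeasible` naming the violated constraint(s).
#' @export
select_panel <- function(candidates, profiles,
                         constraints = design_constraints(),
                         species = NULL, panel_name = "panel",
                         max_pairs_per_species = 40L,
                         verify_templates = NULL,
                         verify_policy = match_policy()) {
  if (is.null(species))
    species <- setdiff(unique(candidates$species), "shared")
  if (!length(species)) stop("no species to design for", call. = FALSE)
  pairs_by_sp <- list()
  for (sp in species) {
    p <- .species_pairs(candidates, profiles, sp, constraints)
    if (is.null(p))
      stop(structure(class = c("panel_infeasible", "error", "condition"),
                     list(message = paste0("no candidate pairs for species '",
                                           sp, "'"),
                          call = NULL, violated = "candidates")))
    pairs_by_sp[[sp]] <- .prune_pairs(p, max_pairs_per_species, constraints)
  }
  ## explore species with the fewest options first
  ord <- order(vapply(pairs_by_sp, nrow, integer(1)))
  pairs_by_sp <- pairs_by_sp[ord]
  sp_order <- names(pairs_by_sp)
  nsp <- length(sp_order)

  dimer_cache <- new.env(parent = emptyenv())
  dimer <- function(n1, s1, n2, s2) {
    key <- paste(sort(c(n1, n2)), collapse = "\r")
    v <- dimer_cache[[key]]
    if (is.null(v)) {
      v <- cross_dimer_score(s1, s2)
      dimer_cache[[key]] <- v
    }
    v
  }

  best <- NULL          # list(idx, gap, n_oligos, total, names_key)
  reject <- c(min_size_gap = 0L, max_tm_spread = 0L, max_dimer_run = 0L,
              cross_products = 0L)

  ## binding sites of every candidate primer on every verification
  ## template, computed lazily and cached, so the leaf-level multiplex
  ## check is cheap arithmetic
  if (!is.null(verify_templates) &&
        !all(sp_order %in% names(verify_templates)))
    stop("verify_templates must be named by species", call. = FALSE)
  site_cache <- new.env(parent = emptyenv())
  enc_cache <- new.env(parent = emptyenv())
  template_enc <- function(tpl_sp) {
    v <- enc_cache[[tpl_sp]]
    if (is.null(v)) {
      v <- .encode_template(verify_templates[[tpl_sp]], verify_policy,
                            constraints$primer_len[2] + 5L)
      enc_cache[[tpl_sp]] <- v
    }
    v
  }
  prim_sites <- function(name, seq, tpl_sp) {
    key <- paste(name, tpl_sp, sep = "\r")
    v <- site_cache[[key]]
    if (is.null(v)) {
      s <- .sites_for_primer(primer(name, seq), template_enc(tpl_sp),
                             verify_policy, tpl_sp)
      v <- list(fstart = s$start[s$strand == "+"],
                rstart = s$start[s$strand == "-"],
                rend = s$end[s$strand == "-"], len = nchar(seq))
      site_cache[[key]] <- v
    }
    v
  }
  multiplex_clean <- function(idx) {
    prs <- lapply(seq_len(nsp), function(k) {
      tbl <- pairs_by_sp[[k]]
      list(fn = tbl$fwd_name[idx[k]], fs = tbl$fwd_seq[idx[k]],
           rn = tbl$rev_name[idx[k]], rs = tbl$rev_seq[idx[k]],
           size = tbl$size[idx[k]])
    })
    for (k in seq_len(nsp)) {
      sp <- sp_order[k]
      keys <- character(0)
      sizes <- integer(0)
      for (f in prs) for (r in prs) {
        fsite <- prim_sites(f$fn, f$fs, sp)
        rsite <- prim_sites(r$rn, r$rs, sp)
        for (a in fsite$fstart) {
          len <- rsite$rend - a
          ok <- which(len <= verify_policy$max_product_len &
                        len >= pmax(fsite$len, rsite$len) &
                        rsite$rstart >= a)
          for (b in ok) {
            key <- paste(a, rsite$rend[b])
            if (!key %in% keys) {
              keys <- c(keys, key)
              sizes <- c(sizes, len[b])
            }
          }
        }
      }
      if (length(sizes) != 1L || sizes != prs[[k]]$size) return(FALSE)
    }
    TRUE
  }

  summarise_sel <- function(idx) {
    sizes <- vapply(seq_len(nsp), function(k) pairs_by_sp[[k]]$size[idx[k]],
                    numeric(1))
    nm <- unlist(lapply(seq_len(nsp), function(k) {
      tbl <- pairs_by_sp[[k]]
      c(tbl$fwd_name[idx[k]], tbl$rev_name[idx[k]])
    }))
    list(idx = idx,
         gap = if (nsp > 1L) min(dist(sizes)) else Inf,
         n_oligos = length(unique(nm)), total = sum(sizes),
         names_key = paste(sort(nm), collapse = " "))
  }
  better <- function(a, b) {
    if (a$gap != b$gap) return(a$gap > b$gap)
    if (a$n_oligos != b$n_oligos) return(a$n_oligos < b$n_oligos)
    if (a$total != b$total) return(a$total < b$total)
    a$names_key < b$names_key
  }

  ## depth-first branch and bound; the partial min gap only shrinks as
  ## members are added, so pruning on it is exact
  idx <- integer(nsp)
  recurse <- function(k, cur_gap) {
    if (k > nsp) {
      if (cur_gap < constraints$min_size_gap) {
        reject["min_size_gap"] <<- reject["min_size_gap"] + 1L
        return()
      }
      cand <- summarise_sel(idx)
      if (is.null(best) || better(cand, best)) {
        if (!is.null(verify_templates) && !multiplex_clean(idx)) {
          reject["cross_products"] <<- reject["cross_products"] + 1L
          return()
        }
        best <<- cand
      }
      return()
    }
    tbl <- pairs_by_sp[[k]]
    prev <- if (k > 1L) seq_len(k - 1L) else integer(0)
    prev_sizes <- vapply(prev, function(j) pairs_by_sp[[j]]$size[idx[j]],
                         numeric(1))
    for (i in seq_len(nrow(tbl))) {
      gap_here <- cur_gap
      if (length(prev)) {
        gap_now <- min(abs(prev_sizes - tbl$size[i]))
        gap_here <- min(cur_gap, gap_now)
        if (gap_here < constraints$min_size_gap) {
          reject["min_size_gap"] <<- reject["min_size_gap"] + 1L
          next
        }
        if (!is.null(best) && gap_here < best$gap) next
        ok <- TRUE
        for (j in prev) {
          pt <- pairs_by_sp[[j]]
          pn <- c(pt$fwd_name[idx[j]], pt$rev_name[idx[j]])
          ps <- c(pt$fwd_seq[idx[j]], pt$rev_seq[idx[j]])
          plo <- c(pt$f_tm_min[idx[j]], pt$r_tm_min[idx[j]])
          phi <- c(pt$f_tm_max[idx[j]], pt$r_tm_max[idx[j]])
          nn <- c(tbl$fwd_name[i], tbl$rev_name[i])
          ns <- c(tbl$fwd_seq[i], tbl$rev_seq[i])
          nlo <- c(tbl$f_tm_min[i], tbl$r_tm_min[i])
          nhi <- c(tbl$f_tm_max[i], tbl$r_tm_max[i])
          for (a in 1:2) for (b in 1:2) {
            if (nn[a] == pn[b]) next
            if (.interval_distance(nlo[a], nhi[a], plo[b], phi[b]) >
                  constraints$max_tm_spread) {
              reject["max_tm_spread"] <<- reject["max_tm_spread"] + 1L
              ok <- FALSE; break
            }
            if (dimer(nn[a], ns[a], pn[b], ps[b]) >
                  constraints$max_dimer_run) {
              reject["max_dimer_run"] <<- reject["max_dimer_run"] + 1L
              ok <- FALSE; break
            }
          }
          if (!ok) break
        }
        if (!ok) next
      }
      idx[k] <<- i
      recurse(k + 1L, gap_here)
    }
  }
  recurse(1L, Inf)

  if (is.null(best)) {
    violated <- names(reject)[reject > 0L]
    if (!length(violated)) violated <- "candidates"
    stop(structure(class = c("panel_infeasible", "error", "condition"),
                   list(message = paste0(
                     "no feasible panel; violated constraint(s): ",
                     paste(violated, collapse = ", "),
                     " (rejections: ",
                     paste(sprintf("%s=%d", names(reject), reject),
                           collapse = ", "), ")"),
                     call = NULL, violated = violated, rejections = reject)))
  }
  if (best$gap < constraints$warn_size_gap)
    warning(sprintf("minimum size gap %d bp is below the preferred %d bp",
                    as.integer(best$gap),
                    as.integer(constraints$warn_size_gap)), call. = FALSE)
  members <- lapply(species, function(sp) {
    k <- match(sp, sp_order)
    tbl <- pairs_by_sp[[k]]
    i <- best$idx[k]
    list(species = sp, fwd = primer(tbl$fwd_name[i], tbl$fwd_seq[i]),
         rev = primer(tbl$rev_name[i], tbl$rev_seq[i]),
         expected_size = as.integer(tbl$size[i]))
  })
  panel_design(panel_name, members)
}

#' Validate a panel against target and off-target genomes
#'
#' Runs the full multiplex (all forward x reverse combinations) against
#' every sequence. A target passes when it yields exactly one product, of
#' the expected size, from the intended primer pair for its species; any
#' missing band, wrong size, cross-pair or extra product is a failure with
#' the offending amplicon reported. Off-targets must yield no product at
#' all. With an empty off-target set the specificity section is reported
#' as "not assessed", never as a pass.
#'
#' @param panel a [panel_design].
#' @param targets list of [nuc_sequence] whose `species_label`s appear in
#'   the panel.
#' @param offtargets list of [nuc_sequence] expected to yield nothing
#'   (may be empty).
#' @param policy a [match_policy].
#' @return object of class `panel_validation`: data.frames `targets` and
#'   `offtargets`, logicals `all_pass` and `specificity_assessed`.
#' @export
validate_panel <- function(panel, targets, offtargets = list(),
                           policy = match_policy()) {
  stopifnot(inherits(panel, "panel_design"))
  if (inherits(targets, "nuc_sequence")) targets <- list(targets)
  if (inherits(offtargets, "nuc_sequence")) offtargets <- list(offtargets)
  sizes <- panel_sizes(panel)
  rows <- list()
  for (t in targets) {
    sp <- t$species_label
    if (is.na(sp) || !sp %in% names(sizes))
      stop("species label '", sp, "' of sequence '", t$id,
           "' is not in panel '", panel$name, "'", call. = FALSE)
    member <- panel$members[[match(sp, names(sizes))]]
    amps <- run_multiplex(panel, t, policy)
    ## what the intended pair alone would produce: a single band counts as
    ## intended when its physical coordinates match this, even if the
    ## multiplex deduplication attributed it to an overlapping primer name
    intended <- predict_amplicons(member$fwd, member$rev, t, policy,
                                  with_sequence = FALSE)
    status <- "PASS"; reason <- ""
    if (nrow(amps) == 0L) {
      status <- "FAIL"; reason <- "no amplification"
    } else if (nrow(amps) > 1L) {
      status <- "FAIL"
      reason <- paste0("multiple products: ",
                       paste(sprintf("%s/%s=%dbp", amps$fwd, amps$rev,
                                     amps$length), collapse = ", "))
    } else if (!(nrow(intended) == 1L &&
                   amps$fwd_start == intended$fwd_start &&
                   amps$rev_end == intended$rev_end)) {
      status <- "FAIL"
      reason <- sprintf("cross-pair product %s/%s (%d bp)", amps$fwd,
                        amps$rev, amps$length)
    } else if (amps$length != member$expected_size) {
      status <- "FAIL"
      reason <- sprintf("wrong size: %d bp, expected %d bp", amps$length,
                        member$expected_size)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = t$id, species = sp, expected_size = member$expected_size,
      n_products = nrow(amps),
      observed_sizes = paste(amps$length, collapse = ","),
      status = status, reason = reason, stringsAsFactors = FALSE)
  }
  tdf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), species = character(0),
               expected_size = integer(0), n_products = integer(0),
               observed_sizes = character(0), status = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  orows <- list()
  for (t in offtargets) {
    amps <- run_multiplex(panel, t, policy)
    orows[[length(orows) + 1L]] <- data.frame(
      id = t$id, n_products = nrow(amps),
      observed_sizes = paste(amps$length, collapse = ","),
      status = if (nrow(amps) == 0L) "PASS" else "FAIL",
      stringsAsFactors = FALSE)
  }
  odf <- if (length(orows)) do.call(rbind, orows) else
    data.frame(id = character(0), n_products = integer(0),
               observed_sizes = character(0), status = character(0),
               stringsAsFactors = FALSE)
  structure(list(
    panel = panel$name, targets = tdf, offtargets = odf,
    specificity_assessed = length(offtargets) > 0L,
    all_pass = all(tdf$status == "PASS") && all(odf$status == "PASS"),
    n_pass = sum(tdf$status == "PASS") + sum(odf$status == "PASS"),
    n_fail = sum(tdf$status == "FAIL") + sum(odf$status == "FAIL")),
    class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf("<panel_validation> %s: %d PASS, %d FAIL\n", x$panel,
              x$n_pass, x$n_fail))
  if (nrow(x$targets)) print.data.frame(x$targets, row.names = FALSE)
  if (x$specificity_assessed) {
    cat("off-target specificity:\n")
    print.data.frame(x$offtargets, row.names = FALSE)
  } else {
    cat("off-target specificity: not assessed (no off-targets supplied)\n")
  }
  invisible(x)
}

#' One-call design pipeline: alignment to panel
#'
#' Profiles the alignment, finds diagnostic windows, enumerates candidates
#' for every species across its windows, and selects a size-spaced panel.
#'
#' @param a a species-labelled [alignment].
#' @param constraints a [design_constraints].
#' @param panel_name name for the resulting panel.
#' @param max_pairs_per_species passed to [select_panel].
#' @param max_windows_per_species candidate enumeration is restricted to
#'   this many windows per species, ranked by the number of
#'   discriminating columns in the core (the strongest diagnostic
#'   regions); genome-scale alignments yield many weakly diagnostic
#'   background windows that would otherwise dominate the enumeration.
#' @return a [panel_design].
#' @export
design_panel <- function(a, constraints = design_constraints(),
                         panel_name = "designed",
                         max_pairs_per_species = 40L,
                         max_windows_per_species = 2L) {
  profiles <- column_profiles(a, constraints)
  windows <- find_diagnostic_windows(profiles, constraints)
  if (!nrow(windows))
    stop(structure(class = c("panel_infeasible", "error", "condition"),
                   list(message = "no diagnostic windows found", call = NULL,
                        violated = "windows")))
  keep <- unlist(lapply(split(seq_len(nrow(windows)), windows$species),
                        function(idx)
                          idx[order(-windows$n_disc[idx])][
                            seq_len(min(length(idx), max_windows_per_species))]))
  windows <- windows[sort(keep), , drop = FALSE]
  cands <- list()
  for (i in seq_len(nrow(windows)))
    cands[[i]] <- enumerate_candidates(windows[i, ], profiles, constraints)
  cands <- do.call(rbind, cands)
  cands <- cands[!duplicated(paste(cands$name, cands$species)), , drop = FALSE]
  ## per-species consensus templates (degenerate codes kept: they count as
  ## matches, which is the conservative side for a specificity check)
  templates <- lapply(profiles$species, function(sp) {
    bits <- profiles$consensus_bits[sp, ]
    nuc_sequence(paste0(sp, "_consensus"),
                 paste(.bits_to_code(bits[bits > 0L]), collapse = ""),
                 species_label = sp)
  })
  names(templates) <- profiles$species
  select_panel(cands, profiles, constraints, panel_name = panel_name,
               max_pairs_per_species = max_pairs_per_species,
               verify_templates = templates)
}
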