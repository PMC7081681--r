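## Synthetic stand-ins for the six reference mitochondrial genomes.
##
## The real reference records are GenBank downloads; to keep the package
## self-contained and runnable offline, a deterministic constructor builds
## six circular ~16.8 kb synthetic genomes that carry the published primer
## binding sites at the published spacings: the multiplex products
## (kangaroo 250, wallaby 425, wombat 289; fallow 197, red 482, sambar
## 161 bp), the cytb sequencing products (marsupial 692/662, deer
## 877/784 bp) and a cytb CDS of the published length (1146 bp marsupial,
## 1140 bp deer). Backgrounds are species-specific random sequence;
## construction verifies that no spurious binding site exists under the
## default match policy. These are explicitly synthetic: they validate the
## virtual PCR engine and panel machinery, not sequence identity to the
## real accessions.

.REF_LEN <- 16800L
.REF_SEED <- 101L
.ref_cache <- new.env(parent = emptyenv())

## Evaluate expr under a local RNG seed without disturbing the caller's
## random state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## Implant layout of one diagnostic locus, coordinates 0-based within the
## locus. Concrete resolutions of degenerate primer positions are fixed
## here once (they are the "true" template bases the degenerate primers
## cover).
.marsupial_layout <- function() {
  list(
    locus_len = 1260L, cds = c(40L, 1186L), gene = "cytb",
    clade_implants = list(
      list(at = 0L,    seq = "TTTTAGCATGGACTCTAACC"),          # MarCBF (Y->C)
      list(at = 550L,  seq = "TTCTCCGTGGACAAAGCCAC"),          # MarCB5F (Y->C,R->G)
      list(at = 672L,  seq = revcomp("GGTTGTTGGAGCCTGTTTCA")), # MarCB3R (K->G,R->A)
      list(at = 1189L, seq = revcomp("TGTTAAATTACTTGGACTCTTCA")) # MarCBR
    ),
    species = list(
      "eastern grey kangaroo" = list(
        id = "syn_kangaroo_mt", offset = 1000L,
        implants = list(
          list(at = 255L, seq = "GCATCCATCTTAATTCTCCTCA"),        # macF
          list(at = 482L, seq = revcomp("GGTTTTAGTATGTAGTTTTCAAA")) # marR (Y->T)
        )),
      "swamp wallaby" = list(
        id = "syn_wallaby_mt", offset = 2500L,
        implants = list(
          list(at = 80L,  seq = "GCCCTACTTTCATTAGCAC"),           # walF
          list(at = 482L, seq = revcomp("GGTTTTAGTATGTAGTTTTCAAA"))
        )),
      "common wombat" = list(
        id = "syn_wombat_mt", offset = 4000L,
        implants = list(
          list(at = 200L, seq = "AGCATTCATCGACCTACCCA"),          # VUCytBF
          list(at = 467L, seq = revcomp("TGTTTCTTTGTAGAGGTAGGAG")) # VUCytBR
        ))
    ))
}

.deer_layout <- function() {
  list(
    locus_len = 1240L, cds = c(30L, 1170L), gene = "cytb",
    clade_implants = list(
      list(at = 0L,    seq = "CGTTGTCATTCAACTACAAGAACA"),        # 5DCytBF
      list(at = 410L,  seq = "TGAGGACAAATATCATTCTGAGGA"),        # 3DCytBF
      list(at = 856L,  seq = revcomp("TTGATCGTAGGATTGCGTATG")),  # 5DCytBR
      list(at = 1171L, seq = revcomp("TTTCTGGTTTACAAGACCAGTGT")) # DCytbR
    ),
    species = list(
      "fallow deer" = list(
        id = "syn_fallow_mt", offset = 3000L,
        implants = list(
          list(at = 100L, seq = "AGCAACCTTAACTCGATTCTTC"),          # DDCytBF
          list(at = 275L, seq = revcomp("AGAGAAATAGGAATAGGATGCC"))  # DDCytBR
        )),
      ## the red deer locus is placed across the sequence origin so the
      ## 482 bp product (and the cytb CDS) wrap the circular genome
      "red deer" = list(
        id = "syn_reddeer_mt", offset = 16400L,
        implants = list(
          list(at = 218L, seq = "CGCAGACAAAATCCCCTTTCA"),          # CECytbF3
          list(at = 680L, seq = revcomp("GTTTTCGATTGTGCTGGTGA"))   # CERUR
        )),
      "sambar deer" = list(
        id = "syn_sambar_mt", offset = 6000L,
        implants = list(
          list(at = 539L, seq = "CCAGTGCCTATTCTGAATCTTAGC"),       # RUCytbF4
          list(at = 680L, seq = revcomp("GTTTTCGATTGTGCTGGTGA"))
        ))
    ))
}

.build_clade <- function(layout) {
  L <- .REF_LEN
  out <- list()
  for (sp in names(layout$species)) {
    info <- layout$species[[sp]]
    genome <- .random_bases(L)
    locus <- .random_bases(layout$locus_len)
    for (im in c(layout$clade_implants, info$implants)) {
      ch <- strsplit(im$seq, "")[[1]]
      locus[(im$at + 1L):(im$at + length(ch))] <- ch
    }
    pos <- ((info$offset + seq_len(layout$locus_len) - 1L) %% L) + 1L
    genome[pos] <- locus
    s <- nuc_sequence(info$id, paste(genome, collapse = ""),
                      topology = "circular", species_label = sp,
                      role = "target")
    ## cytb CDS feature in GenBank 1-based inclusive coordinates,
    ## split as join(...) when it spans the origin
    c0 <- (info$offset + layout$cds[1]) %% L
    c1 <- (info$offset + layout$cds[2] - 1L) %% L   # last base, 0-based
    loc <- if (c0 <= c1) sprintf("%d..%d", c0 + 1L, c1 + 1L)
           else sprintf("join(%d..%d,1..%d)", c0 + 1L, L, c1 + 1L)
    attr(s, "features") <- data.frame(
      type = "CDS", gene = layout$gene, location = loc,
      stringsAsFactors = FALSE)
    out[[sp]] <- s
  }
  out
}

#' Synthetic reference mitochondrial genomes for the six study species
#'
#' Builds, deterministically, six circular synthetic mitochondrial genome
#' stand-ins (three marsupials, three deer) carrying the published primer
#' binding sites at the published spacings, plus two divergent off-target
#' genomes standing in for goat and rabbit, and verifies at construction
#' that each multiplex panel produces exactly its expected bands on its
#' targets and nothing anywhere else under the default [match_policy].
#'
#' The red deer locus spans the sequence origin, so its 482 bp product and
#' its cytb CDS wrap the circular genome.
#'
#' @return list with elements `targets` (named list of six circular
#'   [nuc_sequence] with cytb CDS features), `offtargets` (goat and rabbit
#'   stand-ins) and `clade` (named character vector mapping species to
#'   `"marsupial"` or `"deer"`).
#' @export
synthetic_reference_genomes <- function() {
  if (!is.null(.ref_cache$refs)) return(.ref_cache$refs)
  refs <- with_seed(.REF_SEED, {
    mars <- .build_clade(.marsupial_layout())
    deer <- .build_clade(.deer_layout())
    off <- list(
      goat = nuc_sequence("syn_goat_mt", paste(.random_bases(.REF_LEN),
                                               collapse = ""),
                          topology = "circular", species_label = "goat",
                          role = "offtarget"),
      rabbit = nuc_sequence("syn_rabbit_mt", paste(.random_bases(.REF_LEN),
                                                   collapse = ""),
                            topology = "circular", species_label = "rabbit",
                            role = "offtarget"))
    list(targets = c(mars, deer), offtargets = off,
         clade = c(stats::setNames(rep("marsupial", 3), names(mars)),
                   stats::setNames(rep("deer", 3), names(deer))))
  })
  .verify_references(refs)
  .ref_cache$refs <- refs
  refs
}

## Construction-time check: the intended bands and only the intended bands.
.verify_references <- function(refs) {
  panels <- list(marsupial = mmars_panel(), deer = mdeer_panel())
  for (sp in names(refs$targets)) {
    g <- refs$targets[[sp]]
    for (clade in names(panels)) {
      amps <- run_multiplex(panels[[clade]], g, match_policy())
      if (refs$clade[[sp]] == clade) {
        want <- unname(panel_sizes(panels[[clade]])[sp])
        if (nrow(amps) != 1L || amps$length != want)
          stop("synthetic reference construction failed for ", sp,
               call. = FALSE)
      } else if (nrow(amps) != 0L) {
        stop("synthetic reference construction: cross-clade product on ",
             sp, call. = FALSE)
      }
    }
    for (pair in sequencing_pairs(refs$clade[[sp]])) {
      amps <- predict_amplicons(pair$fwd, pair$rev, g, match_policy(),
                                with_sequence = FALSE)
      if (nrow(amps) != 1L || amps$length != pair$expected_size)
        stop("synthetic reference construction: sequencing pair ",
             pair$fwd$name, " failed on ", sp, call. = FALSE)
    }
  }
  for (g in refs$offtargets) {
    for (p in panels)
      if (nrow(run_multiplex(p, g, match_policy())) != 0L)
        stop("synthetic reference construction: off-target product on ",
             g$id, call. = FALSE)
  }
  invisible(TRUE)
}
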