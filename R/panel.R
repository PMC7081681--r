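#' A multiplex PCR panel
#'
#' One primer pair per species, each with a distinct expected product size,
#' so that species are told apart by band size on a gel. Primers may be
#' shared between members (the shared-reverse-primer strategy); a shared
#' primer is stored once under its name.
#'
#' @param name panel name.
#' @param members list of lists, each with fields `species`, `fwd`
#'   ([primer]), `rev` ([primer]), `expected_size` (bp).
#' @param protocol opaque wet-lab metadata (annealing temperature,
#'   touchdown schedule, ...) carried along untouched.
#' @return object of class `panel_design`.
#' @export
panel_design <- function(name, members, protocol = list()) {
  stopifnot(is.character(name), length(members) >= 1L)
  for (m in members) {
    stopifnot(inherits(m$fwd, "primer"), inherits(m$rev, "primer"),
              is.numeric(m$expected_size), m$expected_size > 0)
  }
  sizes <- vapply(members, function(m) as.integer(m$expected_size), integer(1))
  if (anyDuplicated(sizes))
    stop("expected product sizes must be pairwise distinct", call. = FALSE)
  ## consistency: one sequence per primer name across members
  seqs <- c(lapply(members, function(m) m$fwd), lapply(members, function(m) m$rev))
  nm <- vapply(seqs, `[[`, character(1), "name")
  sq <- vapply(seqs, `[[`, character(1), "seq")
  if (any(tapply(sq, nm, function(x) length(unique(x))) > 1L))
    stop("a primer name is reused with different sequences", call. = FALSE)
  structure(list(name = name, members = members, protocol = protocol),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("<panel_design> %s: %d members, %d distinct oligos\n",
              x$name, length(x$members),
              length(panel_primers(x, "both"))))
  for (m in x$members)
    cat(sprintf("  %-28s %s / %s -> %d bp\n", m$species, m$fwd$name,
                m$rev$name, m$expected_size))
  invisible(x)
}

#' Distinct primers of a panel
#' @param panel a [panel_design].
#' @param which `"fwd"`, `"rev"` or `"both"`.
#' @return named list of [primer]s, one per distinct primer name.
#' @export
panel_primers <- function(panel, which = c("both", "fwd", "rev")) {
  which <- match.arg(which)
  ps <- list()
  if (which %in% c("both", "fwd"))
    ps <- c(ps, lapply(panel$members, function(m) m$fwd))
  if (which %in% c("both", "rev"))
    ps <- c(ps, lapply(panel$members, function(m) m$rev))
  nm <- vapply(ps, `[[`, character(1), "name")
  keep <- !duplicated(nm)
  ps <- ps[keep]
  names(ps) <- nm[keep]
  ps
}

#' Expected band sizes of a panel
#' @param panel a [panel_design].
#' @return named integer vector (names are species).
#' @export
panel_sizes <- function(panel) {
  sizes <- vapply(panel$members, function(m) as.integer(m$expected_size),
                  integer(1))
  names(sizes) <- vapply(panel$members, `[[`, character(1), "species")
  sizes
}

#' Read / write a panel as JSON
#'
#' Schema: `{name, members: [{species, fwd: {name, seq}, rev: {name, seq},
#' expected_size}], protocol: {...}}`.
#'
#' @param path JSON file.
#' @return [read_panel]: a [panel_design]; [write_panel]: `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  members <- lapply(x$members, function(m)
    list(species = m$species,
         fwd = primer(m$fwd$name, m$fwd$seq),
         rev = primer(m$rev$name, m$rev$seq),
         expected_size = as.integer(m$expected_size)))
  panel_design(x$name, members,
               protocol = if (is.null(x$protocol)) list() else x$protocol)
}

#' @param panel a [panel_design].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  x <- list(
    name = panel$name,
    members = lapply(panel$members, function(m)
      list(species = m$species,
           fwd = list(name = m$fwd$name, seq = m$fwd$seq),
           rev = list(name = m$rev$name, seq = m$rev$seq),
           expected_size = m$expected_size)),
    protocol = panel$protocol)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The published marsupial (Mmars) and deer (Mdeer) multiplex panels
#'
#' The two published cytb multiplex assays: Mmars differentiates eastern
#' grey kangaroo (250 bp), swamp wallaby (425 bp) and common wombat
#' (289 bp) with a reverse primer (marR) shared by kangaroo and wallaby;
#' Mdeer differentiates fallow deer (197 bp), red deer (482 bp) and sambar
#' deer (161 bp) with a reverse primer (CERUR) shared by red and sambar
#' deer.
#'
#' @return a [panel_design].
#' @export
mmars_panel <- function() {
  marR <- primer("marR", "GGTTYTAGTATGTAGTTTTCAAA")
  panel_design("Mmars", list(
    list(species = "eastern grey kangaroo",
         fwd = primer("macF", "GCATCCATCTTAATTCTCCTCA"),
         rev = marR, expected_size = 250L),
    list(species = "swamp wallaby",
         fwd = primer("walF", "GCCCTACTTTCATTAGCAC"),
         rev = marR, expected_size = 425L),
    list(species = "common wombat",
         fwd = primer("VUCytBF", "AGCATTCATCGACCTACCCA"),
         rev = primer("VUCytBR", "TGTTTCTTTGTAGAGGTAGGAG"),
         expected_size = 289L)),
    protocol = list(annealing_c = 59, cycles = 35))
}

#' @rdname mmars_panel
#' @export
mdeer_panel <- function() {
  cerur <- primer("CERUR", "GTTTTCGATTGTGCTGGTGA")
  panel_design("Mdeer", list(
    list(species = "fallow deer",
         fwd = primer("DDCytBF", "AGCAACCTTAACTCGATTCTTC"),
         rev = primer("DDCytBR", "AGAGAAATAGGAATAGGATGCC"),
         expected_size = 197L),
    list(species = "red deer",
         fwd = primer("CECytbF3", "CGCAGACAAAATCCCCTTTCA"),
         rev = cerur, expected_size = 482L),
    list(species = "sambar deer",
         fwd = primer("RUCytbF4", "CCAGTGCCTATTCTGAATCTTAGC"),
         rev = cerur, expected_size = 161L)),
    protocol = list(touchdown = "65->60C step -1C/cycle x5, then 30 cycles at 60C"))
}

#' Published cytb sequencing primer pairs
#'
#' Two overlapping pairs per clade used to amplify and Sanger-sequence the
#' full cytb gene: marsupial pairs MarCBF/MarCB3R (692 bp) and
#' MarCB5F/MarCBR (662 bp); deer pairs 5DCytBF/5DCytBR (877 bp) and
#' 3DCytBF/DCytbR (784 bp).
#'
#' @param clade `"marsupial"` or `"deer"`.
#' @return list of pairs, each `list(fwd, rev, expected_size)`.
#' @export
sequencing_pairs <- function(clade = c("marsupial", "deer")) {
  clade <- match.arg(clade)
  if (clade == "marsupial") {
    list(
      list(fwd = primer("MarCBF", "TTTTAGYATGGACTCTAACC"),
           rev = primer("MarCB3R", "GGTTGTTKGAGCCTGTTTCR"),
           expected_size = 692L),
      list(fwd = primer("MarCB5F", "TTYTCCGTRGACAAAGCCAC"),
           rev = primer("MarCBR", "TGTTAAATTACTTGGACTCTTCA"),
           expected_size = 662L))
  } else {
    list(
      list(fwd = primer("5DCytBF", "CGTTGTCATTCAACTACAAGAACA"),
           rev = primer("5DCytBR", "TTGATCGTAGGATTGCGTATG"),
           expected_size = 877L),
      list(fwd = primer("3DCytBF", "TGAGGACAAATATCATTCTGAGGA"),
           rev = primer("DCytbR", "TTTCTGGTTTACAAGACCAGTGT"),
           expected_size = 784L))
  }
}
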