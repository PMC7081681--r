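#' A nucleotide sequence with topology and species metadata
#'
#' Thin S3 wrapper used throughout the package: an upper-case IUPAC residue
#' string plus the metadata the virtual PCR engine and the panel validator
#' need (circular vs linear topology, species label, target/off-target role).
#' `U` is normalised to `T` on construction; gap characters are not allowed
#' (they live only inside [alignment] rows).
#'
#' @param id sequence identifier.
#' @param residues IUPAC string (non-empty).
#' @param topology `"linear"` or `"circular"`; circular is meant for
#'   genome-scale records such as mitochondrial genomes.
#' @param species_label optional species name.
#' @param role one of `"target"`, `"offtarget"`, `"unknown"`.
#' @return object of class `nuc_sequence`.
#' @export
nuc_sequence <- function(id, residues, topology = c("linear", "circular"),
                         species_label = NA_character_,
                         role = c("unknown", "target", "offtarget")) {
  topology <- match.arg(topology)
  role <- match.arg(role)
  ch <- iupac_chars(residues)
  if (length(ch) == 0L) stop("empty sequence for id '", id, "'", call. = FALSE)
  structure(
    list(id = as.character(id), residues = paste(ch, collapse = ""),
         topology = topology, species_label = as.character(species_label),
         role = role),
    class = "nuc_sequence"
  )
}

#' @export
print.nuc_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1, min(n, 40))
  cat(sprintf("<nuc_sequence> %s (%s, %d bp%s)\n  %s%s\n",
              x$id, x$topology, n,
              if (is.na(x$species_label)) "" else paste0(", ", x$species_label),
              head, if (n > 40) "..." else ""))
  invisible(x)
}

#' @export
length.nuc_sequence <- function(x) nchar(x$residues)

#' A species-labelled multiple sequence alignment
#'
#' Rows are gapped IUPAC strings of equal width; ungapping any row yields a
#' valid [nuc_sequence].
#'
#' @param species character vector of per-row species labels.
#' @param rows character vector of gapped sequences, one per species entry.
#' @param ids optional row identifiers (default `species` with suffixes).
#' @return object of class `alignment` with fields `species`, `ids`, `rows`
#'   (upper case), `width`.
#' @export
alignment <- function(species, rows, ids = NULL) {
  stopifnot(length(species) == length(rows), length(rows) >= 1L)
  rows <- vapply(rows, function(r)
    paste(iupac_chars(r, allow_gap = TRUE), collapse = ""), character(1))
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("ragged alignment: row widths ", paste(sort(w), collapse = ", "),
         call. = FALSE)
  if (is.null(ids)) ids <- make.unique(as.character(species), sep = "_")
  structure(
    list(species = as.character(species), ids = as.character(ids),
         rows = unname(rows), width = w),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns; species: %s\n",
              length(x$rows), x$width,
              paste(unique(x$species), collapse = ", ")))
  invisible(x)
}

#' Drop gaps from an alignment row and return it as a sequence
#' @param a an [alignment]; @param i row index.
#' @return a [nuc_sequence] (linear).
#' @export
ungap_row <- function(a, i) {
  stopifnot(inherits(a, "alignment"))
  nuc_sequence(a$ids[i], gsub("-", "", a$rows[i], fixed = TRUE),
               species_label = a$species[i])
}

#' Read reference sequences or an alignment
#'
#' FASTA and aligned FASTA are read with Biostrings; GenBank flat files with
#' the bundled minimal parser (see [read_genbank]), which preserves the
#' LOCUS circular/linear flag and CDS features so genes such as cytb can be
#' extracted by name.
#'
#' @param path input file.
#' @param format `"fasta"`, `"genbank"` or `"aligned-fasta"`.
#' @return a list of [nuc_sequence] for `"fasta"`/`"genbank"` (GenBank
#'   records additionally carry a `features` attribute; see
#'   [extract_gene]), or an [alignment] for `"aligned-fasta"` (species
#'   labels are taken from the FASTA description after the first word, else
#'   the id).
#' @export
read_sequences <- function(path, format = c("fasta", "genbank",
                                            "aligned-fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "genbank") return(read_genbank(path))
  set <- Biostrings::readBStringSet(path)
  nm <- names(set)
  id <- vapply(strsplit(nm, "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", nm)
  if (format == "fasta") {
    seqs <- lapply(seq_along(set), function(i)
      nuc_sequence(id[i], as.character(set[[i]]),
                   species_label = if (nzchar(desc[i])) desc[i]
                                   else NA_character_))
    names(seqs) <- id
    return(seqs)
  }
  ## aligned-fasta
  species <- ifelse(nzchar(desc), desc, id)
  alignment(species, as.character(set), ids = id)
}

#' Write sequences to FASTA
#'
#' @param seqs a list of [nuc_sequence] (or a single one).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "nuc_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
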