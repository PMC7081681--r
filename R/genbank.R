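## Minimal GenBank flat-file support.
##
## Covers what mitochondrial reference records need: the LOCUS
## circular/linear flag, CDS (and gene) features with /gene qualifiers, and
## simple locations -- "a..b", "complement(a..b)" and "join(a..b,c..d)"
## (join is how a CDS that spans the origin of a circular genome is
## written). Coordinates in the file are 1-based inclusive, as in GenBank.

parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  comp <- FALSE
  if (grepl("^complement\\(", loc)) {
    comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  if (any(vapply(m, length, integer(1)) != 3L))
    stop("unsupported GenBank location: ", loc, call. = FALSE)
  spans <- do.call(rbind, lapply(m, function(x)
    c(start = as.integer(x[2]), end = as.integer(x[3]))))
  list(spans = spans, complement = comp)
}

#' Read a GenBank flat file
#'
#' @param path GenBank flat file (possibly multi-record).
#' @return list of [nuc_sequence]; each element carries a `features`
#'   attribute: a data.frame with columns `type`, `gene`, `location`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS line in ", path, call. = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts))
    stop("unterminated GenBank record in ", path, call. = FALSE)
  recs <- lapply(seq_along(starts), function(k)
    parse_gb_record(lines[starts[k]:ends[k]]))
  names(recs) <- vapply(recs, `[[`, character(1), "id")
  recs
}

parse_gb_record <- function(lines) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  id <- locus[2]
  topology <- if ("circular" %in% locus) "circular" else "linear"
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  species <- if (length(org)) trimws(sub("^\\s+ORGANISM\\s+", "", org[1]))
             else NA_character_

  ## features: key lines have the key at column 6, qualifiers at column 22
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  feats <- data.frame(type = character(), gene = character(),
                      location = character(), stringsAsFactors = FALSE)
  if (length(fstart) && length(ostart) && ostart[1] > fstart[1] + 1L) {
    block <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    keyline <- grepl("^ {5}\\S", block)
    idx <- which(keyline)
    for (j in seq_along(idx)) {
      span <- idx[j]:(if (j < length(idx)) idx[j + 1L] - 1L else length(block))
      body <- block[span]
      key <- sub("^ {5}(\\S+).*", "\\1", body[1])
      loc <- trimws(sub("^ {5}\\S+\\s*", "", body[1]))
      ## location may continue on unqualified lines
      more <- body[-1]
      cont <- !grepl("^\\s+/", more)
      if (any(cont)) loc <- paste0(loc, paste(trimws(more[cont]), collapse = ""))
      quals <- trimws(more[grepl("^\\s+/", more)])
      gene <- sub('^/gene="?([^"]*)"?$', "\\1",
                  grep("^/gene=", quals, value = TRUE))
      feats <- rbind(feats, data.frame(
        type = key, gene = if (length(gene)) gene[1] else NA_character_,
        location = loc, stringsAsFactors = FALSE))
    }
  }

  if (!length(ostart)) stop("record ", id, " has no ORIGIN section",
                            call. = FALSE)
  seqlines <- lines[(ostart[1] + 1L):(length(lines) - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  s <- nuc_sequence(id, residues, topology = topology,
                    species_label = species)
  attr(s, "features") <- feats
  s
}

#' Extract an annotated gene from a GenBank record
#'
#' Looks for a CDS (or gene) feature whose `/gene` qualifier matches
#' `gene` case-insensitively and returns the spliced subsequence;
#' `join(...)` locations (e.g. a CDS spanning the origin of a circular
#' genome) are concatenated in order, `complement(...)` is
#' reverse-complemented.
#'
#' @param record a [nuc_sequence] read by [read_genbank].
#' @param gene gene name, e.g. `"cytb"`.
#' @return a linear [nuc_sequence] named `<record id>:<gene>`.
#' @export
extract_gene <- function(record, gene) {
  feats <- attr(record, "features")
  if (is.null(feats))
    stop("record '", record$id, "' carries no feature table", call. = FALSE)
  hit <- which(tolower(feats$gene) == tolower(gene) &
                 feats$type %in% c("CDS", "gene"))
  if (!length(hit))
    stop(sprintf("record '%s' has no annotated gene '%s'", record$id, gene),
         call. = FALSE)
  ## prefer the CDS if both a gene and a CDS feature are present
  hit <- hit[order(feats$type[hit] != "CDS")][1]
  loc <- parse_gb_location(feats$location[hit])
  parts <- apply(loc$spans, 1, function(sp)
    substr(record$residues, sp["start"], sp["end"]))
  seq <- paste(parts, collapse = "")
  if (loc$complement) seq <- revcomp(seq)
  nuc_sequence(paste0(record$id, ":", gene), seq,
               species_label = record$species_label)
}

#' Write records as a GenBank flat file
#'
#' Emits the subset of the format [read_genbank] understands; used for
#' bundled synthetic reference records and round-trip tests.
#'
#' @param records list of [nuc_sequence], each optionally with a `features`
#'   attribute as produced by [read_genbank].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "nuc_sequence")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    n <- nchar(r$residues)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s     UNA",
                       r$id, n, r$topology), con)
    writeLines(sprintf("DEFINITION  %s synthetic record.", r$id), con)
    if (!is.na(r$species_label)) {
      writeLines("SOURCE      synthetic", con)
      writeLines(sprintf("  ORGANISM  %s", r$species_label), con)
    }
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    feats <- attr(r, "features")
    if (!is.null(feats)) {
      for (i in seq_len(nrow(feats))) {
        if (feats$type[i] == "source") next
        writeLines(sprintf("     %-16s%s", feats$type[i], feats$location[i]),
                   con)
        if (!is.na(feats$gene[i]))
          writeLines(sprintf('                     /gene="%s"', feats$gene[i]),
                     con)
      }
    }
    writeLines("ORIGIN", con)
    for (off in seq(1L, n, by = 60L)) {
      chunk <- substr(r$residues, off, min(off + 59L, n))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", off, tolower(paste(tens, collapse = " "))),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
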