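#' Virtual agarose-gel resolution model
#'
#' How far apart two fragment sizes must be before they can be told apart
#' on a gel. The default tolerance, +/- max(5 bp, 5% of size), represents
#' a 1.5% agarose gel read against a 100-bp ladder and keeps the published
#' panels' closest bands (36 bp apart at ~200 bp) distinguishable.
#'
#' @param tolerance function of fragment size (bp) returning the +/- bp
#'   tolerance; must be non-negative and non-decreasing.
#' @return object of class `gel_model`.
#' @export
gel_model <- function(tolerance = function(size) pmax(5, 0.05 * size)) {
  stopifnot(is.function(tolerance))
  structure(list(tolerance = tolerance), class = "gel_model")
}

#' Are two band sizes distinguishable on a gel?
#'
#' True iff the size difference exceeds the gel tolerance at the larger of
#' the two sizes; equality with the tolerance counts as not
#' distinguishable (conservative). Symmetric.
#'
#' @param a,b band sizes (bp, positive).
#' @param gel a [gel_model].
#' @return logical.
#' @export
distinguishable <- function(a, b, gel = gel_model()) {
  stopifnot(all(a > 0), all(b > 0))
  abs(a - b) > gel$tolerance(pmax(a, b))
}

#' Interpret observed gel bands as a species call
#'
#' Each observed band is assigned to the unique panel expected size within
#' gel tolerance. Exactly one assigned band gives a species call; no bands
#' give `no_amplification`; several distinct species, or any band that
#' matches no expected size (or more than one), give `ambiguous` /
#' `uninterpretable` with diagnostics. Panels whose expected sizes are not
#' pairwise distinguishable under the gel are rejected up front as a
#' configuration error. The call is independent of band order.
#'
#' @param bands numeric vector of observed band sizes (bp); may be empty.
#' @param panel a [panel_design].
#' @param gel a [gel_model].
#' @return object of class `species_call`: `status` (one of `"species"`,
#'   `"ambiguous"`, `"no_amplification"`, `"uninterpretable"`), `species`
#'   (character vector; length 1 iff status is `"species"`), `bands`, and
#'   `detail`.
#' @export
bands_to_call <- function(bands, panel, gel = gel_model()) {
  sizes <- panel_sizes(panel)
  cmb <- utils::combn(length(sizes), 2, simplify = FALSE)
  for (ij in cmb) {
    if (!distinguishable(sizes[ij[1]], sizes[ij[2]], gel))
      stop(sprintf(
        "panel '%s' sizes %d and %d bp are not gel-distinguishable",
        panel$name, sizes[ij[1]], sizes[ij[2]]), call. = FALSE)
  }
  bands <- sort(as.numeric(bands))
  if (length(bands) == 0L)
    return(.species_call("no_amplification", character(0), bands, ""))
  hit_species <- character(0)
  for (b in bands) {
    within <- which(abs(b - sizes) <= gel$tolerance(pmax(b, sizes)))
    if (length(within) != 1L)
      return(.species_call("uninterpretable", character(0), bands,
                           sprintf("band %g bp matches %d expected sizes",
                                   b, length(within))))
    hit_species <- c(hit_species, names(sizes)[within])
  }
  hit_species <- unique(hit_species)
  if (length(hit_species) == 1L)
    return(.species_call("species", hit_species, bands, ""))
  .species_call("ambiguous", sort(hit_species), bands,
                sprintf("%d distinct species bands", length(hit_species)))
}

.species_call <- function(status, species, bands, detail) {
  structure(list(status = status, species = species, bands = bands,
                 detail = detail),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  lab <- switch(x$status,
    species = x$species,
    ambiguous = paste0("ambiguous {", paste(x$species, collapse = ", "), "}"),
    no_amplification = "no amplification",
    uninterpretable = paste0("uninterpretable (", x$detail, ")"))
  cat(sprintf("<species_call> %s  [bands: %s]\n", lab,
              if (length(x$bands)) paste(x$bands, collapse = ", ") else "-"))
  invisible(x)
}

#' Genotype survey samples with a panel and call species
#'
#' Runs the full multiplex against each sample template, converts the
#' predicted band sizes to a species call, and returns one record per
#' sample.
#'
#' @param templates named list of [nuc_sequence] (names are sample ids).
#' @param morphological_labels character vector, parallel to `templates`.
#' @param panel a [panel_design].
#' @param policy a [match_policy].
#' @param gel a [gel_model].
#' @return data.frame of class `sample_records`: `sample_id`,
#'   `morphological_label`, `call_status`, `call_species` (NA unless the
#'   status is `"species"`), `bands`, `panel`.
#' @export
classify_samples <- function(templates, morphological_labels, panel,
                             policy = match_policy(), gel = gel_model()) {
  stopifnot(length(templates) == length(morphological_labels))
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("sample", seq_along(templates))
  rows <- lapply(seq_along(templates), function(i) {
    amps <- run_multiplex(panel, templates[[i]], policy)
    call <- bands_to_call(amps$length, panel, gel)
    data.frame(sample_id = ids[i],
               morphological_label = morphological_labels[i],
               call_status = call$status,
               call_species = if (call$status == "species") call$species
                              else NA_character_,
               bands = paste(call$bands, collapse = ","),
               panel = panel$name, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sample_records", class(out))
  out
}

#' Reconcile morphological labels with molecular calls
#'
#' Builds the morphology-by-molecular-outcome confusion table with
#' marginal totals, plus the mismatch count: records whose morphological
#' label names a species different from the molecular species call.
#' "Unknown" labels (any label starting with `"unknown"`) never count as
#' mismatches -- they are resolved by the molecular call, not contradicted
#' by it. Rows and columns are ordered alphabetically (outcome columns
#' after species columns) so the summary is deterministic.
#'
#' @param records a data.frame with columns `sample_id`,
#'   `morphological_label`, `call_status`, `call_species` (as produced by
#'   [classify_samples]).
#' @return object of class `survey_summary`: `confusion` (matrix with
#'   marginals), `mismatch_count`, `n`.
#' @export
summarize_survey <- function(records) {
  needed <- c("sample_id", "morphological_label", "call_status",
              "call_species")
  stopifnot(all(needed %in% names(records)))
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(records$sample_id[duplicated(records$sample_id)]),
               collapse = ", "), call. = FALSE)
  outcome <- ifelse(records$call_status == "species",
                    records$call_species,
                    paste0("<", records$call_status, ">"))
  lab <- records$morphological_label
  conf <- table(morphology = lab, molecular = outcome)
  conf <- conf[order(rownames(conf)), order(colnames(conf)), drop = FALSE]
  conf <- stats::addmargins(conf)
  is_unknown <- grepl("^unknown", lab, ignore.case = TRUE)
  mismatch <- sum(!is_unknown &
                    records$call_status == "species" &
                    records$call_species != lab)
  structure(list(confusion = conf, mismatch_count = mismatch,
                 n = nrow(records)),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("<survey_summary> %d samples, %d morphology/molecular mismatch(es)\n",
              x$n, x$mismatch_count))
  print(x$confusion)
  invisible(x)
}

#' Reconcile calls from the marsupial and deer panels for one sample
#'
#' Samples are normally tested with the panel matching their morphological
#' class; when both panels have been run, a sample amplifying in both is
#' flagged uninterpretable, and otherwise the call of the amplifying panel
#' is returned (no amplification in either panel stays
#' `no_amplification`).
#'
#' @param call_a,call_b [bands_to_call] results from the two panels.
#' @return a `species_call`.
#' @export
reconcile_panels <- function(call_a, call_b) {
  stopifnot(inherits(call_a, "species_call"), inherits(call_b, "species_call"))
  a_amp <- call_a$status != "no_amplification"
  b_amp <- call_b$status != "no_amplification"
  if (a_amp && b_amp)
    return(.species_call("uninterpretable", character(0),
                         c(call_a$bands, call_b$bands),
                         "products in both panels"))
  if (a_amp) call_a else call_b
}
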