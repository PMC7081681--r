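#' Parameters for the synthetic species-genome generator
#'
#' The generator emulates the premise the assay design rests on: species
#' whose genomes are highly similar within species and clearly divergent
#' between species, with diagnostic cassettes -- variable cores flanked by
#' cross-species conserved blocks -- embedded in them. Divergence is the
#' target mean pairwise between-species substitution fraction (each
#' species branch is mutated at half that rate from a common ancestor, so
#' pairwise differences come out at approximately the requested value).
#'
#' @param n_species number of species.
#' @param genome_length genome length (bp).
#' @param topology `"linear"` or `"circular"`.
#' @param between_species_divergence target mean pairwise substitution
#'   fraction between species, in (0, 1).
#' @param within_species_identity identity of individuals to their species
#'   consensus; must exceed `1 - between_species_divergence`.
#' @param n_individuals individuals drawn per species.
#' @param cassettes list of `c(flank, core)` lengths (bp) for implanted
#'   diagnostic cassettes (conserved flank, variable core, conserved
#'   flank).
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return object of class `generator_params`.
#' @export
generator_params <- function(n_species = 3L, genome_length = 16000L,
                             topology = c("circular", "linear"),
                             between_species_divergence = 0.10,
                             within_species_identity = 0.999,
                             n_individuals = 3L,
                             cassettes = list(c(60L, 40L), c(60L, 40L)),
                             seed) {
  topology <- match.arg(topology)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_species >= 2L, genome_length > 0L,
            between_species_divergence > 0,
            between_species_divergence < 1,
            within_species_identity > 1 - between_species_divergence,
            within_species_identity <= 1, n_individuals >= 1L)
  needed <- sum(vapply(cassettes, function(cs) 2L * cs[1] + cs[2],
                       integer(1))) * 2L
  if (needed > genome_length)
    stop("cassettes do not fit in the genome", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 genome_length = as.integer(genome_length),
                 topology = topology,
                 between_species_divergence = between_species_divergence,
                 within_species_identity = within_species_identity,
                 n_individuals = as.integer(n_individuals),
                 cassettes = cassettes, seed = as.integer(seed)),
            class = "generator_params")
}

.mutate <- function(chars, rate, protect = integer(0)) {
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

#' Simulate species-structured genomes with diagnostic cassettes
#'
#' A random ancestor genome is mutated independently per species at half
#' the requested between-species divergence, except inside the implanted
#' cassettes: cassette flanks are kept identical across species, and each
#' cassette core column is forced to differ across species (distinct bases
#' per species where the alphabet allows). Individuals are then drawn per
#' species by mutating the species consensus at `1 -
#' within_species_identity` outside the cassettes -- within the diagnostic
#' regions themselves there is variation among, but not within, species,
#' which is the premise that makes the markers diagnostic. Byte-identical
#' output for identical parameters and seed.
#'
#' @param p a [generator_params].
#' @return list with `consensus` (named list of per-species
#'   [nuc_sequence]), `individuals` (named list of lists of
#'   [nuc_sequence]), `truth` (data.frame of cassette coordinates:
#'   `cassette`, `flank_left_start`, ..., 0-based half-open on the shared
#'   coordinate system), `params`.
#' @export
simulate_species_genomes <- function(p) {
  stopifnot(inherits(p, "generator_params"))
  with_seed(p$seed, {
    L <- p$genome_length
    ancestor <- .random_bases(L)
    ## deterministic, evenly spaced cassette placement
    spans <- lapply(p$cassettes, function(cs) cs)
    widths <- vapply(spans, function(cs) 2L * cs[1] + cs[2], integer(1))
    gap <- (L - sum(widths)) %/% (length(spans) + 1L)
    truth <- NULL
    at <- gap
    for (k in seq_along(spans)) {
      fl <- spans[[k]][1]; co <- spans[[k]][2]
      truth <- rbind(truth, data.frame(
        cassette = k,
        flank_left_start = at, flank_left_end = at + fl,
        core_start = at + fl, core_end = at + fl + co,
        flank_right_start = at + fl + co, flank_right_end = at + widths[k]))
      at <- at + widths[k] + gap
    }
    protect <- unlist(lapply(seq_len(nrow(truth)), function(k)
      (truth$flank_left_start[k] + 1L):truth$flank_right_end[k]))
    core_cols <- unlist(lapply(seq_len(nrow(truth)), function(k)
      (truth$core_start[k] + 1L):truth$core_end[k]))

    ## forced-discriminating cores: distinct base per species per column
    ## (cycled when n_species > 4)
    core_bases <- matrix("", p$n_species, length(core_cols))
    for (j in seq_along(core_cols)) {
      perm <- sample(c("A", "C", "G", "T"))
      core_bases[, j] <- perm[((seq_len(p$n_species) - 1L) %% 4L) + 1L]
    }

    species <- sprintf("species_%02d", seq_len(p$n_species))
    branch_rate <- p$between_species_divergence / 2
    consensus <- list()
    for (si in seq_along(species)) {
      g <- .mutate(ancestor, branch_rate, protect = protect)
      g[core_cols] <- core_bases[si, ]
      consensus[[species[si]]] <- nuc_sequence(
        paste0(species[si], "_consensus"), paste(g, collapse = ""),
        topology = p$topology, species_label = species[si], role = "target")
    }
    indiv_rate <- 1 - p$within_species_identity
    individuals <- lapply(species, function(sp) {
      base <- strsplit(consensus[[sp]]$residues, "")[[1]]
      lapply(seq_len(p$n_individuals), function(k) {
        g <- .mutate(base, indiv_rate, protect = protect)
        nuc_sequence(sprintf("%s_ind%02d", sp, k), paste(g, collapse = ""),
                     topology = p$topology, species_label = sp,
                     role = "target")
      })
    })
    names(individuals) <- species
    list(consensus = consensus, individuals = individuals, truth = truth,
         params = p)
  })
}

#' Build a species-labelled alignment from simulated genomes
#'
#' The substitution-only generator keeps all genomes the same length, so
#' rows align column-for-column without gaps.
#'
#' @param sim result of [simulate_species_genomes].
#' @param use_individuals include the per-species individuals as rows
#'   (default) in addition to nothing else; otherwise one consensus row
#'   per species.
#' @return an [alignment].
#' @export
sim_alignment <- function(sim, use_individuals = TRUE) {
  seqs <- if (use_individuals) unlist(sim$individuals, recursive = FALSE)
          else sim$consensus
  alignment(vapply(seqs, `[[`, character(1), "species_label"),
            vapply(seqs, `[[`, character(1), "residues"),
            ids = vapply(seqs, `[[`, character(1), "id"))
}

#' Parameters for a synthetic faecal-sample survey
#'
#' @param n_samples number of samples.
#' @param proportions named numeric vector of species proportions (must
#'   sum to 1; names must be species present in the genome set).
#' @param morphology_error_rate probability that a labelled sample carries
#'   the wrong species label (drawn among the other surveyed species).
#' @param unknown_fraction probability that a sample is labelled with the
#'   unknown-class label instead of a species.
#' @param unknown_label the unknown-class label.
#' @param seed mandatory integer seed.
#' @return object of class `survey_params`.
#' @export
survey_params <- function(n_samples, proportions,
                          morphology_error_rate = 0.05,
                          unknown_fraction = 0.1,
                          unknown_label = "unknown", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_samples >= 1L, abs(sum(proportions) - 1) < 1e-8,
            !is.null(names(proportions)),
            morphology_error_rate >= 0, morphology_error_rate <= 1,
            unknown_fraction >= 0, unknown_fraction <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 proportions = proportions,
                 morphology_error_rate = morphology_error_rate,
                 unknown_fraction = unknown_fraction,
                 unknown_label = unknown_label, seed = as.integer(seed)),
            class = "survey_params")
}

#' Simulate a faecal-sample survey over simulated genomes
#'
#' Draws `n_samples` templates from the per-species individuals of a
#' genome set; each sample's morphological label equals its true species
#' except that, independently, it is replaced by the unknown-class label
#' with probability `unknown_fraction`, or by a wrong species (uniform
#' among the other surveyed species) with probability
#' `morphology_error_rate`. The truth (including exactly which samples
#' were mislabelled) is retained for scoring.
#'
#' @param genomes result of [simulate_species_genomes] (or any list with
#'   an `individuals` element of the same shape).
#' @param p a [survey_params]; names of `p$proportions` must be species in
#'   `genomes`.
#' @return list with `templates` (named list of [nuc_sequence]),
#'   `records` (data.frame: `sample_id`, `true_species`,
#'   `morphological_label`, `mislabelled`), `n_mislabelled` (injected
#'   morphology errors among non-unknown labels), `params`.
#' @export
simulate_survey <- function(genomes, p) {
  stopifnot(inherits(p, "survey_params"))
  species <- names(p$proportions)
  if (!all(species %in% names(genomes$individuals)))
    stop("survey species must be a subset of the genome set", call. = FALSE)
  with_seed(p$seed, {
    truth <- sample(species, p$n_samples, replace = TRUE,
                    prob = p$proportions)
    u <- stats::runif(p$n_samples)
    v <- stats::runif(p$n_samples)
    label <- truth
    unknown <- u < p$unknown_fraction
    mis <- !unknown & v < p$morphology_error_rate & length(species) > 1L
    label[unknown] <- p$unknown_label
    for (i in which(mis)) label[i] <- sample(setdiff(species, truth[i]), 1L)
    templates <- lapply(seq_len(p$n_samples), function(i) {
      pool <- genomes$individuals[[truth[i]]]
      pool[[sample.int(length(pool), 1L)]]
    })
    ids <- sprintf("s%04d", seq_len(p$n_samples))
    names(templates) <- ids
    list(templates = templates,
         records = data.frame(sample_id = ids, true_species = truth,
                              morphological_label = label,
                              mislabelled = mis, stringsAsFactors = FALSE),
         n_mislabelled = sum(mis), params = p)
  })
}
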