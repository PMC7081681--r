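test_that("the generator is byte-identical for identical seeds", {
  p <- generator_params(n_species = 3, genome_length = 4000, seed = 7)
  a <- simulate_species_genomes(p)
  b <- simulate_species_genomes(p)
  expect_identical(lapply(a$consensus, `[[`, "residues"),
                   lapply(b$consensus, `[[`, "residues"))
  expect_identical(
    lapply(unlist(a$individuals, recursive = FALSE), `[[`, "residues"),
    lapply(unlist(b$individuals, recursive = FALSE), `[[`, "residues"))
  c <- simulate_species_genomes(generator_params(n_species = 3,
                                                 genome_length = 4000,
                                                 seed = 8))
  expect_false(identical(a$consensus$species_01$residues,
                         c$consensus$species_01$residues))
})

test_that("realised between-species divergence tracks the request", {
  p <- generator_params(n_species = 3, genome_length = 16000,
                        between_species_divergence = 0.10, seed = 9)
  sim <- simulate_species_genomes(p)
  chars <- lapply(sim$consensus, function(s) strsplit(s$residues, "")[[1]])
  combs <- utils::combn(length(chars), 2)
  d <- mean(apply(combs, 2, function(ij)
    mean(chars[[ij[1]]] != chars[[ij[2]]])))
  expect_lt(abs(d - 0.10) / 0.10, 0.20)
})

test_that("cassette flanks are identical across species, cores disjoint", {
  p <- generator_params(n_species = 3, genome_length = 5000,
                        cassettes = list(c(50L, 30L)), seed = 10)
  sim <- simulate_species_genomes(p)
  tr <- sim$truth
  chars <- lapply(sim$consensus, function(s) strsplit(s$residues, "")[[1]])
  flank_idx <- c((tr$flank_left_start[1] + 1):tr$flank_left_end[1],
                 (tr$flank_right_start[1] + 1):tr$flank_right_end[1])
  expect_identical(chars[[1]][flank_idx], chars[[2]][flank_idx])
  expect_identical(chars[[1]][flank_idx], chars[[3]][flank_idx])
  core_idx <- (tr$core_start[1] + 1):tr$core_end[1]
  expect_true(all(chars[[1]][core_idx] != chars[[2]][core_idx]))
  expect_true(all(chars[[2]][core_idx] != chars[[3]][core_idx]))
})

test_that("parameter validation catches contradictions", {
  expect_error(generator_params(seed = 1, genome_length = 100,
                                cassettes = list(c(60L, 40L))),
               "do not fit")
  expect_error(generator_params(n_species = 3), "seed is mandatory")
  expect_error(generator_params(seed = 1, between_species_divergence = 0.2,
                                within_species_identity = 0.7))
})

test_that("surveys have exact sample counts and honest labels at rate zero", {
  p <- generator_params(n_species = 3, genome_length = 2000, seed = 11)
  sim <- simulate_species_genomes(p)
  sp0 <- survey_params(n_samples = 200,
                       proportions = c(species_01 = 0.5, species_02 = 0.3,
                                       species_03 = 0.2),
                       morphology_error_rate = 0, unknown_fraction = 0.1,
                       seed = 12)
  sv <- simulate_survey(sim, sp0)
  expect_identical(nrow(sv$records), 200L)
  expect_identical(sv$n_mislabelled, 0L)
  lab <- sv$records$morphological_label
  known <- lab != "unknown"
  expect_identical(lab[known], sv$records$true_species[known])
})

test_that("the realised mislabel rate sits inside its binomial interval", {
  p <- generator_params(n_species = 3, genome_length = 2000,
                        n_individuals = 2, seed = 13)
  sim <- simulate_species_genomes(p)
  sp <- survey_params(n_samples = 2000,
                      proportions = c(species_01 = 0.4, species_02 = 0.4,
                                      species_03 = 0.2),
                      morphology_error_rate = 0.05, unknown_fraction = 0.1,
                      seed = 14)
  sv <- simulate_survey(sim, sp)
  known <- sv$records$morphological_label != "unknown"
  rate <- sum(sv$records$mislabelled) / sum(known)
  ci <- stats::binom.test(sum(sv$records$mislabelled), sum(known),
                          p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("survey species must exist in the genome set", {
  p <- generator_params(n_species = 2, genome_length = 1000, seed = 15)
  sim <- simulate_species_genomes(p)
  sp <- survey_params(n_samples = 10, proportions = c(ghost = 1), seed = 16)
  expect_error(simulate_survey(sim, sp), "subset of the genome set")
})
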