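test_that("gel distinguishability follows the tolerance model", {
  expect_true(distinguishable(250, 425))     # 175 > 21.25
  expect_false(distinguishable(250, 250))
  expect_false(distinguishable(200, 209))    # 9 <= 10.45
  expect_identical(distinguishable(100, 105), distinguishable(105, 100))
  ## boundary: difference equal to the tolerance is not distinguishable
  gel10 <- gel_model(function(size) rep(10, length(size)))
  expect_false(distinguishable(100, 110, gel10))
  expect_true(distinguishable(100, 111, gel10))
})

test_that("bands map to species calls by size", {
  mmars <- mmars_panel()
  mdeer <- mdeer_panel()
  call <- bands_to_call(250, mmars)
  expect_identical(call$status, "species")
  expect_identical(call$species, "eastern grey kangaroo")

  expect_identical(bands_to_call(numeric(0), mmars)$status, "no_amplification")

  amb <- bands_to_call(c(161, 482), mdeer)
  expect_identical(amb$status, "ambiguous")
  expect_setequal(amb$species, c("red deer", "sambar deer"))

  stray <- bands_to_call(c(250, 340), mmars)
  expect_identical(stray$status, "uninterpretable")
  expect_match(stray$detail, "340")

  ## slightly off but within gel tolerance still calls the species
  expect_identical(bands_to_call(258, mmars)$species, "eastern grey kangaroo")
})

test_that("band interpretation does not depend on band order", {
  mdeer <- mdeer_panel()
  a <- bands_to_call(c(482, 161), mdeer)
  b <- bands_to_call(c(161, 482), mdeer)
  expect_identical(a$status, b$status)
  expect_identical(a$species, b$species)
})

test_that("panels with gel-confusable sizes are rejected at load", {
  p <- panel_design("tight", list(
    list(species = "a", fwd = primer("aF", "ACGTACGTACGTACGTAC"),
         rev = primer("aR", "TGCATGCATGCATGCATG"), expected_size = 200L),
    list(species = "b", fwd = primer("bF", "ACGTACGTACGTACGTAG"),
         rev = primer("bR", "TGCATGCATGCATGCATC"), expected_size = 209L)))
  expect_error(bands_to_call(200, p), "not gel-distinguishable")
})

test_that("survey summaries count morphology/molecular mismatches", {
  rec <- function(id, label, species) data.frame(
    sample_id = id, morphological_label = label,
    call_status = if (is.na(species)) "no_amplification" else "species",
    call_species = species, stringsAsFactors = FALSE)
  records <- rbind(
    do.call(rbind, lapply(1:22, function(i)
      rec(paste0("k", i), "kangaroo",
          if (i <= 15) "wallaby" else "wombat"))),
    rec("w1", "wombat", "kangaroo"),
    do.call(rbind, lapply(1:30, function(i)
      rec(paste0("u", i), "unknown marsupial", "kangaroo"))),
    rec("ok1", "wallaby", "wallaby"),
    rec("na1", "kangaroo", NA))
  s <- summarize_survey(records)
  expect_identical(s$n, nrow(records))
  ## 22 mislabelled kangaroos + 1 mislabelled wombat; unknowns and
  ## non-amplifying samples never count
  expect_identical(s$mismatch_count, 23L)
  ## conservation: cells (excluding margins) sum to the record count
  core <- s$confusion[rownames(s$confusion) != "Sum",
                      colnames(s$confusion) != "Sum"]
  expect_identical(as.integer(sum(core)), s$n)
})

test_that("concordant surveys have an empty off-diagonal", {
  records <- data.frame(
    sample_id = paste0("s", 1:10),
    morphological_label = rep(c("a", "b"), 5),
    call_status = "species",
    call_species = rep(c("a", "b"), 5), stringsAsFactors = FALSE)
  s <- summarize_survey(records)
  expect_identical(s$mismatch_count, 0L)
  core <- s$confusion[c("a", "b"), c("a", "b")]
  expect_equal(unname(diag(core)), c(5, 5))
  expect_equal(sum(core) - sum(diag(core)), 0)
})

test_that("duplicate sample ids are rejected", {
  records <- data.frame(sample_id = c("s1", "s1"),
                        morphological_label = c("a", "a"),
                        call_status = "species", call_species = "a",
                        stringsAsFactors = FALSE)
  expect_error(summarize_survey(records), "duplicate sample_id: s1")
})

test_that("samples amplifying in both panels are uninterpretable", {
  mmars <- mmars_panel()
  mdeer <- mdeer_panel()
  both <- reconcile_panels(bands_to_call(250, mmars),
                           bands_to_call(161, mdeer))
  expect_identical(both$status, "uninterpretable")
  one <- reconcile_panels(bands_to_call(numeric(0), mmars),
                          bands_to_call(161, mdeer))
  expect_identical(one$species, "sambar deer")
  none <- reconcile_panels(bands_to_call(numeric(0), mmars),
                           bands_to_call(numeric(0), mdeer))
  expect_identical(none$status, "no_amplification")
})

test_that("classify_samples genotypes templates end to end", {
  refs <- synthetic_reference_genomes()
  mars <- refs$targets[refs$clade == "marsupial"]
  templates <- stats::setNames(mars, paste0("s", seq_along(mars)))
  recs <- classify_samples(templates, rep("unknown marsupial", 3),
                           mmars_panel())
  expect_identical(recs$call_status, rep("species", 3))
  expect_identical(recs$call_species,
                   unname(vapply(mars, `[[`, character(1), "species_label")))
})
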