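## A tiny hand-built alignment: conserved flanks (identical across
## species) around a core where every column carries a different base per
## species, plus 2 rows per species with no within-species variation.
make_cassette_alignment <- function(flank_len = 25L, core_len = 6L,
                                    n_rows = 2L) {
  set.seed(51)
  flankL <- random_dna(flank_len)
  flankR <- random_dna(flank_len)
  cores <- list(sp1 = strrep("A", core_len), sp2 = strrep("C", core_len),
                sp3 = strrep("G", core_len))
  species <- rep(names(cores), each = n_rows)
  rows <- vapply(species, function(sp)
    paste0(flankL, cores[[sp]], flankR), character(1))
  alignment(species, rows)
}

test_that("column profiles separate conserved and discriminating columns", {
  a <- make_cassette_alignment()
  prof <- column_profiles(a)
  expect_identical(prof$width, 56L)
  ## flank columns: conservation 1 everywhere, no discrimination
  expect_true(all(prof$conservation[, 1:25] == 1))
  expect_identical(unname(prof$discrimination[1:25]), rep(0L, 25))
  ## core columns: fixed within species, distinct across -> discriminating
  expect_identical(unname(prof$discrimination[26:31]), rep(1L, 6))
  expect_error(column_profiles(alignment("only", "ACGT")),
               "at least two species")
})

test_that("column profiles equal a direct per-column recount", {
  set.seed(52)
  species <- rep(c("x", "y", "z"), each = 3)
  rows <- vapply(seq_along(species), function(i) random_dna(40), character(1))
  a <- alignment(species, rows)
  prof <- column_profiles(a)
  mat <- do.call(rbind, strsplit(rows, ""))
  for (sp in c("x", "y", "z")) {
    sub <- mat[species == sp, , drop = FALSE]
    for (j in sample(40, 12)) {
      counts <- table(sub[, j])
      expect_equal(unname(prof$conservation[sp, j]), max(counts) / nrow(sub))
    }
  }
})

test_that("implanted diagnostic windows are recovered with exact coordinates", {
  a <- make_cassette_alignment(flank_len = 25L, core_len = 6L)
  win <- find_diagnostic_windows(a |> column_profiles(),
                                 design_constraints(min_flank_len = 20L))
  expect_identical(nrow(win), 3L)            # one per species
  expect_setequal(win$species, c("sp1", "sp2", "sp3"))
  expect_true(all(win$flank_left_start == 1L))
  expect_true(all(win$flank_left_end == 25L))
  expect_true(all(win$core_start == 26L & win$core_end == 31L))
  expect_true(all(win$flank_right_end == 56L))
  expect_true(all(win$n_disc == 6L))
})

test_that("an alignment with zero variation yields no windows", {
  row <- paste(rep("ACGT", 20), collapse = "")
  a <- alignment(c("s1", "s1", "s2", "s2"), rep(row, 4))
  win <- find_diagnostic_windows(column_profiles(a))
  expect_identical(nrow(win), 0L)
})

test_that("shrinking the minimum flank length never removes a window", {
  set.seed(53)
  p <- generator_params(n_species = 3, genome_length = 3000,
                        cassettes = list(c(40L, 30L)), seed = 99)
  sim <- simulate_species_genomes(p)
  prof <- column_profiles(sim_alignment(sim))
  w25 <- find_diagnostic_windows(prof, design_constraints(min_flank_len = 25L))
  w15 <- find_diagnostic_windows(prof, design_constraints(min_flank_len = 15L))
  key <- function(w) paste(w$species, w$core_start, w$core_end)
  expect_true(all(key(w25) %in% key(w15)))
})

test_that("enumerated candidates satisfy the constraints they were built under", {
  a <- make_cassette_alignment(flank_len = 30L, core_len = 8L)
  prof <- column_profiles(a)
  cons <- design_constraints(min_flank_len = 20L, tm_range = c(10, 120),
                             gc_range = c(0, 1))
  win <- find_diagnostic_windows(prof, cons)
  cands <- enumerate_candidates(win[win$species == "sp1", ][1, ], prof, cons)
  expect_gt(nrow(cands), 0)
  expect_true(all(nchar(cands$seq) >= cons$primer_len[1]))
  expect_true(all(nchar(cands$seq) <= cons$primer_len[2]))
  expect_true(all(cands$degeneracy <= cons$max_degeneracy))
  ## concrete 3' base under the clamp
  last <- substr(cands$seq, nchar(cands$seq), nchar(cands$seq))
  expect_true(all(last %in% c("A", "C", "G", "T")))
  ## species-specific candidates mismatch every other species somewhere
  spc <- cands[cands$species == "sp1", ]
  expect_true(all(spc$min_mismatch_vs_others >= 1))
  ## shared candidates lie entirely in conserved flanks
  sh <- cands[cands$species == "shared", ]
  expect_true(all(sh$aln_end <= 30 | sh$aln_start >= 39))
})

test_that("a window where everything is too degenerate yields no candidates", {
  ## high within-species disagreement pushes every column to a degenerate
  ## union; max_degeneracy 1 then rejects every subsequence
  set.seed(54)
  species <- rep(c("a", "b"), each = 4)
  rows <- vapply(seq_along(species), function(i) random_dna(60), character(1))
  a <- alignment(species, rows)
  cons <- design_constraints(max_degeneracy = 1L, min_flank_len = 5L,
                             conservation_threshold = 1.01)
  prof <- column_profiles(a, cons)
  fake_win <- data.frame(species = "a", flank_left_start = 1L,
                         flank_left_end = 10L, core_start = 11L,
                         core_end = 20L, flank_right_start = 21L,
                         flank_right_end = 40L, n_disc = 1L)
  cands <- enumerate_candidates(fake_win, prof, cons)
  expect_identical(nrow(cands), 0L)
})

## Candidate fixture for selection tests: concrete primers at controlled
## template spacings; the loose constraints leave only the size machinery
## active.
make_selection_fixture <- function(rev_cols_by_sp) {
  set.seed(55)
  width <- max(unlist(rev_cols_by_sp)) + 30L
  row <- random_dna(width)
  species <- names(rev_cols_by_sp)
  prof <- column_profiles(alignment(rep(species, each = 2),
                                    rep(row, 2 * length(species))))
  fwd_seq <- "ACTGGATCCAGTACGGATCA"
  rev_seq <- "TGCAGGATCCAGTTAGCGTA"
  rows <- list()
  for (sp in species) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(sp, "_F"), species = sp, orientation = "fwd",
      seq = fwd_seq, aln_start = 1L, aln_end = 20L, degeneracy = 1,
      gc = 0.5, tm_min = 60, tm_max = 60, min_mismatch_vs_others = 1L,
      min_mismatch_3p = 1L, tpl_start = 0L, tpl_end = 20L,
      stringsAsFactors = FALSE)
    for (rc in rev_cols_by_sp[[sp]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(sp, "_R", rc), species = sp, orientation = "rev",
        seq = rev_seq, aln_start = rc - 19L, aln_end = rc, degeneracy = 1,
        gc = 0.5, tm_min = 60, tm_max = 60, min_mismatch_vs_others = 1L,
        min_mismatch_3p = 1L, tpl_start = rc - 20L, tpl_end = rc,
        stringsAsFactors = FALSE)
    }
  }
  cands <- do.call(rbind, rows)
  class(cands) <- c("primer_candidates", class(cands))
  list(cands = cands, prof = prof)
}

loose <- design_constraints(tm_range = c(0, 200), max_tm_spread = 200,
                            max_dimer_run = 40L, gc_range = c(0, 1))

test_that("selection maximises the minimum size gap", {
  fx <- make_selection_fixture(list(s1 = c(120L, 150L), s2 = c(200L, 210L),
                                    s3 = c(255L, 260L)))
  panel <- select_panel(fx$cands, fx$prof, loose, panel_name = "toy")
  sizes <- sort(unname(panel_sizes(panel)))
  ## best of the 8 combinations: {120, 200, 260} with minimum gap 60
  expect_identical(sizes, c(120L, 200L, 260L))
  expect_identical(min(diff(sizes)), 60L)
})

test_that("selection is deterministic", {
  fx <- make_selection_fixture(list(s1 = c(120L, 150L), s2 = c(200L, 210L),
                                    s3 = c(255L, 260L)))
  p1 <- select_panel(fx$cands, fx$prof, loose)
  p2 <- select_panel(fx$cands, fx$prof, loose)
  expect_identical(panel_sizes(p1), panel_sizes(p2))
  expect_identical(vapply(p1$members, function(m) m$fwd$name, character(1)),
                   vapply(p2$members, function(m) m$fwd$name, character(1)))
})

test_that("the reported minimum gap is truly maximal (exhaustive check)", {
  fx <- make_selection_fixture(list(s1 = c(60L, 95L, 130L),
                                    s2 = c(70L, 110L, 150L),
                                    s3 = c(80L, 125L, 170L)))
  panel <- suppressWarnings(select_panel(fx$cands, fx$prof, loose))
  got_gap <- min(dist(unname(panel_sizes(panel))))
  sizes_by_sp <- list(c(60L, 95L, 130L), c(70L, 110L, 150L),
                      c(80L, 125L, 170L))
  best <- -Inf
  for (i in sizes_by_sp[[1]]) for (j in sizes_by_sp[[2]])
    for (k in sizes_by_sp[[3]])
      best <- max(best, min(dist(c(i, j, k))))
  expect_identical(as.numeric(got_gap), as.numeric(best))
})

test_that("infeasible size spacing produces a structured report", {
  fx <- make_selection_fixture(list(s1 = 120L, s2 = 125L, s3 = 128L))
  err <- tryCatch(select_panel(fx$cands, fx$prof, loose),
                  panel_infeasible = identity)
  expect_s3_class(err, "panel_infeasible")
  expect_match(conditionMessage(err), "min_size_gap")
  expect_true("min_size_gap" %in% err$violated)
})

test_that("published panel members pass validation on the reference set", {
  refs <- synthetic_reference_genomes()
  mars_targets <- refs$targets[refs$clade == "marsupial"]
  deer_targets <- refs$targets[refs$clade == "deer"]
  rep1 <- validate_panel(mmars_panel(), mars_targets,
                         c(deer_targets, refs$offtargets))
  expect_true(rep1$all_pass)
  expect_identical(rep1$n_fail, 0L)
  expect_true(all(rep1$offtargets$n_products == 0L))
  rep2 <- validate_panel(mdeer_panel(), deer_targets,
                         c(mars_targets, refs$offtargets))
  expect_true(rep2$all_pass)
})

test_that("a promiscuous primer fails validation naming the extra product", {
  set.seed(56)
  aF <- primer("aF", "ACGGATTACCAGGCATCAAG")
  bF <- primer("bF", "TGCCATTGACGGAAGTCCTA")
  R <- primer("comR", "CATTGGCAGCCTTAGACGAT")
  rcR <- revcomp(R$seq)
  tA <- nuc_sequence("gA", paste0(random_dna(30), aF$seq, random_dna(160),
                                  rcR, random_dna(30)),
                     species_label = "species a")
  ## species b's genome also carries an aF site: the promiscuous forward
  ## primer produces a second, cross-species band there
  tB <- nuc_sequence("gB", paste0(random_dna(30), aF$seq, random_dna(100),
                                  bF$seq, random_dna(260), rcR,
                                  random_dna(30)),
                     species_label = "species b")
  bad <- panel_design("bad", list(
    list(species = "species a", fwd = aF, rev = R, expected_size = 200L),
    list(species = "species b", fwd = bF, rev = R, expected_size = 300L)))
  rep <- validate_panel(bad, list(tA, tB))
  expect_false(rep$all_pass)
  expect_identical(rep$targets$status, c("PASS", "FAIL"))
  expect_match(rep$targets$reason[2], "multiple products")
  expect_match(rep$targets$reason[2], "aF/comR")
})

test_that("validation without off-targets reports 'not assessed'", {
  refs <- synthetic_reference_genomes()
  rep <- validate_panel(mmars_panel(),
                        refs$targets[refs$clade == "marsupial"], list())
  expect_false(rep$specificity_assessed)
  expect_true(rep$all_pass)
  expect_match(paste(capture.output(print(rep)), collapse = "\n"),
               "not assessed")
  expect_error(
    validate_panel(mmars_panel(), refs$targets["fallow deer"], list()),
    "not in panel")
})
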