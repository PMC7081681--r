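macF <- primer("macF", "GCATCCATCTTAATTCTCCTCA")
marR <- primer("marR", "GGTTYTAGTATGTAGTTTTCAAA")

test_that("binding sites are found on both strands of constructed templates", {
  t1 <- nuc_sequence("t1", paste0(strrep("A", 10), macF$seq, strrep("A", 10)))
  s1 <- find_binding_sites(macF, t1)
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$strand, "+")
  expect_identical(s1$start, 10L)
  expect_identical(s1$mismatches, 0L)
  expect_identical(s1$end - s1$start, nchar(macF$seq))

  t2 <- nuc_sequence("t2", paste0(strrep("G", 8), revcomp(concrete1(marR$seq)),
                                  strrep("G", 8)))
  s2 <- find_binding_sites(marR, t2)
  expect_identical(nrow(s2), 1L)
  expect_identical(s2$strand, "-")
  expect_identical(s2$start, 8L)
})

test_that("product length is primer-inclusive for F + spacer + revcomp(R)", {
  set.seed(31)
  for (spacer_len in c(100L, 37L, 250L)) {
    tmpl <- nuc_sequence("t", paste0(macF$seq, random_dna(spacer_len),
                                     revcomp(concrete1(marR$seq))))
    amps <- predict_amplicons(macF, marR, tmpl)
    expect_identical(nrow(amps), 1L)
    expect_identical(amps$length, 22L + spacer_len + 23L)
    expect_identical(nchar(amps$sequence), amps$length)
    expect_identical(amps$sequence, tmpl$residues)
  }
})

test_that("engine matches the brute-force oracle on random instances", {
  set.seed(32)
  policies <- list(match_policy(0, 5, 0, 1000), match_policy(1, 5, 0, 1000),
                   match_policy(2, 5, 0, 1000), match_policy(2, 3, 1, 400))
  for (k in 1:40) {
    n <- sample(120:400, 1)
    tmpl_str <- random_dna(n)
    circular <- k %% 2 == 0
    tmpl <- nuc_sequence("t", tmpl_str,
                         topology = if (circular) "circular" else "linear")
    pol <- policies[[1 + (k %% length(policies))]]
    fseq <- random_iupac(sample(12:22, 1),
                         codes = c("A", "C", "G", "T", "Y", "R"))
    rseq <- random_dna(sample(12:22, 1))
    f <- primer("f", fseq); r <- primer("r", rseq)

    got <- find_binding_sites(f, tmpl, pol)
    want <- oracle_sites(fseq, tmpl_str, circular, pol)
    expect_identical(got$start, want$start)
    expect_identical(got$strand, want$strand)
    expect_identical(got$mismatches, as.integer(want$mismatches))

    amps <- predict_amplicons(f, r, tmpl, pol, with_sequence = FALSE)
    oamps <- oracle_amplicons(fseq, rseq, tmpl_str, circular, pol)
    expect_identical(amps$fwd_start, oamps$fwd_start)
    expect_identical(amps$length, oamps$length)
  }
})

test_that("circular results are invariant under rotation of the origin", {
  set.seed(33)
  spacer <- random_dna(160)
  core <- paste0(macF$seq, spacer, revcomp(concrete1(marR$seq)))
  genome <- paste0(core, random_dna(700))
  n <- nchar(genome)
  lens <- integer(0)
  wraps <- logical(0)
  for (rot in c(0L, 150L, n - 50L, n - 200L)) {
    ## the product (originally at positions 0..204) moves to start at
    ## (n - rot) mod n in the rotated genome
    rotated <- paste0(substr(genome, rot + 1, n), substr(genome, 1, rot))
    t <- nuc_sequence("rot", rotated, topology = "circular")
    amps <- predict_amplicons(macF, marR, t, with_sequence = FALSE)
    expect_identical(nrow(amps), 1L)
    lens <- c(lens, amps$length)
    wraps <- c(wraps, amps$wraps_origin)
  }
  expect_identical(unique(lens), 22L + 160L + 23L)
  expect_identical(wraps, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("relaxing the mismatch budget never removes a site", {
  set.seed(34)
  for (k in 1:15) {
    tmpl <- nuc_sequence("t", random_dna(300))
    p <- primer("p", random_dna(15))
    prev <- NULL
    for (mm in 0:3) {
      s <- find_binding_sites(p, tmpl, match_policy(mm, 5, mm, 1000))
      key <- paste(s$strand, s$start)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
  }
})

test_that("multiplex returns all cross-pair products exactly once", {
  mmars <- mmars_panel()
  walF <- primer("walF", "GCCCTACTTTCATTAGCAC")
  marR_rc <- revcomp(concrete1(marR$seq))
  set.seed(35)
  chimera <- nuc_sequence("chimera",
    paste0(macF$seq, random_dna(205), marR_rc,    # kangaroo-style 250 bp
           random_dna(50),
           walF$seq, random_dna(383), marR_rc))   # wallaby-style 425 bp
  amps <- run_multiplex(mmars, chimera)
  ## the two diagnostic bands plus macF priming through to the second
  ## marR site (22 + 205 + 23 + 50 + 19 + 383 + 23 = 725 bp)
  expect_setequal(amps$length, c(250L, 425L, 725L))
  expect_identical(nrow(amps), 3L)
  expect_identical(sum(amps$length == 250L), 1L)

  set.seed(36)
  offtarget <- nuc_sequence("off", random_dna(2000))
  expect_identical(nrow(run_multiplex(mmars, offtarget)), 0L)
})

test_that("an empty panel is rejected", {
  p <- mmars_panel()
  p$members <- list()
  expect_error(run_multiplex(p, nuc_sequence("t", random_dna(100))),
               "empty panel")
})
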