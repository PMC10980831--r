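test_that("match_primer finds IUPAC-compatible sites", {
  hits <- match_primer("TTACGTTT", "ACGT", max_mismatch = 0)
  expect_identical(hits$position, 2L)
  expect_identical(hits$mismatches, 0L)

  # R = {A, G}
  expect_identical(match_primer("TTACGTTT", "ACRT", 0)$position, 2L)
  expect_identical(match_primer("TTACATTT", "ACRT", 0)$position, 2L)

  # mismatch in the 3'-terminal 5-base window is disqualifying even when
  # the total budget would allow it
  expect_identical(nrow(match_primer("AAACCTTT", "ACGT", 1)), 0L)

  expect_error(match_primer("ACGT", ""), class = "rb_invalid_argument")
})

test_that("minus-strand matching reports plus-strand coordinates", {
  primer <- "ACGGT"
  seq <- paste0("TTTT", revcomp(primer), "AAAA")
  hits <- match_primer(seq, primer, 0, strand = "-")
  expect_identical(hits$position, 4L)
})

test_that("extract_region takes the outermost primer footprints", {
  fwd <- "AGAGTTTGATCATGGCTCAG"; rev <- "ATTACCGCGGCTGCTGG"
  core <- strrep("ACGTTGCA", 10)  # 80 bp
  pair <- primer_pair("V1-V3", fwd, rev, max_mismatch = 0)
  seq <- paste0("NNN", fwd, core, revcomp(rev), "NN")
  hit <- extract_region(seq, pair, "g1")
  expect_identical(hit$sequence, core)
  expect_identical(hit$start, 3L + nchar(fwd))
  expect_identical(hit$end, hit$start + nchar(core))

  # two forward sites: leftmost used
  seq2 <- paste0("NNN", fwd, strrep("T", 60), fwd, core, revcomp(rev))
  hit2 <- extract_region(seq2, pair, "g1")
  expect_identical(hit2$start, 3L + nchar(fwd))

  expect_error(extract_region(paste0("NNN", fwd, core), pair, "g1"),
               class = "rb_no_amplicon")
  expect_error(extract_region(paste0(core, revcomp(rev)), pair, "g1"),
               class = "rb_no_amplicon")
  short <- paste0(fwd, strrep("A", 20), revcomp(rev))
  expect_error(extract_region(short, pair, "g1"), class = "rb_amplicon_length")
})

test_that("choose_copy prefers length then identifier", {
  one <- c(g1_rrnA = "ACGT")
  expect_identical(choose_copy(one), one)
  two <- c(g1_rrnA = strrep("A", 1500), g1_rrnB = strrep("A", 1540))
  expect_identical(names(choose_copy(two)), "g1_rrnB")
  tie <- c(g1_rrnB = strrep("A", 1540), g1_rrnA = strrep("C", 1540))
  expect_identical(names(choose_copy(tie)), "g1_rrnA")
  expect_error(choose_copy(character(0)), class = "rb_invalid_argument")
})

test_that("extract_panel reports drops without removing other regions", {
  g <- simulate_genus(sim_config(n_species = 3, strains_per_species = 1,
                                 genome_length = 1100, seed = 3))
  ex <- extract_panel(g$ssu, g$panel)
  expect_identical(nrow(ex$drops), 0L)
  expect_true(all(vapply(ex$hits, length, 1L) == 3))

  # break one genome's V4 reverse site
  lay <- synthetic_region_layout()
  ssu <- g$ssu
  rs <- lay$rev_starts[3]
  substr(ssu[[2]], rs + 1, rs + 20) <- strrep("A", 20)
  ex2 <- extract_panel(ssu, g$panel)
  expect_identical(ex2$drops$region_label, "V4")
  expect_identical(ex2$drops$genome_id, names(ssu)[2])
  expect_length(ex2$hits[["V4"]], 2)
  expect_true(all(vapply(ex2$hits[setdiff(names(ex2$hits), "V4")], length, 1L) == 3))

  empty <- extract_panel(setNames(character(0), character(0)), g$panel)
  expect_length(empty$hits[["V1-V3"]], 0)
  expect_identical(nrow(empty$drops), 0L)
})

test_that("extraction is position-consistent and rc-invariant", {
  g <- simulate_genus(sim_config(n_species = 4, strains_per_species = 2,
                                 genome_length = 1100, seed = 9))
  ex <- extract_panel(g$ssu, g$panel)
  for (lab in names(ex$hits)) {
    starts <- vapply(ex$hits[[lab]], `[[`, numeric(1), "start")
    ends <- vapply(ex$hits[[lab]], `[[`, numeric(1), "end")
    expect_length(unique(starts), 1)  # gap-free simulation => fixed coords
    expect_length(unique(ends), 1)
  }
  # reverse-complemented input yields the reverse-complemented region:
  # swap the pair's primers so it amplifies the minus strand
  pair <- g$panel[[2]]
  flipped <- primer_pair(pair$region_label, pair$reverse, pair$forward,
                         pair$max_mismatch)
  fwd_hit <- extract_region(g$ssu[[1]], pair, "g")
  rc_hit <- extract_region(revcomp(g$ssu[[1]]), flipped, "g")
  expect_identical(rc_hit$sequence, revcomp(fwd_hit$sequence))
})
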