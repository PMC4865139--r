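test_that("reverse complement handles both alphabets and is an involution", {
  expect_equal(reverse_complement("AUGC", "RNA"), "GCAU")
  expect_equal(reverse_complement("ACGT", "DNA"), "ACGT") # self-complementary
  expect_error(reverse_complement("AUGC", "DNA"), class = "dg_alphabet_error")
  withr::local_seed(9)
  for (k in 1:10) {
    s <- rand_rna(sample(5:30, 1))
    expect_equal(reverse_complement(reverse_complement(s, "RNA"), "RNA"), s)
  }
})

test_that("chemistry conversion round-trips on the letters", {
  s <- "ATGGCATCC"
  expect_equal(convert_alphabet(convert_alphabet(s, "RNA"), "DNA"), s)
})

test_that("sense and antisense oligos follow the published design rule", {
  # element subsequence AUGGCAUCC: sense keeps it, antisense is its
  # reverse complement; DNA chemistry swaps U for T
  utr <- utr_sequence("u", "GGAUGGCAUCCAA")
  el <- tibble::tibble(seq_id = "u", start = 3L, end = 11L, rank_label = "e1")
  oo <- design_oligos(utr, el, categories = c("sense", "antisense"),
                      chemistry = "dna")
  expect_equal(oo$residues[oo$category == "sense"], "ATGGCATCC")
  expect_equal(oo$residues[oo$category == "antisense"], "GGATGCCAT")
  expect_equal(oo$name, c("dG_e1_s", "dG_e1_as"))
  # in RNA chemistry the pair are exact reverse complements of each other
  oo2 <- design_oligos(utr, el, categories = c("sense", "antisense"),
                       chemistry = "2ome")
  expect_equal(reverse_complement(oo2$residues[1], "RNA"), oo2$residues[2])
})

test_that("element bounds and insertion length are validated", {
  utr <- utr_sequence("u", "GGAUGGCAUCCAA")
  bad <- tibble::tibble(seq_id = "u", start = 10L, end = 20L, rank_label = "e1")
  expect_error(design_oligos(utr, bad), class = "dg_bounds_error")
  el <- tibble::tibble(seq_id = "u", start = 1L, end = 8L, rank_label = "e1")
  expect_error(design_oligos(utr, el, insertion_len = 4), class = "dg_config_error")
})

test_that("miR-like oligos insert centrally and keep their flanks", {
  utr <- utr_sequence("u", rand_rna_fixed20())
  el <- tibble::tibble(seq_id = "u", start = 1L, end = 20L, rank_label = "e1")
  oo <- design_oligos(utr, el, categories = "mir_like_antisense",
                      chemistry = "2ome", insertion_len = 3)
  parent <- reverse_complement(utr$residues, "RNA")
  expect_equal(oo$length, 23L)
  expect_equal(oo$insertion_pos, 10L)
  expect_equal(substr(oo$residues, 1, 10), substr(parent, 1, 10))
  expect_equal(substr(oo$residues, 14, 23), substr(parent, 11, 20))
  expect_equal(nchar(oo$insertion_seq), 3L)

  # removing the insertion restores full complementarity to the target
  trimmed <- paste0(substr(oo$residues, 1, 10), substr(oo$residues, 14, 23))
  rep_full <- hybridization_report(trimmed, utr)
  expect_equal(rep_full$longest_complementary_run, 20L)
  # with the insertion in place, the best gapless run is one flank
  rep_mir <- hybridization_report(oo$residues, utr)
  expect_equal(rep_mir$longest_complementary_run, 10L)
  # the inserted bases do not pair with the apposed target residues
  ins <- strsplit(oo$insertion_seq, "")[[1]]
  apposed <- substr(utr$residues, 10, 11)
  for (b in ins) {
    for (t in strsplit(apposed, "")[[1]]) {
      expect_false(dgenhancer:::pairs_with(b, t))
    }
  }
})

test_that("2-nt insertions are supported", {
  utr <- utr_sequence("u", rand_rna_fixed20())
  el <- tibble::tibble(seq_id = "u", start = 1L, end = 20L, rank_label = "e1")
  oo <- design_oligos(utr, el, categories = "mir_like_sense",
                      chemistry = "dna", insertion_len = 2)
  expect_equal(oo$length, 22L)
  expect_equal(nchar(oo$insertion_seq), 2L)
})

test_that("hybridization report counts Watson-Crick and wobble appositions", {
  # exact antisense 10-mer of an internal target region
  target <- utr_sequence("t", "AAGGCAUCCAUGGAA")
  oligo <- reverse_complement(substr(target$residues, 3, 12), "RNA")
  rep1 <- hybridization_report(oligo, target)
  expect_equal(rep1$longest_complementary_run, 10L)
  expect_equal(rep1$total_matched, 10L)
  expect_equal(rep1$wobble_positions, 0L)

  # one central mismatch splits the run
  oligo_mm <- oligo
  substr(oligo_mm, 5, 5) <- if (substr(oligo, 5, 5) == "A") "C" else "A"
  rep2 <- hybridization_report(oligo_mm, target)
  expect_equal(rep2$longest_complementary_run, 5L)

  # G against U is wobble, never Watson-Crick
  rep3 <- hybridization_report("GGGGG", utr_sequence("t", "UUUUU"))
  expect_equal(rep3$total_matched, 0L)
  expect_equal(rep3$wobble_positions, 5L)
  expect_equal(rep3$overlap, 5L)
})

test_that("scrambled controls preserve composition, reproduce, and bound binding", {
  withr::local_seed(31)
  target <- utr_sequence("t", rand_rna(100))
  el <- tibble::tibble(seq_id = "t", start = 41L, end = 60L, rank_label = "e1")
  parent <- design_oligos(target, el, categories = "antisense",
                          chemistry = "2ome")
  sc1 <- make_scrambled(parent, target, seed = 17)
  sc2 <- make_scrambled(parent, target, seed = 17)
  expect_identical(sc1$residues, sc2$residues)         # seeded reproducibility
  expect_false(sc1$degenerate)
  expect_equal(sort(strsplit(sc1$residues, "")[[1]]),
               sort(strsplit(parent$residues, "")[[1]])) # composition multiset
  expect_lt(hybridization_report(sc1, target)$longest_complementary_run, 7)
  expect_equal(sc1$category, "scrambled")
})

test_that("homopolymer parents are flagged degenerate or exhaust", {
  target <- utr_sequence("t", "GGCAGGCAGGCAGGCA")
  sc <- make_scrambled("AAAAAA", target, seed = 1)
  expect_true(sc$degenerate)
  expect_equal(sc$residues, "AAAAAA")
  # force exhaustion: any run of 1 is already too long
  expect_error(make_scrambled("AAAAAA", utr_sequence("t", "UUUUUUUU"), seed = 1,
                              max_run = 1),
               class = "dg_exhaustion_error")
})
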