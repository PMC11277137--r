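al <- al_sequence()

test_that("circular codon reading exposes one word per offset", {
  expect_identical(circular_codons("ACG"), c("ACG", "CGA", "GAC"))
  expect_identical(circular_codons("AAAA"), rep("AAA", 4L))
  cods <- circular_codons(al)
  expect_length(cods, 22L)
  expect_identical(which(cods == "ATG"), c(1L, 5L))  # offsets 0 and 4
  expect_true("TGA" %in% cods)
  expect_error(circular_codons("AC"), "shorter")
})

test_that("coverage predicate matches a direct class tally", {
  expect_true(covers_all_amino_acids(al))
  expect_false(covers_all_amino_acids(strrep("A", 22)))
  # toy ring: four circular dimers AA, AC, CC, CA cover all four classes
  expect_true(covers_all_amino_acids("AACC", toy_table(c("A", "C"), 2)))
  expect_false(covers_all_amino_acids("AAAC", toy_table(c("A", "C"), 2)))
})

test_that("pruned enumeration equals brute force on toy codes", {
  cases <- list(
    list(tab = toy_table(c("A", "C"), 2), L = 4L),
    list(tab = toy_table(c("A", "C"), 2), L = 5L),
    list(tab = toy_table(c("A", "C"), 2), L = 7L),
    list(tab = toy_table(c("A", "C", "G"), 1), L = 4L),
    list(tab = toy_table(c("A", "C", "G", "T"), 1), L = 5L),
    list(tab = toy_table(c("A", "C", "G", "T"), 1), L = 6L)
  )
  for (cs in cases) {
    got <- enumerate_rings(cs$L, cs$tab, reading = "offsets")
    expect_identical(sort(got$rings), bf_enumerate(cs$L, cs$tab),
                     info = sprintf("L=%d over {%s}", cs$L,
                                    paste(cs$tab$alphabet, collapse = ",")))
    expect_equal(got$census$n_solutions, length(got$rings))
  }
  # the documented toy case: exactly one ring covers all four dimers at L=4
  got <- enumerate_rings(4, toy_table(c("A", "C"), 2), reading = "offsets")
  expect_identical(got$rings, "AACC")
})

test_that("every rotation of a solution is a solution and canonicalisation is idempotent", {
  tab <- toy_table(c("A", "C"), 2)
  sols <- enumerate_rings(5, tab, reading = "offsets")$rings
  for (s in sols) {
    for (r in rotations(s)) {
      expect_true(covers_all_amino_acids(r, tab))
      expect_identical(canonical_rotation(r), s)
    }
    expect_identical(canonical_rotation(canonical_rotation(s)),
                     canonical_rotation(s))
  }
})

test_that("no coverage ring exists below length 22 for the standard code", {
  # L = 19: only 19 codons, fewer than the 20 required classes
  expect_equal(enumerate_rings(19)$census$n_solutions, 0)
  # L = 20: coprime with 3, searched exhaustively with pruning
  expect_equal(enumerate_rings(20)$census$n_solutions, 0)
  # L = 21: a continuous overlap reading only visits 7 codon slots
  expect_equal(enumerate_rings(21)$census$n_solutions, 0)
  expect_error(enumerate_rings(25), "bounded")
})

test_that("the AL ring passes the single-repeat and start/stop filters", {
  srf <- single_repeat_filter(al)
  expect_identical(srf$rings, al)
  expect_identical(names(srf$histogram), "ATG/ATG")
  # literal by-codon variant agrees on AL (its doubled pair is a true repeat)
  expect_identical(single_repeat_filter(al, by = "codon")$rings, al)
  expect_identical(start_stop_filter(al), al)
  expect_identical(start_stop_filter(character(0)), character(0))
  expect_identical(start_stop_filter(strrep("A", 22)), character(0))
  expect_identical(single_repeat_filter(strrep("A", 22))$rings, character(0))
  # no T anywhere: TGA impossible
  expect_identical(start_stop_filter("AAGGCCAAGGCCAAGGCCAAGG"), character(0))
})

test_that("the ring census classifies repeat structure correctly on known rings", {
  cen <- ring_census(al)
  expect_identical(cen$n_single_repeat, 1L)
  expect_identical(cen$frac_AUG, 1)
  expect_identical(cen$n_start_stop, 1L)
})
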