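al <- al_sequence()

test_that("linear greedy folding pairs outward-in and respects min_loop", {
  f <- fold_hairpin("GGGAAACCC")
  expect_identical(f$score, 3L)
  expect_equal(f$loop, c(3, 6))  # loop AAA, 0-based half-open
  expect_identical(f$pairs[, 1], 0:2)
  expect_identical(f$pairs[, 2], 8:6)

  # A pairs with nothing here: no stem at all
  expect_identical(fold_hairpin("AAAAAAA")$score, 0L)

  # wobble G.T counts as complementary unless disabled
  expect_identical(fold_hairpin("GGGAAATCC")$score, 3L)
  expect_identical(fold_hairpin("GGGAAATCC", wobble = FALSE)$score, 2L)

  expect_error(fold_hairpin("ACGT"), "too short")
})

test_that("the circular AL fold has a 9-pair stem with the loop at the ring closure", {
  f <- fold_hairpin(al, circular = TRUE)
  expect_identical(f$score, 9L)
  expect_setequal(f$loop_ring, c(20, 21, 0))
  # every stem pair is complementary under WC + wobble
  s <- rotations(al)[[f$rotation + 1L]]
  v <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_len(nrow(f$pairs))) {
    x <- v[f$pairs[k, 1] + 1L]; y <- v[f$pairs[k, 2] + 1L]
    expect_true(comp[[x]] == y || (x == "G" && y == "T") ||
                  (x == "T" && y == "G"))
  }
  # pairs are nested: no pseudoknots
  expect_true(all(diff(f$pairs[, 1]) > 0) && all(diff(f$pairs[, 2]) < 0))
})

test_that("fold score is invariant under reverse complement (Watson-Crick pairing)", {
  # G.T wobble is strand-asymmetric (its reverse complement A.C does not
  # pair), so the invariance holds for the pure Watson-Crick rule set
  set.seed(31)
  for (i in 1:10) {
    s <- random_seq(sample(9:16, 1))
    expect_identical(fold_hairpin(s, wobble = FALSE)$score,
                     fold_hairpin(reverse_complement(s), wobble = FALSE)$score,
                     info = s)
  }
  expect_identical(
    fold_hairpin(al, circular = TRUE, wobble = FALSE)$score,
    fold_hairpin(reverse_complement(al), circular = TRUE,
                 wobble = FALSE)$score)
})

test_that("the AL hairpin head reproduces the nine-pentamer set", {
  hp <- head_pentamers(fold_hairpin(al, circular = TRUE))
  expect_setequal(hp$members, al_pentamers("al9")$members)
})

test_that("head windows around a linear loop are clamped and flanked", {
  f <- fold_hairpin("GGGAAACCC")
  hp <- head_pentamers(f)
  # windows overlapping loop positions 3..5, clamped to the 5 valid starts
  expect_setequal(hp$members,
                  unique(substring("GGGAAACCC", 1:5, 5:9)))
})

test_that("a fold without a loop has no defined head", {
  fake <- structure(list(seq = "GGGGCCCC", rotation = 0L, overhang = c(0L, 0L),
                         pairs = cbind(0:3, 7:4), score = 4L,
                         loop = c(4, 4), loop_ring = integer(0),
                         circular = FALSE),
                    class = "hairpin_fold")
  expect_error(head_pentamers(fake), "no loop")
})
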