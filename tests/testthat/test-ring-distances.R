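test_that("circular Hamming minimises over rotations", {
  expect_identical(circular_hamming("ACGT", "ACGT"), 0)
  expect_identical(circular_hamming("ACGT", "CGTA"), 0)
  expect_identical(circular_hamming("AACG", "AAGC"), 2)
  expect_error(circular_hamming("AAA", "AAAA"), "equal length")
  # brute-force cross-check on random pairs
  set.seed(7)
  for (i in 1:25) {
    a <- random_seq(sample(4:9, 1)); b <- random_seq(nchar(a))
    expect_equal(circular_hamming(a, b),
                 min(vapply(rotations(b), function(r) {
                   sum(strsplit(a, "")[[1]] != strsplit(r, "")[[1]])
                 }, numeric(1))))
  }
})

test_that("circular edit distance minimises Levenshtein over rotations", {
  expect_equal(circular_edit("ACGT", "ACGT"), 0)
  expect_equal(circular_edit("AAAA", "AAA"), 1)
  expect_equal(circular_edit("ACGT", "AGT"), 1)
  set.seed(11)
  for (i in 1:20) {
    a <- random_seq(sample(3:8, 1)); b <- random_seq(sample(3:8, 1))
    expect_equal(circular_edit(a, b),
                 min(vapply(rotations(b), function(r) bf_lev(a, r), numeric(1))))
  }
})

test_that("permutation distance equals brute-force swap search and flags non-anagrams", {
  expect_identical(permutation_distance("ACGT", "ACGT"), 0L)
  expect_identical(permutation_distance("AC", "CA"), 0L)  # rotation
  expect_identical(permutation_distance("AACG", "AAGC"), 1L)
  expect_true(is.na(permutation_distance("AAAA", "CCCC")))
  set.seed(13)
  for (i in 1:15) {
    a <- random_seq(sample(4:6, 1))
    b <- paste(sample(strsplit(a, "")[[1]]), collapse = "")  # anagram
    expect_identical(permutation_distance(a, b), bf_circular_swaps(a, b),
                     info = paste(a, b))
  }
})

test_that("circular metrics satisfy symmetry, rotation invariance and known inequalities", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    a <- random_seq(n); b <- random_seq(n)
    ch <- circular_hamming(a, b)
    ce <- circular_edit(a, b)
    expect_equal(ch, circular_hamming(b, a))
    expect_equal(ce, circular_edit(b, a))
    # invariance under rotating either argument
    ra <- rotations(a)[[sample(n, 1)]]
    rb <- rotations(b)[[sample(n, 1)]]
    expect_equal(circular_hamming(ra, rb), ch)
    expect_equal(circular_edit(ra, rb), ce)
    # circular Hamming bounds a fixed alignment; edit bounds Hamming
    expect_lte(ch, sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
    expect_lte(ce, ch)
  }
  # triangle inequality for the edit metric
  set.seed(19)
  for (i in 1:10) {
    a <- random_seq(5); b <- random_seq(6); c <- random_seq(7)
    expect_lte(circular_edit(a, c),
               circular_edit(a, b) + circular_edit(b, c))
  }
})

test_that("barycenter is the medoid of the set", {
  expect_identical(barycenter("ACGT")$ring, "ACGT")
  expect_equal(barycenter("ACGT")$mean_distance, 0)
  expect_error(barycenter(character(0)), "empty")

  rings <- c("AAAA", "AAAC", "AAAG")
  d <- ring_distance_matrix(rings)
  expect_true(all(d == t(d)) && all(diag(d) == 0))
  means <- rowSums(d) / 2
  bc <- barycenter(rings)
  expect_equal(bc$mean_distance, min(means))
  expect_true(bc$ring %in% rings)

  tie <- barycenter(c("AAAA", "AAAA", "AAAA"))
  expect_false(tie$unique)
  expect_equal(tie$mean_distance, 0)

  # medoid membership on random cohorts, all metrics
  rings <- generate_ring_cohort(8, 7, seed = 5)
  for (m in c("circular_hamming", "circular_edit")) {
    expect_true(barycenter(rings, m)$ring %in% rings)
  }
})
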