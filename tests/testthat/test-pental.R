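al <- al_sequence()

test_that("pentamer sets validate members and carry p = k/1024", {
  ps <- pentamer_set(c("AAAAA", "ACGUA"))
  expect_identical(ps$members[2], "ACGTA")
  expect_equal(ps$p, 2 / 1024)
  expect_equal(al_pentamers("al9")$p, 9 / 1024)
  expect_setequal(al_pentamers("al5")$members,
                  c("AGATG", "GATGA", "GTGGC", "TGGCC", "GGCCT"))
  expect_error(pentamer_set(c("AAAA")), "5-mers")
  expect_error(pentamer_set(c("AAAAA", "AAAAA")), "distinct")
  expect_error(pentamer_set(character(0)), "at least one")
})

test_that("count_matches agrees with the hand-rolled window scan", {
  expect_identical(count_matches("ACGTACGT"), 0L)
  expect_identical(count_matches(al), 5L)
  expect_identical(count_matches(al, topology = "circular"), 9L)
  expect_identical(count_matches("AAAAAA", pentamer_set("AAAAA")), 2L)
  expect_error(count_matches("ACG"), "at least 5")
  expect_error(count_matches("ACGTN"), "non-ACGT")

  set.seed(23)
  for (i in 1:30) {
    s <- random_seq(sample(5:80, 1))
    k <- sample(1:6, 1)
    members <- unique(vapply(1:k, function(j) random_seq(5), character(1)))
    ps <- pentamer_set(members)
    for (topo in c("linear", "circular")) {
      expect_identical(count_matches(s, ps, topo),
                       bf_count(s, members, topo),
                       info = paste(topo, s))
    }
  }
})

test_that("ppal_score implements the Poisson-null arithmetic", {
  r <- ppal_score(13, 552)
  expect_equal(r$n_e, 552 * 9 / 1024)
  expect_equal(r$sigma_e, sqrt(r$n_e))
  expect_equal(r$p_al, (13 - r$n_e) / r$sigma_e)
  expect_equal(r$Pp_al, 2 * r$p_al)
  expect_equal(round(r$Pp_al, 1), 7.4)

  # observed equals expected: score is exactly zero
  z <- ppal_score(9, 1024)
  expect_equal(z$n_e, 9)
  expect_equal(z$p_al, 0)
  expect_equal(z$Pp_al, 0)

  expect_error(ppal_score(5, 0), "degenerate")
  expect_error(ppal_score(-1, 10), "nonnegative")

  # strictly increasing in n_o at fixed N; decreasing in N for n_o > N p
  scores_no <- vapply(5:15, function(k) ppal_score(k, 500)$p_al, numeric(1))
  expect_true(all(diff(scores_no) > 0))
  scores_N <- vapply(c(300, 500, 800, 1200),
                     function(N) ppal_score(20, N)$p_al, numeric(1))
  expect_true(all(diff(scores_N) < 0))
})

test_that("score_sequence composes counting and scoring (N, not window count)", {
  r <- score_sequence(al, topology = "circular")
  expect_identical(r$n_o, 9L)
  expect_identical(r$N, 22L)
  expect_equal(r$n_e, 22 * 9 / 1024, tolerance = 1e-12)
  expect_equal(signif(r$sigma_e, 2), 0.44)
  expect_error(score_sequence(""), "degenerate|empty")
})

test_that("the Gaussian tail at 4 sigma is below 5e-5", {
  expect_lt(tail_probability(4), 5e-5)
  expect_equal(tail_probability(4), 3.167124e-05, tolerance = 1e-6)
  expect_equal(tail_probability(0), 0.5)
  expect_equal(tail_probability(50), 0)
})

test_that("gradient_report averages per molecule and sorts ascending", {
  df <- data.frame(
    molecule = rep(c("L18", "Helicase"), each = 4),
    species = rep(c("HS", "SC", "Mv", "Mmi"), 2),
    Pp_al = c(7.4, 10, 6, 9.8, 12.6, 26.6, 15.2, 18.2)
  )
  rep_ <- gradient_report(df)
  expect_identical(rep_$molecule, c("L18", "Helicase"))
  expect_equal(rep_$mean_Pp_al, c(8.3, 18.15))
  single <- gradient_report(data.frame(molecule = "x", species = "y",
                                       Pp_al = 3.2))
  expect_equal(single$mean_Pp_al, 3.2)
  empty <- gradient_report(data.frame(molecule = character(0),
                                      Pp_al = numeric(0)))
  expect_identical(nrow(empty), 0L)
})
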