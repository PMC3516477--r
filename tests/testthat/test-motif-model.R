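test_that("build_pwm applies background-proportional pseudocounts", {
  cm <- motif_counts(matrix(c(4, 0, 0, 0), nrow = 4,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm <- build_pwm(cm, background_model(), pseudocount_total = 1)
  expect_equal(as.numeric(pwm$probs), c(0.85, 0.05, 0.05, 0.05))
  expect_equal(unname(pwm$logodds["A", 1]), log(0.85 / 0.25), tolerance = 1e-9)
  expect_equal(unname(round(pwm$logodds["A", 1], 4)), 1.2238)

  flat <- build_pwm(
    motif_counts(matrix(1, nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL)))
  )
  expect_equal(as.numeric(flat$logodds), rep(0, 4))
})

test_that("a single consensus sequence yields a PWM of its length", {
  pwm <- build_pwm(sites_to_counts("ACACCCATACATT"))
  expect_equal(motif_length(pwm), 13)
  expect_equal(consensus_sequence(pwm), "ACACCCATACATT")
})

test_that("build_pwm without pseudocount reproduces ML frequencies and errors on zero columns", {
  cm <- motif_counts(matrix(c(3, 1, 0, 0, 2, 2, 2, 2), nrow = 4,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm <- build_pwm(cm, pseudocount_total = 0)
  expect_equal(pwm$probs[, 1], c(A = 0.75, C = 0.25, G = 0, T = 0))
  expect_equal(pwm$probs[, 2], c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))

  zero_col <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), nrow = 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(build_pwm(motif_counts(zero_col), pseudocount_total = 0),
               "undefined")
  # invariants hold for random PWMs
  set.seed(101)
  for (i in 1:10) {
    p <- random_pwm()
    expect_equal(colSums(p$probs), rep(1, motif_length(p)), tolerance = 1e-9)
    expect_equal(p$logodds, log(p$probs / as.numeric(p$background)),
                 tolerance = 1e-9)
  }
})

test_that("sites_to_counts tallies aligned sites and validates input", {
  cm <- sites_to_counts(c("AC", "AC", "AT"))
  expect_equal(unname(cm["C", 2]), 2)
  expect_equal(unname(cm["T", 2]), 1)
  expect_equal(unname(cm["A", 1]), 3)

  single <- sites_to_counts("ACACCCATACATT")
  expect_equal(motif_length(single), 13)
  expect_equal(colSums(unclass(single))[1:3], c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(unname(single["A", 1]), 1)
  expect_equal(unname(single["C", 2]), 1)

  weighted <- sites_to_counts(c("A", "C"), weights = c(3, 2))
  expect_equal(unname(weighted["A", 1]), 3)
  expect_equal(unname(weighted["C", 1]), 2)

  expect_error(sites_to_counts(c("AC", "ACG")), "same length")
  expect_error(sites_to_counts("ANA"), "non-ACGT")
  expect_error(sites_to_counts(character(0)), "non-empty")
})

test_that("information content matches analytic values and stays in [0, 2]", {
  mk <- function(col) {
    build_pwm(motif_counts(matrix(col, nrow = 4,
                                  dimnames = list(c("A", "C", "G", "T"), NULL))),
              pseudocount_total = 0)
  }
  expect_equal(information_content(mk(c(1, 0, 0, 0)))$bits, 2)
  expect_equal(information_content(mk(c(1, 1, 1, 1)))$bits, 0)
  expect_equal(information_content(mk(c(1, 1, 0, 0)))$bits, 1)
  set.seed(7)
  for (i in 1:10) {
    bits <- information_content(random_pwm())$bits
    expect_true(all(bits >= 0 & bits <= 2 + 1e-12))
  }
})

test_that("score_word sums per-position log-odds and rejects bad words", {
  set.seed(3)
  pwm <- random_pwm(L = 5)
  best_word <- paste(c("A", "C", "G", "T")[apply(pwm$logodds, 2, which.max)],
                     collapse = "")
  expect_equal(score_word(pwm, best_word), sum(apply(pwm$logodds, 2, max)))

  flat <- build_pwm(
    motif_counts(matrix(1, nrow = 4, ncol = 3,
                        dimnames = list(c("A", "C", "G", "T"), NULL)))
  )
  expect_equal(score_word(flat, "ACG"), 0)

  expect_error(score_word(pwm, "ACGTN"), "ambiguous")
  expect_error(score_word(pwm, "ACG"), "length")
})

test_that("exact score distribution matches analytic single-column cases", {
  one <- build_pwm(motif_counts(matrix(c(10, 1, 1, 1), nrow = 4,
                                       dimnames = list(c("A", "C", "G", "T"), NULL))))
  d1 <- exact_score_distribution(one)
  expect_equal(sum(d1$prob), 1, tolerance = 1e-6)
  expect_equal(pwm_pvalue(d1, sum(apply(one$logodds, 2, max))), 0.25)

  two <- build_pwm(motif_counts(matrix(c(10, 1, 1, 1, 1, 10, 1, 1), nrow = 4,
                                       dimnames = list(c("A", "C", "G", "T"), NULL))))
  d2 <- exact_score_distribution(two)
  expect_equal(pwm_pvalue(d2, sum(apply(two$logodds, 2, max))), 0.0625)
  expect_error(exact_score_distribution(two, granularity = 0), "positive")
})

test_that("p-values are monotone, bounded, and match enumeration on random PWMs", {
  set.seed(11)
  for (i in 1:8) {
    pwm <- random_pwm(L = sample(1:6, 1))
    d <- exact_score_distribution(pwm)
    expect_equal(sum(d$prob), 1, tolerance = 1e-6)
    smin <- min(d$bin) * d$granularity
    smax <- max(d$bin) * d$granularity
    expect_equal(pwm_pvalue(d, smin - 1), 1)
    expect_equal(pwm_pvalue(d, smax + 1), 0)
    grid <- seq(smin - 0.5, smax + 0.5, length.out = 60)
    pv <- pwm_pvalue(d, grid)
    expect_true(all(diff(pv) <= 1e-15))

    tail_fn <- enumeration_tail(pwm)
    slack <- (motif_length(pwm) / 2 + 1) * d$granularity
    probe <- seq(smin, smax, length.out = 15)
    expect_true(all(pwm_pvalue(d, probe) <= tail_fn(probe - slack) + 1e-12))
    expect_true(all(pwm_pvalue(d, probe) >= tail_fn(probe + slack) - 1e-12))
  }
})

test_that("threshold_for_pvalue is strict, attains boundaries, and signals unattainable levels", {
  two <- build_pwm(motif_counts(matrix(c(10, 1, 1, 1, 1, 10, 1, 1), nrow = 4,
                                       dimnames = list(c("A", "C", "G", "T"), NULL))))
  d <- exact_score_distribution(two)

  # alpha = 1: minimum support score plus one bin
  t1 <- threshold_for_pvalue(d, 1)
  expect_equal(t1, (min(d$bin) + 1) * d$granularity, tolerance = 1e-12)

  # with P(max word) = 0.0625 the strict rule makes any alpha <= 0.0625
  # unattainable: even the best word has p-value 0.0625
  expect_identical(threshold_for_pvalue(d, 0.05), Inf)
  expect_identical(threshold_for_pvalue(d, 0.01), Inf)

  # just above P(max word) the threshold sits between the runner-up and the
  # maximal word; cross-checked against exhaustive enumeration
  t07 <- threshold_for_pvalue(d, 0.07)
  tail_fn <- enumeration_tail(two)
  max_score <- sum(apply(two$logodds, 2, max))
  expect_lte(t07, max_score + d$granularity)
  expect_lt(tail_fn(t07 + d$granularity), 0.07)
  expect_gte(tail_fn(t07 - 2 * d$granularity), 0.07)
  expect_error(threshold_for_pvalue(d, 0), "0, 1")
})

test_that("score distribution cache round-trips through TSV", {
  pwm <- rap1_test_pwm()
  d <- exact_score_distribution(pwm)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_distribution(d, path)
  d2 <- read_score_distribution(path)
  expect_equal(d2$granularity, d$granularity)
  expect_equal(d2$bin, d$bin)
  expect_equal(d2$prob, d$prob)
  probe <- c(-5, 0, 5, 10, 17)
  expect_equal(pwm_pvalue(d2, probe), pwm_pvalue(d, probe))
})
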