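mk_matches <- function(positions, region = "r1", chrom = "chrI", motif = "M") {
  tibble::tibble(
    motif_id = motif, region_id = region, chromosome = chrom,
    position = as.integer(positions)
  )
}

test_that("proto-silencer pairing respects the distance window boundary", {
  r <- mk_matches(100, motif = "RAP1")
  expect_equal(nrow(find_proto_silencers(r, mk_matches(151, motif = "ABF1"))), 0)
  at50 <- find_proto_silencers(r, mk_matches(150, motif = "ABF1"))
  expect_equal(nrow(at50), 1)
  expect_equal(at50$distance, 50)
  expect_error(find_proto_silencers(r, r, window = -1), "non-negative")
})

test_that("all qualifying pairs are reported and pairing is symmetric and order-invariant", {
  r <- mk_matches(100, motif = "RAP1")
  a <- mk_matches(c(90, 140), motif = "ABF1")
  both <- find_proto_silencers(r, a)
  expect_equal(nrow(both), 2)
  expect_equal(sort(both$abf1_position), c(90L, 140L))

  swapped <- find_proto_silencers(a, r)
  expect_equal(nrow(swapped), 2)
  expect_setequal(swapped$rap1_position, both$abf1_position)
  expect_setequal(swapped$abf1_position, both$rap1_position)

  shuffled <- find_proto_silencers(r, a[2:1, ])
  expect_equal(shuffled, both)

  # different regions never pair
  far <- mk_matches(100, region = "r2", motif = "ABF1")
  expect_equal(nrow(find_proto_silencers(r, far)), 0)
})

test_that("widening the window only adds pairs", {
  set.seed(17)
  r <- mk_matches(sample(1:500, 30))
  a <- mk_matches(sample(1:500, 30), motif = "ABF1")
  key <- function(df) paste(df$rap1_position, df$abf1_position)
  for (w in c(10, 25, 50, 100)) {
    small <- find_proto_silencers(r, a, window = w)
    big <- find_proto_silencers(r, a, window = w * 2)
    expect_true(all(key(small) %in% key(big)))
  }
})

test_that("chi-squared 2x2 matches the closed form and stats::chisq.test", {
  id <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)

  skew <- chi_square_2x2(matrix(c(20, 10, 10, 20), 2))
  expect_equal(skew$statistic, 60 * (400 - 100)^2 / (30 * 30 * 30 * 30))
  expect_equal(round(skew$statistic, 4), 6.6667)

  expect_error(chi_square_2x2(matrix(c(0, 5, 0, 5), 2)), "marginal")

  set.seed(23)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi_square_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    ours_y <- chi_square_2x2(tab, yates = TRUE)
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours_y$statistic, unname(ref_y$statistic), tolerance = 1e-12)
  }

  # p decreases as the association |ad - bc| grows at fixed marginals
  stats_seq <- vapply(0:5, function(k) {
    chi_square_2x2(matrix(c(10 + k, 10 - k, 10 - k, 10 + k), 2))$p_value
  }, numeric(1))
  expect_true(all(diff(stats_seq) < 0))
})

mk_calls <- function(conserved, region_prefix = "g", motif = "RAP1") {
  n <- length(conserved)
  tibble::tibble(
    motif_id = motif,
    region_id = paste0(region_prefix, seq_len(n)),
    chromosome = "chrI",
    position = seq_len(n) * 100L,
    strand = "+",
    conserved = conserved
  )
}

test_that("conservation comparison separates classes and excludes overlap from genome-wide", {
  null_cmp <- compare_conservation(
    mk_calls(rep(c(TRUE, FALSE), each = 100)),
    mk_calls(rep(c(TRUE, FALSE), each = 25), region_prefix = "p")
  )
  expect_gt(null_cmp$test$p_value, 0.9)

  sep <- compare_conservation(
    mk_calls(rep(FALSE, 50)),
    mk_calls(rep(TRUE, 50), region_prefix = "p")
  )
  expect_lt(sep$test$p_value, 0.05)

  # proto-silencer sites do not double-count in the genome-wide cell
  gw <- mk_calls(rep(TRUE, 60))
  proto <- gw[1:10, ]
  proto$conserved <- FALSE # same sites, recoded, must displace the gw copies
  cmp <- compare_conservation(gw, proto)
  expect_equal(cmp$fractions$n, c(10L, 50L))
  expect_equal(sum(cmp$table), 60)

  g <- glance(cmp)
  expect_equal(g$n_genome_wide, 50L)
  expect_equal(nrow(tidy(cmp)), 2)

  expect_error(compare_conservation(gw[0, ], proto), "non-empty")
})

test_that("conservation_fraction averages the conserved flags", {
  expect_equal(conservation_fraction(mk_calls(rep(TRUE, 5))), 1)
  expect_equal(conservation_fraction(mk_calls(rep(FALSE, 4))), 0)
  expect_equal(conservation_fraction(c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_error(conservation_fraction(logical(0)), "zero calls")
})

test_that("transcription-factor filtering applies strict p and inclusive region thresholds", {
  chip <- dplyr::bind_rows(
    tibble::tibble(factor = "KEEP60", region_id = paste0("r", 1:60), p = 0.01),
    tibble::tibble(factor = "DROP59", region_id = paste0("r", 1:59), p = 0.01),
    tibble::tibble(factor = "BOUNDARY", region_id = paste0("r", 1:60), p = 0.05),
    tibble::tibble(factor = "JUSTUNDER", region_id = paste0("r", 1:60), p = 0.049999)
  )
  kept <- filter_tf_sets(chip)
  expect_setequal(unique(kept$factor), c("KEEP60", "JUSTUNDER"))
  expect_equal(sum(kept$factor == "KEEP60"), 60)

  # duplicated regions count once
  dup <- tibble::tibble(
    factor = "DUP", region_id = rep(paste0("r", 1:30), 2), p = 0.01
  )
  expect_equal(nrow(filter_tf_sets(dup, min_regions = 31)), 0)
  expect_equal(nrow(filter_tf_sets(dup, min_regions = 30)), 30)

  # invariant: no kept factor violates either threshold
  set.seed(8)
  rand <- tibble::tibble(
    factor = sample(LETTERS[1:6], 600, TRUE),
    region_id = sample(paste0("r", 1:150), 600, TRUE),
    p = runif(600)
  )
  out <- filter_tf_sets(rand, p_max = 0.5, min_regions = 20)
  expect_true(all(out$p < 0.5))
  counts <- dplyr::count(dplyr::distinct(out, factor, region_id), factor)
  expect_true(all(counts$n >= 20))
})

test_that("motif frequency is matches per bound length times the scale", {
  regions <- tibble::tibble(
    region_id = c("r1", "r2", "r3"),
    start = c(1L, 1L, 1L),
    end = c(5000L, 5000L, 5000L)
  )
  tf <- tibble::tibble(factor = "TF1", region_id = c("r1", "r2", "r3"), p = 0.01)
  matches <- tibble::tibble(
    motif_id = "ABF1",
    region_id = c("r1", "r1", "r2"),
    position = c(10L, 200L, 50L)
  )
  fr <- motif_frequency(tf, matches, regions)
  expect_equal(fr$n_matches, 3L)
  expect_equal(fr$total_length, 15000)
  expect_equal(fr$freq_per_10kb, 2)

  none <- motif_frequency(tf, matches[0, ], regions)
  expect_equal(nrow(none), 0) # no motifs at all -> nothing to tabulate

  other <- motif_frequency(
    tf, dplyr::mutate(matches, region_id = "r9"), regions
  )
  expect_equal(other$n_matches, 0L)
  expect_equal(other$freq_per_10kb, 0)

  zero_len <- dplyr::mutate(regions, end = start - 1L)
  zero_len$end[1] <- 0L
  expect_error(
    motif_frequency(tf, matches, dplyr::mutate(regions, start = 1L, end = 0L)),
    "end < start|zero total length|non-negative"
  )
})
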