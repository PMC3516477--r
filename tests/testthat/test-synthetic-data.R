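small_config <- function(...) {
  simulation_config(n_regions = 30, seed = 404, ...)
}

test_that("cohort generation is a pure function of the configuration", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(a$regions, b$regions)
  expect_identical(a$truth, b$truth)
  expect_identical(a$similarities, b$similarities)
  expect_identical(a$chip, b$chip)

  different <- generate_cohort(simulation_config(n_regions = 30, seed = 405))
  expect_false(identical(a$regions$sequence, different$regions$sequence))
})

test_that("zero divergence and full retention reproduce the ancestor in every species", {
  co <- generate_cohort(
    simulation_config(
      n_regions = 10, substitution_prob = 0, site_retention_prob = 1, seed = 2
    )
  )
  ref <- dplyr::filter(co$regions, species == co$reference)
  for (sp in setdiff(co$species, co$reference)) {
    other <- dplyr::filter(co$regions, species == sp)
    expect_identical(other$sequence, ref$sequence)
  }
})

test_that("planting controls are honoured", {
  none <- generate_cohort(small_config(planting_rate = 0))
  expect_equal(nrow(none$truth), 0)

  # a planting rate far beyond region capacity cannot be placed
  expect_error(
    generate_cohort(simulation_config(
      n_regions = 2, region_length_meanlog = log(60), region_length_sdlog = 0,
      planting_rate = 40, seed = 3
    )),
    "density too high"
  )
})

test_that("planted truth positions lie inside their regions and sites match the sequence", {
  co <- generate_cohort(small_config())
  ref <- dplyr::filter(co$regions, species == co$reference)
  joined <- dplyr::inner_join(
    co$truth, ref, by = "region_id", suffix = c("", ".region")
  )
  expect_equal(nrow(joined), nrow(co$truth))
  L <- nchar(joined$site_seq)
  expect_true(all(joined$position >= 1))
  expect_true(all(joined$position + L - 1 <= joined$end))
  embedded <- substr(joined$sequence, joined$position, joined$position + L - 1)
  expected <- ifelse(joined$strand == "+", joined$site_seq,
                     reverse_complement(joined$site_seq))
  expect_identical(embedded, expected)

  # retained sites are intact in the derived species sequence
  spar <- dplyr::filter(co$regions, species == "Spar")
  j2 <- dplyr::inner_join(
    dplyr::mutate(co$truth, spar_id = sub("_Scer$", "_Spar", region_id)),
    spar,
    by = c("spar_id" = "region_id")
  )
  kept <- dplyr::filter(j2, retained_Spar)
  emb <- substr(kept$sequence, kept$position, kept$position + nchar(kept$site_seq) - 1)
  exp_site <- ifelse(kept$strand == "+", kept$site_seq,
                     reverse_complement(kept$site_seq))
  expect_identical(emb, exp_site)
})

test_that("the ChIP table emulates the binding filter's two regimes", {
  co <- generate_cohort(simulation_config(n_regions = 100, seed = 9))
  chip <- emit_chip_table(co, n_factors = 3, bound_fraction = 0.7, seed = 31)
  expect_true(all(chip$p[chip$bound] < 0.05))
  expect_true(all(chip$p[!chip$bound] >= 0.05))
  kept <- filter_tf_sets(chip, p_max = 0.05, min_regions = 60)
  expect_setequal(unique(kept$factor), c("TF01", "TF02", "TF03"))

  sparse <- emit_chip_table(co, n_factors = 2, bound_fraction = 0.1, seed = 31)
  expect_equal(nrow(filter_tf_sets(sparse, min_regions = 60)), 0)

  expect_identical(
    emit_chip_table(co, n_factors = 3, bound_fraction = 0.7, seed = 31),
    chip
  )
  expect_error(emit_chip_table(co, n_factors = 0), ">= 1")
})

test_that("noise-free similarities recover the orthology truth exactly", {
  co <- generate_cohort(small_config())
  orth <- rbh_orthology(
    co$similarities,
    dplyr::select(co$regions, region_id, species, left_gene, right_gene),
    reference = co$reference
  )
  truth <- dplyr::arrange(co$orthology, region_id, species)
  expect_equal(dplyr::arrange(orth, region_id, species), truth)
  expect_error(perturb_similarities(co, noise_prob = 1), "\\[0, 1\\)")
})

test_that("10% similarity noise still recovers at least 80% of orthologous regions", {
  co <- generate_cohort(simulation_config(n_regions = 50, seed = 11))
  noisy <- perturb_similarities(co, noise_prob = 0.1, seed = 11)
  orth <- rbh_orthology(
    noisy,
    dplyr::select(co$regions, region_id, species, left_gene, right_gene),
    reference = co$reference
  )
  correct <- dplyr::inner_join(
    orth, co$orthology,
    by = c("region_id", "species", "ortho_region_id")
  )
  recovery <- nrow(correct) / nrow(co$orthology)
  expect_gte(recovery, 0.8)
  # and nothing recovered is wrong
  expect_equal(nrow(correct), nrow(orth))
})

test_that("scanning a cohort recovers retained exact-consensus sites with a controlled false-positive rate", {
  pwm <- rap1_test_pwm()
  co <- generate_cohort(simulation_config(
    n_regions = 150, motifs = list(RAP1 = pwm), seed = 77
  ))
  alpha <- 1e-6
  exact <- dplyr::filter(co$truth, site_seq == rap1_consensus())
  expect_gt(nrow(exact), 50)

  ref <- dplyr::filter(co$regions, species == co$reference)
  m <- scan_region_set(pwm, ref, alpha)
  planted_found <- dplyr::semi_join(
    exact, m,
    by = c("region_id", "position", "strand")
  )
  expect_equal(nrow(planted_found), nrow(exact)) # 100% recall of exact sites

  # false positives per scanned window, away from any planted site
  L <- motif_length(pwm)
  off_target <- dplyr::anti_join(
    m,
    dplyr::mutate(co$truth, lo = position - L + 1, hi = position + L - 1),
    by = "region_id"
  )
  fp_in_planted_regions <- dplyr::inner_join(
    m, dplyr::select(co$truth, region_id, tpos = position),
    by = "region_id", relationship = "many-to-many"
  ) |>
    dplyr::group_by(region_id, position, strand) |>
    dplyr::summarise(near = any(abs(position - tpos) < L), .groups = "drop") |>
    dplyr::filter(!near)
  n_fp <- nrow(off_target) + nrow(fp_in_planted_regions)
  n_windows <- sum(2 * (nchar(ref$sequence) - L + 1))
  bound <- n_windows * alpha + 3 * sqrt(n_windows * alpha)
  expect_lte(n_fp, max(bound, 3))
})
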