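# Shared test helpers: random fixtures and the independent oracles that
# the dynamic-programming p-values and the vectorised scanner are checked
# against.

random_background <- function() {
  f <- stats::runif(4, 0.5, 2)
  background_model(stats::setNames(f / sum(f), c("A", "C", "G", "T")))
}

random_pwm <- function(L = NULL, background = NULL, motif_id = "random") {
  if (is.null(L)) L <- sample(1:8, 1)
  if (is.null(background)) background <- random_background()
  counts <- matrix(stats::rpois(4 * L, 5) + stats::runif(4 * L), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  build_pwm(motif_counts(counts, motif_id), background,
            pseudocount_total = stats::runif(1, 0.1, 2))
}

random_dna_string <- function(n, gc = 0.38) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exhaustive enumeration oracle: exact scores of all 4^L words and their
# background probabilities, with no discretisation. Returns a function
# giving P(score >= t) for any t.
enumeration_tail <- function(pwm) {
  lo <- pwm$logodds
  bg <- as.numeric(pwm$background)
  scores <- 0
  probs <- 1
  for (i in seq_len(ncol(lo))) {
    scores <- as.vector(outer(scores, lo[, i], "+"))
    probs <- as.vector(outer(probs, bg, "*"))
  }
  function(t) vapply(t, function(ti) sum(probs[scores >= ti]), numeric(1))
}

# Naive window-rescoring scanner oracle: substring every window, score it
# with score_word(), keep p < alpha, with the same coordinate/strand and
# ordering conventions the scanner documents.
naive_scan_region <- function(pwm, region, alpha, dist) {
  L <- motif_length(pwm)
  seq <- toupper(region$sequence)
  n <- nchar(seq)
  rows <- list()
  if (n >= L) {
    for (j in seq_len(n - L + 1)) {
      word_f <- substr(seq, j, j + L - 1)
      for (strand in c("+", "-")) {
        word <- if (strand == "+") word_f else reverse_complement(word_f)
        if (grepl("[^ACGT]", word)) next
        s <- score_word(pwm, word)
        pv <- pwm_pvalue(dist, s)
        if (pv < alpha) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            motif_id = pwm$motif_id, region_id = region$region_id,
            chromosome = region$chromosome,
            position = as.integer(region$start + j - 1),
            strand = strand, score = s, pvalue = pv
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      motif_id = character(), region_id = character(), chromosome = character(),
      position = integer(), strand = character(), score = numeric(),
      pvalue = numeric()
    ))
  }
  dplyr::arrange(out, position, match(strand, c("+", "-")))
}

naive_scan_set <- function(pwm, regions, alpha) {
  dist <- exact_score_distribution(pwm)
  out <- dplyr::bind_rows(lapply(
    seq_len(nrow(regions)),
    function(i) naive_scan_region(pwm, as.list(regions[i, ]), alpha, dist)
  ))
  dplyr::arrange(out, chromosome, position, match(strand, c("+", "-")))
}

make_region <- function(sequence, region_id = "r1", chromosome = "chrI",
                        start = 1L, species = "Scer") {
  tibble::tibble(
    region_id = region_id, species = species, chromosome = chromosome,
    start = as.integer(start),
    end = as.integer(start + nchar(sequence) - 1L),
    sequence = sequence
  )
}

rap1_test_pwm <- function(weights = 100) {
  build_pwm(
    sites_to_counts(rap1_consensus(), weights = weights, motif_id = "RAP1"),
    background_model(gc_background(0.38))
  )
}
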