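#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. `N` complements to `N`. Vectorised.
#'
#' @param seq Character vector of DNA strings over ACGTN (case kept upper).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACACCCATACATT")
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) {
    abort("`seq` contains characters outside ACGTN.")
  }
  vapply(
    seq,
    function(s) {
      x <- rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]])
      paste(x, collapse = "")
    },
    character(1),
    USE.NAMES = FALSE
  )
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
}

# Window scores of a PWM along an encoded sequence. Accumulates column by
# column with plain double additions in position order, so each window's
# score is bit-identical to score_word() on the same word. Windows touching
# an N (code 5) or invalid character come back NA.
window_scores <- function(logodds, codes) {
  L <- ncol(logodds)
  nw <- length(codes) - L + 1
  if (nw < 1) {
    return(numeric(0))
  }
  s <- numeric(nw)
  for (i in seq_len(L)) {
    col <- c(unname(logodds[, i]), NA_real_)
    block <- codes[i:(i + nw - 1)]
    block[is.na(block)] <- 5L
    s <- s + col[block]
  }
  s
}

as_region_list <- function(region) {
  if (is.data.frame(region)) {
    if (nrow(region) != 1) abort("`region` must be a single region (one row).")
    region <- as.list(region)
  }
  needed <- c("region_id", "chromosome", "start", "end", "sequence")
  missing <- setdiff(needed, names(region))
  if (length(missing) > 0) {
    abort(paste0("Region is missing field(s): ", paste(missing, collapse = ", ")))
  }
  if (region$end < region$start) abort("Region end must be >= start.")
  if (nchar(region$sequence) != region$end - region$start + 1) {
    abort(sprintf(
      "Region %s: sequence length %d does not match end - start + 1 = %d.",
      region$region_id, nchar(region$sequence), region$end - region$start + 1
    ))
  }
  region
}

empty_matches <- function() {
  tibble::tibble(
    motif_id = character(),
    region_id = character(),
    chromosome = character(),
    position = integer(),
    strand = character(),
    score = numeric(),
    pvalue = numeric()
  )
}

#' Scan one region for PWM matches
#'
#' Scores every window of motif length on the forward strand and (by
#' default) the reverse strand, and reports those with exact p-value
#' strictly below `alpha`. Positions are 1-based genomic coordinates of
#' the match's leftmost base on the forward strand, for either strand.
#' Windows containing `N` are skipped. Overlapping and same-position
#' matches are all reported; output is sorted by position, then strand
#' (`+` before `-`).
#'
#' @param pwm A `pwm` object.
#' @param region One region: a one-row tibble or named list with
#'   `region_id`, `chromosome`, `start`, `end`, `sequence` (1-based
#'   inclusive coordinates, `nchar(sequence) == end - start + 1`).
#' @param alpha Matches must have p-value `< alpha` (strict).
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @param dist Optional precomputed [exact_score_distribution()] for
#'   `pwm` (saves recomputation when scanning many regions).
#' @return Tibble of matches with columns `motif_id`, `region_id`,
#'   `chromosome`, `position`, `strand`, `score`, `pvalue`.
#' @export
scan_sequence <- function(pwm, region, alpha, both_strands = TRUE, dist = NULL) {
  region <- as_region_list(region)
  if (is.null(dist)) dist <- exact_score_distribution(pwm)
  L <- motif_length(pwm)
  codes <- encode_dna(region$sequence)
  n <- length(codes)
  if (n < L) {
    return(empty_matches())
  }

  fwd <- window_scores(pwm$logodds, codes)
  pos_fwd <- region$start + seq_along(fwd) - 1L
  keep_f <- !is.na(fwd) & pwm_pvalue(dist, fwd) < alpha

  res <- tibble::tibble(
    position = pos_fwd[keep_f],
    strand = rep("+", sum(keep_f)),
    score = fwd[keep_f]
  )

  if (both_strands) {
    rc_codes <- rev(c(4L, 3L, 2L, 1L, 5L)[codes])
    rev_sc <- window_scores(pwm$logodds, rc_codes)
    # window k on the reverse-complement starts (leftmost, forward strand)
    # at forward index n - k - L + 2
    pos_rev <- region$start + (n - seq_along(rev_sc) - L + 2L) - 1L
    keep_r <- !is.na(rev_sc) & pwm_pvalue(dist, rev_sc) < alpha
    res <- dplyr::bind_rows(
      res,
      tibble::tibble(
        position = pos_rev[keep_r],
        strand = rep("-", sum(keep_r)),
        score = rev_sc[keep_r]
      )
    )
  }

  res <- dplyr::arrange(res, .data$position, match(.data$strand, c("+", "-")))
  tibble::tibble(
    motif_id = rep(pwm$motif_id, nrow(res)),
    region_id = rep(region$region_id, nrow(res)),
    chromosome = rep(region$chromosome, nrow(res)),
    position = as.integer(res$position),
    strand = res$strand,
    score = res$score,
    pvalue = pwm_pvalue(dist, res$score)
  )
}

#' Scan a set of regions for PWM matches
#'
#' Per-region scans concatenated, ordered deterministically by
#' (chromosome, position, strand).
#'
#' @param pwm A `pwm` object.
#' @param regions Regions tibble with columns `region_id`, `chromosome`,
#'   `start`, `end`, `sequence` (unique `region_id`s).
#' @param alpha Strict p-value cutoff.
#' @param both_strands Scan both strands (default `TRUE`).
#' @param dist Optional precomputed score distribution.
#' @return Tibble of matches (see [scan_sequence()]).
#' @export
scan_region_set <- function(pwm, regions, alpha, both_strands = TRUE, dist = NULL) {
  if (nrow(regions) == 0) {
    return(empty_matches())
  }
  if (anyDuplicated(regions$region_id)) {
    abort("`regions` has duplicate region_id values.")
  }
  if (is.null(dist)) dist <- exact_score_distribution(pwm)
  out <- purrr::map(
    seq_len(nrow(regions)),
    function(i) scan_sequence(pwm, regions[i, ], alpha, both_strands, dist)
  )
  out <- dplyr::bind_rows(out)
  dplyr::arrange(
    out, .data$chromosome, .data$position, match(.data$strand, c("+", "-"))
  )
}
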