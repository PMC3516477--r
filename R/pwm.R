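#' @importFrom rlang abort warn .data .env
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Define a mononucleotide background model
#'
#' A background model is the set of base frequencies a motif score is
#' compared against; every log-odds score in this package is relative to
#' one of these.
#'
#' @param freqs Named numeric vector of length 4 (names `A`, `C`, `G`, `T`),
#'   strictly positive, summing to 1 within `1e-9`. Default is uniform.
#' @return A named numeric vector of class `background_model`.
#' @examples
#' background_model()
#' background_model(gc_background(0.38))
#' @export
background_model <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.numeric(freqs) || length(freqs) != 4) {
    abort("`freqs` must be a numeric vector of length 4.")
  }
  if (is.null(names(freqs)) || !setequal(names(freqs), DNA_BASES)) {
    abort("`freqs` must be named with A, C, G, T.")
  }
  freqs <- freqs[DNA_BASES]
  if (any(freqs <= 0)) abort("All background frequencies must be > 0.")
  if (abs(sum(freqs) - 1) > 1e-9) abort("Background frequencies must sum to 1.")
  structure(freqs, class = "background_model")
}

#' Background frequencies for a given GC content
#'
#' @param gc GC fraction in (0, 1); yeast intergenic sequence is about 0.38.
#' @return Named frequency vector suitable for [background_model()].
#' @export
gc_background <- function(gc = 0.38) {
  stopifnot(gc > 0, gc < 1)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' Estimate a background model from sequences
#'
#' Mononucleotide frequencies over a set of sequences (the scanned region
#' set is the natural choice). Non-ACGT characters are ignored.
#'
#' @param sequences Character vector of DNA sequences, or a regions tibble
#'   with a `sequence` column.
#' @return A `background_model`.
#' @export
estimate_background <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  chars <- unlist(strsplit(toupper(paste(sequences, collapse = "")), "", fixed = TRUE))
  counts <- table(factor(chars, levels = DNA_BASES))
  n <- sum(counts)
  if (n == 0) abort("No ACGT characters found; cannot estimate background.")
  background_model(setNames(as.numeric(counts) / n, DNA_BASES))
}

#' Tally aligned binding sites into a count matrix
#'
#' @param aligned_sites Character vector of equal-length DNA strings over
#'   ACGT (one aligned binding site each).
#' @param weights Optional per-site weights (default 1 each).
#' @param motif_id Motif identifier stored on the result.
#' @return A `motif_counts` object: a 4 x L count matrix (rows A/C/G/T)
#'   with the motif id attached.
#' @examples
#' sites_to_counts(c("AC", "AC", "AT"))
#' @export
sites_to_counts <- function(aligned_sites, weights = NULL, motif_id = "motif") {
  if (length(aligned_sites) == 0) abort("`aligned_sites` must be non-empty.")
  aligned_sites <- toupper(aligned_sites)
  lens <- nchar(aligned_sites)
  if (length(unique(lens)) != 1) {
    abort("All aligned sites must have the same length.")
  }
  L <- lens[[1]]
  if (L < 1) abort("Sites must have length >= 1.")
  if (is.null(weights)) weights <- rep(1, length(aligned_sites))
  if (length(weights) != length(aligned_sites) || any(weights < 0)) {
    abort("`weights` must be non-negative, one per site.")
  }
  mat <- matrix(0, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  split_sites <- strsplit(aligned_sites, "", fixed = TRUE)
  for (s in seq_along(split_sites)) {
    idx <- match(split_sites[[s]], DNA_BASES)
    if (anyNA(idx)) {
      abort(sprintf("Site %d contains a non-ACGT character.", s))
    }
    mat[cbind(idx, seq_len(L))] <- mat[cbind(idx, seq_len(L))] + weights[[s]]
  }
  new_motif_counts(mat, motif_id)
}

new_motif_counts <- function(mat, motif_id) {
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  rownames(mat) <- DNA_BASES
  structure(mat, motif_id = motif_id, class = c("motif_counts", "matrix", "array"))
}

#' Construct a motif count matrix directly
#'
#' @param counts 4 x L non-negative numeric matrix; rows must be named
#'   A, C, G, T (any order; they are reordered).
#' @param motif_id Motif identifier.
#' @return A `motif_counts` object.
#' @export
motif_counts <- function(counts, motif_id = "motif") {
  if (!is.matrix(counts) || nrow(counts) != 4) {
    abort("`counts` must be a 4-row matrix (A, C, G, T).")
  }
  if (is.null(rownames(counts)) || !setequal(rownames(counts), DNA_BASES)) {
    abort("`counts` rows must be named A, C, G, T.")
  }
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (all(colSums(counts) <= 0)) abort("At least one position must have a positive total.")
  new_motif_counts(counts, motif_id)
}

#' Build a position weight matrix from counts
#'
#' Converts base counts to per-position probabilities with a
#' background-proportional pseudocount, and to natural-log odds against
#' the background:
#' `probs[b, i] = (counts[b, i] + pseudocount_total * background[b]) /
#' (total_i + pseudocount_total)` and
#' `logodds[b, i] = ln(probs[b, i] / background[b])`.
#'
#' @param counts A `motif_counts` object (see [sites_to_counts()],
#'   [motif_counts()], [read_motif_counts()]).
#' @param background A [background_model()]; default uniform.
#' @param pseudocount_total Total pseudocount added per column, shared
#'   across bases in proportion to the background (default 1, the
#'   PATSER-family convention). With 0, columns containing a zero count
#'   yield `-Inf` log-odds; an all-zero column is an error.
#' @return A `pwm` object with elements `motif_id`, `probs` (4 x L),
#'   `logodds` (4 x L, natural log), `background`, `pseudocount_total`.
#' @examples
#' cm <- sites_to_counts("ACACCCATACATT", motif_id = "RAP1_consensus")
#' pwm <- build_pwm(cm)
#' motif_length(pwm)
#' @export
build_pwm <- function(counts, background = background_model(), pseudocount_total = 1) {
  if (!inherits(counts, "motif_counts")) counts <- motif_counts(counts)
  background <- background_model(unclass(background))
  if (pseudocount_total < 0) abort("`pseudocount_total` must be >= 0.")
  cm <- unclass(counts)
  attr(cm, "motif_id") <- NULL
  totals <- colSums(cm)
  if (pseudocount_total == 0 && any(totals == 0)) {
    abort("All-zero count column with pseudocount_total = 0: probabilities undefined.")
  }
  L <- ncol(cm)
  probs <- (cm + pseudocount_total * as.numeric(background)) /
    rep(totals + pseudocount_total, each = 4)
  logodds <- log(probs / as.numeric(background))
  structure(
    list(
      motif_id = attr(counts, "motif_id"),
      probs = probs,
      logodds = logodds,
      background = background,
      pseudocount_total = pseudocount_total
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s  (length %d, pseudocount %.3g)\n",
    x$motif_id, motif_length(x), x$pseudocount_total
  ))
  cat("consensus:", consensus_sequence(x), "\n")
  invisible(x)
}

#' Motif length of a PWM or count matrix
#' @param x A `pwm` or `motif_counts` object.
#' @return Integer number of positions.
#' @export
motif_length <- function(x) {
  if (inherits(x, "pwm")) ncol(x$probs) else ncol(x)
}

#' Majority-base consensus string of a PWM
#' @param pwm A `pwm` object.
#' @return Single character string.
#' @export
consensus_sequence <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Per-position information content in bits
#'
#' `bits[i] = 2 + sum_b p[b, i] log2 p[b, i]` with `0 log 0 := 0`; the
#' per-position heights of a sequence logo. Bounded by `[0, 2]`.
#'
#' @param pwm A `pwm` object.
#' @return Tibble with columns `position` and `bits`.
#' @export
information_content <- function(pwm) {
  p <- pwm$probs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  tibble::tibble(
    position = seq_len(ncol(p)),
    bits = 2 + colSums(plogp)
  )
}

#' Log-odds score of a single word
#'
#' @param pwm A `pwm` object.
#' @param word DNA string over ACGT of exactly the motif length. Ambiguous
#'   bases (such as N) are not scorable and raise an error; window-skipping
#'   policy belongs to the caller (scanners skip such windows).
#' @return Numeric score (sum of per-position natural-log odds).
#' @export
score_word <- function(pwm, word) {
  word <- toupper(word)
  L <- motif_length(pwm)
  if (nchar(word) != L) {
    abort(sprintf("`word` must have length %d, got %d.", L, nchar(word)))
  }
  idx <- match(strsplit(word, "", fixed = TRUE)[[1]], DNA_BASES)
  if (anyNA(idx)) abort("`word` contains an ambiguous or invalid base; cannot score.")
  lo <- pwm$logodds
  s <- 0
  for (i in seq_len(L)) s <- s + lo[idx[[i]], i]
  unname(s)
}

#' @rdname tidiers
#' @method tidy pwm
#' @export
tidy.pwm <- function(x, ...) {
  L <- motif_length(x)
  tibble::tibble(
    position = rep(seq_len(L), each = 4),
    base = rep(DNA_BASES, L),
    prob = as.numeric(x$probs),
    logodds = as.numeric(x$logodds)
  )
}

#' @rdname tidiers
#' @method glance pwm
#' @export
glance.pwm <- function(x, ...) {
  ic <- information_content(x)
  tibble::tibble(
    motif_id = x$motif_id,
    length = motif_length(x),
    total_bits = sum(ic$bits),
    max_score = sum(apply(x$logodds, 2, max)),
    min_score = sum(apply(x$logodds, 2, min))
  )
}
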