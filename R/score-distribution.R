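#' Exact score distribution of a PWM under its background
#'
#' Dynamic programme over the discretised per-position score
#' distributions: each column's four log-odds scores are rounded to the
#' nearest multiple of `granularity` and convolved column by column under
#' the background base probabilities. The result is the exact null
#' distribution of the score of a random background word of motif length,
#' up to discretisation, from which match p-values are read.
#'
#' @param pwm A `pwm` object.
#' @param granularity Score units per integer bin (> 0). Default is the
#'   total score range (sum over columns of max minus min log-odds)
#'   divided by 10,000, which keeps the discretisation error far below
#'   the p-value regimes of interest for motifs up to tens of bases.
#' @return A `score_distribution` object: integer bin support, bin
#'   probabilities (summing to 1 within 1e-6), the granularity, and the
#'   motif length. Bin `b` represents score `b * granularity`.
#' @examples
#' pwm <- build_pwm(sites_to_counts("ACGT"))
#' d <- exact_score_distribution(pwm)
#' pwm_pvalue(d, score_word(pwm, "ACGT"))
#' @export
exact_score_distribution <- function(pwm, granularity = NULL) {
  lo <- pwm$logodds
  L <- ncol(lo)
  col_max <- apply(lo, 2, max)
  col_min <- apply(lo, 2, min)
  if (is.null(granularity)) {
    granularity <- sum(col_max - col_min) / 10000
    if (granularity <= 0) granularity <- 1e-4 # uninformative PWM: all scores 0
  }
  if (!is.numeric(granularity) || length(granularity) != 1 || granularity <= 0) {
    abort("`granularity` must be a single positive number.")
  }
  bg <- as.numeric(pwm$background)
  bins <- round(lo / granularity)
  pmf <- 1
  offset <- 0
  for (i in seq_len(L)) {
    bi <- bins[, i]
    lo_i <- min(bi)
    out <- numeric(length(pmf) + (max(bi) - lo_i))
    for (b in 1:4) {
      sh <- bi[[b]] - lo_i
      rng <- (1 + sh):(length(pmf) + sh)
      out[rng] <- out[rng] + pmf * bg[[b]]
    }
    pmf <- out
    offset <- offset + lo_i
  }
  structure(
    list(
      granularity = granularity,
      bin = as.integer(offset + seq_along(pmf) - 1),
      prob = pmf,
      tail = rev(cumsum(rev(pmf))), # P(score bin >= bin[i])
      motif_length = L,
      motif_id = pwm$motif_id
    ),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "<score_distribution> %s  length %d, %d bins, granularity %.3g\n",
    x$motif_id %||% "?", x$motif_length, length(x$bin), x$granularity
  ))
  cat(sprintf(
    "score support [%.4g, %.4g], min attainable p-value %.3g\n",
    min(x$bin) * x$granularity, max(x$bin) * x$granularity,
    x$tail[[length(x$tail)]]
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

score_to_bin <- function(dist, score) {
  # floor-to-bin; the small epsilon keeps exact bin boundaries (score ==
  # b * granularity up to double rounding) in their own bin
  floor(score / dist$granularity + 1e-9)
}

#' Exact p-value of a score
#'
#' Probability that a random background word of motif length scores at
#' least `score`, read from the discretised null distribution
#' (floor-to-bin). Monotone non-increasing in `score`; 1 below the
#' support, 0 above it. Vectorised over `score`.
#'
#' @param dist A `score_distribution`.
#' @param score Numeric score(s).
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
pwm_pvalue <- function(dist, score) {
  stopifnot(inherits(dist, "score_distribution"))
  b <- score_to_bin(dist, score)
  first <- dist$bin[[1]]
  idx <- pmax(b - first + 1, 1)
  out <- ifelse(idx > length(dist$tail), 0, dist$tail[pmin(idx, length(dist$tail))])
  as.numeric(out)
}

#' Smallest score with p-value below alpha
#'
#' The smallest representable score `t` (a bin boundary) such that
#' `pwm_pvalue(dist, t) < alpha`, with a strict inequality mirroring a
#' "p-value < alpha" match rule. When even the maximal score has
#' p-value >= alpha the threshold is unattainable and `+Inf` is returned.
#'
#' @param dist A `score_distribution`.
#' @param alpha Significance level in `(0, 1]`.
#' @return Numeric score threshold, or `+Inf` if unattainable.
#' @export
threshold_for_pvalue <- function(dist, alpha) {
  stopifnot(inherits(dist, "score_distribution"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be in (0, 1].")
  }
  # relative guard absorbs cumulative floating-point error in the tail sums
  ok <- which(dist$tail < alpha * (1 - 1e-12))
  if (length(ok) == 0) {
    return(Inf)
  }
  dist$bin[[min(ok)]] * dist$granularity
}

#' @rdname tidiers
#' @method tidy score_distribution
#' @export
tidy.score_distribution <- function(x, ...) {
  tibble::tibble(
    bin = x$bin,
    score = x$bin * x$granularity,
    prob = x$prob,
    pvalue = x$tail
  )
}

#' Write / read a score distribution cache as TSV
#'
#' Plain two-column TSV (`bin`, `probability`) with the granularity and
#' motif length in `#`-prefixed header lines, so an expensive distribution
#' can be reused across runs.
#'
#' @param dist A `score_distribution`.
#' @param path File path.
#' @return `write_score_distribution` returns `path` invisibly;
#'   `read_score_distribution` returns a `score_distribution`.
#' @export
write_score_distribution <- function(dist, path) {
  header <- c(
    sprintf("# granularity\t%.17g", dist$granularity),
    sprintf("# motif_length\t%d", dist$motif_length),
    sprintf("# motif_id\t%s", dist$motif_id %||% "")
  )
  writeLines(
    c(header, "bin\tprobability", sprintf("%d\t%.17g", dist$bin, dist$prob)),
    path
  )
  invisible(path)
}

#' @rdname write_score_distribution
#' @export
read_score_distribution <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", meta), "\t", fixed = TRUE)
  meta <- setNames(
    vapply(kv, function(x) x[[2]] %||% "", ""),
    vapply(kv, `[[`, "", 1)
  )
  body <- utils::read.delim(
    text = lines[!startsWith(lines, "#")],
    sep = "\t", header = TRUE
  )
  prob <- body$probability
  structure(
    list(
      granularity = as.numeric(meta[["granularity"]]),
      bin = as.integer(body$bin),
      prob = prob,
      tail = rev(cumsum(rev(prob))),
      motif_length = as.integer(meta[["motif_length"]]),
      motif_id = if (nzchar(meta[["motif_id"]])) meta[["motif_id"]] else NULL
    ),
    class = "score_distribution"
  )
}
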