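#' Detect proto-silencers: Rap1-Abf1 match pairs within a window
#'
#' A proto-silencer is an intergenic region in which a Rap1 binding-site
#' match and an Abf1 binding-site match lie within `window` base pairs of
#' each other — the silencer-like two-factor architecture outside the
#' silenced loci. Every qualifying (Rap1, Abf1) pair sharing a region is
#' emitted (no greedy one-to-one matching), so one region can contribute
#' several pairs. Distance is the absolute difference of the two anchor
#' coordinates, boundary inclusive (`distance <= window`).
#'
#' @param rap1_matches,abf1_matches Match tibbles (as from
#'   [scan_region_set()] or [read_matches()]): columns `region_id`,
#'   `chromosome`, `position` required; `motif_id`, `strand`, `score`
#'   carried through when present.
#' @param window Maximum anchor distance in bp (default 50).
#' @return Tibble with columns `region_id`, `chromosome`,
#'   `rap1_position`, `abf1_position`, `distance`, plus any carried
#'   `rap1_*`/`abf1_*` columns, sorted by chromosome then `rap1_position`.
#' @examples
#' find_proto_silencers(published_proto_silencer_sites("rap1"),
#'                      published_proto_silencer_sites("abf1"))
#' @export
find_proto_silencers <- function(rap1_matches, abf1_matches, window = 50) {
  if (!is.numeric(window) || length(window) != 1 || window < 0) {
    abort("`window` must be a single non-negative number.")
  }
  prep <- function(m, prefix) {
    need <- c("region_id", "chromosome", "position")
    missing <- setdiff(need, names(m))
    if (length(missing) > 0) {
      abort(paste0("Match table is missing: ", paste(missing, collapse = ", ")))
    }
    keep <- intersect(c("position", "strand", "score", "motif_id"), names(m))
    m <- dplyr::select(m, dplyr::all_of(c("region_id", "chromosome", keep)))
    dplyr::rename_with(m, function(x) paste0(prefix, "_", x), dplyr::all_of(keep))
  }
  r <- prep(rap1_matches, "rap1")
  a <- prep(abf1_matches, "abf1")
  pairs <- dplyr::inner_join(r, a,
    by = c("region_id", "chromosome"),
    relationship = "many-to-many"
  )
  pairs <- dplyr::mutate(pairs,
    distance = abs(.data$rap1_position - .data$abf1_position)
  )
  pairs <- dplyr::filter(pairs, .data$distance <= window)
  front <- c("region_id", "chromosome", "rap1_position", "abf1_position", "distance")
  pairs <- dplyr::select(
    pairs, dplyr::all_of(front),
    dplyr::everything()
  )
  dplyr::arrange(pairs, .data$chromosome, .data$rap1_position, .data$abf1_position)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Closed-form Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with an optional Yates
#' continuity correction (subtract `n/2` from `|ad - bc|` before
#' squaring, floored at 0); p-value from the chi-squared distribution
#' with one degree of freedom.
#'
#' @param table 2x2 non-negative count matrix (all four marginals > 0).
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic`, `p_value`, `df`, `yates`.
#' @examples
#' chi_square_2x2(matrix(c(20, 10, 10, 20), 2))
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2.")
  if (any(table < 0)) abort("Counts must be non-negative.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Chi-squared test undefined: a marginal total is zero.")
  }
  storage.mode(table) <- "double" # marginal products overflow integer range
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c_ + d
  delta <- abs(a * d - b * c_)
  if (yates) delta <- max(delta - n / 2, 0)
  stat <- n * delta^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  tibble::tibble(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    df = 1L,
    yates = yates
  )
}

#' Fraction of conservation calls that are conserved
#'
#' @param calls Conservation-call tibble with a logical `conserved`
#'   column (see [call_conservation()]).
#' @return Fraction in `[0, 1]`.
#' @export
conservation_fraction <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$conserved
  if (length(calls) == 0) abort("Cannot take a conservation fraction of zero calls.")
  mean(calls)
}

site_key_columns <- function(a, b) {
  intersect(
    intersect(c("motif_id", "region_id", "chromosome", "position", "strand"), names(a)),
    names(b)
  )
}

#' Compare conservation between proto-silencer and genome-wide sites
#'
#' Builds the 2x2 table (conserved / not) x (proto-silencer / other) and
#' applies [chi_square_2x2()]. Sites present in the proto-silencer call
#' set are excluded from the genome-wide cells (matched on whichever of
#' motif/region/chromosome/position/strand columns both tables share), so
#' the two classes are disjoint.
#'
#' @param genomewide_calls,protosilencer_calls Conservation-call tibbles
#'   (logical `conserved` column plus site identity columns).
#' @param yates Continuity correction flag, passed to [chi_square_2x2()].
#' @return A `conservation_comparison` object; see [tidy()] / [glance()].
#'   Contains `$fractions` (per-class n and conserved fraction),
#'   `$table` (the 2x2 counts) and `$test` (the chi-squared result).
#' @export
compare_conservation <- function(genomewide_calls, protosilencer_calls, yates = FALSE) {
  if (nrow(genomewide_calls) == 0 || nrow(protosilencer_calls) == 0) {
    abort("Both call sets must be non-empty.")
  }
  keys <- site_key_columns(genomewide_calls, protosilencer_calls)
  other <- if (length(keys) > 0) {
    dplyr::anti_join(genomewide_calls, protosilencer_calls, by = keys)
  } else {
    genomewide_calls
  }
  if (nrow(other) == 0) {
    abort("No genome-wide sites remain after excluding proto-silencer sites.")
  }
  tab <- matrix(
    c(
      sum(protosilencer_calls$conserved), sum(other$conserved),
      sum(!protosilencer_calls$conserved), sum(!other$conserved)
    ),
    nrow = 2,
    dimnames = list(
      class = c("proto_silencer", "genome_wide"),
      conserved = c("conserved", "not_conserved")
    )
  )
  fractions <- tibble::tibble(
    class = c("proto_silencer", "genome_wide"),
    n = c(nrow(protosilencer_calls), nrow(other)),
    conserved_fraction = c(
      conservation_fraction(protosilencer_calls),
      conservation_fraction(other)
    )
  )
  structure(
    list(fractions = fractions, table = tab, test = chi_square_2x2(tab, yates)),
    class = "conservation_comparison"
  )
}

#' @export
print.conservation_comparison <- function(x, ...) {
  cat("<conservation_comparison>\n")
  print(x$fractions)
  cat(sprintf(
    "chi-squared = %.4f, df = 1, p = %.4g%s\n",
    x$test$statistic, x$test$p_value,
    if (x$test$yates) " (Yates-corrected)" else ""
  ))
  invisible(x)
}

#' Tidiers for silencerscan result objects
#'
#' broom-style methods: `tidy()` returns the per-class or per-position
#' detail table, `glance()` a one-row summary.
#'
#' @param x A fitted/result object from this package.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy conservation_comparison
#' @export
tidy.conservation_comparison <- function(x, ...) {
  dplyr::mutate(x$fractions,
    statistic = x$test$statistic,
    p_value = x$test$p_value
  )
}

#' @rdname tidiers
#' @method glance conservation_comparison
#' @export
glance.conservation_comparison <- function(x, ...) {
  tibble::tibble(
    n_proto_silencer = x$fractions$n[[1]],
    n_genome_wide = x$fractions$n[[2]],
    fraction_proto_silencer = x$fractions$conserved_fraction[[1]],
    fraction_genome_wide = x$fractions$conserved_fraction[[2]],
    statistic = x$test$statistic,
    p_value = x$test$p_value,
    yates = x$test$yates
  )
}

#' Filter a ChIP binding table to qualifying transcription factors
#'
#' Keeps factors bound (binding p-value strictly below `p_max`) to at
#' least `min_regions` distinct intergenic regions, and within those
#' factors keeps only the qualifying region rows.
#'
#' @param chip_records Tibble with columns `factor`, `region_id`, `p`.
#' @param p_max Strict binding p-value cutoff (default 0.05).
#' @param min_regions Minimum count of distinct qualifying regions
#'   (default 60, inclusive).
#' @return Tibble of qualifying `(factor, region_id, p)` rows (one per
#'   distinct factor-region pair).
#' @export
filter_tf_sets <- function(chip_records, p_max = 0.05, min_regions = 60) {
  need <- c("factor", "region_id", "p")
  missing <- setdiff(need, names(chip_records))
  if (length(missing) > 0) {
    abort(paste0("`chip_records` is missing: ", paste(missing, collapse = ", ")))
  }
  if (any(chip_records$p < 0 | chip_records$p > 1)) {
    abort("Binding p-values must lie in [0, 1].")
  }
  qualifying <- chip_records |>
    dplyr::filter(.data$p < p_max) |>
    dplyr::distinct(.data$factor, .data$region_id, .keep_all = TRUE)
  kept <- qualifying |>
    dplyr::count(.data$factor) |>
    dplyr::filter(.data$n >= min_regions)
  qualifying |>
    dplyr::semi_join(kept, by = "factor") |>
    dplyr::select(dplyr::all_of(need)) |>
    dplyr::arrange(.data$factor, .data$region_id)
}

#' Motif frequency per 10 kb of factor-bound intergenic sequence
#'
#' For each transcription factor in `tf_sets`, counts motif matches that
#' fall in the factor's bound regions, divides by the summed length of
#' those regions, and scales (default x 10,000, i.e. matches per 10 kb).
#'
#' @param tf_sets Filtered binding tibble from [filter_tf_sets()]
#'   (columns `factor`, `region_id`).
#' @param matches Match tibble (columns `motif_id`, `region_id`).
#' @param regions Region tibble with `region_id`, `start`, `end` (region
#'   length is `end - start + 1`).
#' @param scale Frequency scale in bp (default 10000).
#' @return Tibble with one row per (factor, motif): `factor`, `motif_id`,
#'   `n_matches`, `total_length`, `freq_per_10kb`.
#' @export
motif_frequency <- function(tf_sets, matches, regions, scale = 10000) {
  if (!all(c("factor", "region_id") %in% names(tf_sets))) {
    abort("`tf_sets` needs columns factor, region_id.")
  }
  lens <- regions |>
    dplyr::mutate(length = .data$end - .data$start + 1L) |>
    dplyr::select(dplyr::all_of(c("region_id", "length")))
  unknown <- setdiff(unique(tf_sets$region_id), lens$region_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "%d bound region(s) have no known length (e.g. %s).",
      length(unknown), unknown[[1]]
    ))
  }
  totals <- tf_sets |>
    dplyr::distinct(.data$factor, .data$region_id) |>
    dplyr::left_join(lens, by = "region_id") |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(total_length = sum(.data$length), .groups = "drop")
  if (any(totals$total_length == 0)) {
    abort("A factor's bound regions have zero total length.")
  }
  motifs <- unique(matches$motif_id)
  if (length(motifs) == 0) {
    return(tibble::tibble(
      factor = character(), motif_id = character(), n_matches = integer(),
      total_length = numeric(), freq_per_10kb = numeric()
    ))
  }
  grid <- tidyr::expand_grid(
    factor = totals$factor,
    motif_id = motifs
  )
  counts <- tf_sets |>
    dplyr::distinct(.data$factor, .data$region_id) |>
    dplyr::inner_join(matches, by = "region_id", relationship = "many-to-many") |>
    dplyr::count(.data$factor, .data$motif_id, name = "n_matches")
  grid |>
    dplyr::left_join(counts, by = c("factor", "motif_id")) |>
    dplyr::mutate(n_matches = dplyr::coalesce(.data$n_matches, 0L)) |>
    dplyr::left_join(totals, by = "factor") |>
    dplyr::mutate(freq_per_10kb = .data$n_matches / .data$total_length * scale) |>
    dplyr::arrange(.data$factor, .data$motif_id)
}
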