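#' Resolve orthologous intergenic regions by reciprocal best hits
#'
#' Two genes are orthologs when each is the other's unique top-scoring
#' cross-species hit in a precomputed similarity table (reciprocal best
#' hit, RBH); tied top scores resolve nothing and leave the gene
#' unmatched. A reference-species intergenic region maps to a region in
#' another species only when both of its flanking genes are RBHs and
#' their partners flank one single region there (in either left/right
#' orientation). Regions that fail any of these conditions are simply
#' absent from the map.
#'
#' @param similarities Tibble of scored cross-species gene pairs:
#'   columns `gene_a`, `species_a`, `gene_b`, `species_b`, `score`
#'   (higher = more similar; direction of the pair does not matter).
#' @param regions_by_species Region tibble across species: columns
#'   `region_id`, `species`, `left_gene`, `right_gene`.
#' @param reference Reference species name (default the species of the
#'   first region row).
#' @return Tibble `region_id` (reference region), `species` (target),
#'   `ortho_region_id`.
#' @export
rbh_orthology <- function(similarities, regions_by_species, reference = NULL) {
  need_s <- c("gene_a", "species_a", "gene_b", "species_b", "score")
  if (!all(need_s %in% names(similarities))) {
    abort(paste0("`similarities` needs columns: ", paste(need_s, collapse = ", ")))
  }
  need_r <- c("region_id", "species", "left_gene", "right_gene")
  if (!all(need_r %in% names(regions_by_species))) {
    abort(paste0("`regions_by_species` needs columns: ", paste(need_r, collapse = ", ")))
  }
  if (is.null(reference)) reference <- regions_by_species$species[[1]]

  # normalise pairs to reference -> target
  fwd <- dplyr::filter(similarities, .data$species_a == reference)
  rev_ <- dplyr::filter(
    similarities, .data$species_b == reference, .data$species_a != reference
  )
  pairs <- dplyr::bind_rows(
    dplyr::select(fwd,
      ref_gene = "gene_a", target_gene = "gene_b",
      target_species = "species_b", score = "score"
    ),
    dplyr::select(rev_,
      ref_gene = "gene_b", target_gene = "gene_a",
      target_species = "species_a", score = "score"
    )
  )
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      region_id = character(), species = character(), ortho_region_id = character()
    ))
  }

  unique_best <- function(df, key) {
    df |>
      dplyr::group_by(.data$target_species, .data[[key]]) |>
      dplyr::filter(.data$score == max(.data$score)) |>
      dplyr::filter(dplyr::n() == 1) |> # ties break nothing
      dplyr::ungroup()
  }
  best_of_ref <- unique_best(pairs, "ref_gene")
  best_of_target <- unique_best(pairs, "target_gene")
  rbh <- dplyr::inner_join(
    dplyr::select(best_of_ref, dplyr::all_of(c("ref_gene", "target_gene", "target_species"))),
    dplyr::select(best_of_target, dplyr::all_of(c("ref_gene", "target_gene", "target_species"))),
    by = c("ref_gene", "target_gene", "target_species")
  )

  ref_regions <- dplyr::filter(regions_by_species, .data$species == reference)
  target_regions <- dplyr::filter(regions_by_species, .data$species != reference)

  lookup <- function(genes, sp) {
    m <- dplyr::left_join(
      tibble::tibble(ref_gene = genes, target_species = sp),
      rbh,
      by = c("ref_gene", "target_species")
    )
    m$target_gene
  }

  candidates <- tidyr::expand_grid(
    i = seq_len(nrow(ref_regions)),
    target_species = unique(target_regions$species)
  )
  candidates <- dplyr::mutate(candidates,
    region_id = ref_regions$region_id[.data$i],
    left_partner = lookup(ref_regions$left_gene[.data$i], .data$target_species),
    right_partner = lookup(ref_regions$right_gene[.data$i], .data$target_species)
  )
  candidates <- dplyr::filter(
    candidates, !is.na(.data$left_partner), !is.na(.data$right_partner)
  )
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      region_id = character(), species = character(), ortho_region_id = character()
    ))
  }

  # a candidate resolves iff exactly one target region has the two partner
  # genes as its flanks, in either orientation
  tr <- dplyr::mutate(target_regions,
    flank_lo = pmin(.data$left_gene, .data$right_gene),
    flank_hi = pmax(.data$left_gene, .data$right_gene)
  )
  candidates <- dplyr::mutate(candidates,
    flank_lo = pmin(.data$left_partner, .data$right_partner),
    flank_hi = pmax(.data$left_partner, .data$right_partner)
  )
  hits <- dplyr::inner_join(
    candidates,
    dplyr::select(tr,
      target_species = "species", ortho_region_id = "region_id",
      "flank_lo", "flank_hi"
    ),
    by = c("target_species", "flank_lo", "flank_hi"),
    relationship = "many-to-many"
  )
  hits |>
    dplyr::group_by(.data$region_id, .data$target_species) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("region_id", species = "target_species", "ortho_region_id") |>
    dplyr::arrange(.data$region_id, .data$species)
}

#' Call cross-species conservation of binding-site matches
#'
#' For each reference-species match, a non-reference species counts as
#' "present" when the orthologous region exists in the orthology map and
#' contains at least one PWM match at p-value `< alpha` (either strand,
#' any offset — orthologous intergenic regions are short, so no
#' positional tolerance is imposed). A site is conserved when the number
#' of species with the site (by default including the reference species
#' itself) reaches `min_species`.
#'
#' @param sites Reference-species match tibble (columns `region_id`,
#'   `position`, `strand`, ...; see [scan_region_set()]).
#' @param orthology Orthology map tibble from [rbh_orthology()]:
#'   `region_id`, `species`, `ortho_region_id`.
#' @param species_regions Region tibble across the non-reference species
#'   (columns `region_id`, `species`, `chromosome`, `start`, `end`,
#'   `sequence`).
#' @param pwm A `pwm` object used for the presence scans.
#' @param alpha Strict p-value cutoff for presence scans.
#' @param min_species Conservation threshold (default 3).
#' @param count_reference Count the reference species towards
#'   `min_species` (default `TRUE`).
#' @param species Character vector of non-reference species to assess;
#'   default all species in `orthology`.
#' @return The `sites` tibble with added columns `n_species_present`
#'   (including the reference if counted), `conserved`, and one logical
#'   `in_<species>` column per assessed species.
#' @export
call_conservation <- function(sites, orthology, species_regions, pwm, alpha,
                              min_species = 3, count_reference = TRUE,
                              species = NULL) {
  if (is.null(species)) species <- sort(unique(orthology$species))
  if (nrow(sites) == 0) {
    out <- sites
    out$n_species_present <- integer(0)
    out$conserved <- logical(0)
    return(out)
  }
  if (length(species) == 0) {
    # no species to assess: only the reference can count
    out <- sites
    out$n_species_present <- rep(as.integer(count_reference), nrow(sites))
    out$conserved <- out$n_species_present >= min_species
    return(out)
  }

  # scan each needed orthologous region once
  needed <- orthology |>
    dplyr::filter(.data$species %in% .env$species,
                  .data$region_id %in% unique(.env$sites$region_id)) |>
    dplyr::distinct(.data$species, .data$ortho_region_id)
  scan_targets <- species_regions |>
    dplyr::semi_join(needed, by = c("species", "region_id" = "ortho_region_id"))
  dist <- exact_score_distribution(pwm)
  present_tbl <- if (nrow(scan_targets) > 0) {
    hits <- scan_targets |>
      dplyr::group_by(.data$species) |>
      dplyr::group_modify(function(df, key) {
        m <- scan_region_set(pwm, df, alpha, dist = dist)
        tibble::tibble(ortho_region_id = unique(m$region_id))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(has_match = TRUE)
    orthology |>
      dplyr::left_join(hits, by = c("species", "ortho_region_id")) |>
      dplyr::mutate(present = dplyr::coalesce(.data$has_match, FALSE)) |>
      dplyr::select("region_id", "species", "present")
  } else {
    tibble::tibble(region_id = character(), species = character(), present = logical())
  }

  wide <- tidyr::expand_grid(
    region_id = unique(sites$region_id),
    species = species
  ) |>
    dplyr::left_join(present_tbl, by = c("region_id", "species")) |>
    dplyr::mutate(present = dplyr::coalesce(.data$present, FALSE)) |>
    tidyr::pivot_wider(
      names_from = "species", values_from = "present", names_prefix = "in_"
    )

  out <- dplyr::left_join(sites, wide, by = "region_id")
  in_cols <- paste0("in_", species)
  n_present <- rowSums(as.matrix(out[, in_cols, drop = FALSE])) +
    as.integer(count_reference)
  out$n_species_present <- as.integer(n_present)
  out$conserved <- n_present >= min_species
  out
}

#' Closed-form expected conservation fraction under independent retention
#'
#' If a planted site survives intact in each of `n_other` derived species
#' independently with probability `retention`, the probability that it is
#' called conserved under the at-least-`min_species` rule (reference
#' counted when `count_reference`) is a binomial tail.
#'
#' @param retention Per-species site retention probability.
#' @param n_other Number of non-reference species.
#' @param min_species Conservation threshold.
#' @param count_reference Whether the reference counts towards the rule.
#' @return Probability in `[0, 1]`.
#' @export
expected_conservation_fraction <- function(retention, n_other = 4, min_species = 3,
                                           count_reference = TRUE) {
  need <- min_species - as.integer(count_reference)
  stats::pbinom(need - 1, n_other, retention, lower.tail = FALSE)
}
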