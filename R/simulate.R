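#' Default planting motifs for synthetic cohorts
#'
#' A sharp PWM built from the genome-wide Rap1 consensus
#' (`ACACCCATACATT`, heavily weighted so sampled instances are close to
#' exact) and the packaged synthetic Abf1-like matrix.
#'
#' @param background Background model used to build the PWMs (default
#'   yeast-like intergenic GC of 0.38).
#' @return Named list of `pwm` objects.
#' @export
default_planting_pwms <- function(background = background_model(gc_background(0.38))) {
  rap1 <- build_pwm(
    sites_to_counts(rap1_consensus(), weights = 100, motif_id = "RAP1"),
    background
  )
  abf1 <- build_pwm(
    read_motif_counts(silencerscan_extdata("abf1_synthetic_counts.txt")),
    background
  )
  list(RAP1 = rap1, ABF1 = abf1)
}

#' Configuration for the synthetic multi-species cohort generator
#'
#' The generator emulates a set of sensu-stricto-like yeast intergenic
#' regions: an ancestral region set with planted motif instances, and
#' derived species produced by independent per-site substitution (star
#' phylogeny), with planted sites retained intact per species with a
#' fixed probability and otherwise mutated like background.
#'
#' @param n_regions Number of intergenic regions.
#' @param region_length_meanlog,region_length_sdlog Log-normal
#'   parameters of region length (defaults: median 500 bp, sdlog 0.3 —
#'   yeast intergenic regions are a few hundred bp).
#' @param gc_content Background GC fraction (default 0.38, yeast
#'   intergenic).
#' @param n_species Total species including the reference (default 5,
#'   the sensu stricto count).
#' @param substitution_prob Per-site substitution probability on each
#'   species branch (default 0.30; sensu stricto intergenic sequence is
#'   roughly 30-40% diverged from S. cerevisiae).
#' @param site_retention_prob Probability a planted site survives intact
#'   in a derived species (default 0.8).
#' @param planting_rate Expected planted sites per region per motif
#'   (Poisson; default 1).
#' @param sites_per_region Optional exact number of planted sites per
#'   region per motif, overriding the Poisson draw. Calibration cohorts
#'   use 1 so that each region carries exactly one site and region-level
#'   presence calls correspond one-to-one to sites.
#' @param motifs Named list of `pwm` objects to plant
#'   (default [default_planting_pwms()]).
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_regions = 200,
                              region_length_meanlog = log(500),
                              region_length_sdlog = 0.3,
                              gc_content = 0.38,
                              n_species = 5,
                              substitution_prob = 0.30,
                              site_retention_prob = 0.8,
                              planting_rate = 1,
                              sites_per_region = NULL,
                              motifs = NULL,
                              seed = 1) {
  stopifnot(
    n_regions >= 1, n_species >= 1,
    gc_content > 0, gc_content < 1,
    substitution_prob >= 0, substitution_prob <= 1,
    site_retention_prob >= 0, site_retention_prob <= 1,
    planting_rate >= 0,
    is.null(sites_per_region) || sites_per_region >= 0
  )
  structure(
    list(
      n_regions = as.integer(n_regions),
      region_length_meanlog = region_length_meanlog,
      region_length_sdlog = region_length_sdlog,
      gc_content = gc_content,
      n_species = as.integer(n_species),
      substitution_prob = substitution_prob,
      site_retention_prob = site_retention_prob,
      planting_rate = planting_rate,
      sites_per_region = if (is.null(sites_per_region)) NULL else as.integer(sites_per_region),
      motifs = motifs,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

species_names <- function(n) {
  stock <- c("Scer", "Spar", "Smik", "Skud", "Sbay")
  if (n <= length(stock)) stock[seq_len(n)] else c(stock, sprintf("Ssp%02d", seq_len(n - 5)))
}

random_dna <- function(n, gc) {
  paste(
    sample(DNA_BASES, n, replace = TRUE, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""
  )
}

sample_site_from_pwm <- function(pwm) {
  p <- pwm$probs
  paste(
    vapply(seq_len(ncol(p)), function(i) sample(DNA_BASES, 1, prob = p[, i]), ""),
    collapse = ""
  )
}

mutate_sequence <- function(chars, substitution_prob) {
  hit <- which(stats::runif(length(chars)) < substitution_prob)
  if (length(hit) > 0) {
    # uniform substitution to one of the three other bases
    shift <- sample(1:3, length(hit), replace = TRUE)
    cur <- match(chars[hit], DNA_BASES)
    chars[hit] <- DNA_BASES[((cur - 1 + shift) %% 4) + 1]
  }
  chars
}

#' Generate a truth-known synthetic multi-species cohort
#'
#' Draws ancestral intergenic regions i.i.d. from the GC-parameterised
#' background, plants motif instances sampled from the configured PWMs at
#' non-overlapping positions (random strand), then derives each
#' non-reference species from the ancestor by i.i.d. substitution; each
#' planted site is regenerated intact in a derived species with
#' probability `site_retention_prob` and otherwise left to mutate like
#' background. The reference species is the unmutated ancestor. All
#' outputs are pure functions of the configuration (same seed, same
#' cohort).
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list with tibbles: `regions` (all
#'   species, with sequences; each region on its own chromosome with
#'   `start = 1`), `truth` (planted sites with per-species retention
#'   flags), `orthology` (true region map), `gene_pairs` (true
#'   flanking-gene orthologs), `similarities` (noise-free similarity
#'   table), `chip` (factor-binding table), plus `species`, `motifs`,
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  motifs <- config$motifs
  if (is.null(motifs)) {
    motifs <- default_planting_pwms(background_model(gc_background(config$gc_content)))
  }
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    names(motifs) <- vapply(motifs, function(p) p$motif_id, "")
  }
  sps <- species_names(config$n_species)
  reference <- sps[[1]]
  max_L <- max(vapply(motifs, motif_length, 1L))

  lens <- pmax(
    as.integer(round(stats::rlnorm(
      config$n_regions, config$region_length_meanlog, config$region_length_sdlog
    ))),
    as.integer(4 * max_L + 20)
  )
  rids <- sprintf("r%04d", seq_len(config$n_regions))

  ancestors <- character(config$n_regions)
  truth_rows <- vector("list", config$n_regions)
  for (i in seq_len(config$n_regions)) {
    seq_i <- random_dna(lens[[i]], config$gc_content)
    occupied <- integer(0)
    rows <- list()
    for (m in names(motifs)) {
      pwm <- motifs[[m]]
      L <- motif_length(pwm)
      k <- if (is.null(config$sites_per_region)) {
        stats::rpois(1, config$planting_rate)
      } else {
        config$sites_per_region
      }
      for (j in seq_len(k)) {
        placed <- FALSE
        for (try in seq_len(200)) {
          pos <- sample.int(lens[[i]] - L + 1, 1)
          span <- pos:(pos + L - 1)
          if (!any(span %in% occupied)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort(sprintf(
            "Planting density too high to place sites without overlap (region %s).",
            rids[[i]]
          ))
        }
        occupied <- c(occupied, span)
        site <- sample_site_from_pwm(pwm)
        strand <- sample(c("+", "-"), 1)
        inserted <- if (strand == "+") site else reverse_complement(site)
        substr(seq_i, pos, pos + L - 1) <- inserted
        rows[[length(rows) + 1]] <- tibble::tibble(
          region_id = paste0(rids[[i]], "_", reference),
          ancestor_region = rids[[i]],
          motif_id = m,
          position = pos,
          strand = strand,
          site_seq = site
        )
      }
    }
    ancestors[[i]] <- seq_i
    truth_rows[[i]] <- dplyr::bind_rows(rows)
  }
  truth <- dplyr::bind_rows(truth_rows)
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(
      region_id = character(), ancestor_region = character(),
      motif_id = character(), position = integer(),
      strand = character(), site_seq = character()
    )
  }

  # derived species: background substitution, planted spans restored with
  # probability site_retention_prob
  region_rows <- list()
  for (sp in sps) {
    seqs <- ancestors
    if (sp != reference) {
      retained_col <- logical(nrow(truth))
      for (i in seq_len(config$n_regions)) {
        chars <- strsplit(ancestors[[i]], "", fixed = TRUE)[[1]]
        chars <- mutate_sequence(chars, config$substitution_prob)
        idx <- which(truth$ancestor_region == rids[[i]])
        for (t in idx) {
          retained <- stats::runif(1) < config$site_retention_prob
          retained_col[[t]] <- retained
          if (retained) {
            span <- truth$position[[t]]:(truth$position[[t]] + nchar(truth$site_seq[[t]]) - 1)
            chars[span] <- strsplit(ancestors[[i]], "", fixed = TRUE)[[1]][span]
          }
        }
        seqs[[i]] <- paste(chars, collapse = "")
      }
      truth[[paste0("retained_", sp)]] <- retained_col
    }
    region_rows[[sp]] <- tibble::tibble(
      region_id = paste0(rids, "_", sp),
      species = sp,
      chromosome = rids,
      start = 1L,
      end = lens,
      left_gene = paste0("gL_", rids, "_", sp),
      right_gene = paste0("gR_", rids, "_", sp),
      sequence = seqs
    )
  }
  regions <- dplyr::bind_rows(region_rows)

  orthology <- tidyr::expand_grid(rid = rids, species = sps[-1]) |>
    dplyr::mutate(
      region_id = paste0(.data$rid, "_", reference),
      ortho_region_id = paste0(.data$rid, "_", .data$species)
    ) |>
    dplyr::select("region_id", "species", "ortho_region_id")

  gene_pairs <- tidyr::expand_grid(
    rid = rids, side = c("gL", "gR"), target = sps[-1]
  ) |>
    dplyr::mutate(
      gene_a = paste0(.data$side, "_", .data$rid, "_", reference),
      species_a = reference,
      gene_b = paste0(.data$side, "_", .data$rid, "_", .data$target),
      species_b = .data$target
    ) |>
    dplyr::select("gene_a", "species_a", "gene_b", "species_b")

  cohort <- structure(
    list(
      config = config,
      species = sps,
      reference = reference,
      motifs = motifs,
      regions = regions,
      truth = truth,
      orthology = orthology,
      gene_pairs = gene_pairs
    ),
    class = "synthetic_cohort"
  )
  cohort$similarities <- perturb_similarities(
    cohort,
    noise_prob = 0, seed = config$seed + 1L
  )
  cohort$chip <- emit_chip_table(cohort, seed = config$seed + 2L)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d regions x %d species, %d planted sites (motifs: %s)\n",
    x$config$n_regions, length(x$species), nrow(x$truth),
    paste(names(x$motifs), collapse = ", ")
  ))
  invisible(x)
}

#' Simulate a ChIP-style factor-binding table for a cohort
#'
#' Each factor binds a random subset of the reference-species regions;
#' bound regions get binding p-values drawn uniformly below 0.05 and
#' unbound regions above it. The table carries the ground-truth `bound`
#' flag alongside `p`. Deterministic for a fixed seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_factors Number of factors (default 6, named TF01...).
#' @param bound_fraction Fraction of regions each factor binds (default
#'   0.3).
#' @param seed Integer seed.
#' @return Tibble with columns `factor`, `region_id`, `p`, `bound`.
#' @export
emit_chip_table <- function(cohort, n_factors = 6, bound_fraction = 0.3, seed = 1) {
  if (n_factors < 1) abort("`n_factors` must be >= 1.")
  if (bound_fraction <= 0 || bound_fraction > 1) {
    abort("`bound_fraction` must be in (0, 1].")
  }
  set.seed(seed)
  ref_regions <- dplyr::filter(
    cohort$regions, .data$species == cohort$reference
  )$region_id
  n <- length(ref_regions)
  n_bound <- max(1L, round(bound_fraction * n))
  purrr::map_dfr(seq_len(n_factors), function(f) {
    bound <- ref_regions %in% sample(ref_regions, n_bound)
    tibble::tibble(
      factor = sprintf("TF%02d", f),
      region_id = ref_regions,
      p = ifelse(bound, stats::runif(n, 0, 0.049), stats::runif(n, 0.05, 1)),
      bound = bound
    )
  })
}

#' Build a (possibly noisy) flanking-gene similarity table
#'
#' Produces the scored cross-species gene-pair table that
#' [rbh_orthology()] consumes. True ortholog pairs receive top-range
#' scores and each reference gene additionally gets decoy pairs with
#' lower scores. With `noise_prob > 0`, that fraction of true-pair
#' scores is pooled with an equal number of decoy scores and the pool is
#' permuted, so a noised true pair usually — but not always — loses its
#' top rank. Deterministic for a fixed seed.
#'
#' @param cohort A `synthetic_cohort` (or a gene-pair tibble with
#'   columns `gene_a`, `species_a`, `gene_b`, `species_b`).
#' @param noise_prob Fraction of true pairs perturbed, in `[0, 1)`.
#' @param seed Integer seed.
#' @param n_decoys Decoy pairs per reference gene per species (default 3).
#' @return Similarity tibble: `gene_a`, `species_a`, `gene_b`,
#'   `species_b`, `score`, `true_pair`.
#' @export
perturb_similarities <- function(cohort, noise_prob = 0, seed = 1, n_decoys = 3) {
  if (noise_prob < 0 || noise_prob >= 1) abort("`noise_prob` must be in [0, 1).")
  truth <- if (inherits(cohort, "synthetic_cohort")) cohort$gene_pairs else cohort
  set.seed(seed)
  true_rows <- dplyr::mutate(truth,
    score = stats::runif(dplyr::n(), 150, 200),
    true_pair = TRUE
  )
  decoy_rows <- true_rows |>
    dplyr::group_by(.data$species_b) |>
    dplyr::group_modify(function(df, key) {
      genes_b <- df$gene_b
      purrr::map_dfr(seq_len(nrow(df)), function(i) {
        others <- setdiff(genes_b, df$gene_b[[i]])
        k <- min(n_decoys, length(others))
        if (k == 0) {
          return(tibble::tibble())
        }
        tibble::tibble(
          gene_a = df$gene_a[[i]],
          species_a = df$species_a[[i]],
          gene_b = sample(others, k),
          score = stats::runif(k, 0, 140),
          true_pair = FALSE
        )
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::select("gene_a", "species_a", "gene_b", "species_b", "score", "true_pair")
  out <- dplyr::bind_rows(true_rows, decoy_rows)
  if (noise_prob > 0 && nrow(decoy_rows) > 0) {
    true_idx <- which(out$true_pair)
    noised <- true_idx[stats::runif(length(true_idx)) < noise_prob]
    if (length(noised) > 0) {
      decoy_idx <- which(!out$true_pair)
      swap <- sample(decoy_idx, min(length(noised), length(decoy_idx)))
      pool_idx <- c(noised[seq_along(swap)], swap)
      out$score[pool_idx] <- sample(out$score[pool_idx])
    }
  }
  out
}
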