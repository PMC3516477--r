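config_abort <- function(msg) abort(msg, class = "silencerscan_config_error")
data_abort <- function(msg) abort(msg, class = "silencerscan_data_error")

stage_abort <- function(stage, e) {
  abort(
    sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
    class = c("silencerscan_stage_error", class(e)[[1]]),
    parent = e
  )
}

#' Run the full proto-silencer analysis pipeline
#'
#' Executes scan -> proto-silencer detection -> (where multi-species
#' inputs exist) orthology + conservation + chi-squared comparison ->
#' per-factor motif frequency, and writes every stage's table, a run
#' log, and a checksum manifest to `out_dir`. Three modes:
#'
#' * `"synthetic"`: generates a truth-known cohort from `sim_config` and
#'   runs every stage, including conservation.
#' * `"scan"`: scans user-supplied regions (`fasta` + `regions`) with
#'   the two motifs; conservation is skipped unless multi-species
#'   regions plus a similarity table are also given.
#' * `"precomputed"`: consumes existing match coordinate tables
#'   (`rap1_matches` / `abf1_matches`, paths or tibbles) and runs the
#'   co-occurrence stage without scanning — the mode in which the
#'   packaged published coordinate table is reproduced exactly.
#'
#' Reruns with identical inputs, configuration and seed produce
#' byte-identical outputs (the manifest checksums are stable).
#'
#' @param out_dir Output directory (created if needed).
#' @param mode `"synthetic"`, `"scan"` or `"precomputed"`.
#' @param config An [analysis_config()].
#' @param sim_config A [simulation_config()] (synthetic mode).
#' @param fasta,regions Paths to region FASTA and region table
#'   (scan mode); `regions` may also be a tibble with sequences.
#' @param rap1_motif,abf1_motif `pwm` objects, or paths to JASPAR-style
#'   count files (scan mode; defaults: the packaged Rap1 consensus and
#'   synthetic Abf1 matrix).
#' @param rap1_matches,abf1_matches Match tables or TSV paths
#'   (precomputed mode).
#' @param chip ChIP binding table (`factor`, `region_id`, `p`) or TSV
#'   path; enables the frequency stage in scan/precomputed mode.
#' @param seed Seed recorded in the log (synthetic mode uses
#'   `sim_config$seed`).
#' @return A `pipeline_run` object: `$results` (named list of stage
#'   tibbles), `$log` (tibble of stage events), `$manifest` (file,
#'   md5), `$config`.
#' @export
run_pipeline <- function(out_dir,
                         mode = c("synthetic", "scan", "precomputed"),
                         config = analysis_config(),
                         sim_config = simulation_config(),
                         fasta = NULL, regions = NULL,
                         rap1_motif = NULL, abf1_motif = NULL,
                         rap1_matches = NULL, abf1_matches = NULL,
                         chip = NULL,
                         seed = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- list()
  note <- function(stage, event, n = NA_integer_) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, event = event, n = as.integer(n)
    )
    message(sprintf("[%s] %s%s", stage, event, if (is.na(n)) "" else paste0(" (n = ", n, ")")))
  }
  results <- list()
  cohort <- NULL

  load_motif <- function(x, default_file) {
    if (is.null(x)) {
      if (is.null(default_file)) config_abort("A motif input is required.")
      x <- silencerscan_extdata(default_file)
    }
    if (inherits(x, "pwm")) {
      return(x)
    }
    if (is.character(x)) {
      if (!file.exists(x)) config_abort(sprintf("Motif file not found: %s", x))
      return(build_pwm(read_motif_counts(x), background_model(gc_background(0.38))))
    }
    config_abort("Motifs must be pwm objects or count-file paths.")
  }
  load_table <- function(x, reader, what) {
    if (is.null(x)) config_abort(sprintf("Mode '%s' requires %s.", mode, what))
    if (is.character(x)) {
      if (!file.exists(x)) config_abort(sprintf("File not found for %s: %s", what, x))
      return(reader(x))
    }
    tibble::as_tibble(x)
  }

  note("setup", paste0("mode=", mode))
  if (mode == "synthetic") {
    seed <- sim_config$seed
    cohort <- tryCatch(generate_cohort(sim_config), error = function(e) stage_abort("simulate", e))
    note("simulate", "cohort generated", nrow(cohort$truth))
    ref_regions <- dplyr::filter(cohort$regions, .data$species == cohort$reference)
    rap1_pwm <- cohort$motifs[[1]]
    abf1_pwm <- if (length(cohort$motifs) > 1) cohort$motifs[[2]] else NULL
    chip_tbl <- cohort$chip
  } else if (mode == "scan") {
    rap1_pwm <- if (is.null(rap1_motif)) {
      build_pwm(
        sites_to_counts(rap1_consensus(), motif_id = "RAP1"),
        background_model(gc_background(0.38))
      )
    } else {
      load_motif(rap1_motif, NULL)
    }
    abf1_pwm <- load_motif(abf1_motif, "abf1_synthetic_counts.txt")
    seqs <- load_table(fasta, read_fasta, "a region FASTA (`fasta`)")
    ref_regions <- if (is.character(regions)) {
      read_regions(regions, sequences = seqs)
    } else if (is.data.frame(regions)) {
      tibble::as_tibble(regions)
    } else {
      config_abort("Mode 'scan' requires `regions` (path or tibble).")
    }
    chip_tbl <- if (is.null(chip)) NULL else load_table(chip, function(p) readr::read_tsv(p, show_col_types = FALSE), "chip")
  } else {
    ref_regions <- NULL
    chip_tbl <- if (is.null(chip)) NULL else load_table(chip, function(p) readr::read_tsv(p, show_col_types = FALSE), "chip")
  }

  # scanning stage
  if (mode %in% c("synthetic", "scan")) {
    scan_one <- function(pwm) {
      tryCatch(
        scan_region_set(pwm, ref_regions, config$scan_alpha),
        error = function(e) stage_abort("scan", e)
      )
    }
    results$rap1_matches <- scan_one(rap1_pwm)
    note("scan", paste0("rap1 motif ", rap1_pwm$motif_id), nrow(results$rap1_matches))
    if (!is.null(abf1_pwm)) {
      results$abf1_matches <- scan_one(abf1_pwm)
      note("scan", paste0("abf1 motif ", abf1_pwm$motif_id), nrow(results$abf1_matches))
    }
  } else {
    results$rap1_matches <- load_table(rap1_matches, read_matches, "rap1 match table (`rap1_matches`)")
    results$abf1_matches <- load_table(abf1_matches, read_matches, "abf1 match table (`abf1_matches`)")
    note("scan", "precomputed matches loaded",
         nrow(results$rap1_matches) + nrow(results$abf1_matches))
  }

  # proto-silencer stage
  if (!is.null(results$abf1_matches)) {
    results$proto_silencers <- tryCatch(
      find_proto_silencers(
        results$rap1_matches, results$abf1_matches,
        window = config$cooccurrence_window
      ),
      error = function(e) stage_abort("protosilencers", e)
    )
    note("protosilencers", "pairs within window", nrow(results$proto_silencers))
  }

  # conservation stage (synthetic mode: full orthology + scans)
  if (mode == "synthetic" && length(cohort$species) > 1) {
    cons <- tryCatch(
      {
        orth <- rbh_orthology(
          cohort$similarities,
          dplyr::select(cohort$regions, dplyr::all_of(
            c("region_id", "species", "left_gene", "right_gene")
          )),
          reference = cohort$reference
        )
        other_regions <- dplyr::filter(cohort$regions, .data$species != cohort$reference)
        per_motif <- function(matches, pwm) {
          calls <- call_conservation(
            matches, orth, other_regions, pwm,
            alpha = config$scan_alpha,
            min_species = config$min_species_conserved,
            count_reference = config$count_reference
          )
          proto_ids <- unique(results$proto_silencers$region_id)
          proto_calls <- dplyr::filter(calls, .data$region_id %in% proto_ids)
          cmp <- if (nrow(proto_calls) > 0 && nrow(calls) > nrow(proto_calls)) {
            compare_conservation(calls, proto_calls)
          } else {
            NULL
          }
          list(calls = calls, comparison = cmp)
        }
        list(
          orthology = orth,
          rap1 = per_motif(results$rap1_matches, rap1_pwm),
          abf1 = if (!is.null(abf1_pwm)) per_motif(results$abf1_matches, abf1_pwm)
        )
      },
      error = function(e) stage_abort("conservation", e)
    )
    results$orthology <- cons$orthology
    note("conservation", "orthologous regions mapped", nrow(cons$orthology))
    summ <- purrr::imap_dfr(
      cons[c("rap1", "abf1")],
      function(x, motif) {
        if (is.null(x) || is.null(x$comparison)) {
          return(tibble::tibble())
        }
        dplyr::mutate(tidy(x$comparison), motif = motif, .before = 1)
      }
    )
    results$conservation_calls <- dplyr::bind_rows(
      if (!is.null(cons$rap1)) dplyr::mutate(cons$rap1$calls, motif = "rap1", .before = 1),
      if (!is.null(cons$abf1)) dplyr::mutate(cons$abf1$calls, motif = "abf1", .before = 1)
    )
    results$conservation_summary <- summ
    note("conservation", "sites called", nrow(results$conservation_calls))
  }

  # frequency stage
  if (!is.null(chip_tbl) && !is.null(ref_regions)) {
    results$frequency <- tryCatch(
      {
        tf_sets <- filter_tf_sets(
          chip_tbl,
          p_max = config$chip_p_max,
          min_regions = config$chip_min_regions
        )
        all_matches <- dplyr::bind_rows(results$rap1_matches, results$abf1_matches)
        if (nrow(tf_sets) > 0 && nrow(all_matches) > 0) {
          motif_frequency(tf_sets, all_matches, ref_regions,
            scale = config$frequency_scale
          )
        } else {
          tibble::tibble()
        }
      },
      error = function(e) stage_abort("frequency", e)
    )
    note("frequency", "factor-motif frequencies", nrow(results$frequency))
  }

  # write outputs + manifest
  written <- character(0)
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(results[[nm]], f)
      written <- c(written, f)
    }
  }
  cfg_file <- file.path(out_dir, "config.yaml")
  write_analysis_config(config, cfg_file)
  written <- c(written, cfg_file)

  log_tbl <- dplyr::bind_rows(log_rows)
  log_file <- file.path(out_dir, "run_log.tsv")
  readr::write_tsv(
    dplyr::mutate(log_tbl, seed = seed %||% NA_integer_, mode = mode),
    log_file
  )
  written <- c(written, log_file)

  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  note("done", "outputs written", length(written))

  structure(
    list(
      mode = mode, config = config, seed = seed,
      results = results, cohort = cohort,
      log = log_tbl, manifest = manifest, out_dir = out_dir
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> mode=%s, out_dir=%s\n", x$mode, x$out_dir))
  for (nm in names(x$results)) {
    if (is.data.frame(x$results[[nm]])) {
      cat(sprintf("  %-22s %d rows\n", nm, nrow(x$results[[nm]])))
    }
  }
  invisible(x)
}
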