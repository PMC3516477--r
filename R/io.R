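#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata/`; with no
#'   argument, lists the available files.
#' @return File path (character).
#' @export
silencerscan_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "silencerscan")))
  }
  path <- system.file("extdata", file, package = "silencerscan")
  if (!nzchar(path)) abort(sprintf("No packaged file '%s'.", file))
  path
}

#' Read / write FASTA sequence records
#'
#' Reading uppercases sequences, errors on duplicate ids, and masks any
#' non-ACGTN character to `N` with a warning. Writing wraps at 60
#' columns; write-then-read is the identity on ids and sequences.
#'
#' @param path FASTA file path.
#' @param records Tibble with columns `id`, `sequence`.
#' @return `read_fasta` returns a tibble (`id`, `sequence`);
#'   `write_fasta` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("Empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA ids in %s (e.g. %s).", path, ids[duplicated(ids)][[1]]))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warn(sprintf(
      "%d record(s) contain non-ACGTN characters; masking to N.", sum(bad)
    ))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  if (anyDuplicated(records$id)) abort("Duplicate ids; refusing to write FASTA.")
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

region_columns <- c(
  "region_id", "species", "chromosome", "start", "end",
  "left_gene", "right_gene"
)

#' Read an intergenic-region table (TSV or BED)
#'
#' Two dialects, declared by file extension. A `.bed` file is 0-based
#' half-open (BED convention): start `s` becomes internal start `s + 1`;
#' columns are chrom, start, end, region_id, with optional extra columns
#' ignored. Any other extension is read as a headered TSV with 1-based
#' inclusive coordinates and columns `region_id`, `species`,
#' `chromosome`, `start`, `end`, `left_gene`, `right_gene` (missing
#' non-coordinate columns are filled with `NA`). All internal
#' coordinates are 1-based inclusive. Chromosome names are taken as-is.
#'
#' @param path File path.
#' @param sequences Optional tibble from [read_fasta()]; when given,
#'   sequences are joined on `region_id` and lengths validated.
#' @return Region tibble.
#' @export
read_regions <- function(path, sequences = NULL) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    raw <- readr::read_tsv(
      path,
      col_names = FALSE, show_col_types = FALSE, comment = "#"
    )
    if (ncol(raw) < 4) abort("BED region file needs at least 4 columns (chrom, start, end, name).")
    out <- tibble::tibble(
      region_id = as.character(raw[[4]]),
      species = NA_character_,
      chromosome = as.character(raw[[1]]),
      start = as.integer(raw[[2]]) + 1L,
      end = as.integer(raw[[3]]),
      left_gene = NA_character_,
      right_gene = NA_character_
    )
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    need <- c("region_id", "chromosome", "start", "end")
    missing <- setdiff(need, names(raw))
    if (length(missing) > 0) {
      abort(paste0("Region TSV is missing column(s): ", paste(missing, collapse = ", ")))
    }
    for (col in setdiff(region_columns, names(raw))) raw[[col]] <- NA_character_
    out <- dplyr::mutate(
      dplyr::select(raw, dplyr::all_of(region_columns)),
      start = as.integer(.data$start), end = as.integer(.data$end)
    )
  }
  if (any(out$end < out$start)) {
    bad <- which(out$end < out$start)[[1]]
    abort(sprintf("Region %s has end < start.", out$region_id[[bad]]))
  }
  if (anyDuplicated(out$region_id)) abort("Duplicate region_id in region table.")
  if (!is.null(sequences)) {
    out <- dplyr::left_join(
      out, dplyr::rename(sequences, region_id = "id"),
      by = "region_id"
    )
    if (any(is.na(out$sequence))) {
      abort("Some regions have no sequence record in the FASTA input.")
    }
    len_bad <- nchar(out$sequence) != out$end - out$start + 1
    if (any(len_bad)) {
      abort(sprintf(
        "Region %s: sequence length does not match its coordinates.",
        out$region_id[which(len_bad)[[1]]]
      ))
    }
  }
  out
}

#' Write / read a motif-match table as TSV
#'
#' @param matches Match tibble (see [scan_region_set()]).
#' @param path File path.
#' @return `read_matches` returns the match tibble; writers return
#'   `path` invisibly.
#' @export
write_matches <- function(matches, path) {
  readr::write_tsv(matches, path)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("region_id", "chromosome", "position")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    abort(paste0("Match table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  dplyr::mutate(out, position = as.integer(.data$position))
}

#' Write matches as BED6
#'
#' BED is 0-based half-open: a match at internal position `p` of length
#' `L` is written with start `p - 1` and end `p - 1 + L`. The BED score
#' column is the log-odds score min-max scaled across the written set to
#' `0..1000`; name is the motif id.
#'
#' @param matches Match tibble.
#' @param motif_length Motif length in bp (to compute interval ends).
#' @param path File path.
#' @export
write_matches_bed <- function(matches, motif_length, path) {
  rng <- range(matches$score)
  scaled <- if (diff(rng) > 0) (matches$score - rng[[1]]) / diff(rng) else rep(1, nrow(matches))
  bed <- tibble::tibble(
    chrom = matches$chromosome,
    start = matches$position - 1L,
    end = matches$position - 1L + as.integer(motif_length),
    name = matches$motif_id,
    score = as.integer(round(1000 * scaled)),
    strand = matches$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a JASPAR-style plain-text count matrix
#'
#' Four labelled rows A/C/G/T of whitespace-separated counts, optionally
#' bracketed JASPAR-style, optionally preceded by a `>motif_id` header.
#'
#' @param path File path.
#' @return A `motif_counts` object.
#' @export
read_motif_counts <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  motif_id <- tools::file_path_sans_ext(basename(path))
  if (length(lines) > 0 && startsWith(lines[[1]], ">")) {
    motif_id <- trimws(sub("^>", "", lines[[1]]))
    lines <- lines[-1]
  }
  padded <- paste0(lines, " ")
  base_lines <- substr(padded, 1, 1) %in% DNA_BASES &
    substr(padded, 2, 2) %in% c(" ", "\t", "|", "[")
  lines <- lines[base_lines]
  if (length(lines) != 4) {
    abort(sprintf("Expected 4 base rows (A/C/G/T) in %s, found %d.", path, sum(base_lines)))
  }
  parse_row <- function(line) {
    base <- substr(line, 1, 1)
    nums <- gsub("[][|]", " ", substr(line, 2, nchar(line)))
    vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    list(base = base, vals = vals)
  }
  rows <- lapply(lines, parse_row)
  bases <- vapply(rows, `[[`, "", "base")
  if (!setequal(bases, DNA_BASES)) abort("Count rows must be labelled A, C, G, T.")
  lens <- vapply(rows, function(r) length(r$vals), 1L)
  if (length(unique(lens)) != 1) abort("Count rows have differing lengths.")
  mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(mat) <- bases
  motif_counts(mat[DNA_BASES, , drop = FALSE], motif_id = motif_id)
}

#' Read an aligned-sites file
#'
#' One aligned binding site per line (`#` comments and blank lines
#' ignored), all the same length, over ACGT.
#'
#' @param path File path.
#' @param motif_id Motif id for the resulting counts (default: file stem).
#' @return A `motif_counts` object.
#' @export
read_sites <- function(path, motif_id = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("No sites in %s.", path))
  if (is.null(motif_id)) motif_id <- tools::file_path_sans_ext(basename(path))
  sites_to_counts(lines, motif_id = motif_id)
}

#' Analysis configuration
#'
#' The thresholds of the proto-silencer analysis, with the study's
#' defaults: co-occurrence window 50 bp; conservation in at least 3
#' species (reference species counted); scan p-value cutoff 1e-9; ChIP
#' binding filter p < 0.05 over at least 60 distinct regions; frequency
#' scale 10,000 bp (per 10 kb).
#'
#' @param cooccurrence_window,min_species_conserved,scan_alpha,chip_p_max,chip_min_regions,frequency_scale
#'   See description.
#' @param count_reference Whether the reference species counts towards
#'   `min_species_conserved`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cooccurrence_window = 50,
                            min_species_conserved = 3,
                            scan_alpha = 1e-9,
                            chip_p_max = 0.05,
                            chip_min_regions = 60,
                            frequency_scale = 10000,
                            count_reference = TRUE) {
  stopifnot(
    cooccurrence_window > 0, min_species_conserved > 0,
    scan_alpha > 0, scan_alpha <= 1,
    chip_p_max > 0, chip_p_max <= 1,
    chip_min_regions > 0, frequency_scale > 0
  )
  structure(
    list(
      cooccurrence_window = cooccurrence_window,
      min_species_conserved = as.integer(min_species_conserved),
      scan_alpha = scan_alpha,
      chip_p_max = chip_p_max,
      chip_min_regions = as.integer(chip_min_regions),
      frequency_scale = frequency_scale,
      count_reference = isTRUE(count_reference)
    ),
    class = "analysis_config"
  )
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path; keys are the [analysis_config()] fields
#'   (missing keys take the defaults; unknown keys error).
#' @param config An `analysis_config`.
#' @return `read_analysis_config` returns an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
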