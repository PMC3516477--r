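#' The genome-wide Rap1 consensus binding-site sequence
#'
#' `ACACCCATACATT`, the 13-bp genome-wide consensus bound by Rap1 with
#' roughly ten-fold higher affinity than the weak silencer variant.
#'
#' @return Character scalar.
#' @export
rap1_consensus <- function() "ACACCCATACATT"

#' Rap1 binding-site sequence variants
#'
#' The genome-wide consensus plus the weak silencer-resident variants
#' (the HMR-E variant circulates in three printed forms, all kept and
#' labelled; no canonical form is asserted) and the HML-E site.
#'
#' @return Tibble with columns `name`, `sequence`.
#' @export
rap1_site_variants <- function() {
  readr::read_tsv(
    silencerscan_extdata("rap1_site_variants.tsv"),
    comment = "#", show_col_types = FALSE
  )
}

#' The 25 published proto-silencer coordinate pairs
#'
#' The packaged table of euchromatic loci at which Rap1 and Abf1
#' binding-site matches co-occur within 50 bp (chromosome plus the two
#' single-coordinate site anchors, from the MacIsaac et al. 2006 site
#' map). Each row is one locus; a synthetic `region_id` (`ps_01` ...)
#' ties the pair together for precomputed-matches analyses.
#'
#' @return Tibble with columns `region_id`, `chromosome`,
#'   `rap1_position`, `abf1_position`.
#' @export
published_proto_silencers <- function() {
  tab <- readr::read_tsv(
    silencerscan_extdata("published_proto_silencers.tsv"),
    comment = "#", show_col_types = FALSE
  )
  dplyr::mutate(tab,
    region_id = sprintf("ps_%02d", dplyr::row_number()),
    .before = 1
  )
}

#' Published proto-silencer coordinates as a match table
#'
#' Reshapes [published_proto_silencers()] into the match-table layout the
#' analysis functions consume ("precomputed-matches" mode), for one
#' factor at a time.
#'
#' @param factor `"rap1"` or `"abf1"`.
#' @return Match tibble with columns `motif_id`, `region_id`,
#'   `chromosome`, `position`.
#' @export
published_proto_silencer_sites <- function(factor = c("rap1", "abf1")) {
  factor <- match.arg(factor)
  tab <- published_proto_silencers()
  tibble::tibble(
    motif_id = toupper(factor),
    region_id = tab$region_id,
    chromosome = tab$chromosome,
    position = tab[[paste0(factor, "_position")]]
  )
}
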