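#' Shipped TRPM8 study inputs
#'
#' The package ships the tabular inputs of its worked protein family, the
#' cold- and menthol-activated TRPM8 cation channel, as plain TSV under
#' `extdata`:
#'
#' * `trpm8_region_map()` -- the 28 named domains/motifs of human TRPM8
#'   (MHR1-4, transmembrane segments and loops, pore region, TRP
#'   box/domain, coiled coils, functional motifs), 1-based inclusive
#'   coordinates on NP_076985.4. Regions overlap by design.
#' * `trpm8_manifest()` -- the 39 family accessions (24 full-length, 15
#'   fragmented) with species, expected length and source database.
#' * `trpm8_divergence_config()` -- the lineage comparisons for the
#'   rate-versus-time analysis, with literature divergence-time anchors
#'   (MYA). Edit or replace to change the time axis.
#' * `trpm8_epitope()` -- the 13-mer antibody epitope peptide
#'   (pore-loop residues 917-929 of human TRPM8).
#'
#' @return A tibble (or character scalar for the epitope).
#' @name trpm8_inputs
NULL

#' @rdname trpm8_inputs
#' @export
trpm8_region_map <- function() {
  load_region_map(system.file("extdata", "trpm8_regions.tsv",
                              package = "domevol"))
}

#' @rdname trpm8_inputs
#' @export
trpm8_manifest <- function() {
  load_manifest(system.file("extdata", "trpm8_manifest.tsv",
                            package = "domevol"))
}

#' @rdname trpm8_inputs
#' @export
trpm8_divergence_config <- function() {
  readr::read_tsv(system.file("extdata", "trpm8_divergence_times.tsv",
                              package = "domevol"),
                  show_col_types = FALSE)
}

#' @rdname trpm8_inputs
#' @export
trpm8_epitope <- function() "SDVDGTTYDFAHC"
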