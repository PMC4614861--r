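#' Fetch protein sequences by accession (optional, needs network)
#'
#' Downloads protein FASTA records from NCBI (efetch) or Ensembl (REST)
#' into a cache directory, one file per accession, and returns them as a
#' sequence tibble. This is optional plumbing: nothing else in the
#' package requires network access, and no test performs a fetch. Ensembl
#' protein ids (`ENS...P...`) are routed to Ensembl automatically.
#'
#' @param accessions Character vector of protein accessions.
#' @param cache_dir Directory for per-accession FASTA files; existing
#'   files are reused without a download.
#' @param quiet Passed to [utils::download.file()].
#' @return A sequence tibble (see [read_fasta()]), rows in `accessions`
#'   order with `id` replaced by the accession.
#' @export
fetch_protein_sequences <- function(accessions,
                                    cache_dir = file.path(tempdir(), "domevol_cache"),
                                    quiet = TRUE) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  one <- function(acc) {
    dest <- file.path(cache_dir, paste0(acc, ".fa"))
    if (!file.exists(dest)) {
      url <- if (grepl("^ENS", acc)) {
        paste0("https://rest.ensembl.org/sequence/id/", sub("\\.\\d+$", "", acc),
               "?type=protein;content-type=text/x-fasta")
      } else {
        paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=protein&id=", acc, "&rettype=fasta&retmode=text")
      }
      status <- tryCatch(utils::download.file(url, dest, quiet = quiet),
                         error = function(e) -1L, warning = function(w) -1L)
      if (!identical(status, 0L) || !file.size(dest)) {
        unlink(dest)
        abort(paste0("could not fetch accession ", acc,
                     " (network unavailable?)"))
      }
    }
    s <- read_fasta(dest, source = "fetched")
    s$id <- acc
    s
  }
  bind_rows(map(accessions, one))
}

#' Align sequences with an external aligner
#'
#' Runs MAFFT (or any executable with a compatible FASTA-in/FASTA-out
#' interface) on a sequence tibble and returns the validated alignment.
#'
#' @param seqs Sequence tibble.
#' @param exec Aligner executable.
#' @param args Extra command-line arguments.
#' @return An alignment tibble.
#' @export
align_sequences <- function(seqs, exec = "mafft", args = "--auto") {
  if (!nzchar(Sys.which(exec))) abort(paste0("aligner not found: ", exec))
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".afa")
  write_fasta(seqs, fin)
  status <- system2(exec, c(args, "--quiet", fin), stdout = fout)
  if (!identical(status, 0L)) abort("aligner failed")
  read_alignment(fout)
}

#' The jointly aligned full-length family reference MSA
#'
#' Loads the cached joint alignment of the full-length family members
#' (for the worked TRPM8 set: the 24 complete accessions of the shipped
#' manifest, fetched and aligned with [fetch_protein_sequences()] and
#' [align_sequences()]). The alignment is not shipped with the package --
#' the sequences live in public databases -- so this errors with build
#' instructions until a cache has been created on a networked machine.
#'
#' @param path Path to the cached aligned FASTA; the default looks for
#'   `trpm8_vertebrates.afa` under the package's `extdata` or in
#'   `getOption("domevol.msa_cache")`.
#' @return An alignment tibble.
#' @export
reference_family_msa <- function(path = NULL) {
  path <- path %||% getOption("domevol.msa_cache") %||%
    system.file("extdata", "trpm8_vertebrates.afa", package = "domevol")
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    abort(paste0(
      "reference family MSA not cached. On a networked machine run:\n",
      "  mf <- load_manifest(system.file('extdata', 'trpm8_manifest.tsv',",
      " package = 'domevol'))\n",
      "  seqs <- fetch_protein_sequences(mf$accession[mf$complete])\n",
      "  aln <- align_sequences(seqs)\n",
      "  write_fasta(aln, '<cache>/trpm8_vertebrates.afa')\n",
      "then set options(domevol.msa_cache = '<cache>/trpm8_vertebrates.afa')."))
  }
  read_alignment(path)
}
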