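#' Read protein sequences from a FASTA file
#'
#' Sequences are returned as a tibble with one row per record, the
#' representation every other function in the package consumes. Record ids
#' are the first whitespace-delimited token of each header; the remainder of
#' the header (if any) is kept as the `species` label. Letters are
#' upper-cased, `.` is normalised to the gap character `-`, and the ambiguity
#' codes B, Z and U are collapsed to `X` with a warning.
#'
#' @param path Path to a FASTA file.
#' @param source Free-text provenance tag stored in the `source` column
#'   (defaults to the file name).
#' @param gaps Should gap characters be accepted? `read_fasta()` refuses
#'   them; [read_alignment()] allows them.
#' @return A tibble with columns `id`, `species`, `residues`, `source`.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 Homo sapiens", "MKLSACDE", ">s2", "MKLSACDD"), path)
#' read_fasta(path)
read_fasta <- function(path, source = basename(path), gaps = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort("no sequences in FASTA file")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("\\s", headers),
                    sub("^\\S+\\s+", "", headers), NA_character_)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  residues <- clean_residues(unname(as.character(set)), ids, gaps = gaps)
  tibble(id = ids, species = species, residues = residues, source = source)
}

# Upper-case, normalise '.' to '-', map B/Z/U to X, reject anything else.
clean_residues <- function(residues, ids, gaps = FALSE) {
  residues <- toupper(residues)
  residues <- gsub(".", "-", residues, fixed = TRUE)
  if (any(grepl("[BZU]", residues))) {
    warn("ambiguous residues B/Z/U mapped to X")
    residues <- gsub("[BZU]", "X", residues)
  }
  allowed <- paste0(AA_OK_REGEX, if (gaps) "-" else "")
  bad <- regexpr(paste0("[^", allowed, "]"), residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("illegal character '%s' in sequence '%s' at position %d",
                  substr(residues[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(!nzchar(residues))) {
    abort(paste0("empty sequence: ", ids[which(!nzchar(residues))[1]]))
  }
  residues
}
AA_OK_REGEX <- "ARNDCQEGHILKMFPSTWYVX"

#' Write sequences to a FASTA file
#'
#' @param seqs A sequence tibble (see [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  species <- if ("species" %in% names(seqs)) seqs$species else NA_character_
  hdr <- ifelse(is.na(species) | !nzchar(species), seqs$id,
                paste(seqs$id, species))
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    substring(s, seq(1, nchar(s), width),
              pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
  }
  lines <- unlist(map2(hdr, seqs$residues,
                       function(h, s) c(paste0(">", h), wrap(s))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal format. All rows must have identical
#' length; columns consisting entirely of gaps are removed (with a message
#' giving the count) so that downstream column statistics are well defined.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @inheritParams read_fasta
#' @return An alignment tibble: columns `id`, `species`, `residues`,
#'   `source`, with every `residues` string the same length (the attribute
#'   is recoverable via [aln_ncols()]).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           source = basename(path)) {
  format <- match.arg(format)
  if (format == "clustal") {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    set <- as.character(Biostrings::unmasked(msa))
    aln <- tibble(id = names(set), species = NA_character_,
                  residues = clean_residues(unname(set), names(set), gaps = TRUE),
                  source = source)
  } else {
    aln <- read_fasta(path, source = source, gaps = TRUE)
  }
  as_alignment(aln)
}

#' Validate a tibble as a multiple sequence alignment
#'
#' Checks for at least two rows, unique ids and equal row lengths, then
#' drops all-gap columns.
#'
#' @param seqs Sequence tibble with gapped `residues`.
#' @return The validated alignment tibble.
#' @export
as_alignment <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  if (nrow(seqs) < 2) abort("an alignment needs at least 2 sequences")
  dup <- unique(seqs$id[duplicated(seqs$id)])
  if (length(dup)) abort(paste0("duplicate sequence id(s): ",
                                paste(dup, collapse = ", ")))
  len <- nchar(seqs$residues)
  if (length(unique(len)) > 1) {
    ragged <- seqs$id[len != max(len)]
    abort(paste0("ragged alignment rows: ", paste(ragged, collapse = ", ")))
  }
  m <- aln_matrix(seqs)
  all_gap <- colSums(m != "-") == 0
  if (any(all_gap)) {
    inform(sprintf("removed %d all-gap column(s)", sum(all_gap)))
    m <- m[, !all_gap, drop = FALSE]
    seqs$residues <- unname(apply(m, 1, paste, collapse = ""))
  }
  seqs
}

#' Alignment dimensions and matrix view
#'
#' `aln_ncols()` returns the aligned length; `aln_matrix()` returns the
#' alignment as a character matrix (rows = sequences, columns = alignment
#' columns) for column-wise computation.
#'
#' @param aln An alignment tibble.
#' @return An integer, or a character matrix with rownames taken from `id`.
#' @export
aln_ncols <- function(aln) {
  len <- unique(nchar(aln$residues))
  if (length(len) != 1) abort("ragged alignment")
  len
}

#' @rdname aln_ncols
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Map reference positions to alignment columns and back
#'
#' `ref_to_column()` returns the 1-based alignment column holding the
#' `pos`-th non-gap residue of the reference row; `column_to_ref()` is the
#' inverse and returns `NA` for columns where the reference is gapped.
#' Both are vectorised over positions.
#'
#' @param aln An alignment tibble.
#' @param reference_id Id of the anchoring row.
#' @param pos 1-based ungapped reference positions.
#' @param column 1-based alignment columns.
#' @return An integer vector.
#' @export
#' @examples
#' aln <- tibble::tibble(id = c("r", "s"), residues = c("A-CD", "AACD"))
#' ref_to_column(aln, "r", 2)  # -> 3
#' column_to_ref(aln, "r", 2)  # -> NA (gap)
ref_to_column <- function(aln, reference_id, pos) {
  row <- reference_row(aln, reference_id)
  nongap <- which(row != "-")
  if (any(pos < 1 | pos > length(nongap))) {
    abort(sprintf("position out of range 1..%d for reference '%s'",
                  length(nongap), reference_id))
  }
  nongap[pos]
}

#' @rdname ref_to_column
#' @export
column_to_ref <- function(aln, reference_id, column) {
  row <- reference_row(aln, reference_id)
  if (any(column < 1 | column > length(row))) {
    abort(sprintf("column out of range 1..%d", length(row)))
  }
  refpos <- cumsum(row != "-")
  out <- refpos[column]
  out[row[column] == "-"] <- NA_integer_
  as.integer(out)
}

reference_row <- function(aln, reference_id) {
  i <- match(reference_id, aln$id)
  if (is.na(i)) abort(paste0("reference id not in alignment: ", reference_id))
  strsplit(aln$residues[i], "", fixed = TRUE)[[1]]
}

#' Locate an epitope peptide in each sequence
#'
#' Slides the peptide along each (ungapped) sequence and reports the window
#' with the most exact positional matches; a hit is reported only when the
#' number of mismatches is at most `max_mismatch`. Ties are broken by the
#' smallest start. The worked family's use case is the 13-mer antibody
#' epitope `SDVDGTTYDFAHC` (pore-loop residues 917-929 of human TRPM8).
#'
#' @param seqs Sequence tibble.
#' @param peptide Peptide to locate (amino-acid letters).
#' @param max_mismatch Maximum tolerated mismatches for a hit.
#' @return A tibble with columns `id`, `start`, `matches`, `mismatches`,
#'   `hit`. `start`/`matches` refer to the best window even when `hit` is
#'   `FALSE`.
#' @export
scan_epitope <- function(seqs, peptide, max_mismatch = 0) {
  if (!nzchar(peptide)) abort("empty peptide")
  peptide <- toupper(peptide)
  if (grepl(paste0("[^", AA_OK_REGEX, "]"), peptide)) {
    abort("peptide contains non amino-acid letters")
  }
  pep <- strsplit(peptide, "")[[1]]
  m <- length(pep)
  one <- function(resid, id) {
    s <- strsplit(gsub("-", "", resid, fixed = TRUE), "")[[1]]
    if (length(s) < m) {
      abort(sprintf("peptide longer than sequence '%s'", id))
    }
    nwin <- length(s) - m + 1
    matches <- vapply(seq_len(nwin), function(st) {
      sum(s[st:(st + m - 1)] == pep)
    }, integer(1))
    best <- which.max(matches)  # which.max takes the first (smallest start)
    n_match <- matches[best]
    tibble(id = id, start = as.integer(best),
           matches = n_match,
           mismatches = m - n_match,
           hit = (m - n_match) <= max_mismatch)
  }
  bind_rows(map2(seqs$residues, seqs$id, one))
}

#' Load a reference-anchored region map
#'
#' A region map names intervals (1-based, inclusive) on the ungapped
#' reference sequence: domains, transmembrane segments, loops, motifs.
#' Overlapping regions are permitted (domain tables routinely overlap).
#'
#' @param path TSV with columns `region`, `start`, `end`.
#' @return A tibble with columns `region`, `start`, `end`, `length`.
#' @export
load_region_map <- function(path) {
  rm <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          region = readr::col_character(),
                          start = readr::col_integer(),
                          end = readr::col_integer()))
  validate_region_map(rm)
}

#' @rdname load_region_map
#' @param region_map A region-map tibble.
#' @param reference_length Optional ungapped reference length to bind the
#'   coordinates against; regions running past it raise an error.
#' @export
validate_region_map <- function(region_map, reference_length = NULL) {
  need <- c("region", "start", "end")
  if (!all(need %in% names(region_map))) {
    abort("region map needs columns region, start, end")
  }
  dup <- unique(region_map$region[duplicated(region_map$region)])
  if (length(dup)) abort(paste0("duplicate region name(s): ",
                                paste(dup, collapse = ", ")))
  bad <- region_map$start < 1 | region_map$start > region_map$end
  if (any(bad)) {
    abort(paste0("invalid interval for region(s): ",
                 paste(region_map$region[bad], collapse = ", ")))
  }
  if (!is.null(reference_length)) {
    over <- region_map$end > reference_length
    if (any(over)) {
      abort(paste0("region(s) beyond reference length ", reference_length,
                   ": ", paste(region_map$region[over], collapse = ", ")))
    }
  }
  mutate(as_tibble(region_map),
         length = .data$end - .data$start + 1L)
}

#' Load a sequence manifest
#'
#' A manifest lists the family members under study: one row per accession
#' with the species label, expected length and source database, plus a
#' completeness flag separating full-length from fragmented sequences.
#'
#' @param path TSV with columns `species`, `scientific_name`, `accession`,
#'   `length`, `source`, `complete`.
#' @return A validated tibble.
#' @export
load_manifest <- function(path) {
  mf <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("species", "accession", "source", "complete")
  if (!all(need %in% names(mf))) {
    abort(paste0("manifest needs columns: ", paste(need, collapse = ", ")))
  }
  dup <- unique(mf$accession[duplicated(mf$accession)])
  if (length(dup)) abort(paste0("duplicate accession(s): ",
                                paste(dup, collapse = ", ")))
  if (!"length" %in% names(mf)) mf$length <- NA_integer_
  if (any(is.na(mf$length))) warn("manifest rows with missing expected length")
  if (any(!is.na(mf$length) & mf$length <= 0)) {
    abort("expected lengths must be positive")
  }
  mf$complete <- as.logical(mf$complete)
  as_tibble(mf)
}
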