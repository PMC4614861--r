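#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with a substitution matrix and affine gap costs (a gap of length L costs
#' `gap_open + L * gap_extend`). The default scoring (BLOSUM62, open 10,
#' extend 0.5) approximates the defaults of the common protein aligners.
#'
#' @param seqs A sequence tibble with exactly two rows (or from which the
#'   two ids in `pair` are taken).
#' @param pair Optional character vector of two ids selecting the rows.
#' @param substitution Name of the substitution matrix (any matrix shipped
#'   with Biostrings, e.g. `"BLOSUM62"`), or a matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A two-row alignment tibble with attribute `score`.
#' @export
global_align <- function(seqs, pair = NULL, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!is.null(pair)) {
    seqs <- seqs[match(pair, seqs$id), , drop = FALSE]
  }
  if (nrow(seqs) != 2) abort("global_align needs exactly two sequences")
  if (any(!nzchar(seqs$residues))) abort("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqs$residues[1]),
    Biostrings::AAString(seqs$residues[2]),
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  out <- tibble(
    id = seqs$id,
    species = if ("species" %in% names(seqs)) seqs$species else NA_character_,
    residues = c(as.character(Biostrings::alignedPattern(pa)),
                 as.character(Biostrings::alignedSubject(pa))),
    source = "global_align")
  attr(out, "score") <- Biostrings::score(pa)
  out
}

#' Percent identity between two aligned rows
#'
#' @param pair A two-row alignment tibble.
#' @param mode Denominator convention: `"both"` counts columns where
#'   neither row is a gap (the default and the convention used for the
#'   family identity tables), `"shorter"` divides by the shorter ungapped
#'   sequence length, `"alignment"` by the full alignment length.
#' @return A one-row tibble: `id_a`, `id_b`, `percent_identity`,
#'   `n_compared`, `mode`.
#' @export
percent_identity <- function(pair, mode = c("both", "shorter", "alignment")) {
  mode <- match.arg(mode)
  if (nrow(pair) != 2) abort("percent_identity needs a 2-row alignment")
  m <- aln_matrix(pair)
  a <- m[1, ]; b <- m[2, ]
  both <- a != "-" & b != "-"
  ident <- sum(a == b & both)
  denom <- switch(mode,
                  both = sum(both),
                  shorter = min(sum(a != "-"), sum(b != "-")),
                  alignment = length(a))
  if (denom < 1) abort(sprintf("no comparable columns for pair %s / %s",
                               pair$id[1], pair$id[2]))
  tibble(id_a = pair$id[1], id_b = pair$id[2],
         percent_identity = 100 * ident / denom,
         n_compared = as.integer(denom), mode = mode)
}

#' All pairwise identities within a multiple alignment
#'
#' Computes [percent_identity()] for every (or a selected) pair of rows of
#' a family MSA -- the computation behind published identity tables, where
#' each cell is the identity of two members measured within the joint
#' alignment.
#'
#' @param msa An alignment tibble.
#' @param pairs Optional two-column data frame of id pairs; default all
#'   unordered pairs.
#' @inheritParams percent_identity
#' @return A tibble, one row per pair.
#' @export
pairwise_identity <- function(msa, pairs = NULL, mode = "both") {
  if (is.null(pairs)) {
    cmb <- utils::combn(msa$id, 2)
    pairs <- tibble(id_a = cmb[1, ], id_b = cmb[2, ])
  } else {
    pairs <- setNames(as_tibble(pairs), c("id_a", "id_b"))
  }
  bind_rows(pmap(pairs, function(id_a, id_b) {
    percent_identity(msa[match(c(id_a, id_b), msa$id), ], mode = mode)
  }))
}

# Integer-coded alignment matrix: 1..20 for residues, 0 for gap/X.
aln_int_matrix <- function(msa) {
  m <- aln_matrix(msa)
  im <- match(m, AA20, nomatch = 0L)
  dim(im) <- dim(m)
  rownames(im) <- rownames(m)
  im
}

# p-distance between two integer-coded rows under pairwise deletion.
# Returns c(p, n_compared); X and gaps are excluded from comparison.
p_dist_rows <- function(x, y) {
  ok <- x > 0L & y > 0L
  n <- sum(ok)
  c(p = if (n) sum(x[ok] != y[ok]) / n else NA_real_, n = n)
}

#' Pairwise distance matrix from an alignment
#'
#' Uncorrected p-distances (fraction of differing residues over comparable
#' columns, pairwise deletion of columns where either row has a gap),
#' optionally scaled to changes per 100 sites and/or Poisson-corrected
#' (`-ln(1 - p) * 100`). Pairwise deletion is the default because family
#' sets routinely include fragmented sequences.
#'
#' @param msa An alignment tibble.
#' @param scale `"fraction"` or `"per100"` (changes per 100 sites).
#' @param correction `"none"` or `"poisson"`.
#' @return A long tibble `id_a`, `id_b`, `distance`, `n_compared` covering
#'   all unordered pairs, with class `"dist_tbl"`. Use [as_dist_matrix()]
#'   for the square-matrix view.
#' @export
p_distance_matrix <- function(msa, scale = c("per100", "fraction"),
                              correction = c("none", "poisson")) {
  scale <- match.arg(scale)
  correction <- match.arg(correction)
  if (nrow(msa) < 2) abort("need at least 2 sequences")
  im <- aln_int_matrix(msa)
  cmb <- utils::combn(nrow(msa), 2)
  res <- apply(cmb, 2, function(ij) p_dist_rows(im[ij[1], ], im[ij[2], ]))
  if (anyNA(res["p", ])) {
    bad <- which(is.na(res["p", ]))[1]
    abort(sprintf("no comparable columns for pair %s / %s",
                  msa$id[cmb[1, bad]], msa$id[cmb[2, bad]]))
  }
  d <- unname(res["p", ])
  if (correction == "poisson") {
    if (any(d >= 1)) abort("Poisson correction undefined at p >= 1")
    d <- -log(1 - d)
  }
  if (scale == "per100") d <- d * 100
  out <- tibble(id_a = msa$id[cmb[1, ]], id_b = msa$id[cmb[2, ]],
                distance = d, n_compared = as.integer(res["n", ]))
  class(out) <- c("dist_tbl", class(out))
  attr(out, "labels") <- msa$id
  attr(out, "scale") <- scale
  attr(out, "correction") <- correction
  out
}

#' Square-matrix view of a pairwise distance table
#'
#' @param d A `dist_tbl` from [p_distance_matrix()].
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
as_dist_matrix <- function(d) {
  labels <- attr(d, "labels") %||% unique(c(d$id_a, d$id_b))
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  i <- match(d$id_a, labels); j <- match(d$id_b, labels)
  m[cbind(i, j)] <- d$distance
  m[cbind(j, i)] <- d$distance
  m
}
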