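#' Parse a variant table
#'
#' Reads a TSV of per-variant records. The protein change can be given
#' either as a single `protein_change` column in `p.Arg1008Gln` or
#' `R1008Q` style, or as separate `ref_aa` / `protein_position` / `alt_aa`
#' columns. Three-letter codes are normalised to one-letter. Rows with a
#' malformed protein change, or with `ref_aa == alt_aa`, are rejected with
#' a warning (count stored in attribute `n_rejected`). SIFT and PolyPhen
#' numeric scores are optional columns; `variant_class` and `consequence`
#' are carried as free strings.
#'
#' @param path Path to a TSV file with a header.
#' @return A tibble of variant records: `protein_position`, `ref_aa`,
#'   `alt_aa`, `variant_class`, `consequence`, `sift`, `polyphen`.
#' @export
parse_variants <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  normalise_variants(raw)
}

#' @rdname parse_variants
#' @param variants A data frame in either of the accepted layouts.
#' @export
normalise_variants <- function(variants) {
  v <- as_tibble(variants)
  if ("protein_change" %in% names(v) &&
      !all(c("ref_aa", "protein_position", "alt_aa") %in% names(v))) {
    parsed <- parse_protein_change(v$protein_change)
    v$ref_aa <- parsed$ref_aa
    v$protein_position <- parsed$protein_position
    v$alt_aa <- parsed$alt_aa
  }
  need <- c("ref_aa", "protein_position", "alt_aa")
  if (!all(need %in% names(v))) {
    abort("variant table needs protein_change or ref_aa/protein_position/alt_aa")
  }
  v$ref_aa <- normalise_aa(v$ref_aa)
  v$alt_aa <- normalise_aa(v$alt_aa)
  v$protein_position <- as.integer(v$protein_position)
  for (col in c("variant_class", "consequence")) {
    if (!col %in% names(v)) v[[col]] <- NA_character_
  }
  for (col in c("sift", "polyphen")) {
    if (!col %in% names(v)) v[[col]] <- NA_real_
    v[[col]] <- as.numeric(v[[col]])
    bad <- !is.na(v[[col]]) & (v[[col]] < 0 | v[[col]] > 1)
    if (any(bad)) abort(paste0(col, " scores must lie in [0, 1]"))
  }
  ok <- !is.na(v$ref_aa) & !is.na(v$alt_aa) & !is.na(v$protein_position) &
    v$protein_position >= 1 & v$ref_aa != v$alt_aa
  if (any(!ok)) {
    warn(sprintf("rejected %d malformed or degenerate variant row(s)",
                 sum(!ok)))
  }
  out <- v[ok, ]
  attr(out, "n_rejected") <- sum(!ok)
  out
}

# "p.Arg1008Gln", "Arg1008Gln" or "R1008Q" -> components (NA when malformed)
parse_protein_change <- function(x) {
  x <- sub("^p\\.", "", x)
  m3 <- regmatches(x, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", x))
  m1 <- regmatches(x, regexec("^([A-Z])(\\d+)([A-Z])$", x))
  one <- function(m3i, m1i) {
    if (length(m3i) == 4) {
      ref <- unname(THREE_TO_ONE[m3i[2]]); alt <- unname(THREE_TO_ONE[m3i[4]])
      c(ref %||% NA_character_, m3i[3], alt %||% NA_character_)
    } else if (length(m1i) == 4) {
      m1i[2:4]
    } else c(NA_character_, NA_character_, NA_character_)
  }
  parts <- map2(m3, m1, one)
  tibble(ref_aa = map_chr(parts, 1),
         protein_position = suppressWarnings(as.integer(map_chr(parts, 2))),
         alt_aa = map_chr(parts, 3))
}

normalise_aa <- function(x) {
  x <- as.character(x)
  three <- nchar(x) == 3 & !is.na(x)
  x[three] <- unname(THREE_TO_ONE[x[three]])
  x <- toupper(x)
  x[!x %in% AA20] <- NA_character_
  x
}

#' Write a variant table to TSV
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Combine GD, SIFT and PolyPhen into damaging-vote tiers
#'
#' Each predictor casts a damaging vote (SIFT at or below its cutoff,
#' PolyPhen at or above, Grantham deviation at or above); the tier is the
#' number of damaging votes: `none`, `one`, `two` or `three`. Absent
#' scores are non-votes. The GD cutoff default of 65 is the classical
#' boundary of "radical" Grantham exchanges; SIFT 0.05 and PolyPhen 0.5
#' are the tools' conventional thresholds.
#'
#' @param gd,sift,polyphen Numeric score vectors (NA = absent).
#' @param gd_cutoff,sift_cutoff,polyphen_cutoff Damaging thresholds.
#' @return An ordered factor with levels `none < one < two < three`.
#' @export
vote_tier <- function(gd, sift, polyphen, gd_cutoff = 65,
                      sift_cutoff = 0.05, polyphen_cutoff = 0.5) {
  if (all(is.na(gd) & is.na(sift) & is.na(polyphen))) {
    abort("at least one score must be present")
  }
  votes <- (!is.na(gd) & gd >= gd_cutoff) +
    (!is.na(sift) & sift <= sift_cutoff) +
    (!is.na(polyphen) & polyphen >= polyphen_cutoff)
  factor(c("none", "one", "two", "three")[votes + 1],
         levels = c("none", "one", "two", "three"), ordered = TRUE)
}

#' Annotate variants with alignment-aware GV/GD and vote tiers
#'
#' For each missense record, maps the protein position to its alignment
#' column, evaluates [gvgd()] against the residues observed across the
#' family at that column, and adds the damaging-vote tier. Positions whose
#' column is all-gap apart from the reference fall back to the plain
#' Grantham distance (GV = 0 behaviour); positions beyond the reference
#' are skipped with a warning.
#'
#' @param variants Variant tibble (see [parse_variants()]).
#' @param msa Family alignment tibble.
#' @param reference_id Id of the reference row the protein positions
#'   refer to.
#' @inheritParams vote_tier
#' @return The variant tibble with columns `gv`, `gd`, `n_observed`,
#'   `tier` added (skipped rows dropped; count in attribute `n_skipped`).
#' @export
annotate_gvgd <- function(variants, msa, reference_id, gd_cutoff = 65,
                          sift_cutoff = 0.05, polyphen_cutoff = 0.5) {
  ref_len <- sum(reference_row(msa, reference_id) != "-")
  ok <- variants$protein_position <= ref_len
  if (any(!ok)) {
    warn(sprintf("skipped %d variant(s) beyond reference length %d",
                 sum(!ok), ref_len))
  }
  v <- variants[ok, ]
  m <- aln_matrix(msa)
  cols <- ref_to_column(msa, reference_id, v$protein_position)
  gg <- bind_rows(map2(cols, v$alt_aa, function(col, alt) {
    obs <- m[, col]
    obs <- obs[!obs %in% c("-", "X")]
    if (length(obs)) gvgd(obs, alt) else tibble(gv = NA, gd = NA, n_observed = 0L)
  }))
  # sequence-only fallback for unalignable positions
  fall <- is.na(gg$gd)
  if (any(fall)) {
    gg$gv[fall] <- 0
    gg$gd[fall] <- grantham_distance(v$ref_aa[fall], v$alt_aa[fall])
  }
  v$gv <- gg$gv
  v$gd <- gg$gd
  v$n_observed <- gg$n_observed
  v$tier <- vote_tier(v$gd, v$sift, v$polyphen, gd_cutoff, sift_cutoff,
                      polyphen_cutoff)
  attr(v, "n_skipped") <- sum(!ok)
  v
}

#' Tally variants by class and consequence
#'
#' @param variants Variant tibble with `variant_class` and `consequence`
#'   columns (free strings).
#' @return An object of class `variant_summary`: list with `by_class` and
#'   `by_consequence` tibbles (`level`, `n`, `pct`, sorted by count) and
#'   `total`.
#' @export
tally_variants <- function(variants) {
  one <- function(col) {
    if (!nrow(variants)) {
      return(tibble(level = character(), n = integer(), pct = numeric()))
    }
    out <- count(tibble(level = variants[[col]]), .data$level, sort = TRUE)
    mutate(out, pct = 100 * .data$n / sum(.data$n))
  }
  structure(list(by_class = one("variant_class"),
                 by_consequence = one("consequence"),
                 total = nrow(variants)),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("Variant summary: %d records\n", x$total))
  cat("By class:\n"); print(x$by_class)
  cat("By consequence:\n"); print(x$by_consequence)
  invisible(x)
}

#' Missense density per region
#'
#' Counts missense records falling in each region of a region map and
#' divides by region length, giving variants per residue. Records outside
#' the reference (i.e. past the last region end) are skipped with a
#' warning count.
#'
#' @param variants Variant tibble with `protein_position`.
#' @param region_map Region-map tibble.
#' @param reference_length Length of the reference protein; positions
#'   beyond it are skipped (default: max region end).
#' @return A tibble `region`, `start`, `end`, `length`, `n_variants`,
#'   `density`.
#' @export
positional_density <- function(variants, region_map,
                               reference_length = max(region_map$end)) {
  region_map <- validate_region_map(region_map)
  outside <- variants$protein_position > reference_length
  if (any(outside)) {
    warn(sprintf("skipped %d variant(s) outside the reference", sum(outside)))
    variants <- variants[!outside, ]
  }
  mutate(region_map,
         n_variants = map_int(seq_len(nrow(region_map)), function(i) {
           sum(variants$protein_position >= region_map$start[i] &
                 variants$protein_position <= region_map$end[i])
         }),
         density = .data$n_variants / .data$length)
}
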