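#' Extract the alignment slice for a named region
#'
#' Maps the region's reference coordinates onto alignment columns (via
#' [ref_to_column()]) and returns the spanned slice. Rows that are entirely
#' gaps within the slice are dropped with a warning: they carry no signal
#' for the region and would otherwise produce incomparable pairs.
#'
#' @param msa An alignment tibble.
#' @param region_map Region-map tibble (see [load_region_map()]).
#' @param name Region name to extract.
#' @param reference_id Id of the row anchoring the region coordinates.
#' @return An alignment tibble restricted to the region's columns.
#' @export
extract_region <- function(msa, region_map, name, reference_id) {
  r <- region_map[region_map$region == name, ]
  if (nrow(r) != 1) abort(paste0("unknown region: ", name))
  cols <- ref_to_column(msa, reference_id, c(r$start, r$end))
  m <- aln_matrix(msa)[, cols[1]:cols[2], drop = FALSE]
  keep <- rowSums(m != "-") > 0
  if (any(!keep)) {
    warn(sprintf("region '%s': dropped %d all-gap row(s): %s", name,
                 sum(!keep), paste(msa$id[!keep], collapse = ", ")))
  }
  out <- msa[keep, ]
  out$residues <- unname(apply(m[keep, , drop = FALSE], 1, paste, collapse = ""))
  out
}

#' Score the divergence of every region of a region map
#'
#' For each region, computes all pairwise divergences (changes per 100
#' sites, pairwise deletion) among the sequences over the region's
#' alignment columns. Lower scores mean stronger conservation. Regions are
#' returned ranked by mean divergence ascending (most conserved first).
#' Regions with fewer than two usable rows are excluded with a warning;
#' pairs with no comparable columns inside a region are dropped.
#'
#' @inheritParams extract_region
#' @return A tibble with one row per region: `region`, `start`, `end`,
#'   `length`, `n_seqs`, `n_pairs`, `mean_divergence`, `median_divergence`
#'   and a list-column `divergences` holding the full per-pair
#'   distributions.
#' @export
score_regions <- function(msa, region_map, reference_id) {
  region_map <- validate_region_map(
    region_map,
    reference_length = sum(reference_row(msa, reference_id) != "-"))
  one <- function(region, start, end, length) {
    sub <- withCallingHandlers(
      extract_region(msa, region_map, region, reference_id),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(sub) < 2) return(NULL)
    im <- aln_int_matrix(sub)
    cmb <- utils::combn(nrow(sub), 2)
    d <- apply(cmb, 2, function(ij) p_dist_rows(im[ij[1], ], im[ij[2], ])["p"])
    d <- 100 * d[!is.na(d)]
    if (!length(d)) return(NULL)
    tibble(region = region, start = start, end = end, length = length,
           n_seqs = nrow(sub), n_pairs = length(d),
           mean_divergence = mean(d), median_divergence = median(d),
           divergences = list(d))
  }
  out <- bind_rows(pmap(region_map[c("region", "start", "end", "length")], one))
  dropped <- setdiff(region_map$region, out$region)
  if (length(dropped)) {
    warn(paste0("region(s) excluded (fewer than 2 usable rows): ",
                paste(dropped, collapse = ", ")))
  }
  arrange(out, .data$mean_divergence)
}

#' Kruskal-Wallis heterogeneity test across region divergences
#'
#' Tests whether the per-region pairwise-divergence distributions share a
#' common location, i.e. whether regions of the protein evolved under
#' measurably different constraint. Uses the rank-based H statistic with
#' tie correction and a chi-square reference distribution on k - 1 degrees
#' of freedom.
#'
#' @param scores Output of [score_regions()].
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`,
#'   `n_regions`, and a list-column `group_sizes`.
#' @export
kruskal_wallis_regions <- function(scores) {
  if (nrow(scores) < 2) abort("need at least 2 regions")
  if (any(lengths(scores$divergences) < 2)) {
    abort("each region needs at least 2 divergence values")
  }
  values <- unlist(scores$divergences)
  groups <- factor(rep(scores$region, lengths(scores$divergences)),
                   levels = scores$region)
  if (length(unique(values)) == 1) {
    warn("all divergence values identical across regions; p = 1")
    return(tibble(statistic = 0, df = nrow(scores) - 1L, p_value = 1,
                  n_regions = nrow(scores),
                  group_sizes = list(lengths(scores$divergences))))
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n_regions = nrow(scores),
         group_sizes = list(setNames(lengths(scores$divergences),
                                     scores$region)))
}

#' Per-site conservation report
#'
#' For chosen reference positions, reports the aligned residue of every
#' sequence and a conservation class: `invariant` (a single residue state,
#' gaps ignored), `conservative` (several states, all within one Dayhoff
#' physicochemical group), or `variable`. Positions mapping to an all-gap
#' column are flagged as not alignable.
#'
#' @param msa An alignment tibble.
#' @param reference_id Anchoring row id.
#' @param positions 1-based ungapped reference positions.
#' @return A tibble with columns `position`, `column`, `ref_aa`,
#'   `alignable`, `class`, `n_states`, `states`, and a list-column
#'   `residues` (named character vector, one entry per sequence).
#' @export
site_report <- function(msa, reference_id, positions) {
  cols <- ref_to_column(msa, reference_id, positions)
  m <- aln_matrix(msa)
  one <- function(pos, col) {
    res <- setNames(m[, col], msa$id)
    obs <- res[res != "-"]
    states <- unique(obs[obs != "X"])
    alignable <- length(obs) > 0
    cls <- if (!alignable) {
      NA_character_
    } else if (length(states) <= 1 && !any(obs == "X")) {
      "invariant"
    } else {
      grp <- unique(dayhoff_group(states))
      if (length(grp) == 1 && !anyNA(grp) && !any(obs == "X")) {
        "conservative"
      } else "variable"
    }
    tibble(position = pos, column = col,
           ref_aa = res[[reference_id]],
           alignable = alignable, class = cls,
           n_states = length(states),
           states = paste(sort(states), collapse = ""),
           residues = list(res))
  }
  out <- bind_rows(map2(positions, cols, one))
  if (any(!out$alignable)) {
    warn(paste0("position(s) not alignable (all-gap column): ",
                paste(out$position[!out$alignable], collapse = ", ")))
  }
  out
}
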