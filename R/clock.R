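#' Mean divergence between two lineage groups
#'
#' The Dickerson-plot y-value for one lineage comparison: the mean of the
#' pairwise changes-per-100-sites distances over all cross pairs (every
#' member of group A against every member of group B), pairwise deletion.
#'
#' @param msa An alignment tibble.
#' @param group_a,group_b Character vectors of sequence ids.
#' @return A single number (mean changes per 100 sites).
#' @export
lineage_pair_change <- function(msa, group_a, group_b) {
  miss <- setdiff(c(group_a, group_b), msa$id)
  if (length(miss)) abort(paste0("id(s) not in alignment: ",
                                 paste(miss, collapse = ", ")))
  if (length(intersect(group_a, group_b))) {
    abort("groups must be disjoint")
  }
  if (!length(group_a) || !length(group_b)) abort("empty group")
  im <- aln_int_matrix(msa)
  pairs <- expand.grid(a = group_a, b = group_b, stringsAsFactors = FALSE)
  d <- map2_dbl(pairs$a, pairs$b, function(a, b) {
    p_dist_rows(im[a, ], im[b, ])["p"]
  })
  if (anyNA(d)) abort("cross pair with no comparable columns")
  100 * mean(d)
}

#' Evaluate a full divergence-time configuration
#'
#' Applies [lineage_pair_change()] to every comparison of a divergence
#' configuration, yielding the point set of a Dickerson plot.
#'
#' @param msa An alignment tibble.
#' @param config A tibble with columns `comparison`, `group_a`, `group_b`
#'   (list-columns of ids or `;`-separated strings) and `mya` (divergence
#'   time, million years).
#' @return A tibble `comparison`, `mya`, `change` suitable for
#'   [fit_rate_curve()].
#' @export
lineage_points <- function(msa, config) {
  split_ids <- function(x) {
    if (is.list(x)) x else strsplit(x, ";", fixed = TRUE)
  }
  ga <- split_ids(config$group_a)
  gb <- split_ids(config$group_b)
  tibble(comparison = config$comparison, mya = config$mya,
         change = pmap(list(ga, gb), function(a, b) {
           lineage_pair_change(msa, trimws(a), trimws(b))
         }) |> unlist())
}

#' Fit a rate-versus-time curve through the origin
#'
#' Least squares through the origin over (divergence time, mean change)
#' points: `slope = sum(t*y) / sum(t^2)` in changes per 100 sites per
#' million years. The unit evolutionary period (UEP), the number of
#' million years per 1% sequence change, is the reciprocal of the slope.
#'
#' @param points Tibble with columns `mya` and `change` (and optionally
#'   `comparison`).
#' @return An object of class `rate_curve`: list with `points` (input plus
#'   `fitted` and `residual`), `slope`, `uep`, `n`.
#' @export
#' @examples
#' fit_rate_curve(tibble::tibble(mya = c(10, 50, 100),
#'                               change = c(1, 5, 10)))
fit_rate_curve <- function(points) {
  stopifnot(all(c("mya", "change") %in% names(points)))
  if (nrow(points) < 1 || all(points$mya == 0)) {
    abort("need at least one point with mya > 0")
  }
  if (any(points$mya < 0)) abort("divergence times must be >= 0")
  slope <- sum(points$mya * points$change) / sum(points$mya^2)
  points <- mutate(as_tibble(points),
                   fitted = slope * .data$mya,
                   residual = .data$change - .data$fitted)
  structure(list(points = points, slope = slope,
                 uep = if (slope > 0) 1 / slope else Inf,
                 n = nrow(points)),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf(
    "Rate curve: %d points; slope %.4g changes/100 sites per MY; UEP %.4g MY\n",
    x$n, x$slope, x$uep))
  print(x$points)
  invisible(x)
}

#' Rank a target rate curve against baseline curves
#'
#' Orders the target protein's clock rate against reference proteins
#' (classically a strongly conserved histone H4-like baseline and a
#' semi-conserved cytochrome-c-like one). Curves with equal slope share a
#' rank; no ordering is asserted between them.
#'
#' @param target_curve A `rate_curve` for the protein under study.
#' @param baseline_curves Named list of `rate_curve` objects.
#' @return A tibble `curve`, `slope`, `uep`, `rank` (1 = most conserved,
#'   i.e. smallest slope), `is_target`.
#' @export
baseline_compare <- function(target_curve, baseline_curves) {
  curves <- c(list(target = target_curve), baseline_curves)
  out <- tibble(
    curve = names(curves),
    slope = map_dbl(curves, "slope"),
    uep = map_dbl(curves, "uep"),
    is_target = names(curves) == "target")
  out$rank <- as.integer(rank(out$slope, ties.method = "min"))
  arrange(out, .data$rank)
}
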