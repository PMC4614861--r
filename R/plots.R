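#' Plot per-region divergence scores
#'
#' Bar chart of mean pairwise divergence per region (ascending: most
#' conserved first), the domain-resolved conservation profile.
#'
#' @param scores Output of [score_regions()].
#' @return A ggplot object.
#' @export
plot_region_scores <- function(scores) {
  scores$region <- factor(scores$region, levels = scores$region)
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$region, y = .data$mean_divergence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Mean changes per 100 sites",
                  title = "Region conservation profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Dickerson plot of a rate curve
#'
#' Divergence against divergence time with the fitted through-origin
#' line; baselines (if given) are overlaid as their best-fit lines.
#'
#' @param object A `rate_curve`.
#' @param baselines Optional named list of `rate_curve` baselines.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_curve <- function(object, baselines = NULL, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$mya, y = .data$change)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = 0, slope = object$slope) +
    ggplot2::labs(x = "Divergence time (MYA)",
                  y = "Changes per 100 sites",
                  title = sprintf("Rate curve (UEP %.1f MY)", object$uep)) +
    ggplot2::theme_minimal()
  for (nm in names(baselines)) {
    p <- p + ggplot2::geom_abline(intercept = 0,
                                  slope = baselines[[nm]]$slope,
                                  linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the per-column coupling profile
#'
#' Cumulative mutual information per column with per-column conservation
#' as the colour scale -- the linearised version of a circular coupling
#' plot.
#'
#' @param coupling A `coupling` object from [coupling_analysis()].
#' @return A ggplot object.
#' @export
plot_coupling_profile <- function(coupling) {
  ggplot2::ggplot(coupling$columns,
                  ggplot2::aes(x = .data$column, y = .data$cmi,
                               fill = .data$conservation)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = "Alignment column", y = "Cumulative MI (z)",
                  fill = "KL cons.") +
    ggplot2::theme_minimal()
}

#' Lollipop plot of variant tiers along the protein
#'
#' Grantham deviation against protein position, coloured by the
#' damaging-vote tier (green/blue/red for one/two/three votes).
#'
#' @param variants Variant tibble with `gd` and `tier` columns (see
#'   [annotate_gvgd()]).
#' @return A ggplot object.
#' @export
plot_variant_tiers <- function(variants) {
  cols <- c(none = "grey70", one = "forestgreen", two = "royalblue",
            three = "red2")
  ggplot2::ggplot(variants,
                  ggplot2::aes(x = .data$protein_position, y = .data$gd,
                               colour = .data$tier)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$protein_position,
                                       yend = 0), linewidth = 0.3) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = "Protein position", y = "Grantham deviation",
                  colour = "Damaging votes") +
    ggplot2::theme_minimal()
}

#' Plot synteny block scores per genome
#'
#' @param report Output of [synteny_report()].
#' @return A ggplot object.
#' @export
plot_synteny_blocks <- function(report) {
  report$genome <- factor(report$genome, levels = report$genome)
  ggplot2::ggplot(report, ggplot2::aes(x = .data$genome,
                                       y = .data$block_score)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = NULL, y = "Signed-LCS block score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
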