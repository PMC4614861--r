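#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted rate curve
#'
#' @param x A `rate_curve` from [fit_rate_curve()].
#' @param ... Unused.
#' @return The point table with `fitted` and `residual` columns.
#' @exportS3Method generics::tidy
tidy.rate_curve <- function(x, ...) x$points

#' @rdname tidy.rate_curve
#' @return `glance()` returns a one-row tibble with `slope`, `uep`, `n`,
#'   `rss`.
#' @exportS3Method generics::glance
glance.rate_curve <- function(x, ...) {
  tibble(slope = x$slope, uep = x$uep, n = x$n,
         rss = sum(x$points$residual^2))
}

#' Tidy coupling results
#'
#' @param x A `coupling` object from [coupling_analysis()].
#' @param ... Unused.
#' @return `tidy()` returns the edge table; `glance()` a one-row summary.
#' @exportS3Method generics::tidy
tidy.coupling <- function(x, ...) x$edges

#' @rdname tidy.coupling
#' @exportS3Method generics::glance
glance.coupling <- function(x, ...) {
  tibble(n_columns = nrow(x$columns), n_edges = nrow(x$edges),
         threshold = x$threshold,
         n_permutations = x$zscores$n_permutations,
         max_z = if (nrow(x$edges)) max(x$edges$z) else NA_real_)
}

#' Tidy a variant summary
#'
#' @param x A `variant_summary` from [tally_variants()].
#' @param ... Unused.
#' @return A long tibble `dimension`, `level`, `n`, `pct`.
#' @exportS3Method generics::tidy
tidy.variant_summary <- function(x, ...) {
  bind_rows(mutate(x$by_class, dimension = "class"),
            mutate(x$by_consequence, dimension = "consequence"))[
              , c("dimension", "level", "n", "pct")]
}

#' @rdname tidy.variant_summary
#' @exportS3Method generics::glance
glance.variant_summary <- function(x, ...) {
  tibble(total = x$total,
         n_classes = nrow(x$by_class),
         n_consequences = nrow(x$by_consequence))
}
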