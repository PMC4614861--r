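#' Identity-based sequence weights
#'
#' Down-weights redundant sequences: rows are clustered by single linkage
#' at a pairwise-identity threshold (default 0.62, the convention of
#' mutual-information servers), and each row receives weight 1 / cluster
#' size, so weights sum to the number of clusters.
#'
#' @param msa An alignment tibble.
#' @param identity_threshold Fractional identity at or above which two
#'   rows are linked.
#' @return A tibble `id`, `cluster`, `weight`.
#' @export
sequence_weights <- function(msa, identity_threshold = 0.62) {
  n <- nrow(msa)
  if (n < 2) abort("need at least 2 sequences")
  im <- aln_int_matrix(msa)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- im[i, ] > 0L & im[j, ] > 0L
      ident <- if (any(ok)) sum(im[i, ok] == im[j, ok]) / sum(ok) else 0
      d[i, j] <- d[j, i] <- 1 - ident
    }
  }
  cl <- if (n == 2) {
    if (d[1, 2] <= 1 - identity_threshold) c(1L, 1L) else c(1L, 2L)
  } else {
    cutree(hclust(as.dist(d), method = "single"),
           h = 1 - identity_threshold)
  }
  tibble(id = msa$id, cluster = as.integer(cl),
         weight = 1 / as.vector(table(cl))[cl])
}

#' Mutual information matrix over alignment columns
#'
#' Weighted, pseudocounted mutual information (in nats) between the
#' residue distributions of every retained pair of columns:
#' `MI(i,j) = sum f_ij(a,b) ln[f_ij(a,b) / (f_i(a) f_j(b))]` over the
#' 20-letter alphabet. Gaps (and `X`) are excluded from the counts; a
#' pseudocount `lambda` is added to every joint cell and the marginals are
#' taken from the pseudocounted joint, which keeps MI exactly non-negative.
#' Columns whose non-gap occupancy falls below `min_occupancy` are dropped.
#'
#' @param msa An alignment tibble.
#' @param weights Optional per-sequence weights in `msa` row order
#'   (defaults to [sequence_weights()] at threshold 0.62).
#' @param pseudocount Joint-cell pseudocount lambda (default 0.05).
#' @param min_occupancy Minimum non-gap column occupancy (default 0.5).
#' @return A symmetric matrix over retained columns (`NA` diagonal) with
#'   attribute `columns` giving the original column indices.
#' @export
mi_matrix <- function(msa, weights = NULL, pseudocount = 0.05,
                      min_occupancy = 0.5) {
  im <- aln_int_matrix(msa)
  if (is.null(weights)) weights <- sequence_weights(msa)$weight
  cols <- which(colMeans(im > 0L) >= min_occupancy)
  if (length(cols) < 2) abort("fewer than 2 retained columns")
  mi <- mi_from_int(im[, cols, drop = FALSE], weights, pseudocount)
  attr(mi, "columns") <- cols
  mi
}

# Core MI computation on an integer-coded (n x p) matrix with states 1..20
# and 0 for gap. Implemented with sparse indicator algebra so the whole
# p x p matrix (and each permutation replicate) costs a few sparse
# products: with C the weighted joint-count block matrix,
#   MI_ij = log S_ij - (Ma_ij + Ma_ji - J_ij) / S_ij
# where J, Ma collect (count+lambda) log(count+lambda) block/marginal sums
# and S_ij = N_ij + 400 lambda is the pseudocounted total.
mi_from_int <- function(im, w, lambda) {
  n <- nrow(im); p <- ncol(im)
  ij <- which(im > 0L, arr.ind = TRUE)
  X <- Matrix::sparseMatrix(
    i = ij[, 1], j = (ij[, 2] - 1L) * 20L + im[im > 0L],
    x = 1, dims = c(n, 20L * p))
  A <- Matrix::sparseMatrix(
    i = seq_len(20L * p), j = rep(seq_len(p), each = 20L),
    x = 1, dims = c(20L * p, p))
  C <- Matrix::crossprod(X, w * X)           # joint weighted counts
  N <- as.matrix(Matrix::crossprod(A, C %*% A))
  S <- N + 400 * lambda
  g <- function(x) (x + lambda) * log(x + lambda)
  Cg <- C
  Cg@x <- g(Cg@x) - g(0)
  J <- as.matrix(Matrix::crossprod(A, Cg %*% A)) + 400 * g(0)
  R <- C %*% A                               # R[(a,i), j] = marginal counts
  h <- function(x) (x + 20 * lambda) * log(x + 20 * lambda)
  Rh <- R
  Rh@x <- h(Rh@x) - h(0)
  Ma <- as.matrix(Matrix::crossprod(A, Rh)) + 20 * h(0)
  mi <- log(S) - (Ma + t(Ma) - J) / S
  diag(mi) <- NA_real_
  # numerical floor: exact arithmetic gives MI >= 0
  mi[mi < 0 & mi > -1e-9] <- 0
  mi
}

#' Permutation z-scores for column coupling
#'
#' Builds a null by independently permuting the residues within each
#' column (which preserves every column's composition but destroys the
#' pairing), recomputes the full MI matrix for each replicate, and
#' standardises the observed MI: `z = (MI - mean_null) / sd_null`.
#' Deterministic under a fixed seed. Pairs whose null standard deviation
#' is zero up to float jitter (below 1e-8 nats, e.g. near-invariant
#' columns that permutation cannot move) get z = 0 and are flagged.
#'
#' @inheritParams mi_matrix
#' @param n_permutations Number of permutation replicates (>= 20).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `mi_z`: list with `z`, `mi`, `mean_null`,
#'   `sd_null` matrices (over retained columns), `columns`,
#'   `n_permutations`, `degenerate` (logical matrix flagging sd = 0).
#' @export
mi_zscores <- function(msa, n_permutations = 100, seed = 1,
                       weights = NULL, pseudocount = 0.05,
                       min_occupancy = 0.5) {
  if (n_permutations < 20) abort("n_permutations must be >= 20")
  im <- aln_int_matrix(msa)
  if (is.null(weights)) weights <- sequence_weights(msa)$weight
  cols <- which(colMeans(im > 0L) >= min_occupancy)
  if (length(cols) < 2) abort("fewer than 2 retained columns")
  im <- im[, cols, drop = FALSE]
  obs <- mi_from_int(im, weights, pseudocount)
  p <- ncol(im)
  acc <- matrix(0, p, p); acc2 <- matrix(0, p, p)
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- apply(im, 2, sample)
      mib <- mi_from_int(perm, weights, pseudocount)
      mib[is.na(mib)] <- 0
      acc <- acc + mib
      acc2 <- acc2 + mib^2
    }
  })
  mu <- acc / n_permutations
  va <- pmax(acc2 / n_permutations - mu^2, 0) *
    n_permutations / (n_permutations - 1)
  sdn <- sqrt(va)
  # a null that permutation cannot move (e.g. near-invariant columns) has
  # zero variance up to float jitter; flag it rather than emit huge z
  degenerate <- sdn < 1e-8
  z <- (obs - mu) / sdn
  z[degenerate] <- 0
  diag(z) <- NA_real_
  structure(list(z = z, mi = obs, mean_null = mu, sd_null = sdn,
                 columns = cols, n_permutations = n_permutations,
                 degenerate = degenerate),
            class = "mi_z")
}

#' @export
print.mi_z <- function(x, ...) {
  cat(sprintf("MI z-scores over %d retained columns (%d permutations)\n",
              length(x$columns), x$n_permutations))
  invisible(x)
}

#' Cumulative mutual information per column
#'
#' `cMI_i = sum_j z_ij * 1[z_ij > threshold]`: each position's summed
#' above-threshold coupling, the histogram track of a circular coupling
#' plot.
#'
#' @param zs An `mi_z` object (or bare z matrix with a `columns`
#'   attribute).
#' @param threshold Coupling threshold on the z scale (default 6.5).
#' @return A tibble `column`, `cmi`.
#' @export
cumulative_mi <- function(zs, threshold = 6.5) {
  z <- if (inherits(zs, "mi_z")) zs$z else zs
  cols <- if (inherits(zs, "mi_z")) zs$columns else
    attr(zs, "columns") %||% seq_len(ncol(z))
  zt <- z
  zt[is.na(zt) | zt <= threshold] <- 0
  tibble(column = cols, cmi = rowSums(zt))
}

#' Tiered coupling edges
#'
#' Edges are column pairs whose z exceeds the threshold, ranked by z and
#' partitioned into the display tiers of circular coupling plots: the top
#' 5% (`top5`), the 70th-95th percentile band (`mid`), and the remaining
#' 70% (`rest`).
#'
#' @inheritParams cumulative_mi
#' @return A tibble `column_i`, `column_j`, `z`, `tier` ordered by
#'   decreasing z.
#' @export
classify_edges <- function(zs, threshold = 6.5) {
  z <- if (inherits(zs, "mi_z")) zs$z else zs
  cols <- if (inherits(zs, "mi_z")) zs$columns else
    attr(zs, "columns") %||% seq_len(ncol(z))
  idx <- which(upper.tri(z) & !is.na(z) & z > threshold, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(tibble(column_i = integer(), column_j = integer(),
                  z = numeric(), tier = character()))
  }
  out <- tibble(column_i = cols[idx[, 1]], column_j = cols[idx[, 2]],
                z = z[idx])
  out <- arrange(out, desc(.data$z))
  n <- nrow(out)
  r <- seq_len(n)
  out$tier <- ifelse(r <= ceiling(0.05 * n), "top5",
                     ifelse(r <= ceiling(0.30 * n), "mid", "rest"))
  out
}

#' Per-column conservation as divergence from background
#'
#' Kullback-Leibler divergence (nats) of each column's weighted residue
#' composition from a background amino-acid distribution (default the
#' Robinson-Robinson frequencies). An invariant column of a rare residue
#' scores highest (`-ln` of its background frequency); a column matching
#' the background scores 0.
#'
#' @param msa An alignment tibble.
#' @param background Named numeric vector of 20 background frequencies
#'   summing to 1.
#' @param weights Optional per-sequence weights.
#' @return A tibble `column`, `occupancy`, `conservation`.
#' @export
column_conservation <- function(msa, background = NULL, weights = NULL) {
  background <- background %||% AA_BACKGROUND
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  bg <- background[AA20]
  if (anyNA(bg)) abort("background must cover the 20 standard residues")
  im <- aln_int_matrix(msa)
  if (is.null(weights)) weights <- rep(1, nrow(msa))
  kl <- vapply(seq_len(ncol(im)), function(j) {
    s <- im[, j]
    ok <- s > 0L
    if (!any(ok)) return(NA_real_)
    f <- vapply(1:20, function(a) sum(weights[ok][s[ok] == a]), numeric(1))
    f <- f / sum(f)
    nz <- f > 0
    sum(f[nz] * log(f[nz] / bg[nz]))
  }, numeric(1))
  tibble(column = seq_len(ncol(im)),
         occupancy = colMeans(im > 0L),
         conservation = kl)
}

#' Full column-coupling analysis
#'
#' Convenience wrapper chaining [sequence_weights()], [mi_zscores()],
#' [cumulative_mi()], [classify_edges()] and [column_conservation()].
#'
#' @inheritParams mi_zscores
#' @param threshold Edge threshold on the z scale.
#' @return An object of class `coupling`: list with `zscores` (`mi_z`),
#'   `edges`, `columns` (per-column tibble joining cMI and conservation),
#'   `weights`, `threshold`.
#' @export
coupling_analysis <- function(msa, n_permutations = 100, seed = 1,
                              threshold = 6.5, pseudocount = 0.05,
                              min_occupancy = 0.5) {
  w <- sequence_weights(msa)
  zs <- mi_zscores(msa, n_permutations = n_permutations, seed = seed,
                   weights = w$weight, pseudocount = pseudocount,
                   min_occupancy = min_occupancy)
  cons <- column_conservation(msa, weights = w$weight)
  cols <- left_join(cumulative_mi(zs, threshold), cons, by = "column")
  structure(list(zscores = zs, edges = classify_edges(zs, threshold),
                 columns = cols, weights = w, threshold = threshold),
            class = "coupling")
}

#' @export
print.coupling <- function(x, ...) {
  cat(sprintf(
    "Coupling analysis: %d retained columns, %d edges above z = %.2f\n",
    nrow(x$columns), nrow(x$edges), x$threshold))
  invisible(x)
}
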