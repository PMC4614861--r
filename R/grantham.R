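#' Grantham physicochemical property table
#'
#' Composition (c), polarity (p) and side-chain volume (v) for the 20
#' standard amino acids, together with the quadratic-form constants
#' `alpha`, `beta`, `gamma` and the scale `rho`. `rho` is fixed so that the
#' mean of all 190 unordered pair distances is 100 (the conventional
#' normalisation; the shipped value gives 99.87).
#'
#' @return A list with elements `properties` (tibble: `aa`, `c`, `p`, `v`),
#'   `alpha`, `beta`, `gamma`, `rho`.
#' @export
grantham_table <- function() {
  properties <- tibble(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170)
  )
  list(properties = properties,
       alpha = 1.833, beta = 0.1018, gamma = 0.000399,
       rho = 50.723)
}

grantham_props <- function(aa, table) {
  i <- match(aa, table$properties$aa)
  if (anyNA(i)) {
    abort(paste0("unknown residue(s): ",
                 paste(unique(aa[is.na(i)]), collapse = ", ")))
  }
  table$properties[i, c("c", "p", "v")]
}

grantham_form <- function(dc, dp, dv, table) {
  table$rho * sqrt(table$alpha * dc^2 + table$beta * dp^2 +
                     table$gamma * dv^2)
}

#' Grantham distance between amino acids
#'
#' The classical physicochemical distance
#' \deqn{D = \rho\,[\alpha (c_1-c_2)^2 + \beta (p_1-p_2)^2 +
#'           \gamma (v_1-v_2)^2]^{1/2}}
#' scaled so the mean over all 190 residue pairs is 100. Vectorised over
#' `aa1`/`aa2`.
#'
#' @param aa1,aa2 One-letter amino-acid codes.
#' @param table Property table from [grantham_table()].
#' @return Numeric distances.
#' @export
#' @examples
#' grantham_distance("L", "I")  # ~5, a most-conservative exchange
#' grantham_distance("C", "W")  # ~215, the most radical exchange
grantham_distance <- function(aa1, aa2, table = grantham_table()) {
  p1 <- grantham_props(aa1, table)
  p2 <- grantham_props(aa2, table)
  grantham_form(p1$c - p2$c, p1$p - p2$p, p1$v - p2$v, table)
}

#' Full 20 x 20 Grantham distance matrix
#'
#' @inheritParams grantham_distance
#' @return A symmetric matrix with zero diagonal, residues as dimnames.
#' @export
grantham_matrix <- function(table = grantham_table()) {
  aa <- table$properties$aa
  g <- expand.grid(aa1 = aa, aa2 = aa, stringsAsFactors = FALSE)
  matrix(grantham_distance(g$aa1, g$aa2, table), 20, 20,
         dimnames = list(aa, aa))
}

#' Alignment-aware Grantham variation and deviation (GV/GD)
#'
#' Extends the Grantham distance to a multiple-sequence-alignment column.
#' GV measures the physicochemical spread of the residues observed at the
#' column (the quadratic form over each property's observed range); GD
#' measures how far a substituting residue falls outside that range, zero
#' when it lies inside on every property. On an invariant column GV is 0
#' and GD reduces to the plain Grantham distance.
#'
#' @param column_residues Character vector of residues observed at the
#'   column (gaps and `X` are dropped).
#' @param alt_aa The substituting residue.
#' @inheritParams grantham_distance
#' @return A one-row tibble with columns `gv`, `gd`, `n_observed`.
#' @export
gvgd <- function(column_residues, alt_aa, table = grantham_table()) {
  obs <- column_residues[!column_residues %in% c("-", "X")]
  if (!length(obs)) abort("no observed residues at column")
  p <- grantham_props(obs, table)
  pa <- grantham_props(alt_aa, table)
  rng <- function(x) range(x)
  dev <- function(x, r) max(0, r[1] - x, x - r[2])
  rc <- rng(p$c); rp <- rng(p$p); rv <- rng(p$v)
  gv <- grantham_form(diff(rc), diff(rp), diff(rv), table)
  gd <- grantham_form(dev(pa$c, rc), dev(pa$p, rp), dev(pa$v, rv), table)
  tibble(gv = gv, gd = gd, n_observed = length(obs))
}
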