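# Fixture generators and small independent oracles shared across tests.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seqs <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    id = paste0("s", seq_len(n)),
    species = paste("species", seq_len(n)),
    residues = vapply(seq_len(n), function(i) {
      paste(sample(AA, len, replace = TRUE), collapse = "")
    }, character(1)),
    source = "fixture")
}

# Random gapped alignment: mutate a common ancestor and sprinkle gaps.
random_gapped_aln <- function(n = 4, len = 30, gap_prob = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  root <- sample(AA, len, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    s <- root
    mut <- runif(len) < 0.3
    s[mut] <- sample(AA, sum(mut), replace = TRUE)
    s[runif(len) < gap_prob] <- "-"
    paste(s, collapse = "")
  }, character(1))
  aln <- tibble::tibble(id = paste0("s", seq_len(n)),
                        species = NA_character_,
                        residues = rows, source = "fixture")
  # keep at least one residue per column so validation does not drop columns
  m <- do.call(rbind, strsplit(aln$residues, ""))
  allgap <- colSums(m != "-") == 0
  m[1, allgap] <- sample(AA, sum(allgap), replace = TRUE)
  aln$residues <- apply(m, 1, paste, collapse = "")
  aln
}

# Plain recursive longest-common-subsequence oracle (memoised).
brute_lcs <- function(a, b) {
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (a[i] == b[j]) rec(i - 1, j - 1) + 1L
    else max(rec(i - 1, j), rec(i, j - 1))
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# Direct per-pair mutual information oracle over explicit frequency tables.
brute_mi_pair <- function(col_i, col_j, w, lambda = 0.05) {
  ok <- col_i %in% AA & col_j %in% AA
  C <- matrix(0, 20, 20, dimnames = list(AA, AA))
  for (r in which(ok)) C[col_i[r], col_j[r]] <- C[col_i[r], col_j[r]] + w[r]
  P <- (C + lambda) / sum(C + lambda)
  pa <- rowSums(P); pb <- colSums(P)
  sum(P * log(P / outer(pa, pb)))
}
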