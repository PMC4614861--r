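test_that("sequence weights are inverse cluster sizes", {
  same <- tibble::tibble(id = paste0("s", 1:4),
                         residues = rep("MKLSMKLS", 4))
  w <- sequence_weights(same)
  expect_equal(w$weight, rep(1 / 4, 4))
  expect_equal(sum(w$weight), 1)  # weights sum to the number of clusters

  # two clusters of sizes 2 and 3 constructed with known identities:
  # within-cluster identity 0.9, between-cluster 0.1
  base1 <- strsplit("AAAAAAAAAA", "")[[1]]
  base2 <- strsplit("WWWWWWWWWW", "")[[1]]
  tweak <- function(b, i, aa) { b[i] <- aa; paste(b, collapse = "") }
  aln <- tibble::tibble(
    id = paste0("s", 1:5),
    residues = c(tweak(base1, 1, "C"), tweak(base1, 2, "D"),
                 tweak(base2, 1, "C"), tweak(base2, 2, "D"),
                 tweak(base2, 3, "E")))
  w <- sequence_weights(aln, identity_threshold = 0.62)
  expect_equal(w$weight, c(1 / 2, 1 / 2, 1 / 3, 1 / 3, 1 / 3))
  expect_equal(sum(w$weight), 2)

  distinct <- random_seqs(4, 30, seed = 10)
  w <- sequence_weights(distinct, identity_threshold = 1.0)
  expect_equal(w$weight, rep(1, 4))
})

test_that("mutual information matches a direct frequency-table oracle", {
  set.seed(21)
  for (rep in 1:5) {
    aln <- random_gapped_aln(n = 10, len = 6, gap_prob = 0.1, seed = rep)
    m <- do.call(rbind, strsplit(aln$residues, ""))
    w <- runif(10, 0.5, 1.5)
    mi <- mi_matrix(aln, weights = w, min_occupancy = 0)
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(mi[i, j], brute_mi_pair(m[, i], m[, j], w), tolerance = 1e-10)
    }
    expect_equal(mi, t(mi))
    expect_true(all(mi[upper.tri(mi)] >= -1e-9))
  }
})

test_that("copied columns carry high MI; independent columns carry low MI", {
  # 20 distinct residues, column j a copy of column i
  aln <- tibble::tibble(id = paste0("s", 1:20),
                        residues = paste0(AA, AA, "A"))
  mi <- mi_matrix(aln, weights = rep(1, 20), min_occupancy = 0)
  expect_gt(mi[1, 2], mi[1, 3])  # invariant third column couples to nothing
  # analytic value for a perfect 20-state copy at n = 20, lambda = 0.05:
  # diagonal cells (1.05/40) ln(10.5) plus off-diagonal (0.05/40) ln(0.5)
  expect_equal(mi[1, 2],
               20 * (1.05 / 40) * log(10.5) + 380 * (0.05 / 40) * log(0.5),
               tolerance = 1e-10)

  # independent uniform columns at n = 500 sit at the finite-sample bias
  # floor of plug-in MI, ~ (20-1)^2 / (2 (n + 400 lambda)) ~ 0.35 nats --
  # far below the perfect-copy value; the permutation z-scores exist to
  # absorb exactly this bias
  bias_floor <- 19^2 / (2 * (500 + 400 * 0.05))
  mis <- vapply(1:50, function(seed) {
    set.seed(seed)
    aln <- tibble::tibble(
      id = paste0("s", 1:500),
      residues = paste0(sample(AA, 500, TRUE), sample(AA, 500, TRUE)))
    mi_matrix(aln, weights = rep(1, 500), min_occupancy = 0)[1, 2]
  }, numeric(1))
  expect_lt(mean(mis), 1.5 * bias_floor)
  expect_gt(min(mis), 0)
})

test_that("permutation z-scores flag planted covarying pairs and are reproducible", {
  # star tree: leaves evolve independently from the root, so non-planted
  # column pairs satisfy the permutation null's independence assumption
  # (a deep shared phylogeny inflates MI at every pair; see the vignette)
  star <- paste0("(", paste0("t", 1:30, ":1", collapse = ","), ");")
  cfg <- sim_config(tree = star, n_sites = 40, base_rate = 1.5,
                    covarying_pairs = cbind(5L, 25L), seed = 77)
  sim <- simulate_msa(cfg)
  zs <- mi_zscores(sim$alignment, n_permutations = 30, seed = 1)
  expect_gt(zs$z[5, 25], 6.5)

  # determinism under the same seed
  zs2 <- mi_zscores(sim$alignment, n_permutations = 30, seed = 1)
  expect_identical(zs$z, zs2$z)

  # doubling permutations keeps the planted pair decisively above threshold
  zs3 <- mi_zscores(sim$alignment, n_permutations = 60, seed = 1)
  expect_gt(zs3$z[5, 25], 6.5)

  # independent columns rarely reach |z| = 3
  off <- abs(zs$z[upper.tri(zs$z)])
  planted <- zs$z[5, 25]
  expect_gt(mean(off[off != planted] < 3, na.rm = TRUE), 0.99)
})

test_that("cumulative MI and edge tiers partition as specified", {
  z <- matrix(0, 4, 4); diag(z) <- NA
  expect_equal(cumulative_mi(z)$cmi, rep(0, 4))
  expect_equal(nrow(classify_edges(z)), 0)

  z[1, 3] <- z[3, 1] <- 8
  cm <- cumulative_mi(z)
  expect_equal(cm$cmi, c(8, 0, 8, 0))
  ed <- classify_edges(z)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$tier, "top5")

  # 100 synthetic edges -> tier counts 5 / 25 / 70
  p <- 200
  zz <- matrix(0, p, p); diag(zz) <- NA
  vals <- seq(6.6, 20, length.out = 100)
  ij <- cbind(1:100, 101:200)
  zz[ij] <- vals; zz[ij[, 2:1]] <- vals
  ed <- classify_edges(zz)
  expect_equal(as.integer(table(ed$tier)[c("top5", "mid", "rest")]),
               c(5L, 25L, 70L))
  # cMI at a member column equals the sum of its qualifying z values
  cm <- cumulative_mi(zz)
  expect_equal(cm$cmi[1], zz[1, 101])
})

test_that("column conservation is KL divergence from background", {
  # uniform background, uniform column -> 0
  ubg <- setNames(rep(1 / 20, 20), AA)
  aln <- tibble::tibble(id = paste0("s", 1:20), residues = AA)
  cc <- column_conservation(aln, background = ubg)
  expect_equal(cc$conservation, 0, tolerance = 1e-12)

  # an invariant column of the rarest residue scores ~ -ln(freq) and tops
  # columns of commoner residues
  aln <- tibble::tibble(id = paste0("s", 1:10),
                        residues = rep("WAL", 10))
  cc <- column_conservation(aln)
  expect_equal(cc$conservation[1], -log(0.0133), tolerance = 1e-3)
  expect_gt(cc$conservation[1], cc$conservation[2])
  expect_gt(cc$conservation[1], cc$conservation[3])

  expect_error(column_conservation(aln, background = ubg * 2), "sum to 1")
})
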