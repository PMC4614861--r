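test_that("Grantham distances reproduce the published matrix scale", {
  D <- grantham_matrix()
  expect_equal(diag(D), setNames(rep(0, 20), colnames(D)))
  expect_equal(D, t(D))
  expect_true(all(D[upper.tri(D)] > 0))
  expect_equal(mean(D[upper.tri(D)]), 100, tolerance = 0.5 / 100)

  # classic entries of the published matrix (integer-rounded there)
  published <- list(c("L", "I", 5), c("R", "K", 26), c("C", "W", 215),
                    c("D", "E", 45), c("F", "Y", 22), c("S", "R", 110))
  for (p in published) {
    expect_lt(abs(grantham_distance(p[1], p[2]) - as.numeric(p[3])), 1)
  }
  # C-W is the most radical exchange in the whole matrix
  expect_equal(max(D), D["C", "W"])
  expect_error(grantham_distance("J", "A"), "unknown residue")
})

test_that("GV/GD extend Grantham distance to alignment columns", {
  # invariant column: GV = 0 and GD equals the plain Grantham distance
  for (x in c("A", "W", "S")) {
    g <- gvgd(rep(x, 8), "Y")
    expect_equal(g$gv, 0)
    expect_equal(g$gd, grantham_distance(x, "Y"))
  }
  # alt inside every observed property range scores GD = 0
  g <- gvgd(c("L", "F"), "I")
  expect_equal(g$gd, 0)
  expect_gt(g$gv, 0)

  # hand-evaluated quadratic form for column {S, R, L}, alt W:
  # ranges c [0, 1.42], p [4.9, 10.5], v [32, 124]; W (0.13, 5.4, 170)
  # deviates only in volume by 46, giving
  # GV = 50.723 sqrt(1.833*1.42^2 + 0.1018*5.6^2 + 0.000399*92^2) = 162.52
  # GD = 50.723 sqrt(0.000399 * 46^2) = 46.61
  g <- gvgd(c("S", "R", "L"), "W")
  expect_equal(g$gv, 162.52, tolerance = 1e-4)
  expect_equal(g$gd, 46.61, tolerance = 1e-4)

  # gaps are ignored; an all-gap column errors
  expect_equal(gvgd(c("A", "-", "A"), "C")$n_observed, 2)
  expect_error(gvgd(c("-", "-"), "C"), "no observed residues")
})

test_that("vote tiers count damaging calls and are monotone", {
  expect_equal(as.character(vote_tier(120, 0.01, 0.95)), "three")
  expect_equal(as.character(vote_tier(10, 0.5, 0.1)), "none")
  expect_equal(as.character(vote_tier(NA, 0.01, NA)), "one")
  expect_error(vote_tier(NA_real_, NA_real_, NA_real_), "at least one score")

  # monotonicity: strictly more damaging scores never lower the tier
  set.seed(31)
  for (rep in 1:200) {
    gd <- runif(1, 0, 215); sift <- runif(1); poly <- runif(1)
    t0 <- vote_tier(gd, sift, poly)
    t1 <- vote_tier(min(gd + runif(1, 0, 80), 215),
                    max(sift - runif(1, 0, 0.5), 0),
                    min(poly + runif(1, 0, 0.5), 1))
    expect_gte(as.integer(t1), as.integer(t0))
  }
})

test_that("variant parsing normalises protein changes and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_change\tvariant_class\tconsequence\tsift\tpolyphen",
               "p.Arg1008Gln\tSNP\tmissense_variant\t0.02\t0.9",
               "K100K\tSNP\tmissense_variant\t0.5\t0.1",
               "p.Bad\tSNP\tmissense_variant\t\t",
               "L55M\tSNP\tmissense_variant\t\t"), path)
  expect_warning(v <- parse_variants(path), "rejected 2")
  expect_equal(nrow(v), 2)
  expect_equal(v$ref_aa, c("R", "L"))
  expect_equal(v$protein_position, c(1008L, 55L))
  expect_equal(v$alt_aa, c("Q", "M"))
  expect_equal(attr(v, "n_rejected"), 2)

  # round-trip on random tables
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:20, 1)
    ref <- sample(AA, n, TRUE)
    alt <- AA[(match(ref, AA) + sample(19, n, TRUE) - 1) %% 20 + 1]
    tab <- tibble::tibble(protein_position = sample(1000, n), ref_aa = ref,
                          alt_aa = alt, variant_class = "SNP",
                          consequence = "missense_variant",
                          sift = runif(n), polyphen = runif(n))
    write_variants(tab, path)
    back <- parse_variants(path)
    expect_equal(as.list(back[names(tab)]), as.list(tab), ignore_attr = TRUE)
  }
})

test_that("tallies count classes and consequences with percentages summing to 100", {
  empty <- tally_variants(tibble::tibble(variant_class = character(),
                                         consequence = character()))
  expect_equal(empty$total, 0)
  expect_equal(nrow(empty$by_class), 0)

  toy <- tibble::tibble(
    variant_class = c(rep("SNP", 6), rep("insertion", 3), "deletion"),
    consequence = c(rep("intron_variant", 5), rep("missense_variant", 4),
                    "stop_gained"))
  ts <- tally_variants(toy)
  expect_equal(ts$by_class$n, c(6L, 3L, 1L))
  expect_equal(ts$by_class$pct, c(60, 30, 10))
  expect_equal(ts$by_consequence$n[ts$by_consequence$level == "intron_variant"], 5L)
  td <- tidy(ts)
  expect_equal(sum(td$pct[td$dimension == "class"]), 100, tolerance = 0.1)
  expect_equal(sum(td$pct[td$dimension == "consequence"]), 100, tolerance = 0.1)
})

test_that("planted tier compositions and regional enrichment are recovered", {
  sv <- simulate_variants(1000, tier_mix = c(0.1, 0.2, 0.3, 0.4), seed = 9)
  v <- sv$variants
  v$tier <- vote_tier(v$gd, v$sift, v$polyphen)
  expect_identical(v$tier, v$true_tier)
  expect_equal(as.integer(table(v$tier)), unname(sv$tier_counts))
  expect_equal(unname(sv$tier_counts), c(100L, 200L, 300L, 400L))

  all3 <- simulate_variants(50, tier_mix = c(0, 0, 0, 1), seed = 2)
  expect_true(all(all3$variants$true_tier == "three"))

  # 2:1 N-terminal vs C-terminal enrichment recovered within 20%
  enr <- tibble::tibble(region = c("N-terminal", "C-terminal"),
                        start = c(1L, 693L), end = c(692L, 1104L),
                        weight = c(2, 1))
  sv <- simulate_variants(1000, enrichment = enr, seed = 12)
  dens <- positional_density(sv$variants,
                             tibble::tibble(region = enr$region,
                                            start = enr$start, end = enr$end))
  ratio <- dens$density[dens$region == "N-terminal"] /
    dens$density[dens$region == "C-terminal"]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("positional density counts per region and skips out-of-range records", {
  rm <- tibble::tibble(region = c("left", "right"),
                       start = c(1L, 6L), end = c(5L, 10L))
  v <- tibble::tibble(protein_position = c(1L, 2L, 7L, 30L))
  expect_warning(dens <- positional_density(v, rm, reference_length = 10),
                 "skipped 1")
  expect_equal(dens$n_variants, c(2L, 1L))
  expect_equal(dens$density, c(2 / 5, 1 / 5))
})

test_that("alignment-aware GD annotation falls back gracefully", {
  aln <- tibble::tibble(
    id = c("human", "m1", "m2"),
    residues = c("AWLK", "AWIK", "AWVK"))
  v <- tibble::tibble(protein_position = c(2L, 3L, 9L),
                      ref_aa = c("W", "L", "A"), alt_aa = c("C", "M", "V"),
                      variant_class = "SNP", consequence = "missense_variant",
                      sift = c(0.01, 0.8, 0.5), polyphen = c(0.99, 0.2, 0.5))
  expect_warning(av <- annotate_gvgd(v, aln, "human"), "skipped 1")
  expect_equal(nrow(av), 2)
  # invariant column 2: GD equals plain Grantham distance W->C
  expect_equal(av$gd[1], grantham_distance("W", "C"))
  # column 3 observes {L, I, V}; M lies inside every property range
  expect_equal(av$gd[2], 0)
  expect_equal(as.character(av$tier), c("three", "none"))
})
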