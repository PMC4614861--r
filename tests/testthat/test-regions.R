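test_that("region extraction maps reference coordinates onto alignment columns", {
  aln <- random_seqs(3, 20, seed = 5)
  rm <- tibble::tibble(region = "all", start = 1L, end = 20L)
  expect_equal(extract_region(aln, rm, "all", "s1")$residues, aln$residues)

  # gapped fixture checked by manual column enumeration:
  # reference r = A-CD-E, region 2..3 covers reference residues C (col 3)
  # and D (col 4)
  aln <- tibble::tibble(id = c("r", "q"),
                        residues = c("A-CD-E", "AWCDYE"))
  rm <- tibble::tibble(region = "mid", start = 2L, end = 3L)
  sub <- extract_region(aln, rm, "mid", "r")
  expect_equal(sub$residues, c("CD", "CD"))

  # rows all-gap inside the slice are dropped with a warning
  aln <- tibble::tibble(id = c("r", "q", "z"),
                        residues = c("ACDE", "A--E", "AQWE"))
  rm <- tibble::tibble(region = "core", start = 2L, end = 3L)
  expect_warning(sub <- extract_region(aln, rm, "core", "r"), "all-gap.*q")
  expect_equal(sub$id, c("r", "z"))
})

test_that("region scores rank conservation and respond to planted rate ratios", {
  # invariant region scores exactly zero
  aln <- tibble::tibble(id = c("a", "b", "c"),
                        residues = c("MKLSWWEE", "MKLSAAEE", "MKLSCCEE"))
  rm <- tibble::tibble(region = c("left", "mid"),
                       start = c(1L, 5L), end = c(4L, 6L))
  sc <- score_regions(aln, rm, "a")
  expect_equal(sc$mean_divergence[sc$region == "left"], 0)
  expect_gt(sc$mean_divergence[sc$region == "mid"], 0)
  expect_equal(sc$region[1], "left")  # ranked most conserved first
  expect_equal(sc$n_pairs, c(3L, 3L))

  # two regions simulated at rates r and 4r: mean score ratio ~ 4
  rm <- tibble::tibble(region = c("slow", "fast"),
                       start = c(1L, 401L), end = c(400L, 800L))
  ratios <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_taxa = 10, n_sites = 800, base_rate = 0.01,
                      region_map = rm, multipliers = c(1, 4), seed = seed)
    sim <- simulate_msa(cfg)
    sc <- score_regions(sim$alignment, rm, sim$alignment$id[1])
    sc$mean_divergence[sc$region == "fast"] /
      sc$mean_divergence[sc$region == "slow"]
  }, numeric(1))
  expect_gt(mean(ratios), 3.2)
  expect_lt(mean(ratios), 4.8)
})

test_that("region scores are invariant to row order and all-gap padding", {
  aln <- random_gapped_aln(n = 5, len = 40, seed = 8)
  rm <- tibble::tibble(region = c("x", "y"), start = c(1L, 11L),
                       end = c(10L, 25L))
  ref <- aln$id[1]
  base <- score_regions(aln, rm, ref)
  shuffled <- aln[c(3, 1, 5, 2, 4), ]
  resh <- score_regions(shuffled, rm, ref)
  expect_equal(resh[c("region", "mean_divergence", "median_divergence")],
               base[c("region", "mean_divergence", "median_divergence")])

  padded <- aln
  padded$residues <- paste0(substr(aln$residues, 1, 20), "--",
                            substr(aln$residues, 21, 40))
  padded <- suppressMessages(as_alignment(padded))  # padding stripped
  expect_equal(score_regions(padded, rm, ref)$mean_divergence,
               base$mean_divergence)
})

test_that("Kruskal-Wallis heterogeneity matches hand-ranked arithmetic", {
  mk <- function(region, d) tibble::tibble(
    region = region, start = 1L, end = 2L, length = 2L, n_seqs = 3L,
    n_pairs = length(d), mean_divergence = mean(d),
    median_divergence = stats::median(d), divergences = list(d))

  # 9 values, 3 groups; H computed by hand rank arithmetic (no ties):
  # values 1..9 ranked 1..9; rank sums: g1 = {1,2,3} -> 6, g2 = {4,5,6}
  # -> 15, g3 = {7,8,9} -> 24.
  # H = 12/(9*10) * (36/3 + 225/3 + 576/3) - 3*10 = 0.1333*279/3*... = 7.2
  sc <- dplyr::bind_rows(mk("g1", c(1, 2, 3)), mk("g2", c(4, 5, 6)),
                         mk("g3", c(7, 8, 9)))
  res <- kruskal_wallis_regions(sc)
  expect_equal(res$statistic, 7.2, tolerance = 1e-9)
  expect_equal(res$df, 2)

  # identical values across groups degenerate to p = 1 with a warning
  flat <- dplyr::bind_rows(mk("a", c(2, 2)), mk("b", c(2, 2)))
  expect_warning(res <- kruskal_wallis_regions(flat), "identical")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  # a strong planted rate spread is detected at p < 1e-4
  rm <- tibble::tibble(region = paste0("r", 1:5),
                       start = seq(1L, 801L, 200L),
                       end = seq(200L, 1000L, 200L))
  cfg <- sim_config(n_taxa = 12, n_sites = 1000, base_rate = 0.005,
                    region_map = rm, multipliers = c(0.5, 1, 2, 3.5, 5),
                    seed = 42)
  sim <- simulate_msa(cfg)
  sc <- score_regions(sim$alignment, rm, sim$alignment$id[1])
  expect_lt(kruskal_wallis_regions(sc)$p_value, 1e-4)
})

test_that("site reports classify invariant, conservative and variable columns", {
  aln <- tibble::tibble(
    id = c("a", "b", "c"),
    #          1234567
    residues = c("CKNILAC", "CRNILAC", "CRNVMA-"))
  rep <- site_report(aln, "a", c(1, 2, 4, 6))
  expect_equal(rep$class[rep$position == 1], "invariant")
  # K/R are both basic in the Dayhoff grouping
  expect_equal(rep$class[rep$position == 2], "conservative")
  # I/V hydrophobic at position 4 -> conservative
  expect_equal(rep$class[rep$position == 4], "conservative")
  expect_equal(rep$class[rep$position == 6], "invariant")

  # a two-state column spanning Dayhoff groups is variable
  aln2 <- tibble::tibble(id = c("a", "b"), residues = c("AW", "AD"))
  expect_equal(site_report(aln2, "a", 2)$class, "variable")

  # glycosylation-site pattern: invariant site flanked by invariant Cys
  flank <- tibble::tibble(
    id = paste0("s", 1:4),
    residues = c("ACWNGCA", "TCANGCT", "GCQNGCP", "MCKNGCI"))
  rep <- site_report(flank, "s1", c(2, 4, 6))
  expect_equal(rep$ref_aa, c("C", "N", "C"))
  expect_equal(rep$class, rep("invariant", 3))

  # a column where only the reference has a residue is still alignable
  # (reference positions always map to a reference residue) and invariant
  aln3 <- tibble::tibble(id = c("r", "x", "y"),
                         residues = c("AK", "A-", "A-"))
  rep <- site_report(aln3, "r", 2)
  expect_true(rep$alignable)
  expect_equal(rep$class, "invariant")
})
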