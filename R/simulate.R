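#' Simulation configuration
#'
#' Bundles the parameters of the closed-loop simulator. All downstream
#' generators are deterministic given `seed`: each `simulate_*()` call
#' runs inside [withr::with_seed()] so the same configuration always
#' yields byte-identical output regardless of the caller's RNG state.
#'
#' @param tree An [ape::phylo] tree, a newick string, or `NULL` to draw a
#'   random coalescent (clock-like) tree over `n_taxa` leaves.
#' @param n_taxa Number of leaves when `tree` is `NULL`.
#' @param n_sites Number of alignment columns.
#' @param base_rate Substitutions per site per unit branch length.
#' @param region_map Optional region-map tibble; `multipliers` scales the
#'   rate inside each region (sites outside any region evolve at
#'   `base_rate`).
#' @param multipliers Numeric vector, one per region row, all > 0.
#' @param covarying_pairs Two-column matrix/data frame of site index
#'   pairs to evolve as locked states (the second member mirrors the
#'   first through a fixed residue bijection), or an integer count of
#'   pairs to place automatically.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tree = NULL, n_taxa = 24, n_sites = 1104,
                       base_rate = 0.002, region_map = NULL,
                       multipliers = NULL, covarying_pairs = NULL,
                       seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (!is.null(region_map)) {
    region_map <- validate_region_map(region_map, reference_length = n_sites)
    if (is.null(multipliers) || length(multipliers) != nrow(region_map)) {
      abort("multipliers must match region_map rows")
    }
    if (any(multipliers <= 0)) abort("multipliers must be > 0")
  }
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  structure(list(tree = tree, n_taxa = n_taxa, n_sites = n_sites,
                 base_rate = base_rate, region_map = region_map,
                 multipliers = multipliers,
                 covarying_pairs = covarying_pairs, seed = seed),
            class = "sim_config")
}

# Per-site rates from the region map; overlapping regions multiply.
site_rates <- function(config) {
  r <- rep(config$base_rate, config$n_sites)
  rm <- config$region_map
  if (!is.null(rm)) {
    for (i in seq_len(nrow(rm))) {
      idx <- rm$start[i]:rm$end[i]
      r[idx] <- r[idx] * config$multipliers[i]
    }
  }
  r
}

#' Simulate a protein alignment along a tree
#'
#' Clock-style sequence evolution under the 20-state uniform-replacement
#' model: at each site, substitution events occur as a Poisson process at
#' rate `base_rate` times the site's region multiplier, and each event
#' replaces the residue uniformly by one of the other 19. Branch-end
#' states are drawn from the exact transition probability
#' `P(same) = 1/20 + (19/20) exp(-(20/19) r t)`, the 20-state analogue of
#' the Jukes-Cantor model, which has the closed-form expected p-distance
#' `p(T) = (19/20)(1 - exp(-(20/19) r T))` for two leaves at path length
#' `T`. Covarying site pairs evolve as locked states: the partner site is
#' a fixed residue bijection of the master site at every node, so the
#' pair's columns are perfectly coupled. No indels are generated -- the
#' output is columnar by construction.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_msa`: `alignment` (tibble), `tree`,
#'   `site_rate` (per-site rates), `region_rates` (region map with true
#'   multipliers), `covarying` (tibble `site_i`, `site_j`).
#' @export
simulate_msa <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    tree <- config$tree %||% ape::rcoal(config$n_taxa)
    tree <- ape::reorder.phylo(tree, "cladewise")
    ns <- config$n_sites
    rates <- site_rates(config)
    cov <- config$covarying_pairs
    if (is.numeric(cov) && length(cov) == 1) {
      stopifnot(2 * cov <= ns)
      picks <- sample.int(ns, 2 * cov)
      cov <- cbind(picks[seq_len(cov)], picks[cov + seq_len(cov)])
    }
    cov <- if (is.null(cov)) {
      tibble(site_i = integer(), site_j = integer())
    } else {
      tibble(site_i = as.integer(cov[, 1]), site_j = as.integer(cov[, 2]))
    }
    sigma <- map(seq_len(nrow(cov)), function(i) sample.int(20))
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    states <- matrix(0L, n_node, ns)
    root <- n_tip + 1L
    states[root, ] <- sample.int(20L, ns, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_len <- tree$edge.length[e]
      p_same <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * rates * t_len)
      stay <- runif(ns) < p_same
      s <- states[parent, ]
      shift <- sample.int(19L, ns, replace = TRUE)
      changed <- (s + shift - 1L) %% 20L + 1L
      states[child, ] <- ifelse(stay, s, changed)
    }
    # lock covarying partners to their master through the pair bijection
    for (i in seq_len(nrow(cov))) {
      states[, cov$site_j[i]] <- sigma[[i]][states[, cov$site_i[i]]]
    }
    tips <- states[seq_len(n_tip), , drop = FALSE]
    aln <- tibble(
      id = tree$tip.label,
      species = tree$tip.label,
      residues = apply(tips, 1, function(s) paste(AA20[s], collapse = "")),
      source = "simulate_msa")
    region_rates <- if (!is.null(config$region_map)) {
      mutate(config$region_map, multiplier = config$multipliers)
    } else NULL
    structure(list(alignment = aln, tree = tree, site_rate = rates,
                   region_rates = region_rates, covarying = cov),
              class = "sim_msa")
  })
}

#' Simulate a missense-variant table with planted tiers
#'
#' Generates `n` missense records whose damaging-vote tier is planted:
#' tier counts are the (largest-remainder rounded) shares of `tier_mix`,
#' and each record's SIFT/PolyPhen/GD scores are drawn on the damaging or
#' benign side of the vote thresholds according to its tier, so
#' [vote_tier()] recovers the plant exactly. Positions are drawn from
#' enrichment regions in proportion to `weight * length`, emulating
#' uneven variant density along the protein.
#'
#' @param n Number of records.
#' @param tier_mix Length-4 probabilities for tiers (none, one, two,
#'   three); need not be normalised.
#' @param reference_length Protein length over which positions are drawn.
#' @param enrichment Optional tibble `region`, `start`, `end`, `weight`;
#'   default uniform over the reference.
#' @param seed Mandatory integer seed.
#' @inheritParams vote_tier
#' @return A list of class `sim_variants`: `variants` (tibble including
#'   the planted `true_tier`) and `tier_counts`.
#' @export
simulate_variants <- function(n, tier_mix = c(0.4, 0.3, 0.2, 0.1),
                              reference_length = 1104, enrichment = NULL,
                              seed, gd_cutoff = 65, sift_cutoff = 0.05,
                              polyphen_cutoff = 0.5) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(length(tier_mix) == 4, all(tier_mix >= 0), sum(tier_mix) > 0)
  withr::with_seed(seed, {
    mix <- tier_mix / sum(tier_mix)
    counts <- diff(c(0L, round(cumsum(mix) * n)))
    tiers <- rep(0:3, counts)
    tiers <- tiers[sample.int(length(tiers))]  # shuffle row order
    # which predictors vote damaging, per record
    damaging <- t(vapply(tiers, function(k) {
      v <- c(FALSE, FALSE, FALSE)
      v[sample.int(3, k)] <- TRUE
      v
    }, logical(3)))
    colnames(damaging) <- c("gd", "sift", "polyphen")
    gd <- ifelse(damaging[, "gd"],
                 runif(n, gd_cutoff, 215), runif(n, 0, gd_cutoff - 1e-6))
    sift <- ifelse(damaging[, "sift"],
                   runif(n, 0, sift_cutoff), runif(n, sift_cutoff + 1e-6, 1))
    polyphen <- ifelse(damaging[, "polyphen"],
                       runif(n, polyphen_cutoff, 1),
                       runif(n, 0, polyphen_cutoff - 1e-6))
    if (is.null(enrichment)) {
      enrichment <- tibble(region = "all", start = 1L,
                           end = as.integer(reference_length), weight = 1)
    }
    len <- enrichment$end - enrichment$start + 1
    reg <- sample.int(nrow(enrichment), n, replace = TRUE,
                      prob = enrichment$weight * len)
    pos <- enrichment$start[reg] +
      floor(runif(n) * len[reg])
    ref <- AA20[sample.int(20, n, replace = TRUE)]
    alt <- AA20[(match(ref, AA20) + sample.int(19, n, replace = TRUE) - 1) %% 20 + 1]
    variants <- tibble(
      protein_position = as.integer(pos), ref_aa = ref, alt_aa = alt,
      variant_class = "SNP", consequence = "missense_variant",
      sift = sift, polyphen = polyphen, gd = gd,
      true_tier = factor(c("none", "one", "two", "three")[tiers + 1],
                         levels = c("none", "one", "two", "three"),
                         ordered = TRUE))
    structure(list(variants = variants,
                   tier_counts = setNames(counts,
                                          c("none", "one", "two", "three"))),
              class = "sim_variants")
  })
}

#' Simulate gene-order tables with a planted conserved block
#'
#' Builds a reference neighborhood (anchor gene centered in a window of
#' `2k + 1` genes, plus `filler` unrelated genes at each chromosome end),
#' copies it into each genome, and corrupts each copy with
#' `round(shuffle_rate * 2k)` random adjacent transpositions and
#' `n_inversions` random segment inversions (order reversed, strands
#' flipped). Shuffle rate 0 reproduces the block exactly; inversions
#' alone leave the orientation-aware block score unchanged.
#'
#' @param n_genomes Number of genomes.
#' @param k Flank size of the conserved window.
#' @param shuffle_rate Fraction in `[0, 1]` controlling transposition
#'   count.
#' @param n_inversions Number of segment inversions per genome.
#' @param filler Unrelated genes added at each end of the chromosome.
#' @param anchor Anchor gene symbol.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_gene_orders`: `tables` (named list of
#'   gene-order tibbles; the first, `reference`, is uncorrupted), `window`
#'   (the true conserved signed window), `anchor`, `k`.
#' @export
simulate_gene_orders <- function(n_genomes = 6, k = 5, shuffle_rate = 0,
                                 n_inversions = 0, filler = 3,
                                 anchor = "ANCHOR", seed) {
  if (missing(seed)) abort("seed is mandatory")
  withr::with_seed(seed, {
    w <- 2 * k + 1
    syms <- c(paste0("L", k:1), toupper(anchor), paste0("R", 1:k))
    strands <- sample(c("+", "-"), w, replace = TRUE)
    window <- paste0(strands, syms)
    make_genome <- function(g, corrupt) {
      s <- syms; st <- strands
      if (corrupt) {
        n_swap <- round(shuffle_rate * (w - 1))
        for (sw in seq_len(n_swap)) {
          i <- sample.int(w - 1, 1)
          s[c(i, i + 1)] <- s[c(i + 1, i)]
          st[c(i, i + 1)] <- st[c(i + 1, i)]
        }
        for (iv in seq_len(n_inversions)) {
          ij <- sort(sample.int(w, 2))
          seg <- ij[1]:ij[2]
          s[seg] <- rev(s[seg])
          st[seg] <- rev(ifelse(st[seg] == "+", "-", "+"))
        }
      }
      fl <- function(side) paste0("FILL_", g, "_", side, "_", seq_len(filler))
      sym_all <- c(fl("a"), s, fl("b"))
      str_all <- c(sample(c("+", "-"), filler, TRUE), st,
                   sample(c("+", "-"), filler, TRUE))
      tibble(genome = g, chrom = "chr1",
             start = seq_along(sym_all) * 1000L,
             end = seq_along(sym_all) * 1000L + 500L,
             strand = str_all, symbol = sym_all)
    }
    genomes <- c("reference", paste0("genome", seq_len(n_genomes - 1)))
    tables <- setNames(
      map2(genomes, c(FALSE, rep(TRUE, n_genomes - 1)), make_genome),
      genomes)
    structure(list(tables = tables, window = window,
                   anchor = toupper(anchor), k = k),
              class = "sim_gene_orders")
  })
}
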