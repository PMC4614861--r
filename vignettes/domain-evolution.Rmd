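---
title: "Domain-resolved molecular evolution with domevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-resolved molecular evolution with domevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domevol)
library(tibble)
```

## What the package computes

domevol is a pipeline for asking, of a protein family, *where* and *how
fast* it evolved: which domains were under the strongest constraint, how
the family's overall substitution rate compares with classic conserved
proteins, which alignment columns co-evolve, which human missense variants
look damaging, and whether the gene's chromosomal neighborhood has been
preserved. The worked family throughout is TRPM8, the cold- and
menthol-activated cation channel, for which the package ships a manifest
of 39 database accessions, a 28-region domain map of the human protein
(1104 residues), a divergence-time configuration and the 13-mer pore-loop
antibody epitope. Every analysis, however, takes ordinary tibbles and
works for any family.

All user-facing coordinates are 1-based and inclusive, matching how domain
tables are printed in the literature. Alignments are tibbles (`id`,
`species`, `residues`, `source`); gaps are `-` (a `.` on input is
normalised), residues are the 20 standard letters plus `X` (B/Z/U are
collapsed to `X` with a warning, because downstream statistics need an
unambiguous alphabet).

## Divergence and the clock

The unit of divergence everywhere is *changes per 100 aligned residues*
(the p-distance times 100), with pairwise deletion of columns where either
sequence is gapped. Pairwise deletion rather than complete deletion is
deliberate: family sets routinely include fragmented database sequences,
and complete deletion would let a single ragged sequence erase most
columns. A Poisson correction (`-ln(1 - p) * 100`) is available but off by
default, because the headline analyses are phrased in raw
changes-per-100-residues.

`score_regions()` slices the family alignment by a reference-anchored
region map and computes, per region, all pairwise divergences. The
regions of a real domain table overlap (a full-length C-terminal region
overlaps the TRP box inside it); regions are therefore scored
independently and simply reported side by side. Heterogeneity across
regions is tested with the Kruskal--Wallis rank test (tie-corrected H,
chi-square reference), the appropriate test given that per-region
divergence distributions are non-normal and share no common variance. Both
mean and median per-region divergence are reported, since a bar plot of
such scores could defensibly use either.

`lineage_pair_change()` and `fit_rate_curve()` implement the
rate-versus-time (Dickerson-style) analysis: for each configured lineage
comparison, the mean cross-pair divergence is plotted against the
divergence time, and a least-squares line *through the origin*
(`slope = sum(t y) / sum(t^2)`) summarises the clock. The through-origin
form encodes the model's only assumption: zero time means zero
divergence. The reciprocal of the slope is the unit evolutionary period
(UEP), the number of million years per 1% sequence change, which is the
traditional scale for comparing a family against histone-H4-like
(strongly conserved) and cytochrome-c-like (semi-conserved) baselines via
`baseline_compare()`.

Divergence times are inputs, not estimates: the shipped configuration
(`trpm8_divergence_config()`) encodes the comparison groups as accession
lists with literature anchor times -- non-human primates vs human at 30
MYA, the mammalian radiation at 96 MYA, marsupial vs eutherian at 160
MYA, birds vs amphibians at 360 MYA and amphibians vs mammals at 390 MYA.
These anchors are user-editable; the analysis is only as good as its time
calibration, which is why the configuration is an explicit file rather
than a constant.

## Coupling networks

`mi_matrix()` computes weighted, pseudocounted mutual information (nats)
between the residue distributions of every retained column pair,
`MI(i,j) = sum f_ij ln[f_ij / (f_i f_j)]` over the 20-letter alphabet.
Conventions follow the mutual-information servers used for circular
coupling plots: sequences are down-weighted by single-linkage clustering
at 62% identity (weight = 1 / cluster size), a pseudocount of
lambda = 0.05 per joint cell regularises sparse tables, columns with
non-gap occupancy below 0.5 are dropped, and marginals are taken from the
pseudocounted joint so MI is exactly non-negative.

Raw plug-in MI has a well-known finite-sample bias of roughly
`(K-1)^2 / 2N` nats for a K-letter alphabet -- about 0.35 nats for
independent columns at N = 500. No fixed raw-MI threshold can separate
signal from that floor across alignment sizes, which is why the
thresholded quantity everywhere downstream is the *permutation z-score*:
`mi_zscores()` permutes residues within each column independently
(preserving each column's composition while destroying the pairing),
rebuilds the full MI matrix per replicate, and standardises the observed
MI. The published display convention "MI greater than 6.5" is interpreted
on this z scale; a raw-MI threshold is available by passing a bare matrix
to `classify_edges()`. Edges above threshold are ranked into the familiar
display tiers (top 5%, 70th--95th percentile, remainder), `cumulative_mi()`
sums each position's above-threshold couplings, and `column_conservation()`
scores each column's Kullback--Leibler divergence from the
Robinson--Robinson background frequencies.

One caveat the tests make explicit: a deep *shared* phylogeny inflates MI
at every pair, because related rows co-inherit residues jointly at both
columns. The permutation null assumes exchangeable rows, so coupling
detection is calibrated on star-phylogeny simulations (independent
lineages); on strongly structured real families the z-scores remain
useful for ranking but their absolute calibration is optimistic. The MI
engine itself is implemented with sparse indicator algebra, so the full
200-column matrix and its 50 permutation replicates run in seconds.

## Variant triage

`grantham_distance()` implements the classical physicochemical distance
from composition, polarity and volume, with the quadratic-form constants
(alpha = 1.833, beta = 0.1018, gamma = 0.000399) and scale rho = 50.723
chosen so the 190 pair distances average 100; the shipped table
reproduces the published integer matrix to within a unit (Leu--Ile 5,
Arg--Lys 26, Cys--Trp 215). `gvgd()` extends this to alignment columns in
the Align-GVGD manner: GV is the quadratic form over each property's
observed range at the column, GD the form over the substituting residue's
deviation outside that range (zero inside). On an invariant column GV is
0 and GD degenerates to the plain Grantham distance, which is also the
documented fallback for positions that cannot be aligned.

`vote_tier()` combines three predictors into damaging-vote tiers: SIFT at
most 0.05, PolyPhen at least 0.5, GD at least 65. The SIFT and PolyPhen
cutoffs are the tools' own conventions; the GD cutoff of 65 is the
classical boundary of "radical" Grantham exchanges and is exposed as an
argument, since no standard value exists for GD as a damaging call. Tiers
are the *count* of damaging votes (none/one/two/three), deliberately
simple and monotone: making any score strictly more damaging can never
lower the tier (a property test asserts this). Missing scores are
non-votes rather than errors, because real annotation tables are ragged.
Consequence and class vocabularies are carried as free strings, not
enums -- annotation pipelines differ, and tallying (`tally_variants()`,
`positional_density()`) does not need a controlled vocabulary.

## Synteny

`synteny_report()` formalises the browser-inspection style of synteny
checking as a computable score: take the window of k genes on each side
of the anchor (default k = 5, wide enough to cover the tetrad-plus-dyad
flank arrangement typical of a conserved locus), write it as signed
symbols (`+TRPM8`), and score each genome's window against the reference
window by longest common subsequence over signed symbols. Orientation
matters (a strand flip breaks a match), but because loci are routinely
assembled on the opposite strand, each window is also tested in reverse
orientation (order reversed, strands flipped) and the better score is
kept -- so a whole-window inversion scores perfectly, while partial
inversions lose exactly the genes they displace. Gene symbols must match
after case normalisation; ortholog mapping is upstream of this package.
A partner gene can be reported `present`, `absent`, or `unknown` for
genomes flagged as draft assemblies, where absence of evidence is not
evidence of absence.

## The simulator and what passing tests mean

`simulate_msa()` evolves sequences along a tree under a 20-state
uniform-replacement model: per site, substitutions arrive as a Poisson
process at `base_rate` times the site's region multiplier, and each event
replaces the residue uniformly among the other 19. Branch-end states are
drawn from the exact transition probability
`P(same) = 1/20 + (19/20) exp(-(20/19) r t)`, so the simulation is the
Markov chain itself, not an approximation, and two leaves at path length
T have the closed-form expected p-distance
`(19/20)(1 - exp(-(20/19) r T))` -- the oracle the tests check against.
Covarying pairs evolve as locked states (the partner column is a fixed
residue bijection of its master), planting perfect coupling.
`simulate_variants()` plants damaging-vote tiers exactly by drawing each
score on the correct side of its threshold, and `simulate_gene_orders()`
plants a conserved window and corrupts copies with adjacent
transpositions and segment inversions. All generators take a mandatory
seed and run inside `withr::with_seed()`, so identical configurations are
byte-identical regardless of caller RNG state.

The generator's deliberate idealisations bound what green tests prove:
no indels (real alignment uncertainty is absent), uniform replacement
(no amino-acid exchangeability structure), and site-independent evolution
outside the planted pairs. Passing the closed-loop tests shows the
estimators recover what the model plants -- not that real data satisfy
the model.

Study conditions used by the test-suite and the acceptance script, chosen
once: coupling detection uses 50-taxon star phylogenies, 200 sites, 5
planted pairs, 50 permutations (star, because the permutation null
assumes exchangeable rows -- see above); region-rate recovery uses a
24-leaf star, 1104 sites (the length of the worked reference protein),
10 regions with multipliers 0.2--2x; clock recovery uses a grouped
ultrametric tree with splits at 30/96/160/250/360/450 MYA, 24 taxa and
1000 sites, compared against the through-origin fit of the closed-form
expectations; tree recovery uses a balanced ultrametric 8-taxon tree and
500 sites. These sizes keep each property estimable with comfortable
margins while the whole suite stays quick.

## Real-sequence workflows

Nothing in the package requires network access. The real-family analyses
(identity tables, epitope localisation on the reference accession,
domain heterogeneity on the family MSA) operate on a cache that is built
once on a networked machine with `fetch_protein_sequences()` (NCBI
efetch / Ensembl REST) and `align_sequences()` (MAFFT), then loaded with
`reference_family_msa()`. Identity percentages are computed *within* the
joint family MSA with the both-residues denominator (columns where both
members carry residues), the convention that best matches published
family identity tables; expect percentage-point-level sensitivity to the
aligner and denominator choice. Bayesian tree inference is explicitly out
of scope: `neighbor_joining()` provides the distance-based surrogate, and
externally inferred trees can be supplied as newick.

## Numerical and degenerate-input choices

Ties in `scan_epitope()` resolve to the smallest start. All-gap columns
are removed on alignment load (with a count), so "column" always means a
column with at least one residue. Regions with fewer than two usable
rows are excluded from scoring with a warning rather than an error.
Kruskal--Wallis on identical values degenerates to p = 1 with a warning.
Negative neighbor-joining branch lengths are clamped to zero and counted.
Pseudocount-induced negative MI smaller than 1e-9 in magnitude is floored
at zero. Permutation z-scores with a degenerate (zero-variance) null are
reported as 0 and flagged rather than propagating NaN.
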