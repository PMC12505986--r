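---
title: "Methods: quantifying stator-complex evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stator-complex evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

statorevo implements the computational chain needed to compare bacterial
flagellar ion transporters (FIT: MotAB/PomAB stators) with their generic
ion-transporter relatives (GIT: ExbBD, TolQR, AglRS): operon-synteny pairing
of A and B subunit genes, alignment statistics for the B subunit's
plug+linker segment, conditional-clade-distribution (CCD) summaries of tree
posteriors, marginal ancestral sequence and gap reconstruction, and automated
structural architecture classification of A-subunit monomers. This vignette
records the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generators emulate, and the package's design
decisions where the methodology was genuinely open.

## Operon synteny pairing

B subunits are poorly conserved in sequence, so they are located by genomic
context: in stator operons the B gene lies directly downstream of the A gene.
`pair_downstream()` therefore takes, for each curated A-subunit hit, the next
gene downstream on the contig (in strand orientation; on the minus strand
"downstream" means decreasing coordinate) and accepts it as the B partner
only when it lies on the same strand within `max_gap_bp`.

Parameters and defaults:

* `min_similarity_pct = 10` (in `filter_hits()`): hits *below* 10%
  similarity to the search reference are excluded, so the boundary value is
  retained. Similarity is whatever metric the hit table records (percent
  identity to the reference over mutually non-gap columns is the intended
  convention); keeping the metric in the table makes the filter itself
  metric-agnostic.
* `max_gap_bp = 500`: an operon-scale intergenic distance. "Directly
  downstream" has no canonical cutoff; 500 bp is generous for bacterial
  operons and configurable.
* `dup_window_bp = 10000`: two or more A hits within 10 kb of each other on
  one contig are flagged `excluded_duplicate`, because duplicated A loci
  break the one-A-one-B operon assumption that downstream pairing relies on.

Unpaired hits (no same-strand gene within the window) are reported with
status `unpaired` rather than silently dropped; whether to keep them in
downstream sets is a user decision. Manual confirmation of B identity cannot
be coded, so `product_keyword_report()` provides a non-blocking annotation
check instead. Coordinates are 0-based half-open internally; GFF3 and GenBank
input (1-based inclusive) is converted on read.

## Plug+linker statistics

The plug+linker is the periplasmic segment of the B subunit between its TM
helix and the peptidoglycan-binding (OmpA-like) domain; it gates ion flow,
and FIT plugs are longer and glycine-richer than GIT ones. The default
region is alignment columns 76–133 (58 columns), where the E. coli MotB
reference row reads as a 52-residue ungapped segment. Both the column range
and the reference row are parameters.

* Mean pairwise identity averages, over all unordered sequence pairs,
  identical-residue columns divided by *mutually non-gap* columns (× 100).
  The denominator matters: with alignment length as denominator, sparse
  alignments would be scored incomparably lower. Pairs sharing no columns
  contribute 0 and are flagged.
* Column conservation is `1 − H/ln 20` with `H` the Shannon entropy of the
  column's non-gap residue frequencies; all-gap columns score 0.
* `plug_stats()` counts length, Gly, Pro, and overlapping GG dimers
  ("GGG" counts 2). Overlap counting is a convention choice; it is
  documented here and kept consistent between implementation and tests.
* The FIT-vs-GIT comparison uses a two-sided permutation test on the
  **difference of group medians** (medians, not means, because group
  summaries for these skewed length/count distributions are conventionally
  reported as medians), with
  p = (1 + #{|t*| ≥ |t|}) / (B + 1), B = `n_permutations`. The p-value
  resolution is 1/(B+1). On integer-valued data (residue counts) permuted
  statistics tie with the observed one, which makes the p-value
  conservative — rejection rates at level α are then at or below α. The
  calibration checks reflect this: on continuous null data the type-I error
  is expected to sit at the nominal level; on the integer-valued generator
  null only super-uniformity is asserted.

## Tree-posterior uncertainty via conditional clade distributions

A CCD factorizes a distribution over rooted topologies into conditional
split probabilities. From a tree sample, `build_ccd()` tallies, once per
tree, each observed clade and each observed split (parent clade → unordered
child pair). Two estimators are provided:

* **CCD1** (default): p(split | parent) = split count / parent count.
* **CCD0**: p(split | parent) ∝ product of the two child clades' marginal
  occurrence frequencies, renormalized over the parent's observed splits.
  CCD0 is the usual choice for *summarizing* posteriors; CCD1 is the more
  direct frequency estimator for *entropy*. Both are implemented, reports
  name the one used, and they agree whenever every parent has a single
  observed split.

Clade-support entropy in natural log units is computed by the memoized
recursion `H(C) = Σ_s p(s|C) (−ln p(s|C) + H(C_left) + H(C_right))`, with
`H = 0` for singletons and cherries. This equals the Shannon entropy
−Σ_T p(T) ln p(T) of the tree distribution induced by the CCD, which the
test suite verifies by brute-force enumeration of the CCD support on 6-taxon
samples (tolerance 1e−9). Entropy is 0 exactly when the post-burn-in sample
is topologically constant, and it is invariant to taxon relabeling and tree
order.

Counting conventions are part of the result's meaning: `count_clades()`
counts distinct clades of size ≥ 2 across the retained trees, including the
root clade and excluding singletons (`include_root = FALSE` gives the other
convention; published clade counts rarely state theirs, so both are
available). Burn-in defaults to 10% of the sample in `read_tree_sample()`.

The MAP summary tree maximizes the product of conditional split
probabilities by dynamic programming over observed clades in log space; ties
are broken deterministically by the lexicographically smallest child
bitstring over the sorted taxon order. Node support annotation
(`annotate_support()`) reports the fraction of sample trees containing each
clade, binned for display as white (≤ 0.5), gray (≤ 0.8), dark gray
(≤ 0.95) and black (> 0.95); the 0.95 boundary falls in the dark-gray bin.

## Marginal ancestral reconstruction

Residue and gap histories are reconstructed on a fixed rooted tree by
Felsenstein pruning with reversible models normalized to one expected event
per unit branch length:

* **Residues**: LG exchangeabilities with equilibrium frequencies estimated
  from the data (+F, with a +1 pseudocount) unless supplied. Among-site rate
  variation is deliberately out of scope; reconstructions are therefore
  slightly over-smoothed at fast sites, which matters little for the gap
  analysis the package targets. Ambiguity codes (X/B/Z) and gaps are treated
  as missing data in the residue track.
* **Gaps**: the alignment is recoded as presence(1)/absence(0) and evolved
  under a reversible two-state chain whose stationary frequencies are
  estimated from the observed gap fraction (clamped to [0.01, 0.99]), rate
  fixed so branch lengths are reused from the residue tree — matching a
  single-tree workflow in which one phylogeny underlies both tracks. A
  position is reconstructed as a gap when its marginal gap probability is
  **greater than or equal to** 0.5; the boundary is inclusive by
  definition.
* Marginal posteriors combine post-order partials with pre-order outside
  messages; the root prior is the model's equilibrium distribution. Each
  posterior vector sums to 1 (tolerance 1e−9 in the contract; in practice
  1e−12), and the test suite checks node posteriors against brute-force
  enumeration on small trees.
* `assemble_ancestor()` takes the argmax residue at non-gap positions,
  breaking exact ties alphabetically and flagging tied positions as
  low-confidence.
* `optimize_branch_lengths()` is coordinate-wise bounded univariate
  maximization (branch length ∈ [1e−8, 20], `stats::optimize`), cycling
  until the per-round improvement drops below `tol = 1e-6` or `max_rounds =
  20`; proposals are accepted only when they improve the likelihood, so the
  trace is non-decreasing. For a reversible model only the tip-to-tip path
  length of a two-tip tree is identifiable, which is what the recovery test
  asserts.

## Structural architecture classification

A-subunit monomers are classified from Cα geometry alone (robust to models
lacking full backbones, and exactly what the synthetic generator emits).
The chain is partitioned as N-appendage | TM1 TM2 | TGI region | TM3 TM4 |
C-terminal domain, where the TGI ("cytoplasmic") region is defined
topologically as the TM2–TM3 inter-helix segment — monomer models carry no
membrane frame, but TM2 anchors the torque-generating interface, so the
inter-helix segment is the cytoplasmic bundle.

Secondary structure uses P-SEA-style Cα distance windows: helix when
d(i,i+2) ∈ [5.1, 6.1] Å, d(i,i+3) ∈ [4.6, 6.0] Å, d(i,i+4) ∈ [5.5, 7.3] Å;
strand when d(i,i+2) ∈ [6.3, 7.2] Å and d(i,i+3) ∈ [9.0, 11.0] Å. A passing
helix window marks residues i..i+4 (strand: i..i+3) — marking the whole
window adds redundancy against coordinate noise. Helix runs shorter than 5
and strand runs shorter than 3 revert to coil; single coil residues between
helix runs are merged.

TM candidates are hydrophobicity-defined: each helix segment is extended
over contiguous residues with per-residue Kyte–Doolittle value ≥
`tm_min_kd` (helix ends erode under coordinate noise, hydrophobic spans do
not), touching spans are coalesced, fragments separated by ≤ 6 coil
residues are merged into composite (broken-helix) candidates when both
halves are hydrophobic and each is shorter than a full TM span, and
candidates must span ≥ 15 residues with mean KD ≥ 1.0. The four
best-scoring candidates in sequence order become TM1–TM4; fewer than four
makes the model unclassifiable (fewer than two is reported as the stronger
"no TM protein" condition).

The original classification was done by expert inspection, so every numeric
threshold here is this package's own decision, chosen on idealized helix
geometry so that a MotA-like feature set yields SLNL and an ExbB-like one
LSBL, and validated against the generator sweep; all are configurable via
`arch_config()`:

* N-appendage "large" at ≥ 20 residues before TM1;
* TGI letter L at ≥ 3 helices of ≥ 6 residues in the TGI region, Z at
  ≥ 2 strands of ≥ 3 residues (the Zorya-type beta-sheet cytoplasmic
  domain; never emitted without strand evidence), else S;
* TM3 broken (B) when composite — the coil rule takes precedence, so a
  straight composite is still B — or when its two halves' principal axes
  differ by > 25°;
* C-terminal "large" at ≥ 2 helices after TM4 (one helix is the minimal
  configuration).

Cytoplasmic class follows the TGI-region helix count: 2 → CCD2, 3 → CCD3,
4 → TGI4, 5 → TGI5, anything else "other". A three-helix cytoplasmic bundle
is exactly what the CCD3 class describes, so 3 maps to CCD3 even though the
code letter for ≥ 3 helices is L. The default code space is
{S,L}×{S,L}×{N,B}×{S,L}, 16 codes; allowing Z gives 24.

## What the generators emulate — and what they do not

All generators are driven by one integer seed and write manifests with the
planted truth, so downstream stages can be scored automatically; identical
seeds reproduce outputs byte for byte.

* `gen_yule_tree()`: a pure-birth tree. Default `birth_rate = 2` at 20 taxa
  gives expected root heights near 1.3 substitutions/site — a diverged but
  alignable protein family, the regime in which ancestral reconstruction is
  meaningful.
* `gen_tree_sample()`: posterior spread emulated by Poisson(`nni_rate`)
  random rooted NNI moves per sampled tree. This tests the entropy and
  summary machinery, *not* MCMC: NNI noise has no likelihood structure, so
  passing tests say nothing about inference quality on real posteriors,
  only about the correctness of the CCD computations. Rates 8 / 2 / 0.5
  emulate a diffuse B-subunit-like posterior, a tighter A-subunit-like one
  and a concentrated concatenation-like one.
* `gen_alignment()`: residues evolve under the substitution model; gap
  blocks (geometric lengths, mean 6 columns) evolve as a single binary
  presence character per block with relative rate `indel_rate = 0.1` —
  indel events at roughly a tenth of the substitution rate, consistent with
  empirical indel/substitution ratios — and stationary presence probability
  0.7. This is deliberately the same presence-absence abstraction the gap
  reconstruction uses, not a TKF-style indel model: it provides exact gap
  truth, but cannot probe misalignment or sliding-indel artifacts of real
  data.
* `gen_operon_genome()`: single-contig genomes with planted A–B operons
  (intergenic gaps 5–200 bp), decoy genes placed farther downstream than
  the true B or in their own windows, duplicated-A loci 3 kb apart, and a
  hit table in which decoys score below the 10% similarity threshold.
* `gen_structure()`: canonical α-helices (1.5 Å rise, 2.3 Å radius,
  100°/residue) — four 20-residue TM helices on a 10 Å square, 10-residue
  TGI and C-terminal helices below the membrane plane, a 25-residue
  N-terminal helix for letter L, a 40° kink with a short coil interruption
  for broken TM3, hydrophobic residues (I/L/V/F) in TM segments and polar
  residues elsewhere. Linkers are straight traces at ≤ 2.3 Å spacing and at
  least 6 residues, which matches neither the helix nor the strand distance
  signature and keeps segments separated. Gaussian coordinate noise
  (default σ = 0.1 Å) stands in for model imprecision; real predicted
  structures err in correlated, domain-level ways the generator does not
  imitate.
* `gen_plug_groups()`: 102 FIT-like vs 277 GIT-like sequences (the group
  sizes of a full-scale survey), Poisson lengths with means 52 vs 35 and
  glycine probabilities 0.115 vs 0.06 (the FIT values match the reference
  plug's 52 residues with 6/52 glycines, 5/52 prolines; the GIT values
  encode the shorter, glycine-poorer plugs of generic transporters).

## Problem sizes and numerical notes

The test suite and the acceptance script run at desk scale by design: 6-taxon
samples for enumeration cross-checks, 20-taxon 100-tree samples for the
entropy ordering (20 replicates), 120-column alignments for gap recovery,
160 structures for the classification sweep, 2,000 null simulations with 199
permutations for calibration. Full-scale survey numbers (hundreds of genomes,
BEAST posteriors with tens of thousands of clades) are outside what synthetic
desk-scale data can or should reproduce; the package checks the machinery's
correctness, not those headline values.

Numerical choices worth knowing: transition matrices come from the
symmetrized eigendecomposition of the reversible generator (exact for t = 0
and t → ∞, clipped at 0 and renormalized against rounding); CCD recursions
are memoized over clade keys; MAP ties are broken by child bitstring; argmax
ties in ancestor assembly are broken alphabetically and flagged; degenerate
inputs (all-gap columns, empty regions, zero-overlap sequence pairs,
single-split parents) all have defined, tested behavior.

## Known limitations

* No among-site rate variation and no joint (vs marginal) reconstruction.
* CCD entropies compare *samples*; they inherit whatever burn-in and mixing
  properties the sampler had.
* The structural classifier assumes a monomer with exactly four TM helices;
  fusion proteins or split models are reported unclassifiable rather than
  guessed.
* The permutation test is exchangeability-based; with strong group-size
  imbalance and variance differences its type-I behavior is conservative
  rather than exact.
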