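---
title: "Interface detection and correlated evolution in coat assemblies: methods"
author: "coatmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface detection and correlated evolution in coat assemblies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coatmap)
```

# The problem

Clathrin-coated vesicles are assembled from hundreds of polypeptide
chains: an outer lattice of clathrin heavy and light chains, a middle
layer of heterotetrameric adaptor complexes (AP1, AP2: large
alpha/gamma and beta subunits, a medium mu subunit and a small sigma
subunit), and the cargo-proximal membrane layer. The only structures of
whole coats are cryo-EM fits at 8 to 12 Angstrom resolution that place
C-alpha atoms only, so the classical solvent-accessibility definition of
an interface residue cannot be applied directly. `coatmap` implements a
complete analysis chain for this situation:

1. **Interface detection from accessibility**, in two regimes. For
   all-atom structures, ASA is computed with a 1.4 Angstrom water probe
   and a residue is an interface residue when it is *buried in the
   complex* (relative accessibility strictly below 7%) and *exposed in
   the isolated chain* (strictly above 10%). For C-alpha-only models,
   ASA is computed with an enlarged 3.5 Angstrom probe over
   united-residue C-alpha beads, and the percent criterion is replaced
   by residue-type-dependent absolute cutoffs calibrated to correspond
   to the same 7% and 10% thresholds.
2. **Subcomplex decomposition.** Whole coats are too large to analyse at
   once; chains whose closest inter-chain C-alpha distance is at most
   5 Angstrom are *near neighbours*, and each chain is analysed inside
   the subcomplex formed by itself plus its near neighbours.
3. **Conservation comparison.** Orthologues are filtered (strictly more
   than 30% identity to the query and 70% coverage of its length),
   per-column conservation is scored with the convention that the
   lowest score is the most conserved position, and interface residues
   are compared against non-interface surface-exposed residues of the
   same chain.
4. **Mirror-tree correlation.** For each pair of protein families the
   Pearson correlation between their genetic distance matrices over
   common species measures correlated evolution; significance comes
   from a species-label permutation test and from unrelated baseline
   pairs.

# Solvent accessibility

ASA is computed by Shrake-Rupley point quadrature: each atom's
probe-centre sphere (radius = van der Waals radius + probe) is sampled
at a deterministic golden-spiral point set in a fixed orientation, and a
point is accessible when it lies outside every other atom's expanded
sphere. Residue ASA is the sum over the residue's atoms. The default is
960 points per atom; an isolated sphere is then reproduced to well
within 1% of the closed form $4\pi (r + p)^2$ (machine precision, since
every point of an isolated sphere is accessible).

Numerical behaviour worth knowing:

* Quadrature granularity is about $4\pi(r+p)^2 / 960 \approx 0.14$
  square Angstrom per point. Per-residue areas are therefore rotation
  invariant to about 0.5% for well-exposed residues, but a residue with
  only a few square Angstrom of exposed area can deviate by up to
  ~2 square Angstrom under rotation. Chain totals agree to 0.5%. The
  thresholds of the interface rule act on percentages of reference
  maxima (140 to 290 square Angstrom), so this granularity is well
  below the decision scale except exactly at a threshold.
* Point-in-sphere tests make no reachability argument: a closed internal
  cavity wide enough for the probe counts as accessible. This is the
  standard Shrake-Rupley convention.
* Hydrogens are ignored; radii are a united-atom protein set (C 1.87,
  N 1.65, O 1.40, S 1.85 Angstrom, configurable via `vdw_radii()`).
  C-alpha atoms of C-alpha-only chains are united-residue beads of
  1.87 Angstrom (`calpha_bead_radius()`), a choice the calibration
  step absorbs: cutoffs are calibrated under the same bead radius they
  are applied with.

Relative accessibility divides by a per-type reference maximum.
Published tables differ by a few percent; the table is therefore an
explicit, configurable input (`reference_max_asa()`). Two sets ship with
the package: the theoretical Gly-X-Gly tripeptide maxima of Tien et al.
(2013) for real structures, and a set computed from the package's own
extended synthetic tripeptides for the synthetic benchmark world, so
that generator and detector live on one consistent scale. In the
C-alpha regime classification uses absolute cutoffs and relative values
are informational only.

# Calibrating the C-alpha cutoffs

The low-resolution rule needs, per residue type, the C-alpha ASA values
(3.5 Angstrom probe) that correspond to 7% and 10% all-atom relative
accessibility. Calibration pools training pairs from all-atom
structures: for every residue, its all-atom relative accessibility and
the C-alpha ASA of the same residue with the same structural context
reduced to its C-alpha trace. Both the complexed and each isolated-chain
form contribute, so buried and exposed contexts are both represented. An
isotonic (monotone increasing) regression per residue type maps relative
accessibility to expected C-alpha ASA and is read off at 7 and 10. The
monotone model is assumption-light and reproducible from any training
corpus; types with fewer than 50 training residues fall back to a pooled
all-type fit and are flagged. Because the isotonic fit is a step
function, it can be flat between the two evaluation points; the strict
ordering buried < exposed is then enforced by an epsilon lift, flagged
`degenerate`. On training data where C-alpha ASA is an exact monotone
function of relative accessibility the cutoffs recover the generating
function at both thresholds to well within 2%.

On held-out synthetic bundles the calibrated C-alpha detector reproduces
the all-atom detector with median per-chain F1 around 0.8 (the package's
acceptance suite requires at least 0.6), which is the level of fidelity
one should expect when only C-alpha positions survive the resolution
limit.

# The synthetic benchmark world

All tests run against generated data; nothing is downloaded. The
structure generator builds deterministic complexes from a scenario and a
seed, in two geometries:

* **`paired-helix`**: alpha-helical chains (2.3 Angstrom trace radius,
  100 degrees and 1.5 Angstrom rise per residue) packed side by side,
  as a triangle, or as a hexagonal bundle around a central chain.
  Residues are simplified: four backbone atoms plus one side-chain bead
  per heavy atom, arranged as a compact blob around the outward
  direction. Chains are slid apart deterministically until the closest
  inter-chain atom pair reaches van der Waals contact, so any seed gives
  the tightest sterically valid packing ("contact distance").
* **`bead-lattice`**: a two-chain sandwich of two-layer slabs built from
  extended strands. The smaller chain's contact patch sits in a pocket
  (its backing layer's overhang ring points its side chains up, forming
  the pocket wall) and the larger chain overhangs the patch, so every
  residue of the contact zone is genuinely enveloped in the complex
  while remaining exposed in the isolated chain.

Ground truth is independent of any accessibility computation: a residue
is a true interface residue when any of its heavy atoms lies within
5 Angstrom of another chain. This keeps detector tests non-circular.
The two geometries play different roles. For convex helix pairs, the
5 Angstrom contact set necessarily includes grazing rim residues that
retain part of their surface in the complex; the accessibility rule
(correctly) rejects those, so detection there is conservative: precision
is essentially 1.0 while sensitivity is moderate. The slab geometry is
the benchmark with a fully buried interface, and there the detector
recovers the contact ground truth with median sensitivity of at least
0.8 and precision above 0.9 across seeds. This mirrors real usage:
the dual-criterion rule is a high-confidence detector, not an
enumeration of every residue pair in casual contact.

Two generator-world calibrations follow from the simplified geometry and
are set once in the bundled configuration, not in the function defaults:
the united-residue blobs keep inter-chain C-alpha traces about 5.5 to
7 Angstrom apart even at full contact, so the synthetic pipeline groups
chains with an 8 Angstrom near-neighbour cutoff (the 5 Angstrom default
of `near_neighbors()` matches real packed chains and is unchanged); and
synthetic runs use the self-consistent reference-area set.

The sequence generator evolves gapless orthologue families along a
species tree (supplied, or pure-birth with mean root-to-tip depth 1.0
substitutions per site — a deep, eukaryote-wide divergence) under a
20-state equal-exchangeability model: per branch of length $b$, each
site draws a Poisson($b \cdot$ rate) number of substitutions, each to a
uniformly chosen different amino acid. Two leaves separated by path
length $d$ at rate 1 then differ at a fraction
$\tfrac{19}{20}(1 - e^{-20d/19})$ of sites in expectation, which the
test suite checks directly. Site classes (e.g. interface sites at rate
multiplier 0.2 versus surface sites at 1.0, 30%/70% of sites) model the
stronger constraint on interfaces; a per-family rate scale models the
radial layering of the assembly (outer lattice slow, cargo-proximal
fast). The matching distance estimator is the Poisson correction
$d = -\ln(1-p)$ (or its Gamma generalisation
$d = \alpha((1-p)^{-1/\alpha} - 1)$, which tends to the Poisson form as
$\alpha \to \infty$); near-saturated pairs ($p \ge 0.95$) return a
bounded sentinel distance of 10 substitutions per site, flagged, so
downstream correlations stay defined.

# Conservation scoring

Bayesian rate inference (as in Consurf) is deliberately not
re-implemented; the surrogate is the sequence-weighted Shannon entropy
of each alignment column (Henikoff-Henikoff position-based weights,
gaps excluded from the frequencies, the gap treated as a 21st symbol for
weighting), z-normalised across columns. This preserves the one property
the downstream comparison relies on: the lowest score marks the most
conserved position, as a relative measure within one protein. Columns
with more than 50% gaps are scored but flagged and excluded from group
means. If every column is identical the profile is all zeros by
convention. An import path for externally computed conservation grades
is available simply by constructing the profile data frame.

Two scales coexist on purpose. The z-normalised `score` is the
within-protein measure used for the interface versus surface comparison.
Cross-family statements ("the mu subunit family evolves faster than the
clathrin family") use the unnormalised `raw` entropy, since
z-normalisation removes exactly the between-family differences such
statements are about.

The comparison itself averages scores over interface residues and over
non-interface surface-exposed residues (isolated-form relative
accessibility strictly above 10%, not in the interface; everything else
is buried), reports the difference interface minus surface (negative
means the interface is more conserved), and attaches a seeded bootstrap
percentile interval (default 10,000 resamples). The comparison is
reported per chain; chains are not pooled.

# Mirror-tree correlation

For two families, distance matrices are restricted to their common
species (at least 4), the upper triangles are vectorised in one species
order, and Pearson's r is computed. Significance is assessed two ways,
matching the two natures of the claim:

* a one-sided permutation test (positive co-evolution is the
  hypothesis): species labels of the second matrix are permuted jointly
  over rows and columns, and
  $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$, default 9,999
  permutations, seeded;
* designated unrelated baseline pairs carried through the same batch
  computation, e.g. functionally non-equivalent chains of different
  adaptor complexes, whose r distribution anchors what "uncorrelated"
  looks like in the same data set.

Neighbour-joining trees (ape, negative branches clamped to zero and
flagged) are built for inspection and export; the quantitative claim
rides on the distance matrices and r only, which is why no
maximum-likelihood tree search is included. Externally computed distance
matrices (PHYLIP square format) and trees (Newick) can be imported for
real-data parity.

On simulated pairs (16 taxa, 500 sites) families sharing a species tree
give r around 0.98 with permutation p below 0.05 in over 90% of seeds,
independent-tree pairs give r near 0, and the null false-positive rate
at the 5% level is within sampling error of 5% — the package's
operational check that the statistic discriminates and the test is
calibrated.

# The pipeline

`run_pipeline()` chains the stages from one YAML configuration with
fail-fast validation (paths must exist, every stochastic step must be
seeded, C-alpha structures require a cutoff table or a calibration
corpus before any compute starts). Every stage persists its output as
standard text formats (PDB, TSV, FASTA, PHYLIP, Newick, JSON) in the
output directory, stages communicate only through those files, a JSONL
log records stage progress, and the report carries provenance (package
version, seed, config file hash). Two runs with the same configuration
and seeds produce byte-identical reports.

```{r, eval = FALSE}
cfg <- system.file("extdata", "config_synthetic.yaml", package = "coatmap")
report <- run_pipeline(cfg)
report
```

# Problem sizes and defaults used by the test and acceptance suites

Quadrature uses 960 points where the closed form is asserted and 480
points elsewhere (240 in the bundled end-to-end configuration); the
benchmark complexes are 2-3 chains of 25-40 residues (slabs of 58 and
98 residues); oracle equivalence runs on 20 complexes; calibration
trains on 8 bundles and evaluates on 20 held-out ones; conservation and
radial-ordering checks use 100 replicates of 16-taxon, 300-site
families; mirror discrimination uses 100 replicates of 500-site pairs
with 199 permutations, plus 50 null pairs. These sizes were chosen so
the complete suite exercises every claim at simulation scale on a single
CPU in a few minutes.

# Limitations

* The synthetic residues are geometric stand-ins, not rotamer-accurate
  side chains; passing tests demonstrate the correctness and calibration
  machinery of the method, not its accuracy on any particular real coat
  structure. Real-data runs should supply real PDB files, the published
  reference-area table, and, if available, externally computed
  conservation grades and distance matrices.
* The C-alpha cutoff calibration assumes the training corpus and the
  target structures share atom radii, probe, and bead conventions.
  Cutoff tables therefore record their provenance and should not be
  mixed across conventions.
* The conservation surrogate ignores phylogeny within the alignment
  (beyond sequence weighting); families with extreme taxon sampling
  bias will be scored less reliably than by rate-inference methods.
* Alignments are assumed given; no aligner is bundled. Simulated
  alignments are gapless, so gap handling is exercised only by masked
  columns in the unit tests.
* Interface comparison operates on author residue numbering; structures
  that renumber residues between models must be reconciled upstream.
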