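---
title: "Counting amino-acid pairs in eight dimensions: model and methods"
author: "PairSpace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting amino-acid pairs in eight dimensions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PairSpace)
```

## The model

PairSpace treats a folded protein chain as a population of pairwise
residue interactions and asks where, statistically, those interactions
live. Every unordered pair of residues in the same chain is tested
against two criteria:

* the minimum Euclidean distance between the residues' *functional
  atoms* — the designated side-chain tip atoms (Lys NZ, Ser OG, Gly CA,
  two atoms for the chemically symmetric tips such as Val CG1/CG2; see
  `functionalAtomTable()`) — is below 8.25 Å, and
* both residues fall in the same relative solvent-accessibility (SA)
  bin, i.e. they occupy the same solvent shell.

A qualifying pair is described by eight coordinates: the two residue
types (AA1, AA2), the shared SA bin, the binned functional-atom
distance D, the two secondary-structure categories (SS1, SS2 in
{helix, strand, turn, coil}), the binned length CL of the validated
chain, and the binned sequence separation SD. The discretization
(`defaultBinScheme()`) is 20 x 20 x 12 x 14 x 4 x 4 x 12 x 6 =
77,414,400 cells; all numeric bins are left-open right-closed, with
the extreme bins absorbing out-of-range values (SA may legitimately
exceed 100 %). Each detected pair increments one (or two, see below)
cells of a sparse count tensor; the dense tensor is never
materialized.

The central empirical object is the *rank-frequency table* of the
occupied cells: for each population size R ("rank"), omega(R) is the
number of cells holding exactly R pairs. A scale-free organisation
shows up as an approximately straight line of log2 omega(R) against
log2 R with slope -lambda. `fitPowerLaw()` estimates that slope by
ordinary least squares with one unweighted point per distinct rank,
and reports a 95 % t-interval, the absolute Pearson correlation |r| of
the log-log points (the conventional closer-to-1-is-better figure of
merit for these fits) and the residual RMSE in log2 units.
`subspaceScan()` repeats projection, tabulation and fit over families
of dimension subsets (by default the 64 subsets containing AA1 and
AA2) to locate the smallest sub-space that retains the scale-free
signature.

Significance of individual cells is assessed against a
composition-preserving null: `shuffleLabels()` permutes the
residue-type labels of a chain uniformly while leaving coordinates,
SA, and secondary structure at their positions, `buildReference()`
re-runs the full pair pipeline on every shuffled chain and averages
the tensors of (by default) 10 repetitions, and `ratioMap()` divides
observed by expected cell-wise. Cells observed in the real corpus but
never produced by the null have no finite ratio and are flagged
infinite; they are the strongest signals.

## Insertion modes

A pair of types A and B can be stored once or in both orientations.
The default `symmetric` mode increments both (A,B,...,SS1,SS2,...) and
the swapped (B,A,...,SS2,SS1,...) cell, so the tensor is invariant
under the simultaneous AA/SS swap and the total equals twice the
number of observations; mirrored type pairs then show equal counts, as
a symmetric contact relation should. The `canonical` mode stores a
single increment in the cell with AA1 <= AA2 (ties broken by SS1 <=
SS2), so the total equals the observation count. Both modes are
first-class and recorded in the tensor header; all conservation
identities are stated relative to the mode multiplier.

## Validation rules

`mergeAndValidate()` joins a coordinate file (ATOM records only,
first alternate location, first model) with a per-residue annotation
table keyed by (structure, chain, author number, insertion code). A
residue survives only if it has a C-alpha, every functional atom its
type prescribes, an annotation row, and a finite SA. The residue type
of the annotation wins over the coordinate record on conflict (the
annotation is the curated source), with a log entry. Sequence
positions used for the SD dimension are ordinal positions among the
*validated* residues (author numbering has gaps and insertions), and
the chain length entering CL is counted after discarding. Discards are
tallied per reason so corpus reports can reconcile input and output
residue counts exactly.

Secondary-structure codes are mapped through an explicit table,
default H to helix, E to strand, T to turn and everything else (G, I,
B, S, C, blank) to coil; the four target categories do not uniquely
partition the DSSP/HSSP code alphabet, so the mapping is a
configuration item rather than a constant.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| distance cut-off | 8.25 (strict `<`) | Å | upper edge of the last distance bin; 4–5 Å is a typical side-chain contact, the longer tail keeps second-shell contacts |
| SA bins | <=0, 10-wide to 100, >100 | % | relative accessibility; >100 occurs for reference-state artefacts, <=0 for fully buried reports |
| rank threshold for "highly populated" | 50 | pairs/cell | the threshold at which hydrophobic-core enrichment is read out; exposed as a flag everywhere |
| `nReps` (reference) | 10 | – | shuffling repetitions averaged into the null |
| fit range `rMin`/`rMax` | all observed ranks | rank | the per-residue curves conventionally restrict to rank 1:300; exposed for that reason |
| insertion mode | symmetric | – | see above |

## The synthetic corpus

Because the pipeline's statistical claims must be testable without
downloading structure databases, `generateCorpus()` builds corpora
with known structure. Each chain is a self-avoiding C-alpha walk with
~3.8 Å steps: idealized alpha-helical segments (1.5 Å rise, 100°
twist, 2.3 Å radius) and extended strands (3.3 Å rise, 0.9 Å zigzag)
at random orientations, joined by centroid-attracted random coil/turn
steps with a 3.0 Å C-alpha exclusion radius. When a rigid segment
orientation cannot be placed without a clash the generator advances
residue-by-residue with flexible steps, and as a last resort rebuilds
the chain from a derived sub-seed; generation is deterministic given
the seed. Segment categories and lengths follow a simple segment model
(mean lengths 10/6/3/6 for helix/strand/turn/coil). Residue types are
drawn from a natural composition (Leu, Ala, Glu among the most
frequent); inside helix and strand segments the hydrophobic types
(Ala, Ile, Leu, Val, Phe, Met) are enriched by a factor 1.8, and those
types are buried (SA in (0,10]) with probability 0.65 against 0.30 for
the rest — a deliberately crude analogue of the hydrophobic core.
Functional atoms are pseudo-atoms at fixed per-type offsets from the
C-alpha in random directions (two for two-atom types). Chain lengths
are uniform on a configurable range with the 40-residue minimum of the
reference corpus design.

What the generator does *not* emulate: real rotamer geometry, backbone
dihedral statistics, hydrogen-bond-driven sheet pairing, chain-chain
interfaces, or any correlation between SA and the actual depth of a
residue in the walk. Passing tests on synthetic corpora therefore
demonstrate the *counting, binning, conservation and inference
machinery* — not that any particular biological number is reproduced.
Quantities that depend on the corpus (fitted slopes, cell occupancy,
enrichment fractions) are reported for the synthetic conditions and
will differ from values obtained on curated structure sets, whose
reproduction requires the full corpus of structures plus annotations.

## Numerical choices

* **Bin boundaries.** The `(lower, upper]` convention is taken
  literally from the bin notation; the distance criterion is a strict
  `< 8.25`, consistent with the last bin (7.75, 8.25].
* **Minimum-distance rule.** For residue types with two functional
  atoms the pair distance is the minimum over all atom combinations —
  the natural, symmetric contact criterion.
* **Fit construction.** One point per distinct rank, unweighted,
  base-2 logarithms. Ranks with omega = 0 cannot enter (log of zero),
  which censors the sparse tail: once the expected omega(R) drops
  below 1, present ranks appear only as isolated omega = 1 points
  that sit far above the power-law line and drag a full-range OLS
  slope towards zero. For exponent-recovery studies the fit is
  therefore restricted to the contiguous head of the rank table
  (`contiguousRankMax()`), the largest R with all ranks 1..R
  populated; with that restriction the generator's exponents 1.5,
  2.3 and 3.0 are recovered within 0.15 in >=90 % of seeds at 1e5
  cells. The default fit range remains "all observed ranks" so that
  corpus-scale fits remain comparable with the conventional
  construction; both choices are exposed.
* **Reference averaging.** Averaged null counts are kept as exact
  floating means (never rounded); ratios use the unrounded mean.
  Sub-seeds for each (chain, repetition) are spawned from one master
  seed, so results are reproducible regardless of evaluation order.
* **Degenerate inputs.** Chains shorter than 2 residues produce no
  pairs; an empty observation set produces a valid all-zero tensor;
  fits refuse fewer than 3 distinct ranks with an informative error;
  a perfect fit yields a zero-width confidence interval; a
  zero-variance rank table reports |r| = 0.
* **Provenance strings.** Structure id + zero-padded 4-digit author
  number + chain id, twice. Author numbers above 9999 cannot be
  padded and are emitted unpadded with a warning.

## Design decisions taken where the design was open

* The label-permutation null keeps the geometry, SA and secondary
  structure of every position fixed and permutes only the residue-type
  labels within each chain. Re-deriving accessibility or secondary
  structure for a shuffled sequence would require re-solved
  structures; a positional null is the only option that needs no
  rebuilt coordinates, and it cleanly isolates "which type sits here"
  as the randomized quantity. Distances are always computed from the
  functional atoms observed at each position.
* Shuffling is within-chain, the finest unit consistent with
  same-chain pairing.
* In per-type and per-category rank curves, a cell whose two members
  share the type (or category) is counted once — the curves count
  cells, and counting twice would double-count a single cell.
* The per-residue marginal of a pair matrix is row + column sums with
  the diagonal counted once, so each observation involving a type
  contributes exactly the mode multiplier to that type's marginal.
* "Population above 50 (rank 50)" is read as >= 50, matching the
  `at_least` predicate; the threshold is a parameter, not a constant.
* The SD = 0 bin exists for format fidelity but is empty by
  construction, since self-pairs are excluded.
* Cumulative pair curves are reported per rank as C(R) = sum of
  R'·omega(R') over R' >= R, anchored at the tensor total.

## Problem sizes used in the shipped analyses

The test suite exercises corpora of up to 100 chains of 40–160
residues and ground-truth power-law tensors of 1e5 cells; the
acceptance script uses 150 chains of 60–300 residues, a 10-repetition
reference, and a 1e5-cell recovery tensor. These sizes give stable
statistics for every reported quantity while keeping a full run in the
tens of seconds on a single core.

## Known limitations

* Inter-chain pairs are out of scope by definition of the pair rule.
* Annotations (SA, secondary structure) are inputs; the package never
  computes them from coordinates.
* mmCIF files and NMR multi-model ensembles are not supported (first
  model only).
* The log-log OLS estimator is the conventional construction for this
  analysis, not a maximum-likelihood power-law test; no formal
  scale-free hypothesis test is performed.
* Which HSSP accessibility field represents percent SA, and how values
  above 100 % arise, is annotation-source dependent; any finite value
  is accepted and the SA > 100 bin absorbs the excess.
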