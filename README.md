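# PairSpace

Amino-acid pair interactions in folded proteins, counted in an
8-dimensional space.

## The problem

The packing of a protein is the cumulative result of pairwise
residue–residue interactions. PairSpace quantifies each interaction by
eight descriptors — the two residue types (AA1, AA2), the shared
relative solvent-accessibility shell (SA), the distance D between the
residues' side-chain *functional atoms* (e.g. Lys NZ, Ser OG, Val
CG1/CG2; full table in `functionalAtomTable()`), the two
secondary-structure categories (SS1, SS2), the chain length (CL) and
the sequence separation (SD) — and accumulates every detected pair
into a sparse count tensor of 20·20·12·14·4·4·12·6 = 77,414,400
cells. Two residues form a pair when they belong to the same chain,
sit in the same SA bin, and their minimum functional-atom distance is
below 8.25 Å.

The analysis centres on the rank-frequency behaviour of the occupied
cells. With ω(R) the number of cells whose population equals R, a
scale-free organisation

&nbsp;&nbsp;&nbsp;&nbsp;ω(R) ∝ R<sup>−λ</sup>

appears as a straight line of log₂ ω(R) against log₂ R with slope −λ.
The package fits that line (OLS, one point per distinct rank, 95% CI,
|Pearson r| and RMSE as goodness), scans all dimension subsets
containing AA1/AA2 for the smallest sub-space that retains the
signature, and assesses per-cell significance against a
composition-preserving null in which residue-type labels are shuffled
within each chain (geometry, SA and secondary structure stay put),
the pipeline re-run, and 10 repetitions averaged. Descriptive
summaries (pair matrices above a rank threshold, SA×distance
histograms, secondary-structure and per-residue rank profiles,
cumulative pair counts, composition vs pair participation) mirror the
standard read-outs of this analysis.

It is aimed at structural bioinformaticians who want contact
statistics beyond simple Cα distance cut-offs, and at anyone needing a
reproducible, fully testable implementation of the 8-D pair-count /
rank-frequency methodology — including a synthetic corpus generator so
every stage can be validated without downloading structure databases.

## Worked example

```r
library(PairSpace)

params <- corpusParams(nChains = 40, lengthRange = c(60, 140), seed = 71)
corpus <- generateCorpus(params)          # synthetic validated chains
tensor <- buildTensor(corpus)             # detect pairs, fill the tensor
tensor
#> PairTensor [symmetric] over (AA1,AA2,SA,D,SS1,SS2,CL,SD): 6992 non-zero cells, total 7744 (3872 observations)

fitPowerLaw(tensor)                       # log2-log2 rank-frequency fit
#> PowerLawFit: slope -4.309 (95% CI -5.916 .. -2.702), intercept 12.78, |r| 0.966, RMSE 1.010, n=6

ref    <- buildReference(corpus, nReps = 10, seed = 71)
ratios <- ratioMap(tensor, ref)
length(attr(ratios, "infiniteCells"))     # observed, never expected
#> [1] 3906

M <- pairMatrix(tensor, rankAtLeast(5))   # pairs in highly populated cells
sort(attr(M, "marginals"), decreasing = TRUE)[1:4]
#> ALA LEU ILE VAL
#>  28  28  12  12
```

Reading the output: the corpus yields 3,872 pair observations stored
symmetrically (7,744 insertions) in 6,992 cells. The rank-frequency
fit is steep (most cells hold one pair; a few hold many) with |r| =
0.966 over its 6 distinct ranks — small corpora give short rank
tables; the acceptance run below uses a larger one. 3,906 occupied
cells never occur in the 10-fold shuffled reference (infinite
observed/expected ratio), and the pairs in cells of population ≥ 5
are carried overwhelmingly by Ala, Leu, Ile and Val — the
hydrophobic-core enrichment the synthetic generator builds in.

Real structures enter through the same door: `readStructure()` (PDB
ATOM records), `readAnnotations()` (per-residue TSV or DSSP-style
HSSP lines carrying secondary structure and percent SA), then
`mergeAndValidate()`.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "pairspace.R", package = "PairSpace")` with
subcommands `simulate`, `build`, `reference`, `ratios`, `rank`,
`fit`, `scan`, `summaries`.

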