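---
title: "Methods: models, parameters and design choices in airtraffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in airtraffic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, and the places
where a design was genuinely open and a choice had to be pinned down.

## The trafficking model

The central question is whether B cells move between tissue sites in a
preferred direction. The data are clonal lineage trees: each clone's
unique sequences, related by somatic hypermutation (SHM), with the tissue
of origin known for every observed sequence.

**Ancestral tissue states.** `reconstructTissueStates()` assigns tissues
to internal nodes by Sankoff dynamic programming with unit transition
cost, i.e. it finds assignments that minimise the number of
tissue-switching events along the tree. The minimum cost is unique and,
for two tissues, coincides with the classic Fitch union/intersection
count (a property the test suite checks). Three choices deserve comment:

- *The germline root is unconstrained.* The founder cell's location is
  unobserved; constraining it would presuppose part of the answer.
- *Ties are resolved stochastically.* Several assignments usually attain
  the minimum. When states tie at a node, one is drawn uniformly at
  random and the directed transition-type counts are averaged over
  `R = 20` independent resolutions. Averaging over a fixed number of
  draws (rather than enumerating all minimum-cost reconstructions) keeps
  the cost per tree bounded; 20 draws makes the Monte-Carlo error in the
  count matrix small relative to between-tree variation.
- *Trees entering the test* need at least 3 observed tips spanning at
  least 2 tissues; smaller or single-tissue trees carry no directional
  information and are counted as 0-transition trees.

**The permutation null.** Tip tissue labels are permuted *within* each
tree, preserving both the topology and each tree's tissue composition.
This matches the scientific null — "tissues are interchangeable given
this clone's composition" — and protects against confounding by
clone-level composition differences. The per-direction statistic is
`count[a,b]/total` summed over trees, so large trees do not dominate by
their absolute transition counts. P-values use the plus-one correction
and therefore never reach zero; with `nPerm = 100` the smallest
attainable p is 1/101. The total-transition statistic (mean minimal
transitions per tree) is tested one-sided for being *smaller* than the
null: fewer transitions than random means sequences from the same tissue
cluster on the trees.

Analyses restricted to a tissue subset (e.g. nasal + bronchial only,
versus all compartments including blood) are run by building trees from
the correspondingly restricted record set, mirroring how such subset
analyses condition the data rather than the algorithm.

## Lineage trees

`buildTree()` collapses duplicate sequences per (tissue, isotype) into
single tips with multiplicities, adds the clone germline as an outgroup,
and searches for a maximum-parsimony topology. For clones with at most 7
tips (germline included) every unrooted topology is scored — at 7 tips
that is 945 trees — so the returned score is provably the global
minimum; larger clones use a neighbour-joining start tree refined by
nearest-neighbour-interchange hill climbing on the Fitch score. Branch
lengths are ACCTRAN-assigned nucleotide changes, so the parsimony score
equals the sum of branch lengths. Determinism is obtained by sorting
tips lexicographically and taking the first topology among score ties in
that fixed enumeration. Ambiguous bases (N) match any base; gap columns
are shared within a clone and contribute nothing.

Parsimony was chosen over maximum-likelihood trees because the
trafficking statistic is itself parsimony-based, and because exhaustive
verification (every small clone checked against brute-force enumeration)
is only tractable for a discrete score.

## QC filtering

`applyFilters()` removes records in a fixed order: PhiX flag,
constant-region mismatches, any sliding 10-nucleotide window with **more
than six** mismatches against the germline (exactly six is kept), single
contributing reads (`duplicate_count == 1`), and non-functional
sequences (internal stop codon, junction length not divisible by 3, or
`productive` false). The source filters are listed without an order; a
fixed order with first-triggering-rule attribution was chosen so that
reports are reproducible and satisfy the conservation identity
`input = kept + sum(removed)`. The window rule runs in alignment space
with gap positions skipped — the only frame in which "a 10-nucleotide
stretch" is well defined for gapped records. Unparseable records fall
under a separate `malformed` tally. Constant-region mismatches are
consumed as a precomputed integer column; primer-level matching is out
of scope.

## Clonal inference

Records are partitioned by subject, V gene, J gene (allele suffixes
stripped; ambiguous calls take the first listed gene) and junction
length; within a partition, sequences are linked when the normalized
Hamming distance between junctions is **at most** `t` (the boundary is
inclusive — the source does not state it, so it is pinned here), and
clones are the connected components. Clustering is per subject only.
`chooseThreshold()` implements the standard distance-to-nearest
heuristic: the distances from each unique junction to its nearest
non-identical neighbour are typically bimodal (clonal relatives near 0,
unrelated junctions far away); the threshold is the minimum-density
valley between the two dominant modes of a kernel density estimate
(bandwidth 0.02 on the [0,1] distance scale). If fewer than 100 records
are available or no valley exists, a default of 0.15 is returned with a
warning.

## Diversity

Hill numbers `^qD = (sum p_i^q)^(1/(1-q))` unify richness (q = 0), the
exponential of Shannon entropy (q = 1, reported as the Shannon
diversity) and the inverse Simpson index (q = 2). Abundances are unique
sequences per clone, matching the clone-level framing of repertoire
expansion. Because richness-like quantities are strongly
depth-dependent, profiles are computed on `B = 200` subsamples drawn
without replacement at a common depth `m` (default: the minimum depth of
the samples being compared) and summarised by mean and 2.5/97.5
percentiles. Rarefaction curves report expected unique-clone counts over
a depth grid. Between-group comparisons of any diversity value use the
two-tailed Wilcoxon rank-sum test across individuals.

## Selection strength

For each sequence, mutated codons within IMGT positions 1–104 (FWR1
1–26, CDR1 27–38, FWR2 39–55, CDR2 56–65, FWR3 66–104; CDR3/FWR4
excluded) are classified replacement (R) or silent (S); codons with
several mutations average the R/S attribution over all mutation orders.
The no-selection expectation `p_r` is computed by enumerating every
single-nucleotide substitution in the region's germline codons,
excluding stop-creating changes, under a uniform mutation model (an
optional WRC/GYW hot-spot weighting is available; the published
targeting tables are external resources and are not bundled).

Selection strength Sigma shifts the replacement probability to
`pi(Sigma) = p_r e^Sigma / (p_r e^Sigma + 1 - p_r)`; each sequence
contributes a Binomial(R + S, pi(Sigma)) likelihood. The group-level
posterior multiplies these likelihoods under a flat prior on the grid
(default −8 to 8, step 0.02), i.e. it treats Sigma as shared within the
group. This was a genuinely open design point: aggregating per-sequence
posteriors by averaging produces a mixture whose width never shrinks
with group size, and aggregating by convolution (the density of the mean
per-sequence Sigma) inherits the heavy tails and bias of flat-prior
per-sequence posteriors under the nonlinear `pi(Sigma)` map — neither
yields credible intervals with near-nominal frequentist coverage under
the model, while the shared-Sigma product does (the test suite checks
coverage directly by simulation). Group-vs-group comparisons use
`p = 2 min(P(Sigma_A > Sigma_B), P(Sigma_B > Sigma_A))` evaluated
numerically from the two independent group densities, with ties split
evenly. This implementation targets recovery of planted selection on
simulated data, not numeric identity with any particular published
implementation.

The per-position amino-acid preference analysis (`pwmAnalysis`) compares
residue frequencies between a target and a background group for IGHV
genes used by more than 2.5% of sequences in at least three individuals
(strict inequality, so exactly 2.5% is excluded). Scores are
`log2((f_t + 0.01)/(f_b + 0.01))`; per-position significance comes from
Fisher's exact test on the residue-count table with Benjamini–Hochberg
correction across positions; positions with fewer than 10 observations
in either group are masked.

## CDR3 properties

The CDR3 is the junction minus its two anchor residues (a convention
stated explicitly because it changes lengths by exactly 2). The eight
properties — length, GRAVY (Kyte–Doolittle mean hydropathy), aliphatic
index (Ikai, coefficients Ala 1, Val 2.9, Ile/Leu 3.9), aromatic
fraction (F, W, Y, H), net side-chain charge at pH 7.4
(Henderson–Hasselbalch with a standard side-chain pKa set), acidic
fraction (D, E), basic fraction (K, R, H) and mean Grantham polarity —
follow the standard repertoire-analysis property set; the source defers
its exact list to supplementary material, so the set is pinned here and
the constants ship as a plain-text table (`inst/extdata/
aa_properties.tsv`). PCA operates on z-scored properties with a
deterministic sign convention (largest-magnitude loading positive).
Junctions containing ambiguous residues are excluded from the PCA.
Hierarchical clustering of gene-usage profiles is pinned to correlation
distance with average linkage.

## The simulator: what it emulates, and what it does not

`simulateRepertoire()` exists to make every downstream stage testable
against a known truth. Its generative choices are deliberately simple:

- **Clone growth** is uniform sequential attachment (each new node picks
  a uniform parent among the existing nodes of its clone) — a Yule-like
  model whose simplicity makes oracles easy; clone sizes follow a
  bounded power law (default exponent 2.0, maximum 60).
- **Tissues** evolve along branches under a row-stochastic trafficking
  matrix. The default plants a nasal-to-bronchial bias (NBx row: 0.75
  stay, 0.20 to BBx, 0.05 to blood; BBx row: 0.90 stay, 0.04 back)
  with blood reachable from every compartment, emulating the airway
  scenario of mucosal trafficking partially via circulation.
- **Isotypes** start at IgM (configurable) and switch only 3'-ward in
  the IGHC locus order IGHM, IGHD, IGHG3, IGHG1, IGHA1, IGHG2, IGHG4,
  IGHE, IGHA2 — class-switch recombination deletes intervening DNA and
  is irreversible. Default switch weights make switched IgA dominate,
  as in airway mucosa.
- **SHM** is uniform per-site substitution at `shmRate` per branch
  (default 0.01, i.e. roughly 1–4% mutation at the tips of typical
  clones at desk scale); an optional hot-spot mode is available for the
  `p_r` enumeration but the simulator itself stays uniform — sufficient
  for every oracle that consumes it. Substitutions that would create a
  stop codon or a >6-mismatch 10-nt window are redrawn, so emitted
  records violate QC rules only where `plantQcViolations()` planted
  them; that is what makes exact filter accounting testable.
- **IgD-only clones** (default 6% of clones) are planted with pure IGHD
  isotype, SHM multiplied by 2.2, CDR3 lengths shifted +4 amino acids
  and IGHJ6 usage raised to 50% versus a 23% background.
- **Germlines** are synthetic V/J segments bundled as
  `inst/extdata/synthetic_germlines.fasta` (not derived from licensed
  reference directories): V genes occupy IMGT codons 1–104 (312
  alignment columns, dots filling unoccupied CDR1/CDR2 codons, conserved
  Cys23/Trp41/Cys104), the junction starts at the 2nd-CYS codon and ends
  at the J-encoded Trp, and a 12-nt FR4 tail follows. All region
  arithmetic in the package relies on this fixed convention.

The default cohort is two groups of five subjects with 200 clones per
subject (roughly 550 records per subject). That depth is the smallest at
which the per-individual analyses behave like they do on real data — in
particular, most subjects then clear the 20-IgD-only-sequence
eligibility rule used for IgD-only contrasts — while keeping a full
pipeline run to well under a minute per seed on one core.

What the simulator does **not** emulate: insertions/deletions in SHM,
light chains, read-level errors and UMI consensus building (records
enter at the rearrangement level; read artifacts appear only as planted
flags/fields), context-dependent SHM targeting, affinity-driven
selection, and subject-level covariates beyond the group label. Passing
tests therefore demonstrate that the statistics recover structure the
generative model plants — directional trafficking, diversity contrasts,
selection strength, IgD-only features — not that any particular
biological dataset will show these effects.

## Numerical and degenerate-input conventions

- Junction distances are normalized Hamming (junctions of unequal length
  never meet, by the length partition).
- The clustering threshold comparison is inclusive (`<= t`).
- `hillNumber` requires probability vectors within 1e-9 of summing to 1
  and evaluates q = 1 as the exact Shannon limit (no numeric limit
  taking).
- Selection densities are normalized to integrate to 1 within 1e-6 on
  their grid (enforced by the class validity method); sequences with
  R + S = 0 are skipped and an all-zero group returns a flat density
  flagged uninformative.
- Filter reports always satisfy `input = output + sum(removed)`
  (class-validity enforced), and filtering is idempotent.
- Mutation frequencies are undefined (NA, with a warning) when no
  comparable positions exist.
- Wilcoxon comparisons on all-tied input return p = 1 with a warning.
- All seeded operations restore the caller's RNG state.

## Known limitations

- The trafficking test conditions on inferred trees and clone
  assignments; errors in either propagate. The test suite bounds this
  risk (exact parsimony for small clones, clustering validated against
  ground truth) but cannot eliminate it for large clones where NNI hill
  climbing may return a local optimum.
- Tie-averaging over 20 random resolutions approximates the average over
  all equally parsimonious reconstructions rather than enumerating them.
- The selection model ignores SHM targeting biases unless the hot-spot
  mode is enabled, and its flat prior on a bounded grid truncates
  extreme selection strengths at |Sigma| = 8.
- The automatic clustering threshold assumes a bimodal
  distance-to-nearest distribution; heavily expanded or very sparse
  repertoires may trigger the default fallback.
- Sequence-level overlap requires exact nucleotide identity, so it is
  sensitive to residual sequencing error in real data.
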