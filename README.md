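# airtraffic

B-cell receptor repertoire analysis of lymphocyte trafficking between
tissue sites, built for AIRR-seq studies that sample the same subject at
several locations — for example nasal mucosa (`NBx`), bronchial mucosa
(`BBx`) and peripheral blood (`PBMC`). The package is aimed at
immunologists and computational biologists who want to go from AIRR
Rearrangement tables to statements like *"B cells traffic preferentially
from the upper to the lower airway"* with a defensible null model.

## What it does

The core method is **maximum-parsimony tissue phylogeography with a
within-tree permutation null**. For each B-cell clone a lineage tree is
built over its unique sequences, rooted at the inferred germline. Given
the tissue label of every observed sequence, ancestral tissue states are
assigned by Sankoff parsimony with unit transition cost, so each tree
yields its minimal number of trafficking events and a directed count
matrix `count[a, b]` of tissue transitions (ties among equally
parsimonious states are resolved uniformly at random and averaged over
`R` draws). The per-direction statistic

```
S(a -> b) = sum over trees of count[a, b] / total transitions in the tree
```

is compared against the same statistic on trees whose tip tissue labels
are permuted *within each tree* (preserving every tree's label multiset
and topology). One-sided p-values use the plus-one correction
`(1 + #{null >= observed}) / (N + 1)`; a separate one-sided statistic
tests whether the *total* number of transitions is smaller than random,
i.e. whether same-tissue sequences cluster on the trees.

Around this core the package provides the full analysis pipeline:

- **AIRR I/O and QC filtering** (`readAirr`, `writeAirr`, `applyFilters`)
  with exact accounting: PhiX flags, constant-region mismatches, more
  than six mismatches in any 10-nucleotide stretch, single contributing
  reads, and non-functional sequences.
- **Clonal inference** (`assignClones`, `chooseThreshold`): V/J/junction
  length partition, then single-linkage clustering of junctions under
  normalized Hamming distance, with an automatic distance-to-nearest
  threshold.
- **Lineage trees** (`buildTree`): Fitch-parsimony topology search
  (exhaustive for small clones), germline outgroup rooting, ACCTRAN
  branch lengths in nucleotide changes.
- **Diversity** (`hillNumber`, `resampledProfile`, `rarefactionCurve`):
  Hill-number profiles with subsampling to common depth.
- **Selection** (`countRsMutations`, `selectionPosterior`,
  `pwmAnalysis`): replacement/silent partitioning by IMGT region, a
  BASELINe-style posterior over selection strength Sigma, and positional
  amino-acid preference matrices.
- **Repertoire features** (`isotypeFrequencies`, `cloneOverlap`,
  `globalPartition`, `classifyIgdOnly`, `cdr3Properties`, `geneUsage`,
  `compareGroups`): isotype and gene usage, clone overlap/Venn counts,
  global vs tissue-restricted clones, IgD-only classification, and eight
  physicochemical CDR3 properties with PCA.
- **A seeded simulator** (`simulationConfig`, `simulateRepertoire`,
  `plantQcViolations`): multi-subject, multi-tissue repertoires with
  known clone memberships, true lineage trees, a configurable directional
  trafficking bias, locus-order-constrained isotype switching, an
  IgD-only subpopulation and plantable QC artifacts — so every stage is
  testable without external data.
- **One-call orchestration** (`pipelineConfig`, `runPipeline`): the whole
  chain with a single global seed and a machine-readable JSON report.

## Worked example

```r
library(airtraffic)

cfg <- simulationConfig(seed = 42, nSubjects = 2, nClonesPerSubject = 120)
sim <- simulateRepertoire(cfg)

flt <- applyFilters(sim$records)
rec <- assignClones(flt$kept, threshold = "auto")

tis <- rec[grepl("^[NB]Bx", rec$tissue), ]   # nasal + bronchial analysis
keep <- names(which(
  tapply(tis$tissue, tis$clone_id, function(x) length(unique(x))) >= 2 &
  tapply(tis$sequence_id, tis$clone_id, length) >= 3))
trees <- buildTrees(tis, cloneIds = keep)

set.seed(1)
permutationTest(trees, nPerm = 100)
```

```
EnrichmentResult: 21 trees, 100 permutations
  mean transitions/tree: observed 1.52, null 2.04 (p = 0.009901)
  BBx -> NBx: obs 10.442, null 12.412, p = 1
  NBx -> BBx: obs 10.558, null 8.588, p = 0.009901
```

Reading the output: across the 21 multi-tissue clonal trees, sequences
from the same tissue sit closer on the trees than permuted labels allow
(1.52 observed transitions per tree versus 2.04 under the null,
p = 0.0099), and the nasal-to-bronchial direction is significantly
enriched (p = 0.0099) while the reverse direction is not (p = 1) — the
simulator's default trafficking matrix plants exactly this asymmetry, and
the test recovers it.

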