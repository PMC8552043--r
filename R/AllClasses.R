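#' Simulation configuration for synthetic multi-tissue repertoires
#'
#' Holds every parameter of the repertoire simulator. Build one with
#' [simulationConfig()], which supplies defaults emulating a two-group,
#' multi-tissue airway cohort; the validity method enforces that the
#' trafficking matrix is row-stochastic and that all probabilities lie in
#' \[0, 1\].
#'
#' @slot seed integer; fully determines the simulator output.
#' @slot nSubjects integer number of subjects.
#' @slot groups character vector of per-subject group labels (length
#'   `nSubjects`), e.g. `"AA"` / `"NANA"`.
#' @slot tissues character vector of tissue site labels. Labels beginning
#'   `NBx` are treated as nasal, `BBx` as bronchial, `PBMC` as blood.
#' @slot nClonesPerSubject integer clones per subject.
#' @slot cloneSizeExponent,cloneSizeMax power-law exponent and maximum of the
#'   clone-size distribution.
#' @slot shmRate expected per-nucleotide substitution probability per branch.
#' @slot traffickingMatrix row-stochastic matrix `T[a, b]`: probability that
#'   a child node in tissue `a` resides in tissue `b`.
#' @slot rootTissueProbs probability vector over tissues for clone founders.
#' @slot rootIsotypeProbs probability vector over IGHC segments for founder
#'   isotypes.
#' @slot switchProb per-branch probability of a class-switch event.
#' @slot isotypeWeights relative weights over IGHC segments used to choose a
#'   switch target among segments 3' of the current one.
#' @slot igdOnlyFraction fraction of clones planted as IgD-only.
#' @slot igdOnlyShmMultiplier multiplier on `shmRate` for IgD-only clones.
#' @slot ighjUsage,ighjUsageIgd probability vectors over IGHJ1..IGHJ6 for
#'   background and IgD-only clones.
#' @slot cdr3LengthMeanAa,cdr3LengthSdAa,igdCdr3LengthBonusAa CDR3
#'   amino-acid length model (normal, rounded), with an additive mean shift
#'   for IgD-only clones.
#' @slot readArtifactRates named rates for [plantQcViolations()]
#'   (`phix`, `c_region`, `window`, `singleton`, `stop`).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer", nSubjects = "integer", groups = "character",
    tissues = "character", nClonesPerSubject = "integer",
    cloneSizeExponent = "numeric", cloneSizeMax = "integer",
    shmRate = "numeric", traffickingMatrix = "matrix",
    rootTissueProbs = "numeric", rootIsotypeProbs = "numeric",
    switchProb = "numeric", isotypeWeights = "numeric",
    igdOnlyFraction = "numeric", igdOnlyShmMultiplier = "numeric",
    ighjUsage = "numeric", ighjUsageIgd = "numeric",
    cdr3LengthMeanAa = "numeric", cdr3LengthSdAa = "numeric",
    igdCdr3LengthBonusAa = "numeric", readArtifactRates = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  tm <- object@traffickingMatrix
  if (!all(dim(tm) == length(object@tissues)))
    msg <- c(msg, "traffickingMatrix must be square over tissues")
  else {
    if (any(abs(rowSums(tm) - 1) > 1e-12))
      msg <- c(msg, "traffickingMatrix rows must sum to 1 (tolerance 1e-12)")
    if (any(tm < 0 | tm > 1))
      msg <- c(msg, "traffickingMatrix entries must be probabilities")
  }
  probs <- c(object@rootTissueProbs, object@rootIsotypeProbs,
             object@ighjUsage, object@ighjUsageIgd, object@switchProb,
             object@igdOnlyFraction, object@readArtifactRates)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
  if (object@shmRate < 0 || object@shmRate > 1)
    msg <- c(msg, "shmRate must be in [0, 1]")
  if (length(object@groups) != object@nSubjects)
    msg <- c(msg, "groups must have one label per subject")
  if (length(msg)) msg else TRUE
})

#' Quality-control filter report
#'
#' Accounting of [applyFilters()]: per-rule removal counts with
#' first-triggering-rule attribution, so that
#' `input == output + sum(removed)` always holds (enforced by validity).
#'
#' @slot input,output integer record counts before/after filtering.
#' @slot removed named integer vector of per-rule removal counts, in filter
#'   order (see [filterRules()]).
#' @exportClass FilterReport
setClass("FilterReport",
  representation(input = "integer", output = "integer", removed = "integer"))

setValidity("FilterReport", function(object) {
  if (object@input != object@output + sum(object@removed))
    "input must equal output + sum(removed)" else TRUE
})

#' Germline-rooted clonal lineage tree
#'
#' A maximum-parsimony lineage tree over the unique sequences of one clone.
#' The underlying `ape::phylo` keeps the inferred germline as a tip
#' (`germlineLabel(x)`) on whose pendant edge the root is placed; edge
#' lengths are parsimony-assigned nucleotide changes, and
#' `parsimonyScore(x)` equals their sum.
#'
#' @slot phylo rooted `ape::phylo` tree.
#' @slot germline tip label of the germline.
#' @slot tipData data.frame with one row per non-germline tip: `label`,
#'   `tissue`, `isotype`, `multiplicity`, `sequence_ids`.
#' @slot score Fitch parsimony score (total nucleotide changes).
#' @slot cloneId clone identifier.
#' @exportClass LineageTree
setClass("LineageTree",
  representation(phylo = "ANY", germline = "character",
                 tipData = "data.frame", score = "numeric",
                 cloneId = "character"))

#' Directional trafficking enrichment result
#'
#' Result of the maximum-parsimony phylogeography permutation test: observed
#' per-direction transition proportions, their permutation null, and
#' plus-one-corrected p-values, together with the total-transition
#' (tissue clustering) statistic.
#'
#' @slot tissues tissue labels indexing the matrices.
#' @slot observedCounts summed tissue-transition counts over trees (averaged
#'   over tie resolutions).
#' @slot observedProp observed per-direction statistic: `count[a,b]/total`
#'   summed over trees.
#' @slot nullProp matrix (`nPerm` x directions) of the same statistic under
#'   within-tree label permutation.
#' @slot pvalues matrix of one-sided p-values per direction (greater-than-null).
#' @slot observedTotalMean,nullTotalMean observed mean transitions per tree
#'   and its permutation null (length `nPerm`).
#' @slot pTotal one-sided p-value for fewer-than-random total transitions.
#' @slot nTrees,nPerm numbers of trees and permutations used.
#' @slot testable FALSE when no multi-tissue tree was available.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(tissues = "character", observedCounts = "matrix",
                 observedProp = "matrix", nullProp = "matrix",
                 pvalues = "matrix", observedTotalMean = "numeric",
                 nullTotalMean = "numeric", pTotal = "numeric",
                 nTrees = "integer", nPerm = "integer", testable = "logical"))

#' Hill-number diversity profile
#'
#' Mean and percentile confidence band of the Hill diversity \eqn{^qD} over
#' a grid of orders q, computed from repeated subsampling to a common depth.
#'
#' @slot q grid of diversity orders.
#' @slot mean,lo,hi per-order mean and 2.5/97.5 percentile bounds over
#'   resamples.
#' @slot depth common subsampling depth m.
#' @slot resamples number of resamples B.
#' @slot sample sample label.
#' @exportClass DiversityProfile
setClass("DiversityProfile",
  representation(q = "numeric", mean = "numeric", lo = "numeric",
                 hi = "numeric", depth = "integer", resamples = "integer",
                 sample = "character"))

setValidity("DiversityProfile", function(object) {
  n <- length(object@q)
  if (length(object@mean) != n || length(object@lo) != n || length(object@hi) != n)
    "q, mean, lo, hi must have equal length" else TRUE
})

#' Posterior density of selection strength
#'
#' Discretised posterior over the selection strength Sigma for one region
#' (CDR or FWR) and one sequence group, from the binomial
#' replacement/silent model. The density is normalised to integrate to 1 on
#' the grid.
#'
#' @slot grid Sigma grid values.
#' @slot density posterior density on the grid.
#' @slot region,group labels.
#' @slot nSeq number of informative sequences combined.
#' @slot informative FALSE when every sequence had R + S = 0 (flat posterior).
#' @exportClass SelectionPosterior
setClass("SelectionPosterior",
  representation(grid = "numeric", density = "numeric", region = "character",
                 group = "character", nSeq = "integer",
                 informative = "logical"))

setValidity("SelectionPosterior", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid and density lengths differ")
  step <- diff(object@grid[1:2])
  if (abs(sum(object@density) * step - 1) > 1e-6)
    return("density must integrate to 1 (tolerance 1e-6)")
  TRUE
})

#' Positional amino-acid preference matrix
#'
#' Per-IMGT-position amino-acid frequencies of a target versus a background
#' sequence group for one IGHV gene, with signed log2 preference scores and
#' per-position Fisher-test significance (Benjamini-Hochberg corrected
#' across positions).
#'
#' @slot gene IGHV gene.
#' @slot positions IMGT codon positions (1..104) carried by the matrices.
#' @slot target,background 20 x positions frequency matrices (columns sum to
#'   1 over observed residues; NA when masked).
#' @slot score signed log2((f_target+eps)/(f_background+eps)) matrix.
#' @slot pvalue,padj per-position Fisher p-values and BH-adjusted values.
#' @slot significant,masked per-position flags; positions with fewer than
#'   the minimum observations in either group are masked.
#' @slot groups the two group labels (target, background).
#' @exportClass PositionWeightMatrix
setClass("PositionWeightMatrix",
  representation(gene = "character", positions = "integer",
                 target = "matrix", background = "matrix", score = "matrix",
                 pvalue = "numeric", padj = "numeric",
                 significant = "logical", masked = "logical",
                 groups = "character"))
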