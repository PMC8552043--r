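# Generics, accessors and show methods.

#' @describeIn LineageTree-class Fitch parsimony score (total nucleotide
#'   changes; equals the sum of edge lengths).
#' @param x,object an object.
#' @export
setGeneric("parsimonyScore", function(x) standardGeneric("parsimonyScore"))
#' @export
setMethod("parsimonyScore", "LineageTree", function(x) x@score)

#' @describeIn LineageTree-class per-tip metadata (tissue, isotype,
#'   multiplicity).
#' @export
setGeneric("tipData", function(x) standardGeneric("tipData"))
#' @export
setMethod("tipData", "LineageTree", function(x) x@tipData)

#' @describeIn LineageTree-class the germline tip label.
#' @export
setGeneric("germlineLabel", function(x) standardGeneric("germlineLabel"))
#' @export
setMethod("germlineLabel", "LineageTree", function(x) x@germline)

#' @describeIn LineageTree-class underlying `ape::phylo` object.
#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))
#' @export
setMethod("treePhylo", "LineageTree", function(x) x@phylo)

setMethod("show", "LineageTree", function(object) {
  cat(sprintf("LineageTree '%s': %d tips + germline, parsimony score %g\n",
              object@cloneId, nrow(object@tipData), object@score))
  tis <- table(object@tipData$tissue)
  cat("  tissues:", paste(sprintf("%s=%d", names(tis), tis), collapse = ", "), "\n")
})

#' @describeIn EnrichmentResult-class matrix of one-sided per-direction
#'   p-values (rows: source tissue, columns: destination).
#' @export
setGeneric("transitionPvalues", function(x) standardGeneric("transitionPvalues"))
#' @export
setMethod("transitionPvalues", "EnrichmentResult", function(x) x@pvalues)

#' @describeIn EnrichmentResult-class observed per-direction proportion
#'   statistic.
#' @export
setGeneric("observedProportions", function(x) standardGeneric("observedProportions"))
#' @export
setMethod("observedProportions", "EnrichmentResult", function(x) x@observedProp)

#' @describeIn EnrichmentResult-class one-sided p-value for fewer total
#'   transitions than the permutation null (tissue clustering).
#' @export
setGeneric("totalTransitionP", function(x) standardGeneric("totalTransitionP"))
#' @export
setMethod("totalTransitionP", "EnrichmentResult", function(x) x@pTotal)

setMethod("show", "EnrichmentResult", function(object) {
  if (!object@testable) {
    cat("EnrichmentResult: untestable (no multi-tissue tree)\n")
    return(invisible(NULL))
  }
  cat(sprintf("EnrichmentResult: %d trees, %d permutations\n",
              object@nTrees, object@nPerm))
  cat(sprintf("  mean transitions/tree: observed %.2f, null %.2f (p = %.4g)\n",
              object@observedTotalMean, mean(object@nullTotalMean),
              object@pTotal))
  s <- object@tissues
  for (a in s) for (b in s) if (a != b)
    cat(sprintf("  %s -> %s: obs %.3f, null %.3f, p = %.4g\n", a, b,
                object@observedProp[a, b],
                mean(object@nullProp[, paste(a, b, sep = "->")]),
                object@pvalues[a, b]))
})

#' @describeIn SelectionPosterior-class grid value with maximal posterior
#'   density.
#' @export
setGeneric("posteriorMode", function(x) standardGeneric("posteriorMode"))
#' @export
setMethod("posteriorMode", "SelectionPosterior",
          function(x) x@grid[which.max(x@density)])

#' @describeIn SelectionPosterior-class posterior mean of Sigma.
#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))
#' @export
setMethod("posteriorMean", "SelectionPosterior", function(x) {
  step <- diff(x@grid[1:2])
  sum(x@grid * x@density) * step
})

#' @describeIn SelectionPosterior-class central credible interval at the
#'   given level.
#' @param level credible level (default 0.95).
#' @export
setGeneric("credibleInterval",
           function(x, level = 0.95) standardGeneric("credibleInterval"))
#' @export
setMethod("credibleInterval", "SelectionPosterior", function(x, level = 0.95) {
  step <- diff(x@grid[1:2])
  cdf <- cumsum(x@density) * step
  a <- (1 - level) / 2
  c(lower = x@grid[which(cdf >= a)[1]],
    upper = x@grid[which(cdf >= 1 - a)[1]])
})

setMethod("show", "SelectionPosterior", function(object) {
  ci <- credibleInterval(object)
  cat(sprintf(
    "SelectionPosterior [%s, %s]: n = %d, mode %.3f, mean %.3f, 95%% CI [%.3f, %.3f]%s\n",
    object@group, object@region, object@nSeq, posteriorMode(object),
    posteriorMean(object), ci[1], ci[2],
    if (object@informative) "" else " (uninformative)"))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: seed %d, %d subjects (%s), %d clones/subject, tissues %s\n",
    object@seed, object@nSubjects,
    paste(sprintf("%s=%d", names(table(object@groups)), table(object@groups)),
          collapse = ", "),
    object@nClonesPerSubject, paste(object@tissues, collapse = ", ")))
  cat(sprintf("  shmRate %.4g, IgD-only fraction %.3g (SHM x%.2g)\n",
              object@shmRate, object@igdOnlyFraction,
              object@igdOnlyShmMultiplier))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d in, %d kept, %d removed\n", object@input,
              object@output, sum(object@removed)))
  for (r in names(object@removed))
    cat(sprintf("  %-12s %d\n", r, object@removed[r]))
})

#' @describeIn FilterReport-class named per-rule removal counts.
#' @export
setGeneric("removedCounts", function(x) standardGeneric("removedCounts"))
#' @export
setMethod("removedCounts", "FilterReport", function(x) x@removed)

setMethod("show", "DiversityProfile", function(object) {
  cat(sprintf(
    "DiversityProfile '%s': %d orders in [%g, %g], depth %d, %d resamples\n",
    object@sample, length(object@q), min(object@q), max(object@q),
    object@depth, object@resamples))
})

#' @describeIn DiversityProfile-class profile as a tidy data.frame
#'   (`sample`, `q`, `mean`, `lo`, `hi`).
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @export
setMethod("profileTable", "DiversityProfile", function(x) {
  data.frame(sample = x@sample, q = x@q, mean = x@mean, lo = x@lo, hi = x@hi,
             stringsAsFactors = FALSE)
})

setMethod("show", "PositionWeightMatrix", function(object) {
  cat(sprintf("PositionWeightMatrix %s (%s vs %s): %d positions, %d significant, %d masked\n",
              object@gene, object@groups[1], object@groups[2],
              length(object@positions), sum(object@significant, na.rm = TRUE),
              sum(object@masked)))
})
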