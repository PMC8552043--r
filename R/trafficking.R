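# Maximum-parsimony tissue phylogeography: ancestral tissue states by
# minimum-transition (Sankoff, unit cost) reconstruction and a within-tree
# label permutation test for directional trafficking enrichment.

# Convert a LineageTree or ground-truth sankoffTree to the edge/state
# structure consumed by the C++ kernel. The germline root is unconstrained.
.toSankoff <- function(x) {
  if (inherits(x, "sankoffTree")) return(x)
  if (!is(x, "LineageTree")) stop("expected a LineageTree or sankoffTree")
  phy <- ape::reorder.phylo(x@phylo, "postorder")
  nTips <- length(phy$tip.label)
  nNodes <- nTips + phy$Nnode
  tissue <- rep(NA_character_, nNodes)
  ix <- match(phy$tip.label, x@tipData$label)
  tissue[seq_len(nTips)] <- x@tipData$tissue[ix]  # germline -> NA
  structure(list(nNodes = nNodes, edge = phy$edge, tissue = tissue),
            class = "sankoffTree")
}

.observedTissues <- function(st) unique(st$tissue[!is.na(st$tissue)])

#' Reconstruct ancestral tissue states on a lineage tree
#'
#' Sankoff parsimony with unit transition costs assigns tissue states to
#' internal nodes so that the number of tissue transitions along the tree
#' is minimal; the germline root state is unconstrained (inferred). The
#' minimum cost is unique; where several states tie at a node, one
#' minimum-cost assignment is drawn uniformly at random and transition-type
#' counts are averaged over `R` such resolutions (seed the session RNG for
#' reproducibility). Trees whose observed nodes all share one tissue have
#' cost 0.
#'
#' @param tree a [LineageTree-class] or a ground-truth tree from
#'   [groundTruthTrees()].
#' @param tissues tissue label set (default: tissues observed on the tree).
#' @param R number of random tie resolutions to average over.
#' @return list: `cost` (minimal transition count), `counts` (tissue x
#'   tissue transition matrix averaged over resolutions), `states` (one
#'   sampled minimum-cost assignment, per node), `tissues`.
#' @export
reconstructTissueStates <- function(tree, tissues = NULL, R = 20L) {
  st <- .toSankoff(tree)
  if (is.null(tissues)) tissues <- sort(.observedTissues(st))
  state <- match(st$tissue, tissues) - 1L
  if (anyNA(state[!is.na(st$tissue)]))
    stop("tree carries tissues outside the supplied tissue set")
  state[is.na(state)] <- -1L
  res <- .cppSankoff(st$edge - 1L, st$nNodes, state, length(tissues),
                     as.integer(R))
  dimnames(res$counts) <- list(tissues, tissues)
  list(cost = res$cost, counts = res$counts,
       states = tissues[res$states + 1L], tissues = tissues)
}

#' Permutation test for directional trafficking enrichment
#'
#' For each tree the minimal-transition reconstruction yields directed
#' tissue-transition counts; the per-direction statistic is
#' `count[a,b] / total` summed over trees. Under the null, tip tissue
#' labels are permuted within each tree (preserving each tree's label
#' multiset and topology) `nPerm` times. One-sided p-values use the
#' plus-one correction `(1 + #null >= observed) / (nPerm + 1)`; the
#' total-transition statistic (mean minimal transitions per tree) is tested
#' for being smaller than random, i.e. tissue clustering.
#'
#' Only trees with at least `minTips` observed tips spanning at least
#' `minTissues` tissues enter the test; if none qualifies the result is
#' flagged untestable.
#'
#' @param trees list of [LineageTree-class] and/or ground-truth trees.
#' @param nPerm number of permutations (default 100).
#' @param R tie resolutions averaged per reconstruction.
#' @param tissues tissue set (default: union observed across trees).
#' @param minTips,minTissues entry criteria per tree.
#' @return an [EnrichmentResult-class].
#' @examples
#' cfg <- simulationConfig(seed = 11, nSubjects = 1, nClonesPerSubject = 40,
#'                         cloneSizeExponent = 1.2, cloneSizeMax = 15)
#' sim <- simulateRepertoire(cfg)
#' set.seed(1)
#' res <- permutationTest(groundTruthTrees(sim$truth), nPerm = 50)
#' transitionPvalues(res)["NBx", "BBx"]
#' @export
permutationTest <- function(trees, nPerm = 100L, R = 20L, tissues = NULL,
                            minTips = 3L, minTissues = 2L) {
  sts <- lapply(trees, .toSankoff)
  keep <- vapply(sts, function(st) {
    obs <- st$tissue[!is.na(st$tissue)]
    length(obs) >= minTips && length(unique(obs)) >= minTissues
  }, logical(1))
  sts <- sts[keep]
  if (is.null(tissues))
    tissues <- sort(unique(unlist(lapply(sts, .observedTissues))))
  S <- length(tissues)
  if (length(sts) == 0L || S < 2L) {
    return(new("EnrichmentResult", tissues = character(0),
               observedCounts = matrix(0, 0, 0),
               observedProp = matrix(0, 0, 0),
               nullProp = matrix(0, 0, 0), pvalues = matrix(0, 0, 0),
               observedTotalMean = NA_real_, nullTotalMean = numeric(0),
               pTotal = NA_real_, nTrees = 0L, nPerm = as.integer(nPerm),
               testable = FALSE))
  }

  edges <- lapply(sts, function(st) st$edge - 1L)
  states <- lapply(sts, function(st) {
    s <- match(st$tissue, tissues) - 1L
    s[is.na(s)] <- -1L
    s
  })
  nNodes <- vapply(sts, function(st) st$nNodes, integer(1))
  res <- .cppTraffickingPerm(edges, states, nNodes, S, as.integer(nPerm),
                             as.integer(R))

  dimnames(res$obs_counts) <- list(tissues, tissues)
  dimnames(res$obs_prop) <- list(tissues, tissues)
  # C++ fills column a*S+b (0-based) = a-th source, b-th destination
  colnames(res$null_prop) <- as.vector(t(outer(
    tissues, tissues, function(a, b) paste(a, b, sep = "->"))))

  eps <- 1e-12
  pv <- matrix(NA_real_, S, S, dimnames = list(tissues, tissues))
  for (a in seq_len(S)) for (b in seq_len(S)) {
    if (a == b) next
    col <- paste(tissues[a], tissues[b], sep = "->")
    pv[a, b] <- (1 + sum(res$null_prop[, col] >= res$obs_prop[a, b] - eps)) /
      (nPerm + 1)
  }
  obsTotal <- mean(res$obs_cost)
  pTotal <- (1 + sum(res$null_total <= obsTotal + eps)) / (nPerm + 1)

  new("EnrichmentResult", tissues = tissues,
      observedCounts = res$obs_counts, observedProp = res$obs_prop,
      nullProp = res$null_prop, pvalues = pv,
      observedTotalMean = obsTotal, nullTotalMean = as.numeric(res$null_total),
      pTotal = pTotal, nTrees = length(sts), nPerm = as.integer(nPerm),
      testable = TRUE)
}
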