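# Germline-rooted maximum-parsimony lineage trees per clone.

# N-aware Hamming distance on equal-length alignments: positions where
# either side is a gap are skipped, N matches anything.
.ntDist <- function(a, b) {
  x <- seqToChars(a)
  y <- seqToChars(b)
  keep <- !isGapChar(x) & !isGapChar(y) & x != "N" & y != "N"
  sum(x[keep] != y[keep])
}

#' Build a maximum-parsimony lineage tree for one clone
#'
#' Collapses duplicate sequences (per tissue and isotype) to single tips
#' with multiplicities, attaches the clone germline as outgroup, and finds a
#' maximum-parsimony topology: exhaustively for small clones (at most 7
#' tips including the germline, where all topologies are scored), and by
#' NJ-start nearest-neighbour-interchange hill climbing on the Fitch score
#' for larger ones. Branch lengths are parsimony-assigned nucleotide
#' changes (ACCTRAN); ambiguous bases (N) match any base. The construction
#' is deterministic: tips are ordered lexicographically by label and
#' equal-score ties resolve to the first topology in that fixed enumeration.
#'
#' @param records records of a single clone (equal-length
#'   `sequence_alignment`s).
#' @param germline germline alignment; defaults to the clone's modal
#'   `germline_alignment`.
#' @param cloneId identifier stored on the tree.
#' @return a [LineageTree-class].
#' @examples
#' rec <- data.frame(
#'   sequence_id = c("s1", "s2"),
#'   sequence_alignment = c("AATACGT", "AATACGG"),
#'   germline_alignment = "AATACGT",
#'   tissue = "NBx", c_call = "IGHM")
#' parsimonyScore(buildTree(rec, cloneId = "demo"))  # one substitution
#' @export
buildTree <- function(records, germline = NULL, cloneId = "clone") {
  if (nrow(records) < 1L) stop("clone has no records")
  germ <- if (is.null(germline)) cloneGermline(records) else germline
  lens <- nchar(records$sequence_alignment)
  if (any(lens != nchar(germ)))
    stop("alignment lengths differ within clone ", cloneId)

  key <- paste(records$sequence_alignment, records$tissue, records$c_call,
               sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  firstId <- vapply(groups, function(ix)
    sort(records$sequence_id[ix])[1], character(1))
  ord <- order(firstId)
  groups <- groups[ord]
  firstId <- firstId[ord]
  tipData <- data.frame(
    label = firstId,
    tissue = vapply(groups, function(ix) records$tissue[ix[1]], character(1)),
    isotype = vapply(groups, function(ix) records$c_call[ix[1]], character(1)),
    multiplicity = lengths(groups),
    sequence_ids = vapply(groups, function(ix)
      paste(sort(records$sequence_id[ix]), collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  seqs <- vapply(groups, function(ix)
    records$sequence_alignment[ix[1]], character(1))

  labels <- c("Germline", tipData$label)
  alig <- c(germ, seqs)
  nTips <- length(labels)

  if (nTips == 2L) {
    d <- .ntDist(alig[1], alig[2])
    phy <- ape::read.tree(text = sprintf("(Germline:0,%s:%d);", labels[2], d))
    return(new("LineageTree", phylo = phy, germline = "Germline",
               tipData = tipData, score = as.numeric(d), cloneId = cloneId))
  }

  mat <- t(vapply(alig, function(s) {
    ch <- tolower(seqToChars(s))
    ch[ch == "."] <- "-"
    ch
  }, character(nchar(germ))))
  rownames(mat) <- labels
  dat <- phangorn::phyDat(mat, type = "DNA")

  if (nTips == 3L) {
    best <- ape::read.tree(text = sprintf("(%s,%s,%s);", labels[1],
                                          labels[2], labels[3]))
  } else if (nTips <= 7L) {
    cand <- phangorn::allTrees(nTips, rooted = FALSE, tip.label = labels)
    scores <- phangorn::parsimony(cand, dat)
    best <- cand[[which.min(scores)]]
  } else {
    dm <- phangorn::dist.hamming(dat)
    start <- phangorn::NJ(dm)
    best <- phangorn::optim.parsimony(start, dat, rearrangements = "NNI",
                                      trace = 0)
  }
  best <- ape::root(best, outgroup = "Germline", resolve.root = TRUE)
  best <- phangorn::acctran(best, dat)
  score <- as.numeric(phangorn::parsimony(best, dat))
  new("LineageTree", phylo = best, germline = "Germline", tipData = tipData,
      score = score, cloneId = cloneId)
}

#' Build lineage trees for all clones of a repertoire
#'
#' @param records records carrying `clone_id` (see [assignClones()]).
#' @param minSize minimum number of unique (sequence, tissue, isotype) tips
#'   for a clone to receive a tree.
#' @param cloneIds optional subset of clones.
#' @return named list of [LineageTree-class] objects.
#' @export
buildTrees <- function(records, minSize = 2L, cloneIds = NULL) {
  recs <- records[!is.na(records$clone_id), , drop = FALSE]
  if (!is.null(cloneIds))
    recs <- recs[recs$clone_id %in% cloneIds, , drop = FALSE]
  out <- list()
  for (cid in unique(recs$clone_id)) {
    sub <- recs[recs$clone_id == cid, , drop = FALSE]
    nTips <- length(unique(paste(sub$sequence_alignment, sub$tissue,
                                 sub$c_call)))
    if (nTips < minSize) next
    out[[cid]] <- buildTree(sub, cloneId = cid)
  }
  out
}

#' Per-sequence somatic hypermutation frequency
#'
#' Fraction of mismatched positions between `sequence_alignment` and
#' `germline_alignment`, over positions where both carry an unambiguous
#' base (gaps and Ns excluded). Sequences with zero comparable positions
#' give `NA` with a warning.
#'
#' @param records AIRR record data.frame.
#' @return numeric vector of per-record mutation frequencies.
#' @export
mutationFrequency <- function(records) {
  out <- vapply(seq_len(nrow(records)), function(i) {
    x <- seqToChars(records$sequence_alignment[i])
    y <- seqToChars(records$germline_alignment[i])
    keep <- !isGapChar(x) & !isGapChar(y) &
      x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    n <- sum(keep)
    if (n == 0L) return(NA_real_)
    sum(x[keep] != y[keep]) / n
  }, numeric(1))
  if (anyNA(out))
    warning(sum(is.na(out)), " sequence(s) with no comparable positions excluded")
  out
}

#' Aggregate SHM frequencies along the clone/isotype/individual hierarchy
#'
#' Frequencies are computed per sequence, averaged within each clone, then
#' averaged over the clones of a given isotype class within each tissue of
#' each individual.
#'
#' @param records records with `clone_id`.
#' @return data.frame `subject_id`, `tissue`, `isotype`, `shm` (mean clone
#'   SHM frequency), `nClones`.
#' @export
aggregateShm <- function(records) {
  recs <- records[!is.na(records$clone_id), , drop = FALSE]
  recs$freq <- mutationFrequency(recs)
  recs$isotype <- isotypeClass(recs$c_call)
  cl <- aggregate(freq ~ subject_id + tissue + isotype + clone_id,
                  data = recs, FUN = mean)
  out <- aggregate(freq ~ subject_id + tissue + isotype, data = cl,
                   FUN = mean)
  nc <- aggregate(clone_id ~ subject_id + tissue + isotype, data = cl,
                  FUN = function(x) length(unique(x)))
  out$nClones <- nc$clone_id
  names(out)[names(out) == "freq"] <- "shm"
  out
}

#' Export lineage trees as annotated Newick
#'
#' One Newick file per tree; tip labels carry tissue, isotype and
#' multiplicity as `label|tissue|isotype|multiplicity`.
#'
#' @param trees list of [LineageTree-class].
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
exportTrees <- function(trees, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tr in trees) {
    phy <- tr@phylo
    td <- tr@tipData
    ix <- match(phy$tip.label, td$label)
    lab <- ifelse(is.na(ix), phy$tip.label,
                  paste(phy$tip.label, td$tissue[ix], td$isotype[ix],
                        td$multiplicity[ix], sep = "|"))
    phy$tip.label <- lab
    path <- file.path(dir, paste0(tr@cloneId, ".nwk"))
    ape::write.tree(phy, file = path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
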