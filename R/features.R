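# Descriptive repertoire statistics: isotype/gene usage, clone overlap,
# global/non-global partition, IgD-only classification, CDR3
# physicochemical properties with PCA, and rank-sum group comparisons.

.dedupeSeqs <- function(records, within = c("subject_id", "tissue")) {
  key <- do.call(paste, c(records[within], list(records$sequence_alignment),
                          sep = "\r"))
  records[!duplicated(key), , drop = FALSE]
}

#' Isotype frequencies per sample
#'
#' Fraction of unique sequences expressing each coarse isotype class (IgM,
#' IgD, IgG, IgA, IgE) per individual and tissue.
#'
#' @param records AIRR record data.frame.
#' @return data.frame `subject_id`, `tissue`, `isotype`, `n`, `freq`
#'   (frequencies sum to 1 within each sample).
#' @export
isotypeFrequencies <- function(records) {
  recs <- .dedupeSeqs(records)
  recs$isotype <- isotypeClass(recs$c_call)
  agg <- aggregate(list(n = recs$sequence_id),
                   by = recs[c("subject_id", "tissue", "isotype")], FUN = length)
  tot <- aggregate(list(total = agg$n),
                   by = agg[c("subject_id", "tissue")], FUN = sum)
  agg <- merge(agg, tot, by = c("subject_id", "tissue"))
  agg$freq <- agg$n / agg$total
  agg$total <- NULL
  agg[order(agg$subject_id, agg$tissue, agg$isotype), ]
}

#' Clone and sequence overlap between the samples of one subject
#'
#' Pairwise counts of shared clones and shared unique sequences (the latter
#' requiring 100% nucleotide identity) between tissue samples, plus the
#' multiway (Venn-style) breakdown of clones by the exact set of tissues
#' they span. Diagonals hold sample totals; fractions are relative to the
#' smaller sample of each pair.
#'
#' @param records records of a single subject, with `clone_id`.
#' @return list: `cloneCounts`, `cloneFrac`, `seqCounts`, `seqFrac`
#'   (matrices over samples), `multiway` (data.frame `tissues`, `nClones`).
#' @export
cloneOverlap <- function(records) {
  if (length(unique(records$subject_id)) > 1L)
    stop("cloneOverlap compares samples within one subject")
  recs <- records[!is.na(records$clone_id), , drop = FALSE]
  samples <- sort(unique(recs$tissue))
  k <- length(samples)
  clones <- lapply(samples, function(ts)
    unique(recs$clone_id[recs$tissue == ts]))
  seqs <- lapply(samples, function(ts)
    unique(recs$sequence_alignment[recs$tissue == ts]))
  names(clones) <- names(seqs) <- samples
  cc <- matrix(0L, k, k, dimnames = list(samples, samples))
  sc <- cc
  for (a in seq_len(k)) for (b in seq_len(k)) {
    cc[a, b] <- length(intersect(clones[[a]], clones[[b]]))
    sc[a, b] <- length(intersect(seqs[[a]], seqs[[b]]))
  }
  frac <- function(m) {
    f <- matrix(0, k, k, dimnames = dimnames(m))
    for (a in seq_len(k)) for (b in seq_len(k))
      f[a, b] <- if (min(m[a, a], m[b, b]) > 0)
        m[a, b] / min(m[a, a], m[b, b]) else 0
    f
  }
  sig <- vapply(split(recs$tissue, recs$clone_id), function(ts)
    paste(sort(unique(ts)), collapse = "+"), character(1))
  multi <- as.data.frame(table(sig), stringsAsFactors = FALSE)
  names(multi) <- c("tissues", "nClones")
  list(cloneCounts = cc, cloneFrac = frac(cc), seqCounts = sc,
       seqFrac = frac(sc), multiway = multi, samples = samples)
}

#' Global / non-global partition of tissue sequences
#'
#' A clone is global when it has at least one nasal and one bronchial
#' member. Nasal-tissue sequences are labelled `NBx_G`/`NBx_NG`, bronchial
#' ones `BBx_G`/`BBx_NG`; blood and other compartments get `NA` (blood-only
#' clones are thereby excluded).
#'
#' @param records records with `clone_id`.
#' @return character vector of labels aligned with `records` rows.
#' @export
globalPartition <- function(records) {
  cls <- tissueClass(records$tissue)
  hasN <- tapply(cls == "nasal", records$clone_id, any)
  hasB <- tapply(cls == "bronchial", records$clone_id, any)
  glob <- as.vector(hasN[records$clone_id] & hasB[records$clone_id])
  lab <- rep(NA_character_, nrow(records))
  nas <- cls == "nasal" & !is.na(records$clone_id)
  bro <- cls == "bronchial" & !is.na(records$clone_id)
  lab[nas] <- ifelse(glob[nas], "NBx_G", "NBx_NG")
  lab[bro] <- ifelse(glob[bro], "BBx_G", "BBx_NG")
  lab
}

#' Classify IgD-only sequences and summarise per individual
#'
#' An IgD sequence is IgD-only iff its clone contains no IgM member.
#' Per-individual frequencies are IgD-only unique sequences over total
#' unique sequences; individuals with fewer than 20 IgD-only sequences are
#' flagged ineligible for IgD-only contrasts.
#'
#' @param records records with `clone_id`.
#' @param minSequences eligibility cutoff (default 20; strictly fewer is
#'   excluded).
#' @return list: `flags` (logical per record), `bySample` (data.frame
#'   `subject_id`, `tissue`, `nIgdOnly`, `nTotal`, `freq`), `eligible`
#'   (named logical per subject).
#' @export
classifyIgdOnly <- function(records, minSequences = 20L) {
  iso <- isotypeClass(records$c_call)
  hasM <- tapply(iso == "IgM", records$clone_id, any)
  flags <- as.logical(iso == "IgD" & !is.na(records$clone_id) &
                        !as.vector(hasM[records$clone_id]))
  recs <- .dedupeSeqs(cbind(records, .igd = flags))
  tot <- aggregate(list(nTotal = recs$sequence_id),
                   by = recs[c("subject_id", "tissue")], FUN = length)
  igd <- aggregate(list(nIgdOnly = recs$.igd),
                   by = recs[c("subject_id", "tissue")], FUN = sum)
  bySample <- merge(tot, igd, by = c("subject_id", "tissue"))
  bySample$freq <- bySample$nIgdOnly / bySample$nTotal
  perSubject <- tapply(bySample$nIgdOnly, bySample$subject_id, sum)
  eligible <- perSubject >= minSequences
  list(flags = flags, bySample = bySample,
       eligible = setNames(as.logical(eligible), names(perSubject)))
}

#' Eight physicochemical properties of the CDR3
#'
#' The CDR3 is the junction amino-acid sequence minus its two anchor
#' residues (the conserved Cys and Trp/Phe). Properties, one row per unique
#' sequence: length (aa); GRAVY (Kyte-Doolittle mean hydropathy); aliphatic
#' index (Ikai: 100 (x_Ala + 2.9 x_Val + 3.9 (x_Ile + x_Leu)));
#' aromatic fraction (F, W, Y, H); net side-chain charge at pH 7.4
#' (Henderson-Hasselbalch); acidic fraction (D, E); basic fraction
#' (K, R, H); mean Grantham polarity. Junctions containing ambiguous or
#' non-amino-acid characters yield `NA` rows (excluded from PCA); matching
#' is case-insensitive.
#'
#' @param records AIRR record data.frame (productive records with
#'   `junction_aa`).
#' @return data.frame `sequence_id` plus the eight property columns.
#' @examples
#' rec <- data.frame(sequence_id = "x", junction_aa = "CGGGW",
#'                   productive = TRUE)
#' cdr3Properties(rec)$gravy  # mean Kyte-Doolittle of "GGG" = -0.4
#' @export
cdr3Properties <- function(records) {
  props <- aaProperties()
  recs <- records[isTRUE_v(records$productive) & !is.na(records$junction_aa) &
                    nchar(records$junction_aa) >= 3, , drop = FALSE]
  cdr3 <- toupper(substr(recs$junction_aa, 2L, nchar(recs$junction_aa) - 1L))
  out <- data.frame(sequence_id = recs$sequence_id,
                    length = NA_real_, gravy = NA_real_, aliphatic = NA_real_,
                    aromatic = NA_real_, charge = NA_real_, acidic = NA_real_,
                    basic = NA_real_, polarity = NA_real_,
                    stringsAsFactors = FALSE)
  pH <- 7.4
  for (i in seq_along(cdr3)) {
    aa <- seqToChars(cdr3[i])
    if (!length(aa) || !all(aa %in% rownames(props))) next
    p <- props[aa, ]
    n <- length(aa)
    basic <- p$basic == 1
    acidic <- !is.na(p$pka_side) & p$charge_sign == -1
    charge <- sum(1 / (1 + 10^(pH - p$pka_side[basic]))) -
      sum(1 / (1 + 10^(p$pka_side[acidic] - pH)))
    out$length[i] <- n
    out$gravy[i] <- mean(p$kd_hydropathy)
    out$aliphatic[i] <- 100 * sum(p$aliphatic_coef) / n
    out$aromatic[i] <- mean(p$aromatic == 1)
    out$charge[i] <- charge
    out$acidic[i] <- mean(p$acidic == 1)
    out$basic[i] <- mean(p$basic == 1)
    out$polarity[i] <- mean(p$grantham_polarity)
  }
  out
}

#' PCA of CDR3 property vectors
#'
#' Principal components of the z-scored property matrix with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive). Rows with missing properties are dropped.
#'
#' @param propTable output of [cdr3Properties()].
#' @param groups optional group label per row (for centroids).
#' @return list: `scores`, `loadings`, `varExplained`, and `centroids`
#'   (group x PC matrix) when groups are given.
#' @export
propertyPca <- function(propTable, groups = NULL) {
  mat <- as.matrix(propTable[, !(names(propTable) %in% "sequence_id")])
  ok <- stats::complete.cases(mat)
  mat <- mat[ok, , drop = FALSE]
  keep <- apply(mat, 2, sd) > 0
  pc <- prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  res <- list(scores = pc$x, loadings = pc$rotation,
              varExplained = pc$sdev^2 / sum(pc$sdev^2))
  if (!is.null(groups)) {
    g <- groups[ok]
    res$centroids <- do.call(rbind, lapply(split(seq_along(g), g), function(ix)
      colMeans(pc$x[ix, , drop = FALSE])))
  }
  res
}

#' Gene usage frequencies and sample clustering
#'
#' Per-sample (subject x tissue) gene-frequency vectors for the V or J
#' segment (alleles collapsed to genes, unique sequences), with
#' average-linkage hierarchical clustering of samples on correlation
#' distance.
#'
#' @param records AIRR record data.frame.
#' @param segment `"v"` or `"j"`.
#' @return list: `usage` (samples x genes frequency matrix, rows sum to 1),
#'   `clustering` (hclust or NULL when fewer than 3 samples).
#' @export
geneUsage <- function(records, segment = c("v", "j")) {
  segment <- match.arg(segment)
  recs <- .dedupeSeqs(records)
  gene <- alleleToGene(recs[[paste0(segment, "_call")]])
  sample <- paste(recs$subject_id, recs$tissue, sep = ":")
  tab <- table(sample, gene)
  usage <- sweep(unclass(tab), 1, rowSums(tab), "/")
  clustering <- NULL
  if (nrow(usage) >= 3L) {
    d <- as.dist(1 - cor(t(usage)))
    clustering <- hclust(d, method = "average")
  }
  list(usage = usage, clustering = clustering)
}

#' Two-tailed Wilcoxon rank-sum comparison
#'
#' The package-wide between-group test. Degenerate input in which every
#' value is tied returns p = 1 with a warning.
#'
#' @param x,y numeric vectors (each n >= 3).
#' @return list `statistic`, `p`.
#' @export
compareGroups <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 values")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; p = 1")
    return(list(statistic = NA_real_, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
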