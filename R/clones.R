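# Clonal inference: V/J/junction-length partition + single-linkage
# clustering of junctions under normalized Hamming distance.

#' Partition records by V gene, J gene and junction length
#'
#' Groups records by subject and by the clonal partition key: V gene and J
#' gene with allele suffixes stripped (ambiguous multi-gene calls use the
#' first listed gene) and exact junction nucleotide length. Clustering never
#' crosses partitions and subjects are never mixed. Records without a usable
#' junction are shunted to an `"unassigned"` attribute.
#'
#' @param records AIRR record data.frame.
#' @return named list of data.frames (one per partition, key
#'   `subject|vGene|jGene|length`), with attribute `unassigned` holding any
#'   junction-less records.
#' @export
partitionRecords <- function(records) {
  junc <- records$junction
  bad <- is.na(junc) | junc == ""
  if (any(bad))
    message(sum(bad), " record(s) without junction shunted to 'unassigned'")
  good <- records[!bad, , drop = FALSE]
  key <- paste(good$subject_id, alleleToGene(good$v_call),
               alleleToGene(good$j_call), nchar(good$junction), sep = "|")
  parts <- split(good, key)
  attr(parts, "unassigned") <- records[bad, , drop = FALSE]
  parts
}

# Single-linkage components of unique junctions at normalized Hamming <= t.
.linkJunctions <- function(junctions, t) {
  n <- length(junctions)
  if (n == 1L) return(1L)
  L <- nchar(junctions[1])
  m <- matrix(unlist(strsplit(junctions, "", fixed = TRUE)), nrow = n,
              byrow = TRUE)
  up <- seq_len(n)
  find <- function(i) {
    while (up[i] != i) {
      up[i] <<- up[up[i]]
      i <- up[i]
    }
    i
  }
  maxMm <- floor(t * L)
  for (i in seq_len(n - 1L)) {
    mm <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                    matrix(m[i, ], n - i, L, byrow = TRUE))
    for (j in which(mm <= maxMm)) {
      ri <- find(i)
      rj <- find(i + j)
      if (ri != rj) up[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

#' Cluster a partition into clones
#'
#' Within each V/J/length partition, records are linked when the normalized
#' Hamming distance between their junctions (mismatches / junction length)
#' is at most `threshold` (inclusive); clones are the connected components
#' of this graph (single linkage). Clone identifiers are unique per subject.
#'
#' @param partition output of [partitionRecords()].
#' @param threshold numeric in (0, 1).
#' @return data.frame `sequence_id`, `clone_id`, `subject_id`, `v_gene`,
#'   `j_gene`, `junction_length`.
#' @examples
#' df <- data.frame(
#'   sequence_id = c("a", "b", "c"), subject_id = "S01",
#'   v_call = "IGHV1-S1*01", j_call = "IGHJ4*01",
#'   junction = c("AAAA", "AAAT", "TTTT"))
#' parts <- partitionRecords(df)
#' table(clusterClones(parts, 0.25)$clone_id)  # {a,b} together, c alone
#' @export
clusterClones <- function(partition, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  out <- vector("list", length(partition))
  counter <- new.env(parent = emptyenv())
  for (pi in seq_along(partition)) {
    df <- partition[[pi]]
    uj <- unique(df$junction)
    comp <- .linkJunctions(uj, threshold)
    memb <- comp[match(df$junction, uj)]
    subj <- df$subject_id[1]
    base <- if (is.null(counter[[subj]])) 0L else counter[[subj]]
    counter[[subj]] <- base + max(memb)
    out[[pi]] <- data.frame(
      sequence_id = df$sequence_id,
      clone_id = sprintf("%s_%05d", subj, base + memb),
      subject_id = subj,
      v_gene = alleleToGene(df$v_call[1]),
      j_gene = alleleToGene(df$j_call[1]),
      junction_length = nchar(df$junction[1]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Choose a clustering threshold from the distance-to-nearest distribution
#'
#' Computes, within each partition, every unique junction's normalized
#' Hamming distance to its nearest non-identical neighbour, and returns the
#' minimum-density valley between the two dominant modes of this typically
#' bimodal distribution. Falls back to `default` with a warning when fewer
#' than 100 records are available or no valley is found.
#'
#' @param records AIRR record data.frame.
#' @param default fallback threshold.
#' @return numeric threshold in (0, 1).
#' @export
chooseThreshold <- function(records, default = 0.15) {
  if (nrow(records) < 100L) {
    warning("fewer than 100 records; returning default threshold ", default)
    return(default)
  }
  parts <- partitionRecords(records)
  dtn <- numeric(0)
  for (df in parts) {
    uj <- unique(df$junction)
    n <- length(uj)
    if (n < 2L) next
    L <- nchar(uj[1])
    m <- matrix(unlist(strsplit(uj, "", fixed = TRUE)), nrow = n, byrow = TRUE)
    for (i in seq_len(n)) {
      mm <- rowSums(m != matrix(m[i, ], n, L, byrow = TRUE))
      dtn <- c(dtn, min(mm[-i]) / L)
    }
  }
  if (length(dtn) < 10L) {
    warning("too few nearest-neighbour distances; returning default ", default)
    return(default)
  }
  den <- density(dtn, from = 0, to = 1, n = 512, bw = 0.02)
  y <- den$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2L) {
    warning("distance-to-nearest distribution not bimodal; returning default ",
            default)
    return(default)
  }
  ord <- peaks[order(y[peaks], decreasing = TRUE)[1:2]]
  lo <- min(ord)
  hi <- max(ord)
  valley <- lo + which.min(y[lo:hi]) - 1L
  den$x[valley]
}

#' Assign clone identifiers to records
#'
#' Convenience wrapper: partitions records, clusters junctions at the given
#' (or automatically chosen) threshold and attaches a `clone_id` column.
#' Records without junction get `NA`.
#'
#' @param records AIRR record data.frame.
#' @param threshold numeric in (0, 1), or `"auto"` for [chooseThreshold()].
#' @return `records` with a `clone_id` column; the threshold used is stored
#'   in attribute `threshold`.
#' @export
assignClones <- function(records, threshold = "auto") {
  t <- if (identical(threshold, "auto")) chooseThreshold(records)
  else as.numeric(threshold)
  parts <- partitionRecords(records)
  memb <- clusterClones(parts, t)
  records$clone_id <- memb$clone_id[match(records$sequence_id,
                                          memb$sequence_id)]
  attr(records, "threshold") <- t
  records
}

# Modal germline alignment among a clone's members.
cloneGermline <- function(records) {
  tab <- table(records$germline_alignment)
  names(tab)[which.max(tab)]
}
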