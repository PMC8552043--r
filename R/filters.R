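# Quality-control filtering of rearrangement records with full accounting.

#' Ordered QC filter rules
#'
#' The fixed order in which [applyFilters()] tests its rules; a removed
#' record is attributed to the first rule it triggers.
#'
#' @return character vector of rule names.
#' @export
filterRules <- function() {
  c("phix", "c_region", "window", "singleton", "nonproductive", "malformed")
}

# Densest 10-nt window mismatch count between aligned sequence and germline,
# computed on positions where both carry a base (gap positions skipped).
maxWindowMismatches <- function(seqAlign, germAlign, width = 10L) {
  s <- seqToChars(seqAlign)
  g <- seqToChars(germAlign)
  keep <- !isGapChar(s) & !isGapChar(g)
  s <- s[keep]
  g <- g[keep]
  n <- length(s)
  if (n == 0L) return(0L)
  mm <- as.integer(s != g)
  if (n <= width) return(sum(mm))
  cs <- cumsum(mm)
  max(cs[width], cs[(width + 1L):n] - cs[1:(n - width)])
}

.hasStop <- function(alignment) {
  grepl("\\*", translateNt(alignment))
}

#' Apply the QC filters to rearrangement records
#'
#' Removes records in a fixed order with first-triggering-rule attribution:
#' (1) PhiX-flagged; (2) constant-region mismatches > 0; (3) more than six
#' mismatches inside any sliding 10-nucleotide window of the aligned
#' sequence against the germline (a window with exactly six is kept);
#' (4) a single contributing read (`duplicate_count == 1`); (5)
#' non-functional records (internal stop codon, junction length not
#' divisible by 3, or `productive` false). Records with missing/unusable
#' core fields are removed under a distinct `malformed` tally. The report
#' satisfies `input = output + sum(removed)` and filtering is idempotent.
#'
#' @param records AIRR record data.frame (see [readAirr()]).
#' @return list with `kept` (data.frame) and `report`
#'   ([FilterReport-class]).
#' @examples
#' cfg <- simulationConfig(seed = 3, nSubjects = 1, nClonesPerSubject = 15,
#'   readArtifactRates = c(singleton = 0.1, stop = 0.05))
#' sim <- simulateRepertoire(cfg)
#' res <- applyFilters(sim$records)
#' res$report
#' @export
applyFilters <- function(records) {
  n <- nrow(records)
  rules <- filterRules()
  removed <- setNames(integer(length(rules)), rules)
  if (n == 0L) {
    return(list(kept = records,
                report = new("FilterReport", input = 0L, output = 0L,
                             removed = removed)))
  }

  malformed <- is.na(records$sequence_alignment) |
    is.na(records$germline_alignment) | records$sequence_alignment == "" |
    nchar(records$sequence_alignment) != nchar(records$germline_alignment) |
    is.na(records$duplicate_count)

  phix <- !malformed & isTRUE_v(records$phix)
  cregion <- !malformed & !phix &
    !is.na(records$c_region_mismatches) & records$c_region_mismatches > 0L

  pending <- which(!malformed & !phix & !cregion)
  window <- rep(FALSE, n)
  window[pending] <- vapply(pending, function(i)
    maxWindowMismatches(records$sequence_alignment[i],
                        records$germline_alignment[i]) > 6L, logical(1))

  singleton <- !malformed & !phix & !cregion & !window &
    records$duplicate_count == 1L

  pending <- which(!malformed & !phix & !cregion & !window & !singleton)
  nonprod <- rep(FALSE, n)
  nonprod[pending] <- vapply(pending, function(i) {
    !isTRUE(records$productive[i]) ||
      nchar(records$junction[i]) %% 3L != 0L ||
      .hasStop(records$sequence_alignment[i])
  }, logical(1))

  removed["phix"] <- sum(phix)
  removed["c_region"] <- sum(cregion)
  removed["window"] <- sum(window)
  removed["singleton"] <- sum(singleton)
  removed["nonproductive"] <- sum(nonprod)
  removed["malformed"] <- sum(malformed)

  keep <- !(malformed | phix | cregion | window | singleton | nonprod)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       report = new("FilterReport", input = n, output = nrow(kept),
                    removed = removed))
}

isTRUE_v <- function(x) if (is.null(x)) FALSE else !is.na(x) & x
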