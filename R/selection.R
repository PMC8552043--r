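# Antigen-driven selection: replacement/silent mutation partitioning by
# IMGT region, expected replacement fractions under a no-selection mutation
# model, a BASELINe-style posterior over selection strength Sigma, the
# R/S-vs-mutation-load correlation, and positional amino-acid preference
# (PWM) analysis.

.regionCodons <- function(region) {
  switch(toupper(region),
         CDR = c(IMGT_REGIONS$CDR1, IMGT_REGIONS$CDR2),
         FWR = c(IMGT_REGIONS$FWR1, IMGT_REGIONS$FWR2, IMGT_REGIONS$FWR3),
         stop("region must be 'CDR' or 'FWR'"))
}

# Average R/S attribution of one mutated codon over all mutation orders.
.codonRS <- function(germCod, obsCod, tab) {
  g <- strsplit(germCod, "")[[1]]
  o <- strsplit(obsCod, "")[[1]]
  diffPos <- which(g != o)
  n <- length(diffPos)
  if (n == 1L) {
    r <- as.numeric(tab[germCod] != tab[obsCod])
    return(c(r = r, s = 1 - r))
  }
  perms <- if (n == 2L) list(diffPos, rev(diffPos))
  else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(ix) diffPos[ix])
  }
  r <- 0
  for (perm in perms) {
    cur <- g
    for (pos in perm) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- o[pos]
      now <- paste(cur, collapse = "")
      if (tab[prev] != tab[now]) r <- r + 1
    }
  }
  r <- r / length(perms)
  c(r = r, s = n - r)
}

#' Replacement and silent mutation counts per region
#'
#' Compares each sequence to its germline codon-by-codon over IMGT
#' positions 1-104 (alignment columns 1-312) and tallies replacement (R)
#' and silent (S) mutations separately for the CDR (CDR1 + CDR2) and FWR
#' (FWR1 + FWR2 + FWR3) regions; CDR3/FWR4 are excluded. Codons containing
#' gaps or ambiguous bases on either side are skipped; codons with several
#' mutated positions are resolved by enumerating all mutation orders and
#' averaging the R/S attribution. Sequences whose alignment is shorter than
#' the V region are excluded with a message.
#'
#' @param records AIRR record data.frame.
#' @return data.frame `sequence_id`, `r_cdr`, `s_cdr`, `r_fwr`, `s_fwr`.
#' @examples
#' rec <- data.frame(sequence_id = "x",
#'   sequence_alignment = paste0(strrep("GGC", 104), "TGTAAATGG"),
#'   germline_alignment = paste0(strrep("GGT", 26), strrep("GGC", 78),
#'                               "TGTAAATGG"))
#' countRsMutations(rec)  # 26 silent FWR1 changes (GGT -> GGC, both Gly)
#' @export
countRsMutations <- function(records) {
  tab <- codonTable()
  cdr <- .regionCodons("CDR")
  n <- nrow(records)
  out <- data.frame(sequence_id = records$sequence_id,
                    r_cdr = 0, s_cdr = 0, r_fwr = 0, s_fwr = 0,
                    stringsAsFactors = FALSE)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    sa <- records$sequence_alignment[i]
    ga <- records$germline_alignment[i]
    if (is.na(sa) || nchar(sa) < IMGT_V_COLS || nchar(sa) != nchar(ga)) {
      drop[i] <- TRUE
      next
    }
    starts <- seq(1L, IMGT_V_COLS, 3L)
    sCod <- substring(sa, starts, starts + 2L)
    gCod <- substring(ga, starts, starts + 2L)
    ok <- grepl("^[ACGT]{3}$", sCod) & grepl("^[ACGT]{3}$", gCod)
    mut <- which(ok & sCod != gCod)
    for (cd in mut) {
      rs <- .codonRS(gCod[cd], sCod[cd], tab)
      if (cd %in% cdr) {
        out$r_cdr[i] <- out$r_cdr[i] + rs["r"]
        out$s_cdr[i] <- out$s_cdr[i] + rs["s"]
      } else {
        out$r_fwr[i] <- out$r_fwr[i] + rs["r"]
        out$s_fwr[i] <- out$s_fwr[i] + rs["s"]
      }
    }
  }
  if (any(drop))
    message(sum(drop), " record(s) with unusable alignment excluded from R/S counting")
  out[!drop, , drop = FALSE]
}

# Mutability weight of a single substitution under the chosen model.
# Hot-spot model: positions inside WRC (mutating the C) or GYW (the G)
# motifs get weight `multiplier`.
.subWeight <- function(dense, pos, model, multiplier) {
  if (model == "uniform") return(1)
  b <- dense[pos]
  n <- length(dense)
  w <- c("A", "T")
  r <- c("A", "G")
  y <- c("C", "T")
  hot <- FALSE
  if (b == "C" && pos >= 3 &&
      dense[pos - 2] %in% w && dense[pos - 1] %in% r) hot <- TRUE
  if (b == "G" && pos <= n - 2 &&
      dense[pos + 1] %in% y && dense[pos + 2] %in% w) hot <- TRUE
  if (hot) multiplier else 1
}

#' Expected replacement fraction under a no-selection mutation model
#'
#' Enumerates every possible single-nucleotide substitution in the region's
#' germline codons, excludes substitutions creating stop codons, weights
#' each by the mutation model (uniform by default, or WRC/GYW hot-spot
#' weighting), and returns the weighted fraction that is non-synonymous.
#'
#' @param germline germline alignment (IMGT-gapped; V region in columns
#'   1-312).
#' @param region `"CDR"` or `"FWR"`.
#' @param model `"uniform"` or `"hotspot"`.
#' @param multiplier hot-spot weight multiplier (ignored for uniform).
#' @return expected replacement fraction p_r in (0, 1\].
#' @examples
#' g <- paste0(strrep("GGG", 104), "TGTTGG")
#' expectedReplacementFraction(g, "FWR")  # 6/9: third-position Gly silent
#' @export
expectedReplacementFraction <- function(germline, region,
                                        model = c("uniform", "hotspot"),
                                        multiplier = 3) {
  model <- match.arg(model)
  tab <- codonTable()
  chars <- seqToChars(substr(germline, 1L, min(nchar(germline), IMGT_V_COLS)))
  codons <- .regionCodons(region)
  bases <- c("A", "C", "G", "T")
  wR <- 0
  wTot <- 0
  seen <- FALSE
  for (cd in codons) {
    cols <- (cd - 1L) * 3L + 1:3
    if (cols[3] > length(chars)) next
    cod <- chars[cols]
    if (any(!cod %in% bases)) next
    seen <- TRUE
    germCod <- paste(cod, collapse = "")
    for (k in 1:3) for (b in bases[bases != cod[k]]) {
      alt <- cod
      alt[k] <- b
      altCod <- paste(alt, collapse = "")
      if (altCod %in% STOP_CODONS) next
      w <- .subWeight(chars, cols[k], model, multiplier)
      wTot <- wTot + w
      if (tab[altCod] != tab[germCod]) wR <- wR + w
    }
  }
  if (!seen) stop("region contains no intact germline codons")
  wR / wTot
}

.sigmaToP <- function(sigma, pR) pR * exp(sigma) / (pR * exp(sigma) + 1 - pR)

#' Posterior density of selection strength for a sequence group
#'
#' BASELINe-style estimation: each sequence's replacement count is modelled
#' as R ~ Binomial(R + S, pi(Sigma)) with
#' pi(Sigma) = p_r e^Sigma / (p_r e^Sigma + 1 - p_r), where p_r is the
#' region's expected replacement fraction without selection. The group
#' posterior treats Sigma as shared across the group's sequences: a flat
#' prior on the grid multiplied by the product of per-sequence binomial
#' likelihoods, so the density concentrates as mutations accumulate and its
#' central credible intervals are calibrated under the model. Sequences
#' with R + S = 0 are uninformative and skipped; if all are, a flat density
#' flagged non-informative is returned.
#'
#' @param r,s integer vectors of per-sequence replacement and silent counts.
#' @param pR expected replacement fraction (scalar or per-sequence vector).
#' @param grid Sigma grid (default -8 to 8, step 0.02).
#' @param region,group labels carried on the result.
#' @return a [SelectionPosterior-class].
#' @examples
#' post <- selectionPosterior(5, 5, 0.5)
#' posteriorMode(post)  # symmetric counts at pi = p_r: mode at 0
#' @export
selectionPosterior <- function(r, s, pR, grid = seq(-8, 8, by = 0.02),
                               region = "CDR", group = "group") {
  stopifnot(length(r) == length(s))
  if (length(pR) == 1L) pR <- rep(pR, length(r))
  if (any(pR <= 0 | pR >= 1)) stop("pR must be in (0, 1)")
  h <- grid[2] - grid[1]
  keep <- (r + s) > 0
  if (!any(keep)) {
    flat <- rep(1 / (h * length(grid)), length(grid))
    return(new("SelectionPosterior", grid = grid,
               density = flat / (sum(flat) * h), region = region,
               group = group, nSeq = 0L, informative = FALSE))
  }
  r <- r[keep]
  s <- s[keep]
  pR <- pR[keep]
  ll <- numeric(length(grid))
  for (p in unique(pR)) {
    ix <- pR == p
    pig <- .sigmaToP(grid, p)
    ll <- ll + sum(r[ix]) * log(pig) + sum(s[ix]) * log1p(-pig)
  }
  ll <- ll - max(ll)
  d <- exp(ll)
  d <- d / (sum(d) * h)
  new("SelectionPosterior", grid = grid, density = d, region = region,
      group = group, nSeq = as.integer(length(r)), informative = TRUE)
}

#' Compare two selection posteriors
#'
#' Two-sided group comparison
#' p = 2 min(P(Sigma_A > Sigma_B), P(Sigma_B > Sigma_A)), evaluated by
#' numeric convolution of the two independent group densities (ties share
#' mass equally).
#'
#' @param a,b [SelectionPosterior-class] objects on the same grid.
#' @return p-value in (0, 1\].
#' @export
compareSelection <- function(a, b) {
  stopifnot(identical(a@grid, b@grid))
  h <- a@grid[2] - a@grid[1]
  pa <- a@density * h
  pb <- b@density * h
  cb <- cumsum(pb) - pb
  pAgtB <- sum(pa * cb) + 0.5 * sum(pa * pb)
  p <- 2 * min(pAgtB, 1 - pAgtB)
  min(max(p, .Machine$double.xmin), 1)
}

#' Correlation of CDR R/S ratio with clonal mutation load
#'
#' Spearman correlation between each clone's pooled CDR replacement/silent
#' ratio and its total mutation count, testing whether heavily mutated
#' clones show a stronger signature of purifying selection.
#'
#' @param records records with `clone_id`.
#' @param minClones minimum clones with CDR S > 0 required.
#' @return list `rho`, `p`, `nClones`.
#' @export
rsVsLoadCorrelation <- function(records, minClones = 10L) {
  counts <- countRsMutations(records)
  counts$clone_id <- records$clone_id[match(counts$sequence_id,
                                            records$sequence_id)]
  counts <- counts[!is.na(counts$clone_id), , drop = FALSE]
  agg <- aggregate(cbind(r_cdr, s_cdr, r_fwr, s_fwr) ~ clone_id,
                   data = counts, FUN = sum)
  agg <- agg[agg$s_cdr > 0, , drop = FALSE]
  if (nrow(agg) < minClones)
    stop("need at least ", minClones, " clones with CDR S > 0")
  ratio <- agg$r_cdr / agg$s_cdr
  load <- agg$r_cdr + agg$s_cdr + agg$r_fwr + agg$s_fwr
  if (sd(ratio) == 0 || sd(load) == 0) {
    warning("degenerate input; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, nClones = nrow(agg)))
  }
  ct <- suppressWarnings(cor.test(ratio, load, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, nClones = nrow(agg))
}

#' Positional amino-acid preference analysis (PWM)
#'
#' For each commonly used IGHV gene (strictly more than `minUsage` usage in
#' at least `minSubjects` individuals), compares per-position amino-acid
#' frequencies between a target and a background sequence group over IMGT
#' positions 1-104. Preference scores are signed
#' log2((f_target + eps) / (f_background + eps)); per-position significance
#' comes from Fisher's exact test on the residue-count table,
#' Benjamini-Hochberg corrected across positions within each gene.
#' Positions with fewer than `minObs` observations in either group are
#' masked.
#'
#' @param records AIRR record data.frame.
#' @param target logical vector over records marking the target group.
#' @param background logical vector (default: complement of target).
#' @param genes IGHV genes to analyse (default: the usage rule above).
#' @param minUsage,minSubjects gene inclusion rule (strict inequality).
#' @param minObs per-position minimum observations per group.
#' @param fdrLevel BH threshold for the significance flags.
#' @param eps pseudo-frequency in the score.
#' @param groups labels for the two groups.
#' @return named list of [PositionWeightMatrix-class] objects.
#' @export
pwmAnalysis <- function(records, target, background = NULL, genes = NULL,
                        minUsage = 0.025, minSubjects = 3L, minObs = 10L,
                        fdrLevel = 0.05, eps = 0.01,
                        groups = c("target", "background")) {
  if (is.null(background)) background <- !target
  gene <- alleleToGene(records$v_call)
  if (is.null(genes)) {
    usage <- table(records$subject_id, gene)
    frac <- usage / rowSums(usage)
    genes <- colnames(frac)[colSums(frac > minUsage) >= minSubjects]
  }
  aaLevels <- rownames(aaProperties())
  tab <- codonTable()
  out <- list()
  for (g in genes) {
    inGene <- gene == g
    idxT <- which(inGene & target)
    idxB <- which(inGene & background)
    if (!length(idxT) || !length(idxB)) next
    getAa <- function(idx, p) {
      cods <- substr(records$sequence_alignment[idx], (p - 1L) * 3L + 1L,
                     (p - 1L) * 3L + 3L)
      aa <- tab[cods]
      aa[!is.na(aa) & aa != "*" & aa %in% aaLevels]
    }
    pos <- 1:IMGT_V_CODONS
    tMat <- matrix(NA_real_, length(aaLevels), length(pos),
                   dimnames = list(aaLevels, pos))
    bMat <- tMat
    score <- tMat
    pv <- rep(NA_real_, length(pos))
    masked <- rep(FALSE, length(pos))
    for (p in pos) {
      aT <- getAa(idxT, p)
      aB <- getAa(idxB, p)
      if (length(aT) < minObs || length(aB) < minObs) {
        masked[p] <- TRUE
        next
      }
      fT <- table(factor(aT, levels = aaLevels)) / length(aT)
      fB <- table(factor(aB, levels = aaLevels)) / length(aB)
      tMat[, p] <- as.numeric(fT)
      bMat[, p] <- as.numeric(fB)
      score[, p] <- log2((as.numeric(fT) + eps) / (as.numeric(fB) + eps))
      ct <- rbind(table(factor(aT, levels = aaLevels)),
                  table(factor(aB, levels = aaLevels)))
      ct <- ct[, colSums(ct) > 0, drop = FALSE]
      pv[p] <- if (ncol(ct) < 2L) 1
      else fisher.test(ct, workspace = 2e7)$p.value
    }
    padj <- rep(NA_real_, length(pos))
    padj[!masked] <- p.adjust(pv[!masked], method = "BH")
    out[[g]] <- new("PositionWeightMatrix", gene = g,
                    positions = as.integer(pos), target = tMat,
                    background = bMat, score = score, pvalue = pv,
                    padj = padj,
                    significant = !masked & !is.na(padj) & padj < fdrLevel,
                    masked = masked, groups = groups)
  }
  out
}
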