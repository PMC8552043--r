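# Synthetic multi-subject, multi-tissue AIRR repertoire simulator with
# plantable ground truth. Clone lineages grow by uniform sequential
# attachment (Yule-like); tissues evolve along branches under a
# row-stochastic trafficking matrix; isotypes switch only 3'-ward in the
# IGHC locus order; SHM is uniform per-site substitution per branch.
# Emitted records are kept free of incidental QC violations so that
# plantQcViolations() bookkeeping exactly determines the filter outcome.

defaultTraffickingMatrix <- function(tissues) {
  n <- length(tissues)
  if (identical(tissues, c("NBx", "BBx", "PBMC"))) {
    m <- matrix(c(0.75, 0.20, 0.05,
                  0.04, 0.90, 0.06,
                  0.10, 0.15, 0.75),
                nrow = 3, byrow = TRUE, dimnames = list(tissues, tissues))
    return(m)
  }
  m <- matrix(0.2 / max(1, n - 1), n, n, dimnames = list(tissues, tissues))
  diag(m) <- if (n > 1) 0.8 else 1
  m
}

#' Build a simulation configuration
#'
#' Returns a [SimulationConfig-class] whose defaults emulate a two-group
#' airway cohort: nasal (`NBx`) and bronchial (`BBx`) mucosa plus blood
#' (`PBMC`), trafficking biased from nasal to bronchial, isotype
#' composition dominated by switched IgA, and a small planted IgD-only
#' clone subpopulation with elevated SHM, longer CDR3s and IGHJ6 bias.
#'
#' @param seed integer seed; fully determines the simulator output.
#' @param nSubjects,groups number of subjects and their group labels
#'   (default alternates `"AA"` / `"NANA"`).
#' @param tissues tissue labels (`NBx*` nasal, `BBx*` bronchial, `PBMC*`
#'   blood).
#' @param nClonesPerSubject clones per subject.
#' @param cloneSizeExponent,cloneSizeMax clone-size power law.
#' @param shmRate per-site substitution probability per branch.
#' @param traffickingMatrix row-stochastic tissue transition matrix;
#'   `NULL` uses a nasal-to-bronchial-biased default.
#' @param rootTissueProbs,rootIsotypeProbs founder tissue / isotype
#'   distributions.
#' @param switchProb,isotypeWeights per-branch class-switch probability and
#'   target weights (3'-ward segments only).
#' @param igdOnlyFraction,igdOnlyShmMultiplier IgD-only planting.
#' @param ighjUsage,ighjUsageIgd IGHJ1..6 usage vectors.
#' @param cdr3LengthMeanAa,cdr3LengthSdAa,igdCdr3LengthBonusAa CDR3 length
#'   model (amino acids).
#' @param readArtifactRates rates for [plantQcViolations()]; all zero by
#'   default.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7, nSubjects = 2, nClonesPerSubject = 10)
#' sim <- simulateRepertoire(cfg)
#' head(sim$records$tissue)
#' @export
simulationConfig <- function(seed = 1L, nSubjects = 10L, groups = NULL,
    tissues = c("NBx", "BBx", "PBMC"), nClonesPerSubject = 200L,
    cloneSizeExponent = 2.0, cloneSizeMax = 60L, shmRate = 0.01,
    traffickingMatrix = NULL, rootTissueProbs = NULL,
    rootIsotypeProbs = NULL, switchProb = 0.9, isotypeWeights = NULL,
    igdOnlyFraction = 0.06, igdOnlyShmMultiplier = 2.2,
    ighjUsage = NULL, ighjUsageIgd = NULL,
    cdr3LengthMeanAa = 15, cdr3LengthSdAa = 2, igdCdr3LengthBonusAa = 4,
    readArtifactRates = c(phix = 0, c_region = 0, window = 0,
                          singleton = 0, stop = 0)) {
  if (is.null(groups))
    groups <- rep(c("AA", "NANA"), length.out = nSubjects)
  if (is.null(traffickingMatrix))
    traffickingMatrix <- defaultTraffickingMatrix(tissues)
  if (is.null(dimnames(traffickingMatrix)))
    dimnames(traffickingMatrix) <- list(tissues, tissues)
  if (is.null(rootTissueProbs)) {
    rootTissueProbs <- if (identical(tissues, c("NBx", "BBx", "PBMC")))
      c(NBx = 0.45, BBx = 0.40, PBMC = 0.15)
    else setNames(rep(1 / length(tissues), length(tissues)), tissues)
  }
  if (is.null(rootIsotypeProbs))
    rootIsotypeProbs <- setNames(as.numeric(IGHC_ORDER == "IGHM"), IGHC_ORDER)
  if (is.null(isotypeWeights))
    isotypeWeights <- c(IGHM = 0, IGHD = 0, IGHG3 = 0.05, IGHG1 = 0.09,
                        IGHA1 = 0.60, IGHG2 = 0.03, IGHG4 = 0.01,
                        IGHE = 0.02, IGHA2 = 0.20)
  if (is.null(ighjUsage))
    ighjUsage <- c(IGHJ1 = 0.04, IGHJ2 = 0.03, IGHJ3 = 0.10, IGHJ4 = 0.45,
                   IGHJ5 = 0.15, IGHJ6 = 0.23)
  if (is.null(ighjUsageIgd))
    ighjUsageIgd <- c(IGHJ1 = 0.02, IGHJ2 = 0.02, IGHJ3 = 0.06,
                      IGHJ4 = 0.28, IGHJ5 = 0.12, IGHJ6 = 0.50)
  new("SimulationConfig", seed = as.integer(seed),
      nSubjects = as.integer(nSubjects), groups = as.character(groups),
      tissues = tissues, nClonesPerSubject = as.integer(nClonesPerSubject),
      cloneSizeExponent = cloneSizeExponent,
      cloneSizeMax = as.integer(cloneSizeMax), shmRate = shmRate,
      traffickingMatrix = traffickingMatrix,
      rootTissueProbs = rootTissueProbs / sum(rootTissueProbs),
      rootIsotypeProbs = rootIsotypeProbs / sum(rootIsotypeProbs),
      switchProb = switchProb, isotypeWeights = isotypeWeights,
      igdOnlyFraction = igdOnlyFraction,
      igdOnlyShmMultiplier = igdOnlyShmMultiplier,
      ighjUsage = ighjUsage / sum(ighjUsage),
      ighjUsageIgd = ighjUsageIgd / sum(ighjUsageIgd),
      cdr3LengthMeanAa = cdr3LengthMeanAa, cdr3LengthSdAa = cdr3LengthSdAa,
      igdCdr3LengthBonusAa = igdCdr3LengthBonusAa,
      readArtifactRates = readArtifactRates)
}

# Parse the bundled synthetic germline FASTA into V alignments and J parts.
loadGermlines <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "synthetic_germlines.fasta",
                        package = "airtraffic")
    lines <- readLines(path)
    heads <- grep("^>", lines)
    nm <- sub("^>", "", lines[heads])
    seqs <- setNames(lines[heads + 1L], nm)
    v <- seqs[grepl("^IGHV", nm)]
    jraw <- seqs[grepl("^IGHJ", nm)]
    j <- lapply(jraw, function(s) {
      n <- nchar(s)
      list(jin = substr(s, 1L, n - 15L), tail = substr(s, n - 11L, n))
    })
    names(j) <- alleleToGene(names(jraw))
    cache <<- list(v = v, j = j)
    cache
  }
})

.randomCodons <- function(n) {
  if (n <= 0L) return(character(0))
  out <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    repeat {
      cd <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    out[i] <- cd
  }
  out
}

# Apply k substitutions to a character-vector sequence, rejecting any that
# would create a stop codon or a >6-mismatch 10-nt window against the
# germline (in gap-stripped coordinates). Returns chars + applied count.
.mutateSeq <- function(chars, germChars, mutable, mm, k) {
  bases <- c("A", "C", "G", "T")
  nDense <- length(mutable)
  applied <- 0L
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in 1:30) {
      d <- sample.int(nDense, 1L)
      pos <- mutable[d]
      cur <- chars[pos]
      newb <- sample(bases[bases != cur], 1L)
      cod0 <- (pos - 1L) %/% 3L
      codIdx <- cod0 * 3L + 1:3
      cod <- chars[codIdx]
      cod[pos - cod0 * 3L] <- newb
      if (paste(cod, collapse = "") %in% STOP_CODONS) next
      newmm <- newb != germChars[pos]
      if (newmm) {
        lo <- max(1L, d - 9L)
        hi <- min(d, nDense - 9L)
        dense <- FALSE
        if (hi >= lo) {
          old <- mm[d]
          mm[d] <- TRUE
          for (st in lo:hi) if (sum(mm[st:(st + 9L)]) > 6L) { dense <- TRUE; break }
          mm[d] <- old
        }
        if (dense) next
      }
      chars[pos] <- newb
      mm[d] <- newmm
      applied <- applied + 1L
      ok <- TRUE
      break
    }
  }
  list(chars = chars, mm = mm, applied = applied)
}

#' Simulate a multi-subject, multi-tissue AIRR repertoire
#'
#' Generates AIRR-conformant rearrangement records with full ground truth:
#' clone memberships, true lineage trees with per-node tissue and isotype,
#' per-clone germlines, and (when `readArtifactRates` are non-zero) planted
#' QC violations. Identical configurations produce identical output; the
#' session RNG state is left untouched.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `records` (data.frame of AIRR records) and `truth`
#'   (list: `clones` record-to-clone map, `trees` per-clone node tables
#'   with columns `node`, `parent` (0 = germline), `tissue`, `isotype`,
#'   `nMut`, `sequence_id`, `germlines` named vector of germline
#'   alignments, `violations` planted QC violations, `config`).
#' @seealso [plantQcViolations()], [groundTruthTrees()]
#' @export
simulateRepertoire <- function(config) {
  validObject(config)
  withSeed(config@seed, .simulate(config))
}

.simulate <- function(config) {
  gl <- loadGermlines()
  vGenes <- alleleToGene(names(gl$v))
  geneSet <- unique(vGenes)
  tissues <- config@tissues
  tm <- config@traffickingMatrix
  recs <- vector("list", 0L)
  cloneRows <- list()
  trees <- list()
  germs <- character(0)

  sizes0 <- seq_len(config@cloneSizeMax)
  sizeProb <- sizes0^(-config@cloneSizeExponent)

  for (s in seq_len(config@nSubjects)) {
    subject <- sprintf("S%02d", s)
    group <- config@groups[s]
    geneW <- rgamma(length(geneSet), shape = 2)
    geneW <- geneW / sum(geneW)
    sizes <- sample(sizes0, config@nClonesPerSubject, replace = TRUE,
                    prob = sizeProb)
    igdFlags <- runif(config@nClonesPerSubject) < config@igdOnlyFraction

    for (cl in seq_len(config@nClonesPerSubject)) {
      cloneId <- sprintf("%s_C%04d", subject, cl)
      igd <- igdFlags[cl]
      gene <- sample(geneSet, 1L, prob = geneW)
      vAllele <- sample(names(gl$v)[vGenes == gene], 1L)
      jUse <- if (igd) config@ighjUsageIgd else config@ighjUsage
      jGene <- sample(names(jUse), 1L, prob = jUse)
      jin <- gl$j[[jGene]]$jin
      jtail <- gl$j[[jGene]]$tail
      jinCod <- nchar(jin) / 3L

      mu <- config@cdr3LengthMeanAa +
        (if (igd) config@igdCdr3LengthBonusAa else 0) +
        (if (jGene == "IGHJ6") 2 else 0)
      cdr3 <- max(jinCod + 1L, round(rnorm(1L, mu, config@cdr3LengthSdAa)))
      nN <- cdr3 - jinCod
      junction <- paste0("TGT", paste(.randomCodons(nN), collapse = ""),
                         jin, "TGG")
      germAlign <- paste0(gl$v[[vAllele]], junction, jtail)
      germChars <- seqToChars(germAlign)
      mutable <- which(!isGapChar(germChars))
      nDense <- length(mutable)
      rate <- config@shmRate * (if (igd) config@igdOnlyShmMultiplier else 1)
      k <- sizes[cl]

      nodeChars <- vector("list", k + 1L)
      nodeMm <- vector("list", k + 1L)
      nodeChars[[1L]] <- germChars
      nodeMm[[1L]] <- rep(FALSE, nDense)
      parent <- integer(k)
      tissue <- character(k)
      isotype <- character(k)
      nMut <- integer(k)

      for (i in seq_len(k)) {
        parent[i] <- if (i == 1L) 0L else sample.int(i - 1L, 1L)
        p <- parent[i]
        tissue[i] <- if (p == 0L)
          sample(tissues, 1L, prob = config@rootTissueProbs)
        else sample(tissues, 1L, prob = tm[tissue[p], ])
        if (igd) {
          isotype[i] <- "IGHD"
        } else {
          iso <- if (p == 0L)
            sample(IGHC_ORDER, 1L, prob = config@rootIsotypeProbs)
          else isotype[p]
          isotype[i] <- iso
          if (runif(1L) < config@switchProb) {
            pos <- match(iso, IGHC_ORDER)
            if (pos < length(IGHC_ORDER)) {
              w <- config@isotypeWeights[IGHC_ORDER[(pos + 1L):length(IGHC_ORDER)]]
              if (sum(w) > 0)
                isotype[i] <- sample(names(w), 1L, prob = w)
            }
          }
        }
        nm <- rbinom(1L, nDense, rate)
        mut <- .mutateSeq(nodeChars[[p + 1L]], germChars, mutable,
                          nodeMm[[p + 1L]], nm)
        nodeChars[[i + 1L]] <- mut$chars
        nodeMm[[i + 1L]] <- mut$mm
        nMut[i] <- mut$applied
      }

      L <- nchar(junction)
      ids <- sprintf("%s_N%03d", cloneId, seq_len(k))
      aligns <- vapply(seq_len(k), function(i)
        paste(nodeChars[[i + 1L]], collapse = ""), character(1))
      juncs <- substr(aligns, JUNCTION_START_COL, JUNCTION_START_COL + L - 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        sequence_id = ids,
        sequence = gsub(".", "", aligns, fixed = TRUE),
        sequence_alignment = aligns,
        germline_alignment = germAlign,
        v_call = vAllele, d_call = "IGHD3-S1*01",
        j_call = paste0(jGene, "*01"), c_call = isotype,
        junction = juncs,
        junction_aa = vapply(juncs, translateNt, character(1), USE.NAMES = FALSE),
        productive = TRUE,
        duplicate_count = 2L + rpois(k, 2),
        consensus_count = 0L,
        subject_id = subject, tissue = tissue, group = group,
        phix = FALSE, c_region_mismatches = 0L,
        stringsAsFactors = FALSE)

      cloneRows[[length(cloneRows) + 1L]] <-
        data.frame(sequence_id = ids, clone_id = cloneId,
                   igd_only = igd, stringsAsFactors = FALSE)
      trees[[cloneId]] <- data.frame(
        node = seq_len(k), parent = parent, tissue = tissue,
        isotype = isotype, nMut = nMut, sequence_id = ids,
        stringsAsFactors = FALSE)
      germs[cloneId] <- germAlign
    }
  }

  records <- do.call(rbind, recs)
  records$consensus_count <- records$duplicate_count + rpois(nrow(records), 1)
  rownames(records) <- NULL
  truth <- list(clones = do.call(rbind, cloneRows), trees = trees,
                germlines = germs,
                violations = data.frame(sequence_id = character(0),
                                        rule = character(0),
                                        stringsAsFactors = FALSE),
                config = config)

  if (any(config@readArtifactRates > 0)) {
    planted <- plantQcViolations(records, config@readArtifactRates)
    records <- planted$records
    truth$violations <- planted$violations
  }
  list(records = records, truth = truth)
}

#' Plant quality-control violations into simulated records
#'
#' Independently per rule, a Bernoulli-chosen subset of records receives a
#' planted artifact mirroring the QC filter list: a PhiX flag, constant
#' region mismatches, a dense-mismatch window (7 substitutions inside 10
#' adjacent non-gap positions), a singleton read (`duplicate_count = 1`), or
#' an internal stop codon. Edited sequence-derived fields (`sequence`,
#' `junction`, `junction_aa`) are kept consistent.
#'
#' @param records AIRR record data.frame.
#' @param rates named rates in \[0,1\] for `phix`, `c_region`, `window`,
#'   `singleton`, `stop` (missing names default to 0).
#' @param seed optional integer; when given, planting is deterministic and
#'   the session RNG is untouched.
#' @return list with edited `records` and `violations` (data.frame
#'   `sequence_id`, `rule`; one row per planted violation, so a record may
#'   appear under several rules).
#' @export
plantQcViolations <- function(records, rates, seed = NULL) {
  full <- c(phix = 0, c_region = 0, window = 0, singleton = 0, stop = 0)
  full[names(rates)] <- rates
  if (any(full < 0 | full > 1)) stop("rates must be in [0, 1]")
  if (!is.null(seed)) return(withSeed(seed, .plant(records, full)))
  .plant(records, full)
}

.plant <- function(records, rates) {
  n <- nrow(records)
  viol <- list()
  pick <- function(rule) {
    hit <- which(runif(n) < rates[[rule]])
    if (length(hit))
      viol[[length(viol) + 1L]] <<- data.frame(
        sequence_id = records$sequence_id[hit], rule = rule,
        stringsAsFactors = FALSE)
    hit
  }

  records$phix[pick("phix")] <- TRUE
  hit <- pick("c_region")
  if (length(hit))
    records$c_region_mismatches[hit] <- 1L + rpois(length(hit), 1)

  for (i in pick("window")) {
    chars <- seqToChars(records$sequence_alignment[i])
    germ <- seqToChars(records$germline_alignment[i])
    dense <- which(!isGapChar(chars))
    st <- sample.int(length(dense) - 9L, 1L)
    for (d in st:(st + 6L)) {
      pos <- dense[d]
      alt <- setdiff(c("A", "C", "G", "T"), germ[pos])
      chars[pos] <- sample(alt, 1L)
    }
    records[i, ] <- .refreshDerived(records[i, ], paste(chars, collapse = ""))
  }

  records$duplicate_count[pick("singleton")] <- 1L

  for (i in pick("stop")) {
    chars <- seqToChars(records$sequence_alignment[i])
    cand <- setdiff(which(vapply(seq_len(103L), function(cd)
      !any(isGapChar(chars[(cd - 1L) * 3L + 1:3])), logical(1))), c(23L, 41L))
    cd <- sample(cand, 1L)
    chars[(cd - 1L) * 3L + 1:3] <- c("T", "A", "A")
    records[i, ] <- .refreshDerived(records[i, ], paste(chars, collapse = ""))
  }

  violations <- if (length(viol)) do.call(rbind, viol)
  else data.frame(sequence_id = character(0), rule = character(0),
                  stringsAsFactors = FALSE)
  list(records = records, violations = violations)
}

.refreshDerived <- function(row, alignment) {
  row$sequence_alignment <- alignment
  row$sequence <- gsub(".", "", alignment, fixed = TRUE)
  L <- nchar(row$junction)
  row$junction <- substr(alignment, JUNCTION_START_COL,
                         JUNCTION_START_COL + L - 1L)
  row$junction_aa <- translateNt(row$junction)
  row
}

#' Lineage trees from simulator ground truth
#'
#' Converts the true per-clone lineage tables into the tree structures
#' consumed by [permutationTest()], with every observed node carrying its
#' true tissue label and the germline root unconstrained. Useful for
#' validating the trafficking statistics independently of tree inference.
#'
#' @param truth the `truth` element returned by [simulateRepertoire()].
#' @param minTips,minTissues minimum observed nodes and distinct tissues for
#'   a clone to be returned (defaults mirror the trafficking test entry
#'   criteria).
#' @return list of `sankoffTree` structures (edge matrix in postorder plus
#'   per-node tissue labels, `NA` for the unconstrained germline root).
#' @export
groundTruthTrees <- function(truth, minTips = 3L, minTissues = 2L) {
  out <- list()
  for (cid in names(truth$trees)) {
    tr <- truth$trees[[cid]]
    k <- nrow(tr)
    if (k < minTips || length(unique(tr$tissue)) < minTissues) next
    edge <- cbind(tr$parent + 1L, tr$node + 1L)
    edge <- edge[order(edge[, 2L], decreasing = TRUE), , drop = FALSE]
    out[[cid]] <- structure(
      list(nNodes = k + 1L, edge = edge,
           tissue = c(NA_character_, tr$tissue)),
      class = "sankoffTree")
  }
  out
}
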