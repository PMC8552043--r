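# Selection: R/S codon classification, expected replacement fractions by
# enumeration, posterior behaviour, R/S-load correlation and PWM recovery.

# Build an IMGT-conformant alignment from 104 codons plus a junction.
alnFromCodons <- function(codons, junction = "TGTAAATGG") {
  stopifnot(length(codons) == 104)
  paste0(paste(codons, collapse = ""), junction)
}

germCodons <- function() {
  cod <- rep("GGT", 104)
  cod[30] <- "GAT"  # Asp inside CDR1
  cod
}

selRecord <- function(id, codons, germ = germCodons()) {
  data.frame(sequence_id = id,
             sequence_alignment = alnFromCodons(codons),
             germline_alignment = alnFromCodons(germ),
             stringsAsFactors = FALSE)
}

test_that("single-codon changes are classified R or S in the right region", {
  germ <- germCodons()
  syn <- germ
  syn[10] <- "GGC"          # Gly -> Gly in FWR1
  rep_ <- germ
  rep_[30] <- "GCT"         # Asp -> Ala in CDR1
  out <- countRsMutations(rbind(selRecord("syn", syn), selRecord("rep", rep_)))
  expect_equal(unname(unlist(
    out[out$sequence_id == "syn", c("r_cdr", "s_cdr", "r_fwr", "s_fwr")])),
    c(0, 0, 0, 1))
  expect_equal(unname(unlist(
    out[out$sequence_id == "rep", c("r_cdr", "s_cdr", "r_fwr", "s_fwr")])),
    c(1, 0, 0, 0))
})

test_that("multi-hit codons average attribution over mutation orders", {
  germ <- germCodons()
  two <- germ
  two[60] <- "CGT"  # GGT -> CGT -> ... two changes: G96 region CDR2
  two[60] <- "CCT"  # positions 1 and 2 changed (GGT -> CCT)
  out <- countRsMutations(selRecord("two", two))
  expect_equal(out$r_cdr + out$s_cdr, 2)
  expect_gte(out$r_cdr, 1)  # every order changes the amino acid at least once
})

test_that("expected replacement fractions match hand enumeration", {
  gGly <- alnFromCodons(rep("GGG", 104))
  expect_equal(expectedReplacementFraction(gGly, "FWR"), 6 / 9)
  expect_equal(expectedReplacementFraction(gGly, "CDR"), 6 / 9)
  gTrp <- alnFromCodons(rep("TGG", 104))
  expect_equal(expectedReplacementFraction(gTrp, "CDR"), 1.0)
  # hot-spot model with multiplier 1 degenerates to uniform
  g <- alnFromCodons(germCodons())
  expect_equal(expectedReplacementFraction(g, "CDR", "hotspot", multiplier = 1),
               expectedReplacementFraction(g, "CDR"))
  expect_error(expectedReplacementFraction(strrep(".", 312), "CDR"), "intact")
})

test_that("pooled R/(R+S) under neutral SHM matches the enumerated p_r", {
  cfg <- simulationConfig(seed = 81, nSubjects = 1, nClonesPerSubject = 100,
                          cloneSizeExponent = 5, cloneSizeMax = 2,
                          shmRate = 0.015, igdOnlyFraction = 0)
  sim <- simulateRepertoire(cfg)
  counts <- countRsMutations(sim$records)
  germs <- sim$records$germline_alignment[match(counts$sequence_id,
                                                sim$records$sequence_id)]
  for (region in c("CDR", "FWR")) {
    r <- if (region == "CDR") counts$r_cdr else counts$r_fwr
    s <- if (region == "CDR") counts$s_cdr else counts$s_fwr
    pr <- vapply(unique(germs), expectedReplacementFraction, numeric(1),
                 region = region)
    pi <- pr[germs]
    n <- r + s
    mu <- sum(n * pi)
    sdv <- sqrt(sum(n * pi * (1 - pi)))
    expect_lt(abs(sum(r) - mu), 3 * sdv)
  }
})

test_that("posterior location responds correctly to the R/S balance", {
  expect_equal(posteriorMode(selectionPosterior(5, 5, 0.5)), 0)
  post <- selectionPosterior(0, 10, 0.75)
  h <- diff(post@grid[1:2])
  expect_gt(sum(post@density[post@grid < 0]) * h, 0.99)
  modes <- vapply(0:10, function(r)
    posteriorMode(selectionPosterior(r, 10 - r, 0.5)), numeric(1))
  expect_true(all(diff(modes) >= 0))
  flat <- selectionPosterior(c(0, 0), c(0, 0), 0.5)
  expect_false(flat@informative)
  expect_equal(sd(flat@density), 0)
})

test_that("posterior densities integrate to one and CIs bracket the mode", {
  set.seed(82)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    tot <- rpois(n, 6) + 1
    r <- rbinom(n, tot, 0.6)
    post <- selectionPosterior(r, tot - r, 0.6)
    h <- diff(post@grid[1:2])
    expect_lt(abs(sum(post@density) * h - 1), 1e-6)
    ci <- credibleInterval(post)
    expect_lte(ci[1], posteriorMode(post))
    expect_gte(ci[2], posteriorMode(post))
  }
})

test_that("group comparison separates opposite planted selection strengths", {
  set.seed(83)
  pr <- 0.7
  pi <- function(sig) pr * exp(sig) / (pr * exp(sig) + 1 - pr)
  tot <- rpois(100, 8) + 1
  a <- selectionPosterior(rbinom(100, tot, pi(1)), tot -
                            rbinom(100, tot, pi(1)), pr)  # noisy but positive
  totB <- rpois(100, 8) + 1
  rB <- rbinom(100, totB, pi(-1))
  b <- selectionPosterior(rB, totB - rB, pr)
  expect_gt(posteriorMean(a), 0)
  expect_lt(posteriorMean(b), 0)
  expect_lt(compareSelection(a, b), 0.01)
  expect_equal(compareSelection(a, a), 1)
})

mkLoadClone <- function(cloneId, rCdr, sCdr, sFwr) {
  germ <- germCodons()
  cod <- germ
  cdrSyn <- c(27:29, 31:38, 56:59, 61:65)
  for (k in seq_len(sCdr)) cod[cdrSyn[k]] <- "GGC"       # silent CDR
  if (rCdr >= 1) cod[30] <- "GCT"                        # replacement CDR
  if (rCdr >= 2) cod[60] <- "GTT"
  fwrSyn <- c(1:26, 39:55)
  for (k in seq_len(sFwr)) cod[fwrSyn[k]] <- "GGC"       # silent FWR
  out <- selRecord(paste0(cloneId, "_m"), cod)
  out$clone_id <- cloneId
  out
}

test_that("anti-monotone R/S vs load gives Spearman rho = -1", {
  recs <- do.call(rbind, lapply(1:12, function(i)
    mkLoadClone(paste0("c", i), rCdr = 1, sCdr = i, sFwr = 0)))
  res <- rsVsLoadCorrelation(recs)
  expect_equal(res$rho, -1)
  expect_lt(res$p, 0.05)
})

test_that("load driven by independent FWR mutations shows no correlation", {
  set.seed(84)
  hits <- 0
  for (run in 1:40) {
    recs <- do.call(rbind, lapply(1:15, function(i)
      mkLoadClone(paste0("c", i), rCdr = sample(1:2, 1),
                  sCdr = sample(1:2, 1), sFwr = sample(0:20, 1))))
    res <- rsVsLoadCorrelation(recs)
    if (res$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 30)
})

test_that("degenerate constant input is flagged", {
  recs <- do.call(rbind, lapply(1:12, function(i)
    mkLoadClone(paste0("c", i), rCdr = 1, sCdr = 1, sFwr = 0)))
  expect_warning(res <- rsVsLoadCorrelation(recs), "degenerate")
  expect_true(is.na(res$rho))
})

pwmRecords <- function(n, subject, edit = NULL, editFrac = 0) {
  gl <- airtraffic:::loadGermlines()
  germ <- paste0(gl$v[["IGHV1-S1*01"]], "TGTAAATGG")
  recs <- data.frame(sequence_id = paste0(subject, "_", seq_len(n)),
                     sequence_alignment = germ, v_call = "IGHV1-S1*01",
                     subject_id = subject, stringsAsFactors = FALSE)
  if (!is.null(edit) && editFrac > 0) {
    hit <- which(runif(n) < editFrac)
    for (i in hit) {
      a <- recs$sequence_alignment[i]
      substr(a, (edit$pos - 1) * 3 + 1, edit$pos * 3) <- edit$codon
      recs$sequence_alignment[i] <- a
    }
  }
  recs
}

test_that("identical groups give zero preference scores and no flags", {
  recs <- rbind(pwmRecords(40, "S01"), pwmRecords(40, "S02"),
                pwmRecords(40, "S03"))
  target <- rep(c(TRUE, FALSE), length.out = nrow(recs))
  pwms <- pwmAnalysis(recs, target, minObs = 10)
  expect_equal(names(pwms), "IGHV1-S1")
  pw <- pwms[[1]]
  expect_true(all(abs(pw@score[!is.na(pw@score)]) < 1e-9))
  expect_false(any(pw@significant, na.rm = TRUE))
})

test_that("gene usage rule is strictly greater than 2.5% in 3+ individuals", {
  base <- rbind(pwmRecords(39, "S01"), pwmRecords(39, "S02"),
                pwmRecords(39, "S03"))
  rare <- base[c(1, 40, 80), ]
  rare$v_call <- "IGHV2-S3*01"
  rare$sequence_id <- paste0("rare", 1:3)
  recs <- rbind(base, rare)  # rare gene at exactly 3/120 = 2.5% per subject
  gene <- airtraffic:::alleleToGene(recs$v_call)
  usage <- table(recs$subject_id, gene)
  expect_equal(unname(usage[, "IGHV2-S3"] / rowSums(usage)),
               rep(0.025, 3))
  pwms <- pwmAnalysis(recs, rep(c(TRUE, FALSE), length.out = nrow(recs)))
  expect_false("IGHV2-S3" %in% names(pwms))
})

test_that("a planted substitution preference is recovered as significant", {
  gl <- airtraffic:::loadGermlines()
  germCod <- substr(gl$v[["IGHV1-S1*01"]], 88, 90)  # codon 30 (CDR1)
  alt <- if (germCod == "GTT") "GCT" else "GTT"
  altAa <- airtraffic:::codonTable()[alt]
  hits <- 0
  for (run in 1:20) {
    set.seed(400 + run)
    tgt <- pwmRecords(60, "S01", edit = list(pos = 30, codon = alt),
                      editFrac = 0.6)
    bg <- pwmRecords(60, "S02")
    recs <- rbind(tgt, bg)
    pwms <- pwmAnalysis(recs, target = c(rep(TRUE, 60), rep(FALSE, 60)),
                        genes = "IGHV1-S1")
    pw <- pwms[[1]]
    if (isTRUE(pw@significant[30]) && pw@score[altAa, 30] > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})
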