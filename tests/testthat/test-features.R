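# Repertoire features: isotype fractions, overlap, global partition,
# IgD-only rules, CDR3 property oracles, PCA, gene usage and rank-sum
# comparisons.

featStub <- function(n, subject = "S01", tissue = "NBx", c_call = "IGHA1",
                     clone = "c1", seqs = NULL) {
  data.frame(sequence_id = paste(subject, tissue, clone, seq_len(n),
                                 sep = "_"),
             sequence_alignment = if (is.null(seqs))
               paste0("AAA", sprintf("%04d", seq_len(n))) else seqs,
             subject_id = subject, tissue = tissue, c_call = c_call,
             clone_id = clone, stringsAsFactors = FALSE)
}

test_that("isotype frequencies sum to one and recover planted composition", {
  one <- featStub(5, c_call = "IGHG1")
  f <- isotypeFrequencies(one)
  expect_equal(f$freq, 1)
  expect_equal(f$isotype, "IgG")

  cfg <- simulationConfig(seed = 91, nSubjects = 2, nClonesPerSubject = 300,
                          cloneSizeMax = 1, switchProb = 0,
                          rootIsotypeProbs = c(IGHM = 0.05, IGHD = 0,
                                               IGHG3 = 0, IGHG1 = 0.09,
                                               IGHA1 = 0.86, IGHG2 = 0,
                                               IGHG4 = 0, IGHE = 0,
                                               IGHA2 = 0),
                          igdOnlyFraction = 0)
  sim <- simulateRepertoire(cfg)
  f <- isotypeFrequencies(sim$records)
  sums <- tapply(f$freq, paste(f$subject_id, f$tissue), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  iga <- f$freq[f$isotype == "IgA"]
  n <- tapply(f$n, paste(f$subject_id, f$tissue), sum)
  expect_true(all(abs(iga - 0.86) < 3 * sqrt(0.86 * 0.14 / n) + 0.02))
})

test_that("clone overlap counts shared clones and identical sequences", {
  a <- featStub(3, tissue = "NBx", clone = "c1",
                seqs = c("AAA", "AAC", "AAG"))
  b <- featStub(2, tissue = "BBx", clone = "c1", seqs = c("AAA", "ATT"))
  c <- featStub(2, tissue = "PBMC", clone = "c9", seqs = c("CCC", "CCG"))
  ov <- cloneOverlap(rbind(a, b, c))
  expect_equal(ov$cloneCounts["NBx", "BBx"], 1)
  expect_equal(ov$cloneCounts["NBx", "PBMC"], 0)
  expect_equal(ov$seqCounts["NBx", "BBx"], 1)   # only "AAA" is shared
  expect_equal(unname(diag(ov$cloneCounts)), c(1, 1, 1))
  expect_equal(unname(diag(ov$seqCounts)), c(2, 3, 2))
  expect_true(isSymmetric(ov$cloneCounts))
  expect_equal(ov$multiway$nClones[ov$multiway$tissues == "BBx+NBx"], 1)
  expect_error(cloneOverlap(rbind(a, featStub(2, subject = "S02"))),
               "one subject")
})

test_that("multiway overlap equals ground-truth tissue sets per clone", {
  sim <- simulateRepertoire(simulationConfig(seed = 92, nSubjects = 1,
                                             nClonesPerSubject = 80))
  rec <- sim$records
  rec$clone_id <- sim$truth$clones$clone_id[match(rec$sequence_id,
                                                  sim$truth$clones$sequence_id)]
  ov <- cloneOverlap(rec)
  truthSig <- table(vapply(split(rec$tissue, rec$clone_id), function(ts)
    paste(sort(unique(ts)), collapse = "+"), character(1)))
  expect_equal(setNames(ov$multiway$nClones, ov$multiway$tissues),
               setNames(as.integer(truthSig), names(truthSig)))
})

test_that("global partition labels follow the clone tissue span", {
  nasal <- featStub(3, tissue = "NBx", clone = "cN")
  lab <- globalPartition(nasal)
  expect_true(all(lab == "NBx_NG"))

  mixed <- rbind(featStub(2, tissue = "NBx", clone = "cG"),
                 featStub(3, tissue = "BBx", clone = "cG"),
                 featStub(1, tissue = "PBMC", clone = "cG"))
  lab <- globalPartition(mixed)
  expect_equal(lab, c("NBx_G", "NBx_G", "BBx_G", "BBx_G", "BBx_G", NA))

  bloodOnly <- featStub(2, tissue = "PBMC", clone = "cP")
  expect_true(all(is.na(globalPartition(bloodOnly))))
})

test_that("IgD-only classification and the 20-sequence eligibility boundary", {
  igdOnly <- featStub(1, c_call = "IGHD", clone = "c1")
  withM <- rbind(featStub(1, c_call = "IGHD", clone = "c2"),
                 featStub(1, c_call = "IGHM", clone = "c2"))
  other <- featStub(2, c_call = "IGHA1", clone = "c3")
  recs <- rbind(igdOnly, withM, other)
  recs$sequence_id <- paste0("s", seq_len(nrow(recs)))
  recs$sequence_alignment <- paste0("AC", seq_len(nrow(recs)))
  res <- classifyIgdOnly(recs)
  expect_equal(res$flags, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  mk <- function(subject, nIgd) {
    rbind(featStub(nIgd, subject = subject, c_call = "IGHD",
                   clone = paste0(subject, "_igd"),
                   seqs = paste0("GG", seq_len(nIgd))),
          featStub(30, subject = subject, c_call = "IGHA1",
                   clone = paste0(subject, "_a"),
                   seqs = paste0("TT", 1:30)))
  }
  recs <- rbind(mk("S19", 19), mk("S20", 20))
  res <- classifyIgdOnly(recs)
  expect_false(res$eligible[["S19"]])
  expect_true(res$eligible[["S20"]])
})

test_that("CDR3 properties match independent table-lookup oracles", {
  # independent copies of the constants
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  set.seed(93)
  aas <- names(kd)
  for (i in 1:50) {
    pep <- paste(sample(aas, sample(5:20, 1), replace = TRUE), collapse = "")
    rec <- data.frame(sequence_id = "x",
                      junction_aa = paste0("C", pep, "W"), productive = TRUE)
    got <- cdr3Properties(rec)
    ch <- strsplit(pep, "")[[1]]
    expect_lt(abs(got$gravy - mean(kd[ch])), 1e-9)
    ali <- 100 * (mean(ch == "A") + 2.9 * mean(ch == "V") +
                    3.9 * (mean(ch == "I") + mean(ch == "L")))
    expect_lt(abs(got$aliphatic - ali), 1e-9)
    expect_equal(got$length, nchar(pep))
    expect_lt(abs(got$aromatic - mean(ch %in% c("F", "W", "Y", "H"))), 1e-9)
    expect_lt(abs(got$acidic - mean(ch %in% c("D", "E"))), 1e-9)
    expect_lt(abs(got$basic - mean(ch %in% c("K", "R", "H"))), 1e-9)
  }
})

test_that("properties are case-insensitive and reject ambiguous residues", {
  up <- cdr3Properties(data.frame(sequence_id = "u", junction_aa = "CGGGW",
                                  productive = TRUE))
  lo <- cdr3Properties(data.frame(sequence_id = "l", junction_aa = "cgggw",
                                  productive = TRUE))
  expect_equal(up$gravy, lo$gravy)
  amb <- cdr3Properties(data.frame(sequence_id = "a", junction_aa = "CGXGW",
                                   productive = TRUE))
  expect_true(is.na(amb$gravy))
})

test_that("PCA separates a planted long-hydrophobic group on PC1", {
  set.seed(94)
  hits <- 0
  for (run in 1:20) {
    hydro <- vapply(1:60, function(i) paste0("C", paste(
      sample(c("V", "I", "L", "F", "A"), 18, replace = TRUE),
      collapse = ""), "W"), character(1))
    polar <- vapply(1:60, function(i) paste0("C", paste(
      sample(c("S", "T", "N", "Q", "G", "D"), 11, replace = TRUE),
      collapse = ""), "W"), character(1))
    rec <- data.frame(sequence_id = paste0("s", 1:120),
                      junction_aa = c(hydro, polar), productive = TRUE)
    props <- cdr3Properties(rec)
    groups <- rep(c("hydro", "polar"), each = 60)
    pca <- propertyPca(props, groups)
    gap <- abs(pca$centroids["hydro", 1] - pca$centroids["polar", 1])
    spread <- sd(pca$scores[, 1])
    if (gap > spread) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # identical groups have coincident centroids
  rec <- data.frame(sequence_id = paste0("s", 1:40),
                    junction_aa = rep(c("CAILVW", "CSSTNW"), 20),
                    productive = TRUE)
  pca <- propertyPca(cdr3Properties(rec), rep(c("g1", "g2"), each = 20))
  expect_lt(max(abs(pca$centroids["g1", ] - pca$centroids["g2", ])), 1e-9)
})

test_that("gene usage rows sum to one and identical samples cluster at zero", {
  sim <- simulateRepertoire(simulationConfig(seed = 95, nSubjects = 3,
                                             nClonesPerSubject = 60))
  gu <- geneUsage(sim$records, "v")
  expect_true(all(abs(rowSums(gu$usage) - 1) < 1e-12))
  rec <- sim$records
  dup <- rec
  dup$tissue <- paste0(dup$tissue, "copy")
  both <- geneUsage(rbind(rec, dup), "v")
  d <- as.matrix(as.dist(1 - cor(t(both$usage))))
  expect_lt(d["S01:NBx", "S01:NBxcopy"], 1e-12)
})

test_that("rank-sum comparison matches the exact enumeration", {
  expect_equal(compareGroups(1:5, 6:10)$p, 2 / choose(10, 5))
  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_warning(tied <- compareGroups(rep(1, 4), rep(1, 4)), "tied")
  expect_equal(tied$p, 1)
  expect_error(compareGroups(1:2, 1:5), "at least 3")
})
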