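# Lineage trees: hand-worked parsimony examples, brute-force oracle
# equality, determinism, and SHM frequency computations.

test_that("a single mutated sequence gives a two-node tree with its distance", {
  germ <- paste0(strrep("GGC", 20), "TGTAAATGG")
  mut <- germ
  substr(mut, 4, 4) <- "A"
  substr(mut, 10, 10) <- "T"
  substr(mut, 16, 16) <- "T"
  rec <- data.frame(sequence_id = "s1", sequence_alignment = mut,
                    germline_alignment = germ, tissue = "NBx",
                    c_call = "IGHM")
  tr <- buildTree(rec, cloneId = "c1")
  expect_equal(parsimonyScore(tr), 3)
  expect_equal(length(treePhylo(tr)$tip.label), 2)
  expect_equal(sum(treePhylo(tr)$edge.length), 3)
})

test_that("nested mutations give the chain topology with unit branches", {
  germ <- paste0(strrep("GGC", 20), "TGTAAATGG")
  s1 <- germ
  substr(s1, 5, 5) <- "T"          # A -> T at position 5 (G -> T here)
  s2 <- s1
  substr(s2, 9, 9) <- "G"          # second mutation on top of the first
  rec <- data.frame(sequence_id = c("s1", "s2"),
                    sequence_alignment = c(s1, s2),
                    germline_alignment = germ, tissue = "NBx",
                    c_call = "IGHM")
  tr <- buildTree(rec, cloneId = "c1")
  expect_equal(parsimonyScore(tr), 2)
  d <- ape::cophenetic.phylo(treePhylo(tr))
  expect_equal(unname(d["Germline", "s1"]), 1)
  expect_equal(unname(d["s1", "s2"]), 1)
  expect_equal(unname(d["Germline", "s2"]), 2)
})

test_that("tree score equals the exhaustive parsimony minimum on random clones", {
  cfg <- simulationConfig(seed = 51, nSubjects = 2, nClonesPerSubject = 40,
                          cloneSizeExponent = 1.0, cloneSizeMax = 6,
                          shmRate = 0.02)
  sim <- simulateRepertoire(cfg)
  truth <- sim$truth$clones
  checked <- 0
  for (cid in unique(truth$clone_id)) {
    sub <- sim$records[sim$records$sequence_id %in%
                         truth$sequence_id[truth$clone_id == cid], ]
    if (length(unique(sub$sequence_alignment)) < 2) next
    tr <- buildTree(sub, germline = sim$truth$germlines[[cid]], cloneId = cid)
    key <- paste(sub$sequence_alignment, sub$tissue, sub$c_call)
    tips <- sub$sequence_alignment[!duplicated(key)]
    seqs <- c(Germline = sim$truth$germlines[[cid]],
              setNames(tips, paste0("t", seq_along(tips))))
    expect_equal(parsimonyScore(tr), bruteParsimonyMin(seqs))
    expect_equal(sum(treePhylo(tr)$edge.length), parsimonyScore(tr))
    checked <- checked + 1
    if (checked >= 30) break
  }
  expect_gte(checked, 20)
})

test_that("tree construction is invariant to input row order", {
  sim <- simulateRepertoire(simulationConfig(seed = 52, nSubjects = 1,
                                             nClonesPerSubject = 30,
                                             cloneSizeExponent = 1.0,
                                             cloneSizeMax = 8))
  truth <- sim$truth$clones
  big <- names(which.max(table(truth$clone_id)))
  sub <- sim$records[sim$records$sequence_id %in%
                       truth$sequence_id[truth$clone_id == big], ]
  a <- buildTree(sub, cloneId = big)
  set.seed(1)
  b <- buildTree(sub[sample(nrow(sub)), ], cloneId = big)
  expect_equal(parsimonyScore(a), parsimonyScore(b))
  expect_equal(sort(ape::cophenetic.phylo(treePhylo(a))["Germline", ]),
               sort(ape::cophenetic.phylo(treePhylo(b))["Germline", ]))
})

test_that("germline is never internalized", {
  sim <- simulateRepertoire(simulationConfig(seed = 53, nSubjects = 1,
                                             nClonesPerSubject = 20,
                                             cloneSizeExponent = 1.0,
                                             cloneSizeMax = 10))
  trees <- buildTrees(assignClones(sim$records, 0.15))
  for (tr in trees) {
    phy <- treePhylo(tr)
    expect_true("Germline" %in% phy$tip.label)
    expect_true(ape::is.rooted(phy))
  }
})

test_that("mutation frequency is mismatches over comparable positions", {
  germ <- strrep("ACGT", 75)  # 300 nt
  s <- germ
  substr(s, 1, 1) <- "G"
  substr(s, 101, 101) <- "C"
  substr(s, 201, 201) <- "T"
  rec <- data.frame(sequence_alignment = c(germ, s),
                    germline_alignment = germ)
  expect_equal(mutationFrequency(rec), c(0, 0.01))
})

test_that("clone mean SHM matches the ground-truth branch expectation", {
  cfg <- simulationConfig(seed = 54, nSubjects = 1, nClonesPerSubject = 60,
                          shmRate = 0.003, cloneSizeExponent = 1.0,
                          cloneSizeMax = 12)
  sim <- simulateRepertoire(cfg)
  freq <- mutationFrequency(sim$records)
  for (cid in utils::head(names(sim$truth$trees), 30)) {
    tr <- sim$truth$trees[[cid]]
    if (nrow(tr) < 4) next
    nSites <- sum(!strsplit(sim$truth$germlines[[cid]], "")[[1]] %in% ".")
    pathMut <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr)))
      pathMut[i] <- tr$nMut[i] + if (tr$parent[i] > 0) pathMut[tr$parent[i]] else 0
    obs <- freq[match(tr$sequence_id, sim$records$sequence_id)] * nSites
    # back-mutations/overwrites can only lower the observed count, slightly
    expect_true(all(obs <= pathMut + 1e-9))
    expect_lt(mean(pathMut - obs), 1.5)
  }
})

test_that("SHM aggregation follows the clone -> isotype -> individual hierarchy", {
  germ <- strrep("ACGT", 25)  # 100 nt
  mk <- function(id, nmut, clone, iso) {
    s <- germ
    for (k in seq_len(nmut)) substr(s, k * 4 - 3, k * 4 - 3) <- "C"
    data.frame(sequence_id = id, sequence_alignment = s,
               germline_alignment = germ, clone_id = clone, c_call = iso,
               subject_id = "S01", tissue = "NBx")
  }
  rec <- rbind(mk("a", 2, "c1", "IGHM"), mk("b", 4, "c1", "IGHM"),
               mk("c", 8, "c2", "IGHM"))
  agg <- aggregateShm(rec)
  # clone means 0.03 and 0.08, isotype mean = 0.055 (not the pooled 0.0467)
  expect_equal(agg$shm, 0.055)
  expect_equal(agg$nClones, 2)
})
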