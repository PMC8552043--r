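# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and phangorn's scorers): parsimony scores come
# from a hand-written Hartigan/Fitch, minimum transition counts from
# exhaustive enumeration, window mismatches from an all-windows scan, and
# clone clustering from BFS connected components.

BASES <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# Bitmask encoding of aligned sequences; gaps/N match anything.
seqBits <- function(seqs) {
  mat <- t(vapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    code <- BASES[ch]
    code[is.na(code)] <- 15L
    code
  }, integer(nchar(seqs[[1]]))))
  rownames(mat) <- names(seqs)
  mat
}

# Exact parsimony length of a (possibly multifurcating) tree by Hartigan's
# generalization of Fitch, vectorized over sites.
hartiganScore <- function(phy, bits) {
  nTips <- length(phy$tip.label)
  total <- nTips + phy$Nnode
  children <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = 1:total))
  changes <- 0L
  rec <- function(v) {
    if (v <= nTips) return(bits[phy$tip.label[v], ])
    sets <- lapply(children[[v]], rec)
    k <- length(sets)
    nS <- length(sets[[1]])
    cnt <- matrix(0L, nS, 4)
    for (s in sets) for (b in 1:4)
      cnt[, b] <- cnt[, b] + as.integer(bitwAnd(s, 2^(b - 1)) > 0)
    m <- pmax(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
    newset <- integer(nS)
    for (b in 1:4) newset <- newset + as.integer(cnt[, b] == m) * 2^(b - 1)
    changes <<- changes + sum(k - m)
    as.integer(newset)
  }
  rec(nTips + 1L)
  changes
}

# Global parsimony minimum by scoring every unrooted topology.
bruteParsimonyMin <- function(seqs) {
  bits <- seqBits(seqs)
  common <- Reduce(bitwAnd, lapply(seq_len(nrow(bits)), function(i) bits[i, ]))
  keep <- which(common == 0L)
  if (!length(keep)) return(0L)
  bits <- bits[, keep, drop = FALSE]
  n <- length(seqs)
  if (n == 2L) {
    both <- bitwAnd(bits[1, ], bits[2, ])
    return(sum(both == 0L))
  }
  topo <- phangorn::allTrees(n, rooted = FALSE, tip.label = names(seqs))
  min(vapply(topo, hartiganScore, integer(1), bits = bits))
}

# Exhaustive minimum transition count: tips constrained, all other nodes
# (internal + root) free. states: integer 1..S for tips, NA otherwise.
bruteSankoffMin <- function(edge, states, S) {
  free <- which(is.na(states))
  if (!length(free)) {
    return(sum(states[edge[, 1]] != states[edge[, 2]]))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(free))))
  best <- Inf
  st <- states
  for (i in seq_len(nrow(grid))) {
    st[free] <- grid[i, ]
    best <- min(best, sum(st[edge[, 1]] != st[edge[, 2]]))
  }
  best
}

# Densest-window mismatch count by scanning every window.
bruteWindowMax <- function(s, g, width = 10L) {
  x <- strsplit(s, "")[[1]]
  y <- strsplit(g, "")[[1]]
  keep <- !(x %in% c(".", "-")) & !(y %in% c(".", "-"))
  mm <- as.integer(x[keep] != y[keep])
  n <- length(mm)
  if (n == 0L) return(0L)
  if (n <= width) return(sum(mm))
  max(vapply(seq_len(n - width + 1L), function(i)
    sum(mm[i:(i + width - 1L)]), integer(1)))
}

# Single-linkage components by explicit O(n^2) graph + BFS.
bruteLinkComponents <- function(junctions, t) {
  n <- length(junctions)
  L <- nchar(junctions[1])
  m <- do.call(rbind, strsplit(junctions, ""))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- sum(m[i, ] != m[j, ]) / L <= t
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# sankoffTree from a parent vector (0 = unconstrained germline root) and
# per-node tissue labels.
makeSankoff <- function(parent, tissue) {
  k <- length(parent)
  edge <- cbind(parent + 1L, seq_len(k) + 1L)
  edge <- edge[order(edge[, 2L], decreasing = TRUE), , drop = FALSE]
  structure(list(nNodes = k + 1L, edge = edge,
                 tissue = c(NA_character_, tissue)),
            class = "sankoffTree")
}

# Random junction of given codon count, stop-free, as used for fixtures.
randomJunction <- function(nCodons) {
  stops <- c("TAA", "TAG", "TGA")
  mid <- replicate(nCodons - 2L, {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!cd %in% stops) return(cd)
    }
  })
  paste0("TGT", paste(mid, collapse = ""), "TGG")
}

# Shared default-cohort pipeline run (used by several acceptance checks).
.runCache <- new.env(parent = emptyenv())
defaultPipelineRun <- function(seed = 301L) {
  key <- as.character(seed)
  if (is.null(.runCache[[key]])) {
    dir <- file.path(tempdir(), paste0("accept_run_", seed))
    cfg <- pipelineConfig(seed = seed, outDir = dir)
    .runCache[[key]] <- list(report = runPipeline(cfg), dir = dir, cfg = cfg)
  }
  .runCache[[key]]
}
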