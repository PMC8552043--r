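# End-to-end pipeline: simulate -> filter -> cluster -> trees ->
# trafficking -> diversity -> selection -> features, with one global seed,
# per-stage accounting and a machine-readable report.

#' Build a pipeline configuration
#'
#' All stage seeds derive deterministically from the single global `seed`.
#' The default simulation is the package's standard synthetic cohort (two
#' groups of five subjects) with small planted QC-artifact rates so the
#' filter stage has work to do.
#'
#' @param seed global integer seed.
#' @param outDir output directory.
#' @param simulation a [SimulationConfig-class]; its seed is re-derived from
#'   `seed`. `NULL` uses the default cohort.
#' @param input optional AIRR TSV path; replaces the simulate stage.
#' @param threshold clonal clustering threshold or `"auto"`.
#' @param nPerm,permR trafficking permutations and tie resolutions.
#' @param qGrid,resamples diversity orders and resamples per sample.
#' @param sigmaGrid selection-strength grid.
#' @param minDepth minimum sample depth entering diversity profiles.
#' @param stages character vector of enabled stages, in dependency order.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("airtraffic_run_"),
                           simulation = NULL, input = NULL,
                           threshold = "auto", nPerm = 100L, permR = 20L,
                           qGrid = seq(0, 4, by = 0.5), resamples = 100L,
                           sigmaGrid = seq(-8, 8, by = 0.02), minDepth = 10L,
                           stages = c("simulate", "filter", "cluster",
                                      "trees", "trafficking", "diversity",
                                      "selection", "features")) {
  seed <- as.integer(seed)
  if (is.null(simulation))
    simulation <- simulationConfig(
      seed = seed + 1000L,
      readArtifactRates = c(phix = 0.01, c_region = 0.01, window = 0.01,
                            singleton = 0.03, stop = 0.01))
  else
    simulation@seed <- seed + 1000L
  structure(list(seed = seed, outDir = outDir, simulation = simulation,
                 input = input, threshold = threshold,
                 nPerm = as.integer(nPerm), permR = as.integer(permR),
                 qGrid = qGrid, resamples = as.integer(resamples),
                 sigmaGrid = sigmaGrid, minDepth = as.integer(minDepth),
                 stages = stages),
            class = "pipelineConfig")
}

.stageSeed <- function(config, k) (config$seed + 1000L * k) %% 2147483647L

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes stage outputs
#' (AIRR TSVs, Newick trees, TSV/JSON summaries) under `config$outDir`, and
#' returns a nested report. The run is fully determined by the global seed:
#' two runs with the same configuration produce byte-identical
#' `report.json` files. A stage failure aborts with the stage name; outputs
#' of completed stages are retained.
#'
#' @param config a [pipelineConfig()] list.
#' @return the report, invisibly also written to
#'   `file.path(config$outDir, "report.json")`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = config$stages)
  env <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report[[name]] <<- res
    invisible(NULL)
  }

  stage("simulate", function() {
    if (!is.null(config$input)) {
      env$records <- readAirr(config$input)
      env$truth <- NULL
      return(list(source = "input", nRecords = nrow(env$records)))
    }
    sim <- simulateRepertoire(config$simulation)
    env$records <- sim$records
    env$truth <- sim$truth
    writeAirr(sim$records, file.path(config$outDir, "simulated.tsv"))
    write.table(sim$truth$clones, file.path(config$outDir, "truth_clones.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(source = "simulated", nRecords = nrow(sim$records),
         nClonesTrue = length(unique(sim$truth$clones$clone_id)),
         nViolationsPlanted = nrow(sim$truth$violations))
  })

  if (is.null(env$records)) {
    if (is.null(config$input)) stop("no input and simulate stage disabled")
    env$records <- readAirr(config$input)
  }

  stage("filter", function() {
    res <- applyFilters(env$records)
    env$records <- res$kept
    writeAirr(res$kept, file.path(config$outDir, "filtered.tsv"))
    list(input = res$report@input, kept = res$report@output,
         removed = as.list(res$report@removed))
  })

  stage("cluster", function() {
    withSeed(.stageSeed(config, 2L), {
      env$records <- assignClones(env$records, config$threshold)
    })
    writeAirr(env$records, file.path(config$outDir, "cloned.tsv"))
    nPerSample <- aggregate(
      list(nClones = env$records$clone_id),
      by = env$records[c("subject_id", "tissue")],
      FUN = function(x) length(unique(x[!is.na(x)])))
    list(threshold = attr(env$records, "threshold"),
         nClones = length(unique(na.omit(env$records$clone_id))),
         clonesPerSample = nPerSample)
  })

  stage("trees", function() {
    recs <- env$records
    tisRecs <- recs[tissueClass(recs$tissue) %in% c("nasal", "bronchial"), ,
                    drop = FALSE]
    pick <- function(df) {
      tab <- tapply(df$tissue, df$clone_id, function(x) length(unique(x)))
      sz <- tapply(df$sequence_id, df$clone_id, length)
      names(tab)[tab >= 2 & sz >= 3]
    }
    withSeed(.stageSeed(config, 3L), {
      env$treesTissue <- buildTrees(tisRecs, cloneIds = pick(tisRecs))
      env$treesAll <- buildTrees(recs, cloneIds = pick(recs))
    })
    exportTrees(env$treesTissue, file.path(config$outDir, "trees"))
    list(nTreesTissue = length(env$treesTissue),
         nTreesAll = length(env$treesAll),
         meanScore = if (length(env$treesTissue))
           mean(vapply(env$treesTissue, parsimonyScore, numeric(1))) else NA)
  })

  stage("trafficking", function() {
    run <- function(trees, k) withSeed(.stageSeed(config, k), {
      permutationTest(trees, nPerm = config$nPerm, R = config$permR)
    })
    env$traffickingTissue <- run(env$treesTissue, 4L)
    env$traffickingAll <- run(env$treesAll, 5L)
    summarise <- function(res) {
      if (!res@testable) return(list(testable = FALSE))
      dir <- list()
      for (a in res@tissues) for (b in res@tissues) if (a != b)
        dir[[paste(a, b, sep = "->")]] <- list(
          observed = res@observedProp[a, b],
          nullMean = mean(res@nullProp[, paste(a, b, sep = "->")]),
          p = res@pvalues[a, b])
      list(testable = TRUE, nTrees = res@nTrees,
           observedTotalMean = res@observedTotalMean,
           nullTotalMean = mean(res@nullTotalMean), pTotal = res@pTotal,
           directions = dir)
    }
    list(tissuesOnly = summarise(env$traffickingTissue),
         allCompartments = summarise(env$traffickingAll))
  })

  stage("diversity", function() {
    recs <- env$records
    recs$sample <- paste(recs$subject_id, recs$tissue, sep = ":")
    ab <- lapply(split(recs, recs$sample), cloneAbundance)
    depths <- vapply(ab, sum, numeric(1))
    ab <- ab[depths >= config$minDepth]
    m <- min(vapply(ab, sum, numeric(1)))
    profiles <- withSeed(.stageSeed(config, 6L), {
      lapply(names(ab), function(s)
        resampledProfile(ab[[s]], q = config$qGrid, m = m,
                         B = config$resamples, sample = s))
    })
    tab <- do.call(rbind, lapply(profiles, profileTable))
    write.table(tab, file.path(config$outDir, "diversity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    shannon <- vapply(profiles, function(p)
      p@mean[which.min(abs(p@q - 1))], numeric(1))
    names(shannon) <- names(ab)
    list(commonDepth = m, nSamples = length(ab),
         shannon = as.list(round(shannon, 4)))
  })

  stage("selection", function() {
    recs <- .dedupeSeqs(env$records)
    recs$isotype <- isotypeClass(recs$c_call)
    counts <- countRsMutations(recs)
    counts$isotype <- recs$isotype[match(counts$sequence_id,
                                         recs$sequence_id)]
    counts$germ <- recs$germline_alignment[match(counts$sequence_id,
                                                 recs$sequence_id)]
    getPr <- function(germ, region) {
      key <- paste(region, germ)
      if (is.null(env$prCache)) env$prCache <- new.env(parent = emptyenv())
      if (is.null(env$prCache[[key]]))
        env$prCache[[key]] <- expectedReplacementFraction(germ, region)
      env$prCache[[key]]
    }
    out <- list()
    for (iso in sort(unique(counts$isotype))) {
      sub <- counts[counts$isotype == iso, , drop = FALSE]
      if (nrow(sub) < 5L) next
      for (region in c("CDR", "FWR")) {
        r <- if (region == "CDR") sub$r_cdr else sub$r_fwr
        s <- if (region == "CDR") sub$s_cdr else sub$s_fwr
        pr <- vapply(sub$germ, getPr, numeric(1), region = region,
                     USE.NAMES = FALSE)
        post <- selectionPosterior(round(r), round(s), pr,
                                   grid = config$sigmaGrid,
                                   region = region, group = iso)
        ci <- credibleInterval(post)
        out[[paste(iso, region, sep = "_")]] <- list(
          n = post@nSeq, mode = posteriorMode(post),
          mean = posteriorMean(post), ciLower = unname(ci[1]),
          ciUpper = unname(ci[2]), informative = post@informative)
      }
    }
    rsl <- tryCatch(rsVsLoadCorrelation(env$records),
                    error = function(e) list(rho = NA, p = NA, nClones = 0))
    list(posteriors = out, rsVsLoad = rsl)
  })

  stage("features", function() {
    recs <- env$records
    isoFreq <- isotypeFrequencies(recs)
    write.table(isoFreq, file.path(config$outDir, "isotype_frequencies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    part <- globalPartition(recs)
    igd <- classifyIgdOnly(recs)
    uj <- .dedupeSeqs(recs)
    uj$igdOnly <- igd$flags[match(uj$sequence_id, recs$sequence_id)]
    uj$j6 <- alleleToGene(uj$j_call) == "IGHJ6"
    byS <- split(uj, uj$subject_id)
    j6igd <- vapply(byS, function(d)
      if (any(d$igdOnly)) mean(d$j6[d$igdOnly]) else NA_real_, numeric(1))
    j6other <- vapply(byS, function(d) mean(d$j6[!d$igdOnly]), numeric(1))
    eligible <- names(which(igd$eligible))
    cdrlenIgd <- vapply(byS, function(d)
      mean(nchar(d$junction_aa[d$igdOnly]) - 2), numeric(1))
    cdrlenIgm <- vapply(byS, function(d)
      mean(nchar(d$junction_aa[isotypeClass(d$c_call) == "IgM"]) - 2),
      numeric(1))
    shmSeq <- mutationFrequency(uj)
    shmIgd <- vapply(byS, function(d)
      mean(shmSeq[match(d$sequence_id[d$igdOnly], uj$sequence_id)]),
      numeric(1))
    shmOther <- vapply(byS, function(d)
      mean(shmSeq[match(d$sequence_id[!d$igdOnly], uj$sequence_id)]),
      numeric(1))
    ok <- names(byS) %in% eligible
    ct <- function(a, b) {
      a <- a[ok & !is.na(a)]
      b <- b[ok & !is.na(b)]
      if (length(a) >= 3 && length(b) >= 3) compareGroups(a, b)$p
      else NA_real_
    }
    list(
      isotypeMeans = as.list(round(tapply(isoFreq$freq,
        paste(tissueClass(isoFreq$tissue), isoFreq$isotype), mean), 4)),
      partitionCounts = as.list(table(part)),
      igdOnlyFreqMean = mean(igd$bySample$freq),
      igdOnlyEligibleSubjects = length(eligible),
      ighj6UsageIgdOnly = mean(j6igd[ok], na.rm = TRUE),
      ighj6UsageOther = mean(j6other[ok], na.rm = TRUE),
      pIghj6 = ct(j6igd, j6other),
      cdr3LenIgdOnly = mean(cdrlenIgd[ok], na.rm = TRUE),
      cdr3LenIgm = mean(cdrlenIgm[ok], na.rm = TRUE),
      pCdr3Len = ct(cdrlenIgd, cdrlenIgm),
      shmIgdOnly = mean(shmIgd[ok], na.rm = TRUE),
      shmOther = mean(shmOther[ok], na.rm = TRUE),
      pShm = ct(shmIgd, shmOther))
  })

  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
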