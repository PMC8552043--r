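# Internal constants: IGHC locus order, IMGT region boundaries, codon tools.

# 5' -> 3' order of the human IGHC gene segments; class-switch recombination
# deletes intervening segments, so switching only ever moves rightwards.
IGHC_ORDER <- c("IGHM", "IGHD", "IGHG3", "IGHG1", "IGHA1",
                "IGHG2", "IGHG4", "IGHE", "IGHA2")

# Coarse isotype classes used for per-isotype summaries.
ISOTYPE_CLASS <- c(IGHM = "IgM", IGHD = "IgD", IGHG3 = "IgG", IGHG1 = "IgG",
                   IGHA1 = "IgA", IGHG2 = "IgG", IGHG4 = "IgG", IGHE = "IgE",
                   IGHA2 = "IgA")

# IMGT unique-numbering region boundaries (codon positions within the
# V region, which occupies alignment columns 1..312 = codons 1..104).
IMGT_REGIONS <- list(
  FWR1 = 1:26, CDR1 = 27:38, FWR2 = 39:55, CDR2 = 56:65, FWR3 = 66:104
)
IMGT_V_CODONS <- 104L
IMGT_V_COLS <- 312L
# The junction starts at the 2nd-CYS codon (IMGT codon 104).
JUNCTION_START_COL <- 310L

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Required columns of an AIRR Rearrangement table as consumed here.
AIRR_REQUIRED <- c(
  "sequence_id", "sequence", "sequence_alignment", "germline_alignment",
  "v_call", "d_call", "j_call", "c_call", "junction", "junction_aa",
  "productive", "duplicate_count", "consensus_count",
  "subject_id", "tissue", "group"
)
# Optional columns carried through when present.
AIRR_OPTIONAL <- c("phix", "c_region_mismatches", "clone_id")

codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(ifelse(as.character(gc) == "*", "*", as.character(gc)), names(gc))
}

# Translate an in-frame nucleotide string; gap-only codons ("...") dropped,
# codons containing N or partial gaps give "X".
translateNt <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  cods <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  cods <- cods[cods != "..." & cods != "---"]
  if (!length(cods)) return("")
  tab <- codonTable()
  aa <- tab[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

isGapChar <- function(x) x == "." | x == "-"

seqToChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Tissue classing: labels beginning NBx are nasal, BBx bronchial, PBMC blood.
tissueClass <- function(tissue) {
  ifelse(grepl("^NBx", tissue), "nasal",
         ifelse(grepl("^BBx", tissue), "bronchial",
                ifelse(grepl("^PBMC", tissue), "blood", "other")))
}

isotypeClass <- function(c_call) {
  cls <- ISOTYPE_CLASS[c_call]
  unname(ifelse(is.na(cls), "other", cls))
}

# Amino-acid property constants (shipped as a plain-text table).
aaProperties <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "aa_properties.tsv", package = "airtraffic")
      tab <- read.delim(path, stringsAsFactors = FALSE)
      rownames(tab) <- tab$aa
      cache <<- tab
    }
    cache
  }
})

# Gene from an allele call: strip the "*NN" allele suffix; ambiguous
# multi-gene calls keep the first listed gene.
alleleToGene <- function(call) {
  first <- sub(",.*$", "", call)
  sub("\\*.*$", "", first)
}

# Restore the caller's RNG state on exit; used by every seeded operation so
# that simulation seeds do not perturb the session RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
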