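# Hill-number diversity profiles with resampling to common depth, and
# rarefaction curves. Abundances are unique-sequence counts per clone.

#' Hill diversity of order q
#'
#' \eqn{^qD = (\sum_i p_i^q)^{1/(1-q)}}, with the q = 1 limit
#' \eqn{\exp(-\sum_i p_i \log p_i)} (the exponential of Shannon entropy).
#' q = 0 gives richness, q = 2 the inverse Simpson index.
#'
#' @param p probability vector (non-negative, summing to 1 within 1e-9).
#' @param q diversity order (scalar or vector).
#' @return numeric vector of Hill numbers, one per order.
#' @examples
#' hillNumber(rep(1 / 5, 5), q = c(0, 1, 2))  # uniform: all equal 5
#' hillNumber(c(0.9, 0.1), 2)                 # 1 / (0.81 + 0.01)
#' @export
hillNumber <- function(p, q) {
  if (any(p < 0)) stop("p must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("p must sum to 1")
  p <- p[p > 0]
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-12) exp(-sum(p * log(p)))
    else sum(p^qi)^(1 / (1 - qi))
  }, numeric(1))
}

#' Clone abundance vector of a sample
#'
#' Unique-sequence counts per clone (duplicate `sequence_alignment`s within
#' a clone collapse to one).
#'
#' @param records records of one sample, with `clone_id`.
#' @return named integer vector of abundances (sum = sample depth).
#' @export
cloneAbundance <- function(records) {
  recs <- records[!is.na(records$clone_id), , drop = FALSE]
  key <- !duplicated(paste(recs$clone_id, recs$sequence_alignment, sep = "\r"))
  tab <- table(recs$clone_id[key])
  setNames(as.integer(tab), names(tab))
}

#' Depth-corrected Hill diversity profile
#'
#' Draws `B` subsamples of `m` sequences without replacement from the
#' sample's clone-labelled sequences, computes the Hill profile of each,
#' and summarises by the mean and the 2.5/97.5 percentile band. Resampling
#' to a common `m` makes profiles comparable across samples of different
#' sequencing depth.
#'
#' @param abundance clone abundance vector (see [cloneAbundance()]).
#' @param q grid of diversity orders (default 0 to 4 by 0.1).
#' @param m subsampling depth; must not exceed the sample depth.
#' @param B number of resamples (default 200).
#' @param sample sample label carried on the profile.
#' @return a [DiversityProfile-class].
#' @export
resampledProfile <- function(abundance, q = seq(0, 4, by = 0.1),
                             m = sum(abundance), B = 200L,
                             sample = "sample") {
  depth <- sum(abundance)
  if (m > depth) stop("m exceeds sample depth")
  if (B < 1L) stop("B must be >= 1")
  units <- rep(seq_along(abundance), abundance)
  prof <- matrix(0, nrow = B, ncol = length(q))
  for (b in seq_len(B)) {
    sub <- if (m == depth && B == 1L) units else sample(units, m)
    tab <- tabulate(sub)
    prof[b, ] <- hillNumber(tab[tab > 0] / m, q)
  }
  new("DiversityProfile", q = q, mean = colMeans(prof),
      lo = apply(prof, 2, quantile, 0.025, names = FALSE),
      hi = apply(prof, 2, quantile, 0.975, names = FALSE),
      depth = as.integer(m), resamples = as.integer(B), sample = sample)
}

#' Rarefaction curve of clone richness
#'
#' Mean number of distinct clones observed in random subsamples at each
#' depth of `depths`.
#'
#' @param abundance clone abundance vector.
#' @param depths subsampling depths (all at most the sample depth).
#' @param B resamples per depth.
#' @return data.frame `depth`, `richness`.
#' @export
rarefactionCurve <- function(abundance, depths, B = 100L) {
  total <- sum(abundance)
  if (any(depths > total)) stop("depths exceed sample depth")
  units <- rep(seq_along(abundance), abundance)
  rich <- vapply(depths, function(m) {
    mean(vapply(seq_len(B), function(b)
      length(unique(sample(units, m))), numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, richness = rich)
}
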