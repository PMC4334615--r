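# Monte Carlo empirical null of the (mean ratio, CV) pair, empirical
# probabilities, FDR selection and replication shortlisting.

.ratioPairs <- function(Fq, epsilon, cvDenominator) {
  Fq <- clampFrequency(Fq, epsilon)
  R <- fourRatios(Fq[, 1L], Fq[, 2L], Fq[, 3L], Fq[, 4L])
  meanCV(R, cvDenominator)
}

# self-inclusive joint-tail counts of all pairs against the whole sample;
# points with mean >= 1 are scored in the upper regime, others in the lower.
.selfScores <- function(m, cv) {
  up <- m >= 1
  s <- integer(length(m))
  if (any(up)) s[up] <- .quadrantSelfCounts(m[up], cv[up], TRUE)
  if (any(!up)) s[!up] <- .quadrantSelfCounts(m[!up], cv[!up], FALSE)
  s
}

#' Simulate the Monte Carlo null of the (mean, CV) ratio statistic
#'
#' Builds an artificial chromosome: for each of \code{nSnps * nReps}
#' simulated SNPs, four null pool frequencies (two "case", two "control")
#' are drawn, clamped with the same epsilon as the real pipeline, and turned
#' into the mean and coefficient of variation of the four case/control
#' ratios.  Three null frequency models are available:
#' \describe{
#'   \item{uniform}{independent Uniform(0, 1) frequencies (default).}
#'   \item{empirical}{resamples the observed pool frequencies passed in
#'     \code{observed} (independently for the four slots).}
#'   \item{matched}{parametric null matching the synthetic-cohort design: a
#'     population frequency is drawn from the configured MAF spectrum, the
#'     four pool frequencies are binomial allele counts of \code{poolSize}
#'     individuals, and each passes through the same probe-noise and
#'     allelotyping path as the real data.  This preserves the per-SNP
#'     coupling of the four frequencies and is the null used for type-I
#'     calibration checks.}
#' }
#'
#' @param nSnps simulated SNPs per replicate (e.g. the chip's SNP count for
#'   one chromosome).
#' @param nReps number of replicates (default 1000).
#' @param seed integer seed.
#' @param chromosome label stored with the null.
#' @param epsilon frequency clamp, identical to the analysis pipeline's.
#' @param mode null frequency model, see Details.
#' @param observed numeric vector of observed pool frequencies
#'   (\code{mode = "empirical"}).
#' @param config a \code{\link{CohortConfig}} (\code{mode = "matched"}).
#' @param noise optional \code{\link{NoiseModel}} for \code{mode =
#'   "matched"}; defaults to the config's.
#' @param cvDenominator see \code{\link{meanCV}}.
#' @return a \code{\linkS4class{RatioNull}}.
#' @examples
#' null <- simulateNull(nSnps = 100, nReps = 10, seed = 1)
#' null
#' @export
simulateNull <- function(nSnps, nReps = 1000L, seed = 1L,
                         chromosome = "chr1", epsilon = 1e-4,
                         mode = c("uniform", "empirical", "matched"),
                         observed = NULL, config = NULL, noise = NULL,
                         cvDenominator = c("sample", "population")) {
  mode <- match.arg(mode)
  cvDenominator <- match.arg(cvDenominator)
  stopifnot(nSnps >= 1L, nReps >= 1L)
  N <- as.integer(nSnps) * as.integer(nReps)
  set.seed(.deriveSeed(seed, 401L))
  Fq <- switch(mode,
    uniform = matrix(stats::runif(4L * N), ncol = 4L),
    empirical = {
      if (is.null(observed) || !length(observed))
        stop("mode 'empirical' needs observed pool frequencies")
      matrix(sample(observed, 4L * N, replace = TRUE), ncol = 4L)
    },
    matched = {
      if (is.null(config)) stop("mode 'matched' needs a CohortConfig")
      if (is.null(noise)) noise <- config@noise
      p <- stats::runif(N, config@mafLow, config@mafHigh)
      # mirror the generator's arbitrary A/B designation: half the SNPs
      # carry the minor allele as B
      p <- ifelse(stats::runif(N) < 0.5, 1 - p, p)
      true <- matrix(stats::rbinom(4L * N, 2L * config@poolSize, rep(p, 4L)) /
                       (2 * config@poolSize), ncol = 4L)
      est <- matrix(.noisyFrequency(as.vector(true), noise), ncol = 4L)
      est[is.na(est)] <- 0    # non-callable cannot occur with a floor > 0
      est
    })
  mc <- .ratioPairs(Fq, epsilon, cvDenominator)
  scores <- .selfScores(mc$mean_R, mc$cv_R)
  new("RatioNull", chromosome = chromosome, nSnps = as.integer(nSnps),
      nReps = as.integer(nReps), mean = mc$mean_R, cv = mc$cv_R,
      scores = scores, scoresSorted = sort(scores), epsilon = epsilon,
      mode = mode, seed = as.integer(seed))
}

#' Empirical probability of a (mean, CV) pair under the Monte Carlo null
#'
#' The extremeness of an observed pair is its joint-tail count: the number
#' of null pairs whose mean is at least as extreme (at least as large when
#' the observed mean is >= 1, at most as small otherwise) and whose CV does
#' not exceed the observed CV -- large consistent frequency shifts in either
#' direction count as extreme, noisy ones do not.
#'
#' With \code{method = "calibrated"} (default) the reported probability is
#' the add-one-corrected fraction of null pairs whose own joint-tail count
#' is at most the observed count.  This is a monotone transform of the raw
#' count (the SNP ranking is identical) and is uniformly distributed for a
#' draw from the null, so a cut at 0.05 has an actual null exceedance rate
#' of 5\%.  \code{method = "raw"} reports the add-one-corrected joint-tail
#' mass itself, which preserves the historical definition but is not
#' uniform under the null.  Both methods share the floor
#' \code{1 / (1 + nSnps * nReps)}.
#'
#' @param meanObs,cvObs observed mean(s) and CV(s), vectorized.
#' @param null a \code{\linkS4class{RatioNull}}.
#' @param method "calibrated" (default) or "raw".
#' @return vector of probabilities in (0, 1].
#' @examples
#' null <- simulateNull(nSnps = 200, nReps = 50, seed = 1)
#' empiricalP(25, 0.1, null)
#' @export
empiricalP <- function(meanObs, cvObs, null,
                       method = c("calibrated", "raw")) {
  method <- match.arg(method)
  stopifnot(is(null, "RatioNull"), length(meanObs) == length(cvObs))
  N <- length(null@mean)
  if (!N) stop("empty null distribution")
  cnt <- .quadrantQueryCounts(as.numeric(meanObs), as.numeric(cvObs),
                              null@mean, null@cv)
  if (method == "raw")
    return((1 + cnt) / (1 + N))
  (1 + findInterval(cnt, null@scoresSorted)) / (1 + N)
}

# fraction of the null's own pairs that would pass pre-selection and the
# empirical-probability cut: the null tail rate the observed pipeline's
# type-I rate is compared against.
#' Null tail rate of the combined pre-selection + empirical-probability cut
#'
#' Fraction of the null distribution's own pairs that pass the two-sided
#' fold-change pre-selection and have (self-)calibrated empirical
#' probability below \code{alpha}.  On a fully null cohort generated under
#' the same frequency model, the discovery pipeline's fraction of SNPs
#' passing both cuts matches this rate up to binomial error.
#'
#' @param null a \code{\linkS4class{RatioNull}}.
#' @param threshold pre-selection fold-change threshold.
#' @param alpha empirical-probability cut.
#' @return a single rate in [0, 1].
#' @export
nullTailRate <- function(null, threshold = 20, alpha = 0.05) {
  stopifnot(is(null, "RatioNull"))
  N <- length(null@mean)
  selfP <- (1 + findInterval(null@scores, null@scoresSorted)) / (1 + N)
  mean(preselectSnps(null@mean, threshold) & selfP < alpha)
}

#' Select candidate SNPs by empirical probability
#'
#' \code{mode = "plain"} keeps SNPs with empirical probability below
#' \code{alpha} (the historical reading that equates this cut with an FDR of
#' 5\%); \code{mode = "bh"} applies the Benjamini-Hochberg procedure at
#' level \code{alpha} instead.
#'
#' @param p vector of empirical probabilities.
#' @param alpha significance / FDR level (default 0.05).
#' @param mode "plain" (default) or "bh".
#' @return logical vector of selections.
#' @examples
#' fdrSelect(c(0.001, 0.04, 0.2))                 # TRUE TRUE FALSE
#' fdrSelect(c(0.001, 0.04, 0.2), mode = "bh")    # TRUE FALSE FALSE
#' @export
fdrSelect <- function(p, alpha = 0.05, mode = c("plain", "bh")) {
  mode <- match.arg(mode)
  if (!length(p)) return(logical())
  stopifnot(all(p >= 0 & p <= 1))
  switch(mode,
         plain = p < alpha,
         bh = stats::p.adjust(p, method = "BH") <= alpha)
}

#' Shortlist candidate SNPs for individual replication
#'
#' Two rule sets, mirroring a two-stage candidate selection:
#' \describe{
#'   \item{A (wide)}{keep selected SNPs whose gene label carries at least
#'     two selected SNPs, or that are selected in at least two case
#'     subtypes.}
#'   \item{B (stringent)}{keep selected SNPs with empirical probability at
#'     most \code{pMax} whose control-pool allele frequency is within
#'     \code{freqTol} of an external reference frequency (standing in for a
#'     population reference panel).}
#' }
#' Selected SNPs missing from the annotation are kept only under the
#' subtype-sharing criterion, with a warning.
#'
#' @param candidates \code{data.frame} with \code{snp_id}, \code{subtype},
#'   \code{p_mc} and logical \code{selected} (pre-selection + FDR cut).
#' @param annotation \code{data.frame} with \code{snp_id},
#'   \code{gene_label}.
#' @param referenceFreqs optional \code{data.frame} with \code{snp_id},
#'   \code{ref_freq} (frequency of the same allele as
#'   \code{controlFreqs}).
#' @param controlFreqs optional \code{data.frame} with \code{snp_id},
#'   \code{ctrl_freq}: mean control-pool frequency per SNP.
#' @param pMax rule-B probability ceiling (default 0.001).
#' @param freqTol rule-B absolute frequency tolerance (default 0.1).
#' @return \code{candidates} with an added \code{shortlist_rule} column
#'   ("", "A", "B" or "AB").
#' @export
replicationShortlist <- function(candidates, annotation,
                                 referenceFreqs = NULL, controlFreqs = NULL,
                                 pMax = 0.001, freqTol = 0.1) {
  stopifnot(all(c("snp_id", "subtype", "p_mc", "selected") %in%
                  names(candidates)))
  sel <- candidates[candidates$selected, , drop = FALSE]
  gene <- annotation$gene_label[match(sel$snp_id, annotation$snp_id)]
  if (anyNA(gene) && nrow(sel))
    warning("no annotation for SNP(s) ",
            paste(unique(sel$snp_id[is.na(gene)]), collapse = ", "),
            "; kept only under the subtype-sharing criterion")

  nSub <- table(sel$snp_id)
  sharedSubtype <- nSub[sel$snp_id] >= 2L
  geneCount <- table(gene[!duplicated(sel$snp_id)])
  sharedGene <- !is.na(gene) & geneCount[gene] >= 2L
  ruleA <- as.vector(sharedSubtype | sharedGene)

  ruleB <- rep(FALSE, nrow(sel))
  if (!is.null(referenceFreqs) && !is.null(controlFreqs)) {
    fr <- referenceFreqs$ref_freq[match(sel$snp_id, referenceFreqs$snp_id)]
    fc <- controlFreqs$ctrl_freq[match(sel$snp_id, controlFreqs$snp_id)]
    ruleB <- !is.na(fr) & !is.na(fc) & sel$p_mc <= pMax &
      abs(fc - fr) <= freqTol
  }

  rule <- paste0(ifelse(ruleA, "A", ""), ifelse(ruleB, "B", ""))
  candidates$shortlist_rule <- ""
  candidates$shortlist_rule[candidates$selected] <- rule
  candidates
}
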