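#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @useDynLib poolGWAS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Probe-intensity noise model for simulated pooled arrays
#'
#' Describes how probe-level fluorescence is generated from a pool allele
#' frequency.  The perfect-match signal of an allele is linear in the allele
#' frequency (\code{signalScale * frequency}) with multiplicative log-normal
#' noise of a given coefficient of variation per probe, plus a deterministic
#' additive floor shared by PM and MM.  The mismatch probe carries a fixed
#' fraction of the noise-free allele signal (cross-hybridization leakage),
#' again with its own multiplicative noise.  Only PM - MM differences are
#' consumed downstream, so the additive floor cancels in expectation.
#'
#' @param probesPerAllele number of probe quartets per SNP and allele.
#' @param signalScale fluorescence units per unit allele frequency.
#' @param backgroundMmFraction fraction of the allele signal leaking into MM.
#' @param multiplicativeCv per-probe coefficient of variation of the
#'   log-normal multiplicative noise (must be < 1).
#' @param additiveFloor additive fluorescence offset (units of fluorescence).
#'
#' @return A \code{NoiseModel} object.
#' @examples
#' NoiseModel()                     # defaults
#' NoiseModel(multiplicativeCv = 0) # noise-free probes
#' @export
NoiseModel <- function(probesPerAllele = 5L, signalScale = 2000,
                       backgroundMmFraction = 0.2, multiplicativeCv = 0.1,
                       additiveFloor = 50) {
  new("NoiseModel", probesPerAllele = as.integer(probesPerAllele),
      signalScale = as.numeric(signalScale),
      backgroundMmFraction = as.numeric(backgroundMmFraction),
      multiplicativeCv = as.numeric(multiplicativeCv),
      additiveFloor = as.numeric(additiveFloor))
}

setClass("NoiseModel", representation(
  probesPerAllele = "integer",
  signalScale = "numeric",
  backgroundMmFraction = "numeric",
  multiplicativeCv = "numeric",
  additiveFloor = "numeric"
))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@probesPerAllele < 1L)
    msg <- c(msg, "probesPerAllele must be >= 1")
  vals <- c(signalScale = object@signalScale,
            backgroundMmFraction = object@backgroundMmFraction,
            multiplicativeCv = object@multiplicativeCv,
            additiveFloor = object@additiveFloor)
  if (any(!is.finite(vals)) || any(vals < 0))
    msg <- c(msg, "all noise parameters must be finite and >= 0")
  if (object@multiplicativeCv >= 1)
    msg <- c(msg, "multiplicativeCv must be < 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' Parameters of the simulated study: the SNP panel (number of SNPs, split
#' across chromosomes, population minor-allele-frequency spectrum), the group
#' structure (control group first, then case subtypes), the DNA-pool layout
#' (pools per group in biological duplicate, individuals per pool), planted
#' risk alleles, the probe noise model, a genotype missingness rate for the
#' individually genotyped arm, and one global seed from which every random
#' sub-stream is derived.
#'
#' @param nSnps total number of SNPs on the simulated panel.
#' @param nChromosomes number of chromosomes the panel is split over.
#' @param snpsPerChromosome integer vector summing to \code{nSnps}; defaults
#'   to an even split.
#' @param mafLow,mafHigh bounds of the uniform population allele-frequency
#'   spectrum (frequencies of allele B), both in (0, 1).
#' @param groups group labels; the first is the control group.
#' @param nIndividualsPerGroup individuals per group (pooled + individually
#'   genotyped arm).
#' @param poolsPerGroup DNA pools per group (biological duplicates).
#' @param poolSize individuals per pool.
#' @param effectSnps \code{data.frame} with columns \code{snp} (SNP index),
#'   \code{group} (comma-separated case groups carrying the effect),
#'   \code{or} (allelic odds ratio of allele B versus controls, > 0) and
#'   optionally \code{maf} (fixed population base frequency for that SNP;
#'   \code{NA} draws it from the spectrum).
#' @param missingRate genotype missingness rate in the individually genotyped
#'   arm (pooled individuals are never masked, so pool allele counts remain
#'   exact functions of the genotypes).
#' @param snpsPerGene consecutive SNPs sharing one synthetic gene label,
#'   used by the gene-level shortlist rule.
#' @param noise a \code{\link{NoiseModel}}.
#' @param seed integer seed; all sub-streams are derived from it.
#'
#' @return A \code{CohortConfig} object.
#' @examples
#' cfg <- CohortConfig(nSnps = 100, seed = 7)
#' cfg
#' @export
CohortConfig <- function(nSnps = 2000L, nChromosomes = 4L,
                         snpsPerChromosome = NULL,
                         mafLow = 0.05, mafHigh = 0.5,
                         groups = c("CTR", "SUP", "OMA", "DIE"),
                         nIndividualsPerGroup = 120L,
                         poolsPerGroup = 2L, poolSize = 10L,
                         effectSnps = NULL, missingRate = 0.025,
                         snpsPerGene = 5L, noise = NoiseModel(),
                         seed = 1L) {
  nSnps <- as.integer(nSnps)
  nChromosomes <- as.integer(nChromosomes)
  if (is.null(snpsPerChromosome)) {
    base <- nSnps %/% nChromosomes
    snpsPerChromosome <- rep(base, nChromosomes)
    extra <- nSnps - base * nChromosomes
    if (extra > 0)
      snpsPerChromosome[seq_len(extra)] <- snpsPerChromosome[seq_len(extra)] + 1L
  }
  if (is.null(effectSnps))
    effectSnps <- data.frame(snp = integer(), group = character(),
                             or = numeric(), maf = numeric())
  if (is.null(effectSnps$maf)) effectSnps$maf <- NA_real_
  new("CohortConfig", nSnps = nSnps, nChromosomes = nChromosomes,
      snpsPerChromosome = as.integer(snpsPerChromosome),
      mafLow = mafLow, mafHigh = mafHigh, groups = groups,
      nIndividualsPerGroup = as.integer(nIndividualsPerGroup),
      poolsPerGroup = as.integer(poolsPerGroup),
      poolSize = as.integer(poolSize),
      effectSnps = effectSnps, missingRate = missingRate,
      snpsPerGene = as.integer(snpsPerGene), noise = noise,
      seed = as.integer(seed))
}

setClass("CohortConfig", representation(
  nSnps = "integer",
  nChromosomes = "integer",
  snpsPerChromosome = "integer",
  mafLow = "numeric",
  mafHigh = "numeric",
  groups = "character",
  nIndividualsPerGroup = "integer",
  poolsPerGroup = "integer",
  poolSize = "integer",
  effectSnps = "data.frame",
  missingRate = "numeric",
  snpsPerGene = "integer",
  noise = "NoiseModel",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (sum(object@snpsPerChromosome) != object@nSnps)
    msg <- c(msg, "snpsPerChromosome must sum to nSnps")
  if (length(object@snpsPerChromosome) != object@nChromosomes)
    msg <- c(msg, "snpsPerChromosome must have nChromosomes entries")
  if (object@mafLow <= 0 || object@mafHigh >= 1 ||
      object@mafLow > object@mafHigh)
    msg <- c(msg, "need 0 < mafLow <= mafHigh < 1")
  if (length(object@groups) < 2L || anyDuplicated(object@groups))
    msg <- c(msg, "groups must be >= 2 distinct labels (control first)")
  if (object@poolsPerGroup * object@poolSize > object@nIndividualsPerGroup)
    msg <- c(msg, "poolsPerGroup * poolSize must not exceed nIndividualsPerGroup")
  es <- object@effectSnps
  if (nrow(es)) {
    if (!all(c("snp", "group", "or") %in% names(es)))
      msg <- c(msg, "effectSnps needs columns snp, group, or")
    else {
      if (any(es$snp < 1L | es$snp > object@nSnps))
        msg <- c(msg, "effectSnps: SNP index out of range")
      if (any(!is.finite(es$or) | es$or <= 0))
        msg <- c(msg, "effectSnps: odds ratios must be > 0")
      tg <- setdiff(unlist(strsplit(es$group, ",", fixed = TRUE)),
                    object@groups[-1L])
      if (length(tg))
        msg <- c(msg, paste0("effectSnps: unknown case group(s) ",
                             paste(tg, collapse = ", ")))
      if (any(!is.na(es$maf) & (es$maf <= 0 | es$maf >= 1)))
        msg <- c(msg, "effectSnps: fixed maf must be in (0, 1)")
    }
  }
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Synthetic pooled-GWAS cohort
#'
#' A \linkS4class{SummarizedExperiment} holding the genotype matrix (SNPs in
#' rows, individuals in columns, values 0/1/2 counting copies of allele B,
#' \code{NA} for missing calls) together with the DNA-pool layout and the
#' planted-effect truth.  \code{rowData} carries SNP id, chromosome, 1-based
#' position, gene label and the population allele frequency; \code{colData}
#' carries the group label and pool assignment.  The slot \code{poolFreqs}
#' stores the exact per-pool allele-B frequencies (allele count in pool
#' divided by twice the pool size).
#'
#' @slot poolFreqs numeric matrix, SNPs x pools, on the grid k/(2 * poolSize).
#' @slot poolInfo \code{DataFrame} with pool id, group and replicate number.
#' @slot effectTruth \code{data.frame} of planted effects.
#' @slot config the generating \code{\link{CohortConfig}}.
#'
#' @seealso \code{\link{generateCohort}}
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
         contains = "SummarizedExperiment",
         representation(poolFreqs = "matrix",
                        poolInfo = "DataFrame",
                        effectTruth = "data.frame",
                        config = "CohortConfig"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  if (nrow(object@poolFreqs) != nrow(object))
    msg <- c(msg, "poolFreqs must have one row per SNP")
  if (ncol(object@poolFreqs) != nrow(object@poolInfo))
    msg <- c(msg, "poolFreqs must have one column per pool")
  ps <- object@config@poolSize
  if (length(object@poolFreqs)) {
    grid <- object@poolFreqs * 2 * ps
    if (max(abs(grid - round(grid))) > 1e-9)
      msg <- c(msg, "pool frequencies must lie on the grid k/(2*poolSize)")
  }
  if (length(msg)) msg else TRUE
})

#' Monte Carlo null distribution of the (mean, CV) ratio statistic
#'
#' Holds the simulated null sample of per-SNP (mean of four frequency ratios,
#' coefficient of variation) pairs together with each pair's self-inclusive
#' joint-tail count against the whole sample (the extremeness score used for
#' rank calibration of empirical probabilities).
#'
#' @slot chromosome chromosome label the null was built for.
#' @slot nSnps,nReps simulated SNPs per replicate and number of replicates;
#'   the sample holds \code{nSnps * nReps} pairs.
#' @slot mean,cv the simulated pairs.
#' @slot scores self-inclusive joint-tail counts, aligned with the pairs.
#' @slot scoresSorted sorted copy of \code{scores} for fast calibration.
#' @slot epsilon frequency clamp applied before forming ratios.
#' @slot mode null frequency model ("uniform", "empirical" or "matched").
#' @slot seed integer seed used.
#'
#' @seealso \code{\link{simulateNull}}, \code{\link{empiricalP}}
#' @exportClass RatioNull
setClass("RatioNull", representation(
  chromosome = "character",
  nSnps = "integer",
  nReps = "integer",
  mean = "numeric",
  cv = "numeric",
  scores = "integer",
  scoresSorted = "integer",
  epsilon = "numeric",
  mode = "character",
  seed = "integer"
))

setValidity("RatioNull", function(object) {
  msg <- character()
  n <- length(object@mean)
  if (n != object@nSnps * object@nReps)
    msg <- c(msg, "pair count must equal nSnps * nReps")
  if (length(object@cv) != n || length(object@scores) != n)
    msg <- c(msg, "mean, cv and scores must have equal length")
  if (n && any(object@mean <= 0))
    msg <- c(msg, "all simulated means must be > 0")
  if (length(msg)) msg else TRUE
})

#' Genotype counts for one SNP in a case-control contrast
#'
#' A 3 x 2 table of genotype counts (homozygous allele 1, heterozygous,
#' homozygous allele 2; case and control columns) plus the derived 2 x 2
#' allele-count table in which each genotyped individual contributes two
#' alleles.
#'
#' @slot snpId SNP identifier.
#' @slot alleles the two allele labels, in genotype-row order.
#' @slot counts 3 x 2 integer matrix, columns named case then control.
#' @slot callRate fraction of individuals with a non-missing genotype.
#'
#' @seealso \code{\link{genotypeCounts}}, \code{\link{tabulateGenotypes}}
#' @exportClass GenotypeCounts
setClass("GenotypeCounts", representation(
  snpId = "character",
  alleles = "character",
  counts = "matrix",
  callRate = "numeric"
))

setValidity("GenotypeCounts", function(object) {
  msg <- character()
  if (!identical(dim(object@counts), c(3L, 2L)))
    msg <- c(msg, "counts must be a 3 x 2 matrix")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@alleles) != 2L)
    msg <- c(msg, "exactly two allele labels required")
  if (length(msg)) msg else TRUE
})
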