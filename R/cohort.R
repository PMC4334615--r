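# Synthetic cohort generation: HWE genotypes per group, planted allelic
# odds-ratio effects, DNA pools in biological duplicate, probe intensities.

# Deterministic sub-stream seeds derived from the one global seed.
.deriveSeed <- function(seed, offset)
  as.integer((as.numeric(seed) + offset) %% 2147483629)

#' Shift an allele frequency by an allelic odds ratio
#'
#' Solves the case allele frequency \eqn{p_{case}} such that the allelic odds
#' ratio of cases versus a control frequency \eqn{p} equals \code{or}:
#' \deqn{p_{case} = OR \cdot p / (1 - p + OR \cdot p).}
#'
#' @param p control (population) allele frequency in [0, 1].
#' @param or allelic odds ratio, > 0.
#' @return the shifted case allele frequency.
#' @examples
#' oddsRatioShift(0.5, 1)    # 0.5: OR 1 leaves the frequency unchanged
#' oddsRatioShift(0.1, 4)    # enrichment
#' @export
oddsRatioShift <- function(p, or) {
  stopifnot(all(or > 0), all(p >= 0 & p <= 1))
  or * p / (1 - p + or * p)
}

#' Generate a synthetic pooled-GWAS cohort
#'
#' Draws a population allele-frequency spectrum, shifts it in the case groups
#' carrying planted effects (allelic odds-ratio model, then Hardy-Weinberg
#' within group), samples genotypes for every individual, assigns the first
#' \code{poolsPerGroup * poolSize} individuals of each group to DNA pools in
#' biological duplicate, and records the exact pool allele frequencies.
#' Genotypes are drawn by quantile inversion from uniform variates so that
#' two configurations differing only in effect sizes share the same
#' underlying randomness (common random numbers across effect levels).
#'
#' Missing genotype calls (rate \code{missingRate}) are introduced only in
#' the individually genotyped arm (individuals without a pool assignment):
#' pools are built from DNA, and pool frequencies stay exact functions of
#' the genotypes.
#'
#' @param config a \code{\link{CohortConfig}}.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @examples
#' sc <- generateCohort(CohortConfig(nSnps = 50, seed = 3))
#' dim(genotypes(sc))
#' head(poolFrequencies(sc))
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)

  nSnps <- config@nSnps
  groups <- config@groups
  control <- groups[1L]
  nInd <- config@nIndividualsPerGroup

  chrom <- rep(paste0("chr", seq_len(config@nChromosomes)),
               config@snpsPerChromosome)
  pos <- unlist(lapply(config@snpsPerChromosome,
                       function(n) seq_len(n) * 1500L), use.names = FALSE)
  geneIdx <- unlist(lapply(config@snpsPerChromosome, function(n)
    ceiling(seq_len(n) / config@snpsPerGene)), use.names = FALSE)
  geneLabel <- paste0("g", sub("^chr", "", chrom), "_", geneIdx)
  snpId <- sprintf("snp%05d", seq_len(nSnps))

  set.seed(.deriveSeed(config@seed, 101L))
  maf <- stats::runif(nSnps, config@mafLow, config@mafHigh)
  # the array's A/B designation is arbitrary with respect to minor/major:
  # half the SNPs carry the minor allele as B, half as A.  Planted-effect
  # SNPs are exempt so that a configured base frequency refers to allele B
  # directly.
  swap <- stats::runif(nSnps) < 0.5
  es <- config@effectSnps
  swap[es$snp] <- FALSE
  freqB <- ifelse(swap, 1 - maf, maf)

  if (nrow(es) && any(!is.na(es$maf)))
    freqB[es$snp[!is.na(es$maf)]] <- es$maf[!is.na(es$maf)]

  # per-group allele-B frequency: baseline everywhere, OR shift at effects
  pGroup <- matrix(freqB, nrow = nSnps, ncol = length(groups),
                   dimnames = list(snpId, groups))
  truth <- data.frame(snp = integer(), snp_id = character(),
                      group = character(), or = numeric(),
                      base_freq = numeric(), case_freq = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(es)) {
    for (k in seq_len(nrow(es))) {
      tg <- strsplit(es$group[k], ",", fixed = TRUE)[[1L]]
      pc <- oddsRatioShift(freqB[es$snp[k]], es$or[k])
      pGroup[es$snp[k], tg] <- pc
      truth <- rbind(truth, data.frame(
        snp = es$snp[k], snp_id = snpId[es$snp[k]], group = tg,
        or = es$or[k], base_freq = freqB[es$snp[k]], case_freq = pc,
        stringsAsFactors = FALSE))
    }
  }

  indGroup <- rep(groups, each = nInd)
  indId <- paste0(indGroup, "_", sprintf("%03d", rep(seq_len(nInd),
                                                     times = length(groups))))

  # genotypes under HWE within group, by quantile inversion
  set.seed(.deriveSeed(config@seed, 102L))
  U <- matrix(stats::runif(nSnps * length(indId)), nrow = nSnps)
  geno <- matrix(0L, nrow = nSnps, ncol = length(indId),
                 dimnames = list(snpId, indId))
  for (g in groups) {
    cols <- which(indGroup == g)
    geno[, cols] <- as.integer(
      stats::qbinom(U[, cols], size = 2L,
                    prob = rep(pGroup[, g], times = length(cols))))
  }

  # pool layout: first poolsPerGroup * poolSize individuals of each group
  poolId <- rep(NA_character_, length(indId))
  pinfo <- data.frame(pool_id = character(), group = character(),
                      replicate = integer(), stringsAsFactors = FALSE)
  for (g in groups) {
    cols <- which(indGroup == g)
    for (r in seq_len(config@poolsPerGroup)) {
      members <- cols[(r - 1L) * config@poolSize + seq_len(config@poolSize)]
      pid <- paste0(g, "_p", r)
      poolId[members] <- pid
      pinfo <- rbind(pinfo, data.frame(pool_id = pid, group = g,
                                       replicate = r,
                                       stringsAsFactors = FALSE))
    }
  }
  poolFreqs <- computePoolFrequencies(geno, poolId, config@poolSize)
  poolFreqs <- poolFreqs[, pinfo$pool_id, drop = FALSE]

  # missing calls only outside the pools
  if (config@missingRate > 0) {
    set.seed(.deriveSeed(config@seed, 103L))
    unpooled <- which(is.na(poolId))
    mask <- matrix(stats::runif(nSnps * length(unpooled)) < config@missingRate,
                   nrow = nSnps)
    sub <- geno[, unpooled, drop = FALSE]
    sub[mask] <- NA_integer_
    geno[, unpooled] <- sub
  }

  rd <- S4Vectors::DataFrame(snp_id = snpId, chrom = chrom, pos = pos,
                             gene_label = geneLabel, maf = pmin(maf, 1 - maf), freq_b = freqB,
                             is_effect = seq_len(nSnps) %in% es$snp)
  cd <- S4Vectors::DataFrame(individual_id = indId, group = indGroup,
                             pool_id = poolId, row.names = indId)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = geno), rowData = rd, colData = cd)
  new("SyntheticCohort", se, poolFreqs = poolFreqs,
      poolInfo = S4Vectors::DataFrame(pinfo), effectTruth = truth,
      config = config)
}

#' Exact pool allele frequencies from genotypes
#'
#' The frequency of allele B in a pool is the summed allele-B count of its
#' members divided by twice the pool size, so values lie on the grid
#' k/(2 * poolSize).  This stage is noise-free by construction; all noise
#' enters through \code{\link{simulateIntensities}}.
#'
#' @param genotypes integer matrix, SNPs x individuals, values 0/1/2.
#' @param poolAssignment character vector over individuals; \code{NA} marks
#'   individuals outside any pool.
#' @param poolSize required number of members per pool.
#' @return numeric matrix, SNPs x pools.
#' @examples
#' g <- rbind(snp1 = c(0L, 1L, 2L))
#' computePoolFrequencies(g, c("p1", "p1", "p1"), poolSize = 3)  # 0.5
#' @export
computePoolFrequencies <- function(genotypes, poolAssignment, poolSize) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == length(poolAssignment))
  pools <- unique(poolAssignment[!is.na(poolAssignment)])
  if (!length(pools)) stop("no pool assignments given")
  out <- matrix(NA_real_, nrow = nrow(genotypes), ncol = length(pools),
                dimnames = list(rownames(genotypes), pools))
  for (p in pools) {
    members <- which(!is.na(poolAssignment) & poolAssignment == p)
    if (length(members) != poolSize)
      stop("pool ", p, " has ", length(members), " members, expected ",
           poolSize)
    sub <- genotypes[, members, drop = FALSE]
    if (anyNA(sub))
      stop("pool ", p, " contains missing genotypes; pool frequencies must ",
           "be exact functions of genotypes")
    out[, p] <- rowSums(sub) / (2 * poolSize)
  }
  out
}

# Log-normal multiplicative noise factors with unit mean and the given CV.
.lnNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

#' Simulate probe-level pooled-array intensities
#'
#' For every SNP x pool x probe x allele, the perfect-match intensity is
#' \code{signalScale * frequency} of that allele in the pool, with log-normal
#' multiplicative noise per probe, plus the additive floor; the mismatch
#' probe carries \code{backgroundMmFraction} of the noise-free allele signal
#' (its own noise) plus the same floor.  A frequency of exactly zero thus
#' yields PM = MM = floor and a corrected fluorescence of zero.
#'
#' @param x a \code{\linkS4class{SyntheticCohort}}, or a numeric matrix of
#'   pool allele-B frequencies (SNPs x pools) with row and column names.
#' @param noise a \code{\link{NoiseModel}}; defaults to the cohort's.
#' @param seed integer seed.
#' @param annotation optional \code{data.frame} with \code{snp_id},
#'   \code{chrom}, \code{pos} when \code{x} is a bare matrix.
#' @return \code{data.frame} with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{probe_idx}, \code{allele} (A or B), \code{PM},
#'   \code{MM}, \code{pool_id}.
#' @examples
#' sc <- generateCohort(CohortConfig(nSnps = 5, seed = 1))
#' head(simulateIntensities(sc, seed = 1))
#' @export
simulateIntensities <- function(x, noise = NULL, seed = 1L,
                                annotation = NULL) {
  if (is(x, "SyntheticCohort")) {
    freqB <- poolFrequencies(x)
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    annotation <- rd[, c("snp_id", "chrom", "pos")]
    if (is.null(noise)) noise <- x@config@noise
  } else {
    freqB <- x
    if (is.null(noise)) noise <- NoiseModel()
    if (is.null(annotation))
      annotation <- data.frame(snp_id = rownames(freqB),
                               chrom = "chr1",
                               pos = seq_len(nrow(freqB)),
                               stringsAsFactors = FALSE)
  }
  stopifnot(all(freqB >= 0 & freqB <= 1))
  validObject(noise)

  nSnps <- nrow(freqB); nPools <- ncol(freqB)
  P <- noise@probesPerAllele
  # row order: snp (slowest), pool, probe, allele (fastest)
  snpIdx <- rep(seq_len(nSnps), each = nPools * P * 2L)
  poolIdx <- rep(rep(seq_len(nPools), each = P * 2L), times = nSnps)
  probeIdx <- rep(rep(seq_len(P), each = 2L), times = nSnps * nPools)
  allele <- rep(c("A", "B"), times = nSnps * nPools * P)

  fB <- freqB[cbind(snpIdx, poolIdx)]
  freq <- ifelse(allele == "A", 1 - fB, fB)
  mu <- noise@signalScale * freq

  set.seed(.deriveSeed(seed, 301L))
  n <- length(mu)
  PM <- mu * .lnNoise(n, noise@multiplicativeCv) + noise@additiveFloor
  MM <- noise@backgroundMmFraction * mu * .lnNoise(n, noise@multiplicativeCv) +
    noise@additiveFloor

  data.frame(snp_id = annotation$snp_id[snpIdx],
             chrom = annotation$chrom[snpIdx],
             pos = annotation$pos[snpIdx],
             probe_idx = probeIdx, allele = allele, PM = PM, MM = MM,
             pool_id = colnames(freqB)[poolIdx],
             stringsAsFactors = FALSE)
}

# Push pool frequencies through the intensity noise + allelotyping path and
# return the estimated allele-B frequency per pool (NA when non-callable).
# Used by the matched Monte Carlo null so that simulated null frequencies
# carry exactly the measurement noise of the real pipeline.
.noisyFrequency <- function(freqB, noise) {
  P <- noise@probesPerAllele
  n <- length(freqB)
  est <- function(freq) {
    mu <- noise@signalScale * rep(freq, each = P)
    PM <- mu * .lnNoise(n * P, noise@multiplicativeCv) + noise@additiveFloor
    MM <- noise@backgroundMmFraction * mu *
      .lnNoise(n * P, noise@multiplicativeCv) + noise@additiveFloor
    colSums(matrix(pmax(PM - MM, 0), nrow = P))
  }
  fB <- est(freqB)
  fA <- est(1 - freqB)
  tot <- fA + fB
  ifelse(tot > 0, fB / tot, NA_real_)
}
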