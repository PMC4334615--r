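# Synthetic cohort generator: odds-ratio effect model, HWE genotypes,
# exact pool frequencies, probe-intensity noise model.

test_that("odds-ratio frequency shift has the right fixed points and solves the allelic OR", {
  expect_equal(oddsRatioShift(0.5, 1), 0.5)
  expect_equal(oddsRatioShift(0.3, 1), 0.3)
  # the shifted frequency realises exactly the requested allelic odds ratio
  for (p in c(0.05, 0.2, 0.5, 0.9)) {
    for (or in c(0.5, 1.7, 4)) {
      pc <- oddsRatioShift(p, or)
      expect_equal((pc / (1 - pc)) / (p / (1 - p)), or)
    }
  }
  expect_error(oddsRatioShift(0.2, 0))
  expect_error(oddsRatioShift(0.2, -1))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(CohortConfig(nSnps = 10, seed = 1,
                            effectSnps = data.frame(snp = 11, group = "OMA",
                                                    or = 2)),
               "out of range")
  expect_error(CohortConfig(nSnps = 10, seed = 1,
                            effectSnps = data.frame(snp = 1, group = "OMA",
                                                    or = -2)),
               "odds ratios")
  expect_error(CohortConfig(nSnps = 10, poolSize = 100, seed = 1),
               "poolSize")
  expect_error(CohortConfig(nSnps = 10, mafLow = 0, seed = 1))
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- CohortConfig(nSnps = 40, seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(genotypes(a), genotypes(b))
  expect_identical(poolFrequencies(a), poolFrequencies(b))
  c <- generateCohort(CohortConfig(nSnps = 40, seed = 12))
  expect_false(identical(genotypes(a), genotypes(c)))
})

test_that("pool frequencies are exact allele counts on the k/(2n) grid", {
  # toy pools with known genotypes
  g <- rbind(s1 = c(2L, 2L, 2L), s2 = c(0L, 1L, 2L), s3 = c(1L, 1L, 1L))
  pf <- computePoolFrequencies(g, rep("p1", 3), poolSize = 3)
  expect_equal(unname(pf[, "p1"]), c(1.0, 0.5, 0.5))

  sc <- generateCohort(CohortConfig(nSnps = 60, seed = 2))
  pf <- poolFrequencies(sc)
  expect_true(all(abs(pf * 20 - round(pf * 20)) < 1e-12))
  # recompute from the genotype matrix: pooled individuals have no missing
  cd <- phenotypes(sc)
  own <- computePoolFrequencies(genotypes(sc)[, !is.na(cd$pool_id)],
                                cd$pool_id[!is.na(cd$pool_id)], 10)
  expect_equal(pf, own[, colnames(pf)])
})

test_that("malformed pool assignments are rejected", {
  g <- matrix(1L, nrow = 2, ncol = 5)
  expect_error(computePoolFrequencies(g, c("p1", "p1", "p1", "p2", "p2"),
                                      poolSize = 3), "expected 3")
  expect_error(computePoolFrequencies(g, rep(NA_character_, 5), 3),
               "no pool assignments")
  g[1, 1] <- NA_integer_
  expect_error(computePoolFrequencies(g, rep("p1", 5), 5), "missing")
})

test_that("control genotypes satisfy Hardy-Weinberg equilibrium", {
  fails <- 0L; tested <- 0L
  for (seed in 1:2) {
    sc <- generateCohort(CohortConfig(nSnps = 250, seed = seed,
                                      missingRate = 0))
    g <- genotypes(sc)[, phenotypes(sc)$group == "CTR"]
    for (i in seq_len(nrow(g))) {
      counts <- tabulate(g[i, ] + 1L, nbins = 3L)
      h <- hweTest(counts)
      if (!h$monomorphic) {
        tested <- tested + 1L
        if (h$p < 0.001) fails <- fails + 1L
      }
    }
  }
  expect_gte(1 - fails / tested, 0.99)
})

test_that("a null cohort shows no allelic association between groups", {
  # explicit OR = 1 effect: the case frequency equals the control frequency,
  # and the empirical log OR over seeds is centred on zero
  lor <- vapply(1:50, function(s) {
    cfg <- CohortConfig(nSnps = 1, groups = c("CTR", "OMA"),
                        nIndividualsPerGroup = 200, seed = s,
                        missingRate = 0,
                        effectSnps = data.frame(snp = 1, group = "OMA",
                                                or = 1, maf = 0.3))
    sc <- generateCohort(cfg)
    g <- genotypes(sc); grp <- phenotypes(sc)$group
    bCase <- sum(g[1, grp == "OMA"]); bCtrl <- sum(g[1, grp == "CTR"])
    log((bCase / (400 - bCase)) / (bCtrl / (400 - bCtrl)))
  }, numeric(1))
  expect_lt(abs(mean(lor)), 3 * sd(lor) / sqrt(length(lor)))
})

test_that("a planted allelic odds ratio is recovered from full genotypes", {
  # repeat-simulation oracle: mean estimated OR over 200 seeds within
  # 3 Monte Carlo standard errors of the planted 2.2
  ors <- vapply(1:200, function(s) {
    cfg <- CohortConfig(nSnps = 1, groups = c("CTR", "OMA"),
                        nIndividualsPerGroup = 200, seed = s,
                        missingRate = 0,
                        effectSnps = data.frame(snp = 1, group = "OMA",
                                                or = 2.2, maf = 0.3))
    sc <- generateCohort(cfg)
    g <- genotypes(sc); grp <- phenotypes(sc)$group
    bCase <- sum(g[1, grp == "OMA"]); bCtrl <- sum(g[1, grp == "CTR"])
    (bCase / (400 - bCase)) / (bCtrl / (400 - bCtrl))
  }, numeric(1))
  expect_lt(abs(mean(ors) - 2.2), 3 * sd(ors) / sqrt(length(ors)))
})

test_that("probe intensities reduce to the exact signal in the noise-free limit", {
  sc <- generateCohort(CohortConfig(
    nSnps = 30, seed = 4,
    noise = NoiseModel(multiplicativeCv = 0, backgroundMmFraction = 0)))
  intens <- simulateIntensities(sc, seed = 4)
  pf <- allelotypePools(intens)
  truth <- poolFrequencies(sc)
  expect_equal(pf$F_B, truth[cbind(pf$snp_id, pf$pool_id)],
               tolerance = 1e-12)
  # a frequency-zero allele gives PM equal to the additive floor exactly
  zero <- intens$allele == "B" &
    truth[cbind(intens$snp_id, intens$pool_id)] == 0
  if (any(zero))
    expect_true(all(intens$PM[zero] == 50))
})

test_that("default probe noise keeps frequency recovery accurate", {
  sc <- generateCohort(CohortConfig(nSnps = 1000, seed = 8))
  pf <- allelotypePools(simulateIntensities(sc, seed = 8))
  truth <- poolFrequencies(sc)[cbind(pf$snp_id, pf$pool_id)]
  expect_lt(mean(abs(pf$F_B - truth)), 0.05)
  expect_gt(cor(pf$F_B, truth), 0.99)
})

test_that("noise model validation rejects impossible parameters", {
  expect_error(NoiseModel(multiplicativeCv = 1.2), "< 1")
  expect_error(NoiseModel(signalScale = -5))
  expect_error(NoiseModel(probesPerAllele = 0))
})
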