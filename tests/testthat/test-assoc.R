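# Replication-stage statistics: tabulation, genotypic chi-square, oriented
# allelic odds ratio with Woolf CI, HWE, Breslow-Day.

test_that("genotype tabulation counts correctly and tracks the call rate", {
  gc <- tabulateGenotypes(c(0L, 1L, 2L, 2L), c("OMA", "OMA", "CTR", "CTR"),
                          case = "OMA", control = "CTR")
  expect_equal(unname(gc@counts[, "case"]), c(1L, 1L, 0L))
  expect_equal(unname(gc@counts[, "control"]), c(0L, 0L, 2L))
  expect_equal(gc@callRate, 1)

  g <- c(rep(0L, 20), rep(1L, 19), NA)
  gc2 <- tabulateGenotypes(g, rep(c("OMA", "CTR"), each = 20),
                           case = "OMA", control = "CTR")
  expect_equal(gc2@callRate, 0.975)

  expect_error(tabulateGenotypes(c(NA_integer_, NA_integer_),
                                 c("OMA", "CTR"), "OMA", "CTR"),
               "all genotypes missing")
  expect_error(tabulateGenotypes(c(0L, 1L), c("CTR", "CTR"), "OMA", "CTR"),
               "case group")
})

test_that("allele counts conserve margins: two alleles per genotyped individual", {
  set.seed(12)
  for (i in 1:20) {
    m <- randomGenotypeTable()
    gc <- genotypeCounts(case = m[, 1], control = m[, 2])
    ac <- alleleCounts(gc)
    expect_equal(unname(colSums(ac)), unname(2 * colSums(m)))
  }
})

test_that("the genotypic chi-square matches hand expected counts and printed values", {
  gc <- genotypeCounts(case = c(7, 27, 16), control = c(39, 39, 17))
  res <- genotypicChisq(gc)
  expect_equal(res$chi2, 11.63, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(round(res$p, 3), 0.003)

  res2 <- genotypicChisq(genotypeCounts(case = c(24, 21, 5),
                                        control = c(64, 30, 1)))
  expect_equal(round(res2$p, 3), 0.009)

  # identical proportions: no association
  same <- genotypicChisq(genotypeCounts(case = c(10, 20, 10),
                                        control = c(20, 40, 20)))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # degenerate: a single non-empty genotype row
  deg <- genotypicChisq(genotypeCounts(case = c(12, 0, 0),
                                       control = c(30, 0, 0)))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$chi2))

  # an all-zero genotype row is dropped before computing df
  two <- genotypicChisq(genotypeCounts(case = c(12, 8, 0),
                                       control = c(10, 20, 0)))
  expect_equal(two$df, 1)
})

test_that("the oriented odds ratio and Woolf interval reproduce the validated contrasts", {
  gc <- genotypeCounts(case = c(7, 27, 16), control = c(39, 39, 17),
                       alleles = c("A", "G"))
  orr <- allelicOddsRatio(gc)
  expect_equal(orr$or, 2.31, tolerance = 0.005)
  expect_equal(orr$ciLow, 1.41, tolerance = 0.005)
  expect_equal(orr$ciHigh, 3.78, tolerance = 0.005)
  expect_equal(orr$riskAllele, "G")
  expect_false(orr$haldane)

  gc2 <- genotypeCounts(case = c(0, 3, 63), control = c(5, 25, 160),
                        alleles = c("C", "T"))
  orr2 <- allelicOddsRatio(gc2)
  expect_equal(orr2$or, 4.36, tolerance = 0.005)
  expect_equal(orr2$ciLow, 1.32, tolerance = 0.005)
  expect_equal(orr2$ciHigh, 14.43, tolerance = 0.005)
  expect_equal(orr2$riskAllele, "T")

  # equal allele frequencies: OR exactly 1
  eq <- allelicOddsRatio(genotypeCounts(case = c(9, 18, 9),
                                        control = c(25, 50, 25)))
  expect_equal(eq$or, 1)

  # a zero allele cell triggers the Haldane-Anscombe correction
  hz <- allelicOddsRatio(genotypeCounts(case = c(0, 0, 30),
                                        control = c(5, 10, 15)))
  expect_true(hz$haldane)
  expect_true(is.finite(hz$or) && hz$or >= 1)
})

test_that("the odds ratio is invariant to allele relabeling", {
  set.seed(77)
  for (i in 1:25) {
    m <- randomGenotypeTable()
    gc <- genotypeCounts(case = m[, 1], control = m[, 2])
    fl <- genotypeCounts(case = rev(m[, 1]), control = rev(m[, 2]),
                         alleles = c("B", "A"))
    a <- allelicOddsRatio(gc); b <- allelicOddsRatio(fl)
    expect_equal(a$or, b$or)
    expect_equal(a$ciLow, b$ciLow)
    expect_equal(a$ciHigh, b$ciHigh)
    expect_equal(genotypicChisq(gc)$p, genotypicChisq(fl)$p)
  }
})

test_that("HWE tests behave at the exact, degenerate and printed-count cases", {
  perf <- hweTest(c(25, 50, 25))
  expect_equal(perf$chi2, 0)
  expect_equal(perf$p, 1)

  dep <- hweTest(c(50, 0, 50))
  expect_lt(dep$p, 1e-10)

  ctr <- hweTest(c(64, 30, 1))
  expect_gt(ctr$p, 0.05)

  mono <- hweTest(c(40, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$p, 1)

  # exact test agrees in direction and handles the same cases
  expect_gt(hweTest(c(64, 30, 1), method = "exact")$p, 0.05)
  expect_lt(hweTest(c(50, 0, 50), method = "exact")$p, 1e-10)
  expect_true(hweTest(c(0, 0, 33), method = "exact")$monomorphic)
})

test_that("Breslow-Day detects heterogeneity and degrades gracefully", {
  t1 <- matrix(c(30, 70, 30, 70), 2)          # OR 1
  same <- breslowDay(list(t1, t1))
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p, 0.999)

  # OR 1 versus OR 6 with ~100 alleles per stratum: clear heterogeneity
  t2 <- matrix(c(25, 25, 25, 25), 2)
  t3 <- matrix(c(40, 10, 20, 30), 2)
  het <- breslowDay(list(t2, t3))
  expect_lt(het$p, 0.05)

  expect_error(breslowDay(list(t1)), "at least two")
  expect_warning(res <- breslowDay(list(t1, t2, matrix(c(0, 0, 5, 5), 2))),
                 "zero margin")
  expect_equal(res$df, 1L)
})

test_that("the association table integrates all statistics per SNP and subtype", {
  sc <- generateCohort(CohortConfig(nSnps = 6, seed = 13,
                                    nIndividualsPerGroup = 80))
  ph <- phenotypes(sc)
  tab <- associationTable(genotypes(sc), ph$group,
                          snpIds = c("snp00001", "snp00002"))
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(tab$call_rate > 0.8))
  expect_true(all(tab$ci_low <= tab$OR & tab$OR <= tab$ci_high,
                  na.rm = TRUE))
  expect_true(all(tab$OR >= 1, na.rm = TRUE))

  expect_warning(associationTable(genotypes(sc), ph$group,
                                  snpIds = c("snp00001", "nope")),
                 "absent")

  # discovery stratum enables the heterogeneity column
  disc <- list(snp00001 = discoveryAlleleTable(c(0.4, 0.5), c(0.2, 0.25)))
  tab2 <- associationTable(genotypes(sc), ph$group, subtypes = "OMA",
                           snpIds = "snp00001", discoveryTables = disc)
  expect_true(is.finite(tab2$phet))
})
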