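# Frequency-ratio statistics: the four case/control ratios, mean and CV,
# pre-selection rule.

test_that("the four ratios pair duplicate pools in the canonical order", {
  R <- fourRatios(0.4, 0.5, 0.2, 0.25)
  expect_equal(unname(R[1, ]), c(2.0, 1.6, 2.5, 2.0))
  expect_equal(unname(fourRatios(0.3, 0.3, 0.3, 0.3)[1, ]), rep(1, 4))
  eps <- 1e-4
  expect_equal(unname(fourRatios(eps, eps, 0.5, 0.5)[1, ]), rep(2e-4, 4))
  expect_error(fourRatios(0, 0.5, 0.5, 0.5))
})

test_that("mean and CV of the four ratios follow the sample-SD convention", {
  mc <- meanCV(c(2.0, 1.6, 2.5, 2.0))
  expect_equal(mc$mean_R, 2.025)
  expect_equal(mc$cv_R, sqrt(0.4075 / 3) / 2.025, tolerance = 1e-12)
  expect_equal(round(mc$cv_R, 5), 0.182)
  expect_equal(meanCV(c(1, 1, 1, 1)), data.frame(mean_R = 1, cv_R = 0))
  for (const in c(0.01, 3, 250))
    expect_equal(meanCV(rep(const, 4))$cv_R, 0)
  # population convention divides by n
  mcp <- meanCV(c(2.0, 1.6, 2.5, 2.0), cvDenominator = "population")
  expect_equal(mcp$cv_R, sqrt(0.4075 / 4) / 2.025, tolerance = 1e-12)
})

test_that("pre-selection keeps >= 20-fold shifts in either direction", {
  expect_true(preselectSnps(25))
  expect_true(preselectSnps(0.008))
  expect_false(preselectSnps(1.0))
  expect_equal(preselectSnps(c(20, 0.05, 19.99, 0.0501)),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("exchanging case and control pools mirrors the statistic into the reciprocal regime", {
  set.seed(31)
  for (i in 1:50) {
    f <- clampFrequency(runif(4))
    R1 <- fourRatios(f[1], f[2], f[3], f[4])
    R2 <- fourRatios(f[3], f[4], f[1], f[2])
    # the swapped ratios are the elementwise reciprocals (R2 and R3 trade
    # places because the pairing order is case1/ctrl1, case1/ctrl2, ...)
    expect_equal(unname(R2[1, ]), unname(1 / R1[1, c(1, 3, 2, 4)]))
    # Jensen: the swapped mean is at least the reciprocal of the original
    expect_gte(meanCV(R2)$mean_R, 1 / meanCV(R1)$mean_R - 1e-12)
  }
  # a consistent enrichment (every ratio past the threshold) is guaranteed
  # to become a selected depletion after the exchange, and vice versa
  f <- c(0.45, 0.5, 0.01, 0.015)
  Rfwd <- fourRatios(f[1], f[2], f[3], f[4])
  Rrev <- fourRatios(f[3], f[4], f[1], f[2])
  expect_true(all(Rfwd >= 20))
  expect_true(preselectSnps(meanCV(Rfwd)$mean_R))
  expect_true(preselectSnps(meanCV(Rrev)$mean_R))
  expect_lte(meanCV(Rrev)$mean_R, 1 / 20)
})

test_that("ratio statistics assemble per subtype with callability handling", {
  sc <- generateCohort(CohortConfig(nSnps = 30, seed = 6))
  pf <- allelotypePools(simulateIntensities(sc, seed = 6))
  pools <- as.data.frame(poolInfo(sc))
  rs <- ratioStatistics(pf, pools)
  expect_setequal(unique(rs$subtype), c("SUP", "OMA", "DIE"))
  expect_equal(nrow(rs) + nrow(attr(rs, "skipped")), 30 * 3)
  expect_true(all(rs$mean_R > 0 & rs$cv_R >= 0))

  # a non-callable SNP x pool is skipped, not propagated
  pf2 <- pf
  idx <- pf2$snp_id == "snp00001" & pf2$pool_id == "CTR_p1"
  pf2$callable[idx] <- FALSE
  rs2 <- ratioStatistics(pf2, pools)
  expect_false("snp00001" %in% rs2$snp_id)
  expect_equal(sort(unique(attr(rs2, "skipped")$snp_id)), "snp00001")

  expect_error(ratioStatistics(pf, pools, controlGroup = "XXX"),
               "control group")
  expect_error(ratioStatistics(pf, pools[-1, ]), "two pools")
})
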