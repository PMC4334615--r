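# Monte Carlo null, empirical probabilities, FDR selection, shortlist rules.

test_that("the null holds nSnps x nReps pairs and is reproducible", {
  one <- simulateNull(nSnps = 1, nReps = 1, seed = 3)
  expect_length(one@mean, 1)
  expect_length(one@cv, 1)

  a <- simulateNull(nSnps = 100, nReps = 20, seed = 9)
  b <- simulateNull(nSnps = 100, nReps = 20, seed = 9)
  expect_identical(a@mean, b@mean)
  expect_identical(a@cv, b@cv)
  expect_identical(a@scores, b@scores)
  expect_length(a@mean, 2000)
  expect_true(all(a@mean > 0))
})

test_that("the null median of the mean ratio matches the large-sample oracle", {
  # mean of four heavy-tailed frequency ratios is right-skewed: the
  # large-sample median is ~1.257, not 1 (frozen from a 2e5-draw oracle)
  med <- vapply(1:3, function(s)
    median(simulateNull(nSnps = 5000, nReps = 10, seed = s)@mean),
    numeric(1))
  expect_true(all(med > 1.22 & med < 1.30))
})

test_that("empirical probabilities have the add-one floor and saturate at 1", {
  null <- simulateNull(nSnps = 100, nReps = 100, seed = 5)   # 10,000 pairs
  # more extreme than every null pair, both methods
  expect_equal(empiricalP(1e6, 0, null), 1 / 10001)
  expect_equal(empiricalP(1e6, 0, null, method = "raw"), 1 / 10001)
  expect_equal(empiricalP(1e-6, 0, null), 1 / 10001)

  # a degenerate null (all frequencies equal) has every pair at (1, 0):
  # an observation at the same point counts the whole null
  flat <- simulateNull(nSnps = 50, nReps = 10, seed = 2,
                       mode = "empirical", observed = 0.9)
  expect_equal(unique(flat@mean), 1)
  expect_equal(empiricalP(1, Inf, flat), 1)
  expect_equal(empiricalP(1, Inf, flat, method = "raw"), 1)
})

test_that("calibrated probabilities are a monotone transform of the raw joint-tail count", {
  null <- simulateNull(nSnps = 500, nReps = 40, seed = 7)
  set.seed(1)
  m <- exp(rnorm(200)); cv <- abs(rnorm(200, 0.5, 0.3))
  praw <- empiricalP(m, cv, null, method = "raw")
  pcal <- empiricalP(m, cv, null)
  ord <- order(praw)
  expect_true(all(diff(pcal[ord]) >= 0))
  expect_true(all(pcal > 0 & pcal <= 1))
  expect_true(all(pcal >= 1 / (length(null@mean) + 1)))
})

test_that("calibrated probabilities of null draws are uniform", {
  null <- simulateNull(nSnps = 2000, nReps = 50, seed = 21)
  obs <- simulateNull(nSnps = 500, nReps = 1, seed = 22)
  p <- empiricalP(obs@mean, obs@cv, null)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # the raw joint-tail mass is not uniform (this is why calibration exists)
  praw <- empiricalP(obs@mean, obs@cv, null, method = "raw")
  ksRaw <- suppressWarnings(ks.test(praw, "punif"))
  expect_lt(ksRaw$p.value, 1e-6)
})

test_that("FDR selection implements both the plain cut and Benjamini-Hochberg", {
  p <- c(0.001, 0.04, 0.2)
  expect_equal(fdrSelect(p), c(TRUE, TRUE, FALSE))
  expect_equal(fdrSelect(p, mode = "bh"), c(TRUE, FALSE, FALSE))
  expect_equal(fdrSelect(rep(1, 5)), rep(FALSE, 5))
  expect_equal(fdrSelect(numeric()), logical())
})

test_that("shortlist rules capture gene sharing, subtype sharing and the stringent filter", {
  cand <- data.frame(
    snp_id = c("s1", "s2", "s3", "s3", "s4", "s5"),
    subtype = c("SUP", "SUP", "SUP", "OMA", "DIE", "OMA"),
    p_mc = c(0.01, 0.01, 0.02, 0.02, 0.0005, 0.0005),
    selected = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  annot <- data.frame(snp_id = c("s1", "s2", "s3", "s4", "s5"),
                      gene_label = c("G", "G", "H", "I", "J"))
  refs <- data.frame(snp_id = c("s4", "s5"), ref_freq = c(0.55, 0.40))
  ctrl <- data.frame(snp_id = c("s4", "s5"), ctrl_freq = c(0.30, 0.45))
  out <- replicationShortlist(cand, annot, referenceFreqs = refs,
                              controlFreqs = ctrl)
  rule <- setNames(out$shortlist_rule, paste(out$snp_id, out$subtype))
  # s1, s2 share gene G; s3 is selected in two subtypes
  expect_equal(unname(rule[c("s1 SUP", "s2 SUP")]), c("A", "A"))
  expect_equal(unname(rule[c("s3 SUP", "s3 OMA")]), c("A", "A"))
  # s4: p fine but control pool frequency 0.30 vs reference 0.55 fails B
  expect_equal(unname(rule["s4 DIE"]), "")
  # s5: p <= 0.001 and |0.45 - 0.40| <= 0.1 passes B
  expect_equal(unname(rule["s5 OMA"]), "B")

  # missing annotation: kept only via subtype sharing, with a warning
  expect_warning(
    out2 <- replicationShortlist(cand, annot[annot$snp_id != "s3", ]),
    "s3")
  r2 <- setNames(out2$shortlist_rule, paste(out2$snp_id, out2$subtype))
  expect_equal(unname(r2[c("s3 SUP", "s3 OMA")]), c("A", "A"))
})
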