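# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the package's code paths (and
# chisq.test) so that agreement is a genuine cross-check.

# Pearson chi-square on an r x c table by explicit expected-count loops.
bruteChisq <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  n <- sum(tab)
  chi2 <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      chi2 <- chi2 + (tab[i, j] - e)^2 / e
    }
  }
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

# HWE goodness of fit by explicit expected proportions.
bruteHwe <- function(counts) {
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Breslow-Day via numerical root finding for the expected counts (the
# package uses the closed-form quadratic): same Mantel-Haenszel common OR,
# but E[a_k] found with uniroot on the odds-ratio equation.
unirootBreslowDay <- function(strata, tarone = TRUE) {
  a <- sapply(strata, function(t) t[1, 1])
  b <- sapply(strata, function(t) t[1, 2])
  cc <- sapply(strata, function(t) t[2, 1])
  d <- sapply(strata, function(t) t[2, 2])
  n <- a + b + cc + d
  orMH <- sum(a * d / n) / sum(b * cc / n)
  r1 <- a + b; c1 <- a + cc
  expA <- varA <- numeric(length(a))
  for (k in seq_along(a)) {
    lo <- max(0, r1[k] + c1[k] - n[k]); hi <- min(r1[k], c1[k])
    f <- function(E) E * (n[k] - r1[k] - c1[k] + E) /
      ((r1[k] - E) * (c1[k] - E)) - orMH
    E <- uniroot(f, lower = lo + 1e-9, upper = hi - 1e-9,
                 tol = 1e-12)$root
    expA[k] <- E
    varA[k] <- 1 / (1 / E + 1 / (r1[k] - E) + 1 / (c1[k] - E) +
                      1 / (n[k] - r1[k] - c1[k] + E))
  }
  stat <- sum((a - expA)^2 / varA)
  if (tarone) stat <- stat - sum(a - expA)^2 / sum(varA)
  list(statistic = stat,
       p = pchisq(stat, length(a) - 1L, lower.tail = FALSE))
}

# random 3 x 2 genotype table with non-degenerate margins
randomGenotypeTable <- function() {
  repeat {
    m <- matrix(rpois(6, lambda = sample(3:40, 1)), nrow = 3)
    if (all(colSums(m) > 0) && sum(rowSums(m) > 0) >= 2) return(m)
  }
}

# random 2 x 2 allele table with all-positive margins
randomAlleleTable <- function() {
  repeat {
    m <- matrix(rpois(4, lambda = sample(5:60, 1)) + 1L, nrow = 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# the bundled replication-stage genotype counts (five validated
# SNP x subtype contrasts)
readReplicationCounts <- function() {
  read.delim(system.file("extdata", "replication_counts.tsv",
                         package = "poolGWAS"),
             stringsAsFactors = FALSE)
}

# build GenotypeCounts objects for each fixture row
fixtureCounts <- function() {
  tab <- readReplicationCounts()
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    genotypeCounts(case = c(r$case_11, r$case_12, r$case_22),
                   control = c(r$ctrl_11, r$ctrl_12, r$ctrl_22),
                   alleles = c(r$allele1, r$allele2),
                   snpId = paste(r$snp_id, r$subtype))
  })
}

# intensity table for a single SNP x pool from explicit probe values
probeTable <- function(pmA, mmA, pmB, mmB, snp = "s1", pool = "p1") {
  k <- length(pmA)
  data.frame(snp_id = snp, chrom = "chr1", pos = 1L,
             probe_idx = rep(seq_len(k), 2L),
             allele = rep(c("A", "B"), each = k),
             PM = c(pmA, pmB), MM = c(mmA, mmB), pool_id = pool,
             stringsAsFactors = FALSE)
}
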