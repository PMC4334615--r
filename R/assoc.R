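# Replication-stage case-control association statistics from individual
# genotypes: genotypic Pearson chi-square, oriented allelic odds ratio with
# Woolf CI, HWE in controls, Breslow-Day heterogeneity, call-rate QC.

#' Construct genotype counts directly
#'
#' @param case,control integer vectors of length 3: counts of (hom allele 1,
#'   heterozygote, hom allele 2).
#' @param alleles the two allele labels.
#' @param snpId SNP identifier.
#' @param callRate optional call rate to record (default 1).
#' @return a \code{\linkS4class{GenotypeCounts}}.
#' @examples
#' genotypeCounts(case = c(7, 27, 16), control = c(39, 39, 17),
#'                alleles = c("A", "G"), snpId = "rs227849")
#' @export
genotypeCounts <- function(case, control, alleles = c("A", "B"),
                           snpId = "snp", callRate = 1) {
  counts <- cbind(case = as.integer(case), control = as.integer(control))
  rownames(counts) <- c(paste0(alleles[1L], alleles[1L]),
                        paste0(alleles[1L], alleles[2L]),
                        paste0(alleles[2L], alleles[2L]))
  new("GenotypeCounts", snpId = snpId, alleles = alleles, counts = counts,
      callRate = callRate)
}

#' Tabulate genotypes of one SNP into a case-control table
#'
#' Missing genotypes are excluded listwise and recorded in the call rate
#' (genotyped / total individuals in the two groups).
#'
#' @param geno integer vector of genotypes (0/1/2 copies of allele 2,
#'   \code{NA} = missing), one per individual.
#' @param groups group label per individual.
#' @param case,control labels of the case and control group.
#' @param alleles the two allele labels (allele 2 is the counted one).
#' @param snpId SNP identifier.
#' @return a \code{\linkS4class{GenotypeCounts}}.
#' @examples
#' tabulateGenotypes(c(0, 1, 2, 2), c("OMA", "OMA", "CTR", "CTR"),
#'                   case = "OMA", control = "CTR")
#' @export
tabulateGenotypes <- function(geno, groups, case, control,
                              alleles = c("A", "B"), snpId = "snp") {
  stopifnot(length(geno) == length(groups))
  keep <- groups %in% c(case, control)
  if (!any(groups == case)) stop("no individuals in case group ", case)
  if (!any(groups == control)) stop("no individuals in control group ",
                                    control)
  g <- geno[keep]
  grp <- groups[keep]
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g)))
    stop("genotype codes must be 0, 1, 2 or NA")
  total <- length(g)
  ok <- !is.na(g)
  if (!any(ok)) stop("all genotypes missing for SNP ", snpId)
  cnt <- function(lab) tabulate(g[ok & grp == lab] + 1L, nbins = 3L)
  genotypeCounts(case = cnt(case), control = cnt(control),
                 alleles = alleles, snpId = snpId,
                 callRate = sum(ok) / total)
}

#' Allele counts of a genotype table
#'
#' Each genotyped individual contributes two alleles: the allele-1 count is
#' twice the allele-1 homozygote count plus the heterozygote count, and the
#' column sums equal twice the number of genotyped individuals.
#'
#' @param counts a \code{\linkS4class{GenotypeCounts}}.
#' @return 2 x 2 integer matrix (alleles x case/control).
#' @export
alleleCounts <- function(counts) {
  stopifnot(is(counts, "GenotypeCounts"))
  m <- counts@counts
  out <- rbind(2L * m[1L, ] + m[2L, ], 2L * m[3L, ] + m[2L, ])
  rownames(out) <- counts@alleles
  out
}

#' Genotypic Pearson chi-square association test
#'
#' Pearson chi-square on the 3 x 2 genotype table without continuity
#' correction; genotype rows that are empty in both groups are dropped
#' before computing degrees of freedom, df = (rows - 1)(columns - 1).  A
#' degenerate table (a single non-empty genotype row) yields \code{NA}
#' statistics with \code{degenerate = TRUE}.
#'
#' @param counts a \code{\linkS4class{GenotypeCounts}}.
#' @return list with \code{chi2}, \code{df}, \code{p}, \code{degenerate}.
#' @examples
#' gc <- genotypeCounts(case = c(7, 27, 16), control = c(39, 39, 17))
#' genotypicChisq(gc)   # chi2 ~ 11.63, df 2, p ~ 0.003
#' @export
genotypicChisq <- function(counts) {
  stopifnot(is(counts, "GenotypeCounts"))
  m <- counts@counts[rowSums(counts@counts) > 0, , drop = FALSE]
  if (nrow(m) < 2L || any(colSums(m) == 0))
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), degenerate = FALSE)
}

#' Oriented allelic odds ratio with Woolf confidence interval
#'
#' The odds ratio is the cross-product ratio of the 2 x 2 allele table,
#' oriented so that the reported (risk) allele is the case-enriched one,
#' hence OR >= 1.  The 95\% CI is Woolf's log-normal approximation,
#' \eqn{\exp(\ln OR \pm 1.96 \sqrt{\sum 1/n_{ij}})}.  If any allele cell is
#' zero, 0.5 is added to all four cells (Haldane-Anscombe) and the result is
#' flagged.
#'
#' @param counts a \code{\linkS4class{GenotypeCounts}}.
#' @param conf confidence level (default 0.95).
#' @return list with \code{or}, \code{ciLow}, \code{ciHigh},
#'   \code{riskAllele}, \code{haldane}, and \code{alleleFreqs} (percent
#'   frequency of each allele in cases and controls).
#' @examples
#' gc <- genotypeCounts(case = c(7, 27, 16), control = c(39, 39, 17),
#'                      alleles = c("A", "G"))
#' allelicOddsRatio(gc)   # OR 2.31 (1.41-3.78), risk allele G
#' @export
allelicOddsRatio <- function(counts, conf = 0.95) {
  ac <- alleleCounts(counts)
  freqs <- sweep(ac, 2L, colSums(ac), "/") * 100
  haldane <- any(ac == 0)
  a <- ac + if (haldane) 0.5 else 0
  # risk allele: the one enriched in cases (ties keep allele 2)
  risk <- if (a[1L, "case"] * a[2L, "control"] >
              a[2L, "case"] * a[1L, "control"]) 1L else 2L
  other <- 3L - risk
  or <- (a[risk, "case"] * a[other, "control"]) /
    (a[other, "case"] * a[risk, "control"])
  se <- sqrt(sum(1 / a))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ciLow = or * exp(-z * se), ciHigh = or * exp(z * se),
       riskAllele = counts@alleles[risk], haldane = haldane,
       alleleFreqs = freqs)
}

#' Hardy-Weinberg equilibrium test
#'
#' Chi-square goodness of fit (1 df) of the observed genotype counts against
#' the Hardy-Weinberg proportions implied by the observed allele frequency,
#' or the exact test that sums the probabilities of all heterozygote counts
#' no more probable than the observed one, conditional on the allele counts.
#' A monomorphic sample returns p = 1 with \code{monomorphic = TRUE}.
#'
#' @param counts integer vector of length 3 (hom 1, het, hom 2), typically
#'   the control column.
#' @param method "chisq" (default) or "exact".
#' @return list with \code{p}, \code{chi2} (\code{NA} for exact),
#'   \code{monomorphic}.
#' @examples
#' hweTest(c(25, 50, 25))   # exact HWE proportions: chi2 = 0, p = 1
#' hweTest(c(50, 0, 50))    # no heterozygotes: p ~ 0
#' @export
hweTest <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype table")
  nA <- 2 * counts[1L] + counts[2L]
  if (nA == 0 || nA == 2 * n)
    return(list(p = 1, chi2 = if (method == "chisq") 0 else NA_real_,
                monomorphic = TRUE))
  if (method == "chisq") {
    p <- nA / (2 * n)
    expect <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((counts - expect)^2 / expect)
    return(list(p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                chi2 = chi2, monomorphic = FALSE))
  }
  # exact: probability of each possible heterozygote count given allele
  # counts, on the log scale for stability
  nB <- 2 * n - nA
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  pObs <- prob[match(counts[2L], hets)]
  list(p = min(1, sum(prob[prob <= pObs + 1e-12])), chi2 = NA_real_,
       monomorphic = FALSE)
}

#' Breslow-Day test of odds-ratio homogeneity across strata
#'
#' Tests whether the allele odds ratio is common across K strata (e.g.
#' discovery and replication stages).  Expected counts in each stratum are
#' the solution of the quadratic implied by the Mantel-Haenszel common odds
#' ratio; the statistic sums squared deviations over strata, with Tarone's
#' correction subtracting the squared summed deviation over the summed
#' variance (default on), and is chi-square with K - 1 df.  Strata with a
#' zero margin carry no information about the odds ratio and are dropped
#' with a warning.
#'
#' @param strata list of 2 x 2 numeric matrices (rows: allele, columns:
#'   case/control).
#' @param tarone apply Tarone's correction (default \code{TRUE}).
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{commonOr}.
#' @examples
#' t1 <- matrix(c(30, 70, 30, 70), 2)
#' breslowDay(list(t1, t1))   # identical tables: statistic ~ 0, p ~ 1
#' @export
breslowDay <- function(strata, tarone = TRUE) {
  stopifnot(is.list(strata))
  ok <- vapply(strata, function(t)
    all(dim(t) == c(2L, 2L)) && all(rowSums(t) > 0) && all(colSums(t) > 0),
    logical(1L))
  if (any(!ok)) {
    warning(sum(!ok), " stratum/strata with a zero margin dropped")
    strata <- strata[ok]
  }
  K <- length(strata)
  if (K < 2L) stop("Breslow-Day requires at least two informative strata")

  a <- vapply(strata, function(t) t[1L, 1L], numeric(1L))
  b <- vapply(strata, function(t) t[1L, 2L], numeric(1L))
  c_ <- vapply(strata, function(t) t[2L, 1L], numeric(1L))
  d <- vapply(strata, function(t) t[2L, 2L], numeric(1L))
  n <- a + b + c_ + d
  orMH <- sum(a * d / n) / sum(b * c_ / n)

  r1 <- a + b; c1 <- a + c_
  # expected a under the common OR: root of
  # E(n - r1 - c1 + E) * OR^-1 = (r1 - E)(c1 - E)  when OR != 1
  expA <- numeric(K); varA <- numeric(K)
  for (k in seq_len(K)) {
    if (abs(orMH - 1) < 1e-12) {
      E <- r1[k] * c1[k] / n[k]
    } else {
      A <- orMH - 1
      B <- -((r1[k] + c1[k]) * orMH + (n[k] - r1[k] - c1[k]))
      C <- orMH * r1[k] * c1[k]
      disc <- sqrt(max(B^2 - 4 * A * C, 0))
      roots <- c((-B - disc) / (2 * A), (-B + disc) / (2 * A))
      valid <- roots[roots >= max(0, r1[k] + c1[k] - n[k]) - 1e-9 &
                       roots <= min(r1[k], c1[k]) + 1e-9]
      E <- valid[1L]
    }
    expA[k] <- E
    varA[k] <- 1 / (1 / E + 1 / (r1[k] - E) + 1 / (c1[k] - E) +
                      1 / (n[k] - r1[k] - c1[k] + E))
  }
  stat <- sum((a - expA)^2 / varA)
  if (tarone) stat <- stat - sum(a - expA)^2 / sum(varA)
  list(statistic = stat, df = K - 1L,
       p = stats::pchisq(stat, df = K - 1L, lower.tail = FALSE),
       commonOr = orMH)
}

#' Approximate discovery-stage allele table from pool frequencies
#'
#' Converts the mean case-pool and control-pool frequency point estimates of
#' one SNP into an approximate 2 x 2 allele-count table by multiplying each
#' mean frequency by twice the number of pooled individuals and rounding to
#' the nearest integer.  The table is an approximation (pool frequencies are
#' estimates, not counts) and is flagged as such; it exists so that the
#' discovery stage can enter a Breslow-Day heterogeneity test against the
#' replication stage.
#'
#' @param caseFreqs,ctrlFreqs pool frequency estimates of the counted allele
#'   (one value per pool).
#' @param nCase,nCtrl number of pooled individuals per group.
#' @return 2 x 2 matrix (alleles x case/control) with attribute
#'   \code{approximate = TRUE}.
#' @export
discoveryAlleleTable <- function(caseFreqs, ctrlFreqs, nCase = 20L,
                                 nCtrl = 20L) {
  fc <- mean(caseFreqs); f0 <- mean(ctrlFreqs)
  tab <- matrix(c(round(2 * nCase * fc), round(2 * nCtrl * f0),
                  round(2 * nCase * (1 - fc)), round(2 * nCtrl * (1 - f0))),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("B", "A"), c("case", "control")))
  attr(tab, "approximate") <- TRUE
  tab
}

#' Association table for shortlisted SNPs
#'
#' Runs the full replication-stage battery per SNP and case subtype:
#' genotype tabulation with call rate, genotypic Pearson chi-square,
#' oriented allelic odds ratio with Woolf CI, HWE in controls, and (when a
#' discovery-stage allele table is supplied) Breslow-Day heterogeneity
#' between the discovery and replication stages.
#'
#' @param genotypes integer matrix, SNPs x individuals (0/1/2/\code{NA}).
#' @param groups group label per individual (columns of \code{genotypes}).
#' @param subtypes case subtypes to contrast against the control group;
#'   default all non-control groups present.
#' @param controlGroup control group label.
#' @param snpIds SNPs to test (default all rows).
#' @param discoveryTables optional named list (by SNP id) of 2 x 2
#'   discovery-stage allele tables, see
#'   \code{\link{discoveryAlleleTable}}.
#' @param hweMethod method for \code{\link{hweTest}}.
#' @param alpha significance level for the \code{significant} flag.
#' @return \code{data.frame}, one row per SNP x subtype.
#' @export
associationTable <- function(genotypes, groups, subtypes = NULL,
                             controlGroup = "CTR", snpIds = NULL,
                             discoveryTables = NULL,
                             hweMethod = c("chisq", "exact"),
                             alpha = 0.05) {
  hweMethod <- match.arg(hweMethod)
  if (is.null(subtypes))
    subtypes <- setdiff(unique(groups), controlGroup)
  if (is.null(snpIds)) snpIds <- rownames(genotypes)
  absent <- setdiff(snpIds, rownames(genotypes))
  if (length(absent)) {
    warning("SNP(s) absent from genotypes, skipped: ",
            paste(absent, collapse = ", "))
    snpIds <- setdiff(snpIds, absent)
  }
  rows <- list()
  for (s in snpIds) {
    for (st in subtypes) {
      gc <- tabulateGenotypes(genotypes[s, ], groups, case = st,
                              control = controlGroup, snpId = s)
      chi <- genotypicChisq(gc)
      orr <- allelicOddsRatio(gc)
      hwe <- hweTest(gc@counts[, "control"], method = hweMethod)
      phet <- NA_real_
      if (!is.null(discoveryTables) && s %in% names(discoveryTables)) {
        rep2 <- alleleCounts(gc)
        colnames(rep2) <- c("case", "control")
        bd <- tryCatch(
          breslowDay(list(discovery = discoveryTables[[s]],
                          replication = rep2)),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(bd)) phet <- bd$p
      }
      m <- gc@counts
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s, subtype = st,
        n_case_11 = m[1L, "case"], n_case_12 = m[2L, "case"],
        n_case_22 = m[3L, "case"],
        n_ctrl_11 = m[1L, "control"], n_ctrl_12 = m[2L, "control"],
        n_ctrl_22 = m[3L, "control"],
        chi2 = chi$chi2, df = chi$df, p_geno = chi$p,
        risk_allele = orr$riskAllele, OR = orr$or,
        ci_low = orr$ciLow, ci_high = orr$ciHigh,
        hwe_p_controls = hwe$p, phet = phet, call_rate = gc@callRate,
        significant = !is.na(chi$p) && chi$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), subtype = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
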