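# Case/control frequency-ratio statistics from duplicate pools.

#' Clamp frequencies away from 0 and 1
#'
#' Frequencies are clamped to [eps, 1 - eps] before any ratio is formed so
#' that all four ratios stay finite and positive.
#'
#' @param f numeric vector of frequencies.
#' @param epsilon clamp width (default 1e-4).
#' @return clamped frequencies.
#' @export
clampFrequency <- function(f, epsilon = 1e-4) pmin(pmax(f, epsilon), 1 - epsilon)

#' The four case/control frequency ratios of duplicate pools
#'
#' With two case pools and two control pools per contrast, the four ratios
#' are all case/control pairings:
#' R1 = case1/ctrl1, R2 = case1/ctrl2, R3 = case2/ctrl1, R4 = case2/ctrl2.
#'
#' @param fCase1,fCase2,fCtrl1,fCtrl2 clamped allele frequencies in
#'   (0, 1); vectorized over SNPs.
#' @return matrix with columns R1..R4.
#' @examples
#' fourRatios(0.4, 0.5, 0.2, 0.25)   # 2.0, 1.6, 2.5, 2.0
#' @export
fourRatios <- function(fCase1, fCase2, fCtrl1, fCtrl2) {
  stopifnot(all(c(fCase1, fCase2, fCtrl1, fCtrl2) > 0))
  cbind(R1 = fCase1 / fCtrl1, R2 = fCase1 / fCtrl2,
        R3 = fCase2 / fCtrl1, R4 = fCase2 / fCtrl2)
}

#' Mean and coefficient of variation of the four ratios
#'
#' The mean is the arithmetic mean; the coefficient of variation is the
#' standard deviation divided by the mean.  The standard deviation uses the
#' sample (n - 1) denominator by default; the population (n) convention is
#' available for comparison.
#'
#' @param R matrix with columns R1..R4 (rows are SNPs), or a vector of four
#'   ratios.
#' @param cvDenominator "sample" (n - 1, default) or "population" (n).
#' @return \code{data.frame} with columns \code{mean_R}, \code{cv_R}.
#' @examples
#' meanCV(c(2.0, 1.6, 2.5, 2.0))   # mean 2.025, CV 0.182
#' @export
meanCV <- function(R, cvDenominator = c("sample", "population")) {
  cvDenominator <- match.arg(cvDenominator)
  if (is.null(dim(R))) R <- matrix(R, nrow = 1L)
  m <- rowMeans(R)
  dev2 <- rowSums((R - m)^2)
  s <- sqrt(dev2 / (ncol(R) - (cvDenominator == "sample")))
  data.frame(mean_R = m, cv_R = s / m)
}

#' Pre-selection of SNPs by the mean frequency ratio
#'
#' Keeps SNPs whose mean ratio shows at least a \code{threshold}-fold
#' frequency difference in either direction: \code{mean_R >= threshold} or
#' \code{mean_R <= 1/threshold}.  The rule is two-sided because the ratio is
#' always formed with the array's designated A allele; a depleted A allele
#' (tiny mean) is the same signal as an enriched one.
#'
#' @param meanR vector of mean ratios (> 0).
#' @param threshold fold-change threshold (default 20).
#' @return logical vector.
#' @examples
#' preselectSnps(c(25, 0.008, 1))   # TRUE TRUE FALSE
#' @export
preselectSnps <- function(meanR, threshold = 20) {
  stopifnot(all(meanR > 0), threshold > 1)
  meanR >= threshold | meanR <= 1 / threshold
}

#' Per-SNP, per-subtype ratio statistics from pool frequencies
#'
#' For every case subtype, pairs its two duplicate pools with the two control
#' pools, forms the four frequency ratios from clamped frequencies, and
#' computes their mean and coefficient of variation plus the pre-selection
#' flag.  SNPs with any non-callable pool in a contrast are skipped and
#' reported in the \code{skipped} attribute.
#'
#' @param poolFreq \code{data.frame} from \code{\link{allelotypePools}} (or
#'   the same schema read back from disk).
#' @param pools \code{data.frame} with \code{pool_id}, \code{group},
#'   \code{replicate}; exactly two pools per group.
#' @param controlGroup label of the control group.
#' @param freqColumn which frequency enters the ratio (default \code{"F_A"};
#'   the two-sided pre-selection makes the choice immaterial).
#' @param epsilon frequency clamp.
#' @param threshold pre-selection fold-change threshold.
#' @param cvDenominator see \code{\link{meanCV}}.
#' @return \code{data.frame} with columns \code{snp_id}, \code{chrom},
#'   \code{subtype}, \code{R1}..\code{R4}, \code{mean_R}, \code{cv_R},
#'   \code{selected}; attribute \code{skipped} lists non-callable SNP x
#'   subtype pairs.
#' @export
ratioStatistics <- function(poolFreq, pools, controlGroup = "CTR",
                            freqColumn = "F_A", epsilon = 1e-4,
                            threshold = 20,
                            cvDenominator = c("sample", "population")) {
  cvDenominator <- match.arg(cvDenominator)
  stopifnot(all(c("snp_id", "pool_id", freqColumn, "callable") %in%
                  names(poolFreq)),
            all(c("pool_id", "group", "replicate") %in% names(pools)))
  if (!controlGroup %in% pools$group)
    stop("control group ", controlGroup, " not present in pool table")
  cnt <- table(pools$group)
  if (any(cnt != 2L))
    stop("ratio statistics require exactly two pools per group ",
         "(biological duplicates)")

  snps <- unique(poolFreq$snp_id)
  Fmat <- matrix(NA_real_, nrow = length(snps), ncol = nrow(pools),
                 dimnames = list(snps, pools$pool_id))
  Fmat[cbind(match(poolFreq$snp_id, snps),
             match(poolFreq$pool_id, pools$pool_id))] <-
    poolFreq[[freqColumn]]
  call <- matrix(FALSE, nrow = length(snps), ncol = nrow(pools),
                 dimnames = dimnames(Fmat))
  call[cbind(match(poolFreq$snp_id, snps),
             match(poolFreq$pool_id, pools$pool_id))] <- poolFreq$callable

  chromOf <- if ("chrom" %in% names(poolFreq))
    poolFreq$chrom[match(snps, poolFreq$snp_id)] else NA_character_

  ctrlIds <- pools$pool_id[pools$group == controlGroup][
    order(pools$replicate[pools$group == controlGroup])]
  subtypes <- setdiff(unique(pools$group), controlGroup)

  out <- list()
  skipped <- list()
  for (st in subtypes) {
    caseIds <- pools$pool_id[pools$group == st][
      order(pools$replicate[pools$group == st])]
    ok <- call[, caseIds[1L]] & call[, caseIds[2L]] &
      call[, ctrlIds[1L]] & call[, ctrlIds[2L]]
    if (any(!ok))
      skipped[[st]] <- data.frame(snp_id = snps[!ok], subtype = st,
                                  stringsAsFactors = FALSE)
    Fc <- clampFrequency(Fmat[ok, , drop = FALSE], epsilon)
    R <- fourRatios(Fc[, caseIds[1L]], Fc[, caseIds[2L]],
                    Fc[, ctrlIds[1L]], Fc[, ctrlIds[2L]])
    mc <- meanCV(R, cvDenominator)
    out[[st]] <- data.frame(snp_id = snps[ok], chrom = chromOf[ok],
                            subtype = st, R, mc,
                            selected = preselectSnps(mc$mean_R, threshold),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "skipped") <- if (length(skipped))
    do.call(rbind, c(skipped, list(make.row.names = FALSE)))
  else
    data.frame(snp_id = character(), subtype = character())
  res
}
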