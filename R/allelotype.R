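# Pool allelotyping: probe-level PM/MM intensities -> per-pool allele
# frequency estimates.

#' Background-corrected probe fluorescence
#'
#' The allele signal of a probe quartet is the perfect-match minus the
#' mismatch intensity, clamped at zero (cross-hybridization can push MM above
#' PM on real arrays; clamping keeps downstream frequencies inside [0, 1]).
#'
#' @param pm,mm non-negative fluorescence intensities.
#' @return \code{max(pm - mm, 0)}, vectorized.
#' @examples
#' correctedFluorescence(200, 50)   # 150
#' correctedFluorescence(40, 60)    # 0 (clamped)
#' @export
correctedFluorescence <- function(pm, mm) {
  if (any(pm < 0, na.rm = TRUE) || any(mm < 0, na.rm = TRUE))
    stop("PM and MM intensities must be non-negative")
  pmax(pm - mm, 0)
}

#' Allele-frequency estimate from per-allele fluorescence
#'
#' \eqn{F_A = f_A / (f_A + f_B)} and \eqn{F_B = 1 - F_A}.  When both summed
#' fluorescences are zero the frequency is undefined and the SNP x pool is
#' marked non-callable rather than raising an error.
#'
#' @param fA,fB non-negative summed corrected fluorescences per allele.
#' @return \code{data.frame} with columns \code{F_A}, \code{F_B},
#'   \code{callable}; \code{F_A} is \code{NA} when non-callable.
#' @examples
#' estimateFrequency(150, 50)   # F_A = 0.75
#' estimateFrequency(0, 0)      # non-callable
#' @export
estimateFrequency <- function(fA, fB) {
  if (any(fA < 0, na.rm = TRUE) || any(fB < 0, na.rm = TRUE))
    stop("per-allele fluorescences must be non-negative")
  tot <- fA + fB
  callable <- tot > 0
  FA <- ifelse(callable, fA / tot, NA_real_)
  data.frame(F_A = FA, F_B = 1 - FA, callable = callable)
}

#' Allelotype DNA pools from a probe-intensity table
#'
#' Corrects each probe quartet (PM - MM, clamped at zero), sums the corrected
#' fluorescence across the probes of each allele (ratio of sums, which is
#' more robust to a single dim probe than a mean of per-probe ratios), and
#' forms the allele-frequency estimate per SNP and pool.
#'
#' @param intensities \code{data.frame} in the probe-intensity schema
#'   (\code{snp_id}, \code{chrom}, \code{pos}, \code{probe_idx},
#'   \code{allele}, \code{PM}, \code{MM}, \code{pool_id}).
#' @return \code{data.frame} with one row per SNP x pool: \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{pool_id}, \code{f_A}, \code{f_B},
#'   \code{F_A}, \code{F_B}, \code{callable}.
#' @examples
#' sc <- generateCohort(CohortConfig(nSnps = 5, seed = 1))
#' pf <- allelotypePools(simulateIntensities(sc, seed = 1))
#' head(pf)
#' @export
allelotypePools <- function(intensities) {
  req <- c("snp_id", "probe_idx", "allele", "PM", "MM", "pool_id")
  miss <- setdiff(req, names(intensities))
  if (length(miss))
    stop("intensity table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(intensities$allele %in% c("A", "B")))
    stop("allele column must contain only A and B")

  f <- correctedFluorescence(intensities$PM, intensities$MM)
  key <- paste(intensities$snp_id, intensities$pool_id, sep = "\r")
  sums <- rowsum(data.frame(
    fA = ifelse(intensities$allele == "A", f, 0),
    fB = ifelse(intensities$allele == "B", f, 0),
    nA = as.numeric(intensities$allele == "A"),
    nB = as.numeric(intensities$allele == "B")), key, reorder = FALSE)

  bad <- sums$nA == 0 | sums$nB == 0
  if (any(bad)) {
    kb <- strsplit(rownames(sums)[which(bad)[1L]], "\r", fixed = TRUE)[[1L]]
    stop("missing probes for one allele at SNP ", kb[1L], ", pool ", kb[2L])
  }

  first <- !duplicated(key)
  meta <- intensities[first, intersect(c("snp_id", "chrom", "pos", "pool_id"),
                                       names(intensities)), drop = FALSE]
  stopifnot(identical(paste(meta$snp_id, meta$pool_id, sep = "\r"),
                      rownames(sums)))
  est <- estimateFrequency(sums$fA, sums$fB)
  out <- cbind(meta, f_A = sums$fA, f_B = sums$fB, est)
  rownames(out) <- NULL
  out
}
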