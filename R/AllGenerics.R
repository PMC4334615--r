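#' @rdname SyntheticCohort-class
#' @param x a \code{SyntheticCohort}.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("poolFrequencies", function(x) standardGeneric("poolFrequencies"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("poolInfo", function(x) standardGeneric("poolInfo"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("effectTruth", function(x) standardGeneric("effectTruth"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @describeIn SyntheticCohort-class genotype matrix (SNPs x individuals,
#'   copies of allele B, \code{NA} = missing call).
setMethod("genotypes", "SyntheticCohort", function(x)
  SummarizedExperiment::assay(x, "genotype"))

#' @describeIn SyntheticCohort-class exact per-pool allele-B frequencies
#'   (SNPs x pools).
setMethod("poolFrequencies", "SyntheticCohort", function(x) x@poolFreqs)

#' @describeIn SyntheticCohort-class pool id, group and replicate table.
setMethod("poolInfo", "SyntheticCohort", function(x) x@poolInfo)

#' @describeIn SyntheticCohort-class planted effect SNPs (index, target
#'   groups, allelic odds ratio, base and shifted frequencies).
setMethod("effectTruth", "SyntheticCohort", function(x) x@effectTruth)

#' @describeIn SyntheticCohort-class individual id, group label and pool
#'   assignment as a \code{data.frame}.
setMethod("phenotypes", "SyntheticCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(individual_id = rownames(cd), group = cd$group,
             pool_id = cd$pool_id, row.names = NULL,
             stringsAsFactors = FALSE)
})

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel:", object@probesPerAllele, "probes/allele,",
      "scale", object@signalScale, "| MM leak",
      object@backgroundMmFraction, "| probe CV",
      object@multiplicativeCv, "| floor", object@additiveFloor, "\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSnps, "SNPs on", object@nChromosomes,
      "chromosomes; MAF U(", object@mafLow, ",", object@mafHigh, ")\n")
  cat("  groups:", paste(object@groups, collapse = ", "),
      "(control:", object@groups[1L], ");",
      object@nIndividualsPerGroup, "individuals/group\n")
  cat("  pools:", object@poolsPerGroup, "x", object@poolSize,
      "individuals per group; missing rate", object@missingRate,
      "; seed", object@seed, "\n")
  if (nrow(object@effectSnps))
    cat("  planted effects:", nrow(object@effectSnps), "SNP(s)\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  callNextMethod()
  cat("pools:", ncol(object@poolFreqs), "(",
      paste(unique(object@poolInfo$group), collapse = ", "), ")",
      "| planted effects:", nrow(object@effectTruth), "\n")
})

setMethod("show", "RatioNull", function(object) {
  cat("RatioNull [", object@mode, "] chromosome ", object@chromosome, ": ",
      object@nSnps, " SNPs x ", object@nReps, " reps = ",
      length(object@mean), " pairs (eps = ", object@epsilon,
      ", seed ", object@seed, ")\n", sep = "")
})

setMethod("show", "GenotypeCounts", function(object) {
  cat("GenotypeCounts for", object@snpId, "- alleles",
      paste(object@alleles, collapse = "/"),
      sprintf("(call rate %.3f)\n", object@callRate))
  print(object@counts)
})
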