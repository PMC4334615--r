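# Readers and writers for the pipeline's tab-separated tables.  All writers
# produce deterministic byte streams (fixed column order, no quoting, no row
# names) so identical inputs and seeds give identical files.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname pipelineTables
#' @param intensities probe-intensity \code{data.frame} from
#'   \code{\link{simulateIntensities}}.
#' @export
writeIntensityTable <- function(intensities, path)
  .writeTsv(intensities[, c("snp_id", "chrom", "pos", "probe_idx", "allele",
                            "PM", "MM", "pool_id")], path)

#' Pipeline table input/output
#'
#' TSV readers and writers for every table the pipeline exchanges: probe
#' intensities, pool frequencies, genotype matrix (individuals in rows, SNPs
#' in columns on disk), phenotypes, SNP annotation, and reference allele
#' frequencies.  Readers validate the schema and abort with the offending
#' file name.
#'
#' @param path file path.
#' @return readers return a \code{data.frame} (the genotype reader a SNPs x
#'   individuals integer matrix); writers return the path invisibly.
#' @name pipelineTables
NULL

#' @rdname pipelineTables
#' @export
readIntensityTable <- function(path)
  .readTsv(path, c("snp_id", "chrom", "pos", "probe_idx", "allele", "PM",
                   "MM", "pool_id"), "probe-intensity")

#' @rdname pipelineTables
#' @param poolFreq pool-frequency \code{data.frame} from
#'   \code{\link{allelotypePools}}.
#' @export
writePoolFrequencies <- function(poolFreq, path)
  .writeTsv(poolFreq, path)

#' @rdname pipelineTables
#' @export
readPoolFrequencies <- function(path)
  .readTsv(path, c("snp_id", "pool_id", "F_A", "callable"), "pool-frequency")

#' @rdname pipelineTables
#' @param genotypes SNPs x individuals matrix, or a
#'   \code{\linkS4class{SyntheticCohort}}.
#' @export
writeGenotypeTable <- function(genotypes, path) {
  if (is(genotypes, "SyntheticCohort")) genotypes <- genotypes(genotypes)
  df <- data.frame(individual_id = colnames(genotypes),
                   t(genotypes), check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' @rdname pipelineTables
#' @export
readGenotypeMatrix <- function(path) {
  df <- .readTsv(path, "individual_id", "genotype")
  m <- t(as.matrix(df[, setdiff(names(df), "individual_id"), drop = FALSE]))
  storage.mode(m) <- "integer"
  colnames(m) <- df$individual_id
  m
}

#' @rdname pipelineTables
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @export
writePhenotypeTable <- function(cohort, path) {
  ph <- phenotypes(cohort)
  .writeTsv(ph[, c("individual_id", "group")], path)
}

#' @rdname pipelineTables
#' @export
readPhenotypeTable <- function(path)
  .readTsv(path, c("individual_id", "group"), "phenotype")

#' @rdname pipelineTables
#' @export
writeAnnotationTable <- function(cohort, path) {
  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  .writeTsv(rd[, c("snp_id", "chrom", "pos", "gene_label")], path)
}

#' @rdname pipelineTables
#' @export
readAnnotationTable <- function(path)
  .readTsv(path, c("snp_id", "chrom", "pos", "gene_label"), "annotation")

#' @rdname pipelineTables
#' @export
writeReferenceFrequencies <- function(cohort, path) {
  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  .writeTsv(data.frame(snp_id = rd$snp_id, ref_freq = rd$freq_b), path)
}

#' @rdname pipelineTables
#' @export
readReferenceFrequencies <- function(path)
  .readTsv(path, c("snp_id", "ref_freq"), "reference-frequency")

#' Write all synthetic pipeline inputs for one cohort
#'
#' Convenience wrapper producing every file the discovery and replication
#' stages consume: probe intensities (simulated with the cohort's noise
#' model), genotype matrix, phenotypes, SNP annotation and the reference
#' allele-frequency table (the population frequencies the cohort was drawn
#' from, standing in for an external reference panel).
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @param seed seed for the intensity simulation; defaults to the cohort's.
#' @return named character vector of file paths, invisibly.
#' @export
writeCohortTables <- function(cohort, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(seed)) seed <- cohort@config@seed
  paths <- c(intensities = file.path(dir, "intensities.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             reference = file.path(dir, "reference_freqs.tsv"))
  writeIntensityTable(simulateIntensities(cohort, seed = seed),
                      paths["intensities"])
  writeGenotypeTable(cohort, paths["genotypes"])
  writePhenotypeTable(cohort, paths["phenotypes"])
  writeAnnotationTable(cohort, paths["annotation"])
  writeReferenceFrequencies(cohort, paths["reference"])
  invisible(paths)
}

#' Read genotypes from a minimal VCF
#'
#' Reads GT fields from a VCF (one ALT allele per record) into the package's
#' SNPs x individuals 0/1/2 matrix counting ALT copies.  Requires the
#' \pkg{vcfR} package.
#'
#' @param path VCF file path.
#' @return integer matrix, SNPs x individuals.
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  m <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  m[clean == "0/0"] <- 0L
  m[clean %in% c("0/1", "1/0")] <- 1L
  m[clean == "1/1"] <- 2L
  m
}

#' Write genotypes as a minimal VCF (GT only)
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param path output path; \pkg{vcfR} appends \code{.gz}.
#' @return the path written, invisibly.
#' @export
writeGenotypeVcf <- function(cohort, path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("writing VCF requires the vcfR package")
  g <- genotypes(cohort)
  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g) + 1L)
  gt[, 1L] <- "GT"
  body <- c("0/0", "0/1", "1/1")[g + 1L]
  body[is.na(body)] <- "./."
  gt[, -1L] <- body
  colnames(gt) <- c("FORMAT", colnames(g))
  fix <- cbind(CHROM = rd$chrom, POS = as.character(rd$pos),
               ID = rd$snp_id, REF = "A", ALT = "B", QUAL = ".",
               FILTER = "PASS", INFO = ".")
  v <- new("vcfR", meta = c("##fileformat=VCFv4.2",
                            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
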