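# End-to-end orchestration of the discovery and replication stages, driven
# by a single YAML configuration with one global seed.

.configDefaults <- function() list(
  paths = list(intensities = NULL, annotation = NULL,
               reference_freqs = NULL, genotypes = NULL, phenotypes = NULL,
               shortlist = NULL, discovery_pool_freqs = NULL, outdir = "."),
  epsilon = 1e-4,
  cv_denominator = "sample",
  preselect_threshold = 20,
  n_reps = 1000L,
  fdr_alpha = 0.05,
  fdr_mode = "plain",
  null_mode = "uniform",
  shortlist = list(p_max = 0.001, freq_tol = 0.1),
  chip_profile = NULL,
  control_group = "CTR",
  hwe_method = "chisq",
  alpha = 0.05,
  seed = 1L)

#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file; unknown keys are rejected so
#' that typos cannot silently fall back to defaults.  Every threshold of
#' the pipeline is surfaced here: the frequency clamp \code{epsilon}, the
#' CV denominator convention, the pre-selection fold-change threshold, the
#' number of Monte Carlo replicates, the FDR level and mode, the shortlist
#' rule parameters, and the chip profile (SNPs per chromosome used for the
#' null; observed counts are used when absent).
#'
#' @param path YAML file path, or a named list to validate directly.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  def <- .configDefaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(cfg)) {
    if (nm %in% c("paths", "shortlist") && is.list(cfg[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), names(def[[nm]]))
      if (length(bad))
        stop("unknown config key(s) under ", nm, ": ",
             paste(bad, collapse = ", "))
      def[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else def[[nm]] <- cfg[[nm]]
  }
  stopifnot(def$epsilon > 0, def$epsilon < 0.5,
            def$preselect_threshold > 1,
            def$n_reps >= 1,
            def$fdr_alpha > 0, def$fdr_alpha < 1,
            def$cv_denominator %in% c("sample", "population"),
            def$fdr_mode %in% c("plain", "bh"),
            def$null_mode %in% c("uniform", "empirical"),
            def$hwe_method %in% c("chisq", "exact"))
  def
}

# pools are named "<group>_p<replicate>"; recover the layout from the ids
.poolsFromIds <- function(poolIds) {
  m <- regmatches(poolIds, regexec("^(.*)_p([0-9]+)$", poolIds))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad))
    stop("pool id(s) not of the form <group>_p<replicate>: ",
         paste(poolIds[bad], collapse = ", "))
  data.frame(pool_id = poolIds,
             group = vapply(m, `[`, character(1L), 2L),
             replicate = as.integer(vapply(m, `[`, character(1L), 3L)),
             stringsAsFactors = FALSE)
}

#' Run the discovery stage
#'
#' Pool allelotyping, ratio statistics with pre-selection, per-chromosome
#' Monte Carlo empirical probabilities, FDR selection, and replication
#' shortlisting, with a run manifest (config, seed, per-stage row counts).
#' Outputs are written to \code{paths$outdir}: \code{pool_frequencies.tsv},
#' \code{ratio_stats.tsv}, \code{candidates.tsv}, per-chromosome null
#' caches \code{null_<chrom>.tsv}, and \code{manifest.yaml}.
#'
#' @param config configuration list or YAML path, see
#'   \code{\link{readPipelineConfig}}.
#' @param seed optional seed overriding the config's.
#' @return the candidate \code{data.frame}, invisibly.
#' @export
runDiscovery <- function(config, seed = NULL) {
  cfg <- readPipelineConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outdir <- cfg$paths$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  intens <- readIntensityTable(cfg$paths$intensities)
  annot <- readAnnotationTable(cfg$paths$annotation)

  poolFreq <- allelotypePools(intens)
  writePoolFrequencies(poolFreq, file.path(outdir, "pool_frequencies.tsv"))
  pools <- .poolsFromIds(unique(poolFreq$pool_id))

  rs <- ratioStatistics(poolFreq, pools, controlGroup = cfg$control_group,
                        epsilon = cfg$epsilon,
                        threshold = cfg$preselect_threshold,
                        cvDenominator = cfg$cv_denominator)
  skipped <- attr(rs, "skipped")
  .writeTsv(rs, file.path(outdir, "ratio_stats.tsv"))

  # per-chromosome Monte Carlo null and empirical probabilities
  rs$p_mc <- NA_real_
  chroms <- unique(rs$chrom)
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    nSnpsChrom <- if (!is.null(cfg$chip_profile) &&
                      !is.null(cfg$chip_profile[[ch]]))
      as.integer(cfg$chip_profile[[ch]])
    else length(unique(rs$snp_id[rs$chrom == ch]))
    obs <- if (cfg$null_mode == "empirical")
      poolFreq$F_A[poolFreq$callable &
                     poolFreq$snp_id %in% rs$snp_id[rs$chrom == ch]]
    else NULL
    null <- simulateNull(nSnps = nSnpsChrom, nReps = cfg$n_reps,
                         seed = .deriveSeed(cfg$seed, 500L + i),
                         chromosome = ch, epsilon = cfg$epsilon,
                         mode = cfg$null_mode, observed = obs,
                         cvDenominator = cfg$cv_denominator)
    idx <- rs$chrom == ch
    rs$p_mc[idx] <- empiricalP(rs$mean_R[idx], rs$cv_R[idx], null)
    .writeTsv(data.frame(mean_R = null@mean, cv_R = null@cv,
                         score = null@scores),
              file.path(outdir, paste0("null_", ch, ".tsv")))
  }

  preselected <- rs$selected
  rs$selected <- preselected & fdrSelect(rs$p_mc, alpha = cfg$fdr_alpha,
                                         mode = cfg$fdr_mode)

  refFreqs <- if (!is.null(cfg$paths$reference_freqs))
    readReferenceFrequencies(cfg$paths$reference_freqs) else NULL
  ctrlPools <- pools$pool_id[pools$group == cfg$control_group]
  ctrlSub <- poolFreq[poolFreq$pool_id %in% ctrlPools & poolFreq$callable, ]
  ctrlFreqs <- stats::aggregate(ctrl_freq ~ snp_id,
                                data = data.frame(snp_id = ctrlSub$snp_id,
                                                  ctrl_freq = ctrlSub$F_B),
                                FUN = mean)

  cand <- replicationShortlist(
    data.frame(rs[, c("snp_id", "chrom", "subtype", "mean_R", "cv_R",
                      "p_mc")],
               preselected = preselected, selected = rs$selected,
               stringsAsFactors = FALSE),
    annotation = annot, referenceFreqs = refFreqs, controlFreqs = ctrlFreqs,
    pMax = cfg$shortlist$p_max, freqTol = cfg$shortlist$freq_tol)
  .writeTsv(cand, file.path(outdir, "candidates.tsv"))

  manifest <- list(
    stage = "discovery", seed = cfg$seed, config = cfg,
    counts = list(probe_rows = nrow(intens),
                  snp_pool_rows = nrow(poolFreq),
                  non_callable = sum(!poolFreq$callable),
                  ratio_rows = nrow(rs),
                  skipped_contrasts = nrow(skipped),
                  preselected = sum(preselected),
                  selected = sum(rs$selected),
                  shortlisted = sum(cand$shortlist_rule != "")))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(cand)
}

#' Run the replication stage
#'
#' Individual-genotype association statistics for the shortlisted SNPs, per
#' case subtype: genotypic chi-square, oriented allelic odds ratio with
#' Woolf CI, HWE in controls, call rate, and (when discovery pool
#' frequencies are supplied) Breslow-Day heterogeneity between stages.
#' Writes \code{association.tsv} and \code{manifest_replication.yaml} to
#' \code{paths$outdir}.
#'
#' @param config configuration list or YAML path.
#' @param seed optional seed overriding the config's (recorded in the
#'   manifest; the stage itself is deterministic).
#' @return the association \code{data.frame}, invisibly.
#' @export
runReplication <- function(config, seed = NULL) {
  cfg <- readPipelineConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outdir <- cfg$paths$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  geno <- if (grepl("\\.vcf(\\.gz)?$", cfg$paths$genotypes))
    readGenotypeVcf(cfg$paths$genotypes)
  else readGenotypeMatrix(cfg$paths$genotypes)
  pheno <- readPhenotypeTable(cfg$paths$phenotypes)
  geno <- geno[, pheno$individual_id, drop = FALSE]

  shortPath <- cfg$paths$shortlist
  if (is.null(shortPath))
    shortPath <- file.path(outdir, "candidates.tsv")
  short <- .readTsv(shortPath, "snp_id", "shortlist")
  if ("shortlist_rule" %in% names(short))
    short <- short[!is.na(short$shortlist_rule) &
                     short$shortlist_rule != "", , drop = FALSE]
  short <- short[!is.na(short$snp_id), , drop = FALSE]

  subtypes <- setdiff(unique(pheno$group), cfg$control_group)

  # optional discovery-stage strata for the heterogeneity test
  discTables <- NULL
  if (!is.null(cfg$paths$discovery_pool_freqs)) {
    pf <- readPoolFrequencies(cfg$paths$discovery_pool_freqs)
    pools <- .poolsFromIds(unique(pf$pool_id))
    discTables <- function(subtype) {
      ids <- unique(short$snp_id)
      tabs <- lapply(ids, function(s) {
        fc <- pf$F_B[pf$snp_id == s &
                       pf$pool_id %in% pools$pool_id[pools$group == subtype]]
        f0 <- pf$F_B[pf$snp_id == s &
                       pf$pool_id %in%
                       pools$pool_id[pools$group == cfg$control_group]]
        if (!length(fc) || !length(f0)) return(NULL)
        discoveryAlleleTable(fc, f0)
      })
      names(tabs) <- ids
      tabs[!vapply(tabs, is.null, logical(1L))]
    }
  }

  rows <- list()
  if (nrow(short)) {
    for (st in subtypes) {
      dt <- if (!is.null(discTables)) discTables(st) else NULL
      rows[[st]] <- associationTable(
        geno, pheno$group, subtypes = st,
        controlGroup = cfg$control_group,
        snpIds = unique(short$snp_id), discoveryTables = dt,
        hweMethod = cfg$hwe_method, alpha = cfg$alpha)
    }
  }
  assoc <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(snp_id = character(), subtype = character())
  .writeTsv(assoc, file.path(outdir, "association.tsv"))

  manifest <- list(stage = "replication", seed = cfg$seed, config = cfg,
                   counts = list(shortlist_snps = length(unique(short$snp_id)),
                                 association_rows = nrow(assoc),
                                 significant = if (nrow(assoc))
                                   sum(assoc$significant) else 0L))
  yaml::write_yaml(manifest, file.path(outdir, "manifest_replication.yaml"))
  invisible(assoc)
}

#' Plain-text run report
#'
#' Summarizes the discovery and replication outputs found in a pipeline
#' output directory into \code{report.txt}.
#'
#' @param outdir pipeline output directory.
#' @return the report path, invisibly.
#' @export
pipelineReport <- function(outdir) {
  lines <- c("pooled-sample GWAS pipeline report", "")
  cf <- file.path(outdir, "candidates.tsv")
  if (file.exists(cf)) {
    cand <- utils::read.delim(cf, stringsAsFactors = FALSE)
    lines <- c(lines,
               sprintf("discovery: %d SNP x subtype statistics", nrow(cand)),
               sprintf("  pre-selected: %d", sum(cand$preselected)),
               sprintf("  selected (FDR): %d", sum(cand$selected)),
               sprintf("  shortlisted: %d", sum(cand$shortlist_rule != "")))
  }
  af <- file.path(outdir, "association.tsv")
  if (file.exists(af)) {
    assoc <- utils::read.delim(af, stringsAsFactors = FALSE)
    lines <- c(lines,
               sprintf("replication: %d SNP x subtype tests", nrow(assoc)))
    if (nrow(assoc))
      lines <- c(lines,
                 sprintf("  significant at 0.05: %d",
                         sum(assoc$significant)),
                 sprintf("  mean call rate: %.3f", mean(assoc$call_rate)))
  }
  path <- file.path(outdir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
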