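#' Simulate a complete paired-methylome study
#'
#' One-call wrapper around the synthetic-data module: annotation, cohort,
#' methylation with ground truth, coupled expression and a toy VCF.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param nCoupled coupled probe-gene pairs (default 50).
#' @param vcfRecords,vcfPass toy VCF record counts (default 10 and 4).
#' @return list with \code{annotation} (the full
#'   \code{\link{simulateAnnotation}} output), \code{metadata}, \code{mset},
#'   \code{truth}, \code{expression} and \code{vcf}.
#' @export
simulateStudy <- function(cfg, nCoupled = 50L, vcfRecords = 10L,
                          vcfPass = 4L) {
  ann <- simulateAnnotation(cfg@nProbes, cfg@nGenes, cfg@seed)
  meta <- simulateCohort(cfg)
  meth <- simulateMethylation(ann$annotation, meta, cfg)
  dmps <- meth$truth$probes$probe_id[meth$truth$probes$is_dmp]
  expr <- simulateExpression(ann$annotation, meta, meth$mset, ann$genes, cfg,
                             nCoupled = nCoupled,
                             preferProbes = if (length(dmps)) dmps else NULL)
  vcf <- simulateToyVcf(vcfRecords, vcfPass, seed = cfg@seed)
  list(annotation = ann, metadata = meta, mset = meth$mset,
       truth = meth$truth, expression = expr, vcf = vcf)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes every stage end to end: intensity QC, stratified quantile
#' normalization, probe filtering, the moderated probe-level location model
#' with surrogate variables, region and block calling with bootstrap FWER,
#' differential variability with mean-difference filtering, the paired
#' age-divergence model with trajectory clustering, methylome distance
#' contrasts, methylation-expression association with enrichment, and
#' chromatin-state enrichment of the called regions.
#'
#' @param study list from \code{\link{simulateStudy}}.
#' @param nSv surrogate variables for the probe-level model (default 6).
#' @param B bootstrap iterations for regions/blocks.
#' @param seed integer seed used for every stochastic stage.
#' @param fwerThreshold region/block significance threshold.
#' @return named list with each stage's results.
#' @export
runPipeline <- function(study, nSv = 6, B = 100, seed = 1L,
                        fwerThreshold = 0.1) {
  mset <- study$mset
  qcFlags <- qcMedianIntensity(mset)
  if (length(qcFlags))
    mset <- mset[, !colnames(betaValues(mset)) %in% qcFlags]
  mset <- stratifiedQuantileNormalize(mset)
  mset <- filterProbes(mset)
  ann <- probeAnnotation(mset)

  dmp <- runDmpAnalysis(mset, nSv = nSv, seed = seed)
  dmr <- runDmrAnalysis(mset, svs = dmp$svs, B = B, seed = seed,
                        fwerThreshold = fwerThreshold)
  blocks <- runBlockAnalysis(mset, svs = dmp$svs, B = B, seed = seed,
                             fwerThreshold = fwerThreshold)

  dv <- differentialVariability(betaValues(mset), locationIndicator(mset))
  dv <- filterMeanDm(dv, dmp$fits)

  pd <- pairedDifferences(mset)
  agediv <- fitAgeDivergence(pd, nSv = min(3L, ncol(pd$diffs) - 3L),
                             seed = seed)
  sigAge <- agediv$probe_id[agediv$q < 0.10]
  ageclust <- if (length(sigAge) >= 8L)
    clusterAgePatterns(mset, sigAge, k = 8, seed = seed) else NULL

  meta <- sampleInfo(mset)
  dt <- pairwiseDistances(betaValues(mset), meta$location)
  distContrast <- compareDistanceSets(dt, "scalp vs scalp", "dura vs dura")

  pairs <- mapProbesToFeatures(ann, study$annotation$genes, window = 5000)
  assoc <- associateMethylationExpression(
    betaValues(mset), study$expression$logExpr, pairs)
  sigDmp <- dmp$fits$probe_id[dmp$fits$q < 0.05]
  inPairs <- unique(assoc$probe_id)
  assocSig <- unique(assoc$probe_id[assoc$significant])
  tab <- table(dmp = inPairs %in% sigDmp, assoc = inPairs %in% assocSig)
  enrich <- if (all(dim(tab) == c(2, 2)) && all(tab > 0))
    enrichment2x2(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1]) else NULL

  sigRegions <- dmr$regions[dmr$regions$significant, , drop = FALSE]
  stateEnrich <- if (nrow(sigRegions)) {
    chromatinStateEnrichment(
      GRanges(sigRegions$chrom, IRanges(sigRegions$start, sigRegions$end)),
      study$annotation$segmentation,
      GRanges(ann$chrom, IRanges(ann$pos, width = 1L)))
  } else NULL

  variants <- filterVariants(study$vcf$file)

  list(mset = mset, qcFlags = qcFlags, dmp = dmp, dmr = dmr,
       blocks = blocks, variability = dv, agediv = agediv,
       ageClusters = ageclust, distances = dt,
       distanceContrast = distContrast, association = assoc,
       enrichment = enrich, stateEnrichment = stateEnrich,
       variants = variants)
}
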