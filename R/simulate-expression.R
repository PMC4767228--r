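#' Generate expression data coupled to methylation
#'
#' Produces an FPKM-like gene expression matrix for the simulated cohort in
#' which a chosen number of genes are "coupled" to a nearby probe (within
#' 5 kb): the gene's log2(FPKM + 1) value is a linear function of the probe's
#' beta value plus noise calibrated so the Pearson correlation between the
#' two is \code{couplingR} in expectation. All other genes are independent of
#' the methylome. FPKM values are non-negative by construction.
#'
#' @param annotation probe annotation data.frame (from
#'   \code{\link{simulateAnnotation}}).
#' @param metadata sample metadata (from \code{\link{simulateCohort}}).
#' @param mset the \linkS4class{MethylationExperiment} whose beta values
#'   drive the coupled genes.
#' @param genes \link[GenomicRanges]{GRanges} of gene models with a
#'   \code{gene_id} column.
#' @param cfg a \linkS4class{SimulationConfig} (uses \code{couplingR} and
#'   \code{seed}).
#' @param nCoupled number of coupled probe-gene pairs to plant.
#' @param preferProbes optional character vector of probe ids to couple
#'   preferentially (e.g. planted differential probes).
#' @return list with \code{fpkm} (genes-by-samples matrix), \code{logExpr}
#'   (log2(FPKM + 1)), and \code{coupledPairs} (data.frame gene_id, probe_id,
#'   distance, r_target).
#' @examples
#' cfg <- SimulationConfig(nDonors = 6L, nProbes = 300L, nGenes = 40L,
#'                         nDmrs = 0L, nBlocks = 0L, nAgediv = 0L,
#'                         nVarloci = 0L)
#' sim <- simulateAnnotation(cfg@nProbes, cfg@nGenes, cfg@seed)
#' meta <- simulateCohort(cfg)
#' ms <- simulateMethylation(sim$annotation, meta, cfg)$mset
#' ex <- simulateExpression(sim$annotation, meta, ms, sim$genes, cfg,
#'                          nCoupled = 10L)
#' @export
simulateExpression <- function(annotation, metadata, mset, genes, cfg,
                               nCoupled = 50L, preferProbes = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  r <- cfg@couplingR
  if (abs(r) >= 1) stop("couplingR must lie in (-1, 1)")
  withSeed(cfg@seed + 2L, {
    beta <- betaValues(mset)
    N <- ncol(beta)
    G <- length(genes)
    pairs <- mapProbesToFeatures(annotation, genes, window = 5000)
    if (!is.null(preferProbes)) {
      pref <- pairs[pairs$probe_id %in% preferProbes, , drop = FALSE]
      if (nrow(pref) > 0L) pairs <- pref
    }
    if (nrow(pairs) == 0L)
      stop("no gene has a probe within 5 kb; cannot couple")
    # one probe per gene: the closest candidate
    pairs <- pairs[order(pairs$feature_id, pairs$distance), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$feature_id), , drop = FALSE]
    nCoupled <- min(nCoupled, nrow(pairs))
    sel <- pairs[sample.int(nrow(pairs), nCoupled), , drop = FALSE]

    # within-group biological noise of ~0.5 log2 units; coupled genes get a
    # DNAm-expression slope of 6 log2 units per beta unit (a 20% methylation
    # difference then drives a ~2.3-fold expression change, the scale at
    # which methylation-coupled gene sets visibly separate sample groups)
    logE <- matrix(stats::rnorm(G * N, 0, 0.5), G, N)
    a <- stats::runif(G, 3, 6)
    logE <- logE + a
    rownames(logE) <- genes$gene_id
    colnames(logE) <- metadata$sample_id

    if (nCoupled > 0L && r != 0) {
      b <- 6 * sign(r)
      for (k in seq_len(nCoupled)) {
        g <- sel$feature_id[k]
        p <- sel$probe_id[k]
        bv <- beta[p, ]
        s <- stats::sd(bv)
        if (s == 0) s <- 1e-6
        noise <- stats::rnorm(N, 0, abs(b) * s * sqrt(1 / r^2 - 1))
        logE[g, ] <- a[match(g, genes$gene_id)] +
          b * (bv - mean(bv)) + noise
      }
    }
    logE <- pmax(logE, 0)
    fpkm <- 2^logE - 1
    list(fpkm = fpkm, logExpr = logE,
         coupledPairs = data.frame(gene_id = sel$feature_id,
                                   probe_id = sel$probe_id,
                                   distance = sel$distance,
                                   r_target = r,
                                   stringsAsFactors = FALSE))
  })
}
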