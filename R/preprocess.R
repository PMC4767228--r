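#' Flag low-intensity samples
#'
#' A sample is flagged when the mean of its median log2 methylated and median
#' log2 unmethylated intensities falls below \code{threshold} — the standard
#' array QC heuristic for detecting failed hybridizations. Flagged samples
#' should be dropped before across-sample normalization.
#'
#' @param mset a \linkS4class{MethylationExperiment} with intensity channels.
#' @param threshold log2-intensity cutoff (default 10.5).
#' @return character vector of flagged sample ids (possibly empty).
#' @examples
#' \dontrun{qcMedianIntensity(mset)}
#' @export
qcMedianIntensity <- function(mset, threshold = 10.5) {
  if (!hasIntensities(mset))
    stop("QC on median intensities requires M and U channels")
  m <- apply(log2(pmax(methylated(mset), 1e-6)), 2, stats::median)
  u <- apply(log2(pmax(unmethylated(mset), 1e-6)), 2, stats::median)
  flagged <- (m + u) / 2 < threshold
  colnames(betaValues(mset))[flagged]
}

# Quantile-normalize the columns of a matrix to the mean order statistics.
# Ties receive the mean of the tied order statistics.
quantileNormalizeColumns <- function(x) {
  if (ncol(x) < 2L) return(x)
  sorted <- apply(x, 2, sort)
  target <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- target
    xs <- x[o, j]
    # tie groups share the mean of their order statistics
    ties <- stats::ave(v, match(xs, unique(xs)), FUN = mean)
    out[o, j] <- ties
  }
  out
}

#' Stratified quantile normalization
#'
#' Quantile-normalizes the M and U channels separately across samples within
#' each probe stratum, then recomputes beta with the configured offset. The
#' strata are the combinations of probe design type and CpG island relation,
#' following the spirit of the stratified normalization used for 450k arrays:
#' probes with different chemistries and genomic contexts have different
#' intensity distributions, and normalizing within strata avoids distorting
#' those differences while removing per-sample global scale.
#'
#' After normalization, the within-stratum sorted intensity vectors are
#' identical across samples. With a single sample the input is returned
#' unchanged with a warning. The transform is idempotent.
#'
#' @param mset a \linkS4class{MethylationExperiment} with intensity channels.
#' @param strataBy rowData columns defining strata (default design type and
#'   island relation).
#' @return a \linkS4class{MethylationExperiment} with normalized M/U and
#'   recomputed beta.
#' @export
stratifiedQuantileNormalize <- function(mset,
                                        strataBy = c("design_type",
                                                     "island_relation")) {
  if (!hasIntensities(mset))
    stop("stratified quantile normalization requires M and U channels")
  if (ncol(mset) < 2L) {
    warning("single sample: returning input unchanged")
    return(mset)
  }
  ann <- probeAnnotation(mset)
  miss <- setdiff(strataBy, colnames(ann))
  if (length(miss))
    stop("annotation lacks strata column(s): ", paste(miss, collapse = ", "))
  strat <- interaction(ann[, strataBy, drop = FALSE], drop = TRUE)
  M <- methylated(mset)
  U <- unmethylated(mset)
  for (s in levels(strat)) {
    idx <- which(strat == s)
    M[idx, ] <- quantileNormalizeColumns(M[idx, , drop = FALSE])
    U[idx, ] <- quantileNormalizeColumns(U[idx, , drop = FALSE])
  }
  MethylationExperiment(M = M, U = U, annotation = ann,
                        metadata = sampleInfo(mset), offset = mset@offset)
}

#' Filter probes by SNP overlap and sex chromosomes
#'
#' Removes probes flagged as containing a common SNP at the target CpG or
#' single-base-extension site, and probes on the sex chromosomes, preserving
#' the order and values of the retained probes.
#'
#' @param mset a \linkS4class{MethylationExperiment}.
#' @param dropSnp drop SNP-flagged probes (default TRUE).
#' @param dropSexChroms drop chrX/chrY probes (default TRUE).
#' @return the filtered \linkS4class{MethylationExperiment}.
#' @export
filterProbes <- function(mset, dropSnp = TRUE, dropSexChroms = TRUE) {
  ann <- probeAnnotation(mset)
  keep <- rep(TRUE, nrow(ann))
  if (dropSnp && "snp_flag" %in% colnames(ann))
    keep <- keep & !ann$snp_flag
  if (dropSexChroms)
    keep <- keep & !ann$chrom %in% c("chrX", "chrY")
  if (!any(keep))
    stop("probe filtering removed every probe")
  mset[keep, ]
}
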