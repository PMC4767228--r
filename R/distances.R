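#' Jointly normalize multiple methylation datasets
#'
#' Combines the M and U channels of several datasets over their shared probe
#' universe (intersection), applies one stratified quantile normalization
#' across the union of samples, and drops SNP-flagged and sex-chromosome
#' probes — the preprocessing used before cross-dataset methylome distance
#' comparisons.
#'
#' @param msets list of \linkS4class{MethylationExperiment} objects with
#'   intensity channels. Sample ids must be unique across datasets (they are
#'   prefixed with the list names, or the list index, when not).
#' @return a combined, normalized and filtered
#'   \linkS4class{MethylationExperiment}.
#' @export
jointNormalize <- function(msets) {
  stopifnot(is.list(msets), length(msets) >= 1L)
  ids <- Reduce(intersect, lapply(msets, function(m) rownames(betaValues(m))))
  if (length(ids) == 0L) stop("empty probe intersection across datasets")
  pieces <- lapply(seq_along(msets), function(i) {
    m <- msets[[i]]
    if (!hasIntensities(m)) stop("joint normalization requires intensities")
    meta <- sampleInfo(m)
    list(M = methylated(m)[ids, , drop = FALSE],
         U = unmethylated(m)[ids, , drop = FALSE], meta = meta)
  })
  allIds <- unlist(lapply(pieces, function(p) p$meta$sample_id))
  if (anyDuplicated(allIds)) {
    nms <- names(msets)
    if (is.null(nms)) nms <- paste0("set", seq_along(msets))
    pieces <- lapply(seq_along(pieces), function(i) {
      p <- pieces[[i]]
      p$meta$sample_id <- paste(nms[i], p$meta$sample_id, sep = ".")
      colnames(p$M) <- colnames(p$U) <- p$meta$sample_id
      p
    })
  }
  M <- do.call(cbind, lapply(pieces, `[[`, "M"))
  U <- do.call(cbind, lapply(pieces, `[[`, "U"))
  meta <- do.call(rbind, lapply(pieces, `[[`, "meta"))
  annFull <- probeAnnotation(msets[[1]])
  ann <- annFull[match(ids, annFull$probe_id), , drop = FALSE]
  combined <- MethylationExperiment(M = M, U = U, annotation = ann,
                                    metadata = meta,
                                    offset = msets[[1]]@offset)
  # filter before normalizing so the returned object satisfies the quantile
  # property exactly (identical within-stratum sorted values per sample)
  combined <- filterProbes(combined, dropSnp = TRUE, dropSexChroms = TRUE)
  stratifiedQuantileNormalize(combined)
}

#' Pairwise Euclidean methylome distances
#'
#' Computes Euclidean distances between samples on the proportion-methylation
#' scale, labels each unordered pair by its group comparison, and optionally
#' restricts to selected comparisons. Within-group comparisons exclude
#' self-pairs and count each unordered pair once; between-group comparisons
#' use all cross pairs.
#'
#' @param beta probes-by-samples matrix (no missing values).
#' @param groups character vector of group labels per sample.
#' @param comparisons optional list of 2-vectors \code{c(group_a, group_b)}
#'   selecting comparisons.
#' @return data.frame: \code{sample_a}, \code{sample_b}, \code{group_a},
#'   \code{group_b}, \code{distance}, \code{comparison} (groups joined with
#'   " vs ", alphabetical).
#' @examples
#' b <- cbind(a1 = c(.1, .5), b1 = c(.4, .9))
#' pairwiseDistances(b, groups = c("A", "B"))
#' @export
pairwiseDistances <- function(beta, groups, comparisons = NULL) {
  beta <- as.matrix(beta)
  if (anyNA(beta)) stop("beta contains missing values; no imputation is done")
  n <- ncol(beta)
  if (n < 2L) stop("need >= 2 samples")
  stopifnot(length(groups) == n)
  ids <- colnames(beta)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  d <- as.matrix(stats::dist(t(beta)))
  pr <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(
    sample_a = ids[pr[, 1]], sample_b = ids[pr[, 2]],
    group_a = groups[pr[, 1]], group_b = groups[pr[, 2]],
    distance = d[pr], stringsAsFactors = FALSE)
  swap <- out$group_a > out$group_b
  tmp <- out$group_a[swap]
  out$group_a[swap] <- out$group_b[swap]
  out$group_b[swap] <- tmp
  out$comparison <- paste(out$group_a, out$group_b, sep = " vs ")
  if (!is.null(comparisons)) {
    want <- vapply(comparisons, function(cc)
      paste(sort(cc), collapse = " vs "), character(1))
    out <- out[out$comparison %in% want, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Contrast two sets of methylome distances
#'
#' Welch two-sample t test on the distances of two comparisons, plus an
#' F ratio of their variances, contrasting both the location and the spread
#' of the two distance distributions. Pairwise distances sharing samples are
#' not independent, so the p-values are descriptive rather than exact.
#'
#' @param table data.frame from \code{\link{pairwiseDistances}}.
#' @param setA,setB comparison labels (as in \code{table$comparison}).
#' @return list: \code{t}, \code{p} (Welch), \code{meanA}, \code{meanB},
#'   \code{varRatio} (A over B), \code{varP} (F test), \code{nA}, \code{nB}.
#' @export
compareDistanceSets <- function(table, setA, setB) {
  a <- table$distance[table$comparison == setA]
  b <- table$distance[table$comparison == setB]
  if (length(a) < 2L || length(b) < 2L)
    stop("each distance set needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    t <- 0; p <- 1
    f <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    tt <- stats::t.test(a, b)
    t <- unname(tt$statistic); p <- tt$p.value
    f <- stats::var.test(a, b)
  }
  list(t = t, p = p, meanA = mean(a), meanB = mean(b),
       varRatio = unname(stats::var(a) / stats::var(b)),
       varP = f$p.value, nA = length(a), nB = length(b))
}

#' Cluster samples by methylome
#'
#' Average-linkage hierarchical clustering on the Euclidean distance matrix,
#' or principal component scores. Deterministic given the input order.
#'
#' @param beta probes-by-samples matrix.
#' @param method \code{"average"} (hierarchical; also returns a Newick
#'   string) or \code{"pca"}.
#' @return for \code{"average"}: list with \code{hclust} and \code{newick};
#'   for \code{"pca"}: list with \code{scores} and \code{varFrac}.
#' @export
clusterSamples <- function(beta, method = c("average", "pca")) {
  method <- match.arg(method)
  beta <- as.matrix(beta)
  if (ncol(beta) < 3L) stop("need >= 3 samples")
  if (method == "average") {
    hc <- stats::hclust(stats::dist(t(beta)), method = "average")
    nwk <- ape::write.tree(ape::as.phylo(hc))
    list(hclust = hc, newick = nwk)
  } else {
    pc <- stats::prcomp(t(beta), center = TRUE)
    list(scores = pc$x, varFrac = pc$sdev^2 / sum(pc$sdev^2))
  }
}

#' Permutation test for gene-set driven group separation
#'
#' Measures how well a gene set separates two sample groups: the observed
#' separation is the mean between-group Euclidean distance computed on the
#' expression of the set's genes; the null repeats the computation on
#' \code{nRandom} random gene sets of the same size, and
#' \code{p = (# null >= observed + 1) / (nRandom + 1)}.
#'
#' @param expr genes-by-samples expression matrix (log scale).
#' @param groups two-level group vector per sample.
#' @param geneSet character vector of gene ids, a subset of
#'   \code{rownames(expr)}.
#' @param nRandom number of random sets (default 1000).
#' @param seed integer seed.
#' @return list: \code{observed}, \code{null} (length nRandom), \code{p}.
#' @export
geneSetSeparationTest <- function(expr, groups, geneSet, nRandom = 1000,
                                  seed = 1L) {
  expr <- as.matrix(expr)
  if (nRandom < 1L) stop("nRandom must be >= 1")
  if (!all(geneSet %in% rownames(expr)))
    stop("gene set contains genes absent from the expression matrix")
  if (length(geneSet) > nrow(expr))
    stop("gene set larger than the gene universe")
  gl <- unique(groups)
  if (length(gl) != 2L) stop("need exactly two groups")
  ia <- which(groups == gl[1]); ib <- which(groups == gl[2])
  betweenSep <- function(genes) {
    d <- as.matrix(stats::dist(t(expr[genes, , drop = FALSE])))
    mean(d[ia, ib])
  }
  observed <- betweenSep(geneSet)
  null <- withSeed(seed, {
    vapply(seq_len(nRandom), function(i)
      betweenSep(sample(rownames(expr), length(geneSet))), numeric(1))
  })
  list(observed = observed, null = null,
       p = (sum(null >= observed) + 1) / (nRandom + 1))
}
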