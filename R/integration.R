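#' Map probes to nearby genes or transcripts
#'
#' A probe is paired with a feature when it lies inside the feature's span or
#' within \code{window} basepairs of its nearest edge (boundary inclusive).
#' All qualifying pairs are returned; callers wanting a single feature per
#' probe can keep the strongest correlation downstream.
#'
#' @param annotation probe annotation data.frame with \code{probe_id},
#'   \code{chrom}, \code{pos}.
#' @param features \link[GenomicRanges]{GRanges} of gene/transcript models
#'   with an id in the first metadata column (e.g. \code{gene_id}).
#' @param window maximum distance in bp (default 5000).
#' @return data.frame: \code{probe_id}, \code{feature_id}, \code{distance}
#'   (0 when inside).
#' @export
mapProbesToFeatures <- function(annotation, features, window = 5000) {
  if (window < 0) stop("window must be >= 0")
  probes <- GRanges(annotation$chrom, IRanges(annotation$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(probes, features,
                                      maxgap = window)
  if (length(hits) == 0L)
    return(data.frame(probe_id = character(0), feature_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # arithmetic distance to the nearest feature edge (0 inside)
  p <- annotation$pos[qh]
  s <- GenomicRanges::start(features)[sh]
  e <- GenomicRanges::end(features)[sh]
  d <- ifelse(p < s, s - p, ifelse(p > e, p - e, 0))
  fid <- as.character(S4Vectors::mcols(features)[[1]])
  out <- data.frame(probe_id = annotation$probe_id[qh],
                    feature_id = fid[sh],
                    distance = as.numeric(d),
                    stringsAsFactors = FALSE)
  out <- out[out$distance <= window, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate methylation with expression
#'
#' For each probe-feature pair, fits the simple linear model of log
#' expression on beta, reporting the Pearson correlation and its two-sided
#' p-value; pairs with zero variance on either side are flagged untestable.
#' Significance is called at p < 0.05 by convention.
#'
#' @param beta probes-by-samples matrix.
#' @param expr features-by-samples matrix of log expression, sharing sample
#'   columns with \code{beta}.
#' @param pairs data.frame from \code{\link{mapProbesToFeatures}}.
#' @param pThreshold significance convention (default 0.05).
#' @return the pair data.frame with \code{r}, \code{p}, \code{significant}
#'   and \code{testable} columns.
#' @export
associateMethylationExpression <- function(beta, expr, pairs,
                                           pThreshold = 0.05) {
  shared <- intersect(colnames(beta), colnames(expr))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  b <- beta[pairs$probe_id, shared, drop = FALSE]
  e <- expr[pairs$feature_id, shared, drop = FALSE]
  n <- length(shared)
  bc <- b - rowMeans(b)
  ec <- e - rowMeans(e)
  sb <- sqrt(rowSums(bc^2))
  se <- sqrt(rowSums(ec^2))
  testable <- sb > 0 & se > 0
  r <- rep(NA_real_, nrow(pairs))
  r[testable] <- rowSums(bc * ec)[testable] / (sb * se)[testable]
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  pairs$r <- r
  pairs$p <- p
  pairs$significant <- !is.na(p) & p < pThreshold
  pairs$testable <- testable
  pairs
}

#' Directionality of methylation-expression associations
#'
#' Within each stratum of CpG island relation crossed with overall
#' methylation level (unmethylated < 0.2, partially methylated 0.2-0.8,
#' highly methylated > 0.8 mean beta), counts significant pairs with
#' positive versus negative correlation and tests the balance against 0.5
#' with the two-sided exact binomial test. Empty strata are reported with NA.
#'
#' @param pairs data.frame from
#'   \code{\link{associateMethylationExpression}}.
#' @param annotation probe annotation with \code{probe_id} and
#'   \code{island_relation}.
#' @param beta probes-by-samples matrix (for mean methylation binning).
#' @param bins cutpoints for the three methylation classes (default 0.2 and
#'   0.8).
#' @return data.frame per stratum: \code{island_relation},
#'   \code{methylation_bin}, \code{n_pos}, \code{n_neg}, \code{p_binomial}.
#' @export
directionalitySummary <- function(pairs, annotation, beta,
                                  bins = c(0.2, 0.8)) {
  sig <- pairs[pairs$significant & pairs$testable, , drop = FALSE]
  mb <- rowMeans(beta)[sig$probe_id]
  mbin <- cut(mb, c(-Inf, bins[1], bins[2], Inf),
              labels = c("un", "partial", "high"))
  rel <- annotation$island_relation[match(sig$probe_id, annotation$probe_id)]
  rels <- c("island", "shore", "shelf", "open_sea")
  lv <- expand.grid(island_relation = rels,
                    methylation_bin = c("un", "partial", "high"),
                    stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(lv)), function(i) {
    idx <- which(rel == lv$island_relation[i] & mbin == lv$methylation_bin[i])
    np <- sum(sig$r[idx] > 0)
    nn <- sum(sig$r[idx] < 0)
    p <- if (np + nn == 0) NA_real_
         else stats::binom.test(np, np + nn, 0.5)$p.value
    data.frame(lv[i, , drop = FALSE], n_pos = np, n_neg = nn,
               p_binomial = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' 2x2 enrichment with Yates-corrected chi-squared
#'
#' Tests a 2x2 contingency table (e.g. differential probe x significant
#' expression association) with Pearson's chi-squared and Yates' continuity
#' correction, reporting the odds ratio \code{(a*d)/(b*c)}. The correction
#' term is floored at zero when |observed - expected| < 0.5.
#'
#' @param a,b,c,d cell counts (a/b first row, c/d second row).
#' @return list: \code{counts} (2x2 matrix), \code{odds_ratio},
#'   \code{chi2_yates}, \code{p}.
#' @examples
#' enrichment2x2(20, 10, 10, 20)
#' @export
enrichment2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (sum(cnt) == 0) stop("empty table")
  m <- matrix(cnt, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("a zero margin leaves the chi-squared statistic undefined")
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(counts = m,
       odds_ratio = (a * d) / (b * c),
       chi2_yates = unname(ct$statistic),
       p = ct$p.value)
}

#' Chromatin-state coverage enrichment
#'
#' Computes, for every chromatin state, the basepair coverage of a feature
#' set and of a background set within the state's segmentation intervals;
#' the fold enrichment is the ratio of the two coverage fractions, and folds
#' beyond 1.5 in either direction are highlighted. Sex and mitochondrial
#' chromosomes are dropped before the overlap.
#'
#' @param features \link[GenomicRanges]{GRanges} of feature intervals (e.g.
#'   significant probes, regions or blocks).
#' @param segmentation \code{GRanges} tiling the genome with a \code{state}
#'   metadata column.
#' @param background \code{GRanges} of background intervals (e.g. all
#'   probes, all probe groups).
#' @param highlightFold fold threshold (default 1.5).
#' @return data.frame per state: \code{state}, \code{feature_bp},
#'   \code{background_bp}, \code{feature_frac}, \code{background_frac},
#'   \code{fold} (NA when the state has no background coverage),
#'   \code{highlighted}.
#' @export
chromatinStateEnrichment <- function(features, segmentation, background,
                                     highlightFold = 1.5) {
  dropChrom <- function(gr) {
    gr[!as.character(seqnames(gr)) %in% c("chrX", "chrY", "chrM")]
  }
  features <- dropChrom(features)
  background <- dropChrom(background)
  segmentation <- dropChrom(segmentation)
  states <- sort(unique(segmentation$state))
  cov <- function(set, stateGr) {
    sum(width(GenomicRanges::intersect(
      GenomicRanges::reduce(set), GenomicRanges::reduce(stateGr))))
  }
  fbp <- bbp <- numeric(length(states))
  for (i in seq_along(states)) {
    sg <- segmentation[segmentation$state == states[i]]
    fbp[i] <- cov(features, sg)
    bbp[i] <- cov(background, sg)
  }
  ff <- fbp / sum(fbp)
  bf <- bbp / sum(bbp)
  fold <- ifelse(bf > 0, ff / bf, NA_real_)
  data.frame(state = states, feature_bp = fbp, background_bp = bbp,
             feature_frac = ff, background_frac = bf, fold = fold,
             highlighted = !is.na(fold) &
               (fold > highlightFold | fold < 1 / highlightFold),
             stringsAsFactors = FALSE)
}

#' Filter variant calls on coverage and bias tests
#'
#' Applies the post-call thresholds to a VCF: a record is removed when its
#' depth \code{DP} is below 20, when any of the variant-distance
#' (\code{VDB}), read-position (\code{RPB}), mapping-quality (\code{MQB}),
#' base-quality (\code{BQB}) bias p-values or the inbreeding-coefficient
#' binomial test (\code{ICB}) is below 0.05, or when the homozygote-bias
#' p-value (\code{HOB}) is above 0.05. Records missing a required field are
#' reported as unevaluable and excluded from the pass set. Every removal is
#' annotated with all triggered reasons.
#'
#' @param vcf path to a VCF file with the INFO fields above.
#' @return data.frame with one row per record: \code{id}, \code{chrom},
#'   \code{pos}, the seven fields, \code{status}
#'   (\code{pass}/\code{removed}/\code{unevaluable}) and \code{reasons}
#'   (comma-separated).
#' @export
filterVariants <- function(vcf) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  info <- lapply(vcfFilterFields, function(f)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = f))))
  names(info) <- vcfFilterFields
  n <- nrow(fx)
  status <- character(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    vals <- vapply(info, `[`, numeric(1), i)
    if (anyNA(vals)) {
      status[i] <- "unevaluable"
      reasons[i] <- paste0("missing:",
                           paste(names(vals)[is.na(vals)], collapse = ","))
      next
    }
    why <- character(0)
    if (vals["DP"] < 20) why <- c(why, "coverage")
    for (f in c("VDB", "RPB", "MQB", "BQB"))
      if (vals[f] < 0.05) why <- c(why, paste0(tolower(f)))
    if (vals["ICB"] < 0.05) why <- c(why, "inbreeding")
    if (vals["HOB"] > 0.05) why <- c(why, "homozygote_bias")
    status[i] <- if (length(why)) "removed" else "pass"
    reasons[i] <- paste(why, collapse = ",")
  }
  out <- data.frame(id = fx[, "ID"], chrom = fx[, "CHROM"],
                    pos = as.integer(fx[, "POS"]),
                    as.data.frame(info), status = status,
                    reasons = reasons, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
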