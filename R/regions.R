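#' Cluster probes by genomic gap
#'
#' Greedy scan over position-sorted probes: a new group starts whenever the
#' chromosome changes or the gap to the previous probe exceeds \code{maxGap}.
#'
#' @param annotation data.frame with \code{chrom} and \code{pos} columns,
#'   sorted by (chrom, pos); unsorted input is an error.
#' @param maxGap maximum within-group gap in basepairs (default 500, the
#'   conventional array clustering gap).
#' @return integer vector of group ids, one per probe.
#' @examples
#' ann <- data.frame(chrom = "chr1", pos = c(1, 100, 450, 1200, 1300))
#' clusterProbes(ann, maxGap = 500)
#' @export
clusterProbes <- function(annotation, maxGap = 500) {
  checkSorted(annotation$chrom, annotation$pos)
  gapGroups(annotation$chrom, annotation$pos, maxGap)
}

# Run-state vector: +1 above cutoff, -1 below -cutoff, 0 otherwise.
runIds <- function(coefs, groups, cutoff) {
  st <- (coefs > cutoff) - (coefs < -cutoff)
  n <- length(st)
  brk <- c(TRUE, st[-1] != st[-n] | groups[-1] != groups[-n])
  list(state = st, run = cumsum(brk))
}

#' Candidate differentially methylated regions
#'
#' Scans each probe group for maximal runs of consecutive probes whose
#' coefficients all exceed \code{cutoff} (hypermethylated in scalp) or all
#' fall below \code{-cutoff} (hypomethylated), reporting each run's probe
#' count, mean coefficient and area (the sum of absolute coefficients).
#'
#' @param coefs numeric vector of per-probe location coefficients, aligned
#'   with \code{annotation}.
#' @param annotation data.frame with \code{chrom}/\code{pos} (sorted).
#' @param groups integer group ids from \code{\link{clusterProbes}} (or any
#'   grouping that respects position order).
#' @param cutoff positive coefficient threshold (default 0.1, i.e. a 10\%
#'   methylation difference).
#' @return data.frame of candidate regions: \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive over member probe positions),
#'   \code{n_probes}, \code{direction} (hyper/hypo in scalp),
#'   \code{mean_delta}, \code{area}, plus \code{idx_start}/\code{idx_end}
#'   giving the member index range. Empty when nothing exceeds the cutoff.
#' @export
findCandidateRegions <- function(coefs, annotation, groups, cutoff = 0.1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  stopifnot(length(coefs) == nrow(annotation),
            length(groups) == nrow(annotation))
  ri <- runIds(coefs, groups, cutoff)
  sel <- which(ri$state != 0L)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      direction = character(0), mean_delta = numeric(0),
                      area = numeric(0), idx_start = integer(0),
                      idx_end = integer(0), stringsAsFactors = FALSE)
  if (length(sel) == 0L) return(empty)
  run <- ri$run[sel]
  f <- match(run, unique(run))
  out <- data.frame(
    chrom = annotation$chrom[sel][!duplicated(f)],
    start = as.numeric(tapply(annotation$pos[sel], f, min)),
    end = as.numeric(tapply(annotation$pos[sel], f, max)),
    n_probes = as.integer(tabulate(f)),
    mean_delta = as.numeric(tapply(coefs[sel], f, mean)),
    area = as.numeric(tapply(abs(coefs[sel]), f, sum)),
    idx_start = as.integer(tapply(sel, f, min)),
    idx_end = as.integer(tapply(sel, f, max)),
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$mean_delta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "n_probes", "direction",
          "mean_delta", "area", "idx_start", "idx_end")]
}

# Maximum candidate area of a coefficient vector (0 when no candidate).
maxCandidateArea <- function(coefs, groups, cutoff) {
  ri <- runIds(coefs, groups, cutoff)
  sel <- ri$state != 0L
  if (!any(sel)) return(0)
  max(rowsum(abs(coefs[sel]), ri$run[sel]))
}

#' Bootstrap null distribution of the maximum region area
#'
#' Generates the null-area sample used for family-wise error control in
#' region calling. The null model (the design without its location column) is
#' fitted to every probe; in each iteration the per-sample residual vectors
#' are resampled with replacement and added back to the null fitted values —
#' resampling whole sample vectors preserves the correlation between nearby
#' probes — the location coefficient is re-estimated under the full design,
#' and the maximum candidate-region area is recorded (0 when no candidate).
#'
#' @param y probes-by-samples matrix.
#' @param design full design matrix with the location indicator in column 2
#'   (as built by \code{\link{fitProbeModels}}: intercept, location, SVs).
#' @param groups probe group ids from \code{\link{clusterProbes}}.
#' @param cutoff candidate threshold.
#' @param B bootstrap iterations (>= 1; 1000 for production calls).
#' @param seed integer seed; fixed seed gives an identical null sample.
#' @return numeric vector of length \code{B} of null maximum areas.
#' @export
bootstrapNullAreas <- function(y, design, groups, cutoff = 0.1, B = 1000,
                               seed = 1L) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  y <- as.matrix(y)
  X <- as.matrix(design)
  N <- ncol(y)
  X0 <- X[, -2, drop = FALSE]
  fitted0 <- y %*% X0 %*% solve(crossprod(X0), t(X0))
  R0 <- y - fitted0
  w <- (X %*% solve(crossprod(X)))[, 2]   # coef_loc = Yb %*% w
  withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      coefs <- (fitted0 + R0[, idx, drop = FALSE]) %*% w
      maxCandidateArea(as.vector(coefs), groups, cutoff)
    }, numeric(1))
  })
}

#' Assign family-wise error rates to candidate regions
#'
#' Each candidate's FWER is the add-one bootstrap estimate
#' \code{(# null max areas >= area + 1) / (B + 1)}; regions at or below
#' \code{fwerThreshold} are flagged significant. Candidates with fewer than
#' \code{minProbes} members are dropped (single probes are the probe-level
#' analysis's business).
#'
#' @param candidates data.frame from \code{\link{findCandidateRegions}}.
#' @param nullMaxAreas numeric vector from \code{\link{bootstrapNullAreas}}.
#' @param fwerThreshold significance threshold (default 0.1).
#' @param minProbes minimum member count (default 2).
#' @return the candidate data.frame with \code{fwer} and \code{significant}
#'   columns, ordered by decreasing area.
#' @export
callDmrs <- function(candidates, nullMaxAreas, fwerThreshold = 0.1,
                     minProbes = 2L) {
  if (length(nullMaxAreas) == 0L) stop("null area sample is empty")
  out <- candidates[candidates$n_probes >= minProbes, , drop = FALSE]
  B <- length(nullMaxAreas)
  out$fwer <- vapply(out$area,
                     function(a) (sum(nullMaxAreas >= a) + 1) / (B + 1),
                     numeric(1))
  out$significant <- out$fwer <= fwerThreshold
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full region (DMR) stage
#'
#' Clusters probes, fits the per-probe location model, extracts candidate
#' regions from the location coefficients, builds the bootstrap null and
#' assigns FWERs.
#'
#' @param mset a \linkS4class{MethylationExperiment}.
#' @param svs optional surrogate-variable matrix.
#' @param cutoff candidate threshold (default 0.1).
#' @param maxGap probe clustering gap (default 500 bp).
#' @param B bootstrap iterations (default 1000).
#' @param seed seed for the bootstrap.
#' @param fwerThreshold significance threshold (default 0.1).
#' @return list with \code{regions} (called regions with FWER),
#'   \code{candidates}, \code{nullAreas} and \code{fits}.
#' @export
runDmrAnalysis <- function(mset, svs = NULL, cutoff = 0.1, maxGap = 500,
                           B = 1000, seed = 1L, fwerThreshold = 0.1) {
  ann <- probeAnnotation(mset)
  beta <- betaValues(mset)
  loc <- locationIndicator(mset)
  groups <- clusterProbes(ann, maxGap)
  fits <- fitProbeModels(beta, loc, svs)
  cand <- findCandidateRegions(fits$beta_loc, ann, groups, cutoff)
  design <- cbind(1, loc)
  if (!is.null(svs) && NCOL(svs) > 0) design <- cbind(design, as.matrix(svs))
  nullAreas <- bootstrapNullAreas(beta, design, groups, cutoff, B, seed)
  regions <- callDmrs(cand, nullAreas, fwerThreshold)
  list(regions = regions, candidates = cand, nullAreas = nullAreas,
       fits = fits)
}

#' Collapse open-sea probes for block finding
#'
#' Clusters open-sea probes at \code{clusterGap} and averages each cluster's
#' beta values per sample, yielding one measurement per cluster; the cluster
#' position is the midpoint of the member span. CpG island, shore and shelf
#' probes never contribute: blocks are a phenomenon of the methylated open
#' sea.
#'
#' @param mset a \linkS4class{MethylationExperiment} whose annotation has an
#'   \code{island_relation} column.
#' @param clusterGap clustering gap in bp (default 500).
#' @return list with \code{beta} (clusters-by-samples matrix) and
#'   \code{annotation} (data.frame: cluster_id, chrom, pos, span_start,
#'   span_end, n_probes).
#' @export
collapseForBlocks <- function(mset, clusterGap = 500) {
  ann <- probeAnnotation(mset)
  os <- which(ann$island_relation == "open_sea")
  if (length(os) == 0L) stop("no open-sea probes; cannot collapse for blocks")
  sub <- ann[os, , drop = FALSE]
  beta <- betaValues(mset)[os, , drop = FALSE]
  grp <- gapGroups(sub$chrom, sub$pos, clusterGap)
  collapsed <- rowsum(beta, grp) / as.vector(table(grp))
  cann <- data.frame(
    cluster_id = paste0("cl", sort(unique(grp))),
    chrom = tapply(sub$chrom, grp, `[`, 1),
    pos = floor((tapply(sub$pos, grp, min) + tapply(sub$pos, grp, max)) / 2),
    span_start = as.numeric(tapply(sub$pos, grp, min)),
    span_end = as.numeric(tapply(sub$pos, grp, max)),
    n_probes = as.integer(tabulate(grp)),
    stringsAsFactors = FALSE)
  rownames(collapsed) <- cann$cluster_id
  rownames(cann) <- NULL
  list(beta = collapsed, annotation = cann)
}

#' Full block stage
#'
#' Applies the candidate/bootstrap/FWER machinery of the region stage at the
#' collapsed open-sea scale: collapsed clusters are grouped at
#' \code{blockGap}, the location model is fitted per cluster, candidate
#' blocks must show a coefficient beyond \code{cutoff}, and significance is
#' assessed against the bootstrap null of maximum areas.
#'
#' @param mset a \linkS4class{MethylationExperiment}.
#' @param svs optional surrogate-variable matrix.
#' @param cutoff candidate threshold (default 0.1).
#' @param clusterGap collapse gap (default 500 bp).
#' @param blockGap grouping gap for collapsed clusters (default 250 kb).
#' @param B bootstrap iterations (default 1000).
#' @param seed seed for the bootstrap.
#' @param fwerThreshold significance threshold (default 0.1).
#' @return list with \code{blocks} (called blocks with FWER),
#'   \code{candidates}, \code{nullAreas}, \code{collapsed} and \code{fits}.
#' @export
runBlockAnalysis <- function(mset, svs = NULL, cutoff = 0.1,
                             clusterGap = 500, blockGap = 250000,
                             B = 1000, seed = 1L, fwerThreshold = 0.1) {
  col <- collapseForBlocks(mset, clusterGap)
  loc <- locationIndicator(mset)
  groups <- gapGroups(col$annotation$chrom, col$annotation$pos, blockGap)
  fits <- fitProbeModels(col$beta, loc, svs)
  cand <- findCandidateRegions(fits$beta_loc, col$annotation, groups, cutoff)
  design <- cbind(1, loc)
  if (!is.null(svs) && NCOL(svs) > 0) design <- cbind(design, as.matrix(svs))
  nullAreas <- bootstrapNullAreas(col$beta, design, groups, cutoff, B, seed)
  blocks <- callDmrs(cand, nullAreas, fwerThreshold)
  list(blocks = blocks, candidates = cand, nullAreas = nullAreas,
       collapsed = col, fits = fits)
}

#' Export called regions as BED
#'
#' Writes significant region calls with the 1-based inclusive internal
#' coordinates converted to BED's 0-based half-open convention; the score
#' column carries the area statistic.
#'
#' @param regions data.frame from \code{\link{callDmrs}}.
#' @param file output path.
#' @param significantOnly write only significant calls (default TRUE).
#' @return invisibly, the path.
#' @export
writeRegionsBed <- function(regions, file, significantOnly = TRUE) {
  r <- if (significantOnly) regions[regions$significant, , drop = FALSE]
       else regions
  df <- data.frame(chrom = r$chrom, start = r$start - 1L, end = r$end,
                   name = paste0(r$direction, "_", seq_len(nrow(r))),
                   score = round(r$area, 4), strand = ".")
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
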