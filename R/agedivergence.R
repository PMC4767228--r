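#' Within-donor scalp-minus-dura differences
#'
#' Builds the probes-by-donors matrix of paired beta differences. Only
#' donors contributing both a dura and a scalp sample are used; incomplete
#' donors are dropped, so the paired analysis is sized by donors, not
#' observations.
#'
#' @param mset a \linkS4class{MethylationExperiment}.
#' @return list with \code{diffs} (probes by complete donors, scalp minus
#'   dura) and \code{ages} (donor ages, aligned with the columns).
#' @export
pairedDifferences <- function(mset) {
  meta <- sampleInfo(mset)
  beta <- betaValues(mset)
  donors <- unique(meta$donor_id)
  complete <- donors[vapply(donors, function(d) {
    locs <- meta$location[meta$donor_id == d]
    all(c("dura", "scalp") %in% locs)
  }, logical(1))]
  if (length(complete) < 2L)
    stop("need >= 2 donors with both locations")
  sc <- vapply(complete, function(d)
    meta$sample_id[meta$donor_id == d & meta$location == "scalp"], character(1))
  du <- vapply(complete, function(d)
    meta$sample_id[meta$donor_id == d & meta$location == "dura"], character(1))
  diffs <- beta[, sc, drop = FALSE] - beta[, du, drop = FALSE]
  colnames(diffs) <- complete
  ages <- meta$age_years[match(complete, meta$donor_id)]
  list(diffs = diffs, ages = ages)
}

#' Paired age-divergence model
#'
#' Regresses the within-donor scalp-minus-dura difference at every probe on
#' donor age: \code{diff = gamma + delta * age + zeta * SVs + error}, where
#' \code{gamma} is the location difference at birth and \code{delta} the
#' change in that difference per year of life. Surrogate variables (default
#' 3) are estimated on the difference matrix to absorb shared unmodeled
#' structure. The Wald test on \code{delta} uses the t reference with the
#' OLS residual degrees of freedom (exact at these small donor counts);
#' q-values are Benjamini-Hochberg, with divergence conventionally called at
#' q < 0.10.
#'
#' @param diffs probes-by-donors difference matrix (or the list returned by
#'   \code{\link{pairedDifferences}}).
#' @param ages donor ages (ignored when \code{diffs} is the list).
#' @param nSv surrogate variables to estimate on the difference matrix
#'   (default 3; 0 to skip).
#' @param seed seed for surrogate-variable estimation.
#' @return data.frame: \code{probe_id}, \code{gamma}, \code{delta},
#'   \code{wald_t}, \code{wald_p}, \code{q}.
#' @export
fitAgeDivergence <- function(diffs, ages = NULL, nSv = 3, seed = 1L) {
  if (is.list(diffs) && !is.matrix(diffs)) {
    ages <- diffs$ages
    diffs <- diffs$diffs
  }
  diffs <- as.matrix(diffs)
  n <- ncol(diffs)
  stopifnot(length(ages) == n)
  if (n < nSv + 3L) stop("need donors >= n_sv + 3")
  design <- cbind(1, age = ages)
  svs <- if (nSv > 0) estimateSVs(diffs, design, nSv = nSv, seed = seed)
         else NULL
  X <- design
  if (!is.null(svs) && NCOL(svs) > 0) X <- cbind(X, as.matrix(svs))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("age-divergence design is rank deficient")
  XtXinv <- solve(crossprod(X))
  coef <- diffs %*% X %*% XtXinv
  res <- diffs - coef %*% t(X)
  df <- n - ncol(X)
  sigma2 <- rowSums(res^2) / df
  sigma2[sigma2 < .Machine$double.eps] <- 0
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tstat <- ifelse(se > 0, coef[, 2] / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(
    probe_id = if (is.null(rownames(diffs))) sprintf("p%06d", seq_len(nrow(diffs)))
               else rownames(diffs),
    gamma = coef[, 1], delta = coef[, 2],
    wald_t = tstat, wald_p = p, q = adjustFdr(p),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "svs") <- svs
  attr(out, "df_resid") <- df
  out
}

#' Post-hoc per-location age slopes
#'
#' For each listed probe, the beta-on-age OLS slope is computed separately
#' within the scalp and within the dura samples, together with the percent
#' change per decade of life (slope x 10 x 100).
#'
#' @param mset a \linkS4class{MethylationExperiment}.
#' @param probes character vector of probe ids (e.g. the significant
#'   age-divergent probes); must be non-empty.
#' @return data.frame: \code{probe_id}, \code{slope_scalp},
#'   \code{slope_dura}, \code{intercept_scalp}, \code{intercept_dura},
#'   \code{pct_per_decade_scalp}, \code{pct_per_decade_dura}.
#' @export
posthocLocationSlopes <- function(mset, probes) {
  if (length(probes) == 0L) stop("probe list is empty")
  beta <- betaValues(mset)[probes, , drop = FALSE]
  meta <- sampleInfo(mset)
  fitLoc <- function(loc) {
    idx <- meta$location == loc
    x <- meta$age_years[idx]
    Y <- beta[, idx, drop = FALSE]
    X <- cbind(1, x)
    coef <- Y %*% X %*% solve(crossprod(X))
    coef
  }
  cs <- fitLoc("scalp")
  cd <- fitLoc("dura")
  data.frame(probe_id = probes,
             slope_scalp = cs[, 2], slope_dura = cd[, 2],
             intercept_scalp = cs[, 1], intercept_dura = cd[, 1],
             pct_per_decade_scalp = cs[, 2] * 10 * 100,
             pct_per_decade_dura = cd[, 2] * 10 * 100,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster age-divergence trajectories
#'
#' Summarizes each significant probe by its fitted scalp and dura
#' trajectories over a common age grid (per-location OLS on age), z-scores
#' the concatenated pair per probe (so level and shape, not scale, drive the
#' grouping), and partitions the probes by k-means with a fixed seed and
#' multiple restarts. Cluster mean trajectories are reported mean-centered.
#'
#' @param mset a \linkS4class{MethylationExperiment}.
#' @param probes character vector of significant probe ids (length >= k).
#' @param k number of clusters (default 8, the canonical archetype count).
#' @param seed integer seed for the k-means restarts.
#' @param gridN age-grid resolution (default 18 points over the sample age
#'   range).
#' @param nstart k-means restarts (default 20).
#' @return list with \code{cluster} (named integer vector),
#'   \code{centers} (k x 2*gridN matrix of mean-centered mean trajectories,
#'   scalp grid then dura grid), \code{ageGrid}.
#' @export
clusterAgePatterns <- function(mset, probes, k = 8, seed = 1L, gridN = 18L,
                               nstart = 20L) {
  if (length(probes) < k) stop("k exceeds the number of probes")
  meta <- sampleInfo(mset)
  grid <- seq(min(meta$age_years), max(meta$age_years), length.out = gridN)
  sl <- posthocLocationSlopes(mset, probes)
  traj <- cbind(
    sl$intercept_scalp + outer(sl$slope_scalp, grid),
    sl$intercept_dura + outer(sl$slope_dura, grid))
  # per-probe standardization of the concatenated trajectory pair
  mu <- rowMeans(traj)
  sdv <- apply(traj, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (traj - mu) / sdv
  km <- withSeed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                     iter.max = 100))
  centers <- km$centers - rowMeans(km$centers)
  cl <- km$cluster
  names(cl) <- probes
  list(cluster = cl, centers = centers, ageGrid = grid,
       sizes = as.integer(km$size))
}
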