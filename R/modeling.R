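#' Estimate surrogate variables
#'
#' Two-step surrogate variable estimation. The primary-variable fit is
#' removed from the data and the top right-singular vectors of the residual
#' matrix are taken as candidate directions of unmodeled structure (batch,
#' cellular heterogeneity). Each candidate is then re-estimated from the
#' probes most associated with it: probes whose residuals have the highest
#' squared correlation with the candidate are selected, the original data for
#' those probes are decomposed, and the singular vector best matching the
#' candidate becomes the surrogate variable. Finally the surrogate variables
#' are orthogonalized against the design (so protected effects are never
#' absorbed), mean-centered and orthonormalized.
#'
#' When \code{nSv = "auto"} the dimension is chosen by a permutation
#' (parallel-analysis) criterion: singular values of the residual matrix are
#' compared with those of row-permuted residuals, and components are kept
#' while they exceed the 95th permutation percentile.
#'
#' @param y probes-by-samples numeric matrix.
#' @param design samples-by-k design matrix of the primary model (include an
#'   intercept column).
#' @param nSv number of surrogate variables, or \code{"auto"}.
#' @param seed seed for the permutation criterion.
#' @param nPerm permutations for \code{nSv = "auto"}.
#' @return samples-by-nSv matrix of surrogate variables (zero columns when
#'   the residual matrix is numerically zero, with a warning). Columns are
#'   zero-mean and mutually orthogonal.
#' @export
estimateSVs <- function(y, design, nSv = "auto", seed = 1L, nPerm = 20L) {
  y <- as.matrix(y)
  X <- as.matrix(design)
  N <- ncol(y)
  stopifnot(nrow(X) == N)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  R <- y - y %*% H
  if (max(abs(R)) < 1e-12) {
    warning("residual matrix is zero; returning 0 surrogate variables")
    return(matrix(numeric(0), nrow = N, ncol = 0))
  }
  kmax <- min(N - qr(X)$rank, nrow(y)) - 1L
  sv <- svd(R, nu = 0, nv = min(kmax, N))
  if (identical(nSv, "auto")) {
    obs <- sv$d[seq_len(kmax)]
    permQ <- withSeed(seed, {
      perms <- replicate(nPerm, {
        Rp <- t(apply(R, 1, sample))
        svd(Rp, nu = 0, nv = 0)$d[seq_len(kmax)]
      })
      apply(perms, 1, stats::quantile, probs = 0.95)
    })
    keep <- obs > permQ
    nSv <- if (all(keep)) kmax else (which(!keep)[1] - 1L)
    if (nSv == 0L)
      return(matrix(numeric(0), nrow = N, ncol = 0))
  }
  nSv <- as.integer(nSv)
  if (N <= nSv + qr(X)$rank)
    stop("need n_samples > n_sv + rank(design)")
  rss <- rowSums(R^2)
  svs <- matrix(0, N, nSv)
  for (j in seq_len(nSv)) {
    e <- sv$v[, j]
    proj <- as.vector(R %*% e)
    r2 <- proj^2 / pmax(rss, 1e-300)
    sel <- which(r2 >= stats::quantile(r2, probs = max(0, 1 - 500 / length(r2)),
                                       names = FALSE))
    if (length(sel) < 10L) sel <- order(r2, decreasing = TRUE)[seq_len(
      min(10L, length(r2)))]
    ysub <- y[sel, , drop = FALSE]
    ysub <- ysub - rowMeans(ysub)
    sv2 <- svd(ysub, nu = 0)
    cors <- abs(stats::cor(sv2$v, e))
    svs[, j] <- sv2$v[, which.max(cors)]
  }
  # protect the design: remove its span, then center and orthonormalize
  svs <- svs - H %*% svs
  svs <- scale(svs, center = TRUE, scale = FALSE)
  qrd <- qr(svs)
  svs <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  colnames(svs) <- paste0("SV", seq_len(ncol(svs)))
  svs
}

#' Per-probe linear models for a location effect
#'
#' Fits, by ordinary least squares, the model
#' \code{beta = alpha + beta_loc * location + zeta * SVs + error} to every
#' probe, where \code{location} is the 0/1 sampling-location indicator
#' (dura = 0, scalp = 1). Computation is vectorized through the shared
#' design's normal equations.
#'
#' @param y probes-by-samples matrix of methylation (beta) values.
#' @param location 0/1 vector of length \code{ncol(y)}.
#' @param svs optional samples-by-k surrogate variable matrix.
#' @return data.frame with one row per probe: \code{probe_id}, \code{alpha}
#'   (dura intercept), \code{beta_loc} (scalp minus dura), SV coefficients
#'   \code{zeta*}, \code{sigma2}, \code{df_resid}, \code{unscaled_se} (the
#'   design-only standard error factor of beta_loc), ordinary \code{t} and
#'   \code{p}.
#' @export
fitProbeModels <- function(y, location, svs = NULL) {
  y <- as.matrix(y)
  N <- ncol(y)
  stopifnot(length(location) == N)
  X <- cbind(intercept = 1, location = as.numeric(location))
  if (!is.null(svs) && NCOL(svs) > 0)
    X <- cbind(X, as.matrix(svs))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  XtXinv <- solve(crossprod(X))
  coef <- y %*% X %*% XtXinv
  res <- y - coef %*% t(X)
  df <- N - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- rowSums(res^2) / df
  sigma2[sigma2 < .Machine$double.eps] <- 0   # numerically exact fits
  u <- sqrt(XtXinv[2, 2])
  se <- sqrt(sigma2) * u
  tstat <- ifelse(se > 0, coef[, 2] / se, 0)
  out <- data.frame(
    probe_id = if (is.null(rownames(y))) sprintf("p%06d", seq_len(nrow(y)))
               else rownames(y),
    alpha = coef[, 1], beta_loc = coef[, 2],
    stringsAsFactors = FALSE)
  if (ncol(X) > 2L) {
    zeta <- coef[, -(1:2), drop = FALSE]
    colnames(zeta) <- paste0("zeta", seq_len(ncol(zeta)))
    out <- cbind(out, zeta)
  }
  out$sigma2 <- sigma2
  out$df_resid <- df
  out$unscaled_se <- u
  out$t <- tstat
  out$p <- 2 * stats::pt(-abs(tstat), df)
  rownames(out) <- NULL
  out
}

# Inverse of the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)).
trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of probe statistics
#'
#' Shrinks the per-probe residual variances toward a common value by
#' empirical Bayes, assuming the true variances follow a scaled inverse
#' chi-squared prior with \code{d0} degrees of freedom and scale \code{s02}.
#' The hyperparameters are estimated by matching the moments of the log
#' residual variances to a scaled F distribution; \code{d0} is infinite when
#' the moment equation has no positive root (observed spread no larger than
#' chi-squared sampling noise). The posterior variance of probe i is
#' \code{(d0 * s02 + df * s2_i) / (d0 + df)}; the moderated t uses it in
#' place of \code{s2_i} and is referred to a t distribution on
#' \code{df + d0} degrees of freedom. Benjamini-Hochberg q-values are
#' appended.
#'
#' @param fits data.frame from \code{\link{fitProbeModels}} (>= 10 probes).
#' @param d0,s02 optional forced hyperparameters (used mainly to check the
#'   closed-form limits; both must be given together).
#' @return the input data.frame with columns \code{s2_post}, \code{t_mod},
#'   \code{df_total}, \code{p} (replaced by the moderated p) and \code{q};
#'   the estimated hyperparameters are in \code{attr(, "hyper")}.
#' @export
moderateStatistics <- function(fits, d0 = NULL, s02 = NULL) {
  if (nrow(fits) < 10L && is.null(d0))
    warning("variance shrinkage is unreliable on an ensemble of < 10 probes")
  s2 <- fits$sigma2
  df <- fits$df_resid[1]
  if (all(s2 == 0)) stop("all residual variances are zero; degenerate ensemble")
  if (is.null(d0)) {
    m <- stats::median(s2)
    if (m == 0) stop("more than half the residual variances are zero; degenerate ensemble")
    x <- pmax(s2, 1e-5 * m)   # offset exact zeros away from log(0)
    z <- log(x)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.na(evar) || evar <= 0) {
      # no excess spread beyond chi-squared sampling noise: infinite prior df
      d0 <- Inf
      s02 <- mean(x)
    } else {
      d0 <- 2 * trigammaInverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else if (is.null(s02)) {
    stop("when forcing d0, s02 must be supplied too")
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2))
            else (d0 * s02 + df * s2) / (d0 + df)
  tmod <- ifelse(s2post > 0, fits$beta_loc / (sqrt(s2post) * fits$unscaled_se), 0)
  dft <- df + d0
  p <- if (is.infinite(dft)) 2 * stats::pnorm(-abs(tmod))
       else 2 * stats::pt(-abs(tmod), dft)
  fits$s2_post <- s2post
  fits$t_mod <- tmod
  fits$df_total <- dft
  fits$p <- p
  fits$q <- adjustFdr(p)
  attr(fits, "hyper") <- c(d0 = d0, s02 = s02)
  fits
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values, monotone in the ranks of \code{p}.
#' @examples
#' adjustFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' PCA after removing surrogate variables
#'
#' Regresses the surrogate variables out of every probe while protecting the
#' listed design columns (the surrogate variables are first orthogonalized
#' against them, so protected effects stay in the data), then performs
#' principal component analysis across samples.
#'
#' @param y probes-by-samples matrix.
#' @param svs samples-by-k surrogate variable matrix (may be NULL).
#' @param protect samples-by-m matrix of effects to preserve (e.g. the
#'   location indicator); may be NULL.
#' @return list with \code{scores} (samples by components), \code{varFrac}
#'   (variance fractions, summing to 1) and \code{rotation}.
#' @export
residualizePca <- function(y, svs = NULL, protect = NULL) {
  y <- as.matrix(y)
  if (!is.null(svs) && NCOL(svs) > 0) {
    svs <- as.matrix(svs)
    if (!is.null(protect)) {
      P <- as.matrix(protect)
      P <- cbind(1, P)
      svs <- svs - P %*% solve(crossprod(P), crossprod(P, svs))
    }
    keep <- colSums(svs^2) > 1e-12
    svs <- svs[, keep, drop = FALSE]
    if (ncol(svs) > 0) {
      G <- svs %*% solve(crossprod(svs), t(svs))
      y <- y - y %*% G
    }
  }
  pc <- stats::prcomp(t(y), center = TRUE, scale. = FALSE)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, varFrac = varFrac, rotation = pc$rotation)
}

#' Full differential-methylation-probe stage
#'
#' Convenience wrapper running surrogate-variable estimation, per-probe
#' models, moderation and FDR adjustment on a
#' \linkS4class{MethylationExperiment}.
#'
#' @param mset a \linkS4class{MethylationExperiment}.
#' @param nSv surrogate variables to estimate (default 6) or \code{"auto"};
#'   0 skips adjustment.
#' @param seed passed to \code{\link{estimateSVs}}.
#' @return list with \code{fits} (moderated probe table with q-values) and
#'   \code{svs}.
#' @export
runDmpAnalysis <- function(mset, nSv = 6, seed = 1L) {
  beta <- betaValues(mset)
  loc <- locationIndicator(mset)
  svs <- if (identical(nSv, 0) || identical(nSv, 0L)) NULL
         else estimateSVs(beta, cbind(1, loc), nSv = nSv, seed = seed)
  fits <- fitProbeModels(beta, loc, svs)
  fits <- moderateStatistics(fits)
  list(fits = fits, svs = svs)
}
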