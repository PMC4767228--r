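#' Differential variability between sampling locations
#'
#' Levene's test per probe: a one-way ANOVA F statistic on the absolute
#' deviations of each sample's beta value from its group center (mean by
#' default; median gives the Brown-Forsythe variant). Probes that are
#' constant within both groups have an undefined statistic and are returned
#' flagged rather than tested. q-values are Benjamini-Hochberg over the
#' tested probes.
#'
#' @param beta probes-by-samples matrix.
#' @param location 0/1 or dura/scalp vector of group membership.
#' @param center \code{"mean"} (classical Levene) or \code{"median"}.
#' @return data.frame: \code{probe_id}, \code{levene_stat}, \code{p},
#'   \code{q}, \code{more_variable_in} (the group with larger mean absolute
#'   deviation), \code{tested} (FALSE for degenerate probes).
#' @export
differentialVariability <- function(beta, location,
                                    center = c("mean", "median")) {
  center <- match.arg(center)
  beta <- as.matrix(beta)
  if (is.character(location)) location <- as.integer(location == "scalp")
  g1 <- location == 1L
  g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 3L || n0 < 3L) stop("need >= 3 samples per group")
  cfun <- if (center == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  d <- beta
  d[, g1] <- abs(beta[, g1, drop = FALSE] - cfun(beta[, g1, drop = FALSE]))
  d[, g0] <- abs(beta[, g0, drop = FALSE] - cfun(beta[, g0, drop = FALSE]))
  m1 <- rowMeans(d[, g1, drop = FALSE])
  m0 <- rowMeans(d[, g0, drop = FALSE])
  mAll <- rowMeans(d)
  # one-way ANOVA on the deviation scores
  ssb <- n1 * (m1 - mAll)^2 + n0 * (m0 - mAll)^2
  ssw <- rowSums((d[, g1, drop = FALSE] - m1)^2) +
         rowSums((d[, g0, drop = FALSE] - m0)^2)
  dfw <- n1 + n0 - 2L
  stat <- (ssb / 1) / (ssw / dfw)
  tested <- ssw > 0
  p <- rep(NA_real_, nrow(beta))
  p[tested] <- stats::pf(stat[tested], 1, dfw, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(beta))
  q[tested] <- adjustFdr(p[tested])
  out <- data.frame(
    probe_id = if (is.null(rownames(beta))) sprintf("p%06d", seq_len(nrow(beta)))
               else rownames(beta),
    levene_stat = ifelse(tested, stat, NA_real_),
    p = p, q = q,
    more_variable_in = ifelse(m1 >= m0, "scalp", "dura"),
    tested = tested, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove mean-differential probes before variability FDR
#'
#' Differential variability is confounded by mean differences: beta values
#' are bounded in [0, 1], so gaining methylation from an unmethylated state
#' (or losing it from a full one) inflates variance mechanically. Probes
#' whose mean-difference q-value falls below \code{qThreshold} are therefore
#' removed, and the variability q-values are recomputed on the retained set.
#'
#' @param variability data.frame from \code{\link{differentialVariability}}.
#' @param dmpFits data.frame with \code{probe_id} and \code{q} (from
#'   \code{\link{moderateStatistics}}).
#' @param qThreshold mean-difference significance cutoff (default 0.05).
#' @return the filtered variability data.frame with recomputed \code{q}.
#' @export
filterMeanDm <- function(variability, dmpFits, qThreshold = 0.05) {
  sig <- dmpFits$probe_id[dmpFits$q < qThreshold]
  out <- variability[!variability$probe_id %in% sig, , drop = FALSE]
  out$q <- NA_real_
  out$q[out$tested] <- adjustFdr(out$p[out$tested])
  rownames(out) <- NULL
  out
}
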