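# The eight age-divergence trajectory archetypes: location-specific linear
# drifts in the scalp-dura difference D(age) = gamma + delta * age. Four
# shapes (diverge from equal levels, converge to equal levels, scalp-only
# drift, dura-only drift), each in two directions. `s` is the absolute
# difference slope per year; `amax` the oldest age (where converging pairs
# meet).
agedivArchetypes <- function(s, amax) {
  data.frame(
    archetype = c("diverge_up", "diverge_down", "converge_down",
                  "converge_up", "scalp_up", "scalp_down",
                  "dura_up", "dura_down"),
    offScalp   = c(0, 0,  amax * s / 2, -amax * s / 2, 0, 0, 0, 0),
    offDura    = c(0, 0, -amax * s / 2,  amax * s / 2, 0, 0, 0, 0),
    slopeScalp = c( s / 2, -s / 2, -s / 2,  s / 2,  s, -s, 0, 0),
    slopeDura  = c(-s / 2,  s / 2,  s / 2, -s / 2,  0,  0, s, -s),
    stringsAsFactors = FALSE)
}

#' Generate a paired methylome with planted ground truth
#'
#' Builds probe-by-sample beta values for a paired dura/scalp cohort with
#' planted effects at several spatial scales, then back-computes M/U channel
#' intensities (total intensity 10,000 with per-sample multiplicative jitter,
#' beta offset 100) so the normalization stage has realistic input:
#' \itemize{
#'   \item single differentially methylated probes (fraction
#'     \code{dmpFraction}, effect \code{dmpEffect}, signs balanced);
#'   \item \code{nDmrs} regions of >= 3 contiguous probes sharing a
#'     directionally consistent effect \code{dmrEffect};
#'   \item \code{nBlocks} long-range blocks: open-sea probes across a span of
#'     at least \code{blockSpan} bp shifted by \code{blockEffect};
#'   \item \code{nVarloci} variance-inflated loci (residual SD multiplied by
#'     \code{varInflation}), a share \code{varScalpShare} of them inflated in
#'     scalp and the rest in dura;
#'   \item \code{nAgediv} age-divergent probes following the eight trajectory
#'     archetypes (see \code{truth$probes$agediv_archetype});
#'   \item an additive batch offset at a fraction \code{batchFraction} of
#'     probes.
#' }
#' Residual noise is drawn on the logit scale and inverse-transformed, scaled
#' so its beta-scale SD matches \code{noiseSd}; this keeps values inside
#' (0, 1) without hard clipping and reproduces the mean-variance damping near
#' the boundaries.
#'
#' @param annotation probe annotation data.frame from
#'   \code{\link{simulateAnnotation}}.
#' @param metadata sample metadata from \code{\link{simulateCohort}}.
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return list with \code{mset} (a \linkS4class{MethylationExperiment} with
#'   M, U and beta assays) and \code{truth}: a list with \code{probes} (per
#'   -probe flags and planted parameters), \code{regions} (a
#'   \link[GenomicRanges]{GRanges} of planted DMR/block intervals) and
#'   \code{batch} (the per-sample batch offsets applied).
#' @examples
#' cfg <- SimulationConfig(nDonors = 4L, nProbes = 300L, nGenes = 20L,
#'                         nDmrs = 2L, nBlocks = 1L, nAgediv = 16L,
#'                         nVarloci = 20L)
#' sim <- simulateAnnotation(cfg@nProbes, cfg@nGenes, cfg@seed)
#' meta <- simulateCohort(cfg)
#' res <- simulateMethylation(sim$annotation, meta, cfg)
#' res$mset
#' @export
simulateMethylation <- function(annotation, metadata, cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  checkSorted(annotation$chrom, annotation$pos)
  P <- nrow(annotation)
  N <- nrow(metadata)
  if (P != cfg@nProbes)
    warning("annotation has ", P, " probes; cfg says ", cfg@nProbes)
  withSeed(cfg@seed + 1L, {
    scalp <- metadata$location == "scalp"
    ages <- metadata$age_years
    amax <- max(cfg@ageRange)

    ## baseline means by island relation
    rel <- annotation$island_relation
    base <- numeric(P)
    base[rel == "island"] <- stats::runif(sum(rel == "island"), 0.05, 0.30)
    base[rel == "shore"] <- stats::runif(sum(rel == "shore"), 0.20, 0.60)
    base[rel == "shelf"] <- stats::runif(sum(rel == "shelf"), 0.35, 0.70)
    base[rel == "open_sea"] <- stats::runif(sum(rel == "open_sea"), 0.55, 0.90)

    truth <- data.frame(
      probe_id = annotation$probe_id,
      is_dmp = FALSE, dmp_sign = 0L,
      is_in_dmr = FALSE, is_in_block = FALSE, region_sign = 0L,
      is_var_inflated = FALSE, var_direction = NA_character_,
      is_agediv = FALSE, agediv_archetype = NA_character_,
      delta = 0, stringsAsFactors = FALSE)

    regions <- list()
    locEffect <- numeric(P)   # scalp minus dura shift

    plantedBase <- function(n, effect) {
      lo <- max(0.25, 0.03 + effect)
      hi <- min(0.75, 0.97 - effect)
      if (lo >= hi)
        stop("planted effect of ", effect,
             " pushes means outside [0.02, 0.98]")
      stats::runif(n, lo, hi)
    }

    ## ---- DMRs: clusters of >= 3 contiguous probes (gap <= 500 bp)
    if (cfg@nDmrs > 0L) {
      grp <- gapGroups(annotation$chrom, annotation$pos, 500)
      sizes <- tabulate(grp)
      elig <- which(sizes >= 3L)
      if (length(elig) < cfg@nDmrs)
        stop("not enough probe clusters of >= 3 probes to plant ",
             cfg@nDmrs, " DMRs")
      chosen <- sample(elig, cfg@nDmrs)
      for (g in chosen) {
        idx <- which(grp == g)
        idx <- idx[seq_len(min(length(idx), 8L))]
        sgn <- sample(c(-1L, 1L), 1L)
        base[idx] <- plantedBase(length(idx), cfg@dmrEffect)
        locEffect[idx] <- sgn * cfg@dmrEffect
        truth$is_in_dmr[idx] <- TRUE
        truth$region_sign[idx] <- sgn
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = annotation$chrom[idx[1]],
          start = min(annotation$pos[idx]), end = max(annotation$pos[idx]),
          type = "dmr", sign = sgn, n_probes = length(idx))
      }
    }

    ## ---- blocks: runs of open-sea probes spanning >= blockSpan
    if (cfg@nBlocks > 0L) {
      free <- !truth$is_in_dmr
      os <- which(rel == "open_sea" & free & annotation$chrom == "chr1")
      pos <- annotation$pos[os]
      planted <- 0L
      i <- 1L
      gapBetweenBlocks <- 50000
      while (planted < cfg@nBlocks && i <= length(os)) {
        j <- i
        while (j <= length(os) && pos[j] - pos[i] < cfg@blockSpan) j <- j + 1L
        if (j > length(os)) break
        idx <- os[i:j]
        sgn <- sample(c(-1L, 1L), 1L)
        base[idx] <- plantedBase(length(idx), cfg@blockEffect)
        locEffect[idx] <- sgn * cfg@blockEffect
        truth$is_in_block[idx] <- TRUE
        truth$region_sign[idx] <- sgn
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = annotation$chrom[idx[1]],
          start = min(annotation$pos[idx]), end = max(annotation$pos[idx]),
          type = "block", sign = sgn, n_probes = length(idx))
        planted <- planted + 1L
        # skip forward to leave unplanted open sea between blocks
        i <- j + 1L
        while (i <= length(os) && pos[i] - pos[j] < gapBetweenBlocks)
          i <- i + 1L
      }
      if (planted < cfg@nBlocks)
        stop("could not place ", cfg@nBlocks, " blocks of span ",
             cfg@blockSpan, " bp; increase nProbes")
    }

    pool <- which(!truth$is_in_dmr & !truth$is_in_block)

    ## ---- single-probe DMPs, sign-balanced
    nDmp <- round(cfg@dmpFraction * P)
    if (nDmp > 0L) {
      if (nDmp > length(pool)) stop("dmpFraction too large for the pool")
      idx <- sample(pool, nDmp)
      sgn <- sample(rep(c(-1L, 1L), length.out = nDmp))
      base[idx] <- plantedBase(nDmp, cfg@dmpEffect)
      locEffect[idx] <- sgn * cfg@dmpEffect
      truth$is_dmp[idx] <- TRUE
      truth$dmp_sign[idx] <- sgn
      pool <- setdiff(pool, idx)
    }

    ## ---- age-divergent probes, round-robin over the eight archetypes
    arch <- agedivArchetypes(cfg@agedivSlope, amax)
    offScalp <- offDura <- slopeScalp <- slopeDura <- numeric(P)
    if (cfg@nAgediv > 0L) {
      if (cfg@nAgediv > length(pool)) stop("nAgediv too large for the pool")
      reach <- cfg@agedivSlope * amax
      lo <- max(0.02 + reach + 0.01, 0.42)
      hi <- min(0.98 - reach - 0.01, 0.58)
      if (lo >= hi)
        stop("agedivSlope of ", cfg@agedivSlope,
             " pushes means outside [0.02, 0.98]")
      idx <- sample(pool, cfg@nAgediv)
      a <- rep(seq_len(8L), length.out = cfg@nAgediv)
      base[idx] <- stats::runif(cfg@nAgediv, lo, hi)
      offScalp[idx] <- arch$offScalp[a]
      offDura[idx] <- arch$offDura[a]
      slopeScalp[idx] <- arch$slopeScalp[a]
      slopeDura[idx] <- arch$slopeDura[a]
      truth$is_agediv[idx] <- TRUE
      truth$agediv_archetype[idx] <- arch$archetype[a]
      truth$delta[idx] <- arch$slopeScalp[a] - arch$slopeDura[a]
      pool <- setdiff(pool, idx)
    }

    ## ---- variance-inflated loci (kept off extreme baselines, where the
    ##      logit transform would damp the planted SD ratio)
    if (cfg@nVarloci > 0L) {
      cand <- pool[base[pool] > 0.10 & base[pool] < 0.90]
      if (cfg@nVarloci > length(cand)) stop("nVarloci too large for the pool")
      idx <- sample(cand, cfg@nVarloci)
      nScalp <- round(cfg@varScalpShare * cfg@nVarloci)
      dir <- sample(rep(c("scalp", "dura"),
                        c(nScalp, cfg@nVarloci - nScalp)))
      truth$is_var_inflated[idx] <- TRUE
      truth$var_direction[idx] <- dir
    }

    ## ---- expected means: baseline + location/age effects per sample
    mu <- matrix(base, P, N)
    mu[, scalp] <- mu[, scalp] + locEffect
    agd <- which(truth$is_agediv)
    if (length(agd)) {
      mu[agd, scalp] <- mu[agd, scalp] + offScalp[agd] +
        outer(slopeScalp[agd], ages[scalp])
      mu[agd, !scalp] <- mu[agd, !scalp] + offDura[agd] +
        outer(slopeDura[agd], ages[!scalp])
    }
    planted <- truth$is_dmp | truth$is_in_dmr | truth$is_in_block |
      truth$is_agediv
    if (any(mu[planted, ] < 0.02 - 1e-9 | mu[planted, ] > 0.98 + 1e-9))
      stop("planted effect configuration pushes means outside [0.02, 0.98]")

    ## ---- batch: additive, centered offsets at a fraction of probes
    batchIdx <- match(metadata$batch, sort(unique(metadata$batch)))
    bOff <- cfg@batchEffect * (batchIdx - mean(batchIdx))
    nBatchProbes <- round(cfg@batchFraction * P)
    batchProbes <- if (nBatchProbes > 0L) sample.int(P, nBatchProbes)
                   else integer(0)
    if (length(batchProbes))
      mu[batchProbes, ] <- mu[batchProbes, ] +
        rep(bOff, each = length(batchProbes))
    mu <- pmin(pmax(mu, 0.01), 0.99)

    ## ---- logit-scale noise with the beta-scale target SD
    sdLogit <- cfg@noiseSd / (mu * (1 - mu))
    infl <- matrix(1, P, N)
    vs <- which(truth$is_var_inflated & truth$var_direction == "scalp")
    vd <- which(truth$is_var_inflated & truth$var_direction == "dura")
    if (length(vs)) infl[vs, scalp] <- cfg@varInflation
    if (length(vd)) infl[vd, !scalp] <- cfg@varInflation
    beta <- stats::plogis(stats::qlogis(mu) +
                          matrix(stats::rnorm(P * N), P, N) * sdLogit * infl)

    ## ---- intensities: global scale 10,000 with per-sample jitter
    total <- 10000 * exp(stats::rnorm(N, 0, 0.15))
    M <- sweep(beta, 2, total, `*`)
    U <- sweep(1 - beta, 2, total, `*`) - 100

    mset <- MethylationExperiment(M = M, U = U, annotation = annotation,
                                  metadata = metadata)
    regGr <- if (length(regions)) {
      rdf <- do.call(rbind, regions)
      gr <- GRanges(rdf$chrom, IRanges(rdf$start, rdf$end))
      S4Vectors::mcols(gr) <- rdf[, c("type", "sign", "n_probes")]
      gr
    } else GRanges()
    truthList <- list(probes = truth, regions = regGr,
                      batch = data.frame(sample_id = metadata$sample_id,
                                         batch_offset = bOff),
                      batch_probes = annotation$probe_id[batchProbes])
    list(mset = mset, truth = truthList)
  })
}
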