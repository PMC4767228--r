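#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData rowRanges
NULL

#' Container for array methylation data
#'
#' A \code{MethylationExperiment} extends
#' \linkS4class{RangedSummarizedExperiment} and holds proportion-methylation
#' (beta) values, optionally together with the methylated (\code{M}) and
#' unmethylated (\code{U}) channel intensities they derive from, for a set of
#' array probes measured across samples. Probe annotation (design type, CpG
#' island relation, SNP flag, nearest gene) lives in \code{rowData} with probe
#' coordinates in \code{rowRanges}; sample metadata (donor, sampling location,
#' age, batch) lives in \code{colData}.
#'
#' Beta values are defined as \code{M / (M + U + offset)} with the
#' conventional offset of 100 intensity units; the constructor recomputes beta
#' from intensities when both channels are supplied.
#'
#' @slot offset numeric(1), the intensity offset used when computing beta.
#' @export
setClass("MethylationExperiment",
  contains = "RangedSummarizedExperiment",
  slots = c(offset = "numeric"),
  prototype = prototype(offset = 100)
)

setValidity("MethylationExperiment", function(object) {
  msg <- NULL
  an <- assayNames(object)
  if (!"beta" %in% an)
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if (xor("M" %in% an, "U" %in% an))
    msg <- c(msg, "intensities must be supplied as both M and U or neither")
  cd <- colData(object)
  need <- c("sample_id", "donor_id", "location", "age_years")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  # paired designs use dura/scalp; multi-tissue sets may carry other labels,
  # but a paired cohort may not duplicate a donor-location combination
  if (all(c("donor_id", "location") %in% colnames(cd)) &&
      all(cd$location %in% c("dura", "scalp"))) {
    if (anyDuplicated(paste(cd$donor_id, cd$location)))
      msg <- c(msg, "each donor may contribute at most one sample per location")
  }
  rd <- rowData(object)
  if ("island_relation" %in% colnames(rd) &&
      !all(rd$island_relation %in% c("island", "shore", "shelf", "open_sea")))
    msg <- c(msg, "island_relation must be island/shore/shelf/open_sea")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MethylationExperiment
#'
#' @param beta probes-by-samples matrix of proportion methylation in [0,1].
#'   May be omitted when both intensity channels are given.
#' @param M,U optional probes-by-samples matrices of methylated and
#'   unmethylated channel intensities. When both are present beta is
#'   recomputed as \code{M / (M + U + offset)}.
#' @param annotation data.frame of probe annotation with columns
#'   \code{probe_id}, \code{chrom}, \code{pos} and any of \code{design_type},
#'   \code{island_relation}, \code{snp_flag}, \code{nearest_gene_id},
#'   \code{gene_distance}. Rows must match the matrices.
#' @param metadata data.frame of sample metadata with columns
#'   \code{sample_id}, \code{donor_id}, \code{location} (\code{"dura"} or
#'   \code{"scalp"}), \code{age_years} and optionally \code{batch}.
#' @param offset intensity offset for the beta transform (default 100).
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' ann <- data.frame(probe_id = c("p1", "p2"), chrom = "chr1", pos = c(10L, 50L))
#' meta <- data.frame(sample_id = c("s1", "s2"), donor_id = c("d1", "d1"),
#'                    location = c("dura", "scalp"), age_years = 30)
#' b <- matrix(c(.2, .4, .3, .5), 2, dimnames = list(ann$probe_id, meta$sample_id))
#' MethylationExperiment(beta = b, annotation = ann, metadata = meta)
#' @export
MethylationExperiment <- function(beta = NULL, M = NULL, U = NULL,
                                  annotation, metadata, offset = 100) {
  stopifnot(is.data.frame(annotation), is.data.frame(metadata))
  if (is.null(beta) && (is.null(M) || is.null(U)))
    stop("supply 'beta' or both 'M' and 'U'")
  if (!is.null(M) && !is.null(U)) {
    stopifnot(identical(dim(M), dim(U)))
    beta <- M / (M + U + offset)
  }
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(annotation))
    stop("matrix rows and annotation rows differ")
  if (ncol(beta) != nrow(metadata))
    stop("matrix columns and metadata rows differ")
  rr <- GRanges(annotation$chrom, IRanges(annotation$pos, width = 1L))
  names(rr) <- annotation$probe_id
  extra <- setdiff(colnames(annotation), c("chrom", "pos"))
  S4Vectors::mcols(rr) <- DataFrame(annotation[, extra, drop = FALSE])
  asy <- list(beta = beta)
  if (!is.null(M)) asy <- c(asy, list(M = as.matrix(M), U = as.matrix(U)))
  asy <- lapply(asy, function(a) {
    dimnames(a) <- list(annotation$probe_id, metadata$sample_id)
    a
  })
  se <- SummarizedExperiment(assays = asy, rowRanges = rr,
                             colData = DataFrame(metadata, row.names = metadata$sample_id))
  new("MethylationExperiment", se, offset = offset)
}

#' Simulation configuration for the paired-methylome generator
#'
#' Holds every tunable of the synthetic-data module: cohort size and age span,
#' array size, planted single-probe/region/block location effects, scalp-biased
#' variance inflation, age-divergent loci, batch structure, the residual noise
#' level on the beta scale, and the target methylation-expression coupling.
#' Defaults emulate the statistical structure of a paired scalp/dura
#' fibroblast cohort of 11 donors aged 0.1-85 years in which 22% of probes
#' are differentially methylated by sampling location.
#'
#' @slot nDonors integer, donors (each contributes a dura and a scalp sample).
#' @slot ageRange numeric(2), donor age span in years.
#' @slot nProbes,nGenes integers, array and transcriptome size.
#' @slot dmpFraction proportion of probes with a planted single-probe
#'   location effect.
#' @slot dmpEffect absolute beta difference (scalp minus dura) at planted
#'   differential probes; signs are balanced across probes.
#' @slot nDmrs,nBlocks integers, planted region and block counts.
#' @slot dmrEffect,blockEffect absolute beta difference planted at region and
#'   block members.
#' @slot blockSpan minimum block extent in basepairs.
#' @slot varInflation multiplicative residual-SD factor at variance-inflated
#'   loci.
#' @slot nVarloci integer, number of variance-inflated loci.
#' @slot varScalpShare proportion of variance-inflated loci inflated in scalp
#'   (the remainder are inflated in dura).
#' @slot nAgediv integer, number of age-divergent probes (assigned round-robin
#'   to the eight trajectory archetypes).
#' @slot agedivSlope absolute change in the scalp-dura beta difference per
#'   year at age-divergent probes.
#' @slot nBatches integer, number of processing batches.
#' @slot batchEffect additive beta offset between adjacent batches.
#' @slot batchFraction proportion of probes affected by batch.
#' @slot noiseSd residual SD on the beta scale (noise is drawn on the logit
#'   scale and scaled so the beta-scale SD matches).
#' @slot couplingR target Pearson correlation between a coupled gene's
#'   log2(FPKM + 1) expression and its probe's beta.
#' @slot seed integer random seed; identical configurations give
#'   bit-identical output.
#' @export
setClass("SimulationConfig",
  representation(
    nDonors = "integer", ageRange = "numeric", nProbes = "integer",
    nGenes = "integer", dmpFraction = "numeric", dmpEffect = "numeric",
    nDmrs = "integer", nBlocks = "integer", dmrEffect = "numeric",
    blockEffect = "numeric", blockSpan = "numeric", varInflation = "numeric",
    nVarloci = "integer", varScalpShare = "numeric", nAgediv = "integer",
    agedivSlope = "numeric", nBatches = "integer", batchEffect = "numeric",
    batchFraction = "numeric", noiseSd = "numeric", couplingR = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  fr <- c(dmpFraction = object@dmpFraction, batchFraction = object@batchFraction,
          varScalpShare = object@varScalpShare)
  bad <- fr < 0 | fr > 1
  if (any(bad))
    msg <- c(msg, paste0(names(fr)[bad], " must lie in [0, 1]"))
  if (object@nDonors < 2L) msg <- c(msg, "nDonors must be >= 2")
  if (object@nProbes < 10L) msg <- c(msg, "nProbes must be >= 10")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
    msg <- c(msg, "ageRange must be (min, max) with min <= max")
  if (abs(object@couplingR) >= 1)
    msg <- c(msg, "couplingR must lie in (-1, 1)")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (object@varInflation < 1) msg <- c(msg, "varInflation must be >= 1")
  for (e in c("dmpEffect", "dmrEffect", "blockEffect")) {
    v <- slot(object, e)
    if (v < 0 || v > 0.48)
      msg <- c(msg, paste0(e, " must lie in [0, 0.48] so planted means stay in [0.02, 0.98]"))
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimulationConfig-class
#' @param nDonors,ageRange,nProbes,nGenes,dmpFraction,dmpEffect,nDmrs,nBlocks
#'   see the class slots.
#' @param dmrEffect,blockEffect,blockSpan,varInflation,nVarloci,varScalpShare
#'   see the class slots.
#' @param nAgediv,agedivSlope,nBatches,batchEffect,batchFraction,noiseSd
#'   see the class slots.
#' @param couplingR,seed see the class slots.
#' @return A \code{SimulationConfig}.
#' @examples
#' SimulationConfig(nDonors = 5L, nProbes = 500L)
#' @export
SimulationConfig <- function(nDonors = 11L, ageRange = c(0.1, 85),
                             nProbes = 20000L, nGenes = 1500L,
                             dmpFraction = 0.22, dmpEffect = 0.2,
                             nDmrs = 25L, nBlocks = 5L,
                             dmrEffect = 0.2, blockEffect = 0.15,
                             blockSpan = 2e5, varInflation = 2,
                             nVarloci = 300L, varScalpShare = 0.83,
                             nAgediv = 400L, agedivSlope = 0.003,
                             nBatches = 2L, batchEffect = 0.05,
                             batchFraction = 0.3, noiseSd = 0.03,
                             couplingR = 0.6, seed = 1L) {
  new("SimulationConfig",
      nDonors = as.integer(nDonors), ageRange = as.numeric(ageRange),
      nProbes = as.integer(nProbes), nGenes = as.integer(nGenes),
      dmpFraction = dmpFraction, dmpEffect = dmpEffect,
      nDmrs = as.integer(nDmrs), nBlocks = as.integer(nBlocks),
      dmrEffect = dmrEffect, blockEffect = blockEffect,
      blockSpan = blockSpan, varInflation = varInflation,
      nVarloci = as.integer(nVarloci), varScalpShare = varScalpShare,
      nAgediv = as.integer(nAgediv), agedivSlope = agedivSlope,
      nBatches = as.integer(nBatches), batchEffect = batchEffect,
      batchFraction = batchFraction, noiseSd = noiseSd,
      couplingR = couplingR, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  cohort:", object@nDonors, "donors, ages",
      paste(object@ageRange, collapse = "-"), "years,",
      object@nBatches, "batch(es)\n")
  cat("  array:", object@nProbes, "probes;", object@nGenes, "genes\n")
  cat(sprintf("  planted: %.0f%% DMPs (|db|=%.2f), %d DMRs, %d blocks (>=%g bp),\n",
              100 * object@dmpFraction, object@dmpEffect, object@nDmrs,
              object@nBlocks, object@blockSpan))
  cat(sprintf("           %d var-inflated loci (x%.1f, %.0f%% scalp), %d age-divergent (%.4f/yr)\n",
              object@nVarloci, object@varInflation, 100 * object@varScalpShare,
              object@nAgediv, object@agedivSlope))
  cat(sprintf("  noise SD %.3f (beta scale); expression coupling r=%.2f; seed %d\n",
              object@noiseSd, object@couplingR, object@seed))
})

setMethod("show", "MethylationExperiment", function(object) {
  callNextMethod()
  cat("offset:", object@offset, "\n")
  if (all(c("donor_id", "location") %in% colnames(colData(object)))) {
    cd <- colData(object)
    cat(sprintf("donors: %d; locations: %s\n",
                length(unique(cd$donor_id)),
                paste(sprintf("%s=%d", names(table(cd$location)),
                              as.integer(table(cd$location))), collapse = ", ")))
  }
})
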