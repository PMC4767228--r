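#' Accessors for MethylationExperiment
#'
#' \code{betaValues} returns the proportion-methylation matrix;
#' \code{methylated} and \code{unmethylated} return the channel intensities
#' (error if the object carries beta values only); \code{probeAnnotation}
#' returns the probe annotation as a data.frame with \code{chrom}/\code{pos}
#' columns restored from the ranges; \code{sampleInfo} returns the sample
#' metadata as a data.frame; \code{hasIntensities} says whether both channels
#' are present; \code{locationIndicator} returns the 0/1 coding of sampling
#' location (dura = 0, scalp = 1).
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @return See the individual descriptions.
#' @name MethylationExperiment-accessors
NULL

#' @rdname MethylationExperiment-accessors
#' @export
betaValues <- function(x) assay(x, "beta")

#' @rdname MethylationExperiment-accessors
#' @export
hasIntensities <- function(x) all(c("M", "U") %in% assayNames(x))

#' @rdname MethylationExperiment-accessors
#' @export
methylated <- function(x) {
  if (!hasIntensities(x)) stop("object has no intensity channels")
  assay(x, "M")
}

#' @rdname MethylationExperiment-accessors
#' @export
unmethylated <- function(x) {
  if (!hasIntensities(x)) stop("object has no intensity channels")
  assay(x, "U")
}

#' @rdname MethylationExperiment-accessors
#' @export
probeAnnotation <- function(x) {
  rr <- rowRanges(x)
  out <- data.frame(
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    as.data.frame(S4Vectors::mcols(rr)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if ("probe_id" %in% colnames(out))
    out <- out[, c("probe_id", setdiff(colnames(out), "probe_id"))]
  out
}

#' @rdname MethylationExperiment-accessors
#' @export
sampleInfo <- function(x) {
  out <- as.data.frame(colData(x))
  rownames(out) <- NULL
  out
}

#' @rdname MethylationExperiment-accessors
#' @export
locationIndicator <- function(x) {
  as.integer(colData(x)$location == "scalp")
}
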