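#' Read and write tab-separated matrices and tables
#'
#' Matrices are written probes-by-samples with a header row of sample ids and
#' the row names in the first column. \code{writeSegmentationBed} exports a
#' chromatin-state (or region) \link[GenomicRanges]{GRanges} as BED with the
#' usual 0-based half-open coordinate conversion.
#'
#' @param x matrix (for the matrix writer) or data.frame (for the table
#'   writer).
#' @param file path.
#' @name epimemory-io
NULL

#' @rdname epimemory-io
#' @export
writeMatrixTsv <- function(x, file) {
  df <- data.frame(id = rownames(x), as.data.frame(x), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname epimemory-io
#' @export
readMatrixTsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname epimemory-io
#' @export
writeTableTsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname epimemory-io
#' @param gr a \link[GenomicRanges]{GRanges}; a metadata column named
#'   \code{state} (or the first metadata column) becomes the BED name field.
#' @export
writeSegmentationBed <- function(gr, file) {
  mc <- S4Vectors::mcols(gr)
  nm <- if ("state" %in% colnames(mc)) as.character(mc$state)
        else if (ncol(mc) > 0) as.character(mc[[1]])
        else "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,  # 0-based half-open
                   end = end(gr),
                   name = nm)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a full simulated study to disk
#'
#' Convenience writer for the synthetic-data module: beta/M/U matrices,
#' probe annotation and sample metadata as TSV, the chromatin segmentation as
#' BED.
#'
#' @param sim list as returned by \code{\link{simulateAnnotation}}.
#' @param mset a \linkS4class{MethylationExperiment}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(sim, mset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    writeMatrixTsv(betaValues(mset), file.path(dir, "beta.tsv")),
    if (hasIntensities(mset)) c(
      writeMatrixTsv(methylated(mset), file.path(dir, "M.tsv")),
      writeMatrixTsv(unmethylated(mset), file.path(dir, "U.tsv"))),
    writeTableTsv(probeAnnotation(mset), file.path(dir, "annotation.tsv")),
    writeTableTsv(sampleInfo(mset), file.path(dir, "metadata.tsv")),
    writeSegmentationBed(sim$segmentation, file.path(dir, "segmentation.bed")))
  invisible(files)
}
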