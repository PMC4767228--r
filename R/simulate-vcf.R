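# INFO keys and the direction of each post-call filter: a record is removed
# when DP < 20, when any of VDB/RPB/MQB/BQB/ICB is < 0.05, or when HOB is
# > 0.05.
vcfFilterFields <- c("DP", "VDB", "RPB", "MQB", "BQB", "ICB", "HOB")

#' Write a toy VCF exercising the post-call variant filters
#'
#' Emits a small VCF v4.2 file whose records carry the coverage and bias-test
#' INFO fields used by the variant filtering stage (\code{DP}, \code{VDB},
#' \code{RPB}, \code{MQB}, \code{BQB}, \code{ICB}, \code{HOB}). Exactly
#' \code{nPass} records satisfy all seven thresholds; each failing record
#' violates at least one, and when \code{nRecords - nPass >= 7} every
#' threshold is violated by at least one record.
#'
#' @param nRecords total record count.
#' @param nPass number of records passing all filters (\code{<= nRecords}).
#' @param seed integer seed.
#' @param file output path (default: a tempfile).
#' @return list with \code{file} (the VCF path) and \code{truth} (data.frame
#'   with record id, pass flag and the comma-separated violated fields).
#' @examples
#' v <- simulateToyVcf(10, 4, seed = 1)
#' sum(v$truth$pass)
#' @export
simulateToyVcf <- function(nRecords, nPass, seed = 1L,
                           file = tempfile(fileext = ".vcf")) {
  nRecords <- as.integer(nRecords)
  nPass <- as.integer(nPass)
  if (nRecords < 1L) stop("nRecords must be >= 1")
  if (nPass > nRecords) stop("nPass must be <= nRecords")
  withSeed(seed, {
    nFail <- nRecords - nPass
    passing <- function() {
      c(DP = sample(20:100, 1L),
        VDB = round(stats::runif(1, 0.06, 1), 4),
        RPB = round(stats::runif(1, 0.06, 1), 4),
        MQB = round(stats::runif(1, 0.06, 1), 4),
        BQB = round(stats::runif(1, 0.06, 1), 4),
        ICB = round(stats::runif(1, 0.06, 1), 4),
        HOB = round(stats::runif(1, 0, 0.049), 4))
    }
    violate <- function(vals, field) {
      vals[field] <- switch(field,
        DP = sample(1:19, 1L),
        HOB = round(stats::runif(1, 0.051, 1), 4),
        round(stats::runif(1, 0, 0.049), 4))
      vals
    }
    recs <- vector("list", nRecords)
    violated <- character(nRecords)
    status <- rep(c(TRUE, FALSE), c(nPass, nFail))
    failFields <- if (nFail > 0L)
      vcfFilterFields[(seq_len(nFail) - 1L) %% 7L + 1L] else character(0)
    fi <- 0L
    for (i in seq_len(nRecords)) {
      v <- passing()
      if (!status[i]) {
        fi <- fi + 1L
        flds <- failFields[fi]
        # past the first cycle of seven, occasionally violate extra fields
        if (fi > 7L && stats::runif(1) < 0.3)
          flds <- unique(c(flds, sample(vcfFilterFields, 1L)))
        for (f in flds) v <- violate(v, f)
        violated[i] <- paste(flds, collapse = ",")
      }
      recs[[i]] <- v
    }
    ord <- sample.int(nRecords)
    recs <- recs[ord]
    status <- status[ord]
    violated <- violated[ord]

    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=epimemory-simulateToyVcf",
      "##contig=<ID=chr1>",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
      "##INFO=<ID=VDB,Number=1,Type=Float,Description=\"Variant distance bias p-value\">",
      "##INFO=<ID=RPB,Number=1,Type=Float,Description=\"Read position bias p-value\">",
      "##INFO=<ID=MQB,Number=1,Type=Float,Description=\"Mapping quality bias p-value\">",
      "##INFO=<ID=BQB,Number=1,Type=Float,Description=\"Base quality bias p-value\">",
      "##INFO=<ID=ICB,Number=1,Type=Float,Description=\"Inbreeding coefficient binomial test p-value\">",
      "##INFO=<ID=HOB,Number=1,Type=Float,Description=\"Homozygote bias p-value\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    bases <- c("A", "C", "G", "T")
    pos <- sort(sample.int(1e6, nRecords))
    body <- vapply(seq_len(nRecords), function(i) {
      v <- recs[[i]]
      ref <- sample(bases, 1L)
      alt <- sample(setdiff(bases, ref), 1L)
      info <- paste0(names(v), "=", v, collapse = ";")
      sprintf("chr1\t%d\tvar%03d\t%s\t%s\t50\t.\t%s",
              pos[i], i, ref, alt, info)
    }, character(1))
    writeLines(c(hdr, body), file)
    list(file = file,
         truth = data.frame(id = sprintf("var%03d", seq_len(nRecords)),
                            pass = status, violated = violated,
                            stringsAsFactors = FALSE))
  })
}
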