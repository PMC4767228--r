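# Internal helpers shared across modules.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Greedy gap scan: positions (sorted within chromosome) are split into groups
# whenever the chromosome changes or the gap to the previous position exceeds
# maxGap. Returns an integer group id per position.
gapGroups <- function(chrom, pos, maxGap) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  newGroup <- c(TRUE, chrom[-1] != chrom[-n] | diff(pos) > maxGap)
  cumsum(newGroup)
}

# Assert that annotation-like input is sorted by (chrom, pos).
checkSorted <- function(chrom, pos) {
  o <- order(chrom, pos)
  if (!identical(o, seq_along(pos)))
    stop("annotation must be sorted by (chrom, pos)")
  invisible(TRUE)
}
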