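# Shared fixtures, built in code.

# A small, fast configuration with every effect type planted.
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(nDonors = 10L, nProbes = 2000L, nGenes = 100L, nDmrs = 4L,
         nBlocks = 1L, nAgediv = 80L, nVarloci = 60L),
    list(...))
  do.call(SimulationConfig, args)
}

# A null configuration: nothing planted, no batch.
nullConfig <- function(...) {
  args <- utils::modifyList(
    list(dmpFraction = 0, nDmrs = 0L, nBlocks = 0L, nAgediv = 0L,
         nVarloci = 0L, batchEffect = 0),
    list(...))
  do.call(SimulationConfig, args)
}

# Build a MethylationExperiment directly from a beta matrix.
toyMset <- function(beta, ages = NULL, chrom = "chr1", pos = NULL,
                    island_relation = "open_sea") {
  P <- nrow(beta); N <- ncol(beta)
  stopifnot(N %% 2 == 0)
  if (is.null(pos)) pos <- seq_len(P) * 1000L
  ann <- data.frame(probe_id = sprintf("p%04d", seq_len(P)),
                    chrom = chrom, pos = pos,
                    design_type = "II",
                    island_relation = island_relation,
                    snp_flag = FALSE, stringsAsFactors = FALSE)
  nd <- N / 2
  if (is.null(ages)) ages <- seq(1, 80, length.out = nd)
  meta <- data.frame(
    sample_id = paste0("s", seq_len(N)),
    donor_id = rep(sprintf("d%02d", seq_len(nd)), each = 2),
    location = rep(c("dura", "scalp"), nd),
    age_years = rep(ages, each = 2), stringsAsFactors = FALSE)
  rownames(beta) <- ann$probe_id
  colnames(beta) <- meta$sample_id
  MethylationExperiment(beta = beta, annotation = ann, metadata = meta)
}

# Quadratic-time Benjamini-Hochberg step-up oracle.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i)          # rank of p[i]
    cand <- vapply(r:n, function(j) p[o[j]] * n / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Exhaustive candidate-region scanner oracle: walks every maximal run by
# brute force.
runScannerOracle <- function(coefs, groups, cutoff) {
  n <- length(coefs)
  res <- list()
  i <- 1L
  while (i <= n) {
    s <- sign(coefs[i]) * (abs(coefs[i]) > cutoff)
    if (s == 0) { i <- i + 1L; next }
    j <- i
    while (j < n && groups[j + 1] == groups[i] &&
           sign(coefs[j + 1]) * (abs(coefs[j + 1]) > cutoff) == s)
      j <- j + 1L
    res[[length(res) + 1L]] <- data.frame(
      idx_start = i, idx_end = j, n_probes = j - i + 1L,
      area = sum(abs(coefs[i:j])),
      direction = if (s > 0) "hyper" else "hypo")
    i <- j + 1L
  }
  if (length(res)) do.call(rbind, res) else NULL
}
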