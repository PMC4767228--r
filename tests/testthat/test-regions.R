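test_that("probe clustering follows the greedy gap scan", {
  ann <- data.frame(chrom = "chr1", pos = c(1, 100, 450, 1200, 1300))
  expect_equal(clusterProbes(ann, maxGap = 500), c(1, 1, 1, 2, 2))
  ann2 <- data.frame(chrom = "chr1", pos = c(100, 700))
  expect_equal(clusterProbes(ann2, maxGap = 500), c(1, 2))
  expect_equal(clusterProbes(data.frame(chrom = "chr1", pos = 5), 500), 1)
  # chromosome change always breaks a group
  ann3 <- data.frame(chrom = c("chr1", "chr2"), pos = c(100, 150))
  expect_equal(clusterProbes(ann3, 500), c(1, 2))
  expect_error(clusterProbes(data.frame(chrom = "chr1", pos = c(5, 2)), 500),
               "sorted")
})

test_that("candidate regions match hand cases and the brute-force scanner", {
  ann <- data.frame(chrom = "chr1", pos = c(100, 200, 300))
  g <- c(1, 1, 1)
  expect_equal(nrow(findCandidateRegions(c(0, 0, 0), ann, g)), 0)
  one <- findCandidateRegions(c(0.15, 0.20, 0.12), ann, g, cutoff = 0.1)
  expect_equal(one$n_probes, 3)
  expect_equal(one$area, 0.47)
  expect_equal(one$direction, "hyper")
  expect_equal(one$start, 100); expect_equal(one$end, 300)
  two <- findCandidateRegions(c(0.15, -0.20), ann[1:2, ], c(1, 1), 0.1)
  expect_equal(two$n_probes, c(1, 1))
  expect_equal(two$direction, c("hyper", "hypo"))
  expect_error(findCandidateRegions(c(0.2), ann[1, , drop = FALSE], 1,
                                    cutoff = 0), "positive")
  # brute-force equality on random coefficient vectors with random groups
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    coefs <- rnorm(n, 0, 0.12)
    groups <- cumsum(c(1, runif(n - 1) < 0.2))
    annR <- data.frame(chrom = "chr1", pos = seq_len(n) * 10)
    got <- findCandidateRegions(coefs, annR, groups, cutoff = 0.1)
    want <- runScannerOracle(coefs, groups, cutoff = 0.1)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$idx_start, want$idx_start)
      expect_equal(got$idx_end, want$idx_end)
      expect_equal(got$area, want$area, tolerance = 1e-12)
      expect_equal(got$direction, want$direction)
    }
    expect_equal(epimemory:::maxCandidateArea(coefs, groups, 0.1),
                 if (is.null(want)) 0 else max(want$area),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap null areas are deterministic and vanish without residual noise", {
  loc <- rep(c(0, 1), each = 5)
  ann <- data.frame(chrom = "chr1", pos = 1:20 * 100)
  groups <- rep(1, 20)
  # zero residuals under the null, no location effect
  y <- matrix(rep(runif(20, 0.3, 0.7), 10), 20, 10)
  nulls <- bootstrapNullAreas(y, cbind(1, loc), groups, cutoff = 0.1,
                              B = 20, seed = 3)
  expect_equal(nulls, rep(0, 20))
  set.seed(71)
  y2 <- y + matrix(rnorm(200, 0, 0.2), 20, 10)
  n1 <- bootstrapNullAreas(y2, cbind(1, loc), groups, B = 50, seed = 9)
  n2 <- bootstrapNullAreas(y2, cbind(1, loc), groups, B = 50, seed = 9)
  expect_identical(n1, n2)
  expect_error(bootstrapNullAreas(y2, cbind(1, loc), groups, B = 0), "B must")
})

test_that("FWER assignment uses the add-one estimator", {
  cand <- data.frame(chrom = "chr1", start = 1, end = 100, n_probes = 3L,
                     direction = "hyper", mean_delta = 0.2, area = 5,
                     idx_start = 1L, idx_end = 3L)
  nulls <- runif(999, 0, 1)   # all below the observed area
  called <- callDmrs(cand, nulls, fwerThreshold = 0.1)
  expect_equal(called$fwer, 1 / 1000)
  expect_true(called$significant)
  called2 <- callDmrs(transform(cand, area = -1), nulls)
  expect_equal(called2$fwer, 1)
  expect_false(called2$significant)
  expect_error(callDmrs(cand, numeric(0)), "empty")
})

test_that("collapsing for blocks averages open-sea clusters only", {
  beta <- matrix(c(0.2, 0.4, 0.6, 0.5), 4, 1)
  beta <- cbind(beta, beta + 0.1, beta, beta + 0.1)
  ann <- data.frame(probe_id = paste0("p", 1:4), chrom = "chr1",
                    pos = c(100, 200, 300, 5000), design_type = "II",
                    island_relation = c(rep("open_sea", 3), "island"),
                    snp_flag = FALSE)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     donor_id = rep(c("d1", "d2"), each = 2),
                     location = rep(c("dura", "scalp"), 2), age_years = 1)
  rownames(beta) <- ann$probe_id; colnames(beta) <- meta$sample_id
  ms <- MethylationExperiment(beta = beta, annotation = ann, metadata = meta)
  col <- collapseForBlocks(ms, clusterGap = 500)
  expect_equal(nrow(col$beta), 1)           # island probe never contributes
  expect_equal(unname(col$beta[1, 1]), 0.4) # mean of 0.2, 0.4, 0.6
  expect_equal(col$annotation$pos, 200)     # midpoint of member span
  # 100 bp apart vs 1000 bp apart at gap 500
  ann2 <- ann; ann2$pos <- c(100, 200, 1200, 5000)
  ms2 <- MethylationExperiment(beta = beta, annotation = ann2, metadata = meta)
  expect_equal(nrow(collapseForBlocks(ms2, 500)$beta), 2)
  annI <- ann; annI$island_relation <- "island"
  msI <- MethylationExperiment(beta = beta, annotation = annI, metadata = meta)
  expect_error(collapseForBlocks(msI), "open-sea")
})

test_that("planted regions are recovered sign-consistently above the cutoff", {
  cfg <- SimulationConfig(nDonors = 10L, nProbes = 2500L, nGenes = 20L,
                          dmpFraction = 0, nDmrs = 6L, nBlocks = 0L,
                          nAgediv = 0L, nVarloci = 0L, batchEffect = 0,
                          dmrEffect = 0.2, noiseSd = 0.03)
  st <- simulateStudy(cfg)
  res <- runDmrAnalysis(st$mset, B = 60, seed = 4)
  sig <- res$regions[res$regions$significant, , drop = FALSE]
  truthReg <- st$truth$regions[st$truth$regions$type == "dmr"]
  expect_gte(nrow(sig), 5)
  # every called region overlaps a truth interval
  for (i in seq_len(nrow(sig))) {
    ov <- any(sig$start[i] <= GenomicRanges::end(truthReg) &
              sig$end[i] >= GenomicRanges::start(truthReg))
    expect_true(ov)
  }
  # members are sign-consistent and exceed the cutoff on every output
  ann <- probeAnnotation(st$mset)
  groups <- clusterProbes(ann, 500)
  for (i in seq_len(nrow(res$candidates))) {
    idx <- res$candidates$idx_start[i]:res$candidates$idx_end[i]
    cf <- res$fits$beta_loc[idx]
    expect_true(all(abs(cf) > 0.1))
    expect_true(length(unique(sign(cf))) == 1)
  }
})
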