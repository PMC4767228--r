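test_that("annotation construction satisfies its invariants", {
  sim <- simulateAnnotation(100, 10, seed = 1)
  ann <- sim$annotation
  expect_equal(nrow(ann), 100)
  # strictly sorted within chromosome
  for (ch in unique(ann$chrom)) {
    p <- ann$pos[ann$chrom == ch]
    expect_true(all(diff(p) > 0))
  }
  expect_true(all(ann$island_relation %in%
                  c("island", "shore", "shelf", "open_sea")))
  expect_true(all(ann$design_type %in% c("I", "II")))
  expect_true(all(ann$gene_distance >= 0))
  expect_error(simulateAnnotation(5, 10), "nProbes")
  expect_error(simulateAnnotation(100, 0), "nGenes")
})

test_that("island relation follows the 0-2kb shore / 2-4kb shelf convention", {
  isl <- data.frame(start = 10000, end = 10800)
  # oracle: plain interval arithmetic
  expect_equal(islandRelation(10400, isl), "island")
  expect_equal(islandRelation(10800 + 1500, isl), "shore")
  expect_equal(islandRelation(10000 - 1500, isl), "shore")
  expect_equal(islandRelation(10800 + 3000, isl), "shelf")
  expect_equal(islandRelation(10800 + 5000, isl), "open_sea")
  # boundaries: 2000 is still shore, 4000 still shelf
  expect_equal(islandRelation(10800 + 2000, isl), "shore")
  expect_equal(islandRelation(10800 + 4000, isl), "shelf")
  # generated labels agree with reclassification against the island set
  sim <- simulateAnnotation(300, 10, seed = 3)
  for (ch in unique(sim$annotation$chrom)) {
    sub <- sim$annotation[sim$annotation$chrom == ch, ]
    isls <- sim$islands[sim$islands$chrom == ch, ]
    expect_equal(sub$island_relation, islandRelation(sub$pos, isls))
  }
})

test_that("the chromatin segmentation tiles each chromosome without gaps", {
  sim <- simulateAnnotation(200, 10, seed = 2)
  seg <- sim$segmentation
  for (ch in unique(as.character(GenomicRanges::seqnames(seg)))) {
    s <- seg[as.character(GenomicRanges::seqnames(seg)) == ch]
    s <- s[order(GenomicRanges::start(s))]
    st <- GenomicRanges::start(s); en <- GenomicRanges::end(s)
    expect_equal(st[1], 1)
    expect_equal(st[-1], en[-length(en)] + 1)  # no gaps, no overlaps
    chromLen <- max(sim$annotation$pos[sim$annotation$chrom == ch]) + 5000
    expect_equal(sum(GenomicRanges::width(s)), chromLen)
  }
  expect_true(all(seg$state %in% epimemory:::chromatinStates18))
})

test_that("cohort generation pairs locations, spans the age range and is deterministic", {
  cfg <- SimulationConfig(nDonors = 11L, ageRange = c(0.1, 85))
  meta <- simulateCohort(cfg)
  expect_equal(nrow(meta), 22)
  expect_equal(length(unique(meta$donor_id)), 11)
  expect_true(all(meta$age_years >= 0.1 & meta$age_years <= 85))
  expect_equal(range(meta$age_years), c(0.1, 85))
  # each donor: one dura and one scalp sample at the same age
  byDonor <- split(meta, meta$donor_id)
  for (d in byDonor) {
    expect_setequal(d$location, c("dura", "scalp"))
    expect_equal(d$age_years[1], d$age_years[2])
  }
  expect_identical(meta, simulateCohort(cfg))
  expect_error(simulateCohort(SimulationConfig(nDonors = 2L)), NA)
  expect_error(SimulationConfig(nDonors = 1L), "nDonors")
})

test_that("null methylation has near-zero group differences and bounded betas", {
  cfg <- nullConfig(nDonors = 10L, nProbes = 1000L, nGenes = 20L,
                    noiseSd = 0.03)
  st <- simulateStudy(cfg)
  b <- betaValues(st$mset)
  expect_true(all(b >= 0 & b <= 1))
  loc <- locationIndicator(st$mset)
  dd <- rowMeans(b[, loc == 1]) - rowMeans(b[, loc == 0])
  # two-group mean difference has SD noiseSd * sqrt(2/n)
  lim <- 2 * cfg@noiseSd * sqrt(2 / 10)
  expect_gt(mean(abs(dd) <= lim), 0.90)
  # intensities are consistent with beta under the offset-100 transform
  expect_equal(betaValues(st$mset),
               methylated(st$mset) /
                 (methylated(st$mset) + unmethylated(st$mset) + 100),
               tolerance = 1e-12)
})

test_that("planted DMRs show the configured group difference at every member probe", {
  cfg <- SimulationConfig(nDonors = 10L, nProbes = 2000L, nGenes = 20L,
                          dmpFraction = 0, nDmrs = 5L, nBlocks = 0L,
                          nAgediv = 0L, nVarloci = 0L, batchEffect = 0,
                          dmrEffect = 0.2, noiseSd = 0.02)
  st <- simulateStudy(cfg)
  b <- betaValues(st$mset)
  loc <- locationIndicator(st$mset)
  tr <- st$truth$probes
  dd <- rowMeans(b[, loc == 1]) - rowMeans(b[, loc == 0])
  mem <- which(tr$is_in_dmr)
  expect_true(length(mem) >= 15)  # 5 regions x >= 3 probes
  observed <- dd[mem] * tr$region_sign[mem]
  expect_true(all(observed > 0.15 & observed < 0.25))
  # every flagged probe lies inside a truth interval
  reg <- st$truth$regions[st$truth$regions$type == "dmr"]
  ann <- probeAnnotation(st$mset)
  inside <- vapply(mem, function(i) {
    any(ann$pos[i] >= GenomicRanges::start(reg) &
        ann$pos[i] <= GenomicRanges::end(reg) &
        ann$chrom[i] == as.character(GenomicRanges::seqnames(reg)))
  }, logical(1))
  expect_true(all(inside))
})

test_that("planted DMP signs are balanced and defaults reflect the emulated study", {
  cfg <- SimulationConfig()
  expect_equal(cfg@dmpFraction, 0.22)
  expect_equal(cfg@nDonors, 11L)
  expect_equal(cfg@ageRange, c(0.1, 85))
  st <- simulateStudy(smallConfig(dmpFraction = 0.2))
  tr <- st$truth$probes
  nDmp <- sum(tr$is_dmp)
  expect_gte(nDmp, 200)
  expect_lte(abs(sum(tr$dmp_sign == 1) - sum(tr$dmp_sign == -1)),
             0.1 * nDmp)
})

test_that("an infeasible planted effect errors before any clipping", {
  cfg <- smallConfig()
  expect_error(SimulationConfig(dmpEffect = 0.6), "0.48")
  cfg2 <- smallConfig(agedivSlope = 0.02)  # 0.02 * 85 = 1.7 on the beta scale
  ann <- simulateAnnotation(cfg2@nProbes, cfg2@nGenes, cfg2@seed)
  meta <- simulateCohort(cfg2)
  expect_error(simulateMethylation(ann$annotation, meta, cfg2),
               "outside \\[0.02, 0.98\\]")
})

test_that("variance inflation is planted at the configured ratio", {
  cfg <- SimulationConfig(nDonors = 12L, nProbes = 2000L, nGenes = 20L,
                          dmpFraction = 0, nDmrs = 0L, nBlocks = 0L,
                          nAgediv = 0L, nVarloci = 150L, varInflation = 2,
                          batchEffect = 0)
  st <- simulateStudy(cfg)
  b <- betaValues(st$mset)
  loc <- locationIndicator(st$mset)
  tr <- st$truth$probes
  vs <- which(tr$is_var_inflated & tr$var_direction == "scalp")
  expect_gte(length(vs), 100)
  ratio <- apply(b[vs, loc == 1], 1, sd) / apply(b[vs, loc == 0], 1, sd)
  f <- cfg@varInflation
  expect_gt(mean(ratio), 0.7 * f)
  expect_lt(mean(ratio), 1.3 * f)
})

test_that("methylation generation is bit-reproducible under a fixed seed", {
  cfg <- smallConfig()
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(betaValues(a$mset), betaValues(b$mset))
  expect_identical(methylated(a$mset), methylated(b$mset))
  expect_identical(a$truth$probes, b$truth$probes)
  expect_identical(a$expression$logExpr, b$expression$logExpr)
})

test_that("expression coupling hits its target correlation", {
  cfg <- SimulationConfig(nDonors = 11L, nProbes = 2000L, nGenes = 300L,
                          couplingR = 0.8, nDmrs = 0L, nBlocks = 0L,
                          nAgediv = 0L, nVarloci = 0L)
  st <- simulateStudy(cfg, nCoupled = 50L)
  expect_true(all(st$expression$fpkm >= 0))
  cp <- st$expression$coupledPairs
  expect_gte(nrow(cp), 30)
  b <- betaValues(st$mset)
  r <- vapply(seq_len(nrow(cp)), function(i)
    cor(b[cp$probe_id[i], ], st$expression$logExpr[cp$gene_id[i], ]),
    numeric(1))
  expect_gt(mean(r), 0.65)
  expect_lt(mean(r), 0.90)

  cfg0 <- SimulationConfig(nDonors = 11L, nProbes = 2000L, nGenes = 300L,
                           couplingR = 0, nDmrs = 0L, nBlocks = 0L,
                           nAgediv = 0L, nVarloci = 0L)
  st0 <- simulateStudy(cfg0, nCoupled = 50L)
  cp0 <- st0$expression$coupledPairs
  b0 <- betaValues(st0$mset)
  r0 <- vapply(seq_len(nrow(cp0)), function(i)
    cor(b0[cp0$probe_id[i], ], st0$expression$logExpr[cp0$gene_id[i], ]),
    numeric(1))
  expect_lt(mean(abs(r0)), 0.25)
  expect_error(SimulationConfig(couplingR = 1), "couplingR")
})

test_that("toy VCF construction matches its contract", {
  v <- simulateToyVcf(5, 5, seed = 2)
  expect_true(all(v$truth$pass))
  v2 <- simulateToyVcf(7, 0, seed = 3)
  expect_true(all(!v2$truth$pass))
  # one violation per threshold, each observed exactly once
  expect_setequal(v2$truth$violated, epimemory:::vcfFilterFields)
  expect_error(simulateToyVcf(3, 4), "nPass")
  # determinism
  f1 <- tempfile(); f2 <- tempfile()
  simulateToyVcf(10, 4, seed = 7, file = f1)
  simulateToyVcf(10, 4, seed = 7, file = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulation writers round-trip matrices and export BED half-open", {
  cfg <- nullConfig(nDonors = 3L, nProbes = 60L, nGenes = 5L)
  st <- simulateStudy(cfg)
  d <- tempfile()
  writeSimulation(st$annotation, st$mset, d)
  b <- readMatrixTsv(file.path(d, "beta.tsv"))
  expect_equal(b, betaValues(st$mset), tolerance = 1e-12)
  bed <- read.delim(file.path(d, "segmentation.bed"), header = FALSE)
  seg <- st$annotation$segmentation
  expect_equal(bed$V2, GenomicRanges::start(seg) - 1L)
  expect_equal(bed$V3, GenomicRanges::end(seg))
})
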