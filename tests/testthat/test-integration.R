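test_that("probe-to-feature mapping respects the inclusive window boundary", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 20000))
  genes$gene_id <- "g1"
  ann <- data.frame(probe_id = c("in", "edge", "out", "far"),
                    chrom = "chr1",
                    pos = c(15000, 25000, 25001, 50000))
  pairs <- mapProbesToFeatures(ann, genes, window = 5000)
  expect_setequal(pairs$probe_id, c("in", "edge"))
  expect_equal(pairs$distance[pairs$probe_id == "in"], 0)
  expect_equal(pairs$distance[pairs$probe_id == "edge"], 5000)
  expect_error(mapProbesToFeatures(ann, genes, window = -1), ">= 0")
})

test_that("methylation-expression association matches the correlation-test oracle", {
  set.seed(101)
  N <- 22
  beta <- matrix(runif(3 * N, 0.2, 0.8), 3, N,
                 dimnames = list(c("p1", "p2", "p3"), paste0("s", 1:N)))
  expr <- rbind(g1 = 2 + 3 * beta[1, ],          # exact linear
                g2 = rnorm(N),                   # random
                g3 = rep(4, N))                  # constant
  colnames(expr) <- colnames(beta)
  pairs <- data.frame(probe_id = c("p1", "p2", "p3"),
                      feature_id = c("g1", "g2", "g3"),
                      distance = 0)
  out <- associateMethylationExpression(beta, expr, pairs)
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_lt(out$p[1], 1e-12)
  ct <- cor.test(beta[2, ], expr[2, ])
  expect_equal(out$r[2], unname(ct$estimate), tolerance = 1e-10)
  expect_equal(out$p[2], ct$p.value, tolerance = 1e-10)
  expect_false(out$testable[3])
  # sign antisymmetry under beta -> 1 - beta
  out2 <- associateMethylationExpression(1 - beta, expr, pairs)
  expect_equal(out2$r[1:2], -out$r[1:2], tolerance = 1e-12)
})

test_that("directionality summary uses the exact binomial test per stratum", {
  ann <- data.frame(probe_id = sprintf("p%02d", 1:20),
                    island_relation = rep("island", 20))
  beta <- matrix(0.1, 20, 4, dimnames = list(ann$probe_id, NULL))
  pairs <- data.frame(probe_id = ann$probe_id,
                      feature_id = "g", distance = 0,
                      r = c(rep(0.5, 10), rep(c(0.5, -0.5), 5)),
                      p = 0.01, significant = TRUE, testable = TRUE)
  out <- directionalitySummary(pairs[1:10, ], ann, beta)
  row <- out[out$island_relation == "island" & out$methylation_bin == "un", ]
  expect_equal(row$n_pos, 10); expect_equal(row$n_neg, 0)
  expect_equal(row$p_binomial, 2 * 0.5^10, tolerance = 1e-12)
  out2 <- directionalitySummary(pairs[11:20, ], ann, beta)
  row2 <- out2[out2$island_relation == "island" & out2$methylation_bin == "un", ]
  expect_equal(row2$n_pos, 5); expect_equal(row2$n_neg, 5)
  expect_equal(row2$p_binomial, 1)
  # empty strata are NA
  expect_true(all(is.na(out$p_binomial[out$n_pos + out$n_neg == 0])))
})

test_that("Yates 2x2 enrichment matches the textbook formula", {
  r <- enrichment2x2(20, 10, 10, 20)
  expect_equal(r$odds_ratio, 4)
  # hand formula: every expected count is 15, every |O-E| is 5
  chi <- 4 * (5 - 0.5)^2 / 15
  expect_equal(r$chi2_yates, chi, tolerance = 1e-12)
  expect_equal(r$p, pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-12)
  flat <- enrichment2x2(10, 10, 10, 10)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$chi2_yates, 0)
  expect_error(enrichment2x2(0, 0, 5, 5), "margin")
  # random tables against an independent hand-computed oracle
  set.seed(111)
  for (i in 1:200) {
    cc <- rpois(4, 20) + 1
    got <- enrichment2x2(cc[1], cc[2], cc[3], cc[4])
    m <- matrix(cc, 2, byrow = TRUE)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    chi <- sum(pmax(abs(m - E) - 0.5, 0)^2 / E)
    expect_equal(got$chi2_yates, chi, tolerance = 1e-8)
    expect_equal(got$p, pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-8)
    expect_equal(got$odds_ratio, cc[1] * cc[4] / (cc[2] * cc[3]))
  }
})

test_that("chromatin-state folds equal hand-computed coverage ratios", {
  seg <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 101), c(100, 200)))
  seg$state <- c("EnhA1", "Quies")
  # feature: 100 bp fully inside EnhA1; background: half in each state
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  bg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
  out <- chromatinStateEnrichment(feat, seg, bg)
  expect_equal(out$fold[out$state == "EnhA1"], 2)
  expect_true(out$highlighted[out$state == "EnhA1"])
  expect_equal(sum(out$feature_frac), 1, tolerance = 1e-9)
  expect_equal(sum(out$background_frac), 1, tolerance = 1e-9)
  # features identical to background: all folds 1
  out2 <- chromatinStateEnrichment(bg, seg, bg)
  expect_true(all(abs(out2$fold - 1) < 1e-12))
  expect_false(any(out2$highlighted))
  # sex chromosomes are dropped before the overlap
  segX <- suppressWarnings(
    c(seg, GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100),
                                  state = "EnhA1")))
  featX <- suppressWarnings(
    c(feat, GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100))))
  outX <- chromatinStateEnrichment(featX, segX, bg)
  expect_equal(outX$feature_bp, out$feature_bp)
})

test_that("variant filtering applies every threshold with reasons", {
  # boundary: DP = 19 removed for coverage, DP = 20 with passing biases and
  # HOB = 0.01 passes
  dir <- tempfile(); dir.create(dir)
  f <- file.path(dir, "edge.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=VDB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=RPB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MQB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=BQB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=ICB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=HOB,Number=1,Type=Float,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\tv1\tA\tT\t50\t.\tDP=19;VDB=0.5;RPB=0.5;MQB=0.5;BQB=0.5;ICB=0.5;HOB=0.01",
    "chr1\t200\tv2\tA\tT\t50\t.\tDP=20;VDB=0.5;RPB=0.5;MQB=0.5;BQB=0.5;ICB=0.5;HOB=0.01",
    "chr1\t300\tv3\tA\tT\t50\t.\tDP=30;VDB=0.5;RPB=0.5;MQB=0.5;BQB=0.5;ICB=0.5;HOB=0.5",
    "chr1\t400\tv4\tA\tT\t50\t.\tVDB=0.5;RPB=0.5;MQB=0.5;BQB=0.5;ICB=0.5;HOB=0.01"),
    f)
  out <- filterVariants(f)
  expect_equal(out$status, c("removed", "pass", "removed", "unevaluable"))
  expect_equal(out$reasons[1], "coverage")
  expect_equal(out$reasons[3], "homozygote_bias")  # HOB removed when p > 0.05
  expect_match(out$reasons[4], "missing:DP")
  # synthetic VCF by construction
  v <- simulateToyVcf(10, 4, seed = 5)
  res <- filterVariants(v$file)
  expect_equal(sum(res$status == "pass"), 4)
  expect_setequal(res$id[res$status == "pass"], v$truth$id[v$truth$pass])
  # pass set invariant to record order; statuses partition the input
  expect_true(all(res$status %in% c("pass", "removed", "unevaluable")))
  lines <- readLines(v$file)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr]
  f2 <- file.path(dir, "shuffled.vcf")
  writeLines(c(lines[hdr], rev(body)), f2)
  res2 <- filterVariants(f2)
  expect_setequal(res2$id[res2$status == "pass"],
                  res$id[res$status == "pass"])
  # every rejection reason appears when one violation per threshold is planted
  v7 <- simulateToyVcf(7, 0, seed = 6)
  res7 <- filterVariants(v7$file)
  expect_setequal(res7$reasons,
                  c("coverage", "vdb", "rpb", "mqb", "bqb",
                    "inbreeding", "homozygote_bias"))
})
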