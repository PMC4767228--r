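#' CpG island relation of a position
#'
#' Classifies positions against a set of CpG island intervals using the
#' standard array convention: inside an island is \code{"island"}, within
#' 0-2 kb of an island edge is \code{"shore"}, within 2-4 kb is
#' \code{"shelf"}, and beyond 4 kb is \code{"open_sea"}.
#'
#' @param pos integer vector of 1-based positions (single chromosome).
#' @param islands data.frame with \code{start}/\code{end} columns (1-based,
#'   inclusive) of island intervals on the same chromosome.
#' @return character vector of labels.
#' @examples
#' isl <- data.frame(start = 10000, end = 10800)
#' islandRelation(c(10100, 10800 + 1500, 10800 + 3000, 10800 + 5000), isl)
#' @export
islandRelation <- function(pos, islands) {
  if (nrow(islands) == 0L) return(rep("open_sea", length(pos)))
  d <- vapply(pos, function(p) {
    inside <- any(p >= islands$start & p <= islands$end)
    if (inside) return(0)
    min(pmax(islands$start - p, p - islands$end))
  }, numeric(1))
  ifelse(d == 0, "island",
         ifelse(d <= 2000, "shore",
                ifelse(d <= 4000, "shelf", "open_sea")))
}

# Lay out probes for one chromosome as repeated "cassettes": an 800 bp CpG
# island with 8 probes, one shore probe on each side, one shelf probe, then a
# stretch of open-sea probes at multi-kb spacing. Gives realistic island
# clustering for region calling and enough sparse probes for block calling.
cassetteChromosome <- function(n) {
  pos <- integer(0)
  islStart <- integer(0)
  islEnd <- integer(0)
  cur <- 10000L
  while (length(pos) < n) {
    s <- cur + 2000L
    e <- s + 800L
    islStart <- c(islStart, s)
    islEnd <- c(islEnd, e)
    pIsl <- sort(sample(s:e, 8L))
    pShoreL <- s - sample(100:1900, 1L)
    pShoreR <- e + sample(100:1900, 1L)
    pShelf <- e + sample(2100:3900, 1L)
    pOpen <- e + 4000L + cumsum(sample(2000:7000, 6L, replace = TRUE))
    pos <- c(pos, pShoreL, pIsl, pShoreR, pShelf, pOpen)
    cur <- max(pOpen) + sample(6000:12000, 1L)
  }
  pos <- sort(unique(pos))[seq_len(n)]
  list(pos = as.integer(pos),
       islands = data.frame(start = islStart, end = islEnd))
}

# The 18-state chromatin vocabulary (Roadmap-style labels).
chromatinStates18 <- c(
  "TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk",
  "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF_Rpts",
  "Het", "TssBiv", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")

#' Generate synthetic probe annotation, gene models and a chromatin
#' segmentation
#'
#' Builds a 450k-style probe manifest: probes clustered into CpG islands with
#' shore/shelf flanks and interleaved open-sea probes, each labeled by island
#' relation (derived from the actual island intervals), assigned a design
#' type, a SNP flag, and the distance to its nearest gene. A fraction of
#' probes is placed on chrX so sex-chromosome filtering has something to do.
#' Each chromosome is tiled gap- and overlap-free with 18 chromatin-state
#' labels.
#'
#' @param nProbes total probe count (>= 10).
#' @param nGenes total gene count (>= 1).
#' @param seed integer seed; identical calls are bit-identical.
#' @param sexFraction fraction of probes placed on chrX.
#' @param snpFraction fraction of probes flagged as overlapping a common SNP.
#' @return list with \code{annotation} (data.frame sorted by chrom/pos with
#'   columns probe_id, chrom, pos, design_type, island_relation, snp_flag,
#'   nearest_gene_id, gene_distance), \code{islands} (data.frame with chrom,
#'   start, end), \code{genes} (\link[GenomicRanges]{GRanges} with gene_id),
#'   and \code{segmentation} (\code{GRanges} with a \code{state} column tiling
#'   each chromosome).
#' @examples
#' sim <- simulateAnnotation(200, 20, seed = 1)
#' table(sim$annotation$island_relation)
#' @export
simulateAnnotation <- function(nProbes, nGenes, seed = 1L,
                               sexFraction = 0.02, snpFraction = 0.02) {
  nProbes <- as.integer(nProbes)
  nGenes <- as.integer(nGenes)
  if (nProbes < 10L) stop("nProbes must be >= 10")
  if (nGenes < 1L) stop("nGenes must be >= 1")
  withSeed(seed, {
    nX <- as.integer(round(sexFraction * nProbes))
    counts <- c(chr1 = nProbes - nX, chrX = nX)
    counts <- counts[counts > 0L]
    pieces <- lapply(names(counts), function(ch) {
      cc <- cassetteChromosome(counts[[ch]])
      ann <- data.frame(
        chrom = ch, pos = cc$pos,
        island_relation = islandRelation(cc$pos, cc$islands),
        stringsAsFactors = FALSE)
      list(ann = ann,
           islands = data.frame(chrom = ch, cc$islands))
    })
    ann <- do.call(rbind, lapply(pieces, `[[`, "ann"))
    islands <- do.call(rbind, lapply(pieces, `[[`, "islands"))
    ann <- ann[order(ann$chrom, ann$pos), , drop = FALSE]
    rownames(ann) <- NULL
    n <- nrow(ann)
    ann$probe_id <- sprintf("cg%07d", seq_len(n))
    inIsland <- ann$island_relation %in% c("island", "shore")
    ann$design_type <- ifelse(
      stats::runif(n) < ifelse(inIsland, 0.7, 0.2), "I", "II")
    ann$snp_flag <- stats::runif(n) < snpFraction

    # chromosome lengths: just past the last probe
    chromLen <- vapply(split(ann$pos, ann$chrom), max, numeric(1)) + 5000

    # gene models, allocated proportionally to probe counts
    gAlloc <- pmax(1L, as.integer(round(nGenes * counts / sum(counts))))
    gAlloc[1] <- gAlloc[1] + (nGenes - sum(gAlloc))
    genes <- do.call(rbind, lapply(seq_along(counts), function(i) {
      ch <- names(counts)[i]
      k <- gAlloc[i]
      startMax <- max(2L, as.integer(chromLen[ch]) - 25000L)
      st <- sort(sample(seq_len(startMax), k, replace = k > startMax))
      data.frame(chrom = ch, start = st,
                 end = pmin(st + sample(2000:20000, k, replace = TRUE),
                            as.integer(chromLen[ch])),
                 stringsAsFactors = FALSE)
    }))
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    genesGr <- GRanges(genes$chrom, IRanges(genes$start, genes$end))
    genesGr$gene_id <- sprintf("g%05d", seq_len(nGenes))

    probesGr <- GRanges(ann$chrom, IRanges(ann$pos, width = 1L))
    hit <- GenomicRanges::distanceToNearest(probesGr, genesGr)
    ann$nearest_gene_id <- NA_character_
    ann$gene_distance <- NA_real_
    qh <- S4Vectors::queryHits(hit)
    ann$nearest_gene_id[qh] <- genesGr$gene_id[S4Vectors::subjectHits(hit)]
    ann$gene_distance[qh] <- S4Vectors::mcols(hit)$distance

    # chromatin-state tiling: contiguous, gap- and overlap-free
    segmentation <- suppressWarnings(do.call(c, lapply(names(chromLen), function(ch) {
      len <- as.integer(chromLen[ch])
      w <- integer(0)
      while (sum(w) < len)
        w <- c(w, sample(5000:50000, 50L, replace = TRUE))
      cut <- which(cumsum(w) >= len)[1]
      w <- w[seq_len(cut)]
      w[cut] <- len - sum(w[-cut])
      st <- cumsum(c(1L, w[-cut]))
      gr <- GRanges(ch, IRanges(st, width = w))
      gr$state <- sample(chromatinStates18, length(gr), replace = TRUE)
      gr
    })))

    ann <- ann[, c("probe_id", "chrom", "pos", "design_type",
                   "island_relation", "snp_flag", "nearest_gene_id",
                   "gene_distance")]
    list(annotation = ann, islands = islands, genes = genesGr,
         segmentation = segmentation)
  })
}

#' Generate a paired-design cohort
#'
#' Draws donor ages spanning the configured range (endpoints included so the
#' cohort always covers the full span) and emits two samples per donor, one
#' from each sampling location (dura and scalp), with donor-level batch
#' assignment.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return data.frame of sample metadata with columns \code{sample_id},
#'   \code{donor_id}, \code{location}, \code{age_years}, \code{batch}, sorted
#'   by donor then location.
#' @examples
#' meta <- simulateCohort(SimulationConfig(nDonors = 11L))
#' nrow(meta)            # 22 samples
#' range(meta$age_years) # spans the age range
#' @export
simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (cfg@nDonors < 2L) stop("nDonors must be >= 2")
  withSeed(cfg@seed, {
    n <- cfg@nDonors
    ages <- sort(c(cfg@ageRange,
                   stats::runif(n - 2L, cfg@ageRange[1], cfg@ageRange[2])))
    donor <- sprintf("d%02d", seq_len(n))
    batch <- sprintf("b%d", rep(seq_len(cfg@nBatches), length.out = n))
    meta <- data.frame(
      donor_id = rep(donor, each = 2L),
      location = rep(c("dura", "scalp"), times = n),
      age_years = rep(ages, each = 2L),
      batch = rep(batch, each = 2L),
      stringsAsFactors = FALSE)
    meta$sample_id <- paste(meta$donor_id, meta$location, sep = "_")
    meta[, c("sample_id", "donor_id", "location", "age_years", "batch")]
  })
}
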