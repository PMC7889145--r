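mkAln <- function(chrom, pos, len = 100, mapq = "unique", split = FALSE) {
  data.frame(read_id = sprintf("r%03d", seq_along(pos)), chrom = chrom,
             pos = pos, strand = "+", len = len, nm = 0L, mapqClass = mapq,
             split = split, stringsAsFactors = FALSE)
}

test_that("read-to-gene assignment follows the one-gene overlap rule", {
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1000, 2000, 5000),
                                                 c(1800, 2800, 5800)),
                                gene_id = c("g1", "g2", "g3"))
  aln <- mkAln("chr1", c(1200, 1750, 1901, 4990, 9000))
  ct <- countReadsPerGene(aln, ann)
  ## read at 1750 overlaps only g1 (ends 1849 < 2000); 1901 overlaps only g2;
  ## 4990 overlaps g3 by 11 bases
  expect_identical(ct$count, c(2L, 1L, 1L))
  ## a read overlapping two genes is assigned to neither
  ann2 <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1000, 1840), c(1800, 2800)),
                                 gene_id = c("g1", "g2"))
  ct2 <- countReadsPerGene(mkAln("chr1", 1750), ann2)
  expect_identical(ct2$count, c(0L, 0L))
  ## ambiguous and split records are excluded
  ct3 <- countReadsPerGene(mkAln("chr1", 1200, mapq = "ambiguous"), ann)
  expect_identical(sum(ct3$count), 0L)
  expect_error(countReadsPerGene(aln, ann, seqnames = "chr2"),
               "absent from alignment header")
})

test_that("a 50-read fixture matches a brute-force overlap scan", {
  set.seed(12)
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(500, 3000, 8000),
                                                 c(2400, 5200, 9100)),
                                gene_id = c("g1", "g2", "g3"))
  pos <- sample.int(10000, 50)
  aln <- mkAln("chr1", pos)
  ct <- countReadsPerGene(aln, ann)
  brute <- c(0L, 0L, 0L)
  for (p in pos) {
    ov <- which(p <= GenomicRanges::end(ann) &
                (p + 99) >= GenomicRanges::start(ann))
    if (length(ov) == 1) brute[ov] <- brute[ov] + 1L
  }
  expect_identical(ct$count, brute)
})

test_that("TPM normalization matches the closed form and its invariances", {
  one <- data.frame(gene_id = "g", length_bp = 1500L, count = 7L)
  expect_equal(tpmNormalize(one)$tpm, 1e6)
  two <- data.frame(gene_id = c("a", "b"), length_bp = c(1000L, 2000L),
                    count = c(100L, 100L))
  tp <- tpmNormalize(two)
  expect_equal(tp$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(sum(tp$tpm), 1e6)
  ## invariant to uniform count scaling
  two2 <- two; two2$count <- two2$count * 2L
  expect_equal(tpmNormalize(two2)$tpm, tp$tpm)
  expect_error(tpmNormalize(data.frame(gene_id = "g", length_bp = 100L,
                                       count = 0L)), "zero")
})

test_that("coverage copy estimates scale with TPM against the trimmed baseline", {
  counts <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       length_bp = 2000L,
                       count = c(rep(200L, 18), 300L, 200L))
  tp <- tpmNormalize(counts)
  baseline <- mean(tp$tpm, trim = 0.1)
  est <- estimateCopiesFromCoverage(tp, c("g01", "g19"))
  expect_equal(est$estimated_copies[1], 2 * tp$tpm[1] / baseline)
  expect_equal(est$estimated_copies[2] / est$estimated_copies[1], 1.5,
               tolerance = 1e-9)
  expect_error(estimateCopiesFromCoverage(tp, "nope"), "not in count table")
  expect_error(estimateCopiesFromCoverage(tpmNormalize(counts[1:5, ])),
               "at least 10 genes")
})

test_that("simulated coverage recovers passenger and neutral copy numbers", {
  d <- fullDataset(seed = 1)
  ct <- tpmNormalize(countReadsPerGene(list(d$a1, d$a2),
                                       annotation(d$genome)))
  est <- estimateCopiesFromCoverage(ct)
  ann <- annotation(d$genome)
  role <- ann$role[match(est$gene_id, ann$gene_id)]
  expect_true(all(abs(est$estimated_copies[role == "passenger"] - 3) <= 0.3))
  expect_true(all(abs(est$estimated_copies[role == "neutral"] - 2) <= 0.3))
  expect_true(all(abs(est$estimated_copies[role == "reference_assay"] - 2) <= 0.3))
})

test_that("droplet Poisson inversion matches the closed form", {
  expect_identical(ddpcrConcentration(0, 10000), 0)
  ## P/N = 1 - exp(-1) gives lambda 1 and 1/volume copies per uL
  conc <- ddpcrConcentration(6321, 10000, dropletVolumeNl = 0.85)
  expect_equal(conc, -log(1 - 0.6321) / 0.85e-3, tolerance = 1e-12)
  expect_equal(conc, 1 / 0.85e-3, tolerance = 1e-3)
  ## halving droplet volume doubles concentration
  expect_equal(ddpcrConcentration(500, 10000, 0.425),
               2 * ddpcrConcentration(500, 10000, 0.85))
  expect_error(ddpcrConcentration(10000, 10000), "saturated")
  expect_error(ddpcrConcentration(10001, 10000), "0 <= P <= N")
})

test_that("copies per genome normalizes to the two-copy reference", {
  expect_equal(copiesPerGenome(4000, 10000, 4000, 10000), 2)
  ## target concentration 1.5x the reference reads out near 3 copies
  N <- 2e5
  Pt <- round(N * (1 - exp(-1.5 * 0.02)))
  Pr <- round(N * (1 - exp(-1.0 * 0.02)))
  expect_equal(copiesPerGenome(Pt, N, Pr, N), 3, tolerance = 0.01)
  expect_error(copiesPerGenome(0, 1000, 0, 1000), "reference concentration")
})

test_that("replicate wells pool counts before inversion", {
  wells <- data.frame(target = rep(c("t", "ref"), each = 3),
                      P = c(100, 110, 90, 70, 75, 65),
                      N = rep(10000, 6), droplet_volume_nl = 0.85)
  pooled <- poolWells(wells)
  expect_identical(pooled$P[pooled$target == "t"], 300)
  expect_identical(pooled$N[pooled$target == "t"], 30000)
})

test_that("Monte-Carlo droplets at a 1.5x target ratio read out 3 copies per genome", {
  set.seed(21)
  lam_r <- 0.8; lam_t <- 1.2     # lambda ratio 1.5
  N <- 20000
  est <- replicate(20, {
    Pt <- rbinom(3, N, 1 - exp(-lam_t))
    Pr <- rbinom(3, N, 1 - exp(-lam_r))
    copiesPerGenome(Pt, rep(N, 3), Pr, rep(N, 3))
  })
  expect_lt(abs(mean(est) - 3) / 3, 0.05)
})

test_that("the ddPCR estimator bias vanishes as droplet count grows", {
  set.seed(33)
  lam_t <- 1.2; lam_r <- 0.8
  bias <- vapply(c(1e3, 1e4, 1e5), function(N) {
    est <- replicate(300, {
      Pt <- rbinom(1, N, 1 - exp(-lam_t))
      Pr <- rbinom(1, N, 1 - exp(-lam_r))
      if (Pr == N || Pt == N) return(NA_real_)
      copiesPerGenome(Pt, N, Pr, N)
    })
    abs(mean(est, na.rm = TRUE) - 3)
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 1e-6)
  expect_lt(bias[3], 0.01)
  expect_lt(bias[1], 0.15)
})

test_that("coverage and ddPCR estimators agree on matched truth", {
  d <- fullDataset(seed = 1)
  ct <- tpmNormalize(countReadsPerGene(list(d$a1, d$a2), annotation(d$genome)))
  ann <- annotation(d$genome)
  pg <- ann$gene_id[ann$role == "passenger"][1]
  cov3 <- estimateCopiesFromCoverage(ct, pg)$estimated_copies
  set.seed(5)
  N <- 20000
  Pt <- rbinom(3, N, 1 - exp(-1.2))   # 3-copy target
  Pr <- rbinom(3, N, 1 - exp(-0.8))   # 2-copy reference
  dd3 <- copiesPerGenome(Pt, rep(N, 3), Pr, rep(N, 3))
  expect_lt(abs(cov3 - dd3) / dd3, 0.15)
})
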