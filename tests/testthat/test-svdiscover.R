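mkObs <- function(chrom1, pos1, o1, chrom2, pos2, o2, type = "split",
                  id = "r1") {
  data.frame(chrom1 = chrom1, pos1 = pos1, lo1 = pos1, hi1 = pos1,
             orient1 = o1, chrom2 = chrom2, pos2 = pos2, lo2 = pos2,
             hi2 = pos2, orient2 = o2, type = type, read_id = id,
             stringsAsFactors = FALSE)
}

test_that("evidence extraction handles empty input and excludes ambiguity", {
  d <- fullDataset(seed = 1)
  clean <- d$pairs[d$pairs$pairClass == "proper", ][1:20, ]
  expect_identical(nrow(extractEvidence(clean)), 0L)
  obs <- extractEvidence(d$pairs)
  expect_true(all(obs$type %in% c("split", "pair")))
  expect_gt(sum(obs$type == "split"), 0)
  ## canonical side ordering
  expect_true(all(obs$chrom1 < obs$chrom2 |
                  (obs$chrom1 == obs$chrom2 & obs$pos1 <= obs$pos2)))
})

test_that("junction-spanning template count matches a truth recount", {
  d <- fullDataset(seed = 1)
  obs <- extractEvidence(d$pairs)
  truth <- truthAdjacencies(d$genome)
  fr <- d$reads$fragments
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    near <- obs[obs$chrom1 == t$chrom1 & obs$chrom2 == t$chrom2 &
                obs$orient1 == t$orient1 & obs$orient2 == t$orient2 &
                abs(obs$pos1 - t$pos1) <= 500, ]
    ## oracle: templates whose fragment strictly spans the derived junction
    spanning <- sum(fr$hap == "B" & fr$chrom == "chrA" &
                    fr$start <= t$derivedPos & fr$end > t$derivedPos)
    expect_gt(nrow(near), 0)
    expect_lt(abs(nrow(near) - spanning) / spanning, 0.35)
  }
})

test_that("clustering merges by distance within one orientation signature only", {
  a <- mkObs("chrA", 1000, "-", "chrD", 5000, "+")
  b <- mkObs("chrA", 1010, "-", "chrD", 5010, "+", id = "r2")
  c1 <- clusterEvidence(rbind(a, b), window = 500)
  expect_length(c1, 1)
  ## different chromosome pair
  c2 <- clusterEvidence(rbind(a, mkObs("chrA", 1010, "-", "chrB", 5010, "+",
                                       id = "r2")), window = 500)
  expect_length(c2, 2)
  ## opposite orientation signatures never merge
  c3 <- clusterEvidence(rbind(a, mkObs("chrA", 1010, "+", "chrD", 5010, "+",
                                       id = "r2")), window = 500)
  expect_length(c3, 2)
  ## far apart on side 2 only
  c4 <- clusterEvidence(rbind(a, mkObs("chrA", 1010, "-", "chrD", 9010, "+",
                                       id = "r2")), window = 500)
  expect_length(c4, 2)
})

test_that("clustering and calls are invariant to input order", {
  set.seed(7)
  obs <- do.call(rbind, lapply(1:40, function(i) {
    j <- sample(3, 1)
    mkObs("chrA", c(1000, 8000, 20000)[j] + sample(-30:30, 1),
          c("-", "-", "+")[j],
          "chrD", c(5000, 9000, 40000)[j] + sample(-30:30, 1),
          c("+", "-", "+")[j],
          type = sample(c("split", "pair"), 1), id = sprintf("r%02d", i))
  }))
  canon <- function(cl) {
    lapply(cl, function(g) sort(g$read_id))
  }
  base <- clusterEvidence(obs, window = 500)
  for (rep in 1:5) {
    sh <- obs[sample(nrow(obs)), ]
    expect_identical(canon(clusterEvidence(sh, window = 500)), canon(base))
  }
  expect_identical(callAdjacencies(base), callAdjacencies(
    clusterEvidence(obs[rev(seq_len(nrow(obs))), ], window = 500)))
})

test_that("support thresholding gates calls and is monotone", {
  obs <- do.call(rbind, lapply(1:3, function(i)
    mkObs("chrA", 1000, "-", "chrD", 5000, "+", id = paste0("r", i))))
  expect_identical(nrow(callAdjacencies(clusterEvidence(obs), minSupport = 4)), 0L)
  expect_identical(nrow(callAdjacencies(clusterEvidence(obs), minSupport = 3)), 1L)
  d <- fullDataset(seed = 1)
  cl <- clusterEvidence(extractEvidence(d$pairs))
  nCalls <- vapply(c(1, 2, 4, 8, 16, 32),
                   function(ms) nrow(callAdjacencies(cl, ms)), integer(1))
  expect_true(all(diff(nCalls) <= 0))
})

test_that("calls are positioned by split-read median and flagged precise", {
  obs <- rbind(mkObs("chrA", 1000, "-", "chrD", 5000, "+"),
               mkObs("chrA", 1000, "-", "chrD", 5000, "+", id = "r2"),
               mkObs("chrA", 1001, "-", "chrD", 5001, "+", id = "r3"),
               mkObs("chrA", 990, "-", "chrD", 4990, "+", type = "pair", id = "r4"))
  call <- callAdjacencies(clusterEvidence(obs), minSupport = 4)
  expect_identical(call$pos1, 1000L)
  expect_identical(call$pos2, 5000L)
  expect_true(call$precise)
  expect_identical(call$split, 3L)
  expect_identical(call$pairs, 1L)
  ## pair-only cluster is imprecise
  pOnly <- do.call(rbind, lapply(1:4, function(i) {
    o <- mkObs("chrA", 1000, "-", "chrD", 5000, "+", type = "pair",
               id = paste0("p", i))
    o$lo1 <- 950; o$hi1 <- 1450; o$lo2 <- 4950; o$hi2 <- 5450
    o
  }))
  ip <- callAdjacencies(clusterEvidence(pOnly), minSupport = 4)
  expect_false(ip$precise)
})

test_that("the default simulation yields the three truth junctions and a clean screen", {
  d <- fullDataset(seed = 1)
  res <- discoverCalls(d)
  truth <- truthAdjacencies(d$genome)
  expect_identical(nrow(res$screened), 3L)
  sig <- paste0(res$screened$orient1, res$screened$orient2)
  expect_true("++" %in% sig)
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    hit <- res$screened[res$screened$chrom1 == t$chrom1 &
                        res$screened$chrom2 == t$chrom2 &
                        res$screened$orient1 == t$orient1 &
                        res$screened$orient2 == t$orient2, ]
    expect_identical(nrow(hit), 1L)
    expect_lte(abs(hit$pos1 - t$pos1), 1)
    expect_lte(abs(hit$pos2 - t$pos2), 1)
    expect_true(hit$precise)
  }
})

test_that("a wild-type-only simulation calls nothing", {
  g <- buildReference(seed = 10)
  rd <- simulateReads(g, simConfig(seed = 10, meanDepth = 10, haplotypeMix = 0))
  idx <- indexReference(haplotype(g, "A"))
  pr <- classifyPairs(mapReads(idx, rd$r1), mapReads(idx, rd$r2))
  calls <- callAdjacencies(clusterEvidence(extractEvidence(pr)))
  expect_identical(nrow(screenRegion(calls, "chrD", 1, 2e5)), 0L)
})

test_that("region screening keeps donor-linked inter-chromosomal calls only", {
  calls <- callAdjacencies(clusterEvidence(rbind(
    do.call(rbind, lapply(1:4, function(i)
      mkObs("chrA", 109000, "-", "chrD", 80001, "+", id = paste0("a", i)))),
    do.call(rbind, lapply(1:4, function(i)
      mkObs("chrA", 5000, "-", "chrA", 9000, "+", id = paste0("b", i)))),
    do.call(rbind, lapply(1:4, function(i)
      mkObs("chrD", 5000, "-", "chrD", 150000, "+", id = paste0("c", i)))))))
  expect_identical(nrow(calls), 3L)
  kept <- screenRegion(calls, "chrD", 1, 2e5)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$chrom1, "chrA")
  expect_identical(kept$pos2, 80001L)
  expect_error(screenRegion(calls, "chrD", 10, 1), "malformed")
  ## decoy intra-chromosomal calls injected into a simulated call set
  d <- fullDataset(seed = 1)
  res <- discoverCalls(d)
  decoys <- callAdjacencies(clusterEvidence(do.call(rbind, lapply(1:5, function(k)
    do.call(rbind, lapply(1:4, function(i)
      mkObs("chrD", 1000 * k, "-", "chrD", 9e4 + 1000 * k, "+",
            id = sprintf("d%d_%d", k, i))))))), minSupport = 4)
  mixed <- rbind(res$all, decoys)
  surv <- screenRegion(mixed, "chrD", 1, 2e5)
  expect_identical(nrow(surv), 3L)
  expect_true(all(surv$chrom1 == "chrA"))
})

test_that("adjacency notation matches the published format and round-trips", {
  a <- data.frame(chrom1 = "chr16", pos1 = 23118416L, orient1 = "+",
                  chrom2 = "chr9", pos2 = 87704340L, orient2 = "-")
  expect_identical(formatAdjacency(a), "+[chr16:23,118,416]:-[chr9:87,704,340]")
  expect_identical(formatAdjacency(a, pretty = FALSE),
                   "+[chr16:23118416]:-[chr9:87704340]")
  expect_identical(parseAdjacency(formatAdjacency(a)), a)
  set.seed(99)
  rand <- data.frame(chrom1 = sample(c("chr1", "chrX"), 100, TRUE),
                     pos1 = sample.int(2e8, 100),
                     orient1 = sample(c("+", "-"), 100, TRUE),
                     chrom2 = sample(c("chr9", "chr16"), 100, TRUE),
                     pos2 = sample.int(2e8, 100),
                     orient2 = sample(c("+", "-"), 100, TRUE),
                     stringsAsFactors = FALSE)
  for (pretty in c(TRUE, FALSE))
    expect_identical(parseAdjacency(formatAdjacency(rand, pretty)), rand)
})
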