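test_that("k-mer queries match an exhaustive string-scan oracle", {
  g <- buildReference(seed = 1)
  ref <- haplotype(g, "A")
  idx <- indexReference(ref)
  ## single-occurrence and absent k-mers
  one <- as.character(Biostrings::subseq(ref[["chrA"]], 501, 521))
  hit <- queryKmer(idx, one)
  expect_identical(hit, data.frame(chrom = "chrA", pos = 501L))
  expect_identical(nrow(queryKmer(idx, strrep("A", 21))), 0L)
  ## 50 random k-mers drawn from the reference
  set.seed(42)
  for (i in 1:50) {
    ch <- sample(names(ref), 1)
    p <- sample.int(Biostrings::width(ref)[match(ch, names(ref))] - 20, 1)
    km <- as.character(Biostrings::subseq(ref[[ch]], p, p + 20))
    got <- queryKmer(idx, km)
    got <- got[order(got$chrom, got$pos), ]
    want <- do.call(rbind, lapply(names(ref), function(c2) {
      m <- Biostrings::matchPattern(km, ref[[c2]])
      if (length(m)) data.frame(chrom = c2, pos = Biostrings::start(m)) else NULL
    }))
    want <- want[order(want$chrom, want$pos), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("exact substrings map uniquely and strand involution holds", {
  g <- buildReference(seed = 1)
  idx <- indexReference(haplotype(g, "A"))
  sub <- as.character(Biostrings::subseq(haplotype(g, "A")[["chrA"]], 101, 200))
  a <- mapReads(idx, setNames(sub, "x"))
  expect_identical(a$pos, 101L)
  expect_identical(a$nm, 0L)
  expect_identical(a$mapqClass, "unique")
  expect_identical(a$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  b <- mapReads(idx, setNames(rc, "y"))
  expect_identical(b$pos, 101L)
  expect_identical(b$strand, "-")
})

test_that("error-free simulated reads match the exhaustive-scan aligner", {
  g <- buildReference(seed = 8)
  rd <- simulateReads(g, simConfig(seed = 8, meanDepth = 0.5, errorRate = 0,
                                   haplotypeMix = 0))
  ref <- haplotype(g, "A")
  idx <- indexReference(ref)
  n <- min(1000, length(rd$r1))
  reads <- rd$r1[seq_len(n)]
  a <- mapReads(idx, reads)
  for (i in seq_len(n)) {
    want <- oracleExact(ref, as.character(reads[[i]]))
    if (nrow(want) == 1) {
      expect_identical(a$mapqClass[i], "unique")
      expect_identical(a$chrom[i], want$chrom)
      expect_identical(a$pos[i], want$pos)
      expect_identical(a$strand[i], want$strand)
      expect_identical(a$nm[i], 0L)
    } else {
      expect_identical(a$mapqClass[i], "ambiguous")
    }
  }
})

test_that("a constructed junction read is split-mapped at the right loci", {
  g <- buildReference(seed = 1)
  ref <- haplotype(g, "A")
  idx <- indexReference(ref)
  r <- paste0(as.character(Biostrings::subseq(ref[["chrA"]], 1000, 1049)),
              as.character(Biostrings::subseq(ref[["chrD"]], 5000, 5049)))
  a <- mapReads(idx, setNames(r, "jx"))
  expect_true(a$split)
  expect_identical(a$chrom, "chrA")
  expect_identical(a$pos, 1000L)
  expect_identical(a$chrom2, "chrD")
  ## the reported junction is the canonical (microhomology-resolved) form of
  ## the constructed one, and the breakpoint shift matches it
  can <- canonicalizeAdjacency("chrA", 1049, "-", "chrD", 5000, "+", ref)
  expect_identical(a$jchrom1, can$chrom1)
  expect_identical(a$jpos1, can$pos1)
  expect_identical(a$jorient1, can$orient1)
  expect_identical(a$jpos2, can$pos2)
  expect_identical(a$b, 50L - (1049L - can$pos1))
  expect_identical(a$pos2, can$pos2)
  ## a fully mappable read is not split
  full <- mapReads(idx, setNames(as.character(
    Biostrings::subseq(ref[["chrD"]], 7000, 7099)), "f"))
  expect_false(full$split)
  expect_identical(full$pos, 7000L)
})

test_that("junction-spanning reads from the simulator are recovered as splits", {
  d <- fullDataset(seed = 1)
  truth <- truthAdjacencies(d$genome)
  spans <- junctionSpanningReads(d, minFlank = 20)
  refChar <- setNames(as.character(haplotype(d$genome, "A")),
                      names(haplotype(d$genome, "A")))
  total <- 0; good <- 0
  for (j in seq_along(spans)) {
    t <- truth[j, ]
    for (mate in 1:2) {
      a <- if (mate == 1) d$a1 else d$a2
      for (i in spans[[j]][[mate]]) {
        total <- total + 1
        ok <- isTRUE(a$split[i]) &&
          a$jchrom1[i] == t$chrom1 && abs(a$jpos1[i] - t$pos1) <= 1 &&
          a$jchrom2[i] == t$chrom2 && abs(a$jpos2[i] - t$pos2) <= 1
        good <- good + ok
      }
    }
  }
  expect_gt(total, 10)
  expect_gte(good / total, 0.95)
})

test_that("pair classification separates proper, inter-chromosomal and long pairs", {
  aln <- function(id, chrom, pos, strand, len = 100, mapq = "unique",
                  split = FALSE) {
    data.frame(read_id = id, chrom = chrom, pos = pos, strand = strand,
               len = len, nm = 0L, mapqClass = mapq, split = split,
               stringsAsFactors = FALSE)
  }
  im <- insertModel(350, 50)
  a1 <- rbind(aln("p", "chrA", 1000, "+"), aln("ic", "chrA", 1000, "+"),
              aln("far", "chrA", 1000, "+"))
  a2 <- rbind(aln("p", "chrA", 1250, "-"), aln("ic", "chrD", 5000, "-"),
              aln("far", "chrA", 9000, "-"))
  cls <- classifyPairs(a1, a2, im)
  expect_identical(cls$pairClass,
                   c("proper", "discordant_inter_chrom", "discordant_distance"))
  expect_error(classifyPairs(a1, a2[c(2, 1, 3), ], im), "read_id")
})

test_that("wild-type discordance matches the truth fragment-length recount", {
  g <- buildReference(seed = 9)
  rd <- simulateReads(g, simConfig(seed = 9, meanDepth = 5, haplotypeMix = 0))
  expect_gte(length(rd$r1), 10000)
  idx <- indexReference(haplotype(g, "A"))
  im <- insertModel(350, 50)
  pr <- classifyPairs(mapReads(idx, rd$r1), mapReads(idx, rd$r2), im)
  tab <- table(pr$pairClass)
  expect_true(is.na(tab["discordant_inter_chrom"]) ||
              tab["discordant_inter_chrom"] == 0)
  ## oracle recount: discordant-by-distance pairs are the long fragments
  fragLen <- rd$fragments$end - rd$fragments$start + 1
  expected <- sum(fragLen > im$maxConcordant)
  observed <- sum(pr$pairClass == "discordant_distance")
  expect_lte(abs(observed - expected), 2)
})

test_that("SAM writing and parsing round-trip alignment records", {
  g <- applyInsertion(buildReference(seed = 3))
  rd <- simulateReads(g, simConfig(seed = 3, meanDepth = 2))
  idx <- indexReference(haplotype(g, "A"))
  a1 <- mapReads(idx, rd$r1)
  a2 <- mapReads(idx, rd$r2)
  pr <- classifyPairs(a1, a2)
  f <- tempfile(fileext = ".sam")
  writeSam(pr, rd, f, idx@seqlengths)
  s <- readSam(f)
  expect_identical(attr(s, "seqlengths"), idx@seqlengths)
  cols <- c("read_id", "chrom", "pos", "strand", "nm", "mapqClass", "split",
            "jchrom1", "jpos1", "jorient1", "jchrom2", "jpos2", "jorient2")
  for (mate in 1:2) {
    got <- s[s$mate == mate, cols]
    rownames(got) <- NULL
    want <- (if (mate == 1) a1 else a2)[, cols]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})
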