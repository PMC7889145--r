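# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# Full study-condition dataset (default genome + insertion, 40x reads),
# cached per seed. Returns genome, reads, per-mate alignments and pairs.
fullDataset <- function(seed = 1) {
  key <- paste0("data", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  g <- applyInsertion(buildReference(seed = seed))
  rd <- simulateReads(g, simConfig(seed = seed))
  idx <- indexReference(haplotype(g, "A"))
  a1 <- mapReads(idx, rd$r1)
  a2 <- mapReads(idx, rd$r2)
  pairs <- classifyPairs(a1, a2)
  out <- list(genome = g, reads = rd, index = idx, a1 = a1, a2 = a2,
              pairs = pairs)
  .fixtureCache[[key]] <- out
  out
}

# One pass of the discovery core over a dataset: evidence -> clusters ->
# calls -> screen over the donor chromosome.
discoverCalls <- function(d, minSupport = 4) {
  im <- insertModel()
  obs <- extractEvidence(d$pairs, im)
  calls <- callAdjacencies(clusterEvidence(obs, im$maxConcordant), minSupport)
  donor <- d$genome@params$donorChrom
  list(all = calls,
       screened = screenRegion(calls, donor, 1,
                               unname(d$index@seqlengths[donor])))
}

# Exhaustive-scan oracle placement of an error-free read: all exact
# occurrences over both strands of every chromosome.
oracleExact <- function(ref, read) {
  hits <- list()
  pat <- Biostrings::DNAString(read)
  rcp <- Biostrings::reverseComplement(pat)
  for (ch in names(ref)) {
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(if (strand == "+") pat else rcp, ref[[ch]])
      if (length(m))
        hits[[length(hits) + 1]] <- data.frame(chrom = ch,
                                               pos = Biostrings::start(m),
                                               strand = strand)
    }
  }
  if (!length(hits)) return(data.frame(chrom = character(0), pos = integer(0),
                                       strand = character(0)))
  do.call(rbind, hits)
}

# truth-spanning read indices: reads covering a derived junction position
# with at least minFlank bases on each side
junctionSpanningReads <- function(d, minFlank = 20) {
  fr <- d$reads$fragments
  rl <- 100
  siteChrom <- d$genome@params$site$chrom
  if (is.null(siteChrom)) siteChrom <- "chrA"
  juncs <- truthAdjacencies(d$genome)$derivedPos
  r1a <- ifelse(fr$strand == "-", fr$end - rl + 1, fr$start)
  r2a <- ifelse(fr$strand == "-", fr$start, fr$end - rl + 1)
  lapply(juncs, function(dp) {
    onB <- fr$hap == "B" & fr$chrom == siteChrom
    list(r1 = which(onB & r1a <= dp - minFlank + 1 & r1a + rl - 1 >= dp + minFlank),
         r2 = which(onB & r2a <= dp - minFlank + 1 & r2a + rl - 1 >= dp + minFlank))
  })
}

table1Counts <- function() {
  setNames(c(2L, 43L, 43L, 2L),
           c("Cre+;F/F", "Cre+;F/W", "Cre-;F/F", "Cre-;F/W"))
}
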