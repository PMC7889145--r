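#' Build a wild-type toy reference genome with annotation
#'
#' Creates a deterministic two-chromosome reference emulating the genomic
#' context of a BAC transgene study at desk scale: an acceptor chromosome
#' (`chrA`) carrying a multi-exon acceptor gene plus a two-copy reference
#' assay gene, and a donor chromosome (`chrD`) carrying the driver gene and
#' four passenger genes inside a contiguous donor (BAC-like) interval.
#' The remaining annotation is filled with neutral two-copy genes so that a
#' genome-average coverage baseline is meaningful.
#'
#' Both haplotypes of the returned model are identical (wild type); use
#' [applyInsertion()] to plant the transgene on haplotype B.
#'
#' @param seed integer; sequences are uniform random ACGT, byte-identical
#'   for a given seed.
#' @param chromLengths named numeric of chromosome lengths in bp
#'   (each >= 50 kb). The annotation layout scales with the lengths.
#' @param acceptorExons number of acceptor-gene exons (>= 2, so the
#'   insertion can disrupt the final exon).
#' @return A [GenomeModel-class] (wild-type; no truth adjacencies yet).
#' @examples
#' g <- buildReference(seed = 1)
#' g
#' @export
buildReference <- function(seed = 1,
                           chromLengths = c(chrA = 2e5, chrD = 2e5),
                           acceptorExons = 2) {
  if (length(chromLengths) < 2 || is.null(names(chromLengths)))
    stop("chromLengths must be a named vector with at least two chromosomes")
  if (any(chromLengths < 5e4))
    stop("chromosome lengths must be >= 50 kb")
  if (acceptorExons < 2)
    stop("the acceptor gene needs at least 2 exons so that an insertion can disrupt its final exon")
  acceptorChrom <- names(chromLengths)[1]
  donorChrom <- names(chromLengths)[2]
  LA <- chromLengths[[1]]
  LD <- chromLengths[[2]]

  set.seed(seed)
  haps <- randomDna(chromLengths)

  geneLen <- round(0.01 * LA)

  ## acceptor chromosome layout
  aStart <- round(0.50 * LA) + 1
  aEnd <- aStart + round(0.05 * LA) - 1
  finalExon <- c(aEnd - round(0.01 * LA) + 1, aEnd)
  exStarts <- round(seq(aStart, finalExon[1] - round(0.005 * LA),
                        length.out = acceptorExons))
  exons <- data.frame(start = exStarts,
                      end = exStarts + round(0.0075 * LA) - 1)
  exons$end <- pmin(exons$end, finalExon[1] - 1L)
  exons$start[acceptorExons] <- finalExon[1]
  exons$end[acceptorExons] <- finalExon[2]

  neutralStarts <- function(L, excl) {
    s <- seq(round(0.025 * L) + 1, L - 2 * geneLen, by = round(0.03 * L))
    keep <- (s + geneLen - 1) < excl[1] | s > excl[2]
    s[keep]
  }
  sA <- neutralStarts(LA, c(round(0.48 * LA), round(0.60 * LA)))

  ## donor chromosome layout
  ds <- round(0.40 * LD) + 1
  de <- round(0.50 * LD)
  drvStart <- round(0.45 * LD) + 1
  drvEnd <- drvStart + round(0.015 * LD) - 1
  pgStarts <- round(c(0.405, 0.425, 0.4675, 0.485) * LD) + 1
  sD <- neutralStarts(LD, c(round(0.37 * LD), round(0.53 * LD)))

  genes <- rbind(
    data.frame(gene_id = "refA", chrom = acceptorChrom, start = sA[1],
               end = sA[1] + geneLen - 1, role = "reference_assay"),
    data.frame(gene_id = sprintf("gA%02d", seq_along(sA[-1])),
               chrom = acceptorChrom, start = sA[-1],
               end = sA[-1] + geneLen - 1, role = "neutral"),
    data.frame(gene_id = "accT", chrom = acceptorChrom, start = aStart,
               end = aEnd, role = "acceptor"),
    data.frame(gene_id = "drvQ", chrom = donorChrom, start = drvStart,
               end = drvEnd, role = "driver"),
    data.frame(gene_id = c("pgK2", "pgK1", "pgE4", "pgR4"),
               chrom = donorChrom, start = pgStarts,
               end = pgStarts + geneLen - 1, role = "passenger"),
    data.frame(gene_id = sprintf("gD%02d", seq_along(sD)),
               chrom = donorChrom, start = sD,
               end = sD + geneLen - 1, role = "neutral")
  )
  ann <- GRanges(factor(genes$chrom, levels = names(chromLengths)),
                 IRanges(genes$start, genes$end), strand = "+",
                 gene_id = genes$gene_id, role = genes$role)

  exonsGr <- GRanges(acceptorChrom, IRanges(exons$start, exons$end),
                     strand = "+", gene_id = "accT",
                     exon_rank = seq_len(acceptorExons))

  params <- list(
    acceptorChrom = acceptorChrom, donorChrom = donorChrom,
    donorStart = ds, donorEnd = de,
    driverGene = "drvQ",
    sitePos = aEnd - round(0.005 * LA),
    deletedSpan = round(0.015 * LA),
    retainBp = round(0.01 * LA)
  )

  cn <- setNames(rep(2, length(ann)), ann$gene_id)
  new("GenomeModel",
      haplotypeA = haps, haplotypeB = haps,
      annotation = ann, acceptorExons = exonsGr,
      truthAdjacencies = emptyAdjacencyFrame(),
      truthCopyNumber = cn,
      insertionBlocks = data.frame(),
      params = params)
}

emptyAdjacencyFrame <- function() {
  data.frame(chrom1 = character(0), pos1 = integer(0), orient1 = character(0),
             chrom2 = character(0), pos2 = integer(0), orient2 = character(0),
             derivedPos = integer(0), stringsAsFactors = FALSE)
}

# synthetic recombinase marker: fixed sequence independent of the genome seed,
# absent from any reasonably sized random reference
syntheticMarker <- function(len = 1000) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(90210L)
  DNAString(as.character(randomDna(c(cre = len))[[1]]))
}

#' Describe a BAC-style transgene construct
#'
#' The donor fragment spans the driver and passenger genes on the donor
#' chromosome; the first `replacedPrefixBp` bases of the driver gene are
#' replaced by a synthetic recombinase marker absent from the reference,
#' emulating a promoter swap that provides a transgene-only sequence tag.
#'
#' @param genome A [GenomeModel-class] from [buildReference()]; supplies the
#'   default donor interval and driver gene.
#' @param tandemCopies number of tandem cassette copies (>= 1).
#' @param rearranged logical; if `TRUE` (default) the cassette is
#'   `donor-left + marker + retained acceptor fragment + inverted donor-right`,
#'   which plants exactly three inter-chromosomal junctions, one of them with
#'   a +/+ orientation signature. If `FALSE` the cassette is the plain donor
#'   fragment, planting the two flank junctions only.
#' @param replacedPrefixBp driver-gene prefix replaced by the marker (default
#'   222 bp).
#' @param insertSequence optional [Biostrings::DNAString] marker; by default a
#'   fixed 1 kb synthetic sequence.
#' @param retainBp length of the retained acceptor fragment when `rearranged`.
#' @param donorStart,donorEnd donor fragment extent (1-based inclusive).
#' @return A [TransgeneConstruct-class].
#' @export
transgeneConstruct <- function(genome, tandemCopies = 1, rearranged = TRUE,
                               replacedPrefixBp = 222,
                               insertSequence = NULL,
                               retainBp = genome@params$retainBp,
                               donorStart = genome@params$donorStart,
                               donorEnd = genome@params$donorEnd) {
  stopifnot(is(genome, "GenomeModel"))
  if (is.null(insertSequence)) insertSequence <- syntheticMarker()
  obj <- new("TransgeneConstruct",
             donorChrom = genome@params$donorChrom,
             donorStart = donorStart, donorEnd = donorEnd,
             driverGene = genome@params$driverGene,
             replacedPrefixBp = replacedPrefixBp,
             insertSequence = insertSequence,
             tandemCopies = tandemCopies,
             rearranged = rearranged,
             retainBp = if (rearranged) retainBp else 0)
  ann <- annotation(genome)
  covered <- ann[ann$role %in% c("driver", "passenger")]
  inside <- as.character(seqnames(covered)) == obj@donorChrom &
    start(covered) >= donorStart & end(covered) <= donorEnd
  if (!all(inside))
    stop("donor interval must cover the driver and passenger genes")
  obj
}

blockFrame <- function(src, start, end, strand, mappable) {
  data.frame(src = src, start = start, end = end, strand = strand,
             mappable = mappable, stringsAsFactors = FALSE)
}

#' Plant the transgene cassette on haplotype B
#'
#' Modifies haplotype B of a wild-type [GenomeModel-class]: the span
#' `(sitePos, sitePos + deletedSpan]` of the site chromosome is excised and
#' replaced by `tandemCopies` copies of the transgene cassette. With a
#' `rearranged` construct the cassette retains the final `retainBp` bases of
#' the excised span between the marker and the inverted donor tail, so that
#' the derived allele carries three reference-mappable inter-chromosomal
#' junctions (orientation signatures -/+, -/-, +/+); the fourth junction is
#' adjacent to the marker sequence and therefore invisible to reference
#' alignment. Truth adjacencies are enumerated from the derived block
#' structure, canonicalized across junction microhomology, and stored
#' together with per-gene truth copy numbers.
#'
#' @param genome wild-type [GenomeModel-class].
#' @param construct a [TransgeneConstruct-class]; default from
#'   [transgeneConstruct()].
#' @param siteChrom,sitePos insertion site (1-based; default: inside the
#'   acceptor gene's final exon).
#' @param deletedSpan bases deleted to the right of `sitePos` (>= 0).
#' @return The modified [GenomeModel-class] with truth recorded.
#' @export
applyInsertion <- function(genome,
                           construct = transgeneConstruct(genome),
                           siteChrom = genome@params$acceptorChrom,
                           sitePos = genome@params$sitePos,
                           deletedSpan = genome@params$deletedSpan) {
  stopifnot(is(genome, "GenomeModel"), is(construct, "TransgeneConstruct"))
  hapA <- genome@haplotypeA
  if (!siteChrom %in% names(hapA))
    stop("insertion site chromosome '", siteChrom, "' is not in the genome")
  L <- Biostrings::width(hapA)[match(siteChrom, names(hapA))]
  if (sitePos < 1 || sitePos > L)
    stop("insertion site position lies outside chromosome ", siteChrom)
  if (deletedSpan < 0 || sitePos + deletedSpan >= L)
    stop("deleted span exceeds chromosome ", siteChrom)
  dc <- construct@donorChrom
  if (!dc %in% names(hapA)) stop("donor chromosome '", dc, "' is not in the genome")
  if (identical(dc, siteChrom))
    stop("donor and insertion-site chromosomes must differ")
  LD <- Biostrings::width(hapA)[match(dc, names(hapA))]
  if (construct@donorStart < 1 || construct@donorEnd > LD)
    stop("construct interval exceeds the donor chromosome")
  ann <- annotation(genome)
  drv <- ann[ann$gene_id == construct@driverGene]
  if (length(drv) != 1) stop("driver gene not found in annotation")
  r1 <- start(drv)
  rep <- construct@replacedPrefixBp
  if (r1 <= construct@donorStart || r1 + rep - 1 >= construct@donorEnd)
    stop("the driver gene prefix must be internal to the donor fragment")
  if (construct@rearranged && construct@retainBp > deletedSpan)
    stop("retainBp must not exceed deletedSpan")
  marker <- construct@insertSequence
  if (sum(Biostrings::vcountPattern(marker, hapA)) > 0)
    stop("marker insert sequence occurs in the reference; choose another")

  s1 <- sitePos
  s2 <- sitePos + deletedSpan + 1
  ds <- construct@donorStart
  de <- construct@donorEnd
  m2 <- sitePos + deletedSpan
  m1 <- m2 - construct@retainBp + 1

  cassette <- do.call(rbind, lapply(seq_len(construct@tandemCopies), function(i) {
    core <- rbind(
      blockFrame(dc, ds, r1 - 1, "+", TRUE),
      blockFrame("<marker>", 1, length(marker), "+", FALSE))
    if (construct@rearranged) {
      core <- rbind(core,
        blockFrame(siteChrom, m1, m2, "+", TRUE),
        blockFrame(dc, r1 + rep, de, "-", TRUE))
    } else {
      core <- rbind(core, blockFrame(dc, r1 + rep, de, "+", TRUE))
    }
    core
  }))
  blocks <- rbind(
    blockFrame(siteChrom, 1, s1, "+", TRUE),
    cassette,
    blockFrame(siteChrom, s2, L, "+", TRUE))

  ## assemble the derived chromosome
  pieces <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    if (b$src == "<marker>") return(marker)
    s <- Biostrings::subseq(hapA[[b$src]], b$start, b$end)
    if (b$strand == "-") s <- reverseComplement(s)
    s
  })
  derived <- do.call(Biostrings::xscat, pieces)
  hapB <- hapA
  hapB[[siteChrom]] <- derived

  ## enumerate truth junctions from adjacent mappable blocks
  w <- blocks$end - blocks$start + 1
  derEnd <- cumsum(w)
  refChar <- setNames(as.character(hapA), names(hapA))
  adj <- list()
  for (i in seq_len(nrow(blocks) - 1)) {
    b1 <- blocks[i, ]; b2 <- blocks[i + 1, ]
    if (!b1$mappable || !b2$mappable) next
    contiguous <- b1$src == b2$src && b1$strand == b2$strand &&
      ((b1$strand == "+" && b1$end + 1 == b2$start) ||
       (b1$strand == "-" && b1$start == b2$end + 1))
    if (contiguous) next
    side1 <- if (b1$strand == "+") list(b1$src, b1$end, "-") else list(b1$src, b1$start, "+")
    side2 <- if (b2$strand == "+") list(b2$src, b2$start, "+") else list(b2$src, b2$end, "-")
    can <- canonicalizeAdjacency(side1[[1]], side1[[2]], side1[[3]],
                                 side2[[1]], side2[[2]], side2[[3]], refChar)
    can$derivedPos <- derEnd[i]
    adj[[length(adj) + 1]] <- can
  }
  adjDf <- if (length(adj)) unique(do.call(rbind, adj)) else emptyAdjacencyFrame()
  rownames(adjDf) <- NULL

  cn <- genome@truthCopyNumber
  pass <- ann[ann$role == "passenger"]
  contained <- as.character(seqnames(pass)) == dc &
    start(pass) >= ds & end(pass) <= de
  cn[pass$gene_id[contained]] <- 2 + construct@tandemCopies

  out <- genome
  out@haplotypeB <- hapB
  out@truthAdjacencies <- adjDf
  out@truthCopyNumber <- cn
  out@insertionBlocks <- blocks
  out@params$construct <- construct
  out@params$site <- list(chrom = siteChrom, pos = sitePos, deletedSpan = deletedSpan)
  validObject(out)
  out
}

#' Canonicalize an adjacency across junction microhomology
#'
#' A novel junction whose flanks share terminal homology admits several
#' equivalent breakpoint representations (the derived sequence is identical).
#' Split reads sequenced from the two strands of the derived allele would
#' otherwise report representations shifted by the homology length. This
#' walks the full equivalence range and returns the lexicographically
#' smallest representation with canonically ordered sides, which both the
#' truth recorder and the caller use.
#'
#' @param c1,p1,o1,c2,p2,o2 the two junction sides: chromosome, 1-based
#'   position, and orientation (`"+"` joins sequence extending right of the
#'   position on the forward strand, `"-"` extending left).
#' @param ref named character vector (or [Biostrings::DNAStringSet]) of
#'   reference chromosome sequences.
#' @return One-row data.frame `chrom1,pos1,orient1,chrom2,pos2,orient2`.
#' @export
canonicalizeAdjacency <- function(c1, p1, o1, c2, p2, o2, ref) {
  if (!is.character(ref)) ref <- setNames(as.character(ref), names(ref))
  baseAt <- function(ch, p) {
    if (p < 1 || p > nchar(ref[[ch]])) return(NA_character_)
    substr(ref[[ch]], p, p)
  }
  compb <- c(A = "T", C = "G", G = "C", T = "A")
  cmp <- function(b) if (is.na(b)) NA_character_ else unname(compb[b])
  dir1 <- if (o1 == "-") 1L else -1L
  dir2 <- if (o2 == "+") 1L else -1L
  variants <- list(c(p1, p2))
  ## shift forward (+1): junction absorbs the first downstream base
  q1 <- p1; q2 <- p2
  for (i in seq_len(300)) {
    nextUp <- if (o1 == "-") baseAt(c1, q1 + 1) else cmp(baseAt(c1, q1 - 1))
    firstDown <- if (o2 == "+") baseAt(c2, q2) else cmp(baseAt(c2, q2))
    if (is.na(nextUp) || is.na(firstDown) || nextUp != firstDown) break
    q1 <- q1 + dir1; q2 <- q2 + dir2
    variants[[length(variants) + 1]] <- c(q1, q2)
  }
  ## shift backward (-1): junction releases the last upstream base
  q1 <- p1; q2 <- p2
  for (i in seq_len(300)) {
    lastUp <- if (o1 == "-") baseAt(c1, q1) else cmp(baseAt(c1, q1))
    backDown <- if (o2 == "+") baseAt(c2, q2 - 1) else cmp(baseAt(c2, q2 + 1))
    if (is.na(lastUp) || is.na(backDown) || lastUp != backDown) break
    q1 <- q1 - dir1; q2 <- q2 - dir2
    variants[[length(variants) + 1]] <- c(q1, q2)
  }
  rows <- lapply(variants, function(v) {
    orderAdjacencySides(c1, v[1], o1, c2, v[2], o2)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom1, df$pos1, df$chrom2, df$pos2, df$orient1, df$orient2), ,
           drop = FALSE]
  df[1, , drop = FALSE]
}

orderAdjacencySides <- function(c1, p1, o1, c2, p2, o2) {
  swap <- (c1 > c2) || (c1 == c2 && p1 > p2)
  if (swap) {
    tmp <- list(c1, p1, o1)
    c1 <- c2; p1 <- p2; o1 <- o2
    c2 <- tmp[[1]]; p2 <- tmp[[2]]; o2 <- tmp[[3]]
  }
  data.frame(chrom1 = c1, pos1 = as.integer(p1), orient1 = o1,
             chrom2 = c2, pos2 = as.integer(p2), orient2 = o2,
             stringsAsFactors = FALSE)
}

#' Simulate paired-end reads from a diploid genome model
#'
#' Draws forward-reverse templates from the two haplotypes (haplotype B with
#' probability `haplotypeMix`), fragment lengths from a normal distribution,
#' and iid substitution errors, emulating a whole-genome sequencing design
#' at desk scale. The number of templates is
#' `meanDepth * haploid genome length / (2 * readLength)`.
#'
#' @param genome A [GenomeModel-class].
#' @param sim A [SimConfig-class].
#' @return list with `r1`, `r2` (named [Biostrings::DNAStringSet]s in
#'   template order) and `fragments`, a data.frame of truth placements
#'   (haplotype, chromosome, start, end, fragment strand; coordinates are in
#'   the coordinates of the source haplotype).
#' @export
simulateReads <- function(genome, sim) {
  stopifnot(is(genome, "GenomeModel"), is(sim, "SimConfig"))
  validObject(sim)
  hapA <- genome@haplotypeA
  hapB <- genome@haplotypeB
  if (sim@insertMean > min(Biostrings::width(hapA)))
    stop("insertMean exceeds the shortest chromosome")
  rl <- sim@readLength
  lenA <- sum(Biostrings::width(hapA))
  nPairs <- round(sim@meanDepth * lenA / (2 * rl))

  set.seed(sim@seed)
  fromB <- runif(nPairs) < sim@haplotypeMix
  ins <- pmax(round(rnorm(nPairs, sim@insertMean, sim@insertSd)), rl)
  fragMinus <- runif(nPairs) < 0.5

  chromV <- character(nPairs)
  startV <- integer(nPairs)
  endV <- integer(nPairs)
  for (hap in c("A", "B")) {
    hs <- if (hap == "A") hapA else hapB
    idx <- which(fromB == (hap == "B"))
    if (!length(idx)) next
    w <- Biostrings::width(hs)
    ci <- sample.int(length(w), length(idx), replace = TRUE, prob = w)
    insH <- pmin(ins[idx], w[ci])
    st <- floor(runif(length(idx)) * (w[ci] - insH + 1)) + 1
    chromV[idx] <- names(hs)[ci]
    startV[idx] <- st
    endV[idx] <- st + insH - 1
  }

  leftSeq <- character(nPairs)
  rightSeq <- character(nPairs)
  for (hap in c("A", "B")) {
    hs <- if (hap == "A") hapA else hapB
    for (ch in names(hs)) {
      idx <- which((fromB == (hap == "B")) & chromV == ch)
      if (!length(idx)) next
      sq <- hs[[ch]]
      lv <- Biostrings::DNAStringSet(Views(sq, startV[idx], startV[idx] + rl - 1))
      rv <- Biostrings::DNAStringSet(Views(sq, endV[idx] - rl + 1, endV[idx]))
      leftSeq[idx] <- as.character(lv)
      rightSeq[idx] <- as.character(reverseComplement(rv))
    }
  }
  ## leftSeq is the forward-strand read at the left fragment end; rightSeq the
  ## reverse-strand read at the right end. Which is R1 follows fragment strand.
  r1 <- ifelse(fragMinus, rightSeq, leftSeq)
  r2 <- ifelse(fragMinus, leftSeq, rightSeq)
  if (sim@errorRate > 0) {
    r1 <- cpp_inject_errors(r1, sim@errorRate)
    r2 <- cpp_inject_errors(r2, sim@errorRate)
  }
  ids <- sprintf("t%07d", seq_len(nPairs))
  frag <- data.frame(id = ids, hap = ifelse(fromB, "B", "A"),
                     chrom = chromV, start = startV, end = endV,
                     strand = ifelse(fragMinus, "-", "+"),
                     stringsAsFactors = FALSE)
  list(r1 = Biostrings::DNAStringSet(setNames(r1, ids)),
       r2 = Biostrings::DNAStringSet(setNames(r2, ids)),
       fragments = frag)
}

#' Write genome and simulation artifacts as plain files
#'
#' @param genome A [GenomeModel-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeGenomeFiles <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pA <- file.path(dir, "haplotypeA.fa")
  pB <- file.path(dir, "haplotypeB.fa")
  Biostrings::writeXStringSet(genome@haplotypeA, pA)
  Biostrings::writeXStringSet(genome@haplotypeB, pB)
  bed <- file.path(dir, "annotation.bed")
  writeAnnotationBed(annotation(genome), bed)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(adjacencies = truthAdjacencies(genome),
                            copy_number = as.list(truthCopyNumber(genome))),
                       truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pA, pB, bed, truth))
}

#' Read/write gene annotation as BED6+2
#'
#' Columns: chrom, 0-based start, end, gene_id, score 0, strand, role.
#' Coordinates are converted to/from the package's 1-based inclusive
#' convention.
#'
#' @param ann A [GenomicRanges::GRanges] with `gene_id` and `role`.
#' @param path file path.
#' @return `readAnnotationBed` returns a [GenomicRanges::GRanges].
#' @export
writeAnnotationBed <- function(ann, path) {
  df <- data.frame(chrom = as.character(seqnames(ann)),
                   start0 = start(ann) - 1L, end = end(ann),
                   name = ann$gene_id, score = 0L,
                   strand = as.character(strand(ann)),
                   role = ann$role)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotationBed
#' @export
readAnnotationBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start0", "end", "name",
                                 "score", "strand", "role"),
                   stringsAsFactors = FALSE)
  GRanges(df$chrom, IRanges(df$start0 + 1L, df$end), strand = df$strand,
          gene_id = df$name, role = df$role)
}

#' Write paired FASTQ files
#'
#' Base qualities are emitted as constant Q30 (`?`); quality is unused
#' downstream.
#'
#' @param reads list with `r1` and `r2` as returned by [simulateReads()].
#' @param prefix path prefix; files `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @return Invisibly, the two file paths.
#' @export
writeFastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (i in 1:2) {
    x <- reads[[c("r1", "r2")[i]]]
    q <- Biostrings::BStringSet(strrep("?", Biostrings::width(x)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq", qualities = q)
  }
  invisible(paths)
}
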