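#' Build a k-mer seed index over a reference
#'
#' Every k-mer of the reference is retained with all of its positions
#' (ambiguous k-mers are kept with every hit); windows containing non-ACGT
#' characters are masked. A second, shorter seed table (`ksplit`) is kept for
#' breakpoint hunting so that segments near the minimum split length can
#' still anchor a seed.
#'
#' @param ref [Biostrings::DNAStringSet] (or named character) of chromosome
#'   sequences.
#' @param k seed length for full-length placement (default 21).
#' @param ksplit seed length used during split mapping (default 15).
#' @return A [KmerIndex-class].
#' @export
indexReference <- function(ref, k = 21, ksplit = 15) {
  if (is.character(ref)) ref <- Biostrings::DNAStringSet(ref)
  stopifnot(is(ref, "DNAStringSet"), !is.null(names(ref)))
  if (ksplit > k) stop("ksplit must not exceed k")
  ptr <- cpp_index_build(names(ref), as.character(ref), as.integer(k),
                         as.integer(ksplit))
  new("KmerIndex", ptr = ptr, k = k, ksplit = ksplit,
      seqnames = names(ref),
      seqlengths = setNames(Biostrings::width(ref), names(ref)),
      ref = ref)
}

#' Exact k-mer lookup
#'
#' @param index A [KmerIndex-class].
#' @param kmer character(1) of length `k`.
#' @return data.frame `chrom`, `pos` (1-based start of each occurrence);
#'   zero rows when the k-mer is absent or contains non-ACGT characters.
#' @export
queryKmer <- function(index, kmer) {
  stopifnot(is(index, "KmerIndex"))
  m <- cpp_index_query(index@ptr, as.character(kmer))
  data.frame(chrom = index@seqnames[m[, 1]], pos = m[, 2],
             stringsAsFactors = FALSE)
}

#' Fragment-length model defining "discordant"
#'
#' @param mean,sd fragment length mean and standard deviation in bp.
#' @param maxConcordant span bound for a proper pair; defaults to
#'   `mean + 3 * sd`.
#' @return list with class `InsertModel`.
#' @export
insertModel <- function(mean = 350, sd = 50, maxConcordant = mean + 3 * sd) {
  structure(list(mean = mean, sd = sd, maxConcordant = maxConcordant),
            class = "InsertModel")
}

#' Map reads against an indexed reference
#'
#' Ungapped seed-and-extend placement: the unique best-scoring (fewest
#' mismatches, at most `maxMismatchFrac * length`) full-length placement is
#' reported; equal-score ties are flagged `ambiguous` and carry no
#' coordinates. Reads without a full-length placement are split-mapped: the
#' breakpoint partition maximizing total matched bases with both parts of at
#' least `minSegment` bases is sought, the two parts mapped independently
#' (possibly to different chromosomes and strands). Split placements report
#' the junction they span, canonicalized across microhomology with
#' [canonicalizeAdjacency()].
#'
#' @param index A [KmerIndex-class].
#' @param reads named [Biostrings::DNAStringSet] (or character vector).
#' @param maxMismatchFrac maximum mismatch fraction per placement
#'   (default 0.05).
#' @param minSegment minimum split-segment length in bp (default 20).
#' @param trySplit attempt split mapping for reads that fail full-length
#'   placement.
#' @return data.frame, one row per read: `read_id`, `chrom`, `pos` (1-based
#'   leftmost), `strand`, `len`, `nm` (mismatches), `mapqClass`
#'   (`unique`/`ambiguous`/`unmapped`), `split`, and for split placements the
#'   second segment (`chrom2`, `pos2`, `strand2`, `b` = breakpoint offset in
#'   the read) plus the spanned junction
#'   (`jchrom1,jpos1,jorient1,jchrom2,jpos2,jorient2`).
#' @export
mapReads <- function(index, reads, maxMismatchFrac = 0.05, minSegment = 20,
                     trySplit = TRUE) {
  stopifnot(is(index, "KmerIndex"))
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  ids <- names(reads) %||% sprintf("r%06d", seq_along(reads))
  if (length(reads) && min(Biostrings::width(reads)) < 2 * index@k)
    warning("reads shorter than 2k cannot anchor two full-length seeds")
  res <- cpp_map_reads(index@ptr, as.character(reads), maxMismatchFrac,
                       as.integer(minSegment), trySplit)
  df <- data.frame(read_id = ids,
                   chrom = index@seqnames[res$chrom],
                   pos = res$pos, strand = res$strand,
                   len = Biostrings::width(reads),
                   nm = res$nm, mapqClass = res$status, split = res$split,
                   chrom2 = index@seqnames[res$chrom2], pos2 = res$pos2,
                   strand2 = res$strand2, b = res$b,
                   jchrom1 = index@seqnames[res$jchrom1], jpos1 = res$jpos1,
                   jorient1 = res$jorient1,
                   jchrom2 = index@seqnames[res$jchrom2], jpos2 = res$jpos2,
                   jorient2 = res$jorient2,
                   stringsAsFactors = FALSE)
  ## canonicalize split junctions so all observations of one junction agree
  sp <- which(df$split)
  if (length(sp)) {
    refChar <- setNames(as.character(index@ref), names(index@ref))
    for (i in sp) {
      can <- canonicalizeAdjacency(df$jchrom1[i], df$jpos1[i], df$jorient1[i],
                                   df$jchrom2[i], df$jpos2[i], df$jorient2[i],
                                   refChar)
      df[i, c("jchrom1", "jpos1", "jorient1",
              "jchrom2", "jpos2", "jorient2")] <- can[1, 1:6]
    }
  }
  df
}

#' Classify mate pairs as proper or discordant
#'
#' A template is a proper pair when both mates map to the same chromosome in
#' forward-reverse orientation with a span of at most
#' `im$maxConcordant`; otherwise it is discordant with subtype
#' `inter_chrom`, `orientation` or `distance`. Templates with a split-mapped
#' mate are flagged `split`; templates with an unmapped or ambiguous mate are
#' `unpaired`.
#'
#' @param a1,a2 alignment data.frames from [mapReads()] for the two mates,
#'   in identical template order (matching `read_id`).
#' @param im an [insertModel()].
#' @return data.frame with one row per template: the two mates' placements
#'   (suffixes `.1`, `.2`) and `pairClass`.
#' @export
classifyPairs <- function(a1, a2, im = insertModel()) {
  if (!identical(a1$read_id, a2$read_id))
    stop("mate alignment tables must carry identical read_ids in order")
  mapped <- function(a) a$mapqClass != "unmapped" & !a$split
  m1 <- mapped(a1); m2 <- mapped(a2)
  cls <- rep("unpaired", nrow(a1))
  anySplit <- a1$split | a2$split
  cls[anySplit] <- "split"
  both <- m1 & m2 & !anySplit
  same <- both & a1$chrom == a2$chrom
  opp <- same & a1$strand != a2$strand
  ## forward-reverse: the + mate must start at or left of the - mate's end
  plusFirst <- rep(FALSE, nrow(a1))
  pi1 <- which(opp)
  if (length(pi1)) {
    p1 <- ifelse(a1$strand[pi1] == "+", a1$pos[pi1], a2$pos[pi1])
    pEndMinus <- ifelse(a1$strand[pi1] == "-", a1$pos[pi1] + a1$len[pi1] - 1,
                        a2$pos[pi1] + a2$len[pi1] - 1)
    plusFirst[pi1] <- p1 <= pEndMinus
  }
  span <- pmax(a1$pos + a1$len - 1, a2$pos + a2$len - 1) - pmin(a1$pos, a2$pos) + 1
  proper <- opp & plusFirst & !is.na(span) & span <= im$maxConcordant
  cls[both & !same] <- "discordant_inter_chrom"
  cls[same & !opp] <- "discordant_orientation"
  cls[opp & !proper] <- "discordant_distance"
  cls[proper] <- "proper"
  out <- cbind(setNames(a1, paste0(names(a1), ".1")),
               setNames(a2, paste0(names(a2), ".2")))
  out$read_id <- a1$read_id
  out$pairClass <- cls
  out
}

samFlag <- function(mateFirst, strand, mateStrand, mapped, mateMapped, proper) {
  f <- 1L +
    ifelse(proper, 2L, 0L) +
    ifelse(!mapped, 4L, 0L) +
    ifelse(!mateMapped, 8L, 0L) +
    ifelse(mapped & !is.na(strand) & strand == "-", 16L, 0L) +
    ifelse(mateMapped & !is.na(mateStrand) & mateStrand == "-", 32L, 0L) +
    ifelse(mateFirst, 64L, 128L)
  f
}

#' Write classified pairs as SAM
#'
#' Emits a minimal valid SAM 1.6 file: header `@HD`/`@SQ` lines and one
#' record per mate with flags, `POS`/`CIGAR` (`M`/`S` operations for split
#' placements), mate fields and tags `NM:i` (mismatches), `XS:Z` (mapq
#' class), and for split placements `SA:Z` (second segment) and `XJ:Z`
#' (machine-format junction).
#'
#' @param pairs data.frame from [classifyPairs()].
#' @param reads list with `r1`, `r2` read sequences (as simulated).
#' @param path output path.
#' @param seqlengths named integer chromosome lengths for the header.
#' @return Invisibly, `path`.
#' @export
writeSam <- function(pairs, reads, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  recLines <- function(a, mate, mateA, first, seqs) {
    ## ambiguous placements carry no coordinates; write them unmapped-style
    ## (their XS tag preserves the class)
    mapped <- a$mapqClass != "unmapped" & !is.na(a$chrom)
    mateMapped <- mateA$mapqClass != "unmapped" & !is.na(mateA$chrom)
    proper <- pairs$pairClass == "proper"
    flag <- samFlag(first, a$strand, mateA$strand, mapped, mateMapped, proper)
    rname <- ifelse(mapped, a$chrom, "*")
    pos <- ifelse(mapped, a$pos, 0L)
    mapq <- ifelse(a$mapqClass == "unique", 60L, 0L)
    cigar <- ifelse(!mapped, "*",
             ifelse(a$split,
                    ifelse(a$strand == "-",
                           paste0(a$len - a$b, "S", a$b, "M"),
                           paste0(a$b, "M", a$len - a$b, "S")),
                    paste0(a$len, "M")))
    rnext <- ifelse(mateMapped, mateA$chrom, "*")
    pnext <- ifelse(mateMapped, mateA$pos, 0L)
    seqOut <- as.character(seqs)
    rc <- mapped & !is.na(a$strand) & a$strand == "-"
    if (any(rc)) seqOut[rc] <- as.character(
      reverseComplement(Biostrings::DNAStringSet(seqOut[rc])))
    qual <- strrep("?", a$len)
    tags <- paste0("XS:Z:", a$mapqClass,
                   ifelse(mapped & !is.na(a$nm), paste0("\tNM:i:", a$nm), ""))
    isSplit <- a$split
    if (any(isSplit)) {
      sa <- paste0("\tSA:Z:", a$chrom2[isSplit], ",", a$pos2[isSplit], ",",
                   a$strand2[isSplit], ",",
                   paste0(a$b[isSplit], "S", a$len[isSplit] - a$b[isSplit], "M"),
                   ",60,0;")
      xj <- paste0("\tXJ:Z:",
                   formatAdjacency(data.frame(
                     chrom1 = a$jchrom1[isSplit], pos1 = a$jpos1[isSplit],
                     orient1 = a$jorient1[isSplit], chrom2 = a$jchrom2[isSplit],
                     pos2 = a$jpos2[isSplit], orient2 = a$jorient2[isSplit]),
                     pretty = FALSE))
      tags[isSplit] <- paste0(tags[isSplit], sa, xj)
    }
    paste(a$read_id, flag, rname, pos, mapq, cigar, rnext, pnext, 0L,
          seqOut, qual, tags, sep = "\t")
  }
  a1 <- pairs[, grep("\\.1$", names(pairs))]
  a2 <- pairs[, grep("\\.2$", names(pairs))]
  names(a1) <- sub("\\.1$", "", names(a1))
  names(a2) <- sub("\\.2$", "", names(a2))
  l1 <- recLines(a1, 1, a2, TRUE, reads$r1)
  l2 <- recLines(a2, 2, a1, FALSE, reads$r2)
  writeLines(c(hdr, as.vector(rbind(l1, l2))), path)
  invisible(path)
}

#' Parse a SAM file into alignment records
#'
#' Understands plain SAM 1.6 with `M`/`S`/`H` CIGAR operations; records
#' written by [writeSam()] round-trip exactly (mapq class, mismatch count and
#' split junction are recovered from the `XS`/`NM`/`SA`/`XJ` tags; for
#' foreign SAM the mapq class falls back to `MAPQ > 0`).
#'
#' @param path SAM file path.
#' @return data.frame of records in file order with the [mapReads()] columns
#'   plus `flag` and `mate` (1 or 2); attribute `seqlengths` carries the
#'   header.
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*SN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
  f <- strsplit(rec, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(getf(2))
  tagStr <- vapply(f, function(x) paste(x[-(1:11)], collapse = "\t"), character(1))
  tag <- function(name) {
    pat <- paste0("(^|\t)", name, ":[AZif]:[^\t]*")
    m <- regexpr(pat, tagStr)
    out <- rep(NA_character_, length(tagStr))
    hit <- m > 0
    out[hit] <- sub(paste0("^\t?", name, ":[AZif]:"), "", regmatches(tagStr, m))
    out
  }
  unmapped <- bitwAnd(flag, 4L) > 0
  chrom <- ifelse(unmapped, NA_character_, getf(3))
  pos <- ifelse(unmapped, NA_integer_, as.integer(getf(4)))
  strand <- ifelse(unmapped, NA_character_,
                   ifelse(bitwAnd(flag, 16L) > 0, "-", "+"))
  cigar <- getf(6)
  lens <- nchar(getf(10))
  xs <- tag("XS")
  mapqClass <- ifelse(!is.na(xs), xs,
                      ifelse(unmapped, "unmapped",
                             ifelse(as.integer(getf(5)) > 0, "unique", "ambiguous")))
  nm <- suppressWarnings(as.integer(tag("NM")))
  sa <- tag("SA")
  xj <- tag("XJ")
  split <- !is.na(sa)
  matchLen <- function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]", "", toks[grepl("[M=X]$", toks)])))
  }
  b <- ifelse(split, vapply(cigar, matchLen, numeric(1)), NA_integer_)
  chrom2 <- pos2 <- strand2 <- rep(NA_character_, length(rec))
  j <- matrix(NA_character_, length(rec), 6)
  if (any(split)) {
    parts <- strsplit(sub(";$", "", sa[split]), ",", fixed = TRUE)
    chrom2[split] <- vapply(parts, `[[`, character(1), 1)
    pos2[split] <- vapply(parts, `[[`, character(1), 2)
    strand2[split] <- vapply(parts, `[[`, character(1), 3)
    jdf <- parseAdjacency(xj[split])
    j[split, ] <- as.matrix(jdf[, 1:6])
  }
  out <- data.frame(read_id = getf(1), flag = flag,
                    mate = ifelse(bitwAnd(flag, 64L) > 0, 1L, 2L),
                    chrom = chrom, pos = pos, strand = strand, len = lens,
                    nm = nm, mapqClass = mapqClass, split = split,
                    chrom2 = chrom2, pos2 = as.integer(pos2),
                    strand2 = strand2, b = as.integer(b),
                    jchrom1 = j[, 1], jpos1 = as.integer(j[, 2]),
                    jorient1 = j[, 3], jchrom2 = j[, 4],
                    jpos2 = as.integer(j[, 5]), jorient2 = j[, 6],
                    stringsAsFactors = FALSE)
  attr(out, "seqlengths") <- setNames(ln, sn)
  out
}
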