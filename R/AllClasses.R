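#' @importClassesFrom Biostrings DNAStringSet DNAString
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#' @importFrom IRanges IRanges Views
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' Diploid genome model with planted transgene truth
#'
#' Holds the two haplotypes of a toy diploid genome (haplotype A wild-type,
#' haplotype B optionally carrying a transgene cassette), the gene annotation,
#' and the simulation truth: the inter-locus adjacencies created by the
#' insertion and the per-gene copy number of the diploid genome.
#'
#' @slot haplotypeA,haplotypeB [Biostrings::DNAStringSet] of chromosome
#'   sequences, identically named; B differs from A only at the insertion.
#' @slot annotation [GenomicRanges::GRanges] with metadata columns `gene_id`
#'   and `role` (one of driver, passenger, acceptor, neutral, reference_assay).
#' @slot acceptorExons [GenomicRanges::GRanges] exon intervals of the acceptor
#'   gene (the insertion disrupts its final exon by default).
#' @slot truthAdjacencies data.frame of planted junctions with columns
#'   `chrom1,pos1,orient1,chrom2,pos2,orient2,derivedPos`.
#' @slot truthCopyNumber named numeric, copies per diploid genome per gene.
#' @slot insertionBlocks data.frame describing the derived chromosome as a
#'   sequence of source blocks (internal bookkeeping for truth enumeration).
#' @slot params list of layout parameters (donor interval, default site, ...).
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(
    haplotypeA = "DNAStringSet",
    haplotypeB = "DNAStringSet",
    annotation = "GRanges",
    acceptorExons = "GRanges",
    truthAdjacencies = "data.frame",
    truthCopyNumber = "numeric",
    insertionBlocks = "data.frame",
    params = "list"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character(0)
  if (!identical(names(object@haplotypeA), names(object@haplotypeB)))
    msg <- c(msg, "haplotypes must have identical chromosome names")
  ann <- object@annotation
  if (length(ann)) {
    if (!all(c("gene_id", "role") %in% colnames(mcols(ann))))
      msg <- c(msg, "annotation needs gene_id and role metadata columns")
    if (!all(as.character(seqnames(ann)) %in% names(object@haplotypeA)))
      msg <- c(msg, "annotation names a chromosome absent from the genome")
    hits <- findOverlaps(ann, ann)
    if (any(queryHits(hits) != subjectHits(hits)))
      msg <- c(msg, "gene intervals on one chromosome may not overlap")
    if (anyDuplicated(mcols(ann)$gene_id))
      msg <- c(msg, "gene_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' BAC-style transgene construct
#'
#' Describes the donor fragment and its promoter swap: a donor interval
#' covering the driver and passenger genes, with the first
#' `replacedPrefixBp` bases of the driver gene replaced by a synthetic
#' recombinase marker sequence absent from the reference. Optionally the
#' cassette is rearranged (retained acceptor fragment + inverted donor tail)
#' to emulate a multi-junction integration.
#'
#' @slot donorChrom character(1), donor chromosome name.
#' @slot donorStart,donorEnd 1-based inclusive extent of the donor fragment.
#' @slot driverGene gene_id of the promoter-swapped driver gene.
#' @slot replacedPrefixBp integer, bases of the driver gene replaced.
#' @slot insertSequence [Biostrings::DNAString] marker coding sequence.
#' @slot tandemCopies integer >= 1, tandem cassette copies.
#' @slot rearranged logical; if TRUE the cassette carries a retained acceptor
#'   fragment followed by the reverse-complemented donor tail, producing three
#'   inter-chromosomal junctions (one +/+).
#' @slot retainBp integer, length of the retained acceptor fragment.
#' @exportClass TransgeneConstruct
setClass("TransgeneConstruct",
  representation(
    donorChrom = "character",
    donorStart = "numeric",
    donorEnd = "numeric",
    driverGene = "character",
    replacedPrefixBp = "numeric",
    insertSequence = "DNAString",
    tandemCopies = "numeric",
    rearranged = "logical",
    retainBp = "numeric"
  )
)

setValidity("TransgeneConstruct", function(object) {
  msg <- character(0)
  if (object@donorStart > object@donorEnd)
    msg <- c(msg, "donorStart must be <= donorEnd")
  if (object@replacedPrefixBp <= 0)
    msg <- c(msg, "replacedPrefixBp must be > 0")
  if (length(object@insertSequence) == 0)
    msg <- c(msg, "insertSequence must be non-empty")
  if (object@tandemCopies < 1)
    msg <- c(msg, "tandemCopies must be >= 1")
  if (object@rearranged && object@retainBp < 1)
    msg <- c(msg, "retainBp must be >= 1 when rearranged")
  if (length(msg)) msg else TRUE
})

#' Paired-end simulation settings
#'
#' @slot readLength read length in bp (>= 50).
#' @slot meanDepth target fold-coverage of the haploid genome.
#' @slot insertMean,insertSd fragment-length distribution in bp
#'   (insertMean > 2 * readLength).
#' @slot errorRate iid substitution probability per base (0 <= e < 0.05).
#' @slot seed integer RNG seed.
#' @slot haplotypeMix fraction of templates drawn from haplotype B
#'   (0.5 emulates a hemizygous carrier).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    readLength = "numeric", meanDepth = "numeric",
    insertMean = "numeric", insertSd = "numeric",
    errorRate = "numeric", seed = "numeric", haplotypeMix = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@readLength < 50) msg <- c(msg, "readLength must be >= 50")
  if (object@insertMean <= 2 * object@readLength)
    msg <- c(msg, "insertMean must exceed 2 * readLength")
  if (object@errorRate < 0 || object@errorRate >= 0.05)
    msg <- c(msg, "errorRate must be in [0, 0.05)")
  if (object@haplotypeMix < 0 || object@haplotypeMix > 1)
    msg <- c(msg, "haplotypeMix must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct simulation settings
#'
#' @param readLength,meanDepth,insertMean,insertSd,errorRate,seed,haplotypeMix
#'   see the [SimConfig-class] slots. Defaults emulate the study design at
#'   desk scale: 100 bp forward-reverse pairs at 40x over the toy genome,
#'   350 +/- 50 bp fragments, 0.2% substitution error, hemizygous 50:50
#'   haplotype sampling.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(readLength = 100, meanDepth = 40, insertMean = 350,
                      insertSd = 50, errorRate = 0.002, seed = 1,
                      haplotypeMix = 0.5) {
  new("SimConfig",
    readLength = readLength, meanDepth = meanDepth,
    insertMean = insertMean, insertSd = insertSd,
    errorRate = errorRate, seed = seed, haplotypeMix = haplotypeMix)
}

#' K-mer index over a reference
#'
#' Exact-match seed index used by the mapper: every k-mer of the reference is
#' retained with all of its positions (ambiguous k-mers included); windows
#' containing non-ACGT characters are masked from the index.
#'
#' @slot ptr external pointer to the compiled index.
#' @slot k seed length for full-length placement.
#' @slot ksplit shorter seed length used during split mapping.
#' @slot seqnames chromosome names, in index order.
#' @slot seqlengths named integer chromosome lengths.
#' @slot ref the indexed reference, kept for breakpoint canonicalization.
#' @exportClass KmerIndex
setClass("KmerIndex",
  representation(
    ptr = "externalptr", k = "numeric", ksplit = "numeric",
    seqnames = "character", seqlengths = "integer", ref = "DNAStringSet"
  )
)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel with", length(object@haplotypeA), "chromosome(s):",
      paste0(names(object@haplotypeA), " (", Biostrings::width(object@haplotypeA), " bp)",
             collapse = ", "), "\n")
  cat(" ", length(object@annotation), "annotated genes;",
      nrow(object@truthAdjacencies), "planted adjacencies\n")
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex (k =", object@k, ", split seed k =", object@ksplit, ") over",
      length(object@seqnames), "sequence(s),",
      sum(object@seqlengths), "bp total\n")
})

#' Accessors for GenomeModel
#'
#' @param x A [GenomeModel-class].
#' @param which `"A"` (wild-type) or `"B"` (transgenic) haplotype.
#' @return `haplotype()` a [Biostrings::DNAStringSet]; `annotation()` a
#'   [GenomicRanges::GRanges]; `truthAdjacencies()` a data.frame;
#'   `truthCopyNumber()` a named numeric vector.
#' @export
haplotype <- function(x, which = c("A", "B")) {
  stopifnot(is(x, "GenomeModel"))
  if (match.arg(which) == "A") x@haplotypeA else x@haplotypeB
}

#' @rdname haplotype
#' @export
annotation <- function(x) {
  stopifnot(is(x, "GenomeModel"))
  x@annotation
}

#' @rdname haplotype
#' @export
truthAdjacencies <- function(x) {
  stopifnot(is(x, "GenomeModel"))
  x@truthAdjacencies
}

#' @rdname haplotype
#' @export
truthCopyNumber <- function(x) {
  stopifnot(is(x, "GenomeModel"))
  x@truthCopyNumber
}
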