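#' Count reads per gene
#'
#' Read summarization over a gene annotation: a uniquely mapped, full-length
#' read is assigned to a gene when its placement overlaps the gene interval
#' by at least one base; reads overlapping two or more genes are left
#' unassigned, and mates are counted separately (read-level counting, the
#' coverage semantics of a genomic-DNA browser track).
#'
#' @param aln alignment data.frame ([mapReads()] rows, or the per-mate rows
#'   of [readSam()]); only `mapqClass == "unique"` non-split records are
#'   used. Several tables (e.g. both mates) can be supplied in a list.
#' @param ann [GenomicRanges::GRanges] gene annotation with `gene_id`.
#' @param seqnames chromosome names considered present in the alignment
#'   header; annotation chromosomes absent from it raise an error.
#' @return data.frame `gene_id`, `length_bp`, `count`, with attribute
#'   `n_reads_assigned`.
#' @export
countReadsPerGene <- function(aln, ann, seqnames = NULL) {
  if (is.data.frame(aln)) aln <- list(aln)
  a <- do.call(rbind, lapply(aln, function(x)
    x[x$mapqClass == "unique" & !x$split,
      c("chrom", "pos", "len"), drop = FALSE]))
  if (!is.null(seqnames)) {
    missing <- setdiff(as.character(seqnames(ann)), seqnames)
    if (length(missing))
      stop("annotation chromosome(s) absent from alignment header: ",
           paste(missing, collapse = ", "))
  }
  reads <- GRanges(a$chrom, IRanges(a$pos, a$pos + a$len - 1))
  hits <- findOverlaps(reads, ann, minoverlap = 1L)
  nGenes <- tabulate(queryHits(hits), nbins = length(reads))
  keep <- nGenes[queryHits(hits)] == 1
  counts <- tabulate(subjectHits(hits)[keep], nbins = length(ann))
  out <- data.frame(gene_id = ann$gene_id,
                    length_bp = end(ann) - start(ann) + 1L,
                    count = counts, stringsAsFactors = FALSE)
  attr(out, "n_reads_assigned") <- sum(keep)
  out
}

#' Length-normalized coverage (TPM on genomic reads)
#'
#' Applies the transcripts-per-million transform to genomic DNA read counts
#' as a length-normalized coverage measure: `rate = count / (length/1e3)`,
#' `tpm = rate / sum(rate) * 1e6`. The TPM column sums to 1e6 and is
#' invariant to uniform count scaling.
#'
#' @param counts data.frame from [countReadsPerGene()] (columns `gene_id`,
#'   `length_bp`, `count`).
#' @return The input with a `tpm` column and attribute `genome_average_tpm`
#'   (mean per-gene TPM).
#' @export
tpmNormalize <- function(counts) {
  if (any(counts$length_bp <= 0)) stop("gene lengths must be positive")
  if (all(counts$count == 0))
    stop("all counts are zero; TPM normalization is undefined")
  rate <- counts$count / (counts$length_bp / 1e3)
  counts$tpm <- rate / sum(rate) * 1e6
  attr(counts, "genome_average_tpm") <- mean(counts$tpm)
  counts
}

#' Copy number from read coverage
#'
#' A gene's copies per diploid genome are estimated as
#' `baselineCopies * tpm / baseline`, where the baseline is a trimmed mean
#' of per-gene TPM (default 10% two-sided). Trimming keeps
#' transgene-amplified genes from inflating the genome-average baseline in a
#' compact gene set.
#'
#' @param counts TPM table from [tpmNormalize()].
#' @param geneId gene(s) to estimate; default all.
#' @param baselineCopies copies of a baseline gene (2 for autosomal diploid).
#' @param trim two-sided trim fraction for the baseline mean.
#' @return data.frame `gene_id`, `tpm`, `estimated_copies`,
#'   `baseline_copies`.
#' @export
estimateCopiesFromCoverage <- function(counts, geneId = counts$gene_id,
                                       baselineCopies = 2, trim = 0.10) {
  if (is.null(counts$tpm)) stop("run tpmNormalize() first")
  if (nrow(counts) < 10)
    stop("need at least 10 genes for a stable genome-average baseline")
  if (!all(geneId %in% counts$gene_id))
    stop("gene(s) not in count table: ",
         paste(setdiff(geneId, counts$gene_id), collapse = ", "))
  baseline <- mean(counts$tpm, trim = trim)
  i <- match(geneId, counts$gene_id)
  data.frame(gene_id = geneId, tpm = counts$tpm[i],
             estimated_copies = baselineCopies * counts$tpm[i] / baseline,
             baseline_copies = baselineCopies, stringsAsFactors = FALSE)
}

#' Droplet digital PCR target concentration
#'
#' Inverts the Poisson partition model: with `P` positive of `N` droplets,
#' the mean occupancy is `lambda = -ln(1 - P/N)` and the concentration is
#' `lambda / dropletVolume` in copies per microliter.
#'
#' @param P positive droplets (0 <= P < N; saturated wells are rejected).
#' @param N total droplets (> 0).
#' @param dropletVolumeNl droplet volume in nanoliters (instrument-nominal
#'   default 0.85 nL).
#' @return Concentration in copies/uL (vectorized).
#' @export
ddpcrConcentration <- function(P, N, dropletVolumeNl = 0.85) {
  if (any(N <= 0)) stop("total droplet count must be positive")
  if (any(P < 0) || any(P > N)) stop("positive droplets must satisfy 0 <= P <= N")
  if (any(P == N)) stop("saturated well (P = N): concentration is unbounded")
  lambda <- -log(1 - P / N)
  lambda / (dropletVolumeNl * 1e-3)
}

#' Pool replicate ddPCR wells
#'
#' Replicate wells of one target are merged by pooling positive and total
#' droplet counts before the Poisson inversion (the minimum-variance merge).
#'
#' @param wells data.frame with columns `target`, `P`, `N` (and optionally
#'   `droplet_volume_nl`).
#' @return data.frame with one row per target and summed `P`, `N`.
#' @export
poolWells <- function(wells) {
  agg <- aggregate(cbind(P, N) ~ target, data = wells, FUN = sum)
  if (!is.null(wells$droplet_volume_nl)) {
    v <- tapply(wells$droplet_volume_nl, wells$target, unique)
    if (any(lengths(v) != 1)) stop("droplet volume differs between replicate wells")
    agg$droplet_volume_nl <- as.numeric(v[agg$target])
  }
  agg
}

#' Copies per genome from ddPCR
#'
#' Normalizes a target's droplet concentration to a reference assay of known
#' copy number (a two-copy gene by default):
#' `copies = referenceCopies * conc(target) / conc(reference)`.
#'
#' @param targetP,targetN positive/total droplets of the target well(s).
#' @param refP,refN positive/total droplets of the reference well(s).
#' @param referenceCopies copies of the reference gene per diploid genome.
#' @param dropletVolumeNl shared droplet volume in nL.
#' @return Estimated copies per genome (numeric).
#' @export
copiesPerGenome <- function(targetP, targetN, refP, refN,
                            referenceCopies = 2, dropletVolumeNl = 0.85) {
  ct <- ddpcrConcentration(sum(targetP), sum(targetN), dropletVolumeNl)
  cr <- ddpcrConcentration(sum(refP), sum(refN), dropletVolumeNl)
  if (cr == 0) stop("reference concentration is zero; cannot normalize")
  referenceCopies * ct / cr
}

#' @importFrom stats aggregate
NULL
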