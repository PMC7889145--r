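#' Configuration for an end-to-end discovery run
#'
#' Bundles the genome, construct, simulation and calling parameters with a
#' single seed that drives every stochastic stage.
#'
#' @param seed integer; used for the genome sequence and read simulation.
#' @param chromLengths chromosome lengths for [buildReference()].
#' @param tandemCopies,rearranged construct options ([transgeneConstruct()]).
#' @param haplotypeMix,meanDepth,readLength,insertMean,insertSd,errorRate
#'   simulation settings ([simConfig()]).
#' @param minSupport adjacency call threshold ([callAdjacencies()]).
#' @param k,ksplit,maxMismatchFrac,minSegment mapper settings.
#' @param roi region of interest for [screenRegion()]; default the whole
#'   donor chromosome.
#' @param outDir optional output directory; when set, FASTA/FASTQ/SAM/TSV/
#'   JSON intermediates and the report are written there.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1,
                      chromLengths = c(chrA = 2e5, chrD = 2e5),
                      tandemCopies = 1, rearranged = TRUE,
                      haplotypeMix = 0.5, meanDepth = 40, readLength = 100,
                      insertMean = 350, insertSd = 50, errorRate = 0.002,
                      minSupport = 4, k = 21, ksplit = 15,
                      maxMismatchFrac = 0.05, minSegment = 20,
                      roi = NULL, outDir = NULL) {
  structure(list(seed = seed, chromLengths = chromLengths,
                 tandemCopies = tandemCopies, rearranged = rearranged,
                 haplotypeMix = haplotypeMix, meanDepth = meanDepth,
                 readLength = readLength, insertMean = insertMean,
                 insertSd = insertSd, errorRate = errorRate,
                 minSupport = minSupport, k = k, ksplit = ksplit,
                 maxMismatchFrac = maxMismatchFrac, minSegment = minSegment,
                 roi = roi, outDir = outDir),
            class = "RunConfig")
}

#' Run the full in-silico discovery workflow
#'
#' simulate -> map -> classify -> extract evidence -> cluster -> call ->
#' screen -> copy number, with truth-versus-called comparison. Rerunning
#' with the same configuration reproduces the report exactly.
#'
#' @param config a [runConfig()].
#' @return list of class `RunReport`: `calls` (post-screen adjacency calls
#'   with notation), `allCalls` (pre-screen), `truth` (planted adjacencies),
#'   `comparison` (per truth junction: called position error and support),
#'   `copy` (per-gene coverage copy estimates vs truth), `params`, and
#'   `files` (paths written, when `outDir` is set).
#' @export
runAll <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genome <- stage("reference", buildReference(seed = config$seed,
                                              chromLengths = config$chromLengths))
  construct <- stage("construct",
                     transgeneConstruct(genome,
                                        tandemCopies = config$tandemCopies,
                                        rearranged = config$rearranged))
  genome <- stage("insertion", applyInsertion(genome, construct))
  sim <- simConfig(readLength = config$readLength,
                   meanDepth = config$meanDepth,
                   insertMean = config$insertMean, insertSd = config$insertSd,
                   errorRate = config$errorRate, seed = config$seed,
                   haplotypeMix = config$haplotypeMix)
  reads <- stage("simulate", simulateReads(genome, sim))
  idx <- stage("index", indexReference(haplotype(genome, "A"),
                                       k = config$k, ksplit = config$ksplit))
  a1 <- stage("map", mapReads(idx, reads$r1, config$maxMismatchFrac,
                              config$minSegment))
  a2 <- stage("map", mapReads(idx, reads$r2, config$maxMismatchFrac,
                              config$minSegment))
  im <- insertModel(config$insertMean, config$insertSd)
  pairs <- stage("classify", classifyPairs(a1, a2, im))
  obs <- stage("evidence", extractEvidence(pairs, im))
  clusters <- stage("cluster", clusterEvidence(obs, im$maxConcordant))
  allCalls <- stage("call", callAdjacencies(clusters, config$minSupport))
  roi <- config$roi %||% list(chrom = genome@params$donorChrom, start = 1,
                              end = unname(config$chromLengths[genome@params$donorChrom]))
  calls <- stage("screen", screenRegion(allCalls, roi$chrom, roi$start, roi$end))
  counts <- stage("count", countReadsPerGene(list(a1, a2), annotation(genome),
                                             seqnames = idx@seqnames))
  tpm <- stage("tpm", tpmNormalize(counts))
  copy <- stage("copynum", estimateCopiesFromCoverage(tpm))
  copy$truth_copies <- truthCopyNumber(genome)[copy$gene_id]
  copy$role <- annotation(genome)$role[match(copy$gene_id, annotation(genome)$gene_id)]

  truth <- truthAdjacencies(genome)
  comparison <- compareToTruth(truth, calls)

  files <- character(0)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    files <- writeGenomeFiles(genome, config$outDir)
    files <- c(files, writeFastq(reads, file.path(config$outDir, "reads")))
    samPath <- file.path(config$outDir, "alignments.sam")
    writeSam(pairs, reads, samPath, idx@seqlengths)
    callsPath <- file.path(config$outDir, "adjacency_calls.tsv")
    write.table(calls, callsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    copyPath <- file.path(config$outDir, "copy_estimates.tsv")
    write.table(copy, copyPath, sep = "\t", quote = FALSE, row.names = FALSE)
    reportPath <- file.path(config$outDir, "report.json")
    jsonlite::write_json(list(params = unclass(config)[setdiff(names(config), "outDir")],
                              calls = calls, comparison = comparison,
                              copy = copy),
                         reportPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, samPath, callsPath, copyPath, reportPath)
  }

  structure(list(calls = calls, allCalls = allCalls, truth = truth,
                 comparison = comparison, copy = copy,
                 params = unclass(config), files = files),
            class = "RunReport")
}

compareToTruth <- function(truth, calls) {
  if (!nrow(truth)) return(data.frame())
  res <- lapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    cand <- calls[calls$chrom1 == t$chrom1 & calls$chrom2 == t$chrom2 &
                  calls$orient1 == t$orient1 & calls$orient2 == t$orient2, ]
    if (!nrow(cand)) {
      return(data.frame(notation = formatAdjacency(t), recovered = FALSE,
                        err1 = NA_integer_, err2 = NA_integer_,
                        split = 0L, pairs = 0L))
    }
    d <- abs(cand$pos1 - t$pos1) + abs(cand$pos2 - t$pos2)
    j <- which.min(d)
    data.frame(notation = formatAdjacency(t), recovered = TRUE,
               err1 = cand$pos1[j] - t$pos1, err2 = cand$pos2[j] - t$pos2,
               split = cand$split[j], pairs = cand$pairs[j])
  })
  do.call(rbind, res)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Transgene-locus discovery run (seed ", x$params$seed, ")\n", sep = "")
  cat("  adjacency calls after screening:", nrow(x$calls), "\n")
  if (nrow(x$calls)) {
    for (s in x$calls$notation)
      cat("    ", s, "\n", sep = "")
  }
  if (nrow(x$comparison)) {
    cat("  truth junctions recovered: ", sum(x$comparison$recovered), "/",
        nrow(x$comparison), "\n", sep = "")
  }
  elev <- x$copy[x$copy$role %in% c("passenger", "driver"), ]
  if (nrow(elev)) {
    cat("  copy estimates (passenger/driver):\n")
    for (i in seq_len(nrow(elev)))
      cat(sprintf("    %-6s %.2f (truth %d)\n", elev$gene_id[i],
                  elev$estimated_copies[i], elev$truth_copies[i]))
  }
  invisible(x)
}
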