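#' Extract junction observations from classified pairs
#'
#' Split reads yield base-exact junction observations (already canonicalized
#' by [mapReads()]); discordant mate pairs yield interval observations: the
#' breakpoint must lie within the fragment-length bound of each mate's inner
#' edge, on the side the mate's strand points to. A mate on the forward
#' strand flanks the junction from the left, so its junction side has
#' orientation `-`; a reverse-strand mate gives `+`. Records with ambiguous
#' mapq are excluded.
#'
#' @param pairs data.frame from [classifyPairs()].
#' @param im an [insertModel()].
#' @return data.frame of observations: side coordinates (`chrom1`, `pos1`,
#'   `lo1`, `hi1`, `orient1`, and the same for side 2, canonically ordered),
#'   `type` (`split`/`pair`) and `read_id`. Zero rows when there is no
#'   evidence.
#' @export
extractEvidence <- function(pairs, im = insertModel()) {
  obs <- list()
  ## split-read observations (base-exact)
  for (mate in c("1", "2")) {
    sp <- pairs[pairs[[paste0("split.", mate)]] %in% TRUE &
                pairs[[paste0("mapqClass.", mate)]] == "unique", ]
    if (nrow(sp)) {
      g <- function(col) sp[[paste0(col, ".", mate)]]
      obs[[length(obs) + 1]] <- data.frame(
        chrom1 = g("jchrom1"), pos1 = g("jpos1"), lo1 = g("jpos1"),
        hi1 = g("jpos1"), orient1 = g("jorient1"),
        chrom2 = g("jchrom2"), pos2 = g("jpos2"), lo2 = g("jpos2"),
        hi2 = g("jpos2"), orient2 = g("jorient2"),
        type = "split", read_id = sp$read_id, stringsAsFactors = FALSE)
    }
  }
  ## discordant-pair observations (interval)
  dp <- pairs[startsWith(pairs$pairClass, "discordant") &
              pairs$mapqClass.1 == "unique" & pairs$mapqClass.2 == "unique", ]
  if (nrow(dp)) {
    side <- function(chrom, pos, strand, len) {
      inner <- ifelse(strand == "+", pos + len - 1, pos)
      lo <- ifelse(strand == "+", inner, inner - im$maxConcordant)
      hi <- ifelse(strand == "+", inner + im$maxConcordant, inner)
      data.frame(chrom = chrom, pos = inner, lo = lo, hi = hi,
                 orient = ifelse(strand == "+", "-", "+"),
                 stringsAsFactors = FALSE)
    }
    s1 <- side(dp$chrom.1, dp$pos.1, dp$strand.1, dp$len.1)
    s2 <- side(dp$chrom.2, dp$pos.2, dp$strand.2, dp$len.2)
    obs[[length(obs) + 1]] <- data.frame(
      chrom1 = s1$chrom, pos1 = s1$pos, lo1 = s1$lo, hi1 = s1$hi,
      orient1 = s1$orient,
      chrom2 = s2$chrom, pos2 = s2$pos, lo2 = s2$lo, hi2 = s2$hi,
      orient2 = s2$orient,
      type = "pair", read_id = dp$read_id, stringsAsFactors = FALSE)
  }
  if (!length(obs)) {
    return(data.frame(chrom1 = character(0), pos1 = integer(0),
                      lo1 = integer(0), hi1 = integer(0), orient1 = character(0),
                      chrom2 = character(0), pos2 = integer(0),
                      lo2 = integer(0), hi2 = integer(0), orient2 = character(0),
                      type = character(0), read_id = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, obs)
  ## canonical side ordering
  swap <- out$chrom1 > out$chrom2 |
    (out$chrom1 == out$chrom2 & out$pos1 > out$pos2)
  if (any(swap)) {
    c1 <- out[swap, c("chrom1", "pos1", "lo1", "hi1", "orient1")]
    out[swap, c("chrom1", "pos1", "lo1", "hi1", "orient1")] <-
      out[swap, c("chrom2", "pos2", "lo2", "hi2", "orient2")]
    out[swap, c("chrom2", "pos2", "lo2", "hi2", "orient2")] <- c1
  }
  rownames(out) <- NULL
  out
}

#' Cluster junction observations
#'
#' Single-linkage clustering within each (chromosome pair, orientation
#' signature) stratum: two observations are linked when both side positions
#' are within `window` bp. Observations from different orientation
#' signatures never merge, and the output is independent of input order.
#'
#' @param obs data.frame from [extractEvidence()].
#' @param window linkage distance in bp; default insert mean + 3 sd of the
#'   default [insertModel()].
#' @return list of data.frames (one per cluster), ordered by stratum and
#'   leftmost position.
#' @export
clusterEvidence <- function(obs, window = insertModel()$maxConcordant) {
  if (!nrow(obs)) return(list())
  key <- paste(obs$chrom1, obs$chrom2, obs$orient1, obs$orient2, sep = "|")
  out <- list()
  for (k in sort(unique(key))) {
    g <- obs[key == k, , drop = FALSE]
    g <- g[order(g$pos1, g$pos2, g$type, g$read_id), , drop = FALSE]
    n <- nrow(g)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(g$pos1[i] - g$pos1[j]) <= window &&
          abs(g$pos2[i] - g$pos2[j]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in sort(unique(roots)))
      out[[length(out) + 1]] <- g[roots == r, , drop = FALSE]
  }
  out
}

#' Call adjacencies from evidence clusters
#'
#' Clusters whose total support (split + pair observations) reaches
#' `minSupport` become adjacency calls. With at least one split observation
#' the call is `precise` and positioned at the lower median of the split
#' positions; otherwise it is imprecise and positioned at the midpoint of
#' the intersected pair intervals.
#'
#' @param clusters list from [clusterEvidence()].
#' @param minSupport minimum total supporting observations (default 4).
#' @return data.frame of calls: `chrom1,pos1,orient1,chrom2,pos2,orient2`,
#'   `split`, `pairs`, `precise`, and the notation string in `notation`.
#' @export
callAdjacencies <- function(clusters, minSupport = 4) {
  rows <- lapply(clusters, function(g) {
    nSplit <- sum(g$type == "split")
    nPair <- sum(g$type == "pair")
    if (nSplit + nPair < minSupport) return(NULL)
    if (nSplit > 0) {
      s <- g[g$type == "split", ]
      p1 <- as.integer(lowerMedian(s$pos1)); p2 <- as.integer(lowerMedian(s$pos2))
      precise <- TRUE
    } else {
      p1 <- as.integer(round((max(g$lo1) + min(g$hi1)) / 2))
      p2 <- as.integer(round((max(g$lo2) + min(g$hi2)) / 2))
      precise <- FALSE
    }
    data.frame(chrom1 = g$chrom1[1], pos1 = p1, orient1 = g$orient1[1],
               chrom2 = g$chrom2[1], pos2 = p2, orient2 = g$orient2[1],
               split = nSplit, pairs = nPair, precise = precise,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(chrom1 = character(0), pos1 = integer(0),
                      orient1 = character(0), chrom2 = character(0),
                      pos2 = integer(0), orient2 = character(0),
                      split = integer(0), pairs = integer(0),
                      precise = logical(0), stringsAsFactors = FALSE)
    out$notation <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out$notation <- formatAdjacency(out)
  out
}

#' Screen calls against a region of interest
#'
#' Retains calls with one side inside the region of interest (on the donor
#' chromosome) and the other side on a different chromosome — the screen
#' used to shortlist candidate transgene integration junctions.
#'
#' @param calls data.frame from [callAdjacencies()].
#' @param chrom,start,end the region of interest (1-based inclusive).
#' @return The filtered calls.
#' @export
screenRegion <- function(calls, chrom, start, end) {
  if (length(chrom) != 1 || is.na(start) || is.na(end) || start > end)
    stop("malformed region of interest")
  in1 <- calls$chrom1 == chrom & calls$pos1 >= start & calls$pos1 <= end
  in2 <- calls$chrom2 == chrom & calls$pos2 >= start & calls$pos2 <= end
  keep <- (in1 & calls$chrom2 != chrom) | (in2 & calls$chrom1 != chrom)
  calls[keep, , drop = FALSE]
}

#' Adjacency notation
#'
#' Formats an adjacency as `s1[chrom1:pos1]:s2[chrom2:pos2]`, where `s1`/`s2`
#' are the side orientations. In pretty mode positions carry comma
#' thousands-separators (e.g. `+[chr16:23,118,416]:-[chr9:87,704,340]`);
#' machine mode omits them. `parseAdjacency()` inverts either form.
#'
#' @param x data.frame with columns `chrom1,pos1,orient1,chrom2,pos2,orient2`
#'   (extra columns ignored).
#' @param pretty use thousands separators.
#' @return character vector of notation strings.
#' @export
formatAdjacency <- function(x, pretty = TRUE) {
  fmt <- function(p) if (pretty) formatC(p, big.mark = ",", format = "d") else
    format(p, scientific = FALSE, trim = TRUE)
  sprintf("%s[%s:%s]:%s[%s:%s]",
          x$orient1, x$chrom1, fmt(x$pos1),
          x$orient2, x$chrom2, fmt(x$pos2))
}

#' @rdname formatAdjacency
#' @param s character vector of notation strings (pretty or machine form;
#'   whitespace after `:` is tolerated).
#' @export
parseAdjacency <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  pat <- "^([+-])\\[([^:]+):([0-9,]+)\\]:([+-])\\[([^:]+):([0-9,]+)\\]$"
  if (!all(grepl(pat, s))) stop("unparseable adjacency notation")
  num <- function(v) as.integer(gsub(",", "", v))
  data.frame(chrom1 = sub(pat, "\\2", s), pos1 = num(sub(pat, "\\3", s)),
             orient1 = sub(pat, "\\1", s),
             chrom2 = sub(pat, "\\5", s), pos2 = num(sub(pat, "\\6", s)),
             orient2 = sub(pat, "\\4", s), stringsAsFactors = FALSE)
}
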