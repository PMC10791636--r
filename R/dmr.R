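#' Two-sided Fisher exact p-value for per-CpG 2x2 count tables
#'
#' Vectorized exact hypergeometric test on tables
#' \[\[methA, unmethA\], \[methB, unmethB\]\]: the two-sided p-value sums all
#' hypergeometric point probabilities not exceeding the observed one (with
#' the conventional 1 + 1e-7 relative slack for ties).
#'
#' @param methA,unmethA,methB,unmethB non-negative integer count vectors.
#' @return numeric vector of two-sided p-values.
#' @export
cpgTest <- function(methA, unmethA, methB, unmethB) {
  if (any(c(methA, unmethA, methB, unmethB) < 0))
    stop("counts must be non-negative")
  n1 <- methA + unmethA
  n2 <- methB + unmethB
  if (any(n1 == 0 | n2 == 0))
    stop("each condition needs at least one read per site")
  k <- methA + methB
  key <- paste(methA, n1, methB, n2)
  u <- !duplicated(key)
  pu <- mapply(function(x, n1, n2, k) {
    lo <- max(0L, k - n2); hi <- min(k, n1)
    d <- stats::dhyper(lo:hi, n1, n2, k)
    sum(d[d <= d[x - lo + 1L] * (1 + 1e-7)])
  }, methA[u], n1[u], n2[u], k[u])
  pmin(1, pu[match(key, key[u])])
}

#' DMR-calling parameters
#'
#' Defaults follow the region filters of the analysis this package
#' implements: at least 25 CpGs, at least 25 significantly differentially
#' methylated CpGs, and at least a 25% absolute mean methylation
#' difference. `alpha` is the unadjusted per-CpG significance level.
#' Consecutive qualifying CpGs are chained into one run only while the
#' genomic gap stays within `maxGapBp` and at most `maxSkip` non-qualifying
#' CpGs intervene; run boundaries are trimmed until the terminal qualifying
#' CpG has a qualifying neighbour within `anchorSkip` intervening CpGs
#' (isolated significant CpGs cannot extend a region edge).
#'
#' @param minCpGs minimum CpGs spanned by an emitted DMR.
#' @param minSigCpGs minimum significant CpGs.
#' @param minMeanDiff minimum |mean difference| (proportion scale).
#' @param alpha per-CpG significance level (unadjusted).
#' @param maxGapBp maximum gap between consecutive qualifying CpGs.
#' @param maxSkip maximum intervening non-qualifying CpGs within a run.
#' @param anchorSkip boundary-anchor tolerance (intervening CpGs).
#' @param minCoverage per-CpG coverage floor in both conditions.
#' @return a list of class `DMRCallParams`.
#' @export
dmrCallParams <- function(minCpGs = 25L, minSigCpGs = 25L,
                          minMeanDiff = 0.25, alpha = 0.05,
                          maxGapBp = 1000L, maxSkip = 2L, anchorSkip = 1L,
                          minCoverage = 1L) {
  if (minCpGs < 1) stop("minCpGs must be >= 1")
  if (minMeanDiff <= 0 || minMeanDiff > 1)
    stop("minMeanDiff must be in (0, 1]")
  structure(list(minCpGs = as.integer(minCpGs),
                 minSigCpGs = as.integer(minSigCpGs),
                 minMeanDiff = minMeanDiff, alpha = alpha,
                 maxGapBp = as.integer(maxGapBp),
                 maxSkip = as.integer(maxSkip),
                 anchorSkip = as.integer(anchorSkip),
                 minCoverage = as.integer(minCoverage)),
            class = "DMRCallParams")
}

#' Segment differentially methylated regions between two conditions
#'
#' Joins the two per-CpG call tables on shared covered sites, tests each
#' CpG with the exact 2x2 test, chains sign-consistent qualifying CpGs into
#' maximal runs (see [dmrCallParams()]), trims unanchored boundaries, and
#' emits runs passing all three region filters. `meanDiff` is the mean of
#' (test - control) per-CpG level differences over every joined CpG in the
#' span; `hypo` means lower methylation in the test condition.
#'
#' @param cpgA control-condition call table (`chrom`, `pos`, `meth`,
#'   `unmeth`).
#' @param cpgB test-condition call table on the same reference.
#' @param params a [dmrCallParams()].
#' @return a [DMRSet-class]; ranges span the first to last CpG (1-based,
#'   inclusive), with `nCpGs`, `nSigCpGs`, `meanDiff`, `direction` and
#'   `lengthBp` metadata.
#' @export
segmentDmrs <- function(cpgA, cpgB, params = dmrCallParams()) {
  stopifnot(inherits(params, "DMRCallParams"))
  if (nrow(cpgA) > 0 && nrow(cpgB) > 0 &&
      !length(intersect(unique(cpgA$chrom), unique(cpgB$chrom))))
    stop("call tables share no chromosome; are they on the same reference?")
  covA <- cpgA$meth + cpgA$unmeth
  covB <- cpgB$meth + cpgB$unmeth
  a <- cpgA[covA >= params$minCoverage, , drop = FALSE]
  b <- cpgB[covB >= params$minCoverage, , drop = FALSE]
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("A", "B"))
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  emptySet <- new("DMRSet", GenomicRanges::GRanges(
    nCpGs = integer(0), nSigCpGs = integer(0), meanDiff = numeric(0),
    direction = character(0), lengthBp = integer(0)))
  if (nrow(m) == 0) return(emptySet)
  m$p <- cpgTest(m$methA, m$unmethA, m$methB, m$unmethB)
  lvA <- m$methA / (m$methA + m$unmethA)
  lvB <- m$methB / (m$methB + m$unmethB)
  m$diff <- lvB - lvA
  m$qual <- m$p < params$alpha & m$diff != 0

  rows <- list()
  for (chr in unique(m$chrom)) {
    mi <- which(m$chrom == chr)
    for (sgn in c(-1, 1)) {
      q <- mi[m$qual[mi] & sign(m$diff[mi]) == sgn]
      if (!length(q)) next
      ## break runs on genomic gap or too many intervening CpGs
      gapBp <- diff(m$pos[q])
      gapCp <- diff(match(q, mi)) - 1L
      brk <- which(gapBp > params$maxGapBp | gapCp > params$maxSkip)
      runId <- cumsum(c(1L, as.integer(seq_along(gapBp) %in% brk)))
      for (r in split(q, runId)) {
        ## trim unanchored boundaries
        while (length(r) >= 2 &&
               match(r[2], mi) - match(r[1], mi) - 1L > params$anchorSkip)
          r <- r[-1]
        while (length(r) >= 2 &&
               match(r[length(r)], mi) - match(r[length(r) - 1], mi) - 1L >
               params$anchorSkip)
          r <- r[-length(r)]
        if (length(r) < 2) next
        span <- mi[m$pos[mi] >= m$pos[r[1]] & m$pos[mi] <= m$pos[r[length(r)]]]
        nC <- length(span)
        nS <- sum(m$qual[span] & sign(m$diff[span]) == sgn)
        md <- mean(m$diff[span])
        if (nC >= params$minCpGs && nS >= params$minSigCpGs &&
            abs(md) >= params$minMeanDiff && sign(md) == sgn) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chr, start = m$pos[r[1]], end = m$pos[r[length(r)]],
            nCpGs = nC, nSigCpGs = nS, meanDiff = md,
            direction = if (sgn < 0) "hypo" else "hyper")
        }
      }
    }
  }
  if (!length(rows)) return(emptySet)
  d <- do.call(rbind, rows)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    d$chrom, IRanges(d$start, d$end),
    nCpGs = d$nCpGs, nSigCpGs = d$nSigCpGs, meanDiff = d$meanDiff,
    direction = d$direction, lengthBp = d$end - d$start + 1L)
  names(gr) <- sprintf("DMR%03d", seq_along(gr))
  new("DMRSet", gr)
}

#' Annotate DMRs with their genomic feature category
#'
#' Classifies each DMR by its midpoint with priority
#' promoter > exon > intron > TTS > intergenic. The promoter window is
#' \[-1000, +100\] bp around the strand-aware gene start; the TTS window is
#' the mirror \[-100, +1000\] bp around the gene end. When no exon table is
#' supplied the whole gene body counts as exonic.
#'
#' @param dmrs a [DMRSet-class] or GRanges.
#' @param genes gene models (GRanges with strand and `gene_id`).
#' @param exons optional exon GRanges with `gene_id`.
#' @param promoterUp,promoterDown promoter window (bp upstream of the
#'   start, bp into the gene).
#' @param ttsUp,ttsDown TTS window (bp into the gene, bp downstream).
#' @return character vector of categories, one per DMR.
#' @export
annotateDmrs <- function(dmrs, genes, exons = NULL,
                         promoterUp = 1000L, promoterDown = 100L,
                         ttsUp = 100L, ttsDown = 1000L) {
  if (length(dmrs) == 0) return(character(0))
  mid <- as.integer(floor((start(dmrs) + end(dmrs)) / 2))
  midGr <- GenomicRanges::GRanges(seqnames(dmrs), IRanges(mid, width = 1L))
  plus <- as.character(strand(genes)) != "-"
  gs <- ifelse(plus, start(genes), end(genes))   # strand-aware start
  ge <- ifelse(plus, end(genes), start(genes))   # strand-aware end
  prom <- GenomicRanges::GRanges(seqnames(genes), IRanges(
    ifelse(plus, gs - promoterUp, gs - promoterDown),
    ifelse(plus, gs + promoterDown, gs + promoterUp)))
  tts <- GenomicRanges::GRanges(seqnames(genes), IRanges(
    ifelse(plus, ge - ttsUp, ge - ttsDown),
    ifelse(plus, ge + ttsDown, ge + ttsUp)))
  if (is.null(exons)) exons <- genes
  cnt <- function(q, s) suppressWarnings(
    GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE)) > 0
  inProm <- cnt(midGr, prom)
  inExon <- cnt(midGr, exons)
  inBody <- cnt(midGr, genes)
  inTts <- cnt(midGr, tts)
  ifelse(inProm, "promoter",
  ifelse(inExon, "exon",
  ifelse(inBody, "intron",
  ifelse(inTts, "TTS", "intergenic"))))
}

#' Summarize a DMR set per direction
#'
#' @param dmrs a [DMRSet-class].
#' @return data.frame with one row per direction: `n`, `meanLength`,
#'   `medianLength` (bp).
#' @export
dmrSummary <- function(dmrs) {
  out <- data.frame(direction = c("hypo", "hyper"), n = 0L,
                    meanLength = NA_real_, medianLength = NA_real_)
  for (i in seq_len(2)) {
    sel <- dmrs$direction == out$direction[i]
    out$n[i] <- sum(sel)
    if (any(sel)) {
      len <- width(dmrs)[sel]
      out$meanLength[i] <- mean(len)
      out$medianLength[i] <- median(len)
    }
  }
  out
}

#' Associate genes with DMRs
#'
#' A gene is DMR-associated when any DMR overlaps its body extended by
#' `windowBp` on both sides.
#'
#' @param genes gene models (GRanges with `gene_id`).
#' @param dmrs a [DMRSet-class] or GRanges.
#' @param windowBp extension in bp (default 2000).
#' @return data.frame with `gene_id`, `associated` (logical), `dmrIds`
#'   (comma-separated names of overlapping DMRs).
#' @export
mapGenesToDmrs <- function(genes, dmrs, windowBp = 2000L) {
  ext <- GenomicRanges::resize(genes, width(genes) + 2L * windowBp,
                               fix = "center", ignore.strand = TRUE)
  ov <- findOverlaps(ext, dmrs, ignore.strand = TRUE)
  ids <- if (!is.null(names(dmrs))) names(dmrs) else
    as.character(seq_along(dmrs))
  hit <- split(ids[subjectHits(ov)], genes$gene_id[queryHits(ov)])
  data.frame(
    gene_id = genes$gene_id,
    associated = genes$gene_id %in% names(hit),
    dmrIds = vapply(genes$gene_id, function(g)
      paste(hit[[g]], collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
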