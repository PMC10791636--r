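#' Extract per-CpG methylation calls from aligned bisulfite reads
#'
#' Scores each read at the CpG dinucleotides of the reference it covers: on
#' the top strand, a C at the CpG cytosine is a methylated call and a T an
#' unmethylated call; on the bottom strand the mirror logic applies at the
#' G (reported as G = methylated, A = unmethylated on the reference frame).
#' Symmetric CpG calls are merged to the top-strand C coordinate by default.
#' Any other base at a scored position is skipped and counted.
#'
#' @param reads aligned bisulfite records (see [simulateBisulfiteReads()]);
#'   `strand` column or SAM `flag` determines the original strand.
#' @param reference [Biostrings::DNAStringSet] used to locate CpG sites.
#' @param mergeStrands merge bottom-strand calls onto the top-strand C
#'   coordinate (default TRUE); otherwise a `strand` column is kept.
#' @return data.frame with `chrom`, `pos` (1-based top-strand C), `meth`,
#'   `unmeth` (+ `strand` when unmerged), with attribute `skipped` counting
#'   read bases inconsistent with either methylation state.
#' @export
callCpgMethylation <- function(reads, reference, mergeStrands = TRUE) {
  stopifnot(is(reference, "DNAStringSet"))
  top <- if ("strand" %in% names(reads)) reads$strand == "top"
         else bitwAnd(reads$flag, 16L) == 0L
  spans <- as.integer(sub("M$", "", reads$cigar))
  if (anyNA(spans)) stop("callCpgMethylation expects match-only CIGARs")
  res <- list()
  skipped <- 0L
  for (chr in intersect(unique(reads$chrom), names(reference))) {
    refChars <- strsplit(as.character(reference[[chr]]), "")[[1]]
    L <- length(refChars)
    cpg <- which(refChars[-L] == "C" & refChars[-1L] == "G")
    if (!length(cpg)) next
    rIdx <- which(reads$chrom == chr)
    ## top-strand reads must cover the C; bottom-strand reads the G (pos+1)
    scorePos <- ifelse(top[rIdx], 0L, 1L)
    ov <- findOverlaps(IRanges(reads$pos[rIdx], width = spans[rIdx]),
                       IRanges(cpg, width = 2L))
    if (!length(ov)) next
    ri <- rIdx[queryHits(ov)]
    cp <- cpg[subjectHits(ov)]
    tgt <- cp + ifelse(top[ri], 0L, 1L)      # base actually scored
    inside <- tgt >= reads$pos[ri] & tgt <= reads$pos[ri] + spans[ri] - 1L
    ri <- ri[inside]; cp <- cp[inside]; tgt <- tgt[inside]
    if (!length(ri)) next
    off <- tgt - reads$pos[ri] + 1L
    base <- substr(reads$seq[ri], off, off)
    isTop <- top[ri]
    meth <- (isTop & base == "C") | (!isTop & base == "G")
    unmeth <- (isTop & base == "T") | (!isTop & base == "A")
    skipped <- skipped + sum(!meth & !unmeth)
    use <- meth | unmeth
    df <- data.frame(pos = cp[use], strand = ifelse(isTop[use], "+", "-"),
                     meth = as.integer(meth[use]))
    key <- if (mergeStrands) df$pos else paste(df$pos, df$strand)
    mct <- tapply(df$meth, key, sum)
    tot <- tapply(rep(1L, nrow(df)), key, sum)
    if (mergeStrands) {
      res[[chr]] <- data.frame(chrom = chr, pos = as.integer(names(mct)),
                               meth = as.integer(mct),
                               unmeth = as.integer(tot - mct),
                               stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(names(mct), " ")
      res[[chr]] <- data.frame(chrom = chr,
                               pos = as.integer(vapply(parts, `[`, "", 1)),
                               strand = vapply(parts, `[`, "", 2),
                               meth = as.integer(mct),
                               unmeth = as.integer(tot - mct),
                               stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), pos = integer(0),
               meth = integer(0), unmeth = integer(0))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Estimate bisulfite conversion efficiency from the spike-in contig
#'
#' The spike-in is fully unmethylated, so every methylated call there is a
#' conversion failure: efficiency = unmeth / (meth + unmeth) pooled over all
#' spike-in cytosine calls.
#'
#' @param cpgTable per-site call table restricted to the spike-in contig
#'   (e.g. [callCpgMethylation()] on lambda reads).
#' @return list with `efficiency` (NA when not evaluable), `nCalls`, and
#'   `status` (`"ok"` or `"no_coverage"`).
#' @export
conversionEfficiency <- function(cpgTable) {
  tot <- sum(cpgTable$meth) + sum(cpgTable$unmeth)
  if (tot == 0)
    return(list(efficiency = NA_real_, nCalls = 0L, status = "no_coverage"))
  list(efficiency = sum(cpgTable$unmeth) / tot, nCalls = as.integer(tot),
       status = "ok")
}

#' Tile per-CpG calls into fixed windows
#'
#' The window mean is the unweighted mean of per-CpG levels (each CpG one
#' observation, subject to a per-CpG coverage floor), the convention of
#' tiling-window methylation analyses. Terminal partial windows are emitted
#' and flagged. Windows with no qualifying CpG are omitted.
#'
#' @param cpgTable data.frame `chrom`, `pos`, `meth`, `unmeth`.
#' @param windowSize window size in bp (default 10000).
#' @param minCpGs minimum qualifying CpGs per emitted window (default 1).
#' @param minCoverage per-CpG coverage floor (default 1).
#' @param chromLengths optional named lengths used to flag terminal windows.
#' @return data.frame `chrom`, `start` (0-based), `end` (half-open),
#'   `level`, `nCpGs`, `coverage`, `partial`.
#' @export
windowLevels <- function(cpgTable, windowSize = 10000L, minCpGs = 1L,
                         minCoverage = 1L, chromLengths = NULL) {
  cov <- cpgTable$meth + cpgTable$unmeth
  keep <- cov >= minCoverage
  x <- cpgTable[keep, , drop = FALSE]
  if (nrow(x) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), level = numeric(0),
                      nCpGs = integer(0), coverage = integer(0),
                      partial = logical(0)))
  lev <- x$meth / (x$meth + x$unmeth)
  win <- (x$pos - 1L) %/% windowSize
  key <- paste(x$chrom, win)
  agg <- data.frame(
    key = names(tapply(lev, key, mean)),
    level = as.numeric(tapply(lev, key, mean)),
    nCpGs = as.integer(tapply(lev, key, length)),
    coverage = as.integer(tapply(x$meth + x$unmeth, key, sum)))
  parts <- strsplit(agg$key, " ")
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)) * windowSize,
    stringsAsFactors = FALSE)
  out$end <- out$start + as.integer(windowSize)
  out$level <- agg$level
  out$nCpGs <- agg$nCpGs
  out$coverage <- agg$coverage
  out$partial <- FALSE
  if (!is.null(chromLengths)) {
    lens <- chromLengths[out$chrom]
    out$partial <- out$end > lens
    out$end <- pmin(out$end, as.integer(lens))
  }
  out <- out[out$nCpGs >= minCpGs, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global methylation level of a call table
#'
#' @param cpgTable data.frame `chrom`, `pos`, `meth`, `unmeth`.
#' @return list with `weighted` (coverage-weighted, sum(meth)/sum(cov)) and
#'   `unweighted` (mean of per-CpG levels over covered sites).
#' @export
globalLevel <- function(cpgTable) {
  cov <- cpgTable$meth + cpgTable$unmeth
  x <- cpgTable[cov > 0, , drop = FALSE]
  if (nrow(x) == 0) return(list(weighted = NA_real_, unweighted = NA_real_))
  list(weighted = sum(x$meth) / sum(x$meth + x$unmeth),
       unweighted = mean(x$meth / (x$meth + x$unmeth)))
}

#' Compare two sets of window levels (two-sided Wilcoxon rank-sum)
#'
#' Exact test for small tie-free samples (< 50 values in total), normal
#' approximation with tie correction otherwise.
#'
#' @param windowsA,windowsB numeric level vectors or [windowLevels()]
#'   data.frames (their `level` columns are used).
#' @return list with `p.value`, `statistic` (W), `medianA`, `medianB`,
#'   `meanA`, `meanB`.
#' @export
compareWindowSets <- function(windowsA, windowsB) {
  a <- if (is.data.frame(windowsA)) windowsA$level else windowsA
  b <- if (is.data.frame(windowsB)) windowsB$level else windowsB
  if (!length(a) || !length(b)) stop("both window sets must be non-empty")
  exact <- (length(a) + length(b)) < 50 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       medianA = median(a), medianB = median(b),
       meanA = mean(a), meanB = mean(b))
}

#' Average methylation profile over a region set with flanks
#'
#' Region bodies are rescaled to `bodyBins` bins; flanks are fixed-width in
#' bp and binned absolutely. Per-CpG levels are pooled over all regions
#' within each bin and averaged (each covered CpG one observation).
#'
#' @param regions [GenomicRanges::GRanges] (non-degenerate widths).
#' @param cpgTable call table (`chrom`, `pos`, `meth`, `unmeth`).
#' @param bodyBins bins across the region body (default 20).
#' @param flankBp flank width in bp (default 2000).
#' @param flankBins bins per flank (default 10).
#' @return data.frame with `bin` (1..flankBins+bodyBins+flankBins),
#'   `zone` (`upstream`/`body`/`downstream`), `level`, `nCpGs`.
#' @export
regionMetaprofile <- function(regions, cpgTable, bodyBins = 20L,
                              flankBp = 2000L, flankBins = 10L) {
  stopifnot(is(regions, "GRanges"))
  if (any(width(regions) < 2)) stop("regions must be non-degenerate")
  cov <- cpgTable$meth + cpgTable$unmeth
  x <- cpgTable[cov > 0, , drop = FALSE]
  lev <- x$meth / (x$meth + x$unmeth)
  nBins <- 2L * flankBins + bodyBins
  sumLev <- nCp <- numeric(nBins)
  gr <- GenomicRanges::GRanges(x$chrom, IRanges(x$pos, width = 1L))
  ext <- GenomicRanges::resize(regions, width(regions) + 2L * flankBp,
                               fix = "center")
  ov <- findOverlaps(gr, ext, ignore.strand = TRUE)
  if (length(ov)) {
    p <- x$pos[queryHits(ov)]
    ri <- subjectHits(ov)
    s <- start(regions)[ri]; e <- end(regions)[ri]
    bin <- integer(length(p))
    up <- p < s
    dn <- p > e
    body <- !up & !dn
    bin[up] <- flankBins - pmin(flankBins - 1L,
      as.integer((s[up] - p[up] - 1L) %/% (flankBp / flankBins)))
    bin[body] <- flankBins + 1L +
      pmin(bodyBins - 1L, as.integer((p[body] - s[body]) /
                                     (e[body] - s[body] + 1L) * bodyBins))
    bin[dn] <- flankBins + bodyBins + 1L +
      pmin(flankBins - 1L, as.integer((p[dn] - e[dn] - 1L) %/%
                                      (flankBp / flankBins)))
    keep <- bin >= 1L & bin <= nBins
    sl <- tapply(lev[queryHits(ov)][keep], bin[keep], sum)
    nc <- tapply(rep(1, sum(keep)), bin[keep], sum)
    sumLev[as.integer(names(sl))] <- sl
    nCp[as.integer(names(nc))] <- nc
  }
  data.frame(
    bin = seq_len(nBins),
    zone = rep(c("upstream", "body", "downstream"),
               times = c(flankBins, bodyBins, flankBins)),
    level = ifelse(nCp > 0, sumLev / pmax(nCp, 1), NA_real_),
    nCpGs = as.integer(nCp))
}
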