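## parse a match/skip CIGAR (e.g. "60M", "40M200N60M") into aligned blocks;
## returns list(refStart offsets, len, queryStart offsets) relative to POS
.cigarBlocks <- function(cigar) {
  ops <- gregexpr("[0-9]+[MN]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MN]", cigar))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar))
    stop("unsupported CIGAR: ", cigar)
  lens <- as.integer(sub("[MN]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  refOff <- cumsum(c(0L, lens[-length(lens)]))
  qOff <- cumsum(c(0L, (lens * (op == "M"))[-length(lens)]))
  keep <- op == "M"
  list(refOff = refOff[keep], len = lens[keep], qOff = qOff[keep],
       refLen = sum(lens))
}

## does observed base b support allele a, given bisulfite chemistry?
.supports <- function(b, a, top, bisulfite) {
  b == a |
    (bisulfite & top & a == "C" & b == "T") |
    (bisulfite & !top & a == "G" & b == "A")
}

#' Assign aligned reads to the maternal or paternal allele
#'
#' Each read is scored at every informative SNP it covers. In `bisulfite`
#' mode a SNP is unusable when bisulfite conversion can mimic either allele:
#' C/T SNPs (either orientation) for top-strand reads and G/A SNPs for
#' bottom-strand reads; in addition, an observed T may support a C allele on
#' the top strand (converted cytosine) and an observed A a G allele on the
#' bottom strand. A read supporting both alleles is `conflicting`; a read
#' with no usable SNP is `unassigned`. Bases matching neither allele are
#' counted as mismatched-base events and support neither side.
#'
#' @param reads data.frame of aligned records (`qname`, `chrom`, `pos`,
#'   `cigar`, `seq`, and either a `strand` column (`top`/`bottom`) or a SAM
#'   `flag`). CIGARs may contain M and N operations only.
#' @param snps informative-SNP data.frame (`chrom`, `pos`, `maternal`,
#'   `paternal`).
#' @param mode `"dna"`, `"rna"` or `"bisulfite"`.
#' @param chroms optional character vector of known chromosomes; reads on
#'   other chromosomes raise an error (the spike-in contig `lambda` is
#'   always tolerated).
#' @return data.frame with `qname`, `verdict` (`maternal`, `paternal`,
#'   `unassigned`, `conflicting`), `nMaternal`, `nPaternal`, `nMismatch`.
#' @export
classifyReads <- function(reads, snps, mode = c("dna", "rna", "bisulfite"),
                          chroms = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(reads))
  if (!is.null(chroms)) {
    bad <- !(reads$chrom %in% c(chroms, "lambda"))
    if (any(bad))
      stop("read on unknown chromosome: ", reads$chrom[which(bad)[1]])
  }
  n <- nrow(reads)
  top <- if ("strand" %in% names(reads)) reads$strand == "top"
         else bitwAnd(reads$flag, 16L) == 0L
  bisulfite <- mode == "bisulfite"
  nMat <- nPat <- nMis <- integer(n)
  if (n > 0 && nrow(snps) > 0) {
    simple <- grepl("^[0-9]+M$", reads$cigar)
    spans <- integer(n)
    spans[simple] <- as.integer(sub("M$", "", reads$cigar[simple]))
    blocks <- NULL
    if (!all(simple)) {
      blocks <- lapply(reads$cigar[!simple], .cigarBlocks)
      spans[!simple] <- vapply(blocks, `[[`, integer(1), "refLen")
    }
    for (chr in unique(reads$chrom)) {
      sIdx <- which(snps$chrom == chr)
      rIdx <- which(reads$chrom == chr)
      if (!length(sIdx) || !length(rIdx)) next
      ov <- findOverlaps(
        IRanges(reads$pos[rIdx], width = spans[rIdx]),
        IRanges(snps$pos[sIdx], width = 1L))
      if (!length(ov)) next
      ri <- rIdx[queryHits(ov)]
      si <- sIdx[subjectHits(ov)]
      sp <- snps$pos[si]
      ## query offset of the SNP within the read sequence
      qpos <- sp - reads$pos[ri] + 1L
      ok <- rep(TRUE, length(ri))
      if (!all(simple)) {
        cplx <- which(!simple[ri])
        for (k in cplx) {
          b <- blocks[[match(ri[k], which(!simple))]]
          rel <- sp[k] - reads$pos[ri[k]]
          j <- which(rel >= b$refOff & rel < b$refOff + b$len)
          if (length(j) == 1L) qpos[k] <- b$qOff[j] + (rel - b$refOff[j]) + 1L
          else ok[k] <- FALSE  # SNP inside a skipped (N) gap
        }
      }
      ri <- ri[ok]; si <- si[ok]; qpos <- qpos[ok]
      if (!length(ri)) next
      base <- substr(reads$seq[ri], qpos, qpos)
      am <- snps$maternal[si]; ap <- snps$paternal[si]
      rtop <- top[ri]
      unusable <- bisulfite & ((rtop & ((am == "C" & ap == "T") |
                                        (am == "T" & ap == "C"))) |
                               (!rtop & ((am == "G" & ap == "A") |
                                         (am == "A" & ap == "G"))))
      sm <- !unusable & .supports(base, am, rtop, bisulfite)
      sp2 <- !unusable & .supports(base, ap, rtop, bisulfite)
      mis <- !unusable & !sm & !sp2
      nMat <- nMat + tabulate(ri[sm & !sp2], nbins = n)
      nPat <- nPat + tabulate(ri[sp2 & !sm], nbins = n)
      nMis <- nMis + tabulate(ri[mis], nbins = n)
    }
  }
  verdict <- ifelse(nMat > 0 & nPat > 0, "conflicting",
             ifelse(nMat > 0, "maternal",
             ifelse(nPat > 0, "paternal", "unassigned")))
  data.frame(qname = reads$qname, verdict = verdict,
             nMaternal = nMat, nPaternal = nPat, nMismatch = nMis,
             stringsAsFactors = FALSE)
}

#' Split an aligned dataset into allelic partitions
#'
#' @inheritParams classifyReads
#' @return list with `maternal`, `paternal`, `unassigned`, `conflicting`
#'   read data.frames (disjoint and exhaustive), `assignments` (the
#'   per-read table) and `summary` (verdict counts plus mismatched-base
#'   events).
#' @export
splitReads <- function(reads, snps, mode = c("dna", "rna", "bisulfite"),
                       chroms = NULL) {
  mode <- match.arg(mode)
  asg <- classifyReads(reads, snps, mode, chroms)
  parts <- lapply(c(maternal = "maternal", paternal = "paternal",
                    unassigned = "unassigned", conflicting = "conflicting"),
                  function(v) reads[asg$verdict == v, , drop = FALSE])
  summary <- data.frame(
    verdict = c("maternal", "paternal", "unassigned", "conflicting"),
    reads = vapply(parts, nrow, integer(1)))
  summary$mismatchEvents <- sum(asg$nMismatch)
  c(parts, list(assignments = asg, summary = summary))
}

#' Maternal allelic fraction per feature
#'
#' @param reads aligned records carrying a `qname` (and, if `features` is
#'   supplied, coordinates; if the records already carry a `gene_id`
#'   column, `features` may be omitted).
#' @param assignments output of [classifyReads()] for the same records.
#' @param features optional [GenomicRanges::GRanges] with a `gene_id`
#'   metadata column; reads are attributed to the feature overlapping their
#'   span.
#' @param minReads minimum assigned (maternal + paternal) reads for a
#'   feature to be evaluable (default 10).
#' @return data.frame with `gene_id`, `nMaternal`, `nPaternal`,
#'   `maternalFraction` (NA when not evaluable), `evaluable`.
#' @export
allelicFraction <- function(reads, assignments, features = NULL,
                            minReads = 10L) {
  stopifnot(nrow(reads) == nrow(assignments))
  if (is.null(features)) {
    if (!"gene_id" %in% names(reads))
      stop("supply `features` or records with a gene_id column")
    gid <- reads$gene_id
  } else {
    spans <- as.integer(sub("M$", "", reads$cigar))
    gid <- rep(NA_character_, nrow(reads))
    ov <- findOverlaps(
      GenomicRanges::GRanges(reads$chrom, IRanges(reads$pos, width = spans)),
      features, ignore.strand = TRUE)
    gid[queryHits(ov)] <- features$gene_id[subjectHits(ov)]
  }
  keep <- !is.na(gid) & assignments$verdict %in% c("maternal", "paternal")
  tab <- table(factor(gid[keep]),
               factor(assignments$verdict[keep],
                      levels = c("maternal", "paternal")))
  ids <- if (is.null(features)) sort(unique(reads$gene_id)) else
    unique(features$gene_id)
  nM <- nP <- setNames(integer(length(ids)), ids)
  nM[rownames(tab)] <- tab[, "maternal"]
  nP[rownames(tab)] <- tab[, "paternal"]
  tot <- nM + nP
  frac <- ifelse(tot >= minReads, nM / tot, NA_real_)
  data.frame(gene_id = ids, nMaternal = as.integer(nM),
             nPaternal = as.integer(nP),
             maternalFraction = as.numeric(frac),
             evaluable = tot >= minReads,
             row.names = NULL, stringsAsFactors = FALSE)
}
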