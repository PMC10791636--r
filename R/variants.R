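## GATK-style hard filter: a record fails iff any inequality holds.
.HARD_FILTERS <- list(
  QD             = function(x) x < 2.0,
  MQ             = function(x) x < 40.0,
  FS             = function(x) x > 60.0,
  SOR            = function(x) x > 3.0,
  MQRankSum      = function(x) x < -12.5,
  ReadPosRankSum = function(x) x < -8.0
)

#' Hard-filter variant records on the standard quality annotations
#'
#' Applies the GATK-style site filters QD < 2.0, MQ < 40.0, FS > 60.0,
#' SOR > 3.0, MQRankSum < -12.5, ReadPosRankSum < -8.0. All inequalities are
#' strict, so boundary values pass. A missing (NA) annotation does not fail
#' its sub-filter (rank-sum annotations are routinely absent at sites with
#' no heterozygous calls); such records are flagged.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   genotype columns `gtMaternal`, `gtPaternal` (e.g. `"A/A"`), and the six
#'   annotation columns named above (NA allowed).
#' @return list with `pass` and `fail` data.frames (a partition of the
#'   input); `fail` carries a `reasons` column (comma-separated failing
#'   annotations) and both carry `missingAnnotation` flags.
#' @export
hardFilterVariants <- function(records) {
  stopifnot(is.data.frame(records))
  ann <- names(.HARD_FILTERS)
  miss <- setdiff(ann, names(records))
  if (length(miss))
    stop("records lack annotation columns: ", paste(miss, collapse = ", "))
  n <- nrow(records)
  failMat <- matrix(FALSE, nrow = n, ncol = length(ann),
                    dimnames = list(NULL, ann))
  missMat <- matrix(FALSE, nrow = n, ncol = length(ann))
  for (j in seq_along(ann)) {
    x <- records[[ann[j]]]
    missMat[, j] <- is.na(x)
    f <- .HARD_FILTERS[[j]](x)
    failMat[, j] <- !is.na(f) & f
  }
  fails <- rowSums(failMat) > 0
  reasons <- apply(failMat, 1, function(r) paste(ann[r], collapse = ","))
  records$missingAnnotation <- rowSums(missMat) > 0
  pass <- records[!fails, , drop = FALSE]
  fail <- records[fails, , drop = FALSE]
  fail$reasons <- reasons[fails]
  rownames(pass) <- rownames(fail) <- NULL
  list(pass = pass, fail = fail)
}

## parse "A/A" | "A|A" diploid genotype into a 2-vector, NA-safe
.parseGt <- function(gt) {
  strsplit(gt, "[/|]")
}

#' Select informative (homozygous-divergent) parental SNPs
#'
#' Keeps exactly the sites where both parents are homozygous for different
#' alleles -- the only configuration in which every offspring read covering
#' the site reveals its parent of origin. Heterozygous and shared-allele
#' sites are excluded; multi-allelic records (any genotype allele outside
#' \{ref, alt\}) are dropped with a warning.
#'
#' @param records variant data.frame (typically the `pass` set of
#'   [hardFilterVariants()]) with `chrom`, `pos`, `ref`, `alt`,
#'   `gtMaternal`, `gtPaternal`.
#' @return data.frame with `chrom`, `pos` (1-based), `maternal`, `paternal`
#'   single-base alleles, sorted by (chrom, pos).
#' @export
selectInformativeSnps <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      maternal = character(0), paternal = character(0)))
  gm <- .parseGt(records$gtMaternal)
  gp <- .parseGt(records$gtPaternal)
  homM <- vapply(gm, function(g) length(g) == 2 && g[1] == g[2], logical(1))
  homP <- vapply(gp, function(g) length(g) == 2 && g[1] == g[2], logical(1))
  aM <- vapply(gm, `[`, character(1), 1)
  aP <- vapply(gp, `[`, character(1), 1)
  biallelic <- (aM == records$ref | aM == records$alt) &
    (aP == records$ref | aP == records$alt)
  if (any(homM & homP & aM != aP & !biallelic))
    warning("multi-allelic site(s) excluded")
  keep <- homM & homP & aM != aP & biallelic
  out <- data.frame(chrom = records$chrom[keep],
                    pos = as.integer(records$pos[keep]),
                    maternal = aM[keep], paternal = aP[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' N-mask a reference at informative SNP positions
#'
#' Replaces the base at every SNP position with `N`, leaving all other
#' bases untouched, and returns the single-base masked intervals as a
#' 0-based half-open BED data.frame. Masking is idempotent.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param snps data.frame with `chrom` and 1-based `pos` (e.g. from
#'   [selectInformativeSnps()]).
#' @return list with `masked` (DNAStringSet) and `bed` (data.frame `chrom`,
#'   `start`, `end`).
#' @export
maskGenome <- function(reference, snps) {
  stopifnot(is(reference, "DNAStringSet"))
  if (nrow(snps) > 0) {
    bad <- !(snps$chrom %in% names(reference))
    if (any(bad))
      stop("SNP on unknown chromosome: ", snps$chrom[which(bad)[1]], ":",
           snps$pos[which(bad)[1]])
    lens <- setNames(Biostrings::width(reference), names(reference))
    off <- snps$pos < 1 | snps$pos > lens[snps$chrom]
    if (any(off))
      stop("SNP outside its chromosome: ", snps$chrom[which(off)[1]], ":",
           snps$pos[which(off)[1]])
  }
  masked <- reference
  for (chr in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == chr]
    masked[[chr]] <- Biostrings::replaceLetterAt(
      masked[[chr]], p, rep.int("N", length(p)))
  }
  snps <- unique(snps[c("chrom", "pos")])
  bedCoord <- posToBed(snps$pos)
  bed <- data.frame(chrom = snps$chrom, start = bedCoord$start,
                    end = bedCoord$end, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  rownames(bed) <- NULL
  list(masked = masked, bed = bed)
}
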