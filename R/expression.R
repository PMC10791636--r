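#' FPKM from raw counts
#'
#' FPKM = count / (gene length in kb x mapped fragments in millions).
#'
#' @param counts genes x samples integer matrix (rownames = gene ids).
#' @param geneLengths per-gene lengths in bp, named or in row order.
#' @param librarySizes per-sample mapped-fragment totals; defaults to the
#'   column sums of `counts`.
#' @return FPKM matrix of the same shape.
#' @export
computeFpkm <- function(counts, geneLengths, librarySizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(geneLengths)) && !is.null(rownames(counts)))
    geneLengths <- geneLengths[rownames(counts)]
  if (any(geneLengths <= 0)) stop("gene lengths must be positive")
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  sweep(sweep(counts, 1, geneLengths / 1e3, "/"), 2, librarySizes / 1e6, "/")
}

## DESeq-style median-of-ratios size factors
.sizeFactors <- function(counts) {
  logGeo <- rowMeans(log(counts))
  apply(counts, 2, function(cj) {
    r <- log(cj) - logGeo
    exp(median(r[is.finite(r)]))
  })
}

#' Two-group negative-binomial differential expression
#'
#' A self-contained engine: median-of-ratios normalization, per-gene
#' method-of-moments NB dispersion (pooled within groups, floored), and a
#' Wald test on the log ratio of normalized group means with a delta-method
#' standard error. Genes with all-zero counts are excluded and flagged.
#' Threshold flags follow the conventional cutoffs p < 0.01, fold change
#' > 2, baseMean > 10.
#'
#' @param counts genes x samples raw count matrix.
#' @param groups two-level factor (first level = reference/control) along
#'   the columns.
#' @param sizeFactors optional per-sample size factors; estimated by
#'   median-of-ratios when NULL.
#' @param dispersionFloor lower bound on the dispersion (default 0.01).
#' @param pCut,fcCut,baseMeanCut significance cutoffs used for the `sig`
#'   flag (defaults 0.01, 2, 10).
#' @return data.frame with `gene_id`, `baseMean`, `log2FC` (second level
#'   over first), `pvalue`, `dispersion`, `excluded`, `sig`.
#' @export
differentialExpression <- function(counts, groups, sizeFactors = NULL,
                                   dispersionFloor = 0.01,
                                   pCut = 0.01, fcCut = 2, baseMeanCut = 10) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (min(table(groups)) < 2) stop("need >= 2 replicates per group")
  if (is.null(sizeFactors)) sizeFactors <- .sizeFactors(counts)
  norm <- sweep(counts, 2, sizeFactors, "/")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, var)
  baseMean <- rowMeans(norm)
  excluded <- rowSums(counts) == 0

  ## pooled within-group method-of-moments dispersion, floored
  ex1 <- (v1 - m1) / m1^2
  ex2 <- (v2 - m2) / m2^2
  disp <- pmax((ex1 * (n1 - 1) + ex2 * (n2 - 1)) / (n1 + n2 - 2),
               dispersionFloor)
  disp[!is.finite(disp)] <- dispersionFloor

  lfc <- log2(m2 / m1)
  ## delta-method SE of log(mean) under NB sampling: var = mu + a*mu^2
  seLn <- sqrt((m1 + disp * m1^2) / (n1 * m1^2) +
               (m2 + disp * m2^2) / (n2 * m2^2))
  z <- (log(m2) - log(m1)) / seLn
  p <- 2 * pnorm(-abs(z))
  p[excluded] <- NA
  lfc[excluded] <- NA
  sig <- !excluded & !is.na(p) & p < pCut & abs(lfc) > log2(fcCut) &
    baseMean > baseMeanCut
  data.frame(gene_id = rownames(counts), baseMean = baseMean,
             log2FC = lfc, pvalue = p, dispersion = disp,
             excluded = excluded, sig = sig,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call the allelic expression status of a gene
#'
#' @param maternalFraction maternal / (maternal + paternal) read fraction.
#' @param nInformative assigned informative reads behind the fraction.
#' @param bands numeric vector `c(mono, biLow, biHigh)`: paternal when the
#'   fraction is <= `mono`, maternal when >= 1 - `mono`, biallelic inside
#'   \[`biLow`, `biHigh`\], otherwise `not_evaluable`. Defaults 0.15 /
#'   0.30 / 0.70.
#' @param minReads informative-read floor (default 10).
#' @return character vector: `maternal`, `paternal`, `biallelic` or
#'   `not_evaluable`.
#' @export
callAllelicStatus <- function(maternalFraction, nInformative,
                              bands = c(mono = 0.15, biLow = 0.30,
                                        biHigh = 0.70),
                              minReads = 10L) {
  f <- maternalFraction
  out <- rep("not_evaluable", length(f))
  ok <- !is.na(f) & nInformative >= minReads
  out[ok & f <= bands[1]] <- "paternal"
  out[ok & f >= 1 - bands[1]] <- "maternal"
  out[ok & f >= bands[2] & f <= bands[3]] <- "biallelic"
  out
}

#' Imprinted-gene filtration cascade and loss-of-imprinting calls
#'
#' Stage 1 keeps catalogue genes reliably expressed in both groups
#' (FPKM > 1); stage 2 intersects with DMR-associated genes; stage 3
#' applies the fold-change screen (FPKM ratio > 2 or < 0.5). A parallel
#' route intersects the catalogue with differential-expression calls
#' (p < 0.01, FC > 2, baseMean > 10) and then with DMR association. A gene
#' is called LOI (loss of imprinting) when its control-condition expression
#' is monoallelic and its test-condition expression biallelic by the
#' configured bands, or -- when allelic methylation levels are supplied --
#' when a maternal methylation bias in the control condition is lost in the
#' test condition.
#'
#' @param imprintList character vector of catalogue gene ids (or a
#'   data.frame with a `gene_id` column, e.g. the packaged catalogue).
#' @param fpkmControl,fpkmTest named per-gene mean FPKM by group.
#' @param genes gene models (GRanges with `gene_id`).
#' @param dmrs called [DMRSet-class].
#' @param deResults [differentialExpression()] table.
#' @param allelic optional data.frame with `gene_id`,
#'   `fracControl`, `nControl`, `fracTest`, `nTest` allelic expression
#'   summaries.
#' @param methBias optional data.frame with `gene_id`, `matControl`,
#'   `patControl`, `matTest`, `patTest` allelic methylation levels at the
#'   gene's DMR; a maternal bias (mat - pat >= `methBiasDelta`) present in
#'   control and absent in test also triggers LOI.
#' @param params list of cutoffs: `fpkmMin` (1), `fcLow` (0.5), `fcHigh`
#'   (2), `windowBp` (2000), `bands`, `minReads`, `methBiasDelta` (0.3).
#' @return list with staged id vectors (`stage1`, `stage2`, `stage3`,
#'   `degRoute`) and `calls`, a per-gene data.frame of cascade stage,
#'   allelic statuses and the LOI flag.
#' @export
candidateCascade <- function(imprintList, fpkmControl, fpkmTest, genes,
                             dmrs, deResults = NULL, allelic = NULL,
                             methBias = NULL,
                             params = list()) {
  p <- modifyList(list(fpkmMin = 1, fcLow = 0.5, fcHigh = 2,
                       windowBp = 2000L,
                       bands = c(mono = 0.15, biLow = 0.30, biHigh = 0.70),
                       minReads = 10L, methBiasDelta = 0.3), params)
  if (is.data.frame(imprintList)) imprintList <- imprintList$gene_id
  ids <- intersect(imprintList, names(fpkmControl))

  expressed <- ids[fpkmControl[ids] > p$fpkmMin & fpkmTest[ids] > p$fpkmMin]
  assoc <- mapGenesToDmrs(genes, dmrs, windowBp = p$windowBp)
  dmrGenes <- assoc$gene_id[assoc$associated]
  stage2 <- intersect(expressed, dmrGenes)
  fc <- fpkmTest[stage2] / fpkmControl[stage2]
  stage3 <- stage2[fc > p$fcHigh | fc < p$fcLow]

  degRoute <- character(0)
  if (!is.null(deResults)) {
    degs <- deResults$gene_id[deResults$sig]
    degRoute <- intersect(intersect(degs, imprintList), dmrGenes)
  }

  allGenes <- genes$gene_id
  stage <- rep(NA_character_, length(allGenes))
  stage[allGenes %in% imprintList] <- "catalogue"
  stage[allGenes %in% expressed] <- "expressed_candidate"
  stage[allGenes %in% stage2] <- "dmr_associated"
  stage[allGenes %in% stage3] <- "fold_change_aberrant"
  stage[allGenes %in% degRoute] <- ifelse(
    allGenes[allGenes %in% degRoute] %in% stage3,
    "fold_change_aberrant", "de_imprinted")

  statC <- statT <- rep("not_evaluable", length(allGenes))
  loi <- rep(FALSE, length(allGenes))
  if (!is.null(allelic)) {
    i <- match(allGenes, allelic$gene_id)
    statC <- callAllelicStatus(allelic$fracControl[i], allelic$nControl[i],
                               p$bands, p$minReads)
    statT <- callAllelicStatus(allelic$fracTest[i], allelic$nTest[i],
                               p$bands, p$minReads)
    loi <- statC %in% c("maternal", "paternal") & statT == "biallelic"
  }
  if (!is.null(methBias)) {
    i <- match(allGenes, methBias$gene_id)
    biasC <- methBias$matControl[i] - methBias$patControl[i]
    biasT <- methBias$matTest[i] - methBias$patTest[i]
    methLoi <- !is.na(biasC) & biasC >= p$methBiasDelta &
      !is.na(biasT) & biasT < p$methBiasDelta
    loi <- loi | (methLoi & allGenes %in% imprintList)
  }
  calls <- data.frame(gene_id = allGenes, stage = stage,
                      statusControl = statC, statusTest = statT,
                      loi = loi,
                      dmrIds = assoc$dmrIds[match(allGenes, assoc$gene_id)],
                      stringsAsFactors = FALSE)
  list(stage1 = expressed, stage2 = stage2, stage3 = stage3,
       degRoute = degRoute, calls = calls)
}

#' Load the packaged synthetic imprinted-gene catalogue
#'
#' A small catalogue-style table (gene id and reported expressed allele)
#' emulating the structure of public imprinted-gene databases; users
#' normally substitute their own list.
#'
#' @return data.frame with `gene_id` and `expressed_allele`.
#' @export
imprintCatalogue <- function() {
  read.delim(system.file("extdata", "imprinted_genes_synthetic.tsv",
                         package = "alleleMeth"),
             stringsAsFactors = FALSE)
}
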