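test_that("FPKM follows the formula and rescaling invariances", {
  ## count 100, length 1000 bp, library 1e6 -> FPKM 100
  m <- matrix(c(100L, 0L), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  f <- computeFpkm(m, c(a = 1000, b = 500), librarySizes = 1e6)
  expect_equal(f["a", 1], 100)
  expect_equal(f["b", 1], 0)
  ## random matrix equals direct formula recomputation
  set.seed(3)
  cnt <- matrix(rpois(60, 50), nrow = 20,
                dimnames = list(sprintf("g%d", 1:20), NULL))
  len <- setNames(sample(500:5000, 20), rownames(cnt))
  libs <- colSums(cnt)
  f2 <- computeFpkm(cnt, len)
  for (j in 1:3)
    expect_equal(f2[, j], cnt[, j] / (len / 1e3) / (libs[j] / 1e6))
  ## joint library rescaling leaves FPKM unchanged
  f3 <- computeFpkm(cnt * 2L, len, librarySizes = libs * 2)
  expect_equal(f3, f2)
})

test_that("identical groups give log2FC 0 and no significant genes", {
  cnt <- matrix(rep(c(30L, 60L, 90L, 30L, 60L, 90L), each = 4), nrow = 4)
  rownames(cnt) <- sprintf("g%d", 1:4)
  de <- differentialExpression(cnt, factor(rep(c("A", "B"), each = 3)))
  expect_equal(de$log2FC, rep(0, 4))
  expect_false(any(de$sig))
  ## all-zero genes are excluded with a flag
  cnt0 <- rbind(cnt, zero = 0L)
  de0 <- differentialExpression(cnt0, factor(rep(c("A", "B"), each = 3)))
  expect_true(de0$excluded[de0$gene_id == "zero"])
  expect_true(is.na(de0$pvalue[de0$gene_id == "zero"]))
})

test_that("median-of-ratios normalization absorbs a doubled sample", {
  set.seed(12)
  cnt <- matrix(rnbinom(600, mu = 80, size = 10), ncol = 6,
                dimnames = list(sprintf("g%d", 1:100), NULL))
  g <- factor(rep(c("A", "B"), each = 3))
  de1 <- differentialExpression(cnt, g)
  cnt2 <- cnt
  cnt2[, 1] <- cnt2[, 1] * 2L
  de2 <- differentialExpression(cnt2, g)
  ## the doubled sample's size factor doubles relative to the others,
  ## so normalized counts agree up to one global constant and every
  ## fold-change estimate is unchanged
  s1 <- alleleMeth:::.sizeFactors(cnt)
  s2 <- alleleMeth:::.sizeFactors(cnt2)
  expect_equal((s2 / s1)[1] / (s2 / s1)[2], 2, tolerance = 1e-9)
  expect_equal(de1$log2FC, de2$log2FC, tolerance = 1e-9)
})

test_that("planted 4-fold genes are detected with high sensitivity", {
  sens <- fpr <- numeric(5)
  for (s in 1:5) {
    set.seed(100 + s)
    nNull <- 400; nDE <- 40
    mu <- exp(runif(nNull + nDE, log(20), log(500)))
    muB <- mu; muB[seq_len(nDE)] <- mu[seq_len(nDE)] * 4
    cnt <- cbind(
      matrix(rnbinom(3 * length(mu), mu = rep(mu, 3), size = 10), ncol = 3),
      matrix(rnbinom(3 * length(mu), mu = rep(muB, 3), size = 10), ncol = 3))
    rownames(cnt) <- sprintf("g%03d", seq_along(mu))
    de <- differentialExpression(cnt, factor(rep(c("A", "B"), each = 3)))
    sens[s] <- mean(de$sig[seq_len(nDE)])
    fpr[s] <- mean(de$sig[-seq_len(nDE)])
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.02)
})

test_that("the NB Wald engine agrees in direction with DESeq2 on a fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  mu <- c(rep(50, 10), rep(50, 40))
  muB <- mu; muB[1:10] <- 250
  cnt <- cbind(
    matrix(rnbinom(3 * 50, mu = rep(mu, 3), size = 20), ncol = 3),
    matrix(rnbinom(3 * 50, mu = rep(muB, 3), size = 20), ncol = 3))
  rownames(cnt) <- sprintf("g%02d", 1:50)
  g <- factor(rep(c("A", "B"), each = 3))
  de <- differentialExpression(cnt, g)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, S4Vectors::DataFrame(condition = g), ~condition)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  ## size factors and fold-change direction agree (independent cross-check)
  expect_equal(unname(.sizeFactorsOracle <- DESeq2::sizeFactors(
    DESeq2::estimateSizeFactors(dds))),
    unname(alleleMeth:::.sizeFactors(cnt)), tolerance = 1e-6)
  expect_equal(sign(de$log2FC[1:10]), sign(res$log2FoldChange[1:10]))
  expect_true(all(res$padj[1:10] < 0.01 & de$pvalue[1:10] < 0.01))
})

test_that("allelic status bands behave as configured", {
  expect_identical(callAllelicStatus(0.02, 100), "paternal")
  expect_identical(callAllelicStatus(0.5, 100), "biallelic")
  expect_identical(callAllelicStatus(0.98, 100), "maternal")
  expect_identical(callAllelicStatus(0.22, 100), "not_evaluable")
  expect_identical(callAllelicStatus(0.5, 5), "not_evaluable")
  ## simulated monoallelic gene: paternal call in >= 99% of seeds
  calls <- vapply(1:200, function(s) {
    set.seed(s)
    callAllelicStatus(rbinom(1, 50, 0.05) / 50, 50)
  }, character(1))
  expect_gte(mean(calls == "paternal"), 0.99)
})

test_that("cascade stages are nested and recover planted LOI genes", {
  set.seed(61)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1000L, by = 6000L, length.out = 20L),
                             width = 3000L),
    strand = "+", gene_id = sprintf("g%02d", 1:20))
  imprintList <- sprintf("g%02d", 1:8)
  fpC <- setNames(rep(10, 20), genes$gene_id)
  fpT <- fpC
  fpC["g03"] <- 0.5                    # not reliably expressed
  fpT[c("g01", "g02")] <- 50           # aberrant fold change
  dmr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(GenomicRanges::start(genes)[c(1, 2, 4)] + 100L,
                             width = 500L),
    nCpGs = 30L, nSigCpGs = 30L, meanDiff = -0.4, direction = "hypo")
  names(dmr) <- sprintf("DMR%03d", 1:3)
  dmrs <- new("DMRSet", dmr)
  allelic <- data.frame(gene_id = genes$gene_id,
                        fracControl = 0.5, nControl = 100L,
                        fracTest = 0.5, nTest = 100L)
  allelic$fracControl[1:2] <- 0.05     # paternal in control
  cc <- candidateCascade(imprintList, fpC, fpT, genes, dmrs,
                         allelic = allelic)
  expect_true(all(cc$stage3 %in% cc$stage2))
  expect_true(all(cc$stage2 %in% cc$stage1))
  expect_false("g03" %in% cc$stage1)   # FPKM floor removes it
  expect_setequal(cc$stage2, c("g01", "g02", "g04"))
  expect_setequal(cc$stage3, c("g01", "g02"))
  expect_setequal(cc$calls$gene_id[cc$calls$loi], c("g01", "g02"))
  ## empty imprint list empties every stage
  cc0 <- candidateCascade(character(0), fpC, fpT, genes, dmrs)
  expect_length(cc0$stage1, 0)
  expect_length(cc0$stage3, 0)
})

test_that("LOI never fires when both conditions share an allelic distribution", {
  fires <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 100L
    allelic <- data.frame(gene_id = "g",
                          fracControl = rbinom(1, n, 0.5) / n, nControl = n,
                          fracTest = rbinom(1, n, 0.5) / n, nTest = n)
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 1000L),
                                    strand = "+", gene_id = "g")
    cc <- candidateCascade("g", c(g = 10), c(g = 10), genes,
                           new("DMRSet", GenomicRanges::GRanges(
                             nCpGs = integer(0), nSigCpGs = integer(0),
                             meanDiff = numeric(0),
                             direction = character(0))),
                           allelic = allelic)
    any(cc$calls$loi)
  }, logical(1))
  expect_identical(sum(fires), 0L)
})

test_that("the packaged imprint catalogue loads with the expected shape", {
  cat <- imprintCatalogue()
  expect_true(all(c("gene_id", "expressed_allele") %in% names(cat)))
  expect_gt(nrow(cat), 20)
})
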