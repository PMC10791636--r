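test_that("per-CpG exact test reproduces known p-values", {
  ## identical proportions at equal depth
  expect_equal(cpgTest(5L, 5L, 5L, 5L), 1)
  ## [[10,0],[0,10]]: p = 2 / choose(20,10)
  expect_equal(cpgTest(10L, 0L, 0L, 10L), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(cpgTest(0L, 0L, 1L, 1L), "at least one read")
})

test_that("per-CpG test matches the independent exact-test oracle", {
  set.seed(77)
  n <- 300
  mA <- rpois(n, 8); uA <- rpois(n, 8) + 1L
  mB <- rpois(n, 4); uB <- rpois(n, 10) + 1L
  got <- cpgTest(mA, uA, mB, uB)
  want <- mapply(oracleFisherP, mA, uA, mB, uB)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("identical tables yield no DMRs; sub-threshold regions drop out", {
  hg <- tinyHybrid(seed = 41L)
  a <- simulateCpGTable(hg, "control", seed = 1L)
  expect_length(segmentDmrs(a, a), 0)
  ## a planted region with too few CpGs (below minCpGs) is not emitted
  shortSpec <- data.frame(kind = "somatic_hypo", length = 300L,
                          levelA = 0.65, levelB = 0.15, lost = FALSE)
  hgS <- simulateHybridGenomes(simConfig(
    genomeLength = 5e4L, nChromosomes = 1L, snpRate = 0,
    dmrSpecs = shortSpec, depth = 30, rngSeed = 42L))
  nCpGsPlanted <- sum(truthCpg(hgS)$pos >=
                        GenomicRanges::start(plantedDmrs(hgS)) &
                      truthCpg(hgS)$pos <= GenomicRanges::end(plantedDmrs(hgS)))
  expect_lt(nCpGsPlanted, 25)
  d <- segmentDmrs(simulateCpGTable(hgS, "control", seed = 3L),
                   simulateCpGTable(hgS, "test", seed = 4L))
  expect_length(d, 0)
})

test_that("planted regions are recovered with matching direction", {
  specs <- data.frame(kind = c("somatic_hypo", "somatic_hyper"),
                      length = 800L, levelA = c(0.65, 0.15),
                      levelB = c(0.15, 0.65), lost = FALSE)
  hg <- simulateHybridGenomes(simConfig(
    genomeLength = 2e5L, nChromosomes = 1L, snpRate = 0, dmrSpecs = specs,
    depth = 30, rngSeed = 43L))
  d <- segmentDmrs(simulateCpGTable(hg, "control"),
                   simulateCpGTable(hg, "test"))
  pd <- plantedDmrs(hg)
  expect_length(d, 2)
  ov <- GenomicRanges::findOverlaps(d, pd)
  expect_length(ov, 2)
  hit <- pd[S4Vectors::subjectHits(ov)]
  expect_identical(
    d$direction[S4Vectors::queryHits(ov)],
    ifelse(hit$kind == "somatic_hypo", "hypo", "hyper"))
  ## every emitted DMR independently satisfies all three thresholds
  expect_true(all(d$nCpGs >= 25 & d$nSigCpGs >= 25 & abs(d$meanDiff) >= 0.25))
  ## disjoint and sorted
  expect_false(S4Vectors::isSorted(GenomicRanges::start(d)) == FALSE)
  expect_length(GenomicRanges::findOverlaps(d, drop.self = TRUE), 0)
})

test_that("swapping conditions flips every direction with |diff| preserved", {
  specs <- data.frame(kind = "somatic_hypo", length = 800L,
                      levelA = 0.7, levelB = 0.2, lost = FALSE)
  hg <- simulateHybridGenomes(simConfig(
    genomeLength = 1e5L, nChromosomes = 1L, snpRate = 0, dmrSpecs = specs,
    depth = 30, rngSeed = 44L))
  a <- simulateCpGTable(hg, "control")
  b <- simulateCpGTable(hg, "test")
  d1 <- segmentDmrs(a, b)
  d2 <- segmentDmrs(b, a)
  expect_identical(length(d1), length(d2))
  expect_identical(GenomicRanges::start(d1), GenomicRanges::start(d2))
  expect_identical(unname(c(hypo = "hyper", hyper = "hypo")[d1$direction]),
                   d2$direction)
  expect_equal(d1$meanDiff, -d2$meanDiff)
})

test_that("raising minMeanDiff never increases the DMR count", {
  hg <- simulateHybridGenomes(simConfig(
    genomeLength = 1e5L, nChromosomes = 1L, snpRate = 0,
    dmrSpecs = data.frame(kind = c("somatic_hypo", "somatic_hyper"),
                          length = 800L, levelA = c(0.65, 0.3),
                          levelB = c(0.35, 0.62), lost = FALSE),
    depth = 30, rngSeed = 45L))
  a <- simulateCpGTable(hg, "control")
  b <- simulateCpGTable(hg, "test")
  counts <- vapply(c(0.05, 0.25, 0.4), function(md)
    length(segmentDmrs(a, b, dmrCallParams(minMeanDiff = md))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("DMR annotation matches the brute-force interval oracle", {
  set.seed(88)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sort(sample.int(9e4, 8)) , width = 4000L),
    strand = sample(c("+", "-"), 8, TRUE),
    gene_id = sprintf("g%02d", 1:8))
  st <- sample.int(1e5, 120)
  dmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 500L))
  expect_identical(annotateDmrs(dmrs, genes), oracleAnnotate(dmrs, genes))
  ## DMR on an empty contig is intergenic
  far <- GenomicRanges::GRanges("chrEmpty", IRanges::IRanges(10L, 400L))
  expect_identical(annotateDmrs(far, genes), "intergenic")
  ## with an exon table, a mid-gene DMR outside exons is intronic
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000L, 20000L),
                              strand = "+", gene_id = "g1")
  ex <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(10000L, 19000L),
                                                width = 500L),
                               gene_id = "g1")
  dm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(14000L, 14500L))
  expect_identical(annotateDmrs(dm, g, exons = ex), "intron")
})

test_that("summary and gene association behave on hand-built inputs", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100L, 1000L),
                                                width = c(100L, 300L)),
                               nCpGs = c(30L, 40L), nSigCpGs = c(30L, 40L),
                               meanDiff = c(-0.4, 0.5),
                               direction = c("hypo", "hyper"))
  names(gr) <- c("DMR001", "DMR002")
  d <- new("DMRSet", gr)
  s <- dmrSummary(d)
  expect_identical(s$n, c(1L, 1L))
  expect_equal(s$meanLength, c(100, 300))
  expect_identical(dmrSummary(d[0])$n, c(0L, 0L))
  ## gene association: inside, within window, beyond window
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(80L, 1500L, 10000L), width = 200L),
    strand = "+", gene_id = c("in", "near", "far"))
  m <- mapGenesToDmrs(genes, d, windowBp = 300L)
  expect_identical(m$associated, c(TRUE, TRUE, FALSE))
  ## brute-force overlap agreement on random layouts
  set.seed(9)
  rg <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(sample.int(5e4, 40),
                                                width = 400L),
                               strand = "+",
                               gene_id = sprintf("r%02d", 1:40))
  m2 <- mapGenesToDmrs(rg, d, windowBp = 250L)
  brute <- vapply(seq_along(rg), function(i) {
    any(GenomicRanges::start(d) <= GenomicRanges::end(rg)[i] + 250 &
        GenomicRanges::end(d) >= GenomicRanges::start(rg)[i] - 250)
  }, logical(1))
  expect_identical(m2$associated, brute)
})
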