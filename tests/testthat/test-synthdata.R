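test_that("haplotypes differ exactly at planted SNPs and never in CpGs", {
  hg <- tinyHybrid(seed = 3L, snpRate = 3e-3)
  m <- strsplit(as.character(maternalGenome(hg)[["chr1"]]), "")[[1]]
  p <- strsplit(as.character(paternalGenome(hg)[["chr1"]]), "")[[1]]
  snps <- truthSnps(hg)
  expect_gt(nrow(snps), 0)
  ## exhaustive: positions that differ == truth SNP set
  expect_identical(which(m != p), snps$pos)
  expect_true(all(m[snps$pos] == snps$maternal))
  expect_true(all(p[snps$pos] == snps$paternal))
  ## no SNP inside a CpG dinucleotide on either haplotype
  for (chars in list(m, p)) {
    L <- length(chars)
    cpgC <- which(chars[-L] == "C" & chars[-1] == "G")
    expect_length(intersect(snps$pos, c(cpgC, cpgC + 1L)), 0)
  }
  ## both haplotypes share one CpG landscape
  mC <- which(m[-length(m)] == "C" & m[-1] == "G")
  pC <- which(p[-length(p)] == "C" & p[-1] == "G")
  expect_identical(mC, pC)
  expect_identical(mC, truthCpg(hg)$pos)
})

test_that("snpRate 0 gives identical haplotypes and an empty truth set", {
  hg <- tinyHybrid(seed = 5L, snpRate = 0)
  expect_identical(as.character(maternalGenome(hg)),
                   as.character(paternalGenome(hg)))
  expect_identical(nrow(truthSnps(hg)), 0L)
})

test_that("SNP count falls in the central 99.9% binomial interval", {
  hg <- simulateHybridGenomes(simConfig(genomeLength = 1e5L,
                                        nChromosomes = 1L, snpRate = 1e-3,
                                        rngSeed = 11L))
  bounds <- qbinom(c(0.0005, 0.9995), 1e5L, 1e-3)
  n <- nrow(truthSnps(hg))
  expect_gte(n, bounds[1])
  expect_lte(n, bounds[2])
})

test_that("generator is byte-deterministic and planted regions lie in-bounds", {
  a <- tinyHybrid(seed = 9L)
  b <- tinyHybrid(seed = 9L)
  expect_identical(as.character(maternalGenome(a)),
                   as.character(maternalGenome(b)))
  expect_identical(truthSnps(a), truthSnps(b))
  expect_identical(truthCpg(a), truthCpg(b))
  expect_true(all(GenomicRanges::end(plantedDmrs(a)) <= 4e4L))
  expect_true(all(GenomicRanges::start(plantedDmrs(a)) >= 1L))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(genomeLength = 0), "positive")
  expect_error(simConfig(snpRate = 1.2), "snpRate")
  expect_error(simConfig(backgroundMeth = -0.1), "backgroundMeth")
  expect_error(simConfig(dmrSpecs = data.frame(
    kind = "somatic_hypo", length = 1000L, levelA = 0.2, levelB = 0.6,
    lost = FALSE)), "levelB < levelA")
  hg <- tinyHybrid()
  cfgBad <- hg@config
  expect_error(simulateBisulfiteReads(
    simulateHybridGenomes(simConfig(genomeLength = 50L, nChromosomes = 1L,
                                    readLength = 100L, dmrSpecs = data.frame()[0, ],
                                    snpRate = 0))),
    "read_length")
})

test_that("bisulfite reads honour forced conversion regimes", {
  ## conversion 1, methylation 0 everywhere: every genomic C reads T (top)
  hg0 <- simulateHybridGenomes(simConfig(
    genomeLength = 5e3L, nChromosomes = 1L, snpRate = 0,
    backgroundMeth = 0, dmrSpecs = defaultDmrSpecs()[0, ],
    conversionEfficiency = 1, lambdaFraction = 0, depth = 5, rngSeed = 2L))
  rd <- simulateBisulfiteReads(hg0, "control")
  topReads <- rd[rd$strand == "top" & rd$allele == "maternal", ]
  expect_false(any(grepl("C", topReads$seq)))
  botReads <- rd[rd$strand == "bottom" & rd$allele == "maternal", ]
  expect_false(any(grepl("G", botReads$seq)))

  ## methylation 1 everywhere: all CpG cytosines stay C
  hg1 <- simulateHybridGenomes(simConfig(
    genomeLength = 5e3L, nChromosomes = 1L, snpRate = 0,
    backgroundMeth = 1, dmrSpecs = defaultDmrSpecs()[0, ],
    conversionEfficiency = 1, lambdaFraction = 0, depth = 10, rngSeed = 2L))
  rd1 <- simulateBisulfiteReads(hg1, "control")
  cp <- callCpgMethylation(rd1, maternalGenome(hg1))
  expect_true(all(cp$unmeth == 0))
})

test_that("observed methylated fraction matches truth within 3 SE at depth", {
  hg <- simulateHybridGenomes(simConfig(
    genomeLength = 2e3L, nChromosomes = 1L, snpRate = 0,
    backgroundMeth = 0.7, dmrSpecs = defaultDmrSpecs()[0, ],
    conversionEfficiency = 1, lambdaFraction = 0, depth = 1000,
    rngSeed = 4L))
  rd <- simulateBisulfiteReads(hg, "control")
  cp <- callCpgMethylation(rd, maternalGenome(hg))
  i <- which.max(cp$meth + cp$unmeth)
  n <- cp$meth[i] + cp$unmeth[i]
  expect_gt(n, 300)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(cp$meth[i] / n - 0.7), 3 * se)
})

test_that("read count conserves depth x genome / read length; spike-in pure", {
  cfg <- simConfig(genomeLength = 2e4L, nChromosomes = 2L, depth = 10,
                   readLength = 100L, lambdaFraction = 0.05, rngSeed = 6L,
                   conversionEfficiency = 1)
  hg <- simulateHybridGenomes(cfg)
  rd <- simulateBisulfiteReads(hg, "control")
  expect_equal(nrow(rd), round(10 * 4e4 / 100))
  lam <- rd[rd$chrom == "lambda", ]
  expect_equal(nrow(lam), round(0.05 * nrow(rd)))
  ## all lambda cytosine calls are unmethylated at full conversion
  cp <- callCpgMethylation(lam, hg@lambda)
  expect_true(all(cp$meth == 0))
})

test_that("RNA-seq simulator honours fractions, Poisson limit, null log2FC", {
  hg <- tinyHybrid(seed = 8L, snpRate = 5e-3)
  genes <- makeGeneModels(hg, nGenes = 5L, geneLength = 2000L)
  spec <- data.frame(gene_id = genes$gene_id, meanControl = 200,
                     meanTest = 200, dispersion = 0,
                     matFracControl = 1, matFracTest = 0.5,
                     nInformative = 50L)
  rna <- simulateRnaSeq(hg, genes, spec, nReplicates = 30L)
  ## maternal fraction 1 -> all control allelic reads maternal
  ctl <- rna$reads[rna$reads$condition == "control", ]
  expect_true(all(ctl$allele == "maternal"))
  ## dispersion 0, large n: sample mean within 3 SE of the Poisson mean
  m <- rowMeans(rna$counts[, rna$groups == "control"])
  se <- sqrt(200 / 30)
  expect_true(all(abs(m - 200) < 3.5 * se))
  ## equal configured means -> planted log2FC = 0
  expect_true(all(spec$meanTest / spec$meanControl == 1))
  expect_error(simulateRnaSeq(hg, genes, transform(spec, dispersion = -1)),
               "dispersion")
})

test_that("gestation simulator: point mass, median recovery, determinism", {
  pt <- simulateGestation(10L, list(g = list(dist = "point", day = 40)),
                          seed = 1L)
  expect_true(all(pt$day == 40))
  ## exponential with median m: empirical median close at n = 500
  m <- 50
  ex <- simulateGestation(500L, list(g = list(dist = "exponential",
                                              rate = log(2) / m)), seed = 3L)
  ## 99.9% CI of the median of n exponential draws via order statistics
  qs <- qbeta(c(0.0005, 0.9995), 250, 251)
  ci <- -m / log(2) * log(1 - qs)
  expect_gt(median(ex$day), ci[1])
  expect_lt(median(ex$day), ci[2])
  a <- simulateGestation(20L, seed = 5L)
  b <- simulateGestation(20L, seed = 5L)
  expect_identical(a, b)
})

test_that("slide simulator records exact truth areas and rejects bad specs", {
  s0 <- simulatePlacentaSlide(slideSpec(nParticles = 0L), seed = 1L)
  expect_equal(s0$truth$calcAreaMm2, 0)
  sl <- simulatePlacentaSlide(slideSpec(nParticles = 5L), seed = 2L)
  expect_equal(sl$truth$calcAreaMm2, sum(sl$truth$particleAreasMm2))
  ## pixelated ellipse area close to pi * a * b * pixelSize^2
  expect_equal(sl$truth$totalAreaMm2, pi * 160 * 90 * 0.01^2,
               tolerance = 0.01)
  expect_error(slideSpec(semiA = 300L), "within the frame")
  expect_error(slideSpec(particleRadius = c(-1, 2)), "non-negative")
})
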