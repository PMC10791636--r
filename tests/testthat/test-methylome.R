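test_that("CpG extraction recovers truth levels and merges strands", {
  hg <- simulateHybridGenomes(simConfig(
    genomeLength = 5e3L, nChromosomes = 1L, snpRate = 0,
    backgroundMeth = 0.7, dmrSpecs = defaultDmrSpecs()[0, ],
    conversionEfficiency = 1, lambdaFraction = 0, depth = 60, rngSeed = 31L))
  rd <- simulateBisulfiteReads(hg, "control")
  cp <- callCpgMethylation(rd, maternalGenome(hg))
  lev <- sum(cp$meth) / sum(cp$meth + cp$unmeth)
  se <- sqrt(0.7 * 0.3 / sum(cp$meth + cp$unmeth))
  expect_lt(abs(lev - 0.7), 3 * se)
  ## strand-resolved counts sum to the merged counts
  cpS <- callCpgMethylation(rd, maternalGenome(hg), mergeStrands = FALSE)
  pooledMerged <- sum(cp$meth + cp$unmeth)
  pooledStrand <- sum(cpS$meth + cpS$unmeth)
  expect_identical(pooledMerged, pooledStrand)
})

test_that("allelic per-CpG counts decompose the all-reads counts", {
  hg <- tinyHybrid(seed = 33L, snpRate = 5e-3, depth = 10)
  rd <- simulateBisulfiteReads(hg, "control")
  rd <- rd[rd$chrom != "lambda", ]
  sp <- splitReads(rd, truthSnps(hg), mode = "bisulfite")
  ref <- maternalGenome(hg)
  all <- callCpgMethylation(rd, ref)
  parts <- lapply(c("maternal", "paternal", "unassigned", "conflicting"),
                  function(v) callCpgMethylation(sp[[v]], ref))
  expect_identical(sum(all$meth + all$unmeth),
                   as.integer(sum(vapply(parts,
                                         function(p) sum(p$meth + p$unmeth),
                                         numeric(1)))))
})

test_that("conversion efficiency estimates are exact in forced regimes", {
  ## all spike-in Cs read as T -> efficiency 1
  tab <- data.frame(chrom = "lambda", pos = 1:10, meth = 0L, unmeth = 50L)
  expect_equal(conversionEfficiency(tab)$efficiency, 1)
  ## zero coverage -> explicit not-evaluable status
  none <- conversionEfficiency(tab[0, ])
  expect_identical(none$status, "no_coverage")
  expect_true(is.na(none$efficiency))
})

test_that("simulated 0.99 conversion is recovered within 3 SE", {
  hg <- simulateHybridGenomes(simConfig(
    genomeLength = 5e3L, nChromosomes = 1L, snpRate = 0,
    dmrSpecs = defaultDmrSpecs()[0, ], conversionEfficiency = 0.99,
    lambdaFraction = 0.5, lambdaLength = 3e4L, depth = 40, rngSeed = 35L))
  rd <- simulateBisulfiteReads(hg, "control")
  lam <- callCpgMethylation(rd[rd$chrom == "lambda", ], hg@lambda)
  est <- conversionEfficiency(lam)
  expect_gt(est$nCalls, 5000)
  se <- sqrt(0.99 * 0.01 / est$nCalls)
  expect_lt(abs(est$efficiency - 0.99), 3 * se)
})

test_that("window levels equal brute-force re-aggregation", {
  set.seed(44)
  n <- 500
  tab <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                    pos = sample.int(5e4, n),
                    meth = rbinom(n, 20, 0.5))
  tab$unmeth <- 20L - tab$meth
  tab <- tab[!duplicated(tab[c("chrom", "pos")]), ]
  w <- windowLevels(tab, windowSize = 10000L)
  for (i in seq_len(nrow(w))) {
    sel <- tab$chrom == w$chrom[i] & tab$pos > w$start[i] &
      tab$pos <= w$end[i]
    expect_equal(w$level[i], mean(tab$meth[sel] / 20))
    expect_identical(w$nCpGs[i], sum(sel))
  }
  ## constant levels give constant windows; empty windows omitted
  flat <- data.frame(chrom = "chr1", pos = c(5L, 15000L), meth = 5L,
                     unmeth = 5L)
  wf <- windowLevels(flat, windowSize = 10000L)
  expect_identical(nrow(wf), 2L)        # window 2 (10-20 kb) empty of CpGs? no: pos 15000 occupies it
  expect_true(all(wf$level == 0.5))
})

test_that("global levels: weighted vs unweighted and brute-force sums", {
  ## two CpGs 10/10 and 0/10 -> weighted 0.5, unweighted 0.5
  tab <- data.frame(chrom = "c", pos = c(1L, 10L), meth = c(10L, 0L),
                    unmeth = c(0L, 10L))
  g <- globalLevel(tab)
  expect_equal(g$weighted, 0.5)
  expect_equal(g$unweighted, 0.5)
  ## uneven coverage separates the two; brute force agreement
  set.seed(7)
  tab2 <- data.frame(chrom = "c", pos = 1:200,
                     meth = rbinom(200, 30, 0.3),
                     unmeth = rbinom(200, 30, 0.6))
  g2 <- globalLevel(tab2)
  expect_equal(g2$weighted, sum(tab2$meth) / sum(tab2$meth + tab2$unmeth))
  expect_equal(g2$unweighted,
               mean(tab2$meth / (tab2$meth + tab2$unmeth)))
})

test_that("window-set comparison: identity, exact small-sample case, trend", {
  same <- compareWindowSets(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p.value, 0.65)
  ## {1,2,3} vs {4,5,6}: exact two-sided p = 2 / C(6,3) * ... = 0.1
  ex <- compareWindowSets(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ex$p.value, 0.1)
  ## p decreases monotonically with the shift (averaged over seeds)
  ps <- vapply(c(0, 0.3, 0.8), function(shift) {
    mean(vapply(1:5, function(s) {
      set.seed(s)
      compareWindowSets(rnorm(60), rnorm(60) + shift)$p.value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(compareWindowSets(numeric(0), 1:3), "non-empty")
})

test_that("metaprofile: flat input, planted contrast, union additivity", {
  set.seed(55)
  tab <- data.frame(chrom = "chr1", pos = sort(sample.int(5e4, 2000)),
                    meth = 3L, unmeth = 7L)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(10000L, 30000L), width = 2000L))
  ## flat methylome -> flat profile
  prof <- regionMetaprofile(regions, tab)
  expect_true(all(abs(prof$level - 0.3) < 1e-9, na.rm = TRUE))
  ## planted high-methylation bodies exceed flanks
  tab2 <- tab
  inBody <- (tab2$pos >= 10000 & tab2$pos <= 11999) |
    (tab2$pos >= 30000 & tab2$pos <= 31999)
  tab2$meth[inBody] <- 9L; tab2$unmeth[inBody] <- 1L
  p2 <- regionMetaprofile(regions, tab2)
  expect_gt(min(p2$level[p2$zone == "body"], na.rm = TRUE),
            max(p2$level[p2$zone != "body"], na.rm = TRUE))
  ## single region equals direct binning; union equals weighted average
  pA <- regionMetaprofile(regions[1], tab2)
  pB <- regionMetaprofile(regions[2], tab2)
  pU <- regionMetaprofile(regions, tab2)
  wAvg <- (pA$level * pA$nCpGs + pB$level * pB$nCpGs) /
    (pA$nCpGs + pB$nCpGs)
  expect_equal(pU$level, wAvg)
  expect_equal(pU$nCpGs, pA$nCpGs + pB$nCpGs)
})
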