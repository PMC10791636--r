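#' Run the full synthetic-study pipeline end to end
#'
#' Generates a hybrid cross from `config`, writes every artifact the
#' analysis consumes (haplotype FASTA, truth SNP TSV/BED, parental VCF
#' subset, masked reference, aligned SAM-subset reads, per-CpG bedGraphs,
#' DMR BED, DE and imprinting tables, slide PNGs with morphometry, and
#' gestation tables with survival statistics), then runs each analysis
#' stage on the written inputs. A provenance manifest records the config
#' hash, seed and an md5 checksum per output file.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @param outcomes optional embryo-transfer count table for
#'   [outcomeRates()].
#' @return (invisibly) a list with the main in-memory results: `hybrid`,
#'   `snps`, `dmrs`, `de`, `cascade`, `morphometry`, `gestation`,
#'   `conversion`, `manifest`.
#' @export
runPipeline <- function(config = simConfig(), outDir, outcomes = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outDir, ...)

  ## --- synthetic inputs -------------------------------------------------
  hybrid <- simulateHybridGenomes(config)
  writeFasta(maternalGenome(hybrid), pth("maternal.fa"))
  writeFasta(paternalGenome(hybrid), pth("paternal.fa"))
  writeFasta(hybrid@lambda, pth("lambda.fa"))
  writeTsv(truthSnps(hybrid), pth("truth_snps.tsv"))

  ## --- variants: VCF round trip, hard filter, informative SNPs, mask ---
  truth <- truthSnps(hybrid)
  vcf <- data.frame(chrom = truth$chrom, pos = truth$pos,
                    ref = truth$maternal, alt = truth$paternal,
                    gtMaternal = paste(truth$maternal, truth$maternal, sep = "/"),
                    gtPaternal = paste(truth$paternal, truth$paternal, sep = "/"),
                    QD = 25, MQ = 60, FS = 1, SOR = 1,
                    MQRankSum = 0, ReadPosRankSum = 0)
  writeVcfSubset(vcf, pth("parents.vcf"))
  flt <- hardFilterVariants(readVcfSubset(pth("parents.vcf")))
  snps <- selectInformativeSnps(flt$pass)
  msk <- maskGenome(maternalGenome(hybrid), snps)
  writeFasta(msk$masked, pth("reference_masked.fa"))
  writeBed(msk$bed, pth("snps.bed"))

  ## --- bisulfite arm ----------------------------------------------------
  ref <- c(maternalGenome(hybrid), hybrid@lambda)
  bsControl <- simulateBisulfiteReads(hybrid, "control")
  bsTest <- simulateBisulfiteReads(hybrid, "test")
  writeSamSubset(bsControl, pth("bs_control.sam"))
  writeSamSubset(bsTest, pth("bs_test.sam"))
  cpgControl <- callCpgMethylation(bsControl, ref)
  cpgTest <- callCpgMethylation(bsTest, ref)
  conv <- conversionEfficiency(cpgControl[cpgControl$chrom == "lambda", ])
  cpgControl <- cpgControl[cpgControl$chrom != "lambda", ]
  cpgTest <- cpgTest[cpgTest$chrom != "lambda", ]
  writeBedGraph(cpgControl, pth("meth_control.bedGraph"))
  writeBedGraph(cpgTest, pth("meth_test.bedGraph"))

  splitTest <- splitReads(bsTest[bsTest$chrom != "lambda", ], snps,
                          mode = "bisulfite")
  writeTsv(splitTest$summary, pth("split_summary.tsv"))
  for (al in c("maternal", "paternal"))
    writeSamSubset(splitTest[[al]], pth(paste0("bs_test_", al, ".sam")))

  dmrs <- segmentDmrs(cpgControl, cpgTest)
  dmrBed <- data.frame(chrom = as.character(seqnames(dmrs)),
                       start = start(dmrs) - 1L, end = end(dmrs),
                       name = dmrs$direction,
                       score = round(1000 * abs(dmrs$meanDiff)),
                       strand = ".")
  writeBed(dmrBed, pth("dmrs.bed"))
  writeTsv(dmrSummary(dmrs), pth("dmr_summary.tsv"))

  ## --- expression arm ---------------------------------------------------
  ## imprinted genes span the planted imprint regions (their DMRs), the
  ## rest of the gene models are placed independently
  pd <- plantedDmrs(hybrid)
  imp <- pd[pd$kind == "maternal_imprint"]
  impGenes <- GenomicRanges::resize(imp, width(imp) + 2000L, fix = "center")
  S4Vectors::mcols(impGenes) <- NULL
  GenomicRanges::strand(impGenes) <- "+"
  impGenes$gene_id <- sprintf("impGene%02d", seq_along(impGenes))
  total <- sum(Biostrings::width(hybrid@maternal))
  base <- makeGeneModels(hybrid, nGenes = max(4L, min(20L, total %/% 10000L)))
  base <- base[!IRanges::overlapsAny(base, impGenes, ignore.strand = TRUE)]
  genes <- GenomicRanges::sort(c(impGenes, base), ignore.strand = TRUE)
  kinds <- rep("none", length(genes))
  i <- match(impGenes$gene_id, genes$gene_id)
  kinds[i] <- ifelse(imp$lost, "imprint_lost", "imprint_kept")
  spec <- data.frame(gene_id = genes$gene_id,
                     meanControl = 100, meanTest = 100, dispersion = 0.1,
                     matFracControl = 0.5, matFracTest = 0.5,
                     nInformative = 60L)
  spec$matFracControl[kinds != "none"] <- 0.05
  spec$matFracTest[kinds == "imprint_kept"] <- 0.05
  spec$meanTest[kinds == "imprint_lost"] <- 400
  rna <- simulateRnaSeq(hybrid, genes, spec)
  writeTsv(as.data.frame(rna$counts), pth("counts.tsv"))
  de <- differentialExpression(rna$counts, rna$groups)
  writeTsv(de, pth("de_results.tsv"))

  fpkm <- computeFpkm(rna$counts, setNames(width(genes), genes$gene_id))
  fpC <- rowMeans(fpkm[, rna$groups == "control", drop = FALSE])
  fpT <- rowMeans(fpkm[, rna$groups == "test", drop = FALSE])

  allelicTab <- do.call(rbind, lapply(c("control", "test"), function(cond) {
    rd <- rna$reads[rna$reads$condition == cond, , drop = FALSE]
    asg <- classifyReads(rd, snps, mode = "rna")
    af <- allelicFraction(rd, asg)
    af$condition <- cond
    af
  }))
  allelic <- merge(
    setNames(allelicTab[allelicTab$condition == "control",
                        c("gene_id", "maternalFraction", "nMaternal", "nPaternal")],
             c("gene_id", "fracControl", "mC", "pC")),
    setNames(allelicTab[allelicTab$condition == "test",
                        c("gene_id", "maternalFraction", "nMaternal", "nPaternal")],
             c("gene_id", "fracTest", "mT", "pT")))
  allelic$nControl <- allelic$mC + allelic$pC
  allelic$nTest <- allelic$mT + allelic$pT

  imprintList <- genes$gene_id[kinds != "none"]
  cascade <- candidateCascade(imprintList, fpC, fpT, genes, dmrs,
                              deResults = de, allelic = allelic)
  writeTsv(cascade$calls, pth("imprint_calls.tsv"))

  ## --- morphometry arm --------------------------------------------------
  slides <- lapply(1:3, function(i)
    simulatePlacentaSlide(slideSpec(), seed = config@rngSeed + i))
  for (i in seq_along(slides))
    writeSlidePng(slides[[i]]$image, pth(sprintf("slide_%d.png", i)))
  morpho <- computeCalcification(slides)
  writeTsv(data.frame(CCI = morpho$CCI, CCN = morpho$CCN,
                      nDots = morpho$nDots,
                      thicknessMm = morpho$thicknessMm),
           pth("morphometry.tsv"))

  ## --- gestational outcomes --------------------------------------------
  gest <- simulateGestation(30L, seed = config@rngSeed)
  writeTsv(gest, pth("gestation.tsv"))
  gA <- gest[gest$group == "ICSI", ]
  gB <- gest[gest$group == "SCNT", ]
  km <- list(ICSI = kmEstimate(gA$day, gA$event, "ICSI"),
             SCNT = kmEstimate(gB$day, gB$event, "SCNT"))
  lr <- logrankTest(gA$day, gB$day, gA$event, gB$event)
  writeTsv(data.frame(group = c("ICSI", "SCNT"),
                      median = c(km$ICSI$median, km$SCNT$median),
                      logrank_chisq = lr$chisq, logrank_p = lr$p.value),
           pth("survival.tsv"))
  if (!is.null(outcomes)) writeTsv(outcomeRates(outcomes), pth("rates.tsv"))

  ## --- provenance manifest ----------------------------------------------
  cfgFile <- tempfile()
  dput(lapply(slotNames(config), function(s) methods::slot(config, s)),
       file = cfgFile)
  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  manifest <- list(
    package = as.character(utils::packageVersion("alleleMeth")),
    seed = config@rngSeed,
    configMd5 = unname(tools::md5sum(cfgFile)),
    files = as.list(setNames(unname(tools::md5sum(file.path(outDir, files))),
                             files)))
  unlink(cfgFile)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(hybrid = hybrid, snps = snps, dmrs = dmrs, de = de,
                 cascade = cascade, morphometry = morpho,
                 gestation = gest, km = km, logrank = lr,
                 conversion = conv, manifest = manifest))
}
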