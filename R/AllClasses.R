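#' SimConfig: parameters of the synthetic hybrid-cross study
#'
#' Holds every knob of the synthetic-data generator: the toy genome, the
#' parental SNP rate, the CpG methylation landscape including planted DMRs,
#' sequencing depth and read length, bisulfite conversion efficiency and the
#' unmethylated lambda spike-in fraction. The defaults emulate a hybrid
#' two-parent cross with maternally imprinted regions plus somatic-memory
#' hypo/hyper regions.
#'
#' @slot genomeLength bp per chromosome.
#' @slot nChromosomes number of autosome-like contigs.
#' @slot snpRate per-bp probability of a homozygous-divergent parental SNP.
#' @slot backgroundMeth CpG methylation probability per allele outside
#'   planted regions, in [0, 1].
#' @slot dmrSpecs data.frame with columns `kind` (one of
#'   `maternal_imprint`, `somatic_hypo`, `somatic_hyper`), `length` (bp),
#'   `levelA`, `levelB` and `lost` (logical). For `maternal_imprint`,
#'   `levelA`/`levelB` are the maternal/paternal allele levels and `lost`
#'   marks imprints whose maternal methylation is lost in the test
#'   condition; for somatic kinds they are the control/test condition levels
#'   applied to both alleles.
#' @slot depth mean read coverage.
#' @slot readLength read length in bp.
#' @slot conversionEfficiency probability that an unmethylated C reads as T.
#' @slot lambdaFraction fraction of reads drawn from the fully unmethylated
#'   spike-in contig.
#' @slot lambdaLength length of the spike-in contig (bp).
#' @slot nonDirectional logical; reserved flag for non-directional bisulfite
#'   libraries (the default directional model emits original-top and
#'   original-bottom strand reads only).
#' @slot rngSeed master integer seed; identical config + seed gives
#'   byte-identical outputs.
#'
#' @seealso [simConfig()] for the user-facing constructor.
#' @export
setClass("SimConfig", representation(
  genomeLength         = "integer",
  nChromosomes         = "integer",
  snpRate              = "numeric",
  backgroundMeth       = "numeric",
  dmrSpecs             = "data.frame",
  depth                = "numeric",
  readLength           = "integer",
  conversionEfficiency = "numeric",
  lambdaFraction       = "numeric",
  lambdaLength         = "integer",
  nonDirectional       = "logical",
  rngSeed              = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be positive")
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be positive")
  if (!.isProb(object@snpRate)) msg <- c(msg, "snpRate must be in [0,1]")
  if (!.isProb(object@backgroundMeth))
    msg <- c(msg, "backgroundMeth must be in [0,1]")
  if (!.isProb(object@conversionEfficiency))
    msg <- c(msg, "conversionEfficiency must be in [0,1]")
  if (!.isProb(object@lambdaFraction))
    msg <- c(msg, "lambdaFraction must be in [0,1]")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (object@lambdaLength < 1L) msg <- c(msg, "lambdaLength must be positive")
  ds <- object@dmrSpecs
  need <- c("kind", "length", "levelA", "levelB", "lost")
  if (nrow(ds) > 0) {
    if (!all(need %in% names(ds)))
      msg <- c(msg, paste("dmrSpecs needs columns:", paste(need, collapse = ", ")))
    else {
      if (!all(ds$kind %in% c("maternal_imprint", "somatic_hypo", "somatic_hyper")))
        msg <- c(msg, "unknown dmrSpecs kind")
      if (any(ds$length < 2)) msg <- c(msg, "dmrSpecs length must be >= 2 bp")
      if (any(ds$levelA < 0 | ds$levelA > 1 | ds$levelB < 0 | ds$levelB > 1))
        msg <- c(msg, "dmrSpecs levels must be in [0,1]")
      hypo <- ds$kind == "somatic_hypo"
      hyper <- ds$kind == "somatic_hyper"
      if (any(ds$levelB[hypo] >= ds$levelA[hypo]))
        msg <- c(msg, "somatic_hypo requires levelB < levelA")
      if (any(ds$levelB[hyper] <= ds$levelA[hyper]))
        msg <- c(msg, "somatic_hyper requires levelB > levelA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param genomeLength bp per chromosome (default 100 kb).
#' @param nChromosomes number of contigs (default 2).
#' @param snpRate homozygous-divergent SNP rate per bp (default 2e-3, a
#'   generous hybrid-cross density so most reads overlap an informative SNP).
#' @param backgroundMeth background CpG methylation level (default 0.4,
#'   blastocyst-like global methylation).
#' @param dmrSpecs planted-region table; see [SimConfig-class]. The default
#'   plants two maternal imprints (0.9/0.1, one lost in the test condition),
#'   one somatic hypo region (0.65 -> 0.15) and one somatic hyper region
#'   (0.15 -> 0.65), each 2 kb.
#' @param depth mean coverage (default 30).
#' @param readLength read length (default 100).
#' @param conversionEfficiency bisulfite conversion efficiency (default 0.99).
#' @param lambdaFraction spike-in read fraction (default 0.01).
#' @param lambdaLength spike-in contig length (default 20 kb).
#' @param nonDirectional reserved library-protocol flag (default FALSE).
#' @param rngSeed master seed (default 1).
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(genomeLength = 5e4, rngSeed = 7)
#' cfg
#' @export
simConfig <- function(genomeLength = 1e5L,
                      nChromosomes = 2L,
                      snpRate = 2e-3,
                      backgroundMeth = 0.4,
                      dmrSpecs = defaultDmrSpecs(),
                      depth = 30,
                      readLength = 100L,
                      conversionEfficiency = 0.99,
                      lambdaFraction = 0.01,
                      lambdaLength = 2e4L,
                      nonDirectional = FALSE,
                      rngSeed = 1L) {
  if (genomeLength < 1) stop("genomeLength must be positive")
  new("SimConfig",
      genomeLength = as.integer(genomeLength),
      nChromosomes = as.integer(nChromosomes),
      snpRate = snpRate,
      backgroundMeth = backgroundMeth,
      dmrSpecs = as.data.frame(dmrSpecs),
      depth = depth,
      readLength = as.integer(readLength),
      conversionEfficiency = conversionEfficiency,
      lambdaFraction = lambdaFraction,
      lambdaLength = as.integer(lambdaLength),
      nonDirectional = isTRUE(nonDirectional),
      rngSeed = as.integer(rngSeed))
}

#' Default planted-region table for the synthetic methylome
#'
#' @return data.frame of planted DMR specifications (see [SimConfig-class]).
#' @export
defaultDmrSpecs <- function() {
  data.frame(
    kind   = c("maternal_imprint", "maternal_imprint",
               "somatic_hypo", "somatic_hyper"),
    length = c(2000L, 2000L, 2000L, 2000L),
    levelA = c(0.9, 0.9, 0.65, 0.15),
    levelB = c(0.1, 0.1, 0.15, 0.65),
    lost   = c(TRUE, FALSE, FALSE, FALSE)
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: hybrid-cross synthetic study\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp (+%d bp lambda spike-in)\n",
              object@nChromosomes, object@genomeLength, object@lambdaLength))
  cat(sprintf("  snpRate: %g /bp; backgroundMeth: %.2f\n",
              object@snpRate, object@backgroundMeth))
  cat(sprintf("  depth: %gx; readLength: %d; conversion: %.3f; lambdaFraction: %.3f\n",
              object@depth, object@readLength, object@conversionEfficiency,
              object@lambdaFraction))
  cat(sprintf("  planted regions: %d; seed: %d\n",
              nrow(object@dmrSpecs), object@rngSeed))
})

#' HybridGenome: two parental haplotypes plus the simulation truth set
#'
#' The output container of [simulateHybridGenomes()]. The maternal haplotype
#' doubles as the reference; the paternal haplotype differs only at the
#' planted homozygous-divergent SNPs (which never fall inside a CpG
#' dinucleotide, so the CpG landscape is shared). The truth set records the
#' SNPs, the planted DMR intervals and the per-CpG, per-allele methylation
#' probabilities under the control and test conditions.
#'
#' @slot maternal,paternal [Biostrings::DNAStringSet] haplotypes.
#' @slot lambda unmethylated spike-in contig as a DNAStringSet of length 1.
#' @slot snps data.frame with `chrom`, `pos` (1-based), `maternal`,
#'   `paternal` alleles.
#' @slot cpg data.frame with `chrom`, `pos` (1-based C of each top-strand
#'   CpG) and truth levels `matControl`, `patControl`, `matTest`, `patTest`.
#' @slot dmrs [GenomicRanges::GRanges] of planted regions with metadata
#'   columns `kind`, `levelA`, `levelB`, `lost`.
#' @slot config the generating [SimConfig-class].
#' @export
setClass("HybridGenome", representation(
  maternal = "DNAStringSet",
  paternal = "DNAStringSet",
  lambda   = "DNAStringSet",
  snps     = "data.frame",
  cpg      = "data.frame",
  dmrs     = "GRanges",
  config   = "SimConfig"
))

setValidity("HybridGenome", function(object) {
  msg <- character()
  if (!identical(names(object@maternal), names(object@paternal)))
    msg <- c(msg, "haplotypes must share chromosome names")
  if (!identical(Biostrings::width(object@maternal),
                 Biostrings::width(object@paternal)))
    msg <- c(msg, "haplotypes must share chromosome lengths")
  if (nrow(object@snps) > 0 &&
      any(object@snps$maternal == object@snps$paternal))
    msg <- c(msg, "truth SNPs must differ between the parents")
  if (length(object@dmrs) > 0) {
    lens <- setNames(Biostrings::width(object@maternal), names(object@maternal))
    ends <- GenomicRanges::end(object@dmrs)
    chr <- as.character(GenomicRanges::seqnames(object@dmrs))
    if (any(ends > lens[chr]))
      msg <- c(msg, "planted DMR intervals must lie within their chromosome")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HybridGenome", function(object) {
  cat("HybridGenome\n")
  cat(sprintf("  %d chromosome(s), %s bp total; %d truth SNPs; %d CpGs\n",
              length(object@maternal),
              format(sum(Biostrings::width(object@maternal)), big.mark = ","),
              nrow(object@snps), nrow(object@cpg)))
  cat(sprintf("  planted regions: %d (%s)\n", length(object@dmrs),
              paste(unique(object@dmrs$kind), collapse = ", ")))
})

#' @describeIn HybridGenome maternal haplotype accessor
#' @param x a HybridGenome.
#' @export
maternalGenome <- function(x) { stopifnot(is(x, "HybridGenome")); x@maternal }

#' @describeIn HybridGenome paternal haplotype accessor
#' @export
paternalGenome <- function(x) { stopifnot(is(x, "HybridGenome")); x@paternal }

#' @describeIn HybridGenome truth SNP table accessor
#' @export
truthSnps <- function(x) { stopifnot(is(x, "HybridGenome")); x@snps }

#' @describeIn HybridGenome per-CpG truth methylation accessor
#' @export
truthCpg <- function(x) { stopifnot(is(x, "HybridGenome")); x@cpg }

#' @describeIn HybridGenome planted DMR intervals accessor
#' @export
plantedDmrs <- function(x) { stopifnot(is(x, "HybridGenome")); x@dmrs }

#' DMRSet: called differentially methylated regions
#'
#' A [GenomicRanges::GRanges] subclass; each range is one DMR with metadata
#' columns `nCpGs`, `nSigCpGs`, `meanDiff` (test minus control, signed) and
#' `direction` (`hypo` when the test condition is lower, `hyper` when
#' higher). Ranges use 1-based closed GRanges coordinates internally and are
#' exported as 0-based half-open BED.
#'
#' @export
setClass("DMRSet", contains = "GRanges")

setValidity("DMRSet", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object)
  need <- c("nCpGs", "nSigCpGs", "meanDiff", "direction")
  if (!all(need %in% names(mc)))
    return(paste("DMRSet needs metadata columns:", paste(need, collapse = ", ")))
  if (length(object) > 0) {
    if (any(mc$nSigCpGs > mc$nCpGs))
      msg <- c(msg, "nSigCpGs cannot exceed nCpGs")
    if (any(mc$direction == "hypo" & mc$meanDiff >= 0) ||
        any(mc$direction == "hyper" & mc$meanDiff <= 0))
      msg <- c(msg, "direction must match the sign of meanDiff")
    if (any(GenomicRanges::width(object) < 2))
      msg <- c(msg, "DMRs must span at least 2 bp")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DMRSet direction accessor
#' @param x a DMRSet.
#' @export
dmrDirection <- function(x) { stopifnot(is(x, "DMRSet")); x$direction }

setMethod("show", "DMRSet", function(object) {
  cat(sprintf("DMRSet with %d region(s): %d hypo, %d hyper\n",
              length(object),
              sum(object$direction == "hypo"),
              sum(object$direction == "hyper")))
  if (length(object) > 0) methods::callNextMethod()
})
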