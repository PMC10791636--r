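#' Simulate a hybrid two-parent genome with known truth
#'
#' Generates a maternal haplotype (which doubles as the reference), a
#' paternal haplotype differing only at planted homozygous-divergent SNPs,
#' an unmethylated lambda spike-in contig, and a per-CpG, per-allele
#' methylation truth table under a control (normally fertilized) and a test
#' (cloned) condition. SNPs are never placed inside a CpG dinucleotide on
#' either haplotype, so both haplotypes share one CpG landscape and no SNP
#' can be confounded with bisulfite conversion at a scored cytosine.
#'
#' @param config a [SimConfig-class].
#' @return a [HybridGenome-class].
#' @examples
#' hg <- simulateHybridGenomes(simConfig(genomeLength = 2e4, rngSeed = 3))
#' hg
#' @export
simulateHybridGenomes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(stageSeed(config@rngSeed, "genome"))
  bases <- c("A", "C", "G", "T")
  L <- config@genomeLength
  chroms <- paste0("chr", seq_len(config@nChromosomes))

  matSeqs <- patSeqs <- setNames(vector("list", length(chroms)), chroms)
  snpList <- vector("list", length(chroms))
  cpgList <- vector("list", length(chroms))

  for (ci in seq_along(chroms)) {
    ref <- sample(bases, L, replace = TRUE)
    ## candidate SNP positions (keep 1 bp off both ends for context checks)
    cand <- which(runif(L) < config@snpRate)
    cand <- cand[cand > 1 & cand < L]
    ## exclude candidates inside a reference CpG dinucleotide
    inCpG <- (ref[cand] == "C" & ref[cand + 1L] == "G") |
             (ref[cand] == "G" & ref[cand - 1L] == "C")
    cand <- cand[!inCpG]
    alt <- character(length(cand))
    keep <- logical(length(cand))
    for (k in seq_along(cand)) {
      p <- cand[k]
      allowed <- setdiff(bases, ref[p])
      if (ref[p + 1L] == "G") allowed <- setdiff(allowed, "C")
      if (ref[p - 1L] == "C") allowed <- setdiff(allowed, "G")
      if (length(allowed) > 0) {
        alt[k] <- allowed[sample.int(length(allowed), 1L)]
        keep[k] <- TRUE
      }
    }
    cand <- cand[keep]; alt <- alt[keep]
    pat <- ref
    pat[cand] <- alt
    matSeqs[[ci]] <- paste(ref, collapse = "")
    patSeqs[[ci]] <- paste(pat, collapse = "")
    snpList[[ci]] <- data.frame(
      chrom = rep(chroms[ci], length(cand)), pos = cand,
      maternal = ref[cand], paternal = alt,
      stringsAsFactors = FALSE)
    cpgPos <- which(ref[-L] == "C" & ref[-1L] == "G")
    cpgList[[ci]] <- data.frame(chrom = chroms[ci], pos = cpgPos,
                                stringsAsFactors = FALSE)
  }
  lambdaSeq <- paste(sample(bases, config@lambdaLength, replace = TRUE),
                     collapse = "")

  snps <- do.call(rbind, snpList)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  cpg <- do.call(rbind, cpgList)

  ## plant DMR intervals (own substream: re-planting never perturbs the genome)
  set.seed(stageSeed(config@rngSeed, "methylome"))
  specs <- config@dmrSpecs
  dmrs <- GenomicRanges::GRanges()
  if (nrow(specs) > 0) {
    placedChrom <- character(0); placedStart <- placedEnd <- integer(0)
    for (i in seq_len(nrow(specs))) {
      len <- as.integer(specs$length[i])
      if (len > L) stop("planted region longer than the chromosome")
      ok <- FALSE
      for (try in seq_len(1000L)) {
        chr <- chroms[sample.int(length(chroms), 1L)]
        st <- sample.int(L - len + 1L, 1L)
        en <- st + len - 1L
        ## keep planted regions separated by >= 2 kb so calls cannot merge
        clash <- any(placedChrom == chr &
                     placedStart <= en + 2000L & placedEnd >= st - 2000L)
        hasCpg <- any(cpg$chrom == chr & cpg$pos >= st & cpg$pos <= en)
        if (!clash && hasCpg) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place planted region ", i,
                    " without overlap; enlarge the genome")
      placedChrom <- c(placedChrom, chr)
      placedStart <- c(placedStart, st); placedEnd <- c(placedEnd, en)
    }
    dmrs <- GenomicRanges::GRanges(
      placedChrom, IRanges::IRanges(placedStart, placedEnd),
      kind = specs$kind, levelA = specs$levelA, levelB = specs$levelB,
      lost = specs$lost)
  }

  ## per-CpG, per-allele truth levels under both conditions
  bg <- config@backgroundMeth
  cpg$matControl <- cpg$patControl <- cpg$matTest <- cpg$patTest <- bg
  if (length(dmrs) > 0) {
    for (i in seq_along(dmrs)) {
      chr <- as.character(seqnames(dmrs)[i])
      idx <- which(cpg$chrom == chr & cpg$pos >= start(dmrs)[i] &
                   cpg$pos <= end(dmrs)[i])
      kind <- dmrs$kind[i]; la <- dmrs$levelA[i]; lb <- dmrs$levelB[i]
      if (kind == "maternal_imprint") {
        cpg$matControl[idx] <- la; cpg$patControl[idx] <- lb
        if (isTRUE(dmrs$lost[i])) {
          cpg$matTest[idx] <- lb; cpg$patTest[idx] <- lb
        } else {
          cpg$matTest[idx] <- la; cpg$patTest[idx] <- lb
        }
      } else {  # somatic memory: both alleles move together
        cpg$matControl[idx] <- la; cpg$patControl[idx] <- la
        cpg$matTest[idx]    <- lb; cpg$patTest[idx]    <- lb
      }
    }
  }

  new("HybridGenome",
      maternal = DNAStringSet(unlist(matSeqs)),
      paternal = DNAStringSet(unlist(patSeqs)),
      lambda = DNAStringSet(c(lambda = lambdaSeq)),
      snps = snps, cpg = cpg, dmrs = dmrs, config = config)
}

#' Simulate a per-CpG methylation count table directly
#'
#' Draws per-CpG coverage (Poisson around the configured depth) and
#' methylated counts (binomial at the truth level) without going through
#' read simulation; the fast route for genome-scale DMR-calling studies.
#' With `allele = "all"` the coverage is split evenly between the two
#' alleles and each half is drawn at its own truth level.
#'
#' @param hybrid a [HybridGenome-class].
#' @param condition `"control"` or `"test"`.
#' @param allele `"all"`, `"maternal"` or `"paternal"`.
#' @param depth mean coverage; defaults to the config depth.
#' @param seed integer seed; defaults to a substream of the config seed
#'   offset by condition and allele so paired tables are independent draws.
#' @return data.frame with `chrom`, `pos` (1-based top-strand C), `meth`,
#'   `unmeth`; zero-coverage CpGs are omitted.
#' @export
simulateCpGTable <- function(hybrid,
                             condition = c("control", "test"),
                             allele = c("all", "maternal", "paternal"),
                             depth = NULL,
                             seed = NULL) {
  stopifnot(is(hybrid, "HybridGenome"))
  condition <- match.arg(condition)
  allele <- match.arg(allele)
  if (is.null(depth)) depth <- hybrid@config@depth
  if (is.null(seed))
    seed <- stageSeed(hybrid@config@rngSeed, "cpgtable") +
      10L * match(condition, c("control", "test")) +
      match(allele, c("all", "maternal", "paternal"))
  set.seed(seed)
  cpg <- hybrid@cpg
  n <- nrow(cpg)
  cov <- rpois(n, depth)
  lm <- if (condition == "control") cpg$matControl else cpg$matTest
  lp <- if (condition == "control") cpg$patControl else cpg$patTest
  if (allele == "maternal") {
    meth <- rbinom(n, cov, lm)
  } else if (allele == "paternal") {
    meth <- rbinom(n, cov, lp)
  } else {
    covM <- rbinom(n, cov, 0.5)
    meth <- rbinom(n, covM, lm) + rbinom(n, cov - covM, lp)
  }
  out <- data.frame(chrom = cpg$chrom, pos = cpg$pos,
                    meth = meth, unmeth = cov - meth,
                    stringsAsFactors = FALSE)
  out[cov > 0, , drop = FALSE]
}
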