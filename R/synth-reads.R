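#' Simulate aligned bisulfite reads with ground-truth tags
#'
#' Directional whole-genome bisulfite model: each read originates from the
#' maternal or paternal haplotype (50/50), from the original top or original
#' bottom strand (50/50), and is reported on the reference frame like an
#' aligned SAM record (match-only CIGAR). On the top strand every
#' unmethylated cytosine is converted C->T with the configured conversion
#' efficiency; on the bottom strand the mirror conversion appears as G->A on
#' the reference frame. CpG cytosines are methylated according to the
#' per-site, per-allele truth levels of the given condition; all non-CpG
#' cytosines are unmethylated. A configurable fraction of reads is drawn
#' from the always-unmethylated lambda spike-in contig.
#'
#' @param hybrid a [HybridGenome-class].
#' @param condition `"control"` or `"test"` truth methylome.
#' @param seed integer seed (default: a substream of the config seed).
#' @return data.frame of aligned read records with columns `qname`, `flag`
#'   (0 top strand, 16 bottom strand), `chrom`, `pos` (1-based), `cigar`,
#'   `seq`, plus truth tags `strand` (`top`/`bottom`) and `allele`
#'   (`maternal`/`paternal`/`lambda`).
#' @export
simulateBisulfiteReads <- function(hybrid,
                                   condition = c("control", "test"),
                                   seed = NULL) {
  stopifnot(is(hybrid, "HybridGenome"))
  condition <- match.arg(condition)
  cfg <- hybrid@config
  rl <- cfg@readLength
  if (rl > cfg@genomeLength)
    stop("read_length exceeds genome_length")
  if (is.null(seed))
    seed <- stageSeed(cfg@rngSeed, "bsreads") +
      match(condition, c("control", "test"))
  set.seed(seed)

  lens <- setNames(Biostrings::width(hybrid@maternal), names(hybrid@maternal))
  nTotal <- max(1L, round(cfg@depth * sum(lens) / rl))
  nLambda <- round(cfg@lambdaFraction * nTotal)
  nGenomic <- nTotal - nLambda

  chroms <- sample(names(lens), nGenomic, replace = TRUE,
                   prob = lens / sum(lens))
  starts <- integer(nGenomic)
  for (chr in unique(chroms)) {
    i <- chroms == chr
    starts[i] <- sample.int(lens[[chr]] - rl + 1L, sum(i), replace = TRUE)
  }
  alleles <- sample(c("maternal", "paternal"), nGenomic, replace = TRUE)
  strands <- sample(c("top", "bottom"), nGenomic, replace = TRUE)

  ## per-bp truth level lookup for each allele
  lvlCol <- if (condition == "control") c("matControl", "patControl")
            else c("matTest", "patTest")

  seqs <- character(nGenomic)
  hapCharsCache <- list()
  for (chr in unique(chroms)) {
    for (al in c("maternal", "paternal")) {
      sel <- which(chroms == chr & alleles == al)
      if (!length(sel)) next
      key <- paste0(chr, ".", al)
      if (is.null(hapCharsCache[[key]])) {
        hap <- if (al == "maternal") hybrid@maternal[[chr]] else
          hybrid@paternal[[chr]]
        hapCharsCache[[key]] <- strsplit(as.character(hap), "")[[1]]
      }
      hc <- hapCharsCache[[key]]
      lvl <- rep(NA_real_, lens[[chr]])
      ci <- hybrid@cpg$chrom == chr
      lvl[hybrid@cpg$pos[ci]] <-
        hybrid@cpg[[lvlCol[if (al == "maternal") 1L else 2L]]][ci]
      seqs[sel] <- .bisulfiteConvert(hc, lvl, starts[sel], rl,
                                     strands[sel], cfg@conversionEfficiency,
                                     lens[[chr]])
    }
  }

  out <- data.frame(
    qname = sprintf("read%07d", seq_len(nGenomic + nLambda)),
    flag = integer(nGenomic + nLambda),
    chrom = c(chroms, rep("lambda", nLambda)),
    pos = integer(nGenomic + nLambda),
    cigar = paste0(rl, "M"),
    seq = character(nGenomic + nLambda),
    strand = character(nGenomic + nLambda),
    allele = c(alleles, rep("lambda", nLambda)),
    stringsAsFactors = FALSE)
  out$pos[seq_len(nGenomic)] <- starts
  out$seq[seq_len(nGenomic)] <- seqs
  out$strand[seq_len(nGenomic)] <- strands

  if (nLambda > 0) {
    llen <- Biostrings::width(hybrid@lambda)[1]
    if (rl > llen) stop("read_length exceeds the spike-in contig length")
    lst <- sample.int(llen - rl + 1L, nLambda, replace = TRUE)
    lstr <- sample(c("top", "bottom"), nLambda, replace = TRUE)
    lc <- strsplit(as.character(hybrid@lambda[[1]]), "")[[1]]
    lseq <- .bisulfiteConvert(lc, rep(NA_real_, llen), lst, rl, lstr,
                              cfg@conversionEfficiency, llen)
    idx <- nGenomic + seq_len(nLambda)
    out$pos[idx] <- lst
    out$seq[idx] <- lseq
    out$strand[idx] <- lstr
  }
  out$flag <- ifelse(out$strand == "bottom", 16L, 0L)
  out
}

## Vectorized bisulfite conversion of a batch of same-length reads on one
## haplotype. `lvl` is the per-bp CpG methylation level (NA outside CpG Cs).
.bisulfiteConvert <- function(hapChars, lvl, starts, rl, strands, convEff,
                              chromLen) {
  n <- length(starts)
  idx <- matrix(rep(starts, each = rl) + seq_len(rl) - 1L, nrow = rl)
  m <- matrix(hapChars[idx], nrow = rl)
  topCol <- strands == "top"

  ## top strand: C -> T on unmethylated cytosines
  ent <- which(m == "C" & rep(topCol, each = rl))
  if (length(ent)) {
    p <- idx[ent]
    isCpG <- p < chromLen & hapChars[pmin(p + 1L, chromLen)] == "G"
    pm <- ifelse(isCpG, lvl[p], 0)
    pm[is.na(pm)] <- 0
    meth <- runif(length(ent)) < pm
    conv <- !meth & (runif(length(ent)) < convEff)
    m[ent[conv]] <- "T"
  }
  ## bottom strand: G -> A on the reference frame
  ent <- which(m == "G" & rep(!topCol, each = rl))
  if (length(ent)) {
    p <- idx[ent]
    isCpG <- p > 1L & hapChars[pmax(p - 1L, 1L)] == "C"
    pm <- ifelse(isCpG, lvl[pmax(p - 1L, 1L)], 0)
    pm[is.na(pm)] <- 0
    meth <- runif(length(ent)) < pm
    conv <- !meth & (runif(length(ent)) < convEff)
    m[ent[conv]] <- "A"
  }
  do.call(paste0, lapply(seq_len(rl), function(k) m[k, , drop = TRUE]))
}

#' Place non-overlapping gene models on the synthetic genome
#'
#' @param hybrid a [HybridGenome-class].
#' @param nGenes number of genes to place.
#' @param geneLength gene length in bp.
#' @param seed integer seed (default: substream of the config seed).
#' @return [GenomicRanges::GRanges] with strand and a `gene_id` column.
#' @export
makeGeneModels <- function(hybrid, nGenes = 20L, geneLength = 3000L,
                           seed = NULL) {
  stopifnot(is(hybrid, "HybridGenome"))
  if (is.null(seed)) seed <- stageSeed(hybrid@config@rngSeed, "rnaseq")
  set.seed(seed)
  lens <- setNames(Biostrings::width(hybrid@maternal), names(hybrid@maternal))
  placedChrom <- character(0); placedStart <- integer(0)
  for (i in seq_len(nGenes)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      chr <- sample(names(lens), 1L, prob = lens / sum(lens))
      st <- sample.int(lens[[chr]] - geneLength + 1L, 1L)
      clash <- any(placedChrom == chr &
                   abs(placedStart - st) < geneLength + 200L)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", nGenes, " non-overlapping genes; ",
                  "enlarge the genome or shorten the genes")
    placedChrom <- c(placedChrom, chr); placedStart <- c(placedStart, st)
  }
  gr <- GenomicRanges::GRanges(
    placedChrom,
    IRanges::IRanges(placedStart, width = geneLength),
    strand = sample(c("+", "-"), nGenes, replace = TRUE),
    gene_id = sprintf("gene%03d", seq_len(nGenes)))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate RNA-seq counts and allelic read records
#'
#' Counts are negative-binomial per gene and group (`dispersion = 0` gives
#' the Poisson limit). Allelic read records are drawn from the maternal or
#' paternal haplotype with the configured maternal fraction; each record is
#' anchored on an informative SNP inside its gene (emulating the
#' SNP-overlapping subset of an RNA alignment, which is the only subset an
#' allele splitter can use). Genes without SNPs yield no allelic records.
#'
#' @param hybrid a [HybridGenome-class].
#' @param genes gene models from [makeGeneModels()].
#' @param spec data.frame keyed by `gene_id` with columns `meanControl`,
#'   `meanTest`, `dispersion`, `matFracControl`, `matFracTest`,
#'   `nInformative` (allelic read records per gene and condition).
#' @param nReplicates replicates per group (default 3).
#' @param readLength allelic read length (default: config read length).
#' @param seed integer seed (default: substream of the config seed).
#' @return list with `counts` (genes x samples matrix, colnames
#'   `control_1..`, `test_1..`), `groups` (factor), and `reads` (a
#'   data.frame of aligned records with truth `allele` and `gene_id`,
#'   `condition` columns).
#' @export
simulateRnaSeq <- function(hybrid, genes, spec, nReplicates = 3L,
                           readLength = NULL, seed = NULL) {
  stopifnot(is(hybrid, "HybridGenome"))
  if (any(spec$dispersion < 0)) stop("dispersion must be non-negative")
  if (is.null(seed)) seed <- stageSeed(hybrid@config@rngSeed, "rnaseq") + 1L
  if (is.null(readLength)) readLength <- hybrid@config@readLength
  set.seed(seed)
  ids <- genes$gene_id
  spec <- spec[match(ids, spec$gene_id), , drop = FALSE]
  ng <- length(ids)

  drawCounts <- function(mu, disp) {
    if (disp == 0) rpois(1L, mu) else rnbinom(1L, mu = mu, size = 1 / disp)
  }
  counts <- matrix(0L, nrow = ng, ncol = 2L * nReplicates,
                   dimnames = list(ids, c(paste0("control_", seq_len(nReplicates)),
                                          paste0("test_", seq_len(nReplicates)))))
  for (g in seq_len(ng)) {
    for (r in seq_len(nReplicates)) {
      counts[g, r] <- drawCounts(spec$meanControl[g], spec$dispersion[g])
      counts[g, nReplicates + r] <- drawCounts(spec$meanTest[g],
                                               spec$dispersion[g])
    }
  }
  groups <- factor(rep(c("control", "test"), each = nReplicates),
                   levels = c("control", "test"))

  ## allelic read records anchored on informative SNPs
  reads <- list()
  snps <- hybrid@snps
  lens <- setNames(Biostrings::width(hybrid@maternal), names(hybrid@maternal))
  for (g in seq_len(ng)) {
    nInf <- spec$nInformative[g]
    if (is.null(nInf) || is.na(nInf) || nInf < 1) next
    chr <- as.character(seqnames(genes)[g])
    gs <- start(genes)[g]; ge <- end(genes)[g]
    sp <- snps$pos[snps$chrom == chr & snps$pos >= gs & snps$pos <= ge]
    if (!length(sp)) next
    for (cond in c("control", "test")) {
      frac <- if (cond == "control") spec$matFracControl[g] else
        spec$matFracTest[g]
      al <- ifelse(runif(nInf) < frac, "maternal", "paternal")
      anchor <- sp[sample.int(length(sp), nInf, replace = TRUE)]
      st <- anchor - sample.int(readLength, nInf, replace = TRUE) + 1L
      st <- pmax(1L, pmin(st, lens[[chr]] - readLength + 1L))
      sq <- character(nInf)
      for (a in c("maternal", "paternal")) {
        i <- which(al == a)
        if (!length(i)) next
        hap <- if (a == "maternal") hybrid@maternal[[chr]] else
          hybrid@paternal[[chr]]
        sq[i] <- as.character(Biostrings::extractAt(
          hap, IRanges::IRanges(st[i], width = readLength)))
      }
      reads[[length(reads) + 1L]] <- data.frame(
        qname = sprintf("%s_%s_r%05d", ids[g], cond, seq_len(nInf)),
        flag = 0L, chrom = chr, pos = st,
        cigar = paste0(readLength, "M"), seq = sq,
        strand = "top", allele = al, gene_id = ids[g], condition = cond,
        stringsAsFactors = FALSE)
    }
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(qname = character(0), flag = integer(0), chrom = character(0),
               pos = integer(0), cigar = character(0), seq = character(0),
               strand = character(0), allele = character(0),
               gene_id = character(0), condition = character(0))
  list(counts = counts, groups = groups, reads = reads)
}

#' Simulate two-group gestational outcome (abortion-day) tables
#'
#' Event days are drawn from a per-group distribution: `"lognormal"`
#' (parameters `meanlog`, `sdlog`), `"exponential"` (`rate`) or `"point"`
#' (`day`). The default emulates a cloning-study contrast: test-group
#' abortions peaking early in gestation (around day 60) versus control
#' abortions late (around day 130).
#'
#' @param nPerGroup events per group (single value or per-group vector).
#' @param spec named list of per-group distribution specs; each a list with
#'   a `dist` element and its parameters.
#' @param seed integer seed.
#' @return data.frame with `subject`, `group`, `day`, `event` (all 1:
#'   abortion-time tables record events only).
#' @export
simulateGestation <- function(nPerGroup = 30L,
                              spec = defaultGestationSpec(),
                              seed = 1L) {
  set.seed(stageSeed(seed, "gestation"))
  groups <- names(spec)
  n <- rep_len(nPerGroup, length(groups))
  out <- list()
  for (i in seq_along(groups)) {
    s <- spec[[i]]
    day <- switch(s$dist,
      lognormal = {
        if (s$sdlog < 0) stop("sdlog must be non-negative")
        rlnorm(n[i], meanlog = s$meanlog, sdlog = s$sdlog)
      },
      exponential = {
        if (s$rate <= 0) stop("hazard rate must be positive")
        stats::rexp(n[i], rate = s$rate)
      },
      point = rep(s$day, n[i]),
      stop("unknown gestation distribution: ", s$dist))
    out[[i]] <- data.frame(
      subject = sprintf("%s_%03d", groups[i], seq_len(n[i])),
      group = groups[i], day = round(day, 1), event = 1L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @rdname simulateGestation
#' @export
defaultGestationSpec <- function() {
  list(
    ICSI = list(dist = "lognormal", meanlog = log(130), sdlog = 0.30),
    SCNT = list(dist = "lognormal", meanlog = log(60),  sdlog = 0.45)
  )
}
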