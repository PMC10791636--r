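## Independent oracle implementations used to cross-check the package's own
## routines. Each is written naively (loops, base primitives) and must stay
## independent of the code path it checks.

## two-sided Fisher p via stats::fisher.test (independent route)
oracleFisherP <- function(mA, uA, mB, uB) {
  stats::fisher.test(matrix(c(mA, uA, mB, uB), nrow = 2,
                            byrow = TRUE))$p.value
}

## naive Huang fuzzy-entropy criterion, evaluated level by level
oracleHuangCrit <- function(hist, t) {
  occ <- which(hist > 0) - 1L
  C <- max(occ) - min(occ)
  w0 <- s0 <- w1 <- s1 <- 0
  for (g in 0:255) {
    if (g <= t) { w0 <- w0 + hist[g + 1]; s0 <- s0 + g * hist[g + 1] }
    else { w1 <- w1 + hist[g + 1]; s1 <- s1 + g * hist[g + 1] }
  }
  if (w0 == 0 || w1 == 0) return(Inf)
  mu0 <- s0 / w0; mu1 <- s1 / w1
  tot <- 0
  for (g in 0:255) {
    if (hist[g + 1] == 0) next
    mu <- if (g <= t) mu0 else mu1
    u <- 1 / (1 + abs(g - mu) / C)
    h <- if (u <= 1e-12 || u >= 1 - 1e-12) 0 else
      -u * log(u) - (1 - u) * log(1 - u)
    tot <- tot + hist[g + 1] * h
  }
  tot
}

oracleHuang <- function(hist) {
  occ <- which(hist > 0) - 1L
  crit <- vapply(0:254, function(t) oracleHuangCrit(hist, t), numeric(1))
  crit[0:254 < min(occ) | 0:254 >= max(occ)] <- Inf
  which.min(crit) - 1L
}

## naive Yen maximum-correlation criterion
oracleYenCrit <- function(hist, t) {
  p <- hist / sum(hist)
  P1 <- sum(p[seq_len(t + 1)])
  if (P1 <= 0 || P1 >= 1) return(-Inf)
  G1 <- sum(p[seq_len(t + 1)]^2)
  G2 <- sum(p[(t + 2):256]^2)
  if (G1 <= 0 || G2 <= 0) return(-Inf)
  -log(G1 * G2) + 2 * log(P1 * (1 - P1))
}

oracleYen <- function(hist) {
  occ <- which(hist > 0) - 1L
  crit <- vapply(0:254, function(t) oracleYenCrit(hist, t), numeric(1))
  crit[0:254 < min(occ) | 0:254 >= max(occ)] <- -Inf
  which.max(crit) - 1L
}

## stack-based flood-fill connected-component labeling
oracleLabel <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- cur[1] + nb[k, 1]; cc <- cur[2] + nb[k, 2]
        if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

## brute-force midpoint annotation with explicit interval checks
oracleAnnotate <- function(dmrs, genes, promoterUp = 1000, promoterDown = 100,
                           ttsUp = 100, ttsDown = 1000) {
  out <- character(length(dmrs))
  for (i in seq_along(dmrs)) {
    chr <- as.character(GenomicRanges::seqnames(dmrs)[i])
    mid <- floor((GenomicRanges::start(dmrs)[i] +
                  GenomicRanges::end(dmrs)[i]) / 2)
    cat <- "intergenic"
    inProm <- inBody <- inTts <- FALSE
    for (g in seq_along(genes)) {
      if (as.character(GenomicRanges::seqnames(genes)[g]) != chr) next
      gs <- GenomicRanges::start(genes)[g]
      ge <- GenomicRanges::end(genes)[g]
      plus <- as.character(GenomicRanges::strand(genes)[g]) != "-"
      tss <- if (plus) gs else ge
      tes <- if (plus) ge else gs
      pLo <- if (plus) tss - promoterUp else tss - promoterDown
      pHi <- if (plus) tss + promoterDown else tss + promoterUp
      tLo <- if (plus) tes - ttsUp else tes - ttsDown
      tHi <- if (plus) tes + ttsDown else tes + ttsUp
      if (mid >= pLo && mid <= pHi) inProm <- TRUE
      if (mid >= gs && mid <= ge) inBody <- TRUE
      if (mid >= tLo && mid <= tHi) inTts <- TRUE
    }
    if (inProm) cat <- "promoter"
    else if (inBody) cat <- "exon"  # whole body = exonic when no exon table
    else if (inTts) cat <- "TTS"
    out[i] <- cat
  }
  out
}

## small reusable hybrid fixture
tinyHybrid <- function(seed = 7L, ...) {
  simulateHybridGenomes(simConfig(genomeLength = 4e4L, nChromosomes = 1L,
                                  rngSeed = seed, ...))
}
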