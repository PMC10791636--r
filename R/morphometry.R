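#' 256-bin histogram of an 8-bit image
#'
#' @param image numeric matrix with values in 0..255 (fractional values are
#'   rounded to the nearest level).
#' @return integer vector of length 256 (counts for levels 0..255).
#' @export
imageHistogram <- function(image) {
  g <- pmax(0L, pmin(255L, as.integer(round(image))))
  tabulate(g + 1L, nbins = 256L)
}

#' Huang fuzzy-entropy automatic threshold
#'
#' For every candidate threshold t the image is split into two fuzzy
#' classes with means mu0 (levels <= t) and mu1 (levels > t); each level's
#' membership is u = 1 / (1 + |g - mu_class| / C) with bandwidth C equal to
#' the span of the occupied histogram, and the Shannon entropy of the
#' memberships, weighted by the histogram, is minimized. Ties take the
#' lowest level. A constant image has no valid split and returns NA with a
#' degenerate status.
#'
#' @param hist 256-bin histogram (see [imageHistogram()]).
#' @return list with `threshold` (level in 0..254, or NA) and `status`
#'   (`"ok"` or `"degenerate"`).
#' @export
huangThreshold <- function(hist) {
  stopifnot(length(hist) == 256L)
  occ <- which(hist > 0)
  if (length(occ) < 2)
    return(list(threshold = NA_integer_, status = "degenerate"))
  fl <- occ[1] - 1L; ll <- occ[length(occ)] - 1L   # occupied level span
  C <- ll - fl                                     # membership bandwidth
  g <- 0:255
  W <- cumsum(hist)                # class-0 weight up to level t
  S <- cumsum(hist * g)            # class-0 first moment
  totW <- W[256]; totS <- S[256]
  crit <- rep(Inf, 255)            # crit[t + 1] for threshold level t
  for (t in fl:(ll - 1L)) {
    i <- t + 1L
    w0 <- W[i]; w1 <- totW - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- S[i] / w0
    mu1 <- (totS - S[i]) / w1
    u <- numeric(256)
    u[1:i] <- 1 / (1 + abs(g[1:i] - mu0) / C)
    u[(i + 1):256] <- 1 / (1 + abs(g[(i + 1):256] - mu1) / C)
    h <- -u * log(u) - (1 - u) * log(1 - u)
    h[u >= 1 - 1e-12 | u <= 1e-12] <- 0
    crit[i] <- sum(hist * h)
  }
  list(threshold = which.min(crit) - 1L, status = "ok")
}

#' Yen maximum-correlation automatic threshold
#'
#' Maximizes the Yen criterion
#' TC(t) = -log(G1(t) G2(t)) + 2 log(P(t) (1 - P(t))), where G1 and G2 are
#' the sums of squared normalized histogram entries below and above the
#' threshold and P is the cumulative probability. Ties take the lowest
#' level.
#'
#' @inheritParams huangThreshold
#' @return list with `threshold` and `status` as in [huangThreshold()].
#' @export
yenThreshold <- function(hist) {
  stopifnot(length(hist) == 256L)
  occ <- which(hist > 0)
  if (length(occ) < 2)
    return(list(threshold = NA_integer_, status = "degenerate"))
  p <- hist / sum(hist)
  P <- cumsum(p)
  G <- cumsum(p^2)
  totG <- G[256]
  fl <- occ[1] - 1L; ll <- occ[length(occ)] - 1L
  crit <- rep(-Inf, 255)           # crit[t + 1] for threshold level t
  for (t in fl:(ll - 1L)) {
    i <- t + 1L
    P1 <- P[i]
    if (P1 <= 0 || P1 >= 1) next
    G1 <- G[i]; G2 <- totG - G1
    if (G1 <= 0 || G2 <= 0) next
    crit[i] <- -log(G1 * G2) + 2 * log(P1 * (1 - P1))
  }
  list(threshold = which.max(crit) - 1L, status = "ok")
}

#' Label connected particles in a binary mask
#'
#' 8-connectivity (the particle-analysis default of slide morphometry
#' tools) via iterative minimum-label propagation; 4-connectivity is
#' available.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape: 0 background, 1..k particles
#'   (labels renumbered in raster order of first occurrence).
#' @export
labelParticles <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- if (connectivity == 8L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  repeat {
    nxt <- lab
    for (o in offs) {
      s <- shift(lab, o[1], o[2])
      upd <- mask & s > 0L & (nxt == 0L | s < nxt)
      nxt[upd] <- s[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ## renumber compactly in order of first occurrence (column-major)
  u <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Particle analysis of a binary mask
#'
#' Labels connected components and removes particles strictly smaller than
#' `minParticleArea` (mm^2); a particle of exactly the cutoff area is
#' retained.
#'
#' @param mask logical matrix (TRUE = particle).
#' @param pixelSize mm per pixel.
#' @param minParticleArea minimum retained area in mm^2 (default 3e-4).
#' @param connectivity 8 (default) or 4.
#' @return list with `labels` (filtered label matrix) and `particles`
#'   (data.frame `label`, `pixels`, `areaMm2`).
#' @export
particleAnalysis <- function(mask, pixelSize, minParticleArea = 3e-4,
                             connectivity = 8L) {
  if (pixelSize <= 0) stop("pixelSize must be positive")
  if (minParticleArea < 0) stop("minParticleArea must be non-negative")
  lab <- labelParticles(mask, connectivity)
  if (!any(lab > 0L))
    return(list(labels = lab,
                particles = data.frame(label = integer(0), pixels = integer(0),
                                       areaMm2 = numeric(0))))
  px <- tabulate(lab)
  area <- px * pixelSize^2
  keep <- area >= minParticleArea
  newIds <- integer(length(px))
  newIds[keep] <- seq_len(sum(keep))
  sel <- lab > 0L
  lab[sel] <- newIds[lab[sel]]
  list(labels = lab,
       particles = data.frame(label = seq_len(sum(keep)),
                              pixels = px[keep],
                              areaMm2 = area[keep]))
}

#' Section thickness from a tissue mask
#'
#' The maximal extent perpendicular to the section's long axis, measured as
#' the minor dimension of the bounding box of the largest connected tissue
#' component (so staining debris away from the section cannot inflate the
#' measurement; sections are prepared with the long axis horizontal).
#'
#' @param mask logical tissue mask.
#' @param pixelSize mm per pixel.
#' @return thickness in mm (0 for an empty mask).
#' @export
maskThickness <- function(mask, pixelSize) {
  if (!any(mask)) return(0)
  lab <- labelParticles(mask, 8L)
  main <- lab == which.max(tabulate(lab))
  rows <- range(which(rowSums(main) > 0))
  cols <- range(which(colSums(main) > 0))
  min(diff(rows) + 1L, diff(cols) + 1L) * pixelSize
}

#' Calcification morphometry of a set of placenta slides
#'
#' For each slide the total tissue area is segmented with the Huang
#' threshold and the calcified area with the Yen threshold (both masks are
#' the pixels above the threshold; the calcified mask is intersected with
#' the tissue mask); particles below the area cutoff are filtered out.
#' Areas and particle counts are pooled across the slides of one placenta
#' before division:
#' CCI = (total calcified area / total area) * 100 (percent), and
#' CCN = (number of calcified dots / total area) * 100 by the printed
#' formula (`ccnTimes100 = FALSE` reports plain dots per mm^2).
#' Thickness is the mean over slides of the per-slide tissue-mask
#' thickness.
#'
#' @param slides list of slides; each a list with `image` (matrix, 0..255)
#'   and `pixelSize` (mm/px), e.g. from [simulatePlacentaSlide()].
#' @param minParticleArea particle-area cutoff in mm^2 (default 3e-4).
#' @param ccnTimes100 apply the x100 of the printed CCN formula (default
#'   TRUE).
#' @param connectivity particle connectivity (default 8).
#' @return list with `totalAreaMm2`, `calcAreaMm2`, `nDots`, `CCI`
#'   (percent), `CCN`, `thicknessMm`, and `perSlide` (data.frame).
#' @export
computeCalcification <- function(slides, minParticleArea = 3e-4,
                                 ccnTimes100 = TRUE, connectivity = 8L) {
  if (!length(slides)) stop("need at least one slide")
  per <- lapply(slides, function(s) {
    hist <- imageHistogram(s$image)
    th <- huangThreshold(hist)
    ty <- yenThreshold(hist)
    if (th$status != "ok" || ty$status != "ok")
      stop("degenerate slide image: no valid threshold")
    tissue <- s$image > th$threshold
    calc <- (s$image > ty$threshold) & tissue
    pa <- particleAnalysis(calc, s$pixelSize, minParticleArea, connectivity)
    data.frame(totalAreaMm2 = sum(tissue) * s$pixelSize^2,
               calcAreaMm2 = sum(pa$particles$areaMm2),
               nDots = nrow(pa$particles),
               thicknessMm = maskThickness(tissue, s$pixelSize))
  })
  per <- do.call(rbind, per)
  totalArea <- sum(per$totalAreaMm2)
  if (totalArea <= 0) stop("total tissue area is zero")
  calcArea <- sum(per$calcAreaMm2)
  nDots <- sum(per$nDots)
  list(totalAreaMm2 = totalArea, calcAreaMm2 = calcArea, nDots = nDots,
       CCI = calcArea / totalArea * 100,
       CCN = nDots / totalArea * (if (ccnTimes100) 100 else 1),
       thicknessMm = mean(per$thicknessMm),
       perSlide = per)
}
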