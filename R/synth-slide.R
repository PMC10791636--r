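#' Specify a synthetic stained placenta slide
#'
#' Describes an 8-bit grayscale slide: a bright tissue ellipse on a dark
#' background carrying a small population of brighter calcified particles
#' (three well-separated intensity classes, emulating the contrast of an
#' Alizarin-red slide after grayscale conversion).
#'
#' @param width,height image size in pixels.
#' @param pixelSize physical pixel size in mm/pixel.
#' @param semiA,semiB tissue-ellipse semi-axes in pixels (axis-aligned:
#'   `semiA` horizontal, `semiB` vertical; the minor axis is the section
#'   thickness).
#' @param nParticles number of calcified particles.
#' @param particleRadius particle radius range in pixels (min, max).
#' @param bgIntensity,tissueIntensity,calcIntensity class intensities (8-bit).
#' @param noiseAmp half-range of the additive uniform integer pixel jitter;
#'   bounded noise keeps the three intensity classes strictly separated, as
#'   on a well-stained, evenly illuminated slide.
#' @return a list of class `slideSpec`.
#' @export
slideSpec <- function(width = 400L, height = 300L, pixelSize = 0.01,
                      semiA = 160L, semiB = 90L,
                      nParticles = 8L, particleRadius = c(3L, 7L),
                      bgIntensity = 15, tissueIntensity = 120,
                      calcIntensity = 245, noiseAmp = 6L) {
  if (pixelSize <= 0) stop("pixelSize must be positive")
  if (any(particleRadius < 0)) stop("particle radii must be non-negative")
  if (semiA >= width / 2 || semiB >= height / 2)
    stop("tissue region must lie within the frame")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixelSize = pixelSize, semiA = semiA, semiB = semiB,
                 nParticles = as.integer(nParticles),
                 particleRadius = particleRadius,
                 bgIntensity = bgIntensity,
                 tissueIntensity = tissueIntensity,
                 calcIntensity = calcIntensity,
                 noiseAmp = as.integer(noiseAmp)),
            class = "slideSpec")
}

#' Simulate a stained placenta slide with ground-truth areas
#'
#' Particles are placed inside the tissue ellipse with a separation margin
#' so they never touch each other or the tissue border; truth areas are the
#' painted pixel counts times `pixelSize^2`.
#'
#' @param spec a [slideSpec()].
#' @param seed integer seed.
#' @return list with `image` (height x width numeric matrix, 0..255),
#'   `pixelSize`, and `truth` (list: `totalAreaMm2`, `calcAreaMm2`,
#'   `nParticles`, `thicknessMm`, `particleAreasMm2`).
#' @export
simulatePlacentaSlide <- function(spec = slideSpec(), seed = 1L) {
  stopifnot(inherits(spec, "slideSpec"))
  set.seed(stageSeed(seed, "slide"))
  w <- spec$width; h <- spec$height; ps <- spec$pixelSize
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  tissue <- ((xs - cx) / spec$semiA)^2 + ((ys - cy) / spec$semiB)^2 <= 1

  img <- matrix(spec$bgIntensity, nrow = h, ncol = w)
  img[tissue] <- spec$tissueIntensity

  calc <- matrix(FALSE, nrow = h, ncol = w)
  particleAreasPx <- integer(0)
  if (spec$nParticles > 0) {
    rmax <- max(spec$particleRadius)
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    for (i in seq_len(spec$nParticles)) {
      r <- stats::runif(1, spec$particleRadius[1], spec$particleRadius[2])
      ok <- FALSE
      for (try in seq_len(5000L)) {
        px <- stats::runif(1, cx - spec$semiA, cx + spec$semiA)
        py <- stats::runif(1, cy - spec$semiB, cy + spec$semiB)
        ## entire particle (plus margin) inside the tissue ellipse
        inside <- ((px - cx) / (spec$semiA - r - 3))^2 +
                  ((py - cy) / (spec$semiB - r - 3))^2 <= 1
        apart <- nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - px)^2 + (centers[, 2] - py)^2) >
              radii + r + 4)
        if (inside && apart) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place particle ", i, " inside the tissue")
      centers <- rbind(centers, c(px, py)); radii <- c(radii, r)
      blob <- (xs - px)^2 + (ys - py)^2 <= r^2
      if (any(blob & !tissue)) stop("particle outside tissue")
      calc <- calc | blob
      particleAreasPx <- c(particleAreasPx, sum(blob))
    }
    img[calc] <- spec$calcIntensity
  }
  if (spec$noiseAmp > 0) {
    noise <- sample(seq(-spec$noiseAmp, spec$noiseAmp), h * w, replace = TRUE)
    img <- img + matrix(noise, nrow = h)
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  list(image = img, pixelSize = ps,
       truth = list(totalAreaMm2 = sum(tissue) * ps^2,
                    calcAreaMm2 = sum(calc) * ps^2,
                    nParticles = spec$nParticles,
                    thicknessMm = 2 * spec$semiB * ps,
                    particleAreasMm2 = particleAreasPx * ps^2))
}
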