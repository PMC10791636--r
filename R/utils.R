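#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rbinom runif rnbinom rpois rlnorm median var pnorm
#'   pchisq fisher.test wilcox.test density setNames complete.cases
#' @importFrom methods slotNames
#' @importFrom utils read.delim write.table head tail modifyList
NULL

## Per-stage RNG substreams: one user-facing seed, a fixed offset per
## pipeline stage, so adding a stage never perturbs the draws of another.
.STAGE_OFFSETS <- c(
  genome     = 101L,
  methylome  = 211L,
  bsreads    = 307L,
  cpgtable   = 401L,
  rnaseq     = 503L,
  slide      = 601L,
  gestation  = 701L,
  generic    = 811L
)

#' Derive a deterministic per-stage seed from a master seed
#'
#' Keeps every source of randomness traceable to a single integer while
#' decoupling pipeline stages from each other.
#'
#' @param seed master seed (integer).
#' @param stage one of the known stage names.
#' @return an integer seed below 2^31.
#' @keywords internal
stageSeed <- function(seed, stage = "generic") {
  off <- .STAGE_OFFSETS[[match.arg(stage, names(.STAGE_OFFSETS))]]
  as.integer((as.double(seed) %% 65011 + 1) * 32749 + off) %% 2147483629L
}

#' Round half away from zero to a fixed number of decimals
#'
#' Base R's round() is round-half-even; printed outcome-rate tables use
#' conventional half-up rounding (e.g. 2.655 -> 2.7).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Coordinate conventions live in exactly this one place:
## variant tables and SAM records are 1-based inclusive,
## BED intervals are 0-based half-open.

#' Convert 1-based positions to single-base BED intervals and back
#'
#' @param pos 1-based position vector.
#' @return `posToBed`: data.frame with 0-based `start`, half-open `end`.
#' @export
posToBed <- function(pos) {
  stopifnot(all(pos >= 1))
  data.frame(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' @rdname posToBed
#' @param start,end BED coordinates (0-based half-open); must be single-base.
#' @return `bedToPos`: 1-based position vector.
#' @export
bedToPos <- function(start, end) {
  if (any(end - start != 1L))
    stop("bedToPos() expects single-base BED intervals")
  as.integer(start) + 1L
}

## internal: check scalar probability
.isProb <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
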