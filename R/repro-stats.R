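#' Outcome rate as a percentage, half-up rounded to one decimal
#'
#' The convention of embryo-transfer outcome tables: 100 * k / n rounded
#' half away from zero to one decimal (so 3/113 prints 2.7).
#'
#' @param numerator event count k.
#' @param denominator total count n (> 0, >= k).
#' @param digits decimals (default 1).
#' @return numeric percentage.
#' @export
ratePct <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator > denominator)) stop("numerator exceeds denominator")
  if (any(numerator < 0)) stop("numerator must be non-negative")
  roundHalfUp(100 * numerator / denominator, digits)
}

#' Outcome-rate table for an embryo-transfer experiment
#'
#' Rates are calculated against the number of embryos activated, the
#' denominator convention of cloning outcome tables.
#'
#' @param outcomes data.frame with one row per group and count columns
#'   `activated`, `transferred`, `surrogates`, `pregnant`, `implanted`,
#'   `fetuses`, `liveBirths`, `surviving` (missing columns are skipped).
#' @return the input with `_pct` columns appended for every count column
#'   after `activated`.
#' @export
outcomeRates <- function(outcomes) {
  stopifnot("activated" %in% names(outcomes))
  cnt <- intersect(c("transferred", "surrogates", "pregnant", "implanted",
                     "fetuses", "liveBirths", "surviving"), names(outcomes))
  ord <- c("implanted", "fetuses", "liveBirths", "surviving")
  chain <- intersect(ord, names(outcomes))
  for (i in seq_len(length(chain) - 1)) {
    if (any(outcomes[[chain[i + 1]]] > outcomes[[chain[i]]]))
      stop("outcome counts must be non-increasing along the chain: ",
           paste(chain, collapse = " >= "))
  }
  for (cc in setdiff(cnt, c("transferred", "surrogates")))
    outcomes[[paste0(cc, "_pct")]] <-
      ratePct(outcomes[[cc]], outcomes$activated)
  outcomes
}

#' Kaplan-Meier curve with median survival
#'
#' Product-limit estimate of the probability of not yet having aborted by
#' each gestational day; the median is the earliest time at which the
#' survival estimate drops to 0.5 or below (reported as NA when the curve
#' never reaches 0.5).
#'
#' @param times event/censoring days (>= 0).
#' @param events 1 = event (abortion/stillbirth), 0 = censored.
#' @param group optional label stored with the curve.
#' @return list with `time`, `survival`, `nRisk`, `nEvent`, `median`,
#'   `group`.
#' @export
kmEstimate <- function(times, events = rep(1L, length(times)),
                       group = NA_character_) {
  if (any(times < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  ## earliest time at which the estimate drops to 0.5 or below
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else
    NA_real_
  list(time = fit$time, survival = fit$surv, nRisk = fit$n.risk,
       nEvent = fit$n.event, median = med, group = group)
}

#' Log-rank comparison of two abortion-time curves
#'
#' Standard (unweighted) log-rank test on the pooled risk sets, 1 df.
#'
#' @param timesA,timesB event/censoring days per group.
#' @param eventsA,eventsB event indicators (default: all events).
#' @return list with `chisq`, `p.value`, `obs` and `exp` (per-group
#'   observed and expected event counts).
#' @export
logrankTest <- function(timesA, timesB,
                        eventsA = rep(1L, length(timesA)),
                        eventsB = rep(1L, length(timesB))) {
  if (!length(timesA) || !length(timesB))
    stop("both groups must be non-empty")
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- factor(rep(c("A", "B"), c(length(timesA), length(timesB))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chisq = unname(sd$chisq),
       p.value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = unname(sd$obs), exp = unname(sd$exp))
}

#' Gaussian kernel density of abortion times
#'
#' @param times event days.
#' @param bandwidth kernel bandwidth; `"nrd0"` (Silverman's rule, default)
#'   or a number.
#' @param n grid size (default 512).
#' @return data.frame with `day` and `density`; the density integrates to 1
#'   over the evaluated grid.
#' @export
abortionDensity <- function(times, bandwidth = "nrd0", n = 512L) {
  d <- density(times, bw = bandwidth, n = n)
  data.frame(day = d$x, density = d$y)
}
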