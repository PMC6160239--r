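#' Posterior error rate under a Bernoulli model with a Beta(1, 1) prior
#'
#' Given \code{nTrials} inspected items and \code{nErrors} observed errors,
#' the error probability has posterior Beta(nErrors + 1, nTrials - nErrors
#' + 1). Returns the posterior mean and the equal-tailed 95\% credible
#' interval (2.5\% and 97.5\% quantiles). With no trials the uninformative
#' prior itself is returned: mean 0.5, interval (0.025, 0.975).
#'
#' @param nTrials number of inspected items (>= 0).
#' @param nErrors number of observed errors, 0 <= nErrors <= nTrials.
#' @return list with \code{mean} and \code{ci} (length-2 lower/upper).
#' @examples
#' betaErrorRate(1000, 3)  # mean ~0.004, CI ~[0.001, 0.009]
#' @export
betaErrorRate <- function(nTrials, nErrors) {
  stopifnot(nTrials >= 0, nErrors >= 0, nErrors <= nTrials)
  a <- nErrors + 1
  b <- nTrials - nErrors + 1
  list(mean = a / (a + b),
       ci = c(qbeta(0.025, a, b), qbeta(0.975, a, b)))
}

#' Pairwise mismatch matrix of two partitions
#'
#' Counts item pairs by co-membership: \code{a} same cluster in both
#' partitions, \code{b} same in A only, \code{c} same in B only, \code{d}
#' different in both. \code{a + b + c + d = n(n-1)/2}.
#'
#' @param partitionA,partitionB cluster labels over the same items.
#' @return named numeric vector (a, b, c, d).
#' @export
mismatchMatrix <- function(partitionA, partitionB) {
  stopifnot(length(partitionA) == length(partitionB), length(partitionA) >= 2)
  ct <- table(partitionA, partitionB)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  a <- ch2(ct)
  ab <- ch2(rowSums(ct))
  ac <- ch2(colSums(ct))
  n <- length(partitionA)
  tot <- n * (n - 1) / 2
  b <- ab - a
  cc <- ac - a
  d <- tot - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Wallace agreement coefficients between two partitions
#'
#' The directional Wallace coefficient from A to B is \code{a/(a+b)}: the
#' proportion of pairs co-clustered in A that are also co-clustered in B.
#' Used here as the sensitivity of a clustering to a reference annotation,
#' augmented by the specificity \code{d/(c+d)}. Undefined ratios (zero
#' denominator, e.g. singleton-only partitions) are returned as NA.
#'
#' @inheritParams mismatchMatrix
#' @return list with \code{sensitivity}, \code{specificity} and the
#'   \code{mismatch} counts.
#' @export
wallace <- function(partitionA, partitionB) {
  m <- mismatchMatrix(partitionA, partitionB)
  sens <- if ((m["a"] + m["b"]) > 0) unname(m["a"] / (m["a"] + m["b"])) else NA_real_
  spec <- if ((m["c"] + m["d"]) > 0) unname(m["d"] / (m["c"] + m["d"])) else NA_real_
  list(sensitivity = sens, specificity = spec, mismatch = m)
}

#' Average expert score from marked fractions
#'
#' Experts mark images good / intermediate / bad, coded 1.0 / 0.5 / 0.0.
#' Given the fraction marked good and the fraction marked good or
#' intermediate, the average score is \code{good + 0.5 * (goodOrIntermediate
#' - good)}.
#'
#' @param fractionGood fraction of items marked good, in [0, 1].
#' @param fractionGoodOrIntermediate fraction marked good or intermediate;
#'   must be >= \code{fractionGood}.
#' @return the average score.
#' @export
expertScoreSummary <- function(fractionGood, fractionGoodOrIntermediate) {
  if (fractionGood < 0 || fractionGoodOrIntermediate > 1 ||
      fractionGood > fractionGoodOrIntermediate)
    stop("need 0 <= fractionGood <= fractionGoodOrIntermediate <= 1")
  fractionGood + 0.5 * (fractionGoodOrIntermediate - fractionGood)
}
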