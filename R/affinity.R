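#' Affinity propagation clustering
#'
#' Frey-Dueck message passing on a similarity matrix. The shared preference
#' (self-similarity) controls the number of exemplars; smaller preferences
#' yield fewer clusters. Deterministic for a given input (a tiny fixed
#' tie-breaking jitter proportional to the index is added, as is standard,
#' to avoid oscillation on exactly symmetric input).
#'
#' @param S square similarity matrix (larger = more similar).
#' @param preference scalar self-similarity placed on the diagonal; default
#'   the median off-diagonal similarity.
#' @param damping damping factor in [0.5, 1).
#' @param maxIter maximum sweeps.
#' @param convIter sweeps with unchanged exemplars required to declare
#'   convergence.
#' @return list: \code{labels} (1..K), \code{exemplars} (item indices),
#'   \code{K}, \code{converged}.
#' @export
affinityPropagation <- function(S, preference = NULL, damping = 0.9,
                                maxIter = 500, convIter = 50) {
  S <- as.matrix(S)
  n <- nrow(S)
  stopifnot(n == ncol(S), n >= 2, damping >= 0.5, damping < 1)
  off <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- median(off)
  diag(S) <- preference
  # deterministic symmetry-breaking jitter
  sc <- max(abs(S[is.finite(S)]), 1)
  S <- S + matrix(seq_len(n * n), n) * (1e-12 * sc)

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  lastEx <- NULL; stable <- 0L; converged <- FALSE
  for (it in seq_len(maxIter)) {
    # responsibilities
    AS <- A + S
    mx1 <- apply(AS, 1, max)
    w1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), w1)] <- -Inf
    mx2 <- apply(AS2, 1, max)
    Rn <- S - mx1
    Rn[cbind(seq_len(n), w1)] <- S[cbind(seq_len(n), w1)] - mx2
    R <- damping * R + (1 - damping) * Rn
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    An <- matrix(cs, n, n, byrow = TRUE) - Rp
    An[An > 0] <- 0
    diag(An) <- colSums(pmax(R, 0) * (1 - diag(n)))  # positives excluding self
    A <- damping * A + (1 - damping) * An

    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, lastEx)) stable <- stable + 1L else stable <- 0L
    lastEx <- ex
    if (stable >= convIter && length(ex) > 0) { converged <- TRUE; break }
  }
  ex <- lastEx
  if (length(ex) == 0) ex <- which.max(diag(R) + diag(A))
  lab <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  lab[ex] <- seq_along(ex)
  labels <- as.integer(factor(lab, levels = seq_along(ex)))
  list(labels = labels, exemplars = ex, K = length(ex), converged = converged)
}
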