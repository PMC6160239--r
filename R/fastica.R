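#' Symmetric FastICA
#'
#' Fixed-point independent component analysis with the log-cosh contrast and
#' symmetric decorrelation. Data are centred and whitened onto the leading
#' \code{nComp} principal axes before the fixed-point iteration. The model
#' solved is \code{K (X - mean) = M S} with \code{K} the whitening matrix,
#' \code{M} the (orthogonal) mixing matrix in whitened space and \code{S} the
#' unit-variance sources; signs and ordering of the sources are arbitrary.
#'
#' @param X numeric matrix, observations in rows.
#' @param nComp number of components, 1 <= nComp <= ncol(X).
#' @param maxIter maximum fixed-point iterations.
#' @param tol convergence tolerance on the rotation update.
#' @param seed RNG seed for the random orthonormal start.
#' @return list: \code{S} (n x nComp sources), \code{K} (nComp x p
#'   whitening), \code{W} (nComp x nComp rotation), \code{M} (mixing,
#'   \code{t(W)}), \code{axes} (p x nComp independent axis directions in data
#'   space, unit columns, \code{pinv(K) M} normalised), \code{center},
#'   \code{converged}.
#' @export
fastIca <- function(X, nComp, maxIter = 200, tol = 1e-6, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(nComp >= 1, nComp <= p, n > nComp)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)

  sv <- svd(Xc, nu = 0)
  d <- sv$d / sqrt(max(1, n - 1))
  if (d[nComp] < 1e-12 * max(d, 1e-300))
    stop("data rank below requested number of components")
  K <- t(sv$v[, seq_len(nComp), drop = FALSE]) / d[seq_len(nComp)]
  Z <- K %*% t(Xc)                              # nComp x n, white

  W <- .withSeed(if (is.null(seed)) 42L else seed, {
    m <- matrix(rnorm(nComp * nComp), nComp)
    qr.Q(qr(m))
  })
  sym <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nComp) %*%
      t(e$vectors) %*% W
  }
  W <- sym(W)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    U <- W %*% Z                                # nComp x n
    G <- tanh(U)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2), nComp) %*% W
    W1 <- sym(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- t(W %*% Z)
  M <- t(W)
  axes <- .pinv(K) %*% M
  axes <- sweep(axes, 2, pmax(sqrt(colSums(axes^2)), 1e-12), "/")
  list(S = S, K = K, W = W, M = M, axes = axes, center = ctr,
       converged = converged)
}

# Mean per-component Kullback-Leibler divergence of the empirical source
# distributions from their Gaussian fits; 64-bin histograms with add-one
# smoothing.
.sourceKL <- function(S, bins = 64L) {
  kl1 <- function(s) {
    mu <- mean(s); sg <- sd(s)
    if (!is.finite(sg) || sg == 0) return(0)
    br <- seq(min(s) - 1e-9, max(s) + 1e-9, length.out = bins + 1L)
    cnt <- tabulate(findInterval(s, br, rightmost.closed = TRUE), bins)
    p <- (cnt + 1) / (length(s) + bins)
    q <- diff(pnorm(br, mu, sg))
    q <- (q + 1e-12) / sum(q + 1e-12)
    sum(p * log(p / q))
  }
  mean(apply(as.matrix(S), 2, kl1))
}
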