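# Sorting a collection into cleared and un-cleared preparations from
# per-image colour-distribution signatures.

#' Colour-distribution signature of an image
#'
#' The per-image LAB pixel mean and the six lower-triangular entries of the
#' Cholesky factor of the pixel covariance (non-negative diagonal), packed
#' as \code{(m1, m2, m3, l11, l21, l22, l31, l32, l33)}. A singular
#' covariance receives a diagonal jitter of 1e-8 with a warning.
#'
#' @param lab a \linkS4class{LabImage}, \linkS4class{ImageRecord}, or
#'   H x W x 3 LAB array.
#' @return named numeric vector of length 9.
#' @export
colourSignature <- function(lab) {
  if (is(lab, "ImageRecord")) lab <- toLab(lab)
  arr <- if (is(lab, "LabImage")) lab@pixels else lab
  X <- matrix(arr, ncol = 3L)
  m <- colMeans(X)
  C <- cov(X)
  L <- if (max(abs(C)) < 1e-12) matrix(0, 3, 3) else
    tryCatch(t(chol(C)), error = function(e) {
      warning("singular pixel covariance; adding diagonal jitter")
      t(chol(C + diag(1e-8, 3)))
    })
  out <- c(m, L[1, 1], L[2, 1], L[2, 2], L[3, 1], L[3, 2], L[3, 3])
  names(out) <- c("m1", "m2", "m3", "l11", "l21", "l22", "l31", "l32", "l33")
  out
}

#' Classify a collection into cleared and un-cleared images
#'
#' Fits a two-component full-covariance Gaussian mixture to the colour
#' signatures by expectation maximisation and assigns each image to its
#' maximum-posterior component. The component with the higher mean
#' a*-channel (redder, matching the orange/red backgrounds of un-cleared
#' preparations) is labelled "uncleared". Images with a posterior margin
#' below 0.1 whose likelihood falls under the 1st percentile of the fitted
#' mixture, or without a clear posterior winner, are flagged "unclassified".
#'
#' @param signatures n x 9 matrix of \code{\link{colourSignature}} rows
#'   (n >= 4), or a list of such vectors.
#' @param seed RNG seed (the EM initialisation is deterministic; the seed
#'   is accepted for interface uniformity).
#' @return data.frame with columns \code{label} ("cleared", "uncleared" or
#'   "unclassified") and \code{posterior}.
#' @export
classifyCollection <- function(signatures, seed = 1) {
  X <- if (is.list(signatures)) do.call(rbind, signatures)
       else as.matrix(signatures)
  n <- nrow(X)
  stopifnot(n >= 4)
  if (max(apply(X, 2, function(c) diff(range(c)))) < 1e-12)
    stop("collection not separable: all signatures identical")
  fit <- .withSeed(seed, {
    f <- tryCatch(
      suppressWarnings(mclust::Mclust(X, G = 2, modelNames = "VVV",
                                      prior = mclust::priorControl(),
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(f))
      f <- suppressWarnings(mclust::Mclust(X, G = 2, modelNames = "EEE",
                                           prior = mclust::priorControl(),
                                           verbose = FALSE))
    f
  })
  if (is.null(fit)) stop("mixture fit failed for the collection")
  z <- fit$z
  dens <- mclust::dens(X, fit$modelName, logarithm = TRUE,
                       parameters = fit$parameters)
  hard <- max.col(z, ties.method = "first")
  maxPost <- z[cbind(seq_len(n), hard)]
  margin <- abs(z[, 1] - z[, 2])
  outlier <- (maxPost < 0.5 + 1e-6) |
    (dens < quantile(dens, 0.01) & margin < 0.1)

  aMean <- fit$parameters$mean[2, ]           # a* channel of component means
  unclearedComp <- which.max(aMean)
  label <- ifelse(hard == unclearedComp, "uncleared", "cleared")
  label[outlier] <- "unclassified"
  data.frame(label = label, posterior = maxPost,
             stringsAsFactors = FALSE)
}
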