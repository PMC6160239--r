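# Grouping same-gene/same-stage spherical-stage images by expression-pattern
# similarity under affine alignment.

#' Prepare a stain map for alignment
#'
#' Normalises a stain raster by the standard deviation of its pixel
#' intensities and downsamples it so that neither side exceeds the size cap
#' (default 100 px). An all-zero (or constant) map triggers a warning and a
#' zero raster.
#'
#' @param map H x W stain raster.
#' @param cap largest allowed side length after downsampling.
#' @return normalised raster.
#' @export
prepareStainImage <- function(map, cap = 100) {
  map <- as.matrix(map)
  s <- sd(as.vector(map))
  if (!is.finite(s) || s == 0) {
    warning("stain map has zero variance; using a zero raster")
    out <- map * 0
  } else out <- map / s
  if (max(dim(out)) > cap) {
    sc <- cap / max(dim(out))
    out <- .fromEB(EBImage::resize(.asEB(out),
                                   w = max(1L, round(ncol(out) * sc)),
                                   h = max(1L, round(nrow(out) * sc))))
  }
  out
}

# bilinear sampling of img at fractional (x, y) (0-based); 0 outside
.bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  at <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  val <- at(x0, y0) * (1 - fx) * (1 - fy) +
         at(x0 + 1, y0) * fx * (1 - fy) +
         at(x0, y0 + 1) * (1 - fx) * fy +
         at(x0 + 1, y0 + 1) * fx * fy
  val
}

#' Align one stain image to another under an affine transform
#'
#' Minimises \code{sum_x ||S_T(A x + b) - S_R(x)||^2 + alpha (ln|A|^2)^2}
#' over the 2 x 2 matrix A and translation b by BFGS with an analytic
#' gradient, starting from the given initial transform. Coordinates are
#' taken relative to the raster centres; samples of the template falling
#' outside its frame are zero. The log-determinant term penalises scaling.
#'
#' @param ST template raster (sampled under the transform).
#' @param SR reference raster (defines the integration grid).
#' @param init list with elements \code{A} (2 x 2) and \code{b} (length 2).
#' @param alpha scaling-penalty weight.
#' @return list: \code{A}, \code{b}, \code{value} (the residual distance),
#'   \code{converged}; NULL if the objective is non-finite at the start.
#' @export
alignPair <- function(ST, SR, init = list(A = diag(2), b = c(0, 0)),
                      alpha = 1) {
  hR <- nrow(SR); wR <- ncol(SR)
  hT <- nrow(ST); wT <- ncol(ST)
  cxR <- (wR - 1) / 2; cyR <- (hR - 1) / 2
  cxT <- (wT - 1) / 2; cyT <- (hT - 1) / 2
  xs <- as.vector(matrix(rep(seq_len(wR) - 1, each = hR), hR, wR)) - cxR
  ys <- as.vector(matrix(rep(seq_len(hR) - 1, wR), hR, wR)) - cyR
  sr <- as.vector(SR)
  gTx <- (cbind(ST[, -1], ST[, wT]) - cbind(ST[, 1], ST[, -wT])) / 2
  gTy <- (rbind(ST[-1, ], ST[hT, ]) - rbind(ST[1, ], ST[-hT, ])) / 2

  # optim calls fn and gr at the same point back to back; share the
  # forward pass between them
  cache <- new.env(parent = emptyenv())
  forward <- function(p) {
    if (identical(cache$p, p)) return(cache$v)
    A <- matrix(p[1:4], 2); b <- p[5:6]
    tx <- A[1, 1] * xs + A[1, 2] * ys + b[1] + cxT
    ty <- A[2, 1] * xs + A[2, 2] * ys + b[2] + cyT
    v <- list(tx = tx, ty = ty, r = .bilinear(ST, tx, ty) - sr)
    cache$p <- p; cache$v <- v
    v
  }
  fn <- function(p) {
    dA <- p[1] * p[4] - p[2] * p[3]
    if (abs(dA) < 1e-8) return(1e12)
    f <- forward(p)
    sum(f$r * f$r) + alpha * log(dA^2)^2
  }
  gr <- function(p) {
    A <- matrix(p[1:4], 2)
    dA <- det(A)
    if (abs(dA) < 1e-8) return(rep(0, 6))
    f <- forward(p)
    r <- f$r
    gx <- .bilinear(gTx, f$tx, f$ty)
    gy <- .bilinear(gTy, f$tx, f$ty)
    rg <- 2 * r
    pen <- 4 * alpha * log(dA^2)
    Ainv <- solve(A)
    c(sum(rg * gx * xs) + pen * Ainv[1, 1],
      sum(rg * gy * xs) + pen * Ainv[1, 2],
      sum(rg * gx * ys) + pen * Ainv[2, 1],
      sum(rg * gy * ys) + pen * Ainv[2, 2],
      sum(rg * gx), sum(rg * gy))
  }
  p0 <- c(as.vector(init$A), init$b)
  f0 <- fn(p0)
  if (!is.finite(f0)) return(NULL)
  o <- tryCatch(optim(p0, fn, gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-8)),
                error = function(e) NULL)
  if (is.null(o) || !is.finite(o$value)) return(NULL)
  list(A = matrix(o$par[1:4], 2), b = o$par[5:6], value = o$value,
       converged = o$convergence == 0)
}

# the eight canonical starts: rotations by multiples of 90 degrees of the
# original and of a flipped template
.canonicalStarts <- function() {
  rots <- lapply(c(0, 90, 180, 270) * pi / 180, function(t)
    matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2))
  flip <- diag(c(-1, 1))
  c(lapply(rots, function(R) list(A = R, b = c(0, 0))),
    lapply(rots, function(R) list(A = R %*% flip, b = c(0, 0))))
}

#' Expression-pattern distance between two images
#'
#' Aligns each image to the other from the eight canonical starts (four
#' 90-degree rotations of the original and of the flipped template) and
#' returns the minimum of the 16 minimal residuals; symmetric by
#' construction.
#'
#' @param mapI,mapJ prepared stain rasters (see
#'   \code{\link{prepareStainImage}}).
#' @param alpha scaling-penalty weight; default 0.1 times the mean pattern
#'   energy of the pair.
#' @return list: \code{distance}, \code{best} (the winning alignment and
#'   direction).
#' @export
pairDistance <- function(mapI, mapJ, alpha = NULL) {
  if (is.null(alpha))
    alpha <- 0.1 * mean(c(sum(mapI^2), sum(mapJ^2)))
  starts <- .canonicalStarts()
  best <- NULL
  for (dir in 1:2) {
    ST <- if (dir == 1) mapJ else mapI
    SR <- if (dir == 1) mapI else mapJ
    for (s in starts) {
      a <- alignPair(ST, SR, s, alpha = alpha)
      if (is.null(a)) next
      if (is.null(best) || a$value < best$value) {
        best <- a
        best$direction <- dir
        best$start <- s
      }
    }
  }
  if (is.null(best)) stop("no alignment start produced a finite objective")
  list(distance = best$value, best = best)
}

#' Pairwise dissimilarity matrix for a group of stain maps
#'
#' @param maps list of stain rasters (raw; they are prepared internally).
#' @param alpha scaling-penalty weight passed to \code{\link{pairDistance}}.
#' @param cap side-length cap for \code{\link{prepareStainImage}}.
#' @return symmetric matrix of distances with zero diagonal.
#' @export
dissimilarityMatrix <- function(maps, alpha = NULL, cap = 100) {
  prep <- lapply(maps, prepareStainImage, cap = cap)
  n <- length(prep)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pairDistance(prep[[i]], prep[[j]], alpha = alpha)$distance
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Cluster images by expression-pattern similarity
#'
#' Runs affinity propagation on the negated distances. The shared preference
#' starts at the median similarity and is scanned downward (doubled in
#' magnitude) until at most four clusters remain; if no preference
#' converges, a single cluster is returned with a warning.
#'
#' @param D symmetric dissimilarity matrix (or a list of stain maps, which
#'   is converted via \code{\link{dissimilarityMatrix}}).
#' @param maxClusters cluster cap (default 4).
#' @return a \linkS4class{ViewClustering}.
#' @export
clusterViews <- function(D, maxClusters = 4L) {
  if (is.list(D)) D <- dissimilarityMatrix(D)
  n <- nrow(D)
  stopifnot(n >= 2)
  S <- -D
  off <- S[row(S) != col(S)]
  pref <- median(off)
  if (pref >= 0) pref <- -max(abs(off)) / 10 - 1e-9
  res <- NULL
  for (step in 1:25) {
    r <- affinityPropagation(S, preference = pref)
    if (r$converged && r$K <= maxClusters) { res <- r; break }
    pref <- pref * 2
  }
  if (is.null(res)) {
    warning("affinity propagation did not converge; using a single cluster")
    res <- list(labels = rep(1L, n), exemplars = 1L, K = 1L)
  }
  tot <- vapply(seq_len(n), function(i) {
    same <- setdiff(which(res$labels == res$labels[i]), i)
    if (length(same) == 0) 0 else sum(S[i, same])
  }, numeric(1))
  new("ViewClustering", distances = D, labels = as.integer(res$labels),
      exemplars = as.integer(res$exemplars), totalSimilarity = tot)
}
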