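# Unsupervised embryo/background separation: two-scale pyramid features ->
# whitening -> Gaussian mixture with BIC -> Bayesian spatial classification of
# components -> island selection -> contour closing, level-set smoothing and
# contraction.

.kern5 <- c(1, 4, 6, 4, 1) / 16

.convSep <- function(m, k = .kern5) {
  EBImage::filter2(m, outer(k, k), boundary = "replicate")
}

.pyrDownMat <- function(m) {
  s <- .convSep(m)
  s[seq(1, nrow(s), 2), seq(1, ncol(s), 2), drop = FALSE]
}

.pyrUpMat <- function(m, targetDim) {
  up <- matrix(0, 2 * nrow(m), 2 * ncol(m))
  ind <- up
  up[seq(1, nrow(up), 2), seq(1, ncol(up), 2)] <- m
  ind[seq(1, nrow(ind), 2), seq(1, ncol(ind), 2)] <- 1
  k <- outer(2 * .kern5, 2 * .kern5)
  num <- EBImage::filter2(up, k, boundary = "replicate")
  den <- EBImage::filter2(ind, k, boundary = "replicate")
  out <- num / pmax(den, 1e-12)   # partition-of-unity normalisation at borders
  out[seq_len(targetDim[1]), seq_len(targetDim[2]), drop = FALSE]
}

.scharrX <- rbind(c(-3, 0, 3), c(-10, 0, 10), c(-3, 0, 3)) / 32
.scharrY <- t(.scharrX)

# colour + Scharr gradient features for one pyramid layer (h x w x 3 lab)
.layerFeatures <- function(lab) {
  h <- dim(lab)[1]; w <- dim(lab)[2]
  f <- matrix(0, h * w, 9L)
  for (ch in 1:3) {
    m <- lab[, , ch]
    f[, ch] <- as.vector(m)
    f[, 3 + 2 * ch - 1] <- as.vector(EBImage::filter2(m, .scharrX,
                                                      boundary = "replicate"))
    f[, 3 + 2 * ch] <- as.vector(EBImage::filter2(m, .scharrY,
                                                  boundary = "replicate"))
  }
  f
}

#' Two-scale pyramid features for segmentation
#'
#' Builds a Gaussian pyramid (5-tap kernel, 2x decimation) from a CIELAB
#' image and takes the two adjacent layers whose finer member is the first
#' with largest dimension under 200 px. From each layer, the 3 colour
#' channels and their Scharr x/y derivatives give 9 features; the coarse
#' layer is upsampled back to the fine resolution with the same kernel,
#' yielding 18 features per low-resolution pixel.
#'
#' @param lab a \linkS4class{LabImage} or H x W x 3 LAB array.
#' @param layerCap largest allowed dimension of the fine layer (default 200).
#' @return list: \code{features} ((h*w) x 18 matrix, fine-layer features in
#'   columns 1-9), \code{dims} c(h, w) of the fine layer, \code{factor}
#'   native-to-fine downscale factor, \code{fineLab} the fine LAB layer.
#' @export
buildPyramidFeatures <- function(lab, layerCap = 200) {
  arr <- if (is(lab, "LabImage")) lab@pixels else lab
  if (min(dim(arr)[1:2]) < 8) stop("image too small for pyramid features")
  fine <- arr
  factor <- 1
  while (max(dim(fine)[1:2]) >= layerCap) {
    fine <- .pyrDown3(fine)
    factor <- factor * 2
  }
  if (min(dim(fine)[1:2]) < 8)
    stop("image too small to build two pyramid layers under the layer cap")
  coarse <- .pyrDown3(fine)
  fdim <- dim(fine)[1:2]
  fFine <- .layerFeatures(fine)
  fCoarseLow <- .layerFeatures(coarse)
  fCoarse <- matrix(0, prod(fdim), 9L)
  for (j in 1:9) {
    m <- matrix(fCoarseLow[, j], dim(coarse)[1], dim(coarse)[2])
    fCoarse[, j] <- as.vector(.pyrUpMat(m, fdim))
  }
  list(features = cbind(fFine, fCoarse), dims = fdim, factor = factor,
       fineLab = fine)
}

.pyrDown3 <- function(arr) {
  h2 <- length(seq(1, dim(arr)[1], 2)); w2 <- length(seq(1, dim(arr)[2], 2))
  out <- array(0, c(h2, w2, 3))
  for (ch in 1:3) out[, , ch] <- .pyrDownMat(arr[, , ch])
  out
}

#' Whiten a feature stack, dropping uninformative components
#'
#' Centres the data, rotates onto principal axes and scales to unit
#' variance. Components whose singular value, divided by the sum of all
#' singular values, does not exceed 1e-6 are dropped as uninformative.
#' Zero-variance input yields a single all-zero dimension with a warning.
#'
#' @param x feature matrix (rows = pixels) or the list from
#'   \code{\link{buildPyramidFeatures}}.
#' @return list: \code{Z} whitened data, \code{keep} retained component
#'   count, \code{center}, \code{rotation}, \code{scale}.
#' @export
whitenFeatures <- function(x) {
  X <- if (is.list(x)) x$features else as.matrix(x)
  n <- nrow(X)
  stopifnot(n >= 2)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  tot <- sum(sv$d)
  if (tot <= 0) {
    warning("zero-variance feature data; returning a single zero dimension")
    return(list(Z = matrix(0, n, 1), keep = 1L, center = ctr,
                rotation = matrix(0, ncol(X), 1), scale = 1))
  }
  keep <- which(sv$d / tot > 1e-6)
  if (length(keep) == 0) keep <- 1L
  rot <- sv$v[, keep, drop = FALSE]
  sc <- sv$d[keep] / sqrt(n - 1)
  Z <- sweep(Xc %*% rot, 2, sc, "/")
  list(Z = Z, keep = length(keep), center = ctr, rotation = rot, scale = sc)
}

#' Fit the pixel Gaussian mixture
#'
#' Fits full-covariance Gaussian mixtures with 1..K components (K = 2 for
#' un-cleared images, 3 for cleared) to a random sample of whitened
#' low-resolution pixels, excluding pixels within three pixels of the frame;
#' the component count is chosen by BIC. The fit-and-classify cycle is run
#' three times and the run with the highest total data log-likelihood over
#' all pixels is kept.
#'
#' @param white whitening result from \code{\link{whitenFeatures}} (or a
#'   plain matrix of whitened pixels).
#' @param dims c(h, w) of the low-resolution grid.
#' @param cleared logical; allows up to 3 components when TRUE.
#' @param seed RNG seed; the entire fit is deterministic given it.
#' @param sampleSize pixels sampled for fitting (default min(10000, all);
#'   classification always covers every pixel).
#' @return list: \code{G} selected component count, \code{assignment}
#'   (h x w hard labels), \code{logDens} ((h*w) x G component log-densities),
#'   \code{weights}, \code{totalLogLik}, \code{fit} (the mclust model).
#' @export
fitPixelMixture <- function(white, dims, cleared = FALSE, seed = 1,
                            sampleSize = 10000L) {
  Z <- if (is.list(white)) white$Z else as.matrix(white)
  h <- dims[1]; w <- dims[2]
  stopifnot(nrow(Z) == h * w)
  K <- if (cleared) 3L else 2L
  i0 <- seq_len(h * w)
  ys <- (i0 - 1L) %% h
  xs <- (i0 - 1L) %/% h
  interior <- which(xs >= 3 & xs <= w - 4 & ys >= 3 & ys <= h - 4)
  if (length(interior) < 10L) interior <- i0
  mn <- if (ncol(Z) == 1L) "V" else "VVV"

  best <- NULL
  .withSeed(seed, {
    for (rep in 1:3) {
      idx <- if (length(interior) > sampleSize)
        sample(interior, sampleSize) else interior
      Zs <- Z[idx, , drop = FALSE]
      fit <- .fitGmmBic(Zs, K, mn)
      if (is.null(fit)) next
      ld <- mclust::cdens(Z, fit$modelName, logarithm = TRUE,
                          parameters = fit$parameters)
      ld <- matrix(ld, nrow = nrow(Z))
      lw <- log(fit$parameters$pro)
      la <- sweep(ld, 2, lw, "+")
      mx <- apply(la, 1, max)
      tll <- sum(mx + log(rowSums(exp(la - mx))))
      if (is.null(best) || tll > best$totalLogLik) {
        assign <- max.col(la, ties.method = "first")
        best <- list(G = fit$G, assignment = matrix(assign, h, w),
                     logDens = ld, weights = fit$parameters$pro,
                     totalLogLik = tll, fit = fit)
      }
    }
  })
  if (is.null(best))
    stop("Gaussian mixture fitting failed in all three runs")
  best
}

# EM fits (mclust::me) with 1..K components from seeded k-means
# initialisations; the component count is selected by BIC. Uses the RNG of
# the caller (wrapped in .withSeed upstream).
.fitGmmBic <- function(Zs, K, modelName) {
  n <- nrow(Zs); d <- ncol(Zs)
  best <- NULL
  softmax <- function(cl, G) {
    z <- matrix(0.05 / max(1, G - 1), n, G)
    z[cbind(seq_len(n), cl)] <- 0.95
    z
  }
  for (G in seq_len(K)) {
    inits <- if (G == 1) list(matrix(1, n, 1)) else {
      cls <- list()
      # k-means init on the leading axes (least diluted by noise
      # dimensions); the full space is used only when it is all there is
      kmData <- if (d > 3) Zs[, 1:3] else Zs
      km <- tryCatch(suppressWarnings(
        kmeans(kmData, G, nstart = 2, iter.max = 30, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km)) cls <- c(cls, list(km$cluster))
      lapply(cls, softmax, G = G)
    }
    fitG <- NULL
    for (z0 in inits) {
      fit <- tryCatch(
        suppressWarnings(mclust::me(Zs, modelName, z0,
                                    control = mclust::emControl(
                                      tol = c(1e-4, 1e-5), itmax = 60))),
        error = function(e) NULL)
      if (is.null(fit) || is.na(fit$loglik)) next
      if (is.null(fitG) || fit$loglik > fitG$loglik) fitG <- fit
    }
    if (is.null(fitG)) next
    bicv <- mclust::bic(modelName, fitG$loglik, n, d, G)
    if (is.null(best) || bicv > best$bic) {
      best <- list(G = G, modelName = modelName, parameters = fitG$parameters,
                   loglik = fitG$loglik, bic = bicv)
    }
  }
  best
}

# log of the inverse-Wishart marginal for centred 2-D foreground coordinates,
# up to the model-independent additive constant -log Gamma_2(nu/2) (infinite
# at nu = 1 but identical for every candidate model, so dropped).
.logIWMarginal <- function(Xfg, Psi, nu = 1) {
  n <- ncol(Xfg)
  S <- Xfg %*% t(Xfg)
  lgamma2 <- function(a) 0.5 * log(pi) + lgamma(a) + lgamma(a - 0.5)
  (nu / 2) * determinant(Psi, logarithm = TRUE)$modulus[1] +
    lgamma2((nu + n) / 2) - n * log(pi) -
    ((nu + n) / 2) * determinant(Psi + S, logarithm = TRUE)$modulus[1]
}

#' Classify a mixture component as background
#'
#' For each candidate model \code{M_j} (component j is background), the
#' background pixels are modelled as uniform over the frame (density
#' \code{1/(wh)}) and the remaining pixels as a zero-mean Gaussian around the
#' frame centre with an inverse-Wishart prior (nu = 1, Psi =
#' diag((w/2)^2, (h/2)^2)) on the covariance, integrated out in closed form.
#' The model prior is uniform; the argmax wins. If the best two models
#' differ by less than the substantial-evidence margin log(3), the component
#' most frequent on the one-pixel frame border is chosen instead.
#'
#' @param assignment h x w matrix of hard component labels (or the list from
#'   \code{\link{fitPixelMixture}}).
#' @param dims optional c(h, w); taken from the matrix when missing.
#' @return list: \code{index} background component, \code{scores} per-model
#'   log-marginals, \code{fallback} whether the edge rule decided.
#' @export
classifyBackground <- function(assignment, dims = NULL) {
  if (is.list(assignment)) assignment <- assignment$assignment
  h <- nrow(assignment); w <- ncol(assignment)
  comps <- sort(unique(as.vector(assignment)))
  border <- c(assignment[1, ], assignment[h, ],
              assignment[, 1], assignment[, w])
  if (length(comps) == 1L) {
    if (any(border == comps)) {
      return(list(index = comps, scores = setNames(0, comps),
                  fallback = FALSE))
    }
    stop("no background found: single component absent from the frame edge")
  }
  i0 <- seq_len(h * w)
  ys <- (i0 - 1L) %% h
  xs <- (i0 - 1L) %/% h
  Psi <- diag(c((w / 2)^2, (h / 2)^2))
  scores <- vapply(comps, function(j) {
    bg <- as.vector(assignment) == j
    Xfg <- rbind(xs[!bg] - w / 2, ys[!bg] - h / 2)
    sum(bg) * (-log(w * h)) +
      (if (ncol(Xfg) > 0) .logIWMarginal(Xfg, Psi) else 0)
  }, numeric(1))
  names(scores) <- comps
  ord <- order(scores, decreasing = TRUE)
  fallback <- length(comps) > 1 &&
    (scores[ord[1]] - scores[ord[2]]) < log(3)
  idx <- if (fallback) {
    cnt <- vapply(comps, function(j) sum(border == j), numeric(1))
    comps[which.max(cnt)]
  } else comps[ord[1]]
  list(index = idx, scores = scores, fallback = fallback)
}

#' Connected foreground islands
#'
#' Extracts the connected components of the 4-adjacency graph over
#' foreground pixels. (The recursive spectral cut of the zero-eigenvalue
#' Laplacian eigenvector partitions a graph exactly into its connected
#' components; they are computed directly here.)
#'
#' @param mask binary h x w matrix.
#' @return list of integer vectors of pixel indices (column-major), one per
#'   island; empty list for an empty mask.
#' @export
extractIslands <- function(mask) {
  sel <- mask > 0
  if (!any(sel)) return(list())
  membership <- .labelComponents4(sel)
  unname(split(which(sel), membership))
}

#' Select the island most likely to be the embryo
#'
#' Scores each island by \code{sqrt(size) * ||meanColour - M_bg||} and
#' returns the argmax; ties are broken by size, then by first index.
#'
#' @param islands list of pixel-index vectors from
#'   \code{\link{extractIslands}}.
#' @param labLow low-resolution LAB array (h x w x 3) used for mean colours.
#' @param Mbg background mean colour (LAB triple).
#' @return index (into \code{islands}) of the selected island.
#' @export
selectEmbryoIsland <- function(islands, labLow, Mbg) {
  stopifnot(length(islands) >= 1)
  n <- prod(dim(labLow)[1:2])
  sc <- vapply(islands, function(idx) {
    mcol <- c(mean(labLow[idx]), mean(labLow[idx + n]),
              mean(labLow[idx + 2 * n]))
    sqrt(length(idx)) * sqrt(sum((mcol - Mbg)^2))
  }, numeric(1))
  best <- which(sc == max(sc))
  if (length(best) > 1) {
    sizes <- lengths(islands)[best]
    best <- best[sizes == max(sizes)]
  }
  best[1]
}

#' Close the embryo contour and fill holes
#'
#' Fills all 4-connected holes inside the selected island. When the embryo
#' extends beyond the frame the contour is first closed along the frame
#' edge: a random quarter of the pixels in the 2-pixel frame band is marked
#' foreground, single-pixel islands are reverted, holes are filled, and the
#' cycle repeats until the biggest component grows by less than 5\% in an
#' iteration (at most 100 iterations). Band scaffolding that did not become
#' interior is removed afterwards.
#'
#' @param mask binary h x w matrix holding the selected island.
#' @param seed RNG seed for the random band marking.
#' @return closed and filled binary mask.
#' @export
closeAndFill <- function(mask, seed = 1) {
  mask <- (mask > 0) * 1
  h <- nrow(mask); w <- ncol(mask)
  touches <- any(mask[1, ] > 0) || any(mask[h, ] > 0) ||
    any(mask[, 1] > 0) || any(mask[, w] > 0)
  if (!touches) {
    filled <- .fillHoles(mask)
    return(filled)
  }
  band <- matrix(FALSE, h, w)
  band[1:2, ] <- TRUE; band[(h - 1):h, ] <- TRUE
  band[, 1:2] <- TRUE; band[, (w - 1):w] <- TRUE
  bandIdx <- which(band & mask == 0)
  added <- matrix(FALSE, h, w)
  cur <- mask
  .withSeed(seed, {
    prevBig <- max(lengths(extractIslands(cur)), 0)
    for (it in seq_len(100)) {
      pick <- sample(bandIdx, length(bandIdx) %/% 4)
      cur[pick] <- 1
      added[pick] <- TRUE
      isl <- extractIslands(cur)
      for (s in isl[lengths(isl) == 1L]) {
        cur[s] <- 0
        added[s] <- FALSE
      }
      # fill newly enclosed holes, but never a region larger than the
      # embryo itself (an embryo has no giant holes; without the cap a
      # band that encircles the frame would swallow the background)
      big0 <- max(lengths(extractIslands(cur)), 0)
      cur <- .fillHolesCapped(cur, 1.2 * big0)
      big <- max(lengths(extractIslands(cur)), 0)
      # the stop rule needs the random marking to reach closing density
      # first (~76% of the band after four rounds)
      if (it >= 5 && big < prevBig * 1.05) break
      prevBig <- big
    }
  })
  # keep the original island and everything that became interior; of the
  # band scaffolding keep only pixels adjacent to them (the plug), so the
  # mask cannot creep along the frame band
  keep <- (mask > 0) | (cur > 0 & !added)
  # the frame edge itself closes the contour: background pockets that do
  # not reach the border except through the frame edge, and are no larger
  # than the embryo, are interior
  bigSz <- max(lengths(extractIslands(keep * 1)), 0)
  inner <- !keep
  inner[c(1, h), ] <- FALSE
  inner[, c(1, w)] <- FALSE
  if (any(inner)) {
    lab <- matrix(0L, h, w)
    lab[inner] <- .labelComponents4(inner)
    sizes <- tabulate(lab[lab > 0])
    # a pocket enclosed by the embryo and the frame edge reaches at most
    # two frame sides; the open background surrounds the embryo and
    # reaches them all
    nSides <- vapply(seq_along(sizes), function(j) {
      sel <- lab == j
      sum(any(sel[2, ]), any(sel[h - 1, ]), any(sel[, 2]), any(sel[, w - 1]))
    }, numeric(1))
    fillable <- which(sizes <= 3 * bigSz & nSides <= 2)
    keep <- keep | (inner & lab %in% fillable)
  }
  # sweep the one-pixel border strip: border background cells wedged
  # against filled interior become foreground
  for (pass in 1:3) {
    nb <- .fromEB(EBImage::filter2(.asEB(keep * 1),
                                   matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3),
                                   boundary = "replicate"))
    strip <- matrix(FALSE, h, w)
    strip[c(1, h), ] <- TRUE; strip[, c(1, w)] <- TRUE
    keep <- keep | (strip & !keep & nb >= 2)
  }
  plug <- added & (.fromEB(EBImage::dilate(.asEB(keep * 1),
                                           EBImage::makeBrush(3, "box"))) > 0)
  final <- .largestComponent((keep | plug) * 1)
  .fillHoles(final)
}

#' Smooth the embryo outline with a geodesic active contour
#'
#' Level-set evolution with zero balloon force and eight curvature
#' iterations. The attraction field is the sum of the background and
#' foreground log-likelihood maps, each divided by its own minimum over the
#' image; the curvature speed is modulated by the field and the contour is
#' advected along its gradient. If the contour collapses below 9 pixels the
#' unsmoothed mask is returned with a warning.
#'
#' @param mask single-component binary mask (h x w).
#' @param bgLogLik,fgLogLik co-registered log-likelihood maps.
#' @param iterations number of curvature iterations (default 8).
#' @return smoothed binary mask.
#' @export
smoothOutline <- function(mask, bgLogLik, fgLogLik, iterations = 8) {
  mask <- (mask > 0) * 1
  sanitize <- function(ll) {
    bad <- !is.finite(ll)
    if (any(bad)) {
      floor <- if (all(bad)) 0 else min(ll[!bad])
      ll[bad] <- floor
    }
    ll
  }
  bgLogLik <- sanitize(bgLogLik)
  fgLogLik <- sanitize(fgLogLik)
  normTerm <- function(ll) {
    m <- min(ll)
    if (m == 0) return(ll * 0)
    ll / m
  }
  g <- normTerm(bgLogLik) + normTerm(fgLogLik)
  # rescale to [0, 1] so the curvature speed is image-independent; a
  # constant field becomes unit speed (pure curvature flow)
  rg <- range(g)
  g <- if (rg[2] - rg[1] < 1e-12) g * 0 + 1 else (g - rg[1]) / (rg[2] - rg[1])
  # the attraction acts through the renormalised probability of foreground:
  # a signed normal speed (pFg - theta) whose equilibrium is the
  # theta-posterior level set, slightly inside the likelihood-equality
  # locus so residual background halo is shed; an uninformative (constant)
  # field exerts no force
  pFg <- 1 / (1 + exp(.clamp(bgLogLik - fgLogLik, -40, 40)))
  theta <- 0.75
  attract <- if (diff(range(pFg)) < 1e-9) pFg * 0 else pFg - theta
  din <- .fromEB(EBImage::distmap(.asEB(mask)))
  dout <- .fromEB(EBImage::distmap(.asEB(1 - mask)))
  phi <- din - dout

  shiftUp <- function(m) rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE])
  shiftDn <- function(m) rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
  shiftLf <- function(m) cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE])
  shiftRt <- function(m) cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])
  dtC <- 0.25   # curvature step (CFL-stable for speeds <= 1)
  dtA <- 1      # attraction step
  for (it in seq_len(iterations)) {
    px <- (shiftRt(phi) - shiftLf(phi)) / 2
    py <- (shiftDn(phi) - shiftUp(phi)) / 2
    pxx <- shiftRt(phi) - 2 * phi + shiftLf(phi)
    pyy <- shiftDn(phi) - 2 * phi + shiftUp(phi)
    pxy <- (shiftRt(shiftDn(phi)) - shiftRt(shiftUp(phi)) -
            shiftLf(shiftDn(phi)) + shiftLf(shiftUp(phi))) / 4
    g2 <- px^2 + py^2
    kappaGrad <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
      (g2 + 1e-9)                      # curvature * |grad phi|
    phi <- phi + dtC * g * kappaGrad + dtA * attract * sqrt(g2)
  }
  out <- (phi > 0) * 1
  if (sum(out) < 9) {
    warning("smoothed contour collapsed; reverting to the unsmoothed mask")
    return(mask)
  }
  .fillHoles(.largestComponent(out))
}

#' Segment the embryo in a WISH image
#'
#' Full segmentation pipeline: LAB conversion, two-scale pyramid features,
#' whitening, Gaussian-mixture fitting with BIC, Bayesian background
#' classification, island extraction and selection (run on the full
#' foreground and once more ignoring a 3-pixel frame border; the
#' incomplete-embryo flag is set only when the selected island touches the
#' frame in both rounds), contour closing and hole filling, level-set
#' smoothing, upsampling to native resolution and inward contraction by half
#' the downscale factor.
#'
#' @param record an \linkS4class{ImageRecord}.
#' @param cleared TRUE, FALSE, or NULL to use the record's cleared state
#'   (unknown counts as un-cleared).
#' @param seed RNG seed; the segmentation is deterministic given it.
#' @return a \linkS4class{SegmentationResult}.
#' @export
segmentEmbryo <- function(record, cleared = NULL, seed = 1) {
  if (is.null(cleared)) cleared <- identical(record@cleared, "cleared")
  lab <- toLab(record)
  fs <- buildPyramidFeatures(lab)
  h <- fs$dims[1]; w <- fs$dims[2]
  wh <- whitenFeatures(fs)
  mix <- tryCatch(fitPixelMixture(wh, fs$dims, cleared = cleared, seed = seed),
                  error = function(e)
                    stop("segmentation failed for '", record@path, "': ",
                         conditionMessage(e)))
  bg <- classifyBackground(mix$assignment)
  fgMask <- (mix$assignment != bg$index) * 1
  if (sum(fgMask) == 0)
    stop("segmentation failed for '", record@path, "': no foreground pixels")

  n <- h * w
  bgSel <- which(mix$assignment == bg$index)
  Mbg <- c(mean(fs$fineLab[bgSel]), mean(fs$fineLab[bgSel + n]),
           mean(fs$fineLab[bgSel + 2 * n]))

  isl1 <- extractIslands(fgMask)
  s1 <- selectEmbryoIsland(isl1, fs$fineLab, Mbg)
  touch1 <- .touchesFrame(isl1[[s1]], h, w, 0L)
  inner <- fgMask
  inner[c(1:3, (h - 2):h), ] <- 0
  inner[, c(1:3, (w - 2):w)] <- 0
  isl2 <- extractIslands(inner)
  touch2 <- if (length(isl2) == 0) TRUE else {
    s2 <- selectEmbryoIsland(isl2, fs$fineLab, Mbg)
    .touchesFrame(isl2[[s2]], h, w, 3L)
  }
  incomplete <- touch1 && touch2

  sel <- matrix(0, h, w)
  sel[isl1[[s1]]] <- 1
  closed <- closeAndFill(sel, seed = seed)

  lw <- log(mix$weights)
  G <- ncol(mix$logDens)
  bgLL <- matrix(mix$logDens[, bg$index] + lw[bg$index], h, w)
  if (G > 1) {
    others <- setdiff(seq_len(G), bg$index)
    la <- mix$logDens[, others, drop = FALSE] +
      matrix(lw[others], n, length(others), byrow = TRUE)
    mx <- apply(la, 1, max)
    fgLL <- matrix(mx + log(rowSums(exp(la - mx))), h, w)
  } else fgLL <- bgLL
  smooth <- smoothOutline(closed, bgLL, fgLL)

  nat <- dim(record@pixels)
  up <- .fromEB(EBImage::resize(.asEB(smooth), w = nat[2], h = nat[1]))
  maskNat <- (up > 0.5) * 1
  # inward contraction by half the native-to-smallest-layer scaling factor
  # (= one fine-layer pixel width); never less than the coarse-layer pixel
  # width of an undownscaled image, since that layer sets the feature
  # support at the boundary
  r <- max(2L, as.integer(fs$factor))
  er <- .fromEB(EBImage::erode(.asEB(maskNat),
                               EBImage::makeBrush(2 * r + 1, "disc")))
  if (sum(er) >= 9) maskNat <- er
  maskNat <- .fillHoles(.largestComponent(maskNat))
  if (sum(maskNat) == 0)
    stop("segmentation failed for '", record@path, "': empty final mask")

  new("SegmentationResult", mask = maskNat, bbox = .maskBBox(maskNat),
      incomplete = incomplete, backgroundColour = Mbg,
      bgLogLik = bgLL, fgLogLik = fgLL, scaleFactor = fs$factor)
}

.touchesFrame <- function(idx, h, w, margin) {
  ys <- (idx - 1L) %% h
  xs <- (idx - 1L) %/% h
  any(ys <= margin | ys >= h - 1L - margin |
      xs <= margin | xs >= w - 1L - margin)
}
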