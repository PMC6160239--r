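# Hint-based decomposition of embryo pixels into in situ stain, natural
# pigment and background bleed-through, via independent component analysis in
# CMY space.

#' Construct colour hints for stain/pigment unmixing
#'
#' Defaults emulate a typical blue-purple chromogenic in situ stain
#' (RGB 60,60,160) and the red-brown melanin pigment of the Xenopus
#' epidermis (RGB 140,80,50); both are configurable. Hints are unit-length
#' CMY vectors.
#'
#' @param stainHint,pigmentHint hex RGB strings (or R colour names).
#' @param weights confidence weights for (stain, pigment, background).
#' @param lMin minimum CMY length for pixels used in paint estimation.
#' @param dMax effective colour distance from an independent axis.
#' @param rotationLimit hint-plane rotation limit in degrees.
#' @param confidenceCut relative stain-hint contribution required for a
#'   confident call.
#' @return a \linkS4class{ColourHints} object.
#' @export
colourHints <- function(stainHint = "#3C3CA0", pigmentHint = "#8C5032",
                        weights = c(stain = 0.5, pigment = 0.05,
                                    background = 1),
                        lMin = 0.15, dMax = 0.05, rotationLimit = 15,
                        confidenceCut = 0.05) {
  new("ColourHints", stain = .hexToCmyUnit(stainHint),
      pigment = .hexToCmyUnit(pigmentHint), weights = weights,
      lMin = lMin, dMax = dMax, rotationLimit = rotationLimit,
      confidenceCut = confidenceCut)
}

#' Equalise average background luminosity across a group
#'
#' Images that are to be compared (same preparation, same gene/stage group)
#' are assumed to share a background; differences in the mean background L
#' channel are attributed to imaging conditions and removed by shifting each
#' image's L channel so its mean background luminosity equals the group
#' mean. A group of one is returned unchanged.
#'
#' @param records list of \linkS4class{ImageRecord}s.
#' @param segs matching list of \linkS4class{SegmentationResult}s (the
#'   background is the area outside the embryo mask).
#' @return list of adjusted \linkS4class{ImageRecord}s.
#' @export
compensateLuminosity <- function(records, segs) {
  stopifnot(length(records) == length(segs))
  if (length(records) <= 1L) return(records)
  labs <- lapply(records, toLab)
  bgL <- mapply(function(lab, seg) {
    m <- embryoMask(seg) == 0
    mean(lab@pixels[, , 1][m])
  }, labs, segs)
  target <- mean(bgL)
  mapply(function(rec, lab, l0) {
    shift <- target - l0
    if (abs(shift) < 1e-9) return(rec)
    px <- lab@pixels
    px[, , 1] <- .clamp(px[, , 1] + shift, 0, 100)
    new("ImageRecord", pixels = .labToRgbArray(px), path = rec@path,
        gene = rec@gene, stage = rec@stage,
        orientationTag = rec@orientationTag, cleared = rec@cleared)
  }, records, labs, bgL, SIMPLIFY = FALSE)
}

#' Estimate the number of independent colour components
#'
#' Runs FastICA with 1..3 components (bounded by the rank of the pixel
#' cloud) and, for each count, measures the per-component Kullback-Leibler
#' divergence of the empirical source distribution (64-bin histogram,
#' add-one smoothing) from its Gaussian fit. The chosen count is the
#' largest n whose least-informative component still carries substantial
#' information — at least 30\% of the best observed component divergence
#' (with an absolute floor of 0.05 for estimator bias). Averaging the
#' divergence over components collapses whenever sources differ in
#' strength, because the single-component solution concentrates on the
#' strongest source alone; the informative-floor rule keeps every retained
#' component meaningful instead. A non-converging FastICA run is retried
#' with a new seed up to three times, after which the count falls back to 1
#' with a warning.
#'
#' @param pixels N x 3 matrix of CMY embryo pixels (N >= 100).
#' @param seed RNG seed.
#' @return list: \code{n} chosen count, \code{model} the corresponding
#'   FastICA fit.
#' @export
estimateNComponents <- function(pixels, seed = 1) {
  X <- as.matrix(pixels)
  stopifnot(nrow(X) >= 100)
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0)
  rank <- sum(sv$d / max(sum(sv$d), 1e-300) > 1e-8)
  maxN <- max(1L, min(3L, rank))
  kls <- vector("list", maxN)
  models <- vector("list", maxN)
  for (n in seq_len(maxN)) {
    fit <- NULL
    for (att in 1:3) {
      f <- tryCatch(fastIca(X, n, seed = seed + 97L * att),
                    error = function(e) NULL)
      if (!is.null(f) && f$converged) { fit <- f; break }
      if (!is.null(f) && is.null(fit)) fit <- f
    }
    if (is.null(fit)) next
    models[[n]] <- fit
    kls[[n]] <- apply(as.matrix(fit$S), 2,
                      function(s) .sourceKL(matrix(s, ncol = 1)))
  }
  got <- !vapply(kls, is.null, logical(1))
  if (!any(got)) {
    warning("FastICA failed to converge for all component counts; ",
            "falling back to a single component")
    return(list(n = 1L, model = NULL))
  }
  floorKL <- max(0.3 * max(unlist(kls[got])), 0.05)
  ok <- which(got & vapply(kls, function(k)
    !is.null(k) && min(k) >= floorKL, logical(1)))
  n <- if (length(ok) > 0) max(ok) else which(got)[1]
  list(n = as.integer(n), model = models[[n]],
       kl = vapply(seq_len(maxN), function(i)
         if (is.null(kls[[i]])) NA_real_ else mean(kls[[i]]), numeric(1)),
       klPerComponent = kls)
}

#' Resolve which expected colours are present
#'
#' With three components all three expected colours (stain, pigment,
#' background) are kept; with one, only the stain colour. With two, the
#' stain is assumed present and the missing colour is either pigment or
#' background: the candidate set maximising \code{|det cor(sources,
#' candidate loadings)| + 10 |cos(plane normals)|} wins, where the plane
#' normals are those of the candidate colour pair and of the two independent
#' axes.
#'
#' @param n estimated number of components.
#' @param hints a \linkS4class{ColourHints} object.
#' @param cb unit background CMY colour (mean colour outside the outline).
#' @param pixels N x 3 CMY embryo pixels.
#' @param model FastICA fit from \code{\link{estimateNComponents}}.
#' @return 3 x n matrix of expected colours, columns named from
#'   ("stain", "pigment", "background").
#' @export
resolveExpectedColours <- function(n, hints, cb, pixels, model) {
  cs <- hints@stain; cp <- hints@pigment
  mk <- function(cols, nms) {
    m <- do.call(cbind, cols)
    colnames(m) <- nms
    m
  }
  if (n >= 3) return(mk(list(cs, cp, cb), c("stain", "pigment", "background")))
  if (n == 1) return(mk(list(cs), "stain"))
  X <- as.matrix(pixels)
  Xc <- sweep(X, 2, colMeans(X))
  S <- model$S[, 1:2, drop = FALSE]
  score <- function(C) {
    Sc <- t(.pinv(C) %*% t(Xc))
    d <- abs(det(cor(S, Sc)))
    nC <- .unit(.cross3(C[, 1], C[, 2]))
    nT <- .unit(.cross3(model$axes[, 1], model$axes[, 2]))
    d + 10 * abs(sum(nC * nT))
  }
  candB <- mk(list(cs, cb), c("stain", "background"))
  candP <- mk(list(cs, cp), c("stain", "pigment"))
  if (score(candB) >= score(candP)) candB else candP
}

#' Rotate the stain/pigment hint plane toward the pixel principal plane
#'
#' When the pigment colour is retained, both hint vectors are rotated about
#' their mean direction by an angle confined to +/- the rotation limit
#' (default 15 degrees) so that their plane becomes maximally parallel to
#' the principal plane (first two principal components) of the pixel
#' colours. A degenerate principal plane leaves the hints unchanged.
#'
#' @param cs,cp unit stain and pigment CMY vectors.
#' @param pixels N x 3 CMY pixels.
#' @param limitDeg rotation limit in degrees.
#' @return list: rotated unit \code{cs}, \code{cp} and the \code{angle}
#'   used (degrees).
#' @export
adjustHintColours <- function(cs, cp, pixels, limitDeg = 15) {
  X <- as.matrix(pixels)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0)
  if (sum(sv$d / max(sum(sv$d), 1e-300) > 1e-8) < 2)
    return(list(cs = cs, cp = cp, angle = 0))
  nP <- .unit(.cross3(sv$v[, 1], sv$v[, 2]))
  axis <- .unit(cs + cp)
  rot <- function(v, th) {             # Rodrigues rotation about `axis`
    v * cos(th) + .cross3(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
  }
  obj <- function(deg) {
    th <- deg * pi / 180
    nH <- .unit(.cross3(rot(cs, th), rot(cp, th)))
    -abs(sum(nH * nP))
  }
  grid <- seq(-limitDeg, limitDeg, by = 0.5)
  v <- vapply(grid, obj, numeric(1))
  g0 <- grid[which.min(v)]
  o <- optimize(obj, c(max(-limitDeg, g0 - 1), min(limitDeg, g0 + 1)))
  ang <- o$minimum
  th <- ang * pi / 180
  list(cs = .unit(rot(cs, th)), cp = .unit(rot(cp, th)), angle = ang)
}

#' Estimate the paint matrix from independent axes and expected colours
#'
#' For each signed independent axis, a paint colour is proposed as the
#' unit-normalised point on the (mean-anchored) axis where the projection of
#' pixel colours near the axis is maximal: only pixels with CMY length at
#' least \code{lMin} count, weighted by \code{exp(-orth^2 / (2 dMax^2))} in
#' their orthogonal distance to the axis. The assignment of proposals to
#' expected colours minimising the weighted specificity criterion
#' \code{sum_i w_i ||c_i - a_i||^2 / sum_{j != i} ||c_i - a_j||} is
#' accepted. The stain colour is confident when the stain hint's relative
#' positive contribution \code{max(0, q_1) / sum_i max(0, q_i)} with
#' \code{q = pinv(C_e) a_s} exceeds the confidence cut. If the pigment slot
#' captures an estimate resembling the stain hint (a saturation artefact),
#' the estimation is repeated with the pigment colour removed.
#'
#' @param pixels N x 3 CMY embryo pixels.
#' @param model FastICA fit.
#' @param Ce expected-colour matrix from
#'   \code{\link{resolveExpectedColours}}.
#' @param hints a \linkS4class{ColourHints} object.
#' @param hintSet optional 3 x 3 matrix of all expected colours (stain,
#'   pigment, background) used for the confidence decomposition; the
#'   decomposition against the full set lets the flag catch estimates that
#'   are really pigment or background bleed. Defaults to \code{Ce}.
#' @return list: \code{A} (3 x m paint matrix, stain first), \code{confident},
#'   \code{columns} (colour names), \code{proposals}.
#' @export
estimatePaintMatrix <- function(pixels, model, Ce, hints, hintSet = NULL) {
  X <- as.matrix(pixels)
  keep <- sqrt(rowSums(X^2)) >= hints@lMin
  if (!any(keep)) stop("embryo too pale: no pixel reaches the minimum ink length")
  Xk <- X[keep, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(Xk, 2, ctr)
  nAxes <- ncol(model$axes)

  proposals <- vector("list", 2L * nAxes)
  for (k in seq_len(nAxes)) {
    for (zi in 1:2) {
      v <- model$axes[, k] * c(1, -1)[zi]
      tpar <- Xc %*% v
      orth2 <- rowSums(Xc^2) - tpar^2
      wgt <- tpar * exp(-pmax(orth2, 0) / (2 * hints@dMax^2))
      wgt[tpar <= 0] <- -Inf
      if (all(!is.finite(wgt))) next
      i <- which.max(wgt)
      proposals[[2 * (k - 1) + zi]] <- .unit(ctr + drop(tpar[i]) * v)
    }
  }
  ok <- !vapply(proposals, is.null, logical(1))
  propAxis <- rep(seq_len(nAxes), each = 2)[ok]
  props <- proposals[ok]
  if (length(props) == 0) stop("no paint proposals could be formed")

  res <- .assignPaints(props, propAxis, Ce, hints)
  A <- res$A
  cols <- colnames(Ce)

  # saturation fallback: pigment slot resembling the stain hint
  if ("pigment" %in% cols) {
    ap <- A[, match("pigment", cols)]
    if (sum(ap * hints@stain) > sum(ap * hints@pigment)) {
      Ce2 <- Ce[, cols != "pigment", drop = FALSE]
      res <- .assignPaints(props, propAxis, Ce2, hints)
      A <- res$A
      cols <- colnames(Ce2)
    }
  }
  as <- A[, match("stain", cols)]
  CeUsed <- if (is.null(hintSet)) Ce[, cols, drop = FALSE] else hintSet
  q <- drop(.pinv(CeUsed) %*% as)
  conf <- max(0, q[1]) / max(sum(pmax(0, q)), 1e-12) > hints@confidenceCut
  list(A = A, confident = conf, columns = cols, proposals = props)
}

# choose one proposal per expected colour (distinct axes) minimising the
# weighted specificity criterion
.assignPaints <- function(props, propAxis, Ce, hints) {
  m <- ncol(Ce)
  cols <- colnames(Ce)
  wmap <- c(stain = hints@weights[["stain"]],
            pigment = hints@weights[["pigment"]],
            background = hints@weights[["background"]])
  idxSets <- .arrangements(seq_along(props), m)
  bestVal <- Inf; bestA <- NULL
  for (sel in idxSets) {
    if (length(unique(propAxis[sel])) < m) next
    A <- do.call(cbind, props[sel])
    val <- 0
    for (i in seq_len(m)) {
      num <- wmap[[cols[i]]] * sum((Ce[, i] - A[, i])^2)
      den <- if (m > 1)
        sum(vapply(setdiff(seq_len(m), i), function(j)
          sqrt(sum((Ce[, i] - A[, j])^2)), numeric(1)))
      else 1
      val <- val + num / max(den, 1e-12)
    }
    if (val < bestVal) { bestVal <- val; bestA <- A }
  }
  if (is.null(bestA))
    stop("no valid proposal assignment (fewer axes than expected colours)")
  colnames(bestA) <- cols
  list(A = bestA, value = bestVal)
}

# all ordered arrangements of k elements from v
.arrangements <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .arrangements(v[-i], k - 1))
      out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Unmix pixels against a paint matrix
#'
#' Solves \code{X = A S} per pixel in the least-squares sense. The first
#' source row is the stain amount; further rows follow the paint-matrix
#' column order.
#'
#' @param pixels N x 3 CMY pixels.
#' @param A 3 x m paint matrix of full column rank.
#' @return N x m matrix of source amounts.
#' @export
unmixPaints <- function(pixels, A) {
  A <- as.matrix(A)
  if (qr(A)$rank < ncol(A)) stop("paint matrix is rank deficient")
  X <- as.matrix(pixels)
  t(solve(crossprod(A), t(A) %*% t(X)))
}

#' Adaptive threshold for a stain distribution
#'
#' Models the stain values inside the outline as a two-component Gaussian
#' mixture (noise + signal) and sets the threshold at
#' \code{min_i(mu_i + 2 sigma_i)} so that about 95\% of the noise falls
#' below it, clamped to [0.25, 0.67]: weaker values are too close to white
#' to matter and stronger values are significant regardless. A failed
#' mixture fit yields the lower clamp with a warning.
#'
#' @param values numeric vector of stain amounts (>= 50 values).
#' @return the threshold t.
#' @export
adaptiveThreshold <- function(values) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 50)
  s <- sd(values)
  if (!is.finite(s) || s < 1e-6)
    return(min(0.67, max(0.25, mean(values) + 2 * max(s, 0))))
  if (length(values) > 5000)   # quantile-preserving subsample for the fit
    values <- quantile(values, seq(0, 1, length.out = 5000), names = FALSE)
  fit <- NULL
  for (mn in c("V", "E")) {
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(values, G = 2, modelNames = mn,
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$parameters$mean)) break
    fit <- NULL
  }
  if (is.null(fit)) {
    # degenerate distribution (e.g. a single narrow mode): treat it all as
    # noise and place the threshold two standard deviations above it
    s <- sd(values)
    if (is.finite(s)) {
      warning("two-component mixture fit failed; using a single Gaussian")
      return(min(0.67, max(0.25, mean(values) + 2 * s)))
    }
    warning("threshold estimation failed; threshold set to 0.25")
    return(0.25)
  }
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1L) sg <- rep(sg, length(mu))
  min(0.67, max(0.25, min(mu + 2 * sg)))
}

#' Smooth mask suppressing background bleed-through at the embryo rim
#'
#' Background colour with a non-zero projection on the stain colour leaves a
#' rim of false stain just inside the outline. The outline is eroded
#' iteratively (up to 10 rounds, or until the mean stain in the current
#' morphological-gradient band exceeds the background mean plus two standard
#' deviations); a sigmoid profile (steepness 1 per pixel) is placed with its
#' inflexion at the band distance of minimum mean stain — or halfway to the
#' maximum when the band means only increase — and multiplies the stain map.
#'
#' @param stainMap H x W stain raster.
#' @param mask binary embryo outline mask.
#' @return list: \code{map} the masked stain raster, \code{mask} the smooth
#'   mask itself, \code{inflexion} the distance used.
#' @export
bleedMask <- function(stainMap, mask) {
  mask <- (mask > 0) * 1
  bgVals <- stainMap[mask == 0]
  m0 <- mean(bgVals); s0 <- sd(bgVals)
  if (!is.finite(s0)) s0 <- 0
  # bleed-through requires the background itself to project on the stain
  # colour; a near-zero background stain level means there is nothing to
  # suppress
  if (!is.finite(m0) || m0 <= 0.05) {
    depth <- .fromEB(EBImage::distmap(.asEB(mask)))
    sm <- 1 / (1 + exp(-depth))
    sm[mask == 0] <- 0
    return(list(map = stainMap * sm, mask = sm, inflexion = 0))
  }
  cur <- mask
  bandMeans <- numeric(0)
  brush <- EBImage::makeBrush(3, "box")
  for (k in 1:10) {
    er <- .fromEB(EBImage::erode(.asEB(cur), brush))
    band <- cur > 0 & er == 0
    if (!any(band)) break
    bm <- mean(stainMap[band])
    if (length(bandMeans) > 0 && bm > m0 + 2 * s0) break
    bandMeans <- c(bandMeans, bm)
    cur <- er
    if (sum(cur) == 0) break
  }
  if (sum(cur) == 0 && length(bandMeans) >= 10) {
    warning("embryo outline eroded away; bleed mask not applied")
    return(list(map = stainMap * mask, mask = mask, inflexion = 0))
  }
  dstar <- if (length(bandMeans) == 0) 0
  else if (length(bandMeans) >= 2 && all(diff(bandMeans) > 0))
    (which.max(bandMeans) - 1) / 2
  else which.min(bandMeans) - 1
  depth <- .fromEB(EBImage::distmap(.asEB(mask)))
  sm <- 1 / (1 + exp(-(depth - dstar)))
  sm[mask == 0] <- 0
  list(map = stainMap * sm, mask = sm, inflexion = dstar)
}

#' Extract the stain and pigment pattern of one image
#'
#' Full decomposition pipeline for an already-segmented image: CMY
#' conversion, component-count estimation, expected-colour resolution and
#' hint adjustment, paint-matrix estimation, per-pixel unmixing, rim
#' bleed-through masking, adaptive thresholding and scoring (85th percentile
#' of the thresholded stain inside the outline).
#'
#' @param record an \linkS4class{ImageRecord} (luminosity-compensated via
#'   \code{\link{compensateLuminosity}} when part of a group).
#' @param seg its \linkS4class{SegmentationResult}.
#' @param hints a \linkS4class{ColourHints} object.
#' @param seed RNG seed.
#' @param maxPixels cap on embryo pixels used for the ICA estimation stage
#'   (maps are always computed for every pixel).
#' @return a \linkS4class{StainResult}.
#' @export
extractPattern <- function(record, seg, hints = colourHints(), seed = 1,
                           maxPixels = 40000L) {
  cmy <- toCmy(record)@pixels
  d <- dim(cmy)
  Xall <- matrix(cmy, ncol = 3L)
  inMask <- as.vector(embryoMask(seg) > 0)
  Xe <- Xall[inMask, , drop = FALSE]
  if (nrow(Xe) < 100) stop("embryo region too small for stain extraction")
  Xest <- if (nrow(Xe) > maxPixels)
    Xe[.withSeed(seed, sample(nrow(Xe), maxPixels)), , drop = FALSE] else Xe
  cbVec <- .unit(colMeans(Xall[!inMask, , drop = FALSE]))

  est <- estimateNComponents(Xest, seed = seed)
  Ce <- resolveExpectedColours(est$n, hints, cbVec, Xest, est$model)
  if ("pigment" %in% colnames(Ce)) {
    adj <- adjustHintColours(hints@stain, hints@pigment, Xest,
                             limitDeg = hints@rotationLimit)
    Ce[, "stain"] <- adj$cs
    Ce[, "pigment"] <- adj$cp
  }
  csAdj <- if ("stain" %in% colnames(Ce)) Ce[, "stain"] else hints@stain
  cpAdj <- if ("pigment" %in% colnames(Ce)) Ce[, "pigment"] else hints@pigment
  fullSet <- cbind(csAdj, cpAdj, cbVec)
  pm <- estimatePaintMatrix(Xest, est$model, Ce, hints, hintSet = fullSet)

  S <- unmixPaints(Xall, pm$A)
  stain <- matrix(.clamp(S[, 1], 0, 1), d[1], d[2])
  stain[!embryoMask(seg)] <- 0
  pig <- if ("pigment" %in% pm$columns) {
    p <- matrix(.clamp(S[, match("pigment", pm$columns)], 0, 1), d[1], d[2])
    p[!embryoMask(seg)] <- 0
    p
  } else matrix(0, d[1], d[2])

  stainRaw <- matrix(.clamp(S[, 1], 0, 1), d[1], d[2])
  bm <- bleedMask(stainRaw, embryoMask(seg))
  stain <- bm$map
  stain[embryoMask(seg) == 0] <- 0
  # an unconfident stain colour means the recovered component is really
  # pigment or background bleed: there is no stain distribution to report
  if (!pm$confident) stain[] <- 0

  vals <- stain[embryoMask(seg) > 0]
  t <- if (length(vals) >= 50) adaptiveThreshold(vals) else 0.25
  thr <- vals
  thr[thr <= t] <- 0
  score <- unname(quantile(thr, 0.85))

  new("StainResult", stainMap = stain, pigmentMap = pig,
      paintMatrix = pm$A, nComponents = as.integer(est$n),
      threshold = t, confident = pm$confident, stainScore = score)
}
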