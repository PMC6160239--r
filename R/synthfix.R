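#' Specification for a synthetic embryo image
#'
#' Describes one synthetic whole-mount image: frame size, background regime,
#' embryo geometry, preparation type, stain/pigment patch layout and imaging
#' nuisances. Defaults emulate the two imaging regimes of the collections the
#' algorithms target: un-cleared embryos (opaque body, red-brown pigment,
#' blue-purple stain) photographed on orange/red backgrounds, and cleared
#' (translucent) embryos on grey backgrounds.
#'
#' @param width,height frame size in pixels.
#' @param background one of "uniform-orange", "uniform-grey", "gradient",
#'   "granular" (crushed-ice-like texture).
#' @param cleared logical; translucent embryo body.
#' @param shape "ellipse" or "bean".
#' @param centre embryo centre as fractions of (width, height).
#' @param sizeFraction embryo area as a fraction of the frame area.
#' @param aspect minor/major axis ratio.
#' @param angleDeg embryo major-axis angle, degrees.
#' @param stainLayout list of stain patches, each \code{list(u =, v =, r =)}
#'   in embryo-local fractional coordinates (u along the major axis); NULL
#'   for the default single patch, \code{list()} for an unstained embryo.
#' @param stainIntensity stain blending strength in (0, 1].
#' @param pigmentLayout like \code{stainLayout}, for pigment patches.
#' @param patchRotationDeg extra in-plane rotation of the patch layout about
#'   the embryo centre (camera roll; alignment-removable).
#' @param viewLongitudeDeg viewpoint longitude for quasi-spherical embryos:
#'   patch positions are treated as points on a sphere and rotated about the
#'   vertical axis before orthographic projection, so different longitudes
#'   expose genuinely different pattern content (patches on the far
#'   hemisphere are hidden).
#' @param edgeTouching logical; when TRUE the embryo may extend beyond the
#'   frame, when FALSE an embryo that does not fit is an error.
#' @param bleed background bleed-through strength at the embryo rim (the
#'   semi-translucent edge picks up background colour, decaying inward).
#' @param illumGradient relative left-right illumination ramp (e.g. 0.1).
#' @param noiseSd per-channel Gaussian noise sd on the 8-bit scale.
#' @param gene,stage,orientation metadata stored in the generated record.
#' @return a list of class \code{embryoSpec}.
#' @export
embryoSpec <- function(width = 160, height = 120,
                       background = c("uniform-orange", "uniform-grey",
                                      "gradient", "granular"),
                       cleared = FALSE, shape = c("ellipse", "bean"),
                       centre = c(0.5, 0.5), sizeFraction = 0.30,
                       aspect = 0.7, angleDeg = 15,
                       stainLayout = NULL, stainIntensity = 0.85,
                       pigmentLayout = NULL, patchRotationDeg = 0,
                       viewLongitudeDeg = 0,
                       edgeTouching = FALSE, bleed = 0.5, illumGradient = 0,
                       noiseSd = 2.5, gene = NA_character_,
                       stage = NA_integer_, orientation = NA_character_) {
  background <- match.arg(background)
  shape <- match.arg(shape)
  if (is.null(stainLayout))
    stainLayout <- list(list(u = 0.45, v = -0.15, r = 0.5),
                        list(u = 0.3, v = 0.45, r = 0.4))
  if (is.null(pigmentLayout))
    pigmentLayout <- if (cleared) list() else
      list(list(u = -0.5, v = 0.3, r = 0.8),
           list(u = -0.25, v = -0.4, r = 0.6))
  structure(list(width = width, height = height, background = background,
                 cleared = cleared, shape = shape, centre = centre,
                 sizeFraction = sizeFraction, aspect = aspect,
                 angleDeg = angleDeg, stainLayout = stainLayout,
                 stainIntensity = stainIntensity,
                 pigmentLayout = pigmentLayout,
                 patchRotationDeg = patchRotationDeg,
                 viewLongitudeDeg = viewLongitudeDeg,
                 edgeTouching = edgeTouching, bleed = bleed,
                 illumGradient = illumGradient,
                 noiseSd = noiseSd, gene = gene, stage = stage,
                 orientation = orientation),
            class = "embryoSpec")
}

#' Render a synthetic embryo image with exact ground truth
#'
#' Deterministically renders the image described by an \code{embryoSpec}.
#' Ground-truth masks are exact by construction (hard geometric shapes;
#' blending and noise affect only the rendered pixels).
#'
#' @param spec an \code{\link{embryoSpec}}.
#' @param seed RNG seed; the same spec and seed give identical pixels.
#' @return list: \code{record} (\linkS4class{ImageRecord}), \code{masks}
#'   (list of binary H x W matrices \code{embryo}, \code{stain},
#'   \code{pigment}).
#' @export
makeEmbryoImage <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "embryoSpec"))
  .withSeed(seed, .renderEmbryo(spec))
}

.renderEmbryo <- function(spec) {
  W <- spec$width; H <- spec$height
  xx <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  yy <- matrix(rep(seq_len(H) - 1, W), H, W)
  cx <- spec$centre[1] * W; cy <- spec$centre[2] * H

  A <- spec$sizeFraction * W * H
  a <- sqrt(A / (pi * spec$aspect)); b <- a * spec$aspect
  th <- spec$angleDeg * pi / 180
  u <- cos(th) * (xx - cx) + sin(th) * (yy - cy)
  v <- -sin(th) * (xx - cx) + cos(th) * (yy - cy)

  ex <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ey <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  xlo <- cx - ex; xhi <- cx + ex; ylo <- cy - ey; yhi <- cy + ey
  if (spec$shape == "bean") {       # union with the secondary lobe's box
    dx <- cos(th) * 0.55 * a - sin(th) * 0.35 * b
    dy <- sin(th) * 0.55 * a + cos(th) * 0.35 * b
    exL <- sqrt((0.55 * a * cos(th))^2 + (0.55 * b * sin(th))^2)
    eyL <- sqrt((0.55 * a * sin(th))^2 + (0.55 * b * cos(th))^2)
    xlo <- min(xlo, cx + dx - exL); xhi <- max(xhi, cx + dx + exL)
    ylo <- min(ylo, cy + dy - eyL); yhi <- max(yhi, cy + dy + eyL)
  }
  if (!spec$edgeTouching && (xlo < 0 || xhi > W || ylo < 0 || yhi > H))
    stop("infeasible geometry: embryo extends beyond the frame but ",
         "edgeTouching is FALSE")

  embryo <- (u / a)^2 + (v / b)^2 <= 1
  if (spec$shape == "bean") {
    u2 <- u - 0.55 * a; v2 <- v - 0.35 * b
    embryo <- embryo | ((u2 / (0.55 * a))^2 + (v2 / (0.55 * b))^2 <= 1)
  }

  phr <- spec$patchRotationDeg * pi / 180
  # hard mask = exact ground truth; soft profile = rendered intensity with
  # the gradual centre-to-edge shading of real histochemical staining
  vlon <- spec$viewLongitudeDeg * pi / 180
  patchFields <- function(layout) {
    m <- matrix(FALSE, H, W)
    soft <- matrix(0, H, W)
    for (p in layout) {
      pu0 <- p$u; pv0 <- p$v
      if (vlon != 0) {
        lon <- asin(.clamp(p$u, -1, 1)) + vlon
        lat <- asin(.clamp(p$v, -1, 1))
        if (cos(lon) * cos(lat) <= 0.05) next   # far hemisphere: hidden
        pu0 <- sin(lon) * cos(lat)
        pv0 <- sin(lat)
      }
      pu <- cos(phr) * pu0 * a - sin(phr) * pv0 * b
      pv <- sin(phr) * pu0 * a + cos(phr) * pv0 * b
      r <- p$r * b
      d2 <- ((u - pu)^2 + (v - pv)^2) / r^2
      m <- m | (d2 <= 1)
      soft <- pmax(soft, .clamp(1.25 * (1 - d2), 0, 1))
    }
    list(mask = m & embryo, soft = soft * embryo)
  }
  stainF <- patchFields(spec$stainLayout)
  pigF <- patchFields(spec$pigmentLayout)
  stain <- stainF$mask
  pigment <- pigF$mask

  bgNoise <- function(base) {
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- base[ch]
    img
  }
  img <- switch(spec$background,
    "uniform-orange" = bgNoise(c(235, 150, 70)),
    "uniform-grey" = bgNoise(c(170, 170, 170)),
    "gradient" = {
      g <- bgNoise(c(225, 140, 75))
      ramp <- 45 * (xx / W - 0.5) + 25 * (yy / H - 0.5)
      for (ch in 1:3) g[, , ch] <- g[, , ch] + ramp
      g
    },
    "granular" = {
      g <- bgNoise(c(185, 185, 195))
      tex <- matrix(rnorm(H * W), H, W)
      tex <- .fromEB(EBImage::gblur(.asEB(tex), sigma = 1.6)) * 90
      for (ch in 1:3) g[, , ch] <- g[, , ch] + tex
      g
    })

  bodyTint <- c(195, 180, 150)
  stainHue <- c(70, 60, 150)      # blue-purple chromogenic stain
  pigmentHue <- c(85, 55, 40)     # dark red-brown melanin
  softStain <- stainF$soft * spec$stainIntensity
  softPig <- pigF$soft * 0.9

  depth <- .fromEB(EBImage::distmap(.asEB(embryo * 1)))
  beta <- spec$bleed * exp(-pmax(depth - 1, 0) / 8)
  for (ch in 1:3) {
    p <- img[, , ch]
    body <- if (spec$cleared) 0.55 * p[embryo] + 0.45 * bodyTint[ch]
            else bodyTint[ch]
    bodyBled <- body * (1 - beta[embryo]) + p[embryo] * beta[embryo]
    p[embryo] <- bodyBled
    p <- p * (1 - softPig) + pigmentHue[ch] * softPig
    p <- p * (1 - softStain) + stainHue[ch] * softStain
    img[, , ch] <- p
  }

  if (spec$illumGradient != 0) {
    ramp <- 1 + spec$illumGradient * (xx / W - 0.5)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
  }
  img <- img + array(rnorm(H * W * 3, sd = spec$noiseSd), c(H, W, 3))
  img <- round(.clamp(img, 0, 255))

  rec <- new("ImageRecord", pixels = img, path = "",
             gene = spec$gene, stage = spec$stage,
             orientationTag = spec$orientation,
             cleared = ifelse(spec$cleared, "cleared", "uncleared"))
  list(record = rec,
       masks = list(embryo = embryo * 1, stain = (stain & embryo) * 1,
                    pigment = (pigment & embryo) * 1))
}

#' Render one stain pattern at several viewing angles
#'
#' Emulates photographing a quasi-spherical embryo from different
#' directions. Each requested angle is a viewpoint longitude: the stain
#' layout lives on the embryo sphere and different longitudes expose
#' different pattern content. Replicates within a viewpoint differ by
#' in-plane camera roll (which affine alignment can undo) and optional
#' scale jitter. The true view index is stored in the orientation tag for
#' downstream partition scoring.
#'
#' @param patternSpec base \code{\link{embryoSpec}}; its stain layout
#'   defines the pattern (spread patches over longitudes so every viewpoint
#'   shows some stain).
#' @param angles numeric vector of viewpoint longitudes in degrees
#'   (>= 2 values).
#' @param seed RNG seed.
#' @param replicates images per viewpoint.
#' @param rollJitterDeg sd of the per-image in-plane roll.
#' @param scaleJitter sd of per-image relative size jitter.
#' @param inPlane when TRUE the angles are applied as pure in-plane
#'   rotations of the layout instead (all images then show one viewpoint;
#'   useful for alignment tests where maps must be exact rotations).
#' @return list of \code{makeEmbryoImage} results; each record's orientation
#'   tag is \code{"v<i>"} for the i-th angle.
#' @export
makeViewSet <- function(patternSpec, angles, seed = 1, replicates = 1,
                        rollJitterDeg = 0, scaleJitter = 0,
                        inPlane = FALSE) {
  stopifnot(length(angles) >= 2)
  out <- list()
  k <- 0L
  for (i in seq_along(angles)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      sp <- patternSpec
      jit <- .withSeed(seed * 1000L + k, c(rnorm(1, sd = rollJitterDeg),
                                           rnorm(1, sd = scaleJitter)))
      if (inPlane) {
        sp$patchRotationDeg <- angles[i] + jit[1]
      } else {
        sp$viewLongitudeDeg <- angles[i]
        sp$patchRotationDeg <- jit[1]
      }
      sp$sizeFraction <- sp$sizeFraction * (1 + jit[2])
      sp$orientation <- paste0("v", i)
      out[[k]] <- makeEmbryoImage(sp, seed = seed * 1000L + 500L + k)
    }
  }
  out
}

#' Materialise a synthetic image collection on disk
#'
#' Writes a redundant collection (genes x stages x views, half un-cleared on
#' orange backgrounds and half cleared on grey) as PNG files named
#' \code{<gene>_st<stage>_v<k>.png}, plus a \code{manifest.tsv} with the
#' ground-truth metadata. Spherical-stage groups (stage < 22) contain two
#' distinct view orientations of one stain pattern.
#'
#' @param dir output directory.
#' @param genes character vector of gene names.
#' @param stages integer stages (values < 22 get multi-view groups).
#' @param nViews images per gene/stage (split between preparations).
#' @param seed RNG seed.
#' @return invisibly, the manifest data.frame.
#' @export
makeFixtureCollection <- function(dir, genes = c("genea", "geneb", "genec"),
                                  stages = c(15L, 30L), nViews = 8L,
                                  seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- NULL
  gi <- 0L
  for (g in genes) {
    gi <- gi + 1L
    for (st in stages) {
      perPrep <- nViews %/% 2L
      vi <- 0L
      for (prep in c(FALSE, TRUE)) {
        base <- embryoSpec(
          width = 120, height = 90,
          background = if (prep) "uniform-grey" else "uniform-orange",
          cleared = prep, shape = "ellipse",
          aspect = if (st < 22) 0.95 else 0.65,
          angleDeg = 10 * gi, sizeFraction = 0.42,
          stainIntensity = 0.9, bleed = 0.35,
          stainLayout = list(list(u = 0.35, v = -0.2, r = 0.55),
                             list(u = -0.6, v = 0.35, r = 0.45)),
          pigmentLayout = list(),
          gene = g, stage = st)
        sds <- seed + 7919L * gi + 101L * st + as.integer(prep)
        imgs <- if (st < 22) {
          makeViewSet(base, angles = c(0, 90), seed = sds,
                      replicates = ceiling(perPrep / 2), rollJitterDeg = 6)
        } else {
          lapply(seq_len(perPrep), function(r) {
            sp <- base
            sp$angleDeg <- sp$angleDeg + .withSeed(sds + r, rnorm(1, sd = 4))
            sp$orientation <- "v1"
            makeEmbryoImage(sp, seed = sds + 50L + r)
          })
        }
        imgs <- imgs[seq_len(perPrep)]
        for (im in imgs) {
          vi <- vi + 1L
          fn <- sprintf("%s_st%d_v%d.png", g, st, vi)
          EBImage::writeImage(.rgbArrayToEb(imagePixels(im$record)),
                              file.path(dir, fn))
          manifest <- rbind(manifest, data.frame(
            file = fn, gene = g, stage = st,
            cleared = clearedState(im$record),
            trueView = orientationTag(im$record),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
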