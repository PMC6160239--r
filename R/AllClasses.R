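#' @import methods
#' @importFrom stats cov cor sd quantile qbeta optim optimize rnorm runif var median prcomp pnorm setNames kmeans
#' @importFrom utils head tail write.table read.table combn
#' @importFrom grDevices convertColor col2rgb
NULL

#' Single WISH photograph with parsed metadata
#'
#' Container for one whole-mount in situ hybridisation (WISH) image: an 8-bit
#' RGB raster plus the metadata conventionally embedded in the file name
#' (gene identifier, Nieuwkoop-Faber stage, optional orientation tag) and the
#' cleared/un-cleared preparation state.
#'
#' @slot pixels numeric array H x W x 3, 8-bit RGB values in [0, 255];
#'   row index is y (down), column index is x (right).
#' @slot path file path the image was read from ("" for in-memory images).
#' @slot gene gene identifier or NA when absent from the file name.
#' @slot stage integer NF developmental stage or NA.
#' @slot orientationTag free-text orientation annotation or NA.
#' @slot cleared one of "cleared", "uncleared", "unknown".
#' @export
setClass("ImageRecord",
  representation(pixels = "array", path = "character", gene = "character",
                 stage = "integer", orientationTag = "character",
                 cleared = "character"),
  prototype(path = "", gene = NA_character_, stage = NA_integer_,
            orientationTag = NA_character_, cleared = "unknown"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 8L || d[2] < 8L)
      return("image must be at least 8 x 8 pixels")
    r <- range(object@pixels)
    if (!all(is.finite(r)) || r[1] < 0 || r[2] > 255)
      return("pixel channels must lie in [0, 255]")
    if (!object@cleared %in% c("cleared", "uncleared", "unknown"))
      return("cleared must be 'cleared', 'uncleared' or 'unknown'")
    TRUE
  })

#' Real-valued colour-space rasters
#'
#' \code{LabImage} holds CIELAB pixels (L in [0, 100], a and b in
#' [-128, 127]); \code{CMYImage} holds subtractive ink values, each channel
#' in [0, 1], defined as 1 - RGB/255.
#'
#' @slot pixels numeric array H x W x 3.
#' @aliases CMYImage-class
#' @export
setClass("LabImage", representation(pixels = "array"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L) return("pixels must be H x W x 3")
    L <- object@pixels[, , 1]
    if (min(L) < -1e-6 || max(L) > 100 + 1e-6)
      return("L channel out of [0, 100]")
    TRUE
  })

#' @rdname LabImage-class
#' @export
setClass("CMYImage", representation(pixels = "array"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L) return("pixels must be H x W x 3")
    r <- range(object@pixels)
    if (r[1] < -1e-6 || r[2] > 1 + 1e-6) return("CMY channels out of [0, 1]")
    TRUE
  })

#' Embryo segmentation result
#'
#' Output of \code{\link{segmentEmbryo}}: a native-resolution binary embryo
#' mask with exactly one connected foreground component, its tight bounding
#' box, the incomplete-embryo (frame-touching) flag, the estimated background
#' colour, and the low-resolution per-pixel log-likelihood maps under the
#' fitted background/foreground mixture components.
#'
#' @slot mask integer/numeric H x W matrix, 1 = embryo.
#' @slot bbox numeric length-4 vector (x0, y0, x1, y1), 0-based, half-open.
#' @slot incomplete logical; TRUE when the embryo outline touches the frame
#'   in both detection rounds.
#' @slot backgroundColour length-3 LAB triple, mean colour of the background
#'   component at working resolution.
#' @slot bgLogLik,fgLogLik low-resolution matrices of log P(pixel | component)
#'   for the background component and the pooled foreground components.
#' @slot scaleFactor native-to-working-resolution downscale factor.
#' @export
setClass("SegmentationResult",
  representation(mask = "matrix", bbox = "numeric", incomplete = "logical",
                 backgroundColour = "numeric", bgLogLik = "matrix",
                 fgLogLik = "matrix", scaleFactor = "numeric"),
  validity = function(object) {
    if (length(object@bbox) != 4L) return("bbox must have 4 entries")
    if (sum(object@mask) < 1) return("mask is empty")
    bb <- .maskBBox(object@mask)
    if (!isTRUE(all.equal(as.numeric(bb), as.numeric(object@bbox))))
      return("bbox is not the tight bounding box of the mask")
    if (.countComponents(object@mask) != 1L)
      return("mask must have exactly one connected foreground component")
    TRUE
  })

#' Stain/pigment decomposition result
#'
#' Output of \code{\link{extractPattern}}: per-pixel stain and pigment
#' intensity maps (zero outside the embryo mask), the estimated paint matrix
#' with unit-length CMY columns, the adaptive threshold, the stain-colour
#' confidence flag and the scalar stain score (85th percentile of the
#' thresholded stain inside the mask).
#'
#' @slot stainMap,pigmentMap numeric H x W rasters in [0, 1]; pigmentMap may
#'   be all-zero when no pigment component was retained.
#' @slot paintMatrix 3 x n matrix; columns are unit-length CMY paint colours.
#' @slot nComponents estimated number of independent colour components (1-3).
#' @slot threshold adaptive stain threshold, clamped to [0.25, 0.67].
#' @slot confident TRUE when the stain hint contributes more than the
#'   confidence cut to the recovered stain colour.
#' @slot stainScore 85th percentile of the thresholded stain inside the mask.
#' @export
setClass("StainResult",
  representation(stainMap = "matrix", pigmentMap = "matrix",
                 paintMatrix = "matrix", nComponents = "integer",
                 threshold = "numeric", confident = "logical",
                 stainScore = "numeric"),
  validity = function(object) {
    if (object@threshold < 0.25 - 1e-9 || object@threshold > 0.67 + 1e-9)
      return("threshold outside [0.25, 0.67]")
    if (nrow(object@paintMatrix) != 3L)
      return("paintMatrix must have 3 rows (CMY)")
    nrm <- sqrt(colSums(object@paintMatrix^2))
    if (any(abs(nrm - 1) > 1e-6))
      return("paintMatrix columns must be unit length")
    if (object@stainScore < 0 || object@stainScore > 1)
      return("stainScore outside [0, 1]")
    r <- range(object@stainMap)
    if (r[1] < 0 || r[2] > 1) return("stainMap outside [0, 1]")
    TRUE
  })

#' Colour hints for stain/pigment unmixing
#'
#' Expected stain and pigment hues in unit-length CMY coordinates together
#' with the unmixing constants: per-colour confidence weights, the minimum
#' ink length of usable pixels, the effective distance from an independent
#' axis, the hint-rotation limit and the stain-confidence cut.
#'
#' @slot stain,pigment unit-length CMY hint vectors.
#' @slot weights named numeric: confidence weights for stain, pigment and
#'   background (defaults 0.5, 0.05, 1).
#' @slot lMin minimum CMY vector length of pixels used for paint estimation.
#' @slot dMax effective colour distance from an independent axis.
#' @slot rotationLimit hint-plane rotation limit in degrees.
#' @slot confidenceCut minimum relative contribution of the stain hint for a
#'   confident stain-colour call.
#' @export
setClass("ColourHints",
  representation(stain = "numeric", pigment = "numeric", weights = "numeric",
                 lMin = "numeric", dMax = "numeric", rotationLimit = "numeric",
                 confidenceCut = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@stain^2)) - 1) > 1e-6 ||
        abs(sqrt(sum(object@pigment^2)) - 1) > 1e-6)
      return("hint vectors must be unit length")
    if (any(object@weights <= 0)) return("weights must be positive")
    TRUE
  })

#' Pairwise expression-pattern dissimilarities and their clustering
#'
#' Symmetric matrix of affine-alignment distances between the stain patterns
#' of a gene/stage group, the cluster labels obtained by affinity propagation
#' on the negated distances, and each image's total similarity to the other
#' members of its cluster.
#'
#' @slot distances symmetric n x n non-negative matrix, zero diagonal.
#' @slot labels integer cluster labels (at most 4 clusters).
#' @slot exemplars indices of the cluster exemplars.
#' @slot totalSimilarity per-image sum of similarities (negated distances)
#'   to the other images in the same cluster.
#' @export
setClass("ViewClustering",
  representation(distances = "matrix", labels = "integer",
                 exemplars = "integer", totalSimilarity = "numeric"),
  validity = function(object) {
    D <- object@distances
    if (nrow(D) != ncol(D)) return("distances must be square")
    if (max(abs(D - t(D))) > 1e-8) return("distances must be symmetric")
    if (any(abs(diag(D)) > 1e-8)) return("diagonal must be zero")
    if (length(unique(object@labels)) > 4L)
      return("no more than 4 clusters allowed")
    TRUE
  })

#' Selection report for an image collection
#'
#' Per-image ranking table produced by \code{\link{runSelection}} plus the
#' list of failed inputs.
#'
#' @slot table data.frame with columns path, gene, stage, cleared, cluster,
#'   rank, score, incomplete, selected.
#' @slot failures character vector of file paths that could not be analysed.
#' @slot outDir output directory the report and crops were written to.
#' @export
setClass("SelectionReport",
  representation(table = "data.frame", failures = "character",
                 outDir = "character"))
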