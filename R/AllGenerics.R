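# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname ImageRecord-class
#' @param object,x an object of the documented class
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname ImageRecord-class
#' @export
setGeneric("imagePath", function(object) standardGeneric("imagePath"))
#' @rdname ImageRecord-class
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @rdname ImageRecord-class
#' @export
setGeneric("nfStage", function(object) standardGeneric("nfStage"))
#' @rdname ImageRecord-class
#' @export
setGeneric("orientationTag", function(object) standardGeneric("orientationTag"))
#' @rdname ImageRecord-class
#' @export
setGeneric("clearedState", function(object) standardGeneric("clearedState"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("embryoMask", function(object) standardGeneric("embryoMask"))
#' @rdname SegmentationResult-class
#' @export
setGeneric("boundingBox", function(object) standardGeneric("boundingBox"))
#' @rdname SegmentationResult-class
#' @export
setGeneric("isIncomplete", function(object) standardGeneric("isIncomplete"))
#' @rdname SegmentationResult-class
#' @export
setGeneric("backgroundColour", function(object) standardGeneric("backgroundColour"))

#' @rdname StainResult-class
#' @export
setGeneric("stainMap", function(object) standardGeneric("stainMap"))
#' @rdname StainResult-class
#' @export
setGeneric("pigmentMap", function(object) standardGeneric("pigmentMap"))
#' @rdname StainResult-class
#' @export
setGeneric("paintMatrix", function(object) standardGeneric("paintMatrix"))
#' @rdname StainResult-class
#' @export
setGeneric("stainThreshold", function(object) standardGeneric("stainThreshold"))
#' @rdname StainResult-class
#' @export
setGeneric("stainScore", function(object) standardGeneric("stainScore"))
#' @rdname StainResult-class
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname StainResult-class
#' @export
setGeneric("isConfident", function(object) standardGeneric("isConfident"))
#' @rdname StainResult-class
#' @export
setGeneric("thresholdedStain", function(object) standardGeneric("thresholdedStain"))

#' @rdname ViewClustering-class
#' @export
setGeneric("distanceMatrix", function(object) standardGeneric("distanceMatrix"))
#' @rdname ViewClustering-class
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname ViewClustering-class
#' @export
setGeneric("totalSimilarity", function(object) standardGeneric("totalSimilarity"))

#' @rdname SelectionReport-class
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

setMethod("imagePixels", "ImageRecord", function(object) object@pixels)
setMethod("imagePath", "ImageRecord", function(object) object@path)
setMethod("geneId", "ImageRecord", function(object) object@gene)
setMethod("nfStage", "ImageRecord", function(object) object@stage)
setMethod("orientationTag", "ImageRecord", function(object) object@orientationTag)
setMethod("clearedState", "ImageRecord", function(object) object@cleared)

setMethod("imagePixels", "LabImage", function(object) object@pixels)
setMethod("imagePixels", "CMYImage", function(object) object@pixels)

setMethod("embryoMask", "SegmentationResult", function(object) object@mask)
setMethod("boundingBox", "SegmentationResult", function(object) object@bbox)
setMethod("isIncomplete", "SegmentationResult", function(object) object@incomplete)
setMethod("backgroundColour", "SegmentationResult",
          function(object) object@backgroundColour)

setMethod("stainMap", "StainResult", function(object) object@stainMap)
setMethod("pigmentMap", "StainResult", function(object) object@pigmentMap)
setMethod("paintMatrix", "StainResult", function(object) object@paintMatrix)
setMethod("stainThreshold", "StainResult", function(object) object@threshold)
setMethod("stainScore", "StainResult", function(object) object@stainScore)
setMethod("nComponents", "StainResult", function(object) object@nComponents)
setMethod("isConfident", "StainResult", function(object) object@confident)
setMethod("thresholdedStain", "StainResult", function(object) {
  m <- object@stainMap
  m[m <= object@threshold] <- 0
  m
})

setMethod("distanceMatrix", "ViewClustering", function(object) object@distances)
setMethod("clusterLabels", "ViewClustering", function(object) object@labels)
setMethod("totalSimilarity", "ViewClustering", function(object) object@totalSimilarity)

setMethod("reportTable", "SelectionReport", function(object) object@table)

setMethod("show", "ImageRecord", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageRecord %dx%d  gene=%s stage=%s orientation=%s [%s]\n",
              d[2], d[1],
              ifelse(is.na(object@gene), "<absent>", object@gene),
              ifelse(is.na(object@stage), "<absent>", object@stage),
              ifelse(is.na(object@orientationTag), "<absent>",
                     object@orientationTag),
              object@cleared))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(paste0("SegmentationResult: %d embryo pixels, bbox (%g,%g,%g,%g)",
                     ", incomplete=%s, downscale=%gx\n"),
              sum(object@mask), object@bbox[1], object@bbox[2],
              object@bbox[3], object@bbox[4], object@incomplete,
              object@scaleFactor))
})

setMethod("show", "StainResult", function(object) {
  cat(sprintf(paste0("StainResult: %d paint component(s), threshold=%.3f, ",
                     "stain score=%.3f, confident=%s\n"),
              object@nComponents, object@threshold, object@stainScore,
              object@confident))
})

setMethod("show", "ViewClustering", function(object) {
  cat(sprintf("ViewClustering: %d images in %d cluster(s)\n",
              nrow(object@distances), length(unique(object@labels))))
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d images, %d selected, %d failures\n",
              nrow(object@table), sum(object@table$selected),
              length(object@failures)))
})
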