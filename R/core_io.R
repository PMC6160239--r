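#' Load an image and parse metadata from its file name
#'
#' Reads a PNG/JPEG/TIFF photograph into an \linkS4class{ImageRecord} and
#' fills the metadata slots by matching the file name (without extension)
#' against a template such as \code{"{gene}_st{stage}_{orientation}"}.
#' Trailing template fields are optional: a name matching only a prefix of
#' the template yields a record with the remaining fields absent. A name
#' matching no prefix yields a record with all metadata absent and a warning.
#' Metadata are never guessed.
#'
#' @param path path to an image file.
#' @param namePattern template with placeholders \code{{gene}} (word),
#'   \code{{stage}} (integer) and \code{{orientation}} (word).
#' @param cleared preparation state to record: "cleared", "uncleared" or
#'   "unknown" (default; \code{\link{classifyCollection}} can fill it in).
#' @return an \linkS4class{ImageRecord}.
#' @export
loadRecord <- function(path, namePattern = "{gene}_st{stage}_{orientation}",
                       cleared = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path,
                                           ": ", conditionMessage(e)))
  px <- .ebToRgbArray(img)
  meta <- parseImageName(basename(path), namePattern)
  new("ImageRecord", pixels = px, path = path, gene = meta$gene,
      stage = meta$stage, orientationTag = meta$orientation, cleared = cleared)
}

# EBImage Image -> H x W x 3 array in [0, 255].
.ebToRgbArray <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  px <- aperm(a, c(2, 1, 3)) * 255
  .clamp(px, 0, 255)
}

#' Parse gene/stage/orientation metadata from an image file name
#'
#' @param name file name (the extension is stripped).
#' @param namePattern template, see \code{\link{loadRecord}}.
#' @return list with elements \code{gene}, \code{stage}, \code{orientation}
#'   (NA when absent) and \code{matched}.
#' @export
parseImageName <- function(name, namePattern = "{gene}_st{stage}_{orientation}") {
  stem <- sub("\\.[A-Za-z]+$", "", name)
  fields <- c(gene = "[A-Za-z0-9.-]+", stage = "[0-9]+",
              orientation = "[A-Za-z0-9]+")
  out <- list(gene = NA_character_, stage = NA_integer_,
              orientation = NA_character_, matched = FALSE)

  # split the template into literal and placeholder tokens
  toks <- regmatches(namePattern,
                     gregexpr("\\{(gene|stage|orientation)\\}|[^{]+",
                              namePattern))[[1]]
  isPh <- grepl("^\\{", toks)
  phName <- sub("[{}]", "", sub("\\}", "", toks))

  # try the full template, then drop trailing placeholder (+ literal) pairs
  ends <- which(isPh)
  for (k in rev(seq_along(ends))) {
    upto <- ends[k]
    rx <- "^"
    caps <- character(0)
    for (i in seq_len(upto)) {
      if (isPh[i]) {
        caps <- c(caps, phName[i])
        rx <- paste0(rx, "(", fields[[phName[i]]], ")")
      } else {
        rx <- paste0(rx, gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", toks[i]))
      }
    }
    rx <- paste0(rx, "$")
    m <- regmatches(stem, regexec(rx, stem))[[1]]
    if (length(m) > 0) {
      vals <- m[-1]
      for (i in seq_along(caps)) {
        if (caps[i] == "stage") out$stage <- as.integer(vals[i])
        else out[[caps[i]]] <- vals[i]
      }
      out$matched <- TRUE
      return(out)
    }
  }
  warning("file name '", name, "' does not match pattern '", namePattern,
          "'; metadata left absent")
  out
}

#' Convert an RGB record to CIELAB or CMY
#'
#' CIELAB uses the standard sRGB to CIELAB transform under the D65 white
#' point. CMY is the subtractive ink model \code{1 - RGB/255} per channel:
#' white is zero ink, black is full ink.
#'
#' @param x an \linkS4class{ImageRecord} or H x W x 3 RGB array in [0, 255].
#' @return a \linkS4class{LabImage} or \linkS4class{CMYImage}.
#' @export
toLab <- function(x) {
  px <- if (is(x, "ImageRecord")) x@pixels else x
  d <- dim(px)
  m <- matrix(px, ncol = 3L) / 255
  lab <- convertColor(m, from = "sRGB", to = "Lab")
  lab[, 1] <- .clamp(lab[, 1], 0, 100)
  new("LabImage", pixels = array(lab, d))
}

#' @rdname toLab
#' @export
toCmy <- function(x) {
  px <- if (is(x, "ImageRecord")) x@pixels else x
  new("CMYImage", pixels = 1 - px / 255)
}

# LAB array -> 8-bit RGB array (inverse of toLab up to gamut clipping).
.labToRgbArray <- function(lab) {
  d <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  rgb <- convertColor(m, from = "Lab", to = "sRGB")
  .clamp(array(rgb, d) * 255, 0, 255)
}

#' Write segmentation and stain results for one image
#'
#' Writes, with deterministic names \code{<prefix>_overlay.png},
#' \code{<prefix>_mask.png} and \code{<prefix>.json}: an annotated overlay in
#' register with the original (embryo outline drawn just outside the mask,
#' thresholded stain tinted blue, pigment tinted orange), the binary embryo
#' mask, and a JSON sidecar holding the bounding box, incomplete flag,
#' threshold, stain score, paint matrix and component count in a fixed field
#' order.
#'
#' @param record the analysed \linkS4class{ImageRecord}.
#' @param seg its \linkS4class{SegmentationResult}.
#' @param stain its \linkS4class{StainResult}.
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the image file stem.
#' @return invisibly, the named vector of written paths.
#' @export
writeResults <- function(record, seg, stain, outDir, prefix = NULL) {
  if (is.null(prefix)) {
    prefix <- sub("\\.[A-Za-z]+$", "", basename(record@path))
    if (prefix == "") prefix <- "image"
  }
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outDir)) stop("cannot create directory ", outDir)
  }
  ov <- file.path(outDir, paste0(prefix, "_overlay.png"))
  mk <- file.path(outDir, paste0(prefix, "_mask.png"))
  js <- file.path(outDir, paste0(prefix, ".json"))

  EBImage::writeImage(.rgbArrayToEb(.makeOverlay(record, seg, stain)), ov)
  EBImage::writeImage(EBImage::Image(.asEB(embryoMask(seg))), mk)

  sidecar <- list(path = record@path,
                  bbox = as.numeric(boundingBox(seg)),
                  incomplete = isIncomplete(seg),
                  threshold = stainThreshold(stain),
                  stain_score = stainScore(stain),
                  n_components = nComponents(stain),
                  paint_matrix = unname(apply(paintMatrix(stain), 2,
                                              as.numeric, simplify = FALSE)),
                  background_colour = as.numeric(backgroundColour(seg)))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA), js)
  invisible(c(overlay = ov, mask = mk, sidecar = js))
}

#' Reload a JSON sidecar written by \code{writeResults}
#'
#' @param path path to the sidecar file.
#' @return the sidecar as a list (paint matrix as a 3 x n matrix).
#' @export
readSidecar <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$paint_matrix <- matrix(unlist(x$paint_matrix), nrow = 3L)
  x
}

.rgbArrayToEb <- function(px) {
  EBImage::Image(aperm(px / 255, c(2, 1, 3)), colormode = "Color")
}

.makeOverlay <- function(record, seg, stain) {
  px <- record@pixels
  mask <- embryoMask(seg) > 0
  st <- thresholdedStain(stain)
  pg <- pigmentMap(stain)
  # outline ring sits just outside the mask so unstained embryo pixels stay
  # identical to the original
  ring <- (.fromEB(EBImage::dilate(.asEB(mask * 1),
                                   EBImage::makeBrush(3, "box"))) > 0) & !mask
  tintS <- c(40, 40, 200); tintP <- c(200, 120, 40); ringCol <- c(0, 220, 0)
  for (ch in 1:3) {
    p <- px[, , ch]
    a <- st * 0.6
    p <- p * (1 - a) + tintS[ch] * a
    a <- .clamp(pg, 0, 1) * 0.4
    p <- p * (1 - a) + tintP[ch] * a
    p[ring] <- ringCol[ch]
    px[, , ch] <- p
  }
  .clamp(px, 0, 255)
}
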