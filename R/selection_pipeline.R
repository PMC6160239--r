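# End-to-end redundancy reduction: classify -> segment -> extract -> group ->
# cluster (spherical stages) -> rank -> crop -> report.

#' Group records by gene, stage and preparation
#'
#' @param meta data.frame with columns \code{gene}, \code{stage},
#'   \code{cleared} (one row per image). Rows lacking gene or stage go to an
#'   "ungrouped" bin (still split by preparation).
#' @return named list of row-index vectors; names are
#'   \code{"<gene>|<stage>|<cleared>"} or \code{"ungrouped|<cleared>"}.
#' @export
groupImages <- function(meta) {
  key <- ifelse(is.na(meta$gene) | is.na(meta$stage),
                paste("ungrouped", meta$cleared, sep = "|"),
                paste(meta$gene, meta$stage, meta$cleared, sep = "|"))
  split(seq_len(nrow(meta)), key)
}

#' Rank the images of one group
#'
#' Images whose embryo outline touches the frame are demoted below all
#' complete ones, unless every image in the group is incomplete. Within
#' that, images are ordered by descending score: the 85th-percentile stain
#' score, plus the total intra-cluster similarity when the group was
#' clustered. The representative of each cluster (or of the whole group
#' when unclustered) is its top-ranked image.
#'
#' @param df data.frame with columns \code{score}, \code{incomplete} and
#'   optionally \code{cluster} (NA allowed) and \code{totalSim}; row names
#'   or a \code{path} column provide the tie-break order.
#' @return the data.frame with added \code{rank} (1 = best) and
#'   \code{selected} columns, ordered by rank.
#' @export
rankImages <- function(df) {
  n <- nrow(df)
  if (n == 0) return(cbind(df, rank = integer(0), selected = logical(0)))
  totalSim <- if ("totalSim" %in% names(df)) df$totalSim else rep(0, n)
  totalSim[is.na(totalSim)] <- 0
  eff <- df$score + totalSim
  demote <- if (all(df$incomplete)) rep(FALSE, n) else df$incomplete
  tie <- if ("path" %in% names(df)) df$path else rownames(df)
  ord <- order(demote, -eff, tie)
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  cl <- if ("cluster" %in% names(out)) out$cluster else rep(NA, n)
  sel <- rep(FALSE, n)
  if (all(is.na(cl))) sel[1] <- TRUE else {
    for (c in unique(cl)) sel[which(!is.na(cl) & cl == c)[1]] <- TRUE
    if (any(is.na(cl))) sel[which(is.na(cl))[1]] <- TRUE
  }
  out$selected <- sel
  out
}

#' Crop an image around the embryo for display
#'
#' When the embryo is small (bounding-box area below half the frame area),
#' the image is cropped to the bounding box expanded by 15\% of each box
#' dimension on each side, rounded outward and clamped to the frame;
#' otherwise the image is returned uncropped.
#'
#' @param record an \linkS4class{ImageRecord}.
#' @param bbox bounding box (x0, y0, x1, y1), 0-based half-open.
#' @param smallFraction bbox-to-frame area ratio below which cropping
#'   applies.
#' @return list: \code{pixels} (cropped raster), \code{crop} the realised
#'   (x0, y0, x1, y1), \code{cropped} flag.
#' @export
cropForDisplay <- function(record, bbox, smallFraction = 0.5) {
  px <- record@pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  bw <- bbox[3] - bbox[1]; bh <- bbox[4] - bbox[2]
  if (bw * bh >= smallFraction * W * H)
    return(list(pixels = px, crop = c(0, 0, W, H), cropped = FALSE))
  x0 <- max(0, floor(bbox[1] - 0.15 * bw))
  y0 <- max(0, floor(bbox[2] - 0.15 * bh))
  x1 <- min(W, ceiling(bbox[3] + 0.15 * bw))
  y1 <- min(H, ceiling(bbox[4] + 0.15 * bh))
  list(pixels = px[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE],
       crop = c(x0, y0, x1, y1), cropped = TRUE)
}

#' Run the image selection pipeline on a collection
#'
#' Classifies the collection into cleared and un-cleared preparations,
#' segments each embryo and extracts its stain pattern (with group-wise
#' luminosity compensation), groups images by gene/stage/preparation,
#' clusters quasi-spherical-stage groups (stage below the cutoff) by
#' expression-pattern similarity, ranks each group and selects one
#' representative per cluster cell, cropping it for display. Each image is
#' processed in isolation: a failure is recorded and never aborts the run.
#' The report is written as TSV with canonical (path-sorted) ordering and is
#' byte-identical across reruns with the same seed.
#'
#' @param collectionDir directory of PNG/JPEG/TIFF images.
#' @param outDir output directory for the report and selected crops.
#' @param config list of options: \code{pattern} (file-name template),
#'   \code{stain_hint}, \code{pigment_hint} (hex RGB), \code{stage_cutoff}
#'   (default 22), \code{cap} (clustering raster cap, default 100), plus the
#'   \linkS4class{ColourHints} constants \code{weights}, \code{l_min},
#'   \code{d_max}, \code{rotation_limit}.
#' @param seed RNG seed propagated to every stochastic step.
#' @return a \linkS4class{SelectionReport}.
#' @export
runSelection <- function(collectionDir, outDir = file.path(collectionDir, "selected"),
                         config = list(), seed = 1) {
  if (!dir.exists(collectionDir)) stop("unreadable collection: ", collectionDir)
  pattern <- config$pattern %||% "{gene}_st{stage}_{orientation}"
  cutoff <- config$stage_cutoff %||% 22
  cap <- config$cap %||% 100
  hints <- .configHints(config)
  files <- sort(list.files(collectionDir, "\\.(png|jpg|jpeg|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no images found in ", collectionDir)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  n <- length(files)
  recs <- vector("list", n)
  fail <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    recs[i] <- list(tryCatch(
      suppressWarnings(loadRecord(files[i], pattern)),
      error = function(e) { fail[i] <<- conditionMessage(e); NULL }))
  }
  okLoad <- which(!vapply(recs, is.null, logical(1)))

  # preparation classification from colour signatures
  clearedLab <- rep("unknown", n)
  if (length(okLoad) >= 4) {
    sigs <- do.call(rbind, lapply(recs[okLoad], colourSignature))
    cls <- tryCatch(classifyCollection(sigs, seed = seed),
                    error = function(e) NULL)
    if (!is.null(cls)) clearedLab[okLoad] <- cls$label
  }
  clearedLab[clearedLab == "unknown"] <- "uncleared"

  segs <- vector("list", n); stains <- vector("list", n)
  for (i in okLoad) {
    if (clearedLab[i] == "unclassified") { fail[i] <- "unclassified"; next }
    recs[[i]]@cleared <- clearedLab[i]
    segs[i] <- list(tryCatch(
      suppressWarnings(segmentEmbryo(recs[[i]],
                                     cleared = clearedLab[i] == "cleared",
                                     seed = seed + 17L * i)),
      error = function(e) { fail[i] <<- conditionMessage(e); NULL }))
  }
  okSeg <- which(!vapply(segs, is.null, logical(1)))

  meta <- data.frame(
    path = basename(files),
    gene = vapply(recs, function(r) if (is.null(r)) NA_character_ else r@gene,
                  character(1)),
    stage = vapply(recs, function(r) if (is.null(r)) NA_integer_ else r@stage,
                   integer(1)),
    cleared = clearedLab, stringsAsFactors = FALSE)

  groups <- groupImages(meta[okSeg, , drop = FALSE])
  groups <- lapply(groups, function(g) okSeg[g])

  for (g in groups) {
    comp <- tryCatch(compensateLuminosity(recs[g], segs[g]),
                     error = function(e) recs[g])
    for (k in seq_along(g)) {
      i <- g[k]
      stains[i] <- list(tryCatch(
        suppressWarnings(extractPattern(comp[[k]], segs[[i]], hints,
                                        seed = seed + 23L * i)),
        error = function(e) { fail[i] <<- conditionMessage(e); NULL }))
    }
  }

  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    g <- g[!vapply(stains[g], is.null, logical(1))]
    if (length(g) == 0) next
    st <- meta$stage[g[1]]
    cluster <- rep(NA_integer_, length(g))
    totalSim <- rep(0, length(g))
    if (!is.na(st) && st < cutoff && length(g) >= 2) {
      maps <- lapply(g, function(i) {
        bb <- boundingBox(segs[[i]])
        thresholdedStain(stains[[i]])[(bb[2] + 1):bb[4],
                                      (bb[1] + 1):bb[3], drop = FALSE]
      })
      vc <- tryCatch(
        suppressWarnings(clusterViews(dissimilarityMatrix(maps, cap = cap))),
        error = function(e) NULL)
      if (!is.null(vc)) {
        cluster <- clusterLabels(vc)
        totalSim <- totalSimilarity(vc)
      }
    }
    df <- data.frame(
      path = meta$path[g], gene = meta$gene[g], stage = meta$stage[g],
      cleared = meta$cleared[g], cluster = cluster,
      score = vapply(stains[g], stainScore, numeric(1)),
      totalSim = totalSim,
      incomplete = vapply(segs[g], isIncomplete, logical(1)),
      idx = g, stringsAsFactors = FALSE)
    rows[[gname]] <- rankImages(df)
  }

  tab <- do.call(rbind, unname(rows))
  if (is.null(tab))
    tab <- data.frame(path = character(0), gene = character(0),
                      stage = integer(0), cleared = character(0),
                      cluster = integer(0), score = numeric(0),
                      totalSim = numeric(0), incomplete = logical(0),
                      idx = integer(0), rank = integer(0),
                      selected = logical(0))
  tab <- tab[order(tab$path), , drop = FALSE]
  rownames(tab) <- NULL

  selDir <- file.path(outDir, "representatives")
  if (!dir.exists(selDir)) dir.create(selDir)
  for (r in which(tab$selected)) {
    i <- tab$idx[r]
    cr <- cropForDisplay(recs[[i]], boundingBox(segs[[i]]))
    EBImage::writeImage(.rgbArrayToEb(cr$pixels),
                        file.path(selDir, tab$path[r]))
  }

  rep <- tab[, c("path", "gene", "stage", "cleared", "cluster", "rank",
                 "score", "incomplete", "selected")]
  rep$score <- sprintf("%.6f", rep$score)
  write.table(rep, file.path(outDir, "selection_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  new("SelectionReport", table = tab[, names(tab) != "idx"],
      failures = basename(files)[!is.na(fail)], outDir = outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHints <- function(config) {
  args <- list()
  if (!is.null(config$stain_hint)) args$stainHint <- config$stain_hint
  if (!is.null(config$pigment_hint)) args$pigmentHint <- config$pigment_hint
  if (!is.null(config$weights)) args$weights <- unlist(config$weights)
  if (!is.null(config$l_min)) args$lMin <- config$l_min
  if (!is.null(config$d_max)) args$dMax <- config$d_max
  if (!is.null(config$rotation_limit)) args$rotationLimit <- config$rotation_limit
  do.call(colourHints, args)
}
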