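# Shared helpers: similarity metrics and a session-level cache so expensive
# fixtures (segmentation of standard images) are computed once.

iou <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)
dice <- function(a, b) 2 * sum(a > 0 & b > 0) / (sum(a > 0) + sum(b > 0))

.fixCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixCache)) assign(key, force(expr), .fixCache)
  get(key, .fixCache)
}

# standard un-cleared fixture with stain + pigment, segmented
stdFixture <- function(seed = 2) {
  cached(paste0("std", seed), {
    f <- makeEmbryoImage(embryoSpec(), seed = seed)
    f$seg <- suppressWarnings(segmentEmbryo(f$record, seed = 1))
    f
  })
}

# stain-only cleared fixture, segmented
clearedFixture <- function(seed = 7) {
  cached(paste0("clr", seed), {
    f <- makeEmbryoImage(embryoSpec(background = "uniform-grey",
                                    cleared = TRUE), seed = seed)
    f$seg <- suppressWarnings(segmentEmbryo(f$record, cleared = TRUE,
                                            seed = 1))
    f
  })
}

# a small valid SegmentationResult around a disk mask, for IO tests
diskSegmentation <- function(h = 40, w = 48, r = 12) {
  yy <- matrix(rep(seq_len(h) - 1, w), h, w)
  xx <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  mask <- ((xx - w / 2)^2 + (yy - h / 2)^2 <= r^2) * 1
  new("SegmentationResult", mask = mask, bbox = wishtools:::.maskBBox(mask),
      incomplete = FALSE, backgroundColour = c(70, 10, 40),
      bgLogLik = matrix(-1, 10, 12), fgLogLik = matrix(-2, 10, 12),
      scaleFactor = 1)
}

diskStain <- function(seg) {
  m <- embryoMask(seg) * 0
  new("StainResult", stainMap = m, pigmentMap = m,
      paintMatrix = matrix(wishtools:::.unit(c(0.7, 0.7, 0.3)), ncol = 1,
                           dimnames = list(NULL, "stain")),
      nComponents = 1L, threshold = 0.25, confident = TRUE, stainScore = 0)
}

# flood-fill connected components oracle (EBImage bwlabel is 8-connected;
# use a direct queue-based 4-connected fill, independent of the package's
# igraph route)
floodFillIslands <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextLab <- 0L
  for (start in which(mask > 0)) {
    if (lab[start] > 0) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      y <- (p - 1L) %% h + 1L
      x <- (p - 1L) %/% h + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        y2 <- y + d[1]; x2 <- x + d[2]
        if (y2 >= 1 && y2 <= h && x2 >= 1 && x2 <= w) {
          p2 <- (x2 - 1L) * h + y2
          if (mask[p2] > 0 && lab[p2] == 0L) {
            lab[p2] <- nextLab
            queue <- c(queue, p2)
          }
        }
      }
    }
  }
  lab
}

# brute-force Wallace coefficients by enumerating all item pairs
wallaceBrute <- function(a, b) {
  n <- length(a)
  cnt <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    k <- if (sa && sb) "a" else if (sa) "b" else if (sb) "c" else "d"
    cnt[k] <- cnt[k] + 1
  }
  list(sens = if (cnt["a"] + cnt["b"] > 0)
    unname(cnt["a"] / (cnt["a"] + cnt["b"])) else NA_real_,
    spec = if (cnt["c"] + cnt["d"] > 0)
      unname(cnt["d"] / (cnt["c"] + cnt["d"])) else NA_real_,
    cnt = cnt)
}

rot90mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
rot90matCCW <- function(m) t(m[nrow(m):1, , drop = FALSE])
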