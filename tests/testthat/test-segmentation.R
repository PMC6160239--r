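test_that("pyramid picks the two adjacent layers under the 200 px cap", {
  lab <- array(rep(c(50, 10, -10), each = 1200 * 1600), c(1200, 1600, 3))
  fs <- buildPyramidFeatures(lab)
  expect_equal(fs$dims, c(75, 100))
  expect_equal(fs$factor, 16)
  # constant image: all gradient features exactly zero
  expect_equal(max(abs(fs$features[, 4:9])), 0)
  expect_equal(max(abs(fs$features[, 13:18])), 0)

  lab2 <- array(0, c(150, 190, 3))
  fs2 <- buildPyramidFeatures(lab2)
  expect_equal(fs2$dims, c(150, 190))
  expect_equal(fs2$factor, 1)
})

test_that("whitening keeps informative components and flags degeneracy", {
  set.seed(3)
  # rank-2 data embedded in 18 dims
  basis <- qr.Q(qr(matrix(rnorm(18 * 2), 18)))
  X <- matrix(rnorm(500 * 2), 500) %*% t(basis) + 5
  w <- whitenFeatures(X)
  expect_equal(w$keep, 2L)

  # isotropic data: all 18 kept, whitened covariance ~ identity
  Xi <- matrix(rnorm(10000 * 18), 10000)
  wi <- whitenFeatures(Xi)
  expect_equal(wi$keep, 18L)
  expect_lt(max(abs(cov(wi$Z) - diag(18))), 0.02)

  expect_warning(wc <- whitenFeatures(matrix(7, 50, 18)), "zero-variance")
  expect_equal(ncol(wc$Z), 1L)
  expect_equal(max(abs(wc$Z)), 0)
})

test_that("mixture fitting selects the component count by BIC", {
  set.seed(5)
  h <- 40; w <- 50
  # two well-separated clusters arranged on the grid
  labels <- matrix(1L, h, w); labels[, 26:50] <- 2L
  Z <- matrix(rnorm(h * w * 3, sd = 0.3), h * w, 3)
  Z[as.vector(labels) == 2, 1] <- Z[as.vector(labels) == 2, 1] + 5
  mix <- fitPixelMixture(Z, c(h, w), cleared = FALSE, seed = 1)
  expect_equal(mix$G, 2L)
  agree <- max(mean((mix$assignment == 1) == (labels == 1)),
               mean((mix$assignment == 2) == (labels == 1)))
  expect_gte(agree, 0.99)

  # single-Gaussian data: BIC selects one component
  Z1 <- matrix(rnorm(h * w * 3), h * w, 3)
  expect_equal(fitPixelMixture(Z1, c(h, w), seed = 1)$G, 1L)

  # seeded determinism
  m1 <- fitPixelMixture(Z, c(h, w), seed = 9)
  m2 <- fitPixelMixture(Z, c(h, w), seed = 9)
  expect_identical(m1$assignment, m2$assignment)
})

test_that("background classification matches the closed-form model oracle", {
  h <- 20; w <- 20
  # component A scattered uniformly, B a centred blob
  asg <- matrix(1L, h, w)
  asg[8:13, 8:13] <- 2L
  res <- classifyBackground(asg)
  expect_equal(res$index, 1L)

  # independent numerical evaluation of both closed-form marginals
  oracle <- function(asg) {
    h <- nrow(asg); w <- ncol(asg)
    lg2 <- function(a) 0.5 * log(pi) + lgamma(a) + lgamma(a - 0.5)
    Psi <- diag(c((w / 2)^2, (h / 2)^2))
    sc <- sapply(sort(unique(as.vector(asg))), function(j) {
      xy <- which(asg != j, arr.ind = TRUE)
      X <- rbind(xy[, 2] - 1 - w / 2, xy[, 1] - 1 - h / 2)
      n <- ncol(X)
      sum(asg == j) * (-log(w * h)) +
        0.5 * log(det(Psi)) + lg2((1 + n) / 2) - n * log(pi) -
        ((1 + n) / 2) * log(det(Psi + X %*% t(X)))
    })
    sc
  }
  expect_equal(unname(res$scores), oracle(asg), tolerance = 1e-8)

  # blob moved to a corner: the uniform component still wins
  asg2 <- matrix(1L, h, w)
  asg2[1:6, 1:6] <- 2L
  res2 <- classifyBackground(asg2)
  expect_equal(res2$index, 1L)
  expect_equal(unname(res2$scores), oracle(asg2), tolerance = 1e-8)

  # checkerboard: both components spread identically, no model is
  # substantially better, the edge rule decides by border frequency
  asg3 <- matrix(1L, h, w)
  asg3[(row(asg3) + col(asg3)) %% 2 == 0] <- 2L
  res3 <- classifyBackground(asg3)
  expect_true(res3$fallback)
  border <- c(asg3[1, ], asg3[h, ], asg3[, 1], asg3[, w])
  expect_equal(res3$index, c(1L, 2L)[which.max(c(sum(border == 1),
                                                 sum(border == 2)))])
})

test_that("island extraction equals a flood-fill oracle", {
  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 1; m[8:10, 8:10] <- 1
  isl <- extractIslands(m)
  expect_length(isl, 2)
  expect_equal(sort(lengths(isl)), c(9, 9))

  expect_length(extractIslands((m * 0) + (m > 2)), 0)
  expect_length(extractIslands(m * 0 + 1), 1)

  set.seed(11)
  for (i in 1:20) {
    r <- matrix(rbinom(50 * 50, 1, 0.45), 50, 50)
    isl <- extractIslands(r)
    ref <- floodFillIslands(r)
    expect_equal(length(isl), max(ref))
    got <- integer(50 * 50)
    for (k in seq_along(isl)) got[isl[[k]]] <- k
    # identical partition up to label permutation
    expect_equal(length(unique(paste(got, as.vector(ref)))),
                 max(ref) + as.integer(any(r == 0)))
  }
})

test_that("embryo island selection maximises sqrt(size) * colour distance", {
  lab <- array(0, c(10, 20, 3))
  lab[, , 1] <- 50
  isl <- list(1:100, 101:125)        # sizes 100 and 25
  lab1 <- lab; lab1[, , 2][1:100] <- 1; lab1[, , 2][101:125] <- 3
  expect_equal(selectEmbryoIsland(isl, lab1, c(50, 0, 0)), 2L)

  expect_equal(selectEmbryoIsland(list(1:30), lab1, c(50, 0, 0)), 1L)

  # equal scores: the larger island wins
  lab2 <- lab
  lab2[, , 2][1:100] <- 1            # score 10 * 1 = 10
  lab2[, , 2][101:104] <- 5          # score 2 * 5 = 10
  expect_equal(selectEmbryoIsland(list(1:100, 101:104), lab2, c(50, 0, 0)), 1L)
})

test_that("contour closing fills holes and closes along the frame edge", {
  ann <- matrix(0, 30, 30)
  ann[8:22, 8:22] <- 1; ann[12:18, 12:18] <- 0
  expect_equal(sum(closeAndFill(ann, 1)), 15 * 15)

  solid <- matrix(0, 30, 30); solid[5:20, 5:20] <- 1
  expect_equal(closeAndFill(solid, 1), closeAndFill(closeAndFill(solid, 1), 1))

  # half-disk outline cut by the frame edge: the interior must fill
  h <- 40; w <- 40
  yy <- matrix(rep(seq_len(h) - 1, w), h, w)
  xx <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  d <- sqrt((xx - 0)^2 + (yy - 20)^2)
  ring <- (d >= 12 & d <= 15 & xx <= 15) * 1
  out <- closeAndFill(ring, 3)
  interior <- d < 12 & xx <= 12
  expect_gt(mean(out[interior]), 0.95)
  solidHalf <- (d <= 15 & xx <= 15) * 1
  expect_gt(iou(out, solidHalf), 0.75)
})

test_that("outline smoothing rounds corners under a constant field", {
  m <- matrix(0, 30, 30)
  m[10:21, 10:21] <- 1
  g0 <- matrix(-1, 30, 30)           # constant log-likelihoods
  sm <- smoothOutline(m, g0, g0)
  expect_lt(sum(m) - sum(sm), 0.15 * sum(m))   # area loss below 15%
  expect_gt(sum(m) - sum(sm), 0)               # curvature flow shrinks
  expect_equal(sm[10, 10], 0)                  # corners rounded off
  expect_equal(sm[21, 21], 0)
  expect_equal(sm[15, 15], 1)                  # interior intact

  # a smooth disk with a strongly aligned field barely moves
  h <- 40; w <- 40
  yy <- matrix(rep(seq_len(h) - 1, w), h, w)
  xx <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  disk <- ((xx - 20)^2 + (yy - 20)^2 <= 12^2) * 1
  bgLL <- ifelse(disk > 0, -50, -1)
  fgLL <- ifelse(disk > 0, -1, -50)
  smd <- smoothOutline(disk, bgLL, fgLL)
  expect_gt(iou(smd, disk), 0.95)

  # collapse guard: a tiny mask reverts with a warning
  tiny <- matrix(0, 20, 20); tiny[10, 10:11] <- 1
  expect_warning(out <- smoothOutline(tiny, matrix(-1, 20, 20),
                                      matrix(-1, 20, 20)), "collapsed")
  expect_identical(out, tiny)
})

test_that("segmentation recovers masks across preparation types", {
  f <- stdFixture()
  expect_gte(iou(embryoMask(f$seg), f$masks$embryo), 0.85)
  expect_false(isIncomplete(f$seg))
  expect_equal(wishtools:::.countComponents(embryoMask(f$seg)), 1L)
  expect_equal(boundingBox(f$seg), wishtools:::.maskBBox(embryoMask(f$seg)))

  fc <- clearedFixture()
  expect_gte(iou(embryoMask(fc$seg), fc$masks$embryo), 0.85)

  fe <- cached("edge", {
    x <- makeEmbryoImage(embryoSpec(centre = c(0.15, 0.5),
                                    edgeTouching = TRUE), seed = 5)
    x$seg <- suppressWarnings(segmentEmbryo(x$record, seed = 1))
    x
  })
  expect_true(isIncomplete(fe$seg))
  expect_gte(iou(embryoMask(fe$seg), fe$masks$embryo), 0.8)
})

test_that("segmentation is deterministic given the seed", {
  f <- stdFixture()
  seg2 <- suppressWarnings(segmentEmbryo(f$record, seed = 1))
  expect_identical(embryoMask(f$seg), embryoMask(seg2))
  expect_identical(boundingBox(f$seg), boundingBox(seg2))
})
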