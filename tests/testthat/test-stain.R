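test_that("luminosity compensation equalises background brightness", {
  f <- makeEmbryoImage(embryoSpec(width = 64, height = 48, sizeFraction = 0.2),
                       seed = 4)
  seg <- diskSegmentation(48, 64, 10)
  lab <- toLab(f$record)@pixels
  lab2 <- lab
  lab2[, , 1] <- wishtools:::.clamp(lab2[, , 1] + 10, 0, 100)
  rec2 <- new("ImageRecord", pixels = wishtools:::.labToRgbArray(lab2))
  adj <- compensateLuminosity(list(f$record, rec2), list(seg, seg))
  L <- sapply(adj, function(r) {
    m <- embryoMask(seg) == 0
    mean(toLab(r)@pixels[, , 1][m])
  })
  expect_lt(abs(L[1] - L[2]), 0.5)

  # a group of one is returned unchanged
  one <- compensateLuminosity(list(f$record), list(seg))
  expect_identical(one[[1]], f$record)

  # an already-equal group shifts by (almost) nothing
  eq <- compensateLuminosity(list(f$record, f$record), list(seg, seg))
  expect_lt(max(abs(imagePixels(eq[[1]]) - imagePixels(eq[[2]]))), 1e-9)
})

test_that("component count estimation recovers simulated paint counts", {
  h <- colourHints()
  set.seed(5)
  n <- 3000
  one <- runif(n, 0, 0.8) %*% t(h@stain) + matrix(rnorm(3 * n, sd = 0.01), n)
  expect_equal(estimateNComponents(one, seed = 1)$n, 1L)

  two <- cbind(runif(n, 0, 0.7), runif(n, 0, 0.7)) %*%
    t(cbind(h@stain, h@pigment)) + matrix(rnorm(3 * n, sd = 0.005), n)
  expect_equal(estimateNComponents(two, seed = 1)$n, 2L)

  three <- cbind(runif(n, 0, 0.7), runif(n, 0, 0.7), runif(n, 0, 0.7)) %*%
    t(cbind(h@stain, c(0, 1, 0), c(0, 0, 1))) +
    matrix(rnorm(3 * n, sd = 0.005), n)
  expect_equal(estimateNComponents(three, seed = 1)$n, 3L)
})

test_that("expected-colour resolution keeps the right candidate set", {
  h <- colourHints()
  cb <- wishtools:::.unit(c(0.1, 0.5, 0.85))
  set.seed(7)
  n <- 2000
  X2 <- cbind(runif(n, 0, 0.7), runif(n, 0, 0.7)) %*%
    t(cbind(h@stain, cb)) + matrix(rnorm(3 * n, sd = 0.005), n)
  est <- estimateNComponents(X2, seed = 1)

  expect_equal(colnames(resolveExpectedColours(1, h, cb, X2, est$model)),
               "stain")
  expect_equal(colnames(resolveExpectedColours(3, h, cb, X2, est$model)),
               c("stain", "pigment", "background"))
  # a cloud spanned by stain and background keeps the background
  ce <- resolveExpectedColours(2, h, cb, X2, est$model)
  expect_true("background" %in% colnames(ce))
})

test_that("hint rotation recovers a constructed plane twist and clamps", {
  h <- colourHints()
  rodr <- function(v, axis, th) {
    v * cos(th) + wishtools:::.cross3(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
  }
  axis <- wishtools:::.unit(h@stain + h@pigment)
  mkCloud <- function(deg) {
    cs2 <- rodr(h@stain, axis, deg * pi / 180)
    cp2 <- rodr(h@pigment, axis, deg * pi / 180)
    set.seed(3)
    n <- 2000
    cbind(runif(n, 0, .7), runif(n, 0, .7)) %*% t(cbind(cs2, cp2)) +
      matrix(rnorm(3 * n, sd = 0.002), n)
  }
  a0 <- adjustHintColours(h@stain, h@pigment, mkCloud(0))
  expect_lt(abs(a0$angle), 1)
  a10 <- adjustHintColours(h@stain, h@pigment, mkCloud(10))
  expect_lt(abs(a10$angle - 10), 1)
  a25 <- adjustHintColours(h@stain, h@pigment, mkCloud(25))
  expect_lte(abs(a25$angle), 15 + 1e-6)
  # degenerate (rank-1) cloud leaves hints unchanged
  flat <- matrix(rep(h@stain, each = 300), 300) * runif(300)
  af <- adjustHintColours(h@stain, h@pigment, flat)
  expect_equal(af$angle, 0)
})

test_that("paint-matrix estimation recovers simulated paints", {
  h <- colourHints()
  angdeg <- function(u, v) acos(min(1, sum(u * v))) * 180 / pi
  set.seed(9)
  n <- 4000
  cs <- h@stain
  cp <- h@pigment
  X <- cbind(runif(n, 0, 0.7), runif(n, 0, 0.7)) %*% t(cbind(cs, cp)) +
    matrix(rnorm(3 * n, sd = 0.01), n)
  est <- estimateNComponents(X, seed = 1)
  Ce <- cbind(stain = cs, pigment = cp)
  pm <- estimatePaintMatrix(X, est$model, Ce, h)
  expect_lt(angdeg(pm$A[, "stain"], cs), 5)
  expect_lt(angdeg(pm$A[, "pigment"], cp), 8)
  expect_true(pm$confident)

  # pixels below the minimum ink length cannot be used
  expect_error(estimatePaintMatrix(X * 0.01, est$model, Ce, h), "too pale")
})

test_that("unmixing is an exact inverse, linear, and rank-checked", {
  A <- cbind(wishtools:::.unit(c(0.7, 0.7, 0.3)),
             wishtools:::.unit(c(0.4, 0.6, 0.7)))
  set.seed(2)
  S <- matrix(runif(200 * 2), 200)
  X <- S %*% t(A)
  expect_equal(unmixPaints(X, A), S, tolerance = 1e-10)
  expect_equal(unmixPaints(matrix(0, 10, 3), A), matrix(0, 10, 2))
  expect_equal(unmixPaints(3 * X, A), 3 * unmixPaints(X, A), tolerance = 1e-10)

  # least-squares residual is orthogonal to the paint span
  Xr <- matrix(runif(300), 100, 3)
  Sr <- unmixPaints(Xr, A)
  resid <- Xr - Sr %*% t(A)
  expect_lt(max(abs(resid %*% A)), 1e-10)

  expect_error(unmixPaints(Xr, cbind(A[, 1], A[, 1])), "rank deficient")
})

test_that("adaptive threshold clamps to [0.25, 0.67]", {
  set.seed(4)
  mid <- c(rnorm(300, 0.3, 0.1), rnorm(200, 0.85, 0.02))
  t1 <- adaptiveThreshold(mid)
  expect_gte(t1, 0.45); expect_lte(t1, 0.56)

  lo <- c(rnorm(300, 0.03, 0.02), rnorm(200, 0.5, 0.05))
  expect_equal(adaptiveThreshold(lo), 0.25)

  hi <- c(rnorm(300, 0.85, 0.02), rnorm(200, 0.95, 0.01))
  expect_equal(adaptiveThreshold(hi), 0.67)

  # the clamp is a hard invariant
  for (i in 1:10) {
    v <- runif(60, runif(1, 0, 0.5), runif(1, 0.5, 1))
    tt <- suppressWarnings(adaptiveThreshold(v))
    expect_gte(tt, 0.25); expect_lte(tt, 0.67)
  }
})

test_that("bleed masking suppresses rim stain and spares the interior", {
  h <- 60; w <- 60
  yy <- matrix(rep(seq_len(h) - 1, w), h, w)
  xx <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  d <- sqrt((xx - 30)^2 + (yy - 30)^2)
  mask <- (d <= 20) * 1
  set.seed(8)
  noise <- matrix(abs(rnorm(h * w, 0, 0.01)), h, w)

  # zero bleed (background barely projects on stain): mask ~1 well inside
  sm0 <- bleedMask(noise, mask)
  expect_equal(sm0$inflexion, 0)
  expect_gt(mean(sm0$mask[d <= 14]), 0.95)

  # bleed-through: the background stain level is high, a rim inside the
  # outline carries it, decaying toward clean body, then genuine stain
  rim <- noise + 0.55
  rim[mask > 0] <- 0.02
  rim[mask > 0 & d > 17] <- 0.55       # bleed rim, ~background level
  rim[mask > 0 & d > 15 & d <= 17] <- 0.25
  rim[d <= 10] <- 0.5                  # genuine interior stain
  smr <- bleedMask(rim, mask)
  expect_lt(mean(smr$map[mask > 0 & d > 17]) / 0.55, 0.2)
  expect_gt(mean(smr$map[d <= 10]) / 0.5, 0.95)

  # band means rise monotonically (no bleed minimum): inflexion halfway
  # to the maximum
  inc <- noise * 0 + 0.5
  inc[mask > 0] <- 0.1 + 0.02 * (20 - d[mask > 0])
  smi <- bleedMask(inc, mask)
  expect_gt(smi$inflexion, 0)
})

test_that("pattern extraction meets Dice targets on rendered fixtures", {
  f <- stdFixture()
  st <- suppressWarnings(extractPattern(f$record, f$seg, seed = 1))
  expect_gte(dice(thresholdedStain(st) > 0, f$masks$stain), 0.8)
  expect_true(isConfident(st))
  # pigment is mapped and the stain map stays off the pigment field
  expect_gt(mean(pigmentMap(st)[f$masks$pigment > 0] > 0.25), 0.8)
  expect_lt(mean(thresholdedStain(st)[f$masks$pigment > 0] > 0), 0.1)

  fc <- clearedFixture()
  stc <- suppressWarnings(extractPattern(fc$record, fc$seg, seed = 1))
  expect_gte(dice(thresholdedStain(stc) > 0, fc$masks$stain), 0.8)

  # an unstained embryo must score ~0
  fu <- cached("blank", {
    x <- makeEmbryoImage(embryoSpec(stainLayout = list(),
                                    pigmentLayout = list()), seed = 8)
    x$seg <- suppressWarnings(segmentEmbryo(x$record, seed = 1))
    x
  })
  stu <- suppressWarnings(extractPattern(fu$record, fu$seg, seed = 1))
  expect_lt(stainScore(stu), 0.25)

  # pigment-only: no confident stain, stain map ~0 on the pigment field
  fp <- cached("pgonly", {
    x <- makeEmbryoImage(embryoSpec(stainLayout = list()), seed = 2)
    x$seg <- suppressWarnings(segmentEmbryo(x$record, seed = 1))
    x
  })
  stp <- suppressWarnings(extractPattern(fp$record, fp$seg, seed = 1))
  expect_false(isConfident(stp))
  expect_lt(max(thresholdedStain(stp)[fp$masks$pigment > 0]), 1e-9)
})

test_that("swapping stain and pigment hints swaps the recovered maps", {
  h <- colourHints()
  hSwap <- colourHints()
  hSwap@stain <- h@pigment
  hSwap@pigment <- h@stain

  # synthetic two-paint image on a grey surround
  H <- 60; W <- 80
  yy <- matrix(rep(seq_len(H) - 1, W), H, W)
  xx <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  mask <- (abs(xx - 40) <= 28 & abs(yy - 30) <= 20) * 1
  loadA <- wishtools:::.clamp(1 - (sqrt((xx - 28)^2 + (yy - 30)^2)) / 12, 0, 1) * 0.7
  loadB <- wishtools:::.clamp(1 - (sqrt((xx - 52)^2 + (yy - 30)^2)) / 12, 0, 1) * 0.7
  cmy <- array(0, c(H, W, 3))
  for (ch in 1:3)
    cmy[, , ch] <- (loadA * h@stain[ch] + loadB * h@pigment[ch] +
                    0.25 * mask * c(0.5, 0.55, 0.5)[ch]) * mask +
      (1 - mask) * 0.25
  set.seed(6)
  rgb <- wishtools:::.clamp((1 - cmy) * 255 +
                            array(rnorm(H * W * 3, sd = 1), c(H, W, 3)), 0, 255)
  rec <- new("ImageRecord", pixels = rgb)
  seg <- new("SegmentationResult", mask = mask,
             bbox = wishtools:::.maskBBox(mask), incomplete = FALSE,
             backgroundColour = c(80, 0, 0), bgLogLik = matrix(-1, 10, 10),
             fgLogLik = matrix(-2, 10, 10), scaleFactor = 1)
  s1 <- suppressWarnings(extractPattern(rec, seg, h, seed = 1))
  s2 <- suppressWarnings(extractPattern(rec, seg, hSwap, seed = 1))
  inA <- loadA > 0.3; inB <- loadB > 0.3
  expect_gt(mean(stainMap(s1)[inA]), mean(stainMap(s1)[inB]))
  expect_gt(mean(stainMap(s2)[inB]), mean(stainMap(s2)[inA]))
})
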