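test_that("stain maps are normalised and capped for alignment", {
  m <- matrix(rnorm(400, sd = 2), 20, 20)
  p <- prepareStainImage(m)
  expect_equal(sd(p), 1, tolerance = 1e-9)

  big <- matrix(runif(400 * 300), 300, 400)
  pb <- prepareStainImage(big)
  expect_equal(dim(pb), c(75, 100))

  expect_warning(pz <- prepareStainImage(matrix(3, 10, 10)), "zero variance")
  expect_equal(max(abs(pz)), 0)
})

test_that("affine alignment finds identity, rotations and penalised scalings", {
  set.seed(12)
  pat <- matrix(0, 40, 40)
  pat[8:18, 10:16] <- 2          # asymmetric pattern
  pat[25:30, 22:34] <- 1
  pat <- wishtools:::.fromEB(EBImage::gblur(wishtools:::.asEB(pat), 1.5))

  a <- alignPair(pat, pat, list(A = diag(2), b = c(0, 0)), alpha = 1)
  expect_lt(max(abs(a$A - diag(2))), 0.01)
  expect_lt(max(abs(a$b)), 0.1)
  expect_lt(a$value, 1e-4 * sum(pat^2))

  r90 <- rot90mat(pat)
  R <- matrix(c(0, 1, -1, 0), 2)
  a90 <- alignPair(pat, r90, list(A = R, b = c(0, 0)), alpha = 1)
  expect_lt(a90$value, 0.01 * sum(pat^2))

  # scaling penalty pulls |A| toward 1 monotonically in alpha
  half <- wishtools:::.fromEB(EBImage::resize(wishtools:::.asEB(pat),
                                              w = 20, h = 20))
  dets <- sapply(c(0.1, 10, 1000), function(al) {
    r <- alignPair(half, pat, list(A = diag(2), b = c(0, 0)), alpha = al)
    abs(det(r$A))
  })
  expect_true(all(diff(abs(dets - 1)) <= 1e-6))
})

test_that("pair distances are symmetric with near-zero self-distance", {
  set.seed(13)
  m1 <- matrix(0, 30, 30); m1[5:12, 8:14] <- 1
  m2 <- matrix(0, 30, 30); m2[15:25, 4:10] <- 1; m2[5:8, 20:26] <- 0.5
  p1 <- prepareStainImage(m1); p2 <- prepareStainImage(m2)
  expect_lte(pairDistance(p1, p1)$distance, 1e-6)
  d12 <- pairDistance(p1, p2)$distance
  d21 <- pairDistance(p2, p1)$distance
  expect_equal(d12, d21)

  # a ~90 degree rotated, slightly scaled pair is recovered from the
  # right canonical start
  pat <- matrix(0, 40, 40)
  pat[8:18, 10:16] <- 2; pat[25:30, 22:34] <- 1
  pat <- wishtools:::.fromEB(EBImage::gblur(wishtools:::.asEB(pat), 1.5))
  rot <- rot90mat(pat)
  pd <- pairDistance(prepareStainImage(pat), prepareStainImage(rot))
  A <- pd$best$A
  ang <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  expect_lt(min(abs(abs(ang) - 90), abs(ang)), 5)
  expect_lt(abs(abs(det(A)) - 1), 0.05)

  # unrelated dense textures cannot be affinely matched: the residual
  # keeps a substantial fraction of the pattern energy
  set.seed(3)
  t1 <- abs(wishtools:::.fromEB(EBImage::gblur(
    wishtools:::.asEB(matrix(rnorm(900), 30, 30)), 1)))
  t2 <- abs(wishtools:::.fromEB(EBImage::gblur(
    wishtools:::.asEB(matrix(rnorm(900), 30, 30)), 1)))
  dd <- pairDistance(t1, t2)
  expect_gte(dd$distance, 0.3 * 0.5 * (sum(t1^2) + sum(t2^2)))
})

test_that("affinity propagation clusters a planted similarity structure", {
  set.seed(14)
  D <- matrix(8, 8, 8)
  D[1:4, 1:4] <- 1; D[5:8, 5:8] <- 1
  diag(D) <- 0
  D <- D + matrix(runif(64, 0, 0.1), 8); D <- (D + t(D)) / 2; diag(D) <- 0
  vc <- clusterViews(D)
  expect_equal(length(unique(clusterLabels(vc))), 2L)
  expect_equal(length(unique(clusterLabels(vc)[1:4])), 1L)
  expect_equal(length(unique(clusterLabels(vc)[5:8])), 1L)
  # determinism
  expect_identical(clusterLabels(vc), clusterLabels(clusterViews(D)))

  # all-equal distances collapse to one cluster
  De <- matrix(1, 6, 6); diag(De) <- 0
  expect_equal(length(unique(clusterLabels(clusterViews(De)))), 1L)

  # many planted groups are capped at four clusters
  Dm <- matrix(10, 12, 12)
  for (g in 0:5) Dm[g * 2 + 1:2, g * 2 + 1:2] <- 0.5
  diag(Dm) <- 0
  expect_lte(length(unique(clusterLabels(clusterViews(Dm)))), 4L)

  # per-image total similarity sums within the own cluster
  tot <- totalSimilarity(vc)
  lab <- clusterLabels(vc)
  S <- -D
  for (i in 1:8) {
    same <- setdiff(which(lab == lab[i]), i)
    expect_equal(tot[i], sum(S[i, same]))
  }
})
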