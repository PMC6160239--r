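test_that("file-name metadata parsing captures full, partial and no matches", {
  m <- parseImageName("prdm1_st20_lateral.jpg")
  expect_equal(m$gene, "prdm1")
  expect_equal(m$stage, 20L)
  expect_equal(m$orientation, "lateral")

  m <- parseImageName("hoxb3_st35.png")
  expect_equal(m$gene, "hoxb3")
  expect_equal(m$stage, 35L)
  expect_true(is.na(m$orientation))

  expect_warning(m <- parseImageName("IMG_0001.jpg"), "does not match")
  expect_true(is.na(m$gene) && is.na(m$stage) && is.na(m$orientation))
})

test_that("CMY conversion is the complementary ink model and involutive", {
  px <- array(0, c(8, 8, 3))
  px[1, 1, ] <- c(255, 255, 255)
  px[1, 2, ] <- c(0, 0, 0)
  cmy <- toCmy(px)@pixels
  expect_equal(cmy[1, 1, ], c(0, 0, 0))
  expect_equal(cmy[1, 2, ], c(1, 1, 1))
  # involution up to 8-bit quantisation
  set.seed(1)
  rnd <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  back <- round((1 - toCmy(rnd)@pixels) * 255)
  expect_true(max(abs(back - rnd)) <= 1)
})

test_that("LAB conversion uses the D65 white point", {
  px <- array(255, c(8, 8, 3))
  lab <- toLab(px)@pixels
  expect_equal(lab[1, 1, 1], 100, tolerance = 1e-6)
  expect_lt(abs(lab[1, 1, 2]), 0.01)
  expect_lt(abs(lab[1, 1, 3]), 0.01)
  black <- toLab(array(0, c(8, 8, 3)))@pixels
  expect_equal(black[1, 1, 1], 0, tolerance = 1e-6)
})

test_that("results round-trip through overlay, mask and JSON sidecar", {
  f <- makeEmbryoImage(embryoSpec(width = 48, height = 40, sizeFraction = 0.2),
                       seed = 1)
  seg <- diskSegmentation()
  stain <- diskStain(seg)
  out <- withr::local_tempdir()
  paths <- writeResults(f$record, seg, stain, out, prefix = "t")
  expect_true(all(file.exists(paths)))

  # empty stain map: overlay equals the original inside the mask
  ov <- EBImage::readImage(paths["overlay"])
  ovArr <- aperm(EBImage::imageData(ov), c(2, 1, 3)) * 255
  inMask <- embryoMask(seg) > 0
  for (ch in 1:3) {
    d <- abs(ovArr[, , ch][inMask] - imagePixels(f$record)[, , ch][inMask])
    expect_lt(max(d), 1.5)  # PNG 8-bit quantisation only
  }

  # mask raster reloads bitwise-equal
  mk <- EBImage::readImage(paths["mask"])
  expect_equal(t(EBImage::imageData(mk)), embryoMask(seg) * 1,
               ignore_attr = TRUE)

  # sidecar reloads losslessly
  sc <- readSidecar(paths["sidecar"])
  expect_equal(sc$bbox, as.numeric(boundingBox(seg)))
  expect_equal(sc$incomplete, isIncomplete(seg))
  expect_equal(sc$threshold, stainThreshold(stain))
  expect_equal(sc$stain_score, stainScore(stain))
  expect_equal(sc$n_components, nComponents(stain))
  expect_equal(unname(sc$paint_matrix), unname(paintMatrix(stain)))
})

test_that("records loaded from disk keep pixels and metadata", {
  f <- makeEmbryoImage(embryoSpec(width = 48, height = 40, sizeFraction = 0.2,
                                  gene = "genea", stage = 15L), seed = 3)
  out <- withr::local_tempdir()
  p <- file.path(out, "genea_st15_lateral.png")
  EBImage::writeImage(wishtools:::.rgbArrayToEb(imagePixels(f$record)), p)
  rec <- loadRecord(p)
  expect_equal(geneId(rec), "genea")
  expect_equal(nfStage(rec), 15L)
  expect_equal(orientationTag(rec), "lateral")
  expect_lt(max(abs(imagePixels(rec) - imagePixels(f$record))), 1.5)
})
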