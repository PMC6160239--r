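test_that("rendered embryos hit the requested geometry and reproduce", {
  sp <- embryoSpec()
  f <- makeEmbryoImage(sp, seed = 3)
  area <- sum(f$masks$embryo) / (sp$width * sp$height)
  expect_lt(abs(area - sp$sizeFraction) / sp$sizeFraction, 0.01)

  f2 <- makeEmbryoImage(sp, seed = 3)
  expect_identical(imagePixels(f$record), imagePixels(f2$record))
  expect_identical(f$masks, f2$masks)
  expect_false(identical(imagePixels(f$record),
                         imagePixels(makeEmbryoImage(sp, seed = 4)$record)))

  expect_error(makeEmbryoImage(embryoSpec(sizeFraction = 0.9,
                                          centre = c(0.1, 0.5))),
               "infeasible geometry")
})

test_that("granular backgrounds have much higher local variance", {
  localVar <- function(img) {
    L <- img[, , 1]
    k <- matrix(1 / 9, 3, 3)
    mu <- wishtools:::.fromEB(EBImage::filter2(wishtools:::.asEB(L), k))
    m2 <- wishtools:::.fromEB(EBImage::filter2(wishtools:::.asEB(L^2), k))
    mean(pmax(m2 - mu^2, 0))
  }
  u <- makeEmbryoImage(embryoSpec(stainLayout = list(),
                                  pigmentLayout = list()), seed = 6)
  g <- makeEmbryoImage(embryoSpec(background = "granular",
                                  stainLayout = list(),
                                  pigmentLayout = list()), seed = 6)
  bg <- u$masks$embryo == 0
  expect_gte(localVar(imagePixels(g$record)) / localVar(imagePixels(u$record)),
             5)
})

test_that("in-plane view sets are exact rotations of one pattern", {
  # square frame, circular embryo centred on the pixel grid so a 90-degree
  # rotation permutes pixel centres exactly
  sp <- embryoSpec(width = 120, height = 120, aspect = 1, angleDeg = 0,
                   centre = c(59.5 / 120, 59.5 / 120), sizeFraction = 0.25,
                   pigmentLayout = list(),
                   stainLayout = list(list(u = 0.4, v = -0.2, r = 0.35)))
  vs <- makeViewSet(sp, angles = c(0, 90), seed = 5, inPlane = TRUE)
  expect_length(vs, 2)
  expect_identical(rot90matCCW(vs[[1]]$masks$stain), vs[[2]]$masks$stain)
  expect_identical(orientationTag(vs[[1]]$record), "v1")
  expect_identical(orientationTag(vs[[2]]$record), "v2")
})

test_that("spherical view sets expose different pattern content per view", {
  sp <- embryoSpec(aspect = 0.95, angleDeg = 0, pigmentLayout = list(),
                   stainLayout = list(list(u = 0.35, v = -0.2, r = 0.4),
                                      list(u = -0.6, v = 0.35, r = 0.3)))
  vs <- makeViewSet(sp, angles = c(0, 90), seed = 5, replicates = 2,
                    rollJitterDeg = 4)
  expect_length(vs, 4)
  labs <- vapply(vs, function(x) orientationTag(x$record), "")
  expect_equal(labs, c("v1", "v1", "v2", "v2"))
  # the two viewpoints render genuinely different stain masks
  expect_lt(dice(vs[[1]]$masks$stain, vs[[3]]$masks$stain), 0.6)
  # replicates within a viewpoint stay similar
  expect_gt(dice(vs[[1]]$masks$stain, vs[[2]]$masks$stain), 0.7)
})

test_that("fixture collections materialise with a complete manifest", {
  out <- withr::local_tempdir()
  man <- makeFixtureCollection(out, genes = c("ga", "gb"), stages = c(15L, 30L),
                               nViews = 4L, seed = 2)
  expect_equal(nrow(man), 2 * 2 * 4)
  expect_true(all(file.exists(file.path(out, man$file))))
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  expect_setequal(unique(man$cleared), c("cleared", "uncleared"))
})
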