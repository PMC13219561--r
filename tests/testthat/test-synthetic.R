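test_that("episodes are balanced, bounded and reproducible", {
  ep <- generateEpisode(nWay = 5, kShot = 5, nQuery = 15, seed = 1)
  expect_equal(tabulate(ep@supportLabels, 5), rep(5L, 5))
  expect_equal(dim(ep@supportImages), c(25, 1, 32, 32))
  expect_true(all(is.finite(ep@supportImages)))
  expect_true(min(ep@supportImages) >= 0 && max(ep@supportImages) <= 1)
  ep2 <- generateEpisode(nWay = 5, kShot = 5, nQuery = 15, seed = 1)
  expect_identical(ep@supportImages, ep2@supportImages)
  expect_identical(ep@queryLabels, ep2@queryLabels)
  expect_false(identical(ep@supportImages,
                         generateEpisode(nWay = 5, kShot = 5, nQuery = 15,
                                         seed = 2)@supportImages))
  expect_warning(generateEpisode(nWay = 5, kShot = 2, nQuery = 3, seed = 1),
                 "absent")
})

test_that("both pattern families are linearly decodable from pixels at high margin", {
  for (fam in c("texture", "shape")) {
    ep <- generateEpisode(nWay = 5, kShot = 5, nQuery = 25, family = fam,
                          noiseSD = 0.1, margin = 1, seed = 3)
    X <- matrix(ep@supportImages, nrow = 25)
    Q <- matrix(ep@queryImages, nrow = 25)
    M <- sapply(1:5, function(c) colMeans(X[ep@supportLabels == c, , drop = FALSE]))
    scores <- -sapply(1:5, function(c) rowSums(sweep(Q, 2, M[, c])^2))
    expect_gt(macroAUROC(scores, ep@queryLabels)$auroc, 0.9, label = fam)
  }
})

test_that("zero margin yields pixel arrays independent of the labels", {
  ep <- generateEpisode(nWay = 2, kShot = 6, nQuery = 8, margin = 0, seed = 4)
  # identical generator draws with relabeled classes give the same pixels
  ep2 <- generateEpisode(nWay = 2, kShot = 6, nQuery = 8, margin = 0,
                         family = "shape", seed = 4)
  expect_identical(ep@supportImages, ep2@supportImages)
})

test_that("planted labels are a deterministic function of the planted layer's features", {
  bb <- deskBackbone()
  pt <- generatePlantedTask(bb, layer = 3L, nWay = 3L, kShot = 4L,
                            nQuery = 9L, margin = 0.5, seed = 21)
  ep <- pt$episode
  expect_equal(tabulate(ep@supportLabels, 3), rep(4L, 3))
  for (split in c("support", "query")) {
    imgs <- if (split == "support") ep@supportImages else ep@queryImages
    labs <- if (split == "support") ep@supportLabels else ep@queryLabels
    f <- hpfnet:::backboneForward(bb, standardizeImages(imgs), upTo = 3L)$pooled[[3]]
    sc <- sweep((f / pt$labelRule$normScale) %*% t(pt$labelRule$projection),
                2, pt$labelRule$center)
    expect_equal(max.col(sc), labs, label = split)
  }
  # reproducibility
  pt2 <- generatePlantedTask(bb, layer = 3L, nWay = 3L, kShot = 4L,
                             nQuery = 9L, margin = 0.5, seed = 21)
  expect_identical(pt$episode@supportImages, pt2$episode@supportImages)
  expect_error(generatePlantedTask(bb, layer = 9L, seed = 1), "invalid")
  expect_error(generatePlantedTask(bb, layer = 2L, nWay = 2L, kShot = 5L,
                                   nQuery = 10L, margin = 50, seed = 1,
                                   maxTries = 2L), "budget")
})

test_that("label noise flips the requested fraction of labels", {
  bb <- deskBackbone()
  clean <- generatePlantedTask(bb, layer = 2L, nWay = 2L, kShot = 10L,
                               nQuery = 20L, margin = 0.3, seed = 33)
  noisy <- generatePlantedTask(bb, layer = 2L, nWay = 2L, kShot = 10L,
                               nQuery = 20L, margin = 0.3, labelNoise = 0.5,
                               seed = 33)
  # with 50% flip probability some labels must differ under the same draws
  expect_false(identical(clean$episode@queryLabels, noisy$episode@queryLabels) &&
               identical(clean$episode@supportLabels, noisy$episode@supportLabels))
})
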