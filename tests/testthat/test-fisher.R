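test_that("classical Fisher score matches hand computation and handles edge cases", {
  # two classes {0,2} vs {4,6}: numerator 16, population-variance denominator 4
  expect_equal(classicalFisherScore(matrix(c(0, 2, 4, 6)), c(0, 0, 1, 1)), 4.0)
  # identical class means on a dimension -> zero score
  f <- cbind(c(1, 3, 1, 3), c(0, 1, 2, 3))
  expect_equal(classicalFisherScore(f, c(0, 0, 1, 1))[1], 0)
  expect_error(classicalFisherScore(matrix(1:4), c(1, 1, 1, 1)), "two classes")
  # zero within-class variance -> sentinel with warning
  expect_warning(s <- classicalFisherScore(matrix(c(1, 1, 2, 2)), c(0, 0, 1, 1)),
                 "sentinel")
  expect_equal(s, 1e12)
})

test_that("gradient Fisher proxy matches a central finite-difference oracle", {
  # loss as a function of a single feature vector, for numeric differentiation
  ceLoss <- function(f, y, head) {
    z <- as.vector(head$W %*% f) + head$b
    p <- exp(z - max(z)); p <- p / sum(p)
    -log(p[y])
  }
  worst <- 0
  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(4:10, 1); d <- sample(3:8, 1); C <- sample(2:4, 1)
      f <- matrix(rnorm(n * d), n, d)
      y <- c(seq_len(C), sample(C, n - C, replace = TRUE))  # all classes present
      head <- list(W = matrix(rnorm(C * d), C, d), b = rnorm(C))
      got <- fisherProxy(f, y, head)
      h <- 1e-3
      for (c in seq_len(C)) {
        idx <- which(y == c)
        sq <- vapply(idx, function(i) {
          g <- vapply(seq_len(d), function(j) {
            fp <- f[i, ]; fp[j] <- fp[j] + h
            fm <- f[i, ]; fm[j] <- fm[j] - h
            (ceLoss(fp, y[i], head) - ceLoss(fm, y[i], head)) / (2 * h)
          }, numeric(1))
          sum(g^2)
        }, numeric(1))
        worst <- max(worst, abs(mean(sq) - got[c]) / max(abs(got[c]), 1e-8))
      }
    }
  })
  expect_lt(worst, 1e-4)
})

test_that("proxy degenerate cases: zero head, duplication, absent class", {
  f <- matrix(rnorm(12), 4, 3)
  y <- c(1, 1, 2, 2)
  zero <- list(W = matrix(0, 2, 3), b = numeric(2))
  expect_equal(fisherProxy(f, y, zero), c(0, 0))
  head <- list(W = matrix(rnorm(6), 2, 3), b = numeric(2))
  base <- fisherProxy(f, y, head)
  dup <- fisherProxy(rbind(f, f[y == 1, ]), c(y, y[y == 1]), head)
  expect_equal(dup, base)
  expect_warning(p3 <- fisherProxy(f, y, list(W = matrix(rnorm(9), 3, 3),
                                              b = numeric(3))), "absent")
  expect_true(is.na(p3[3]))
})

test_that("layer scores aggregate by max and z-normalize with population std", {
  tab <- layerScores(list(c(1, 3), c(0.5, 2), c(0.1, 1)))
  expect_equal(tab@rawScore, c(3, 2, 1))
  z <- layerScores(list(1, 2, 3))@normScore
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-6)
  # single layer: sigma_s = 0, epsilon guard keeps the score finite at 0
  expect_equal(layerScores(list(c(2, 5)))@normScore, 0)
  expect_error(layerScores(list()), "empty")
  # max dominates the class mean for every layer
  withr::with_seed(1, {
    m <- matrix(abs(rnorm(24)), 6, 4)
    tab2 <- layerScores(m)
    expect_true(all(tab2@rawScore >= rowMeans(m)))
  })
  # permuting class labels permutes proxies but leaves layer scores unchanged
  perm <- sample(4)
  expect_equal(layerScores(m[, perm])@rawScore, tab2@rawScore)
})

test_that("selection is ordered by score with deterministic tie-breaks", {
  tab <- layerScores(list(0.1, 0.9, 0.5))
  expect_equal(selectLayers(tab, 2)@selected, c(2L, 3L))
  expect_equal(selectLayers(tab, 3)@selected, c(2L, 3L, 1L))
  ties <- layerScores(list(1, 1, 1, 1))
  expect_equal(selectLayers(ties, 2)@selected, c(1L, 2L))
  expect_error(selectLayers(tab, 4), "between 1")
  expect_error(selectLayers(tab, 0), "between 1")
})

test_that("probing is deterministic, validates input, and never touches weights", {
  bb <- deskBackbone()
  ep <- generateEpisode(nWay = 3, kShot = 4, nQuery = 6, seed = 5)
  before <- bb@params
  s1 <- probeBackbone(bb, ep, kSelect = 3L, seed = 21)
  s2 <- probeBackbone(bb, ep, kSelect = 3L, seed = 21)
  expect_identical(s1@selected, s2@selected)
  expect_identical(s1@table@rawScore, s2@table@rawScore)
  expect_identical(bb@params, before)   # bitwise frozen
  expect_length(s1@selected, 3L)

  one <- list(images = ep@supportImages[ep@supportLabels == 1, , , , drop = FALSE],
              labels = rep(1L, 4))
  expect_error(probeBackbone(bb, one, kSelect = 2L), "two classes")
  expect_error(probeBackbone(bb, ep, kSelect = 7L), "between 1")
})

test_that("selection frequencies conserve counts", {
  expect_equal(selectionFrequencies(list(), 6), integer(6))
  tab <- layerScores(list(5, 4, 3, 2, 1))
  rs <- lapply(c(31, 32, 33), function(s) selectLayers(tab, 3, seed = s))
  freq <- selectionFrequencies(rs, 5)
  expect_equal(sum(freq), 3 * 3)
  expect_equal(freq, c(3L, 3L, 3L, 0L, 0L))
})

test_that("linear probe separates separable layers and stays near chance on noise", {
  bb <- deskBackbone()
  pt <- generatePlantedTask(bb, layer = 3L, nWay = 2L, kShot = 10L,
                            nQuery = 30L, margin = 1.0, seed = 17)
  res <- linearProbeEval(bb, pt$episode, 3L)
  expect_gt(res$auroc, 0.85)
  # labels independent of pixels: probe near chance
  ep0 <- generateEpisode(nWay = 2, kShot = 10, nQuery = 40, margin = 0, seed = 9)
  res0 <- linearProbeEval(bb, ep0, 2L)
  expect_gt(res0$auroc, 0.25)
  expect_lt(res0$auroc, 0.75)
  expect_error(linearProbeEval(bb, pt$episode, 9L), "invalid layer")
})

test_that("random backbones transport pooled features nearly linearly across layers", {
  # the property that bounds what planted-layer fixtures can demonstrate: a
  # linear readout of one layer largely reconstructs the next layer's
  # pooled features, so linear class structure leaks to neighboring depths
  bb <- deskBackbone()
  imgs <- standardizeImages(randomImages(60, bb@config, seed = 44))
  fw <- hpfnet:::backboneForward(bb, imgs)
  f3 <- scale(fw$pooled[[3]])
  f4 <- scale(fw$pooled[[4]])
  fit <- stats::lm.fit(cbind(1, f3), f4)
  r2 <- 1 - sum(fit$residuals^2) / sum(scale(f4, scale = FALSE)^2)
  expect_gt(r2, 0.85)
})
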