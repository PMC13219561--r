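handState <- function() {
  st <- initFusion(fusionConfig(kSelect = 2L, dim = 2L, nHeads = 1L,
                                dropout = 0), seed = 1)
  st@params$P <- diag(2)
  st@params$bp <- c(0, 0)
  st@params$w <- c(1, 1)
  st@params$q <- c(1, 0)
  st@params$WK <- diag(2)
  st@params$WV <- diag(2)
  st
}

test_that("static layer weights initialize as the descending 1.5..0.5 sequence", {
  expect_equal(initFusion(fusionConfig(kSelect = 3L, dim = 16L, nHeads = 4L),
                          seed = 1)@params$w, c(1.5, 1.0, 0.5))
  expect_equal(initFusion(fusionConfig(kSelect = 2L, dim = 16L, nHeads = 4L),
                          seed = 1)@params$w, c(1.5, 0.5))
  expect_equal(initFusion(fusionConfig(kSelect = 1L, dim = 16L, nHeads = 4L),
                          seed = 1)@params$w, 1.5)
  expect_equal(initFusion(fusionConfig(kSelect = 5L, dim = 16L, nHeads = 4L),
                          seed = 1)@params$w, seq(1.5, 0.5, length.out = 5))
  s1 <- initFusion(fusionConfig(kSelect = 2L, dim = 16L, nHeads = 4L), seed = 9)
  s2 <- initFusion(fusionConfig(kSelect = 2L, dim = 16L, nHeads = 4L), seed = 9)
  expect_identical(s1@params, s2@params)
  expect_error(fusionConfig(kSelect = 0L, dim = 16L), "kSelect")
  expect_error(fusionConfig(dim = 15L, nHeads = 4L), "divisible")
})

test_that("alignment projects, activates and L2-normalizes", {
  st <- handState()
  out <- projectAndNormalize(c(-1, 1), st)
  expect_equal(out, c(-0.1, 1) / sqrt(1.01), tolerance = 1e-4)
  expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-6)
  expect_warning(z <- projectAndNormalize(c(0, 0), st), "zero")
  expect_equal(z, c(0, 0))
})

test_that("hand-computed d=2 attention example matches", {
  st <- handState()
  res <- fuseFeatures(list(c(1, 0), c(0, 1)), st)
  expect_equal(as.vector(res$attention),
               as.vector(softmax <- exp(c(1 / sqrt(2), 0)) / sum(exp(c(1 / sqrt(2), 0)))),
               tolerance = 1e-4)
  expect_equal(res$fused, c(0.6698, 0.3302), tolerance = 1e-4)
  expect_equal(res$out, c(0.8969, 0.4422), tolerance = 1e-4)
})

test_that("fusion output is unit-norm with simplex attention rows", {
  st <- initFusion(fusionConfig(kSelect = 3L, dim = 16L, nHeads = 4L,
                                dropout = 0), seed = 2)
  withr::with_seed(4, feats <- lapply(1:3, function(i) rnorm(16)))
  res <- fuseFeatures(feats, st)
  expect_equal(sqrt(sum(res$out^2)), 1, tolerance = 1e-6)
  expect_true(all(res$attention >= 0))
  expect_equal(rowSums(res$attention), rep(1, 4), tolerance = 1e-9)
  # K_s = 1: the single attention weight is exactly 1
  st1 <- initFusion(fusionConfig(kSelect = 1L, dim = 16L, nHeads = 4L,
                                 dropout = 0), seed = 2)
  res1 <- fuseFeatures(feats[1], st1)
  expect_equal(as.vector(res1$attention), rep(1, 4))
  expect_error(fuseFeatures(feats[1:2], st), "length")
})

test_that("evaluation mode is deterministic and permutation-invariant under equal weights", {
  st <- initFusion(fusionConfig(kSelect = 3L, dim = 16L, nHeads = 4L), seed = 3)
  st@params$w <- rep(1, 3)
  withr::with_seed(5, feats <- lapply(1:3, function(i) rnorm(16)))
  a <- fuseFeatures(feats, st)
  b <- fuseFeatures(feats, st)
  expect_identical(a$out, b$out)
  p <- fuseFeatures(feats[c(3, 1, 2)], st)
  expect_equal(p$out, a$out, tolerance = 1e-12)
  # attention weights are equivariant: permuted stack -> permuted columns
  expect_equal(p$attention, a$attention[, c(3, 1, 2)], tolerance = 1e-12)
})

test_that("dropout perturbs attention only in training mode", {
  st <- initFusion(fusionConfig(kSelect = 3L, dim = 16L, nHeads = 4L,
                                dropout = 0.5), seed = 3)
  withr::with_seed(6, feats <- lapply(1:3, function(i) rnorm(16)))
  ev <- fuseFeatures(feats, st, training = FALSE)
  tr1 <- withr::with_seed(7, fuseFeatures(feats, st, training = TRUE))
  tr2 <- withr::with_seed(7, fuseFeatures(feats, st, training = TRUE))
  expect_identical(tr1$out, tr2$out)       # seeded dropout is reproducible
  expect_false(identical(ev$out, tr1$out)) # but differs from evaluation mode
})

test_that("every fusion tensor receives gradient from the classification loss", {
  bb <- injectLoRA(tinyBackbone(), loraConfig(rank = 2L), seed = 1)
  sel <- selectLayers(layerScores(list(3, 2, 1)), 2L)
  fus <- initFusion(fusionConfig(kSelect = 2L, dim = 16L, nHeads = 4L,
                                 dropout = 0), seed = 2)
  model <- hpfModel(bb, fus, buildHead(2L, 16L, seed = 3), sel)
  imgs <- standardizeImages(randomImages(4, bb@config, seed = 9))
  fb <- hpfnet:::taskForwardBackward(model, imgs, c(1L, 2L, 1L, 2L))
  for (nm in c("P", "bp", "w", "q", "WK", "WV")) {
    g <- fb$grads[[paste0("fusion.", nm)]]
    expect_gt(max(abs(g)), 0, label = paste("gradient on", nm))
  }
})
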