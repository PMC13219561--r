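test_that("AUROC equals the brute-force pairwise oracle and handles ties", {
  expect_equal(aurocBinary(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(aurocBinary(rep(0.3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(aurocBinary(c(3, 2, 1), c(1, 1, 0)), 1.0)
  withr::with_seed(12, {
    for (rep in 1:40) {
      n <- sample(4:30, 1)
      scores <- round(rnorm(n), sample(0:2, 1))   # rounding forces ties
      pos <- rbinom(n, 1, 0.5)
      if (sum(pos) %in% c(0, n)) next
      expect_equal(aurocBinary(scores, pos), aurocOracle(scores, pos))
    }
  })
})

test_that("macro AUROC averages one-vs-rest terms and drops absent classes", {
  probs <- matrix(c(0.8, 0.1, 0.1,
                    0.2, 0.7, 0.1,
                    0.1, 0.2, 0.7,
                    0.6, 0.3, 0.1), 4, 3, byrow = TRUE)
  labs <- c(1L, 2L, 3L, 1L)
  m <- macroAUROC(probs, labs)
  byHand <- mean(c(aurocOracle(probs[, 1], labs == 1),
                   aurocOracle(probs[, 2], labs == 2),
                   aurocOracle(probs[, 3], labs == 3)))
  expect_equal(m$auroc, byHand)
  expect_equal(m$accuracy, 1.0)
  expect_warning(m2 <- macroAUROC(probs[1:2, ], c(1L, 2L)), "absent")
  expect_true(is.na(m2$perClassAuroc[3]))
})

test_that("partition counts match closed forms and groups must be disjoint", {
  bb <- injectLoRA(tinyBackbone(), loraConfig(rank = 2L), seed = 1)
  sel <- selectLayers(layerScores(list(3, 2, 1)), 2L)
  fus <- initFusion(fusionConfig(kSelect = 2L, dim = 16L, nHeads = 4L), seed = 2)
  model <- hpfModel(bb, fus, buildHead(5L, 16L, seed = 3), sel)
  part <- buildTrainablePartition(model)
  expect_equal(part@counts$lora, countLoraParameters(3, 16, 16, 2, 3))
  expect_equal(part@counts$head, 5 * 16 + 5)
  expect_equal(part@counts$fusion, (16 * 16 + 16) + 2 + 16 + 2 * 16 * 16)
  expect_equal(part@counts$total,
               part@counts$lora + part@counts$fusion + part@counts$head)
  # ViT-B-scale closed forms (the ViT-B/16 reference budget)
  expect_equal(countLoraParameters(12, 768, 768, 8, 3), 442368)
  expect_equal(5 * 768 + 5, 3845)
  # a tensor appearing in two groups violates the partition contract
  expect_error(new("TrainablePartition", lora = c("a", "b"), fusion = "b",
                   head = "c", counts = list()), "disjoint")
  plain <- hpfModel(tinyBackbone(), fus, buildHead(5L, 16L, seed = 3), sel)
  expect_error(buildTrainablePartition(plain), "not injected")
})

test_that("zero learning rate is a bitwise no-op with a constant loss trace", {
  bb <- injectLoRA(deskBackbone(), loraConfig(rank = 2L), seed = 2)
  ep <- generateEpisode(nWay = 2, kShot = 3, nQuery = 4, seed = 31)
  sel <- probeBackbone(deskBackbone(), ep, kSelect = 2L, seed = 1)
  fus <- initFusion(fusionConfig(kSelect = 2L, dim = 32L, nHeads = 8L,
                                 dropout = 0), seed = 3)
  model <- hpfModel(bb, fus, buildHead(2L, 32L, seed = 4), sel)
  cfg <- trainingConfig(loraLR = 0, fusionLR = 0, headLR = 0, steps = 10L)
  fit <- trainEpisode(ep, model, config = cfg)
  expect_identical(hpfnet:::trainableTensors(fit$model),
                   hpfnet:::trainableTensors(model))
  expect_equal(diff(range(fit$loss)), 0)
})

test_that("training obeys the freezing, clipping and schedule contracts", {
  pf <- plantedFit()
  fit <- pf$fit
  # frozen base weights are bitwise identical after 50 steps
  expect_identical(fit$model@backbone@params, pf$model0@backbone@params)
  # every trainable group moved
  t0 <- hpfnet:::trainableTensors(pf$model0)
  t1 <- hpfnet:::trainableTensors(fit$model)
  grp <- sub("\\..*$", "", names(t0))
  for (g in c("lora", "fusion", "head")) {
    moved <- any(vapply(which(grp == g), function(i)
      !identical(t0[[i]], t1[[i]]), logical(1)))
    expect_true(moved, label = paste("group", g, "updated"))
  }
  # post-clip global gradient norm never exceeds the threshold
  expect_true(all(fit$gradNorm <= pf$config@clipNorm + 1e-6))
  # cosine schedule: full rate at step 1, <= 1% of it at the last step
  expect_equal(fit$lr[1], 3e-2 * 5 / 5)
  expect_lte(fit$lr[length(fit$lr)], 1e-2 * fit$lr[1])
  # support loss halves on the separable planted episode
  expect_lt(fit$loss[length(fit$loss)], 0.5 * fit$loss[1])
  expect_error(trainEpisode(pf$task$episode, fit$model,
                            config = trainingConfig(steps = 0L)), "steps")
})

test_that("run_task produces a reproducible, contract-conforming record", {
  bb <- deskBackbone()
  pt <- generatePlantedTask(bb, layer = 3L, nWay = 5L, kShot = 5L,
                            nQuery = 20L, margin = 1.0, seed = 55)
  tc <- trainingConfig(steps = 20L)
  r1 <- runTask(pt$episode, bb, kSelect = 3L, training = tc, seed = 77)
  expect_length(r1$selected, 3L)
  expect_true(r1$metrics$auroc >= 0 && r1$metrics$auroc <= 1)
  expect_true(r1$metrics$accuracy >= 0 && r1$metrics$accuracy <= 1)
  expect_length(r1$loss, 20L)
  expect_equal(r1$parameters$lora, countLoraParameters(6, 32, 32, 8, 3))
  r2 <- runTask(pt$episode, bb, kSelect = 3L, training = tc, seed = 77)
  expect_identical(r1, r2)
})

test_that("query evaluation never trains and separable tasks reach high AUROC", {
  # a 12-task batch of planted episodes: the pipeline recovers the planted
  # labels well above chance on held-out queries
  bb <- deskBackbone()
  aurocs <- vapply(1:12, function(s) {
    pt <- generatePlantedTask(bb, layer = 3L, nWay = 5L, kShot = 10L,
                              nQuery = 30L, margin = 1.0, seed = 400 + s)
    runTask(pt$episode, bb, kSelect = 3L,
            training = trainingConfig(steps = 50L, seed = 500 + s),
            seed = 600 + s)$metrics$auroc
  }, numeric(1))
  expect_gt(mean(aurocs), 0.9)
})

test_that("midrank AUROC agrees with an independent ROC implementation", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- sample(8:30, 1)
      scores <- round(rnorm(n), 1)
      pos <- rbinom(n, 1, 0.5)
      if (sum(pos) %in% c(0, n)) next
      ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(aurocBinary(scores, pos), ref)
    }
  })
})
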