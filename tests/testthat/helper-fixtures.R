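# Shared fixtures, built in code and cached for the duration of the run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# 3-layer width-16 backbone on 16x16 images: the cheapest geometry that still
# exercises attention heads, the MLP and multiple layers.
tinyConfig <- function() {
  backboneConfig(nLayers = 3L, hiddenDim = 16L, nHeads = 2L, mlpDim = 24L,
                 patchSize = 8L, imageSize = 16L, nChannels = 1L)
}

tinyBackbone <- function() cached("tinyBB", function() buildBackbone(tinyConfig(), seed = 1))

# Desk-scale geometry used for probe/selection and episodic-training tests.
deskBackbone <- function() cached("deskBB", function() buildBackbone(backboneConfig(), seed = 7))

vitBConfig <- function() {
  backboneConfig(nLayers = 12L, hiddenDim = 768L, nHeads = 12L,
                 mlpDim = 3072L, patchSize = 16L, imageSize = 224L,
                 nChannels = 3L)
}

randomImages <- function(n, config, seed = 1) {
  withr::with_seed(seed, array(runif(n * config@nChannels * config@imageSize^2),
                               c(n, config@nChannels, config@imageSize, config@imageSize)))
}

# Brute-force pairwise AUROC oracle: wins + half-ties over all
# positive-negative pairs.
aurocOracle <- function(scores, positive) {
  positive <- as.logical(positive)
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# A separable planted episode plus one trained fit, reused by the trainer
# contract tests (loss trace, clipping, schedule, frozen-base checks).
plantedFit <- function() cached("plantedFit", function() {
  bb <- deskBackbone()
  pt <- generatePlantedTask(bb, layer = 3L, nWay = 5L, kShot = 10L,
                            nQuery = 30L, margin = 1.0, seed = 41)
  adapted <- injectLoRA(bb, loraConfig(rank = 4L), seed = 2)
  sel <- probeBackbone(bb, pt$episode, kSelect = 3L, seed = 3)
  fus <- initFusion(fusionConfig(kSelect = 3L, dim = 32L, nHeads = 8L), seed = 4)
  model <- hpfModel(adapted, fus, buildHead(5L, 32L, seed = 5), sel)
  cfg <- trainingConfig(steps = 50L, seed = 6L)
  fit <- trainEpisode(pt$episode, model, config = cfg)
  list(task = pt, model0 = model, fit = fit, config = cfg)
})
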