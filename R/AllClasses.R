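#' @import methods
NULL

# ---------------------------------------------------------------- backbone --

#' Backbone configuration
#'
#' Architectural description of the vision-transformer encoder: number of
#' transformer layers `L`, hidden width `d`, attention heads, MLP width,
#' patch geometry and the pooling rule used to turn the token matrix of each
#' layer into a per-image feature vector. With `cls_token` pooling a class
#' token is prepended and its hidden state is the pooled feature; with
#' `mean_tokens` no class token exists and tokens are averaged.
#'
#' @slot nLayers number of transformer layers L.
#' @slot hiddenDim hidden width d.
#' @slot nHeads attention heads (must divide d).
#' @slot mlpDim MLP expansion width.
#' @slot patchSize square patch edge in pixels.
#' @slot imageSize square image edge in pixels (divisible by patchSize).
#' @slot nChannels input channels.
#' @slot pooling `"cls_token"` or `"mean_tokens"`.
#' @export
setClass("BackboneConfig", representation(
  nLayers = "integer", hiddenDim = "integer", nHeads = "integer",
  mlpDim = "integer", patchSize = "integer", imageSize = "integer",
  nChannels = "integer", pooling = "character"
))

setValidity("BackboneConfig", function(object) {
  msgs <- character()
  if (object@nLayers < 0L) msgs <- c(msgs, "nLayers must be >= 0")
  for (s in c("hiddenDim", "nHeads", "mlpDim", "patchSize", "imageSize", "nChannels"))
    if (slot(object, s) < 1L) msgs <- c(msgs, paste(s, "must be positive"))
  if (object@hiddenDim %% object@nHeads != 0L)
    msgs <- c(msgs, "hiddenDim must be divisible by nHeads")
  if (object@imageSize %% object@patchSize != 0L)
    msgs <- c(msgs, "imageSize must be divisible by patchSize")
  if (!object@pooling %in% c("cls_token", "mean_tokens"))
    msgs <- c(msgs, "pooling must be 'cls_token' or 'mean_tokens'")
  if (length(msgs)) msgs else TRUE
})

#' Create a backbone configuration
#'
#' Defaults describe the desk-scale encoder used throughout the examples and
#' tests (6 layers, width 32, 32x32 single-channel images in 8x8 patches).
#' Pass the ViT-B/16 geometry (`nLayers = 12, hiddenDim = 768, nHeads = 12,
#' mlpDim = 3072, patchSize = 16, imageSize = 224, nChannels = 3`) for
#' full-scale parameter accounting.
#'
#' @param nLayers,hiddenDim,nHeads,mlpDim,patchSize,imageSize,nChannels,pooling
#'   see [BackboneConfig-class].
#' @return a [BackboneConfig-class] object.
#' @examples
#' cfg <- backboneConfig()
#' nTokens(cfg)
#' @export
backboneConfig <- function(nLayers = 6L, hiddenDim = 32L, nHeads = 4L,
                           mlpDim = 64L, patchSize = 8L, imageSize = 32L,
                           nChannels = 1L, pooling = "cls_token") {
  new("BackboneConfig",
      nLayers = as.integer(nLayers), hiddenDim = as.integer(hiddenDim),
      nHeads = as.integer(nHeads), mlpDim = as.integer(mlpDim),
      patchSize = as.integer(patchSize), imageSize = as.integer(imageSize),
      nChannels = as.integer(nChannels), pooling = pooling)
}

#' Token count implied by a backbone configuration
#'
#' `(imageSize / patchSize)^2` patch tokens, plus one class token under
#' `cls_token` pooling.
#'
#' @param config a [BackboneConfig-class].
#' @return integer token count T.
#' @export
nTokens <- function(config) {
  np <- (config@imageSize %/% config@patchSize)^2
  as.integer(np + (config@pooling == "cls_token"))
}

#' Vision-transformer backbone
#'
#' A pre-norm transformer encoder whose weights live in the `params` list
#' and are frozen by convention: nothing in the package updates them unless
#' they are explicitly placed in a trainable partition (which base weights
#' never are). Low-rank adapters, when injected, live in `adapters`.
#'
#' @slot config the [BackboneConfig-class].
#' @slot params named list of weight arrays.
#' @slot adapters per-layer list of low-rank adapters (empty before
#'   [injectLoRA()]).
#' @slot loraConfig the [LoRAConfig-class] used at injection, or `NULL`.
#' @slot merged `TRUE` after [mergeAdapters()].
#' @slot seed integer seed the weights were drawn from.
#' @export
setClass("ViTBackbone", representation(
  config = "BackboneConfig", params = "list", adapters = "list",
  loraConfig = "ANY", merged = "logical", seed = "integer"
))

# -------------------------------------------------------------------- LoRA --

#' Low-rank adapter configuration
#'
#' @slot rank adapter rank r.
#' @slot targets subset of `c("query", "key", "value")`.
#' @slot scaling multiplier on the low-rank update BA.
#' @export
setClass("LoRAConfig", representation(
  rank = "integer", targets = "character", scaling = "numeric"
))

setValidity("LoRAConfig", function(object) {
  msgs <- character()
  if (object@rank < 1L) msgs <- c(msgs, "rank must be positive")
  if (!length(object@targets) || !all(object@targets %in% c("query", "key", "value")))
    msgs <- c(msgs, "targets must be a non-empty subset of query/key/value")
  if (anyDuplicated(object@targets)) msgs <- c(msgs, "duplicated targets")
  if (object@scaling <= 0) msgs <- c(msgs, "scaling must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Create a LoRA configuration
#'
#' The default rank is 8 with adapters on all three attention projections and
#' unit scaling (the alpha = r convention).
#'
#' @param rank adapter rank r.
#' @param targets which attention projections to adapt.
#' @param scaling multiplier on BA.
#' @return a [LoRAConfig-class].
#' @export
loraConfig <- function(rank = 8L, targets = c("query", "key", "value"),
                       scaling = 1.0) {
  new("LoRAConfig", rank = as.integer(rank), targets = targets,
      scaling = as.numeric(scaling))
}

# ------------------------------------------------------------------ fusion --

#' Fusion module configuration
#'
#' @slot kSelect number of fused layers K_s.
#' @slot dim feature width d.
#' @slot nHeads attention heads in the fusion cross-attention (default 8).
#' @slot dropout dropout probability on attention weights (default 0.1).
#' @slot leakySlope negative slope of the LeakyReLU activations (default 0.1).
#' @export
setClass("FusionConfig", representation(
  kSelect = "integer", dim = "integer", nHeads = "integer",
  dropout = "numeric", leakySlope = "numeric"
))

setValidity("FusionConfig", function(object) {
  msgs <- character()
  if (object@kSelect < 1L) msgs <- c(msgs, "kSelect must be >= 1")
  if (object@dim < 1L) msgs <- c(msgs, "dim must be positive")
  if (object@dim %% object@nHeads != 0L)
    msgs <- c(msgs, "dim must be divisible by nHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Create a fusion configuration
#'
#' @param kSelect number of selected layers to fuse.
#' @param dim feature width (must match the backbone hidden width).
#' @param nHeads,dropout,leakySlope see [FusionConfig-class].
#' @return a [FusionConfig-class].
#' @export
fusionConfig <- function(kSelect = 3L, dim = 32L, nHeads = 8L,
                         dropout = 0.1, leakySlope = 0.1) {
  new("FusionConfig", kSelect = as.integer(kSelect), dim = as.integer(dim),
      nHeads = as.integer(nHeads), dropout = as.numeric(dropout),
      leakySlope = as.numeric(leakySlope))
}

#' Attention-guided fusion state
#'
#' All tensors in `params` are trainable members of the fusion partition:
#' shared projection `P` (d x d) with bias `bp`, static layer weights `w`
#' (length K_s, initialized as the descending sequence 1.5 to 0.5), fusion
#' query `q` (length d, Xavier-normal), and the key/value projections
#' `WK`, `WV` (d x d).
#'
#' @slot config the [FusionConfig-class].
#' @slot params named list of tensors.
#' @slot seed integer seed used at initialization.
#' @export
setClass("FusionState", representation(
  config = "FusionConfig", params = "list", seed = "integer"
))

# ----------------------------------------------------------------- episode --

#' An N-way K-shot episode
#'
#' Images are stored as `[batch, channels, height, width]` arrays with pixel
#' values in `[0, 1]`; standardization happens inside the pipeline. Labels
#' are integers in `1..nWay`. The support set contains every class exactly
#' `kShot` times.
#'
#' @slot supportImages,supportLabels the adaptation set S.
#' @slot queryImages,queryLabels the held-out evaluation set Q.
#' @slot nWay,kShot episode geometry.
#' @export
setClass("Episode", representation(
  supportImages = "array", supportLabels = "integer",
  queryImages = "array", queryLabels = "integer",
  nWay = "integer", kShot = "integer"
))

setValidity("Episode", function(object) {
  msgs <- character()
  n <- object@nWay; k <- object@kShot
  if (dim(object@supportImages)[1L] != n * k)
    msgs <- c(msgs, "support must hold nWay * kShot images")
  tab <- tabulate(object@supportLabels, nbins = n)
  if (!all(tab == k)) msgs <- c(msgs, "support must contain every class exactly kShot times")
  if (length(object@queryLabels) != dim(object@queryImages)[1L])
    msgs <- c(msgs, "query labels/images length mismatch")
  if (length(object@queryLabels) &&
      (min(object@queryLabels) < 1L || max(object@queryLabels) > n))
    msgs <- c(msgs, "query labels outside 1..nWay")
  if (length(msgs)) msgs else TRUE
})

# ------------------------------------------------------------- probe types --

#' Per-layer Fisher score table
#'
#' Holds the class-wise gradient Fisher proxies `perClassProxy[l, c]`, the
#' per-layer raw score (max over classes), the z-scored layer scores, and
#' the normalization constants.
#'
#' @slot perClassProxy L x C matrix of nonnegative proxies.
#' @slot rawScore per-layer raw score (max over classes).
#' @slot normScore z-scored layer scores.
#' @slot scoreMean,scoreSD mean and population standard deviation of the raw
#'   scores across layers.
#' @slot epsilon stability constant added to the standard deviation.
#' @export
setClass("LayerScoreTable", representation(
  perClassProxy = "matrix", rawScore = "numeric", normScore = "numeric",
  scoreMean = "numeric", scoreSD = "numeric", epsilon = "numeric"
))

#' Result of Fisher-driven layer selection
#'
#' @slot selected ordered layer indices (descending normalized score, ties
#'   broken toward the lower index).
#' @slot table the [LayerScoreTable-class] behind the selection.
#' @slot kSelect number of selected layers.
#' @slot seed seed of the probe head.
#' @export
setClass("SelectionResult", representation(
  selected = "integer", table = "LayerScoreTable", kSelect = "integer",
  seed = "integer"
))

setValidity("SelectionResult", function(object) {
  msgs <- character()
  if (length(object@selected) != object@kSelect)
    msgs <- c(msgs, "selected must hold kSelect indices")
  if (anyDuplicated(object@selected)) msgs <- c(msgs, "selected indices must be distinct")
  L <- length(object@table@rawScore)
  if (L && length(object@selected) &&
      (min(object@selected) < 1L || max(object@selected) > L))
    msgs <- c(msgs, "selected indices outside 1..L")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------- training --

#' Episodic training configuration
#'
#' AdamW over the trainable partition with a cosine-annealed learning rate
#' and global gradient-norm clipping. The head rate follows the
#' task-complexity rule `headLR * nWay / headLRRefN`.
#'
#' @slot loraLR,fusionLR,headLR group base learning rates.
#' @slot headLRRefN reference class count for the head-rate rule.
#' @slot steps optimization steps on the support set.
#' @slot clipNorm global gradient-norm clip threshold.
#' @slot weightDecay decoupled weight decay.
#' @slot seed RNG seed for dropout masks.
#' @export
setClass("TrainingConfig", representation(
  loraLR = "numeric", fusionLR = "numeric", headLR = "numeric",
  headLRRefN = "integer", steps = "integer", clipNorm = "numeric",
  weightDecay = "numeric", seed = "integer"
))

setValidity("TrainingConfig", function(object) {
  msgs <- character()
  if (object@steps < 1L) msgs <- c(msgs, "steps must be >= 1")
  if (any(c(object@loraLR, object@fusionLR, object@headLR) < 0))
    msgs <- c(msgs, "learning rates must be nonnegative")
  if (object@clipNorm <= 0) msgs <- c(msgs, "clipNorm must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Create a training configuration
#'
#' @param loraLR adapter learning rate (small and steady).
#' @param fusionLR fusion-module learning rate.
#' @param headLR base classifier-head learning rate, scaled by
#'   `nWay / headLRRefN` at train time.
#' @param headLRRefN reference class count of the head-rate rule.
#' @param steps,clipNorm,weightDecay,seed see [TrainingConfig-class].
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(loraLR = 1e-3, fusionLR = 1e-2, headLR = 3e-2,
                           headLRRefN = 5L, steps = 50L, clipNorm = 1.0,
                           weightDecay = 1e-4, seed = 1L) {
  new("TrainingConfig", loraLR = loraLR, fusionLR = fusionLR, headLR = headLR,
      headLRRefN = as.integer(headLRRefN), steps = as.integer(steps),
      clipNorm = clipNorm, weightDecay = weightDecay, seed = as.integer(seed))
}

#' Trainable parameter partition
#'
#' Names of the tensors trained during episodic adaptation, split into the
#' three disjoint groups: LoRA adapters, fusion module, classifier head.
#' Everything not named here is frozen.
#'
#' @slot lora,fusion,head character vectors of tensor paths.
#' @slot counts named list of scalar-entry counts per group plus totals.
#' @export
setClass("TrainablePartition", representation(
  lora = "character", fusion = "character", head = "character",
  counts = "list"
))

setValidity("TrainablePartition", function(object) {
  all_ <- c(object@lora, object@fusion, object@head)
  if (anyDuplicated(all_))
    "partition groups must be disjoint (duplicated tensor path)"
  else TRUE
})

# ------------------------------------------------------------------- model --

#' Assembled probe-then-fuse model
#'
#' Bundles the (LoRA-adapted) backbone, the fusion state over the selected
#' layers, the linear classifier head, and the selection that produced the
#' layer set.
#'
#' @slot backbone a [ViTBackbone-class] (with adapters injected for training).
#' @slot fusion a [FusionState-class].
#' @slot head list with `W` (nClasses x d) and `b` (nClasses).
#' @slot selection the [SelectionResult-class] defining the fused layers.
#' @export
setClass("HPFModel", representation(
  backbone = "ViTBackbone", fusion = "FusionState", head = "list",
  selection = "SelectionResult"
))
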