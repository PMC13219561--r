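# Episodic adaptation: freeze the base, train LoRA + fusion + head on the
# support set with AdamW (cosine-annealed, gradient-clipped, differential
# learning rates), evaluate macro one-vs-rest AUROC on the query set.

#' Build the classifier head
#'
#' A linear map from the fused unit-norm feature to the N class logits,
#' seeded truncated-normal weights (sd 0.02) and zero bias.
#'
#' @param nClasses number of classes N.
#' @param dim feature width d.
#' @param seed integer seed.
#' @return list with `W` (N x d) and `b` (length N).
#' @export
buildHead <- function(nClasses, dim, seed = 1L) {
  withr::with_seed(as.integer(seed),
                   list(W = matrix(truncNormal(nClasses * dim, 0.02), nClasses, dim),
                        b = numeric(nClasses)))
}

#' Assemble a probe-then-fuse model
#'
#' @param backbone a LoRA-adapted [ViTBackbone-class].
#' @param fusion a [FusionState-class] with `kSelect` matching the selection.
#' @param head classifier head from [buildHead()].
#' @param selection a [SelectionResult-class].
#' @return an [HPFModel-class].
#' @export
hpfModel <- function(backbone, fusion, head, selection) {
  if (fusion@config@kSelect != selection@kSelect)
    stop("fusion kSelect does not match the selection")
  new("HPFModel", backbone = backbone, fusion = fusion, head = head,
      selection = selection)
}

# Named flat list of the trainable tensors of a model, keyed by dotted path.
trainableTensors <- function(model) {
  out <- list()
  for (l in seq_along(model@backbone@adapters)) {
    for (target in names(model@backbone@adapters[[l]])) {
      ad <- model@backbone@adapters[[l]][[target]]
      out[[sprintf("lora.L%02d.%s.A", l, target)]] <- ad$A
      out[[sprintf("lora.L%02d.%s.B", l, target)]] <- ad$B
    }
  }
  for (nm in c("P", "bp", "w", "q", "WK", "WV"))
    out[[paste0("fusion.", nm)]] <- model@fusion@params[[nm]]
  out[["head.W"]] <- model@head$W
  out[["head.b"]] <- model@head$b
  out
}

setTrainableTensors <- function(model, tensors) {
  for (nm in names(tensors)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (parts[1L] == "lora") {
      l <- as.integer(sub("L", "", parts[2L]))
      model@backbone@adapters[[l]][[parts[3L]]][[parts[4L]]] <- tensors[[nm]]
    } else if (parts[1L] == "fusion") {
      model@fusion@params[[parts[2L]]] <- tensors[[nm]]
    } else {
      model@head[[parts[2L]]] <- tensors[[nm]]
    }
  }
  model
}

#' Build the trainable partition of a model
#'
#' Collects the tensor paths of the three trainable groups (LoRA adapters,
#' fusion module, classifier head), asserts they are disjoint, and counts
#' scalar entries per group. Everything outside the partition -- all base
#' backbone weights -- is frozen.
#'
#' @param model an [HPFModel-class] with adapters injected.
#' @return a [TrainablePartition-class].
#' @export
buildTrainablePartition <- function(model) {
  if (!length(model@backbone@adapters))
    stop("LoRA adapters are not injected; no trainable backbone branch exists")
  tensors <- trainableTensors(model)
  nms <- names(tensors)
  grp <- sub("\\..*$", "", nms)
  sizes <- vapply(tensors, length, numeric(1))
  counts <- list(lora = sum(sizes[grp == "lora"]),
                 fusion = sum(sizes[grp == "fusion"]),
                 head = sum(sizes[grp == "head"]))
  counts$total <- counts$lora + counts$fusion + counts$head
  counts$backboneFrozen <- countParameters(model@backbone@config)
  counts$percentTrainable <- 100 * counts$total / counts$backboneFrozen
  new("TrainablePartition", lora = nms[grp == "lora"],
      fusion = nms[grp == "fusion"], head = nms[grp == "head"],
      counts = counts)
}

# Loss/gradient of one full support batch through backbone -> fusion -> head.
# `images` must already be standardized. Returns loss, probs and (optionally)
# gradients in the trainable-tensor layout.
taskForwardBackward <- function(model, images, labels, training = FALSE,
                                wantGrads = TRUE) {
  sel <- model@selection@selected
  Lmax <- max(sel)
  fw <- backboneForward(model@backbone, images, upTo = Lmax, cache = wantGrads)
  B <- fw$B
  d <- model@backbone@config@hiddenDim
  feats <- lapply(sel, function(l) fw$pooled[[l]])
  fuseCaches <- vector("list", B)
  Fout <- matrix(0, B, d)
  for (b in seq_len(B)) {
    res <- fuseForwardOne(lapply(feats, function(m) m[b, ]), model@fusion,
                          training = training)
    Fout[b, ] <- res$out
    fuseCaches[[b]] <- res$cache
  }
  N <- nrow(model@head$W)
  Z <- addRowVec(Fout %*% t(model@head$W), model@head$b)
  P <- softmaxRows(Z)
  lab <- as.integer(labels)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), lab)], 1e-12)))
  if (!wantGrads)
    return(list(loss = loss, probs = P))
  Y <- matrix(0, B, N)
  Y[cbind(seq_len(B), lab)] <- 1
  dZ <- (P - Y) / B
  grads <- list()
  grads[["head.W"]] <- t(dZ) %*% Fout
  grads[["head.b"]] <- colSums(dZ)
  dFout <- dZ %*% model@head$W
  fusionGrads <- list(P = 0, bp = 0, w = 0, q = 0, WK = 0, WV = 0)
  taps <- stats::setNames(
    lapply(sel, function(l) matrix(0, B, d)), as.character(sel))
  for (b in seq_len(B)) {
    bg <- fuseBackwardOne(fuseCaches[[b]], dFout[b, ], model@fusion)
    for (nm in names(fusionGrads))
      fusionGrads[[nm]] <- fusionGrads[[nm]] + bg[[nm]]
    for (i in seq_along(sel))
      taps[[as.character(sel[i])]][b, ] <-
        taps[[as.character(sel[i])]][b, ] + bg$dFeatures[i, ]
  }
  # a layer may appear once only, but taps at the same layer accumulate
  for (nm in names(fusionGrads))
    grads[[paste0("fusion.", nm)]] <- fusionGrads[[nm]]
  bw <- backboneBackward(model@backbone, fw, taps)
  for (l in seq_along(bw$lora)) {
    if (is.null(bw$lora[[l]])) next
    for (target in names(bw$lora[[l]])) {
      grads[[sprintf("lora.L%02d.%s.A", l, target)]] <- bw$lora[[l]][[target]]$A
      grads[[sprintf("lora.L%02d.%s.B", l, target)]] <- bw$lora[[l]][[target]]$B
    }
  }
  # adapters above Lmax receive no gradient (no loss dependence); emit zeros
  for (l in seq_along(model@backbone@adapters)) {
    for (target in names(model@backbone@adapters[[l]])) {
      for (mat in c("A", "B")) {
        key <- sprintf("lora.L%02d.%s.%s", l, target, mat)
        if (is.null(grads[[key]]))
          grads[[key]] <- model@backbone@adapters[[l]][[target]][[mat]] * 0
      }
    }
  }
  list(loss = loss, probs = P, grads = grads)
}

cosineFactor <- function(step, steps) {
  if (steps <= 1L) return(1)
  0.5 * (1 + cos(pi * (step - 1L) / (steps - 1L)))
}

#' Train one episode
#'
#' Full-batch AdamW on the support set: forward through the LoRA-adapted
#' backbone, fuse the selected layers, classify, cross-entropy loss; clip
#' the global gradient norm; update only the trainable partition with
#' cosine-annealed group learning rates (the head rate additionally scaled
#' by `nWay / headLRRefN`). Base backbone weights are untouched by
#' construction. The query set is never seen.
#'
#' @param episode an [Episode-class].
#' @param model an [HPFModel-class].
#' @param partition the [TrainablePartition-class] of `model` (validated
#'   against it).
#' @param config a [TrainingConfig-class].
#' @return list with `model` (trained), `loss` (per-step trace),
#'   `gradNorm` (post-clip global norms), `lr` (per-step head rate trace).
#' @export
trainEpisode <- function(episode, model, partition = buildTrainablePartition(model),
                         config = trainingConfig()) {
  validObject(config)
  sup <- episodeSupport(episode)
  if (!length(sup$labels)) stop("empty support set")
  tensors <- trainableTensors(model)
  stopifnot(identical(sort(names(tensors)),
                      sort(c(partition@lora, partition@fusion, partition@head))))
  images <- standardizeImages(sup$images)
  headScale <- episode@nWay / config@headLRRefN
  groupOf <- stats::setNames(sub("\\..*$", "", names(tensors)), names(tensors))
  baseLR <- c(lora = config@loraLR, fusion = config@fusionLR,
              head = config@headLR * headScale)
  m <- lapply(tensors, function(t) t * 0)
  v <- lapply(tensors, function(t) t * 0)
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  lossTrace <- numeric(config@steps)
  gradNorms <- numeric(config@steps)
  lrTrace <- numeric(config@steps)
  withr::with_seed(config@seed, {
    for (step in seq_len(config@steps)) {
      fb <- taskForwardBackward(model, images, sup$labels, training = TRUE)
      lossTrace[step] <- fb$loss
      g <- fb$grads[names(tensors)]
      gn <- globalNorm(g)
      if (gn > config@clipNorm) {
        sc <- config@clipNorm / gn
        g <- lapply(g, function(t) t * sc)
      }
      gradNorms[step] <- globalNorm(g)
      eta <- cosineFactor(step, config@steps)
      lrTrace[step] <- baseLR[["head"]] * eta
      for (nm in names(tensors)) {
        lr <- baseLR[[groupOf[nm]]] * eta
        if (lr == 0) next
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        tensors[[nm]] <- tensors[[nm]] -
          lr * (mhat / (sqrt(vhat) + adamEps) + config@weightDecay * tensors[[nm]])
      }
      model <- setTrainableTensors(model, tensors)
    }
  })
  list(model = model, loss = lossTrace, gradNorm = gradNorms, lr = lrTrace)
}

#' Evaluate a model on the query set
#'
#' Deterministic evaluation-mode forward (no dropout); reports macro
#' one-vs-rest AUROC with midrank tie handling, accuracy, and per-class
#' AUROC. A class absent from the query is dropped from the macro mean with
#' a warning.
#'
#' @param model an [HPFModel-class].
#' @param episode an [Episode-class].
#' @return list with `auroc`, `accuracy`, `perClassAuroc`.
#' @export
evaluateQuery <- function(model, episode) {
  qry <- episodeQuery(episode)
  fb <- taskForwardBackward(model, standardizeImages(qry$images), qry$labels,
                            training = FALSE, wantGrads = FALSE)
  queryMetrics(fb$probs, as.integer(qry$labels), episode@nWay)
}

#' Run the full probe-then-fuse pipeline on one episode
#'
#' Fisher-probes the frozen backbone on the support set, selects the top
#' `kSelect` layers, injects LoRA adapters, initializes fusion and head,
#' trains the partition on the support set, and evaluates on the query set.
#' All randomness derives from `seed`, so records are reproducible.
#'
#' @param episode an [Episode-class].
#' @param backbone a frozen, un-adapted [ViTBackbone-class].
#' @param kSelect number of layers to select and fuse (default 3).
#' @param lora a [LoRAConfig-class] (default rank 8 on q/k/v).
#' @param training a [TrainingConfig-class].
#' @param fusionHeads,fusionDropout fusion attention settings.
#' @param seed integer seed driving probe head, adapter/fusion/head
#'   initialization and training dropout.
#' @return a task record: list with `selected`, `scoreTable`, `loss`,
#'   `metrics`, `parameters`, `seed`.
#' @export
runTask <- function(episode, backbone, kSelect = 3L, lora = loraConfig(),
                    training = trainingConfig(), fusionHeads = 8L,
                    fusionDropout = 0.1, seed = 1L) {
  seed <- as.integer(seed)
  selection <- probeBackbone(backbone, episode, kSelect = kSelect, seed = seed)
  adapted <- injectLoRA(backbone, lora, seed = seed + 1L)
  fusion <- initFusion(fusionConfig(kSelect = kSelect,
                                    dim = backbone@config@hiddenDim,
                                    nHeads = fusionHeads,
                                    dropout = fusionDropout), seed = seed + 2L)
  head <- buildHead(episode@nWay, backbone@config@hiddenDim, seed = seed + 3L)
  model <- hpfModel(adapted, fusion, head, selection)
  partition <- buildTrainablePartition(model)
  training@seed <- seed + 4L
  fit <- trainEpisode(episode, model, partition, training)
  metrics <- evaluateQuery(fit$model, episode)
  list(selected = selection@selected,
       scoreTable = selection@table,
       loss = fit$loss,
       metrics = metrics,
       parameters = partition@counts,
       seed = seed)
}

#' Trainable-parameter accounting report
#'
#' Exact counts of the frozen backbone and the three trainable groups, with
#' totals in raw units and millions, and the trainable fraction of the
#' backbone.
#'
#' @param backboneCfg a [BackboneConfig-class].
#' @param rank LoRA rank.
#' @param kSelect number of fused layers.
#' @param nClasses classifier classes.
#' @param nTargets adapted projections per layer.
#' @param fusionBreakdown logical; include the per-tensor fusion inventory.
#' @return named list of counts.
#' @export
parameterReport <- function(backboneCfg, rank = 8L, kSelect = 3L,
                            nClasses = 5L, nTargets = 3L,
                            fusionBreakdown = FALSE) {
  d <- as.numeric(backboneCfg@hiddenDim)
  backboneTotal <- countParameters(backboneCfg)
  loraCount <- countLoraParameters(backboneCfg@nLayers, d, d, rank, nTargets)
  fusion <- list(sharedProjection = d * d + d, staticWeights = kSelect,
                 query = d, keyProjection = d * d, valueProjection = d * d)
  fusionCount <- sum(unlist(fusion))
  headCount <- nClasses * d + nClasses
  # deterministic core: adapters + shared projection + query + static weights
  core <- loraCount + fusion$sharedProjection + fusion$query + fusion$staticWeights
  total <- loraCount + fusionCount + headCount
  out <- list(
    backboneTotal = backboneTotal,
    lora = loraCount, fusion = fusionCount, head = headCount,
    trainableTotal = total,
    coreTrainable = core,
    backboneMillions = round(backboneTotal / 1e6, 2),
    loraMillions = round(loraCount / 1e6, 2),
    trainableMillions = round(total / 1e6, 2),
    coreMillions = round(core / 1e6, 2),
    percentTrainable = 100 * total / backboneTotal,
    percentCore = 100 * core / backboneTotal
  )
  if (fusionBreakdown) out$fusionTensors <- fusion
  out
}
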