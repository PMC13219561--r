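# Low-rank adaptation of the frozen attention projections: W' = W0 + s * B A
# with A (r x d_in) seeded-Gaussian and B (d_out x r) zero at injection, so
# the adapted model is exactly the frozen model at step 0.

#' Inject low-rank adapters into a backbone
#'
#' Wraps the targeted attention projection matrices (query/key/value) of
#' every layer with a low-rank branch. `A` is drawn from N(0, 0.02^2) with
#' the given seed; `B` starts at zero, so the forward pass is unchanged
#' until training moves `B`. Base weights and the projection biases stay
#' frozen. Injecting twice is a state error.
#'
#' @param backbone a [ViTBackbone-class] without adapters.
#' @param config a [LoRAConfig-class].
#' @param seed integer seed for the `A` matrices.
#' @return the adapted [ViTBackbone-class].
#' @export
injectLoRA <- function(backbone, config = loraConfig(), seed = 1L) {
  validObject(config)
  if (length(backbone@adapters))
    stop("LoRA adapters already injected; refusing double injection")
  d <- backbone@config@hiddenDim
  if (config@rank > d / 4)
    warning("LoRA rank is not small relative to the projection width")
  withr::with_seed(as.integer(seed), {
    adapters <- vector("list", backbone@config@nLayers)
    for (l in seq_len(backbone@config@nLayers)) {
      la <- list()
      for (target in config@targets) {
        la[[target]] <- list(
          A = matrix(rnorm(config@rank * d, sd = 0.02), config@rank, d),
          B = matrix(0, d, config@rank),
          scaling = config@scaling
        )
      }
      adapters[[l]] <- la
    }
  })
  backbone@adapters <- adapters
  backbone@loraConfig <- config
  backbone
}

#' Low-rank update matrix of one adapter
#'
#' @param adapter an adapter entry (list with `A`, `B`, `scaling`) as stored
#'   in `backbone@adapters[[layer]][[target]]`.
#' @return the `d_out x d_in` matrix `scaling * B %*% A`.
#' @export
loraDelta <- function(adapter) {
  adapter$scaling * (adapter$B %*% adapter$A)
}

#' Merge or unmerge adapters into the base weights
#'
#' `mergeAdapters` folds every low-rank update into its frozen base weight
#' so inference uses a single dense matrix per projection; `unmergeAdapters`
#' subtracts the updates back out. Merging twice (or unmerging an unmerged
#' model) is a state error.
#'
#' @param backbone an adapted [ViTBackbone-class].
#' @return the backbone with updated merge state.
#' @export
mergeAdapters <- function(backbone) {
  if (!length(backbone@adapters)) stop("no adapters to merge")
  if (backbone@merged) stop("adapters already merged")
  for (l in seq_along(backbone@adapters)) {
    for (target in names(backbone@adapters[[l]])) {
      delta <- loraDelta(backbone@adapters[[l]][[target]])
      slotName <- switch(target, query = "Wq", key = "Wk", value = "Wv")
      backbone@params$layers[[l]][[slotName]] <-
        backbone@params$layers[[l]][[slotName]] + delta
    }
  }
  backbone@merged <- TRUE
  backbone
}

#' @rdname mergeAdapters
#' @export
unmergeAdapters <- function(backbone) {
  if (!length(backbone@adapters)) stop("no adapters present")
  if (!backbone@merged) stop("adapters are not merged")
  for (l in seq_along(backbone@adapters)) {
    for (target in names(backbone@adapters[[l]])) {
      delta <- loraDelta(backbone@adapters[[l]][[target]])
      slotName <- switch(target, query = "Wq", key = "Wk", value = "Wv")
      backbone@params$layers[[l]][[slotName]] <-
        backbone@params$layers[[l]][[slotName]] - delta
    }
  }
  backbone@merged <- FALSE
  backbone
}

#' Closed-form LoRA parameter count
#'
#' `nTargets * L * r * (dIn + dOut)` trainable adapter entries. For the
#' ViT-B geometry (12 layers, width 768, all three projections) this gives
#' 442,368 at rank 8.
#'
#' @param nLayers number of adapted layers L.
#' @param dIn,dOut projection input/output widths.
#' @param rank adapter rank r.
#' @param nTargets number of adapted projections per layer.
#' @return numeric count.
#' @export
countLoraParameters <- function(nLayers, dIn, dOut, rank, nTargets = 3) {
  stopifnot(nLayers >= 1, dIn >= 1, dOut >= 1, rank >= 1, nTargets >= 1)
  as.numeric(nTargets) * nLayers * rank * (dIn + dOut)
}

# Enumerated adapter entries; cross-check of the closed form.
enumerateLoraParameters <- function(backbone) {
  tot <- 0
  for (l in seq_along(backbone@adapters))
    for (target in names(backbone@adapters[[l]])) {
      ad <- backbone@adapters[[l]][[target]]
      tot <- tot + length(ad$A) + length(ad$B)
    }
  tot
}
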