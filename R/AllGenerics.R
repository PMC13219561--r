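# Generics, accessors and show methods.

#' Selected layer indices
#'
#' @param x a [SelectionResult-class] or [HPFModel-class].
#' @return integer vector of layer indices, ordered by descending normalized
#'   Fisher score.
#' @export
setGeneric("selectedLayers", function(x) standardGeneric("selectedLayers"))

#' @rdname selectedLayers
#' @export
setMethod("selectedLayers", "SelectionResult", function(x) x@selected)

#' @rdname selectedLayers
#' @export
setMethod("selectedLayers", "HPFModel", function(x) x@selection@selected)

#' Raw and normalized per-layer Fisher scores
#'
#' @param x a [LayerScoreTable-class] or [SelectionResult-class].
#' @return numeric vector of length L.
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname rawScores
#' @export
setMethod("rawScores", "LayerScoreTable", function(x) x@rawScore)

#' @rdname rawScores
#' @export
setMethod("rawScores", "SelectionResult", function(x) x@table@rawScore)

#' @rdname rawScores
#' @export
setGeneric("normalizedScores", function(x) standardGeneric("normalizedScores"))

#' @rdname rawScores
#' @export
setMethod("normalizedScores", "LayerScoreTable", function(x) x@normScore)

#' @rdname rawScores
#' @export
setMethod("normalizedScores", "SelectionResult", function(x) x@table@normScore)

#' Number of transformer layers
#'
#' @param x a [BackboneConfig-class] or [ViTBackbone-class].
#' @return integer.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname nLayers
#' @export
setMethod("nLayers", "BackboneConfig", function(x) x@nLayers)

#' @rdname nLayers
#' @export
setMethod("nLayers", "ViTBackbone", function(x) x@config@nLayers)

#' Feature width of the backbone
#'
#' @param x a [BackboneConfig-class] or [ViTBackbone-class].
#' @return integer hidden width d.
#' @export
setGeneric("hiddenDim", function(x) standardGeneric("hiddenDim"))

#' @rdname hiddenDim
#' @export
setMethod("hiddenDim", "BackboneConfig", function(x) x@hiddenDim)

#' @rdname hiddenDim
#' @export
setMethod("hiddenDim", "ViTBackbone", function(x) x@config@hiddenDim)

#' Support and query sets of an episode
#'
#' @param x an [Episode-class].
#' @return list with `images` and `labels`.
#' @export
setGeneric("episodeSupport", function(x) standardGeneric("episodeSupport"))

#' @rdname episodeSupport
#' @export
setMethod("episodeSupport", "Episode", function(x)
  list(images = x@supportImages, labels = x@supportLabels))

#' @rdname episodeSupport
#' @export
setGeneric("episodeQuery", function(x) standardGeneric("episodeQuery"))

#' @rdname episodeSupport
#' @export
setMethod("episodeQuery", "Episode", function(x)
  list(images = x@queryImages, labels = x@queryLabels))

setMethod("show", "BackboneConfig", function(object) {
  cat(sprintf("BackboneConfig: L=%d d=%d heads=%d mlp=%d patch=%d image=%d channels=%d pooling=%s\n",
              object@nLayers, object@hiddenDim, object@nHeads, object@mlpDim,
              object@patchSize, object@imageSize, object@nChannels, object@pooling))
})

setMethod("show", "ViTBackbone", function(object) {
  cat(sprintf("ViTBackbone (frozen): %d layers, width %d, %d tokens, %s parameters\n",
              object@config@nLayers, object@config@hiddenDim, nTokens(object@config),
              format(countParameters(object@config), big.mark = ",")))
  if (length(object@adapters)) {
    cat(sprintf("  LoRA: rank %d on {%s}%s\n", object@loraConfig@rank,
                paste(object@loraConfig@targets, collapse = ", "),
                if (object@merged) " [merged]" else ""))
  }
})

setMethod("show", "Episode", function(object) {
  cat(sprintf("Episode: %d-way %d-shot, |S|=%d, |Q|=%d, %dx%d images (%d ch)\n",
              object@nWay, object@kShot, length(object@supportLabels),
              length(object@queryLabels), dim(object@supportImages)[3L],
              dim(object@supportImages)[4L], dim(object@supportImages)[2L]))
})

setMethod("show", "LayerScoreTable", function(object) {
  cat(sprintf("LayerScoreTable: %d layers, %d classes\n",
              nrow(object@perClassProxy), ncol(object@perClassProxy)))
  print(round(data.frame(layer = seq_along(object@rawScore),
                         score = object@rawScore,
                         zscore = object@normScore), 4))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: top-%d layers [%s] (seed %d)\n",
              object@kSelect, paste(object@selected, collapse = ", "),
              object@seed))
})

setMethod("show", "FusionState", function(object) {
  cat(sprintf("FusionState: K_s=%d, d=%d, %d heads, dropout %.2f; static weights [%s]\n",
              object@config@kSelect, object@config@dim, object@config@nHeads,
              object@config@dropout,
              paste(sprintf("%.3f", object@params$w), collapse = ", ")))
})

setMethod("show", "TrainablePartition", function(object) {
  cnt <- object@counts
  cat(sprintf("TrainablePartition: lora=%s fusion=%s head=%s total=%s\n",
              format(cnt$lora, big.mark = ","), format(cnt$fusion, big.mark = ","),
              format(cnt$head, big.mark = ","), format(cnt$total, big.mark = ",")))
})

setMethod("show", "HPFModel", function(object) {
  cat("HPFModel\n")
  show(object@backbone)
  show(object@selection)
  show(object@fusion)
  cat(sprintf("  head: %d classes\n", nrow(object@head$W)))
})
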