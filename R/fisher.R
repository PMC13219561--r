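# Fisher-information-driven layer scoring and selection. The classical
# per-dimension Fisher score is unreliable at few-shot sample sizes, so the
# probe scores whole layer representations by the class-wise mean squared
# gradient of the cross-entropy loss at a fixed random linear head (the
# diagonal empirical Fisher information with respect to the layer feature).

#' Classical per-dimension Fisher score
#'
#' For feature dimension j, the ratio of between-class to within-class
#' variance: `sum_c n_c (mu_cj - mu_j)^2 / sum_c n_c sigma_cj^2` with
#' population (biased) per-class variances. Dimensions with zero
#' within-class variance return the sentinel value `1e12` with a warning;
#' few-shot supports can legitimately have constant features within classes.
#'
#' @param features numeric matrix `n x p`.
#' @param labels vector of class labels, length n, at least two classes.
#' @return numeric vector of p scores.
#' @examples
#' classicalFisherScore(matrix(c(0, 2, 4, 6)), c(0, 0, 1, 1))  # 4
#' @export
classicalFisherScore <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("at least two classes are required")
  if (length(labels) != nrow(features)) stop("labels length must match rows")
  ns <- as.vector(table(labels))
  muc <- apply(features, 2L, function(x) tapply(x, labels, mean))
  muc <- matrix(muc, nrow = nlevels(labels))
  mu <- colMeans(features)
  num <- colSums(ns * sweep(muc, 2L, mu)^2)
  varc <- apply(features, 2L, function(x)
    tapply(x, labels, function(v) mean((v - mean(v))^2)))
  varc <- matrix(varc, nrow = nlevels(labels))
  den <- colSums(ns * varc)
  out <- numeric(ncol(features))
  zero <- den == 0
  if (any(zero)) {
    warning(sprintf("%d dimension(s) with zero within-class variance; returning sentinel 1e12", sum(zero)))
    out[zero] <- 1e12
  }
  out[!zero] <- num[!zero] / den[!zero]
  out
}

#' Class-wise gradient Fisher proxy of a feature matrix
#'
#' For each class c, the mean over its samples of the squared L2 norm of
#' the gradient of the cross-entropy loss with respect to the feature
#' vector, evaluated at a fixed linear head: `g_i = W^T (p_i - y_i)` where
#' `p_i` is the softmax of the head logits. No parameter is updated. A class
#' that has head outputs but no samples gets `NA` with a warning.
#'
#' @param features numeric matrix `n x d` of pooled layer features.
#' @param labels integer labels in `1..C`.
#' @param head list with `W` (C x d) and `b` (length C); the fixed random
#'   probe head.
#' @return numeric vector of C per-class proxies.
#' @export
fisherProxy <- function(features, labels, head) {
  features <- as.matrix(features)
  n <- nrow(features)
  C <- nrow(head$W)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match rows")
  if (any(labels < 1L | labels > C)) stop("labels outside head output range")
  Z <- addRowVec(features %*% t(head$W), head$b)
  P <- softmaxRows(Z)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), labels)] <- 1
  G <- (P - Y) %*% head$W            # row i = gradient of CE w.r.t. f_i
  sq <- rowSums(G * G)
  out <- rep(NA_real_, C)
  for (c in seq_len(C)) {
    idx <- labels == c
    if (any(idx)) out[c] <- mean(sq[idx])
  }
  if (anyNA(out))
    warning("proxy undefined for class(es) absent from labels; returning NA")
  out
}

#' Aggregate per-class proxies into normalized layer scores
#'
#' The raw score of a layer is the maximum class-wise proxy (a layer is
#' worth selecting if it is highly informative for at least one class).
#' Scores are then z-normalized across layers with population standard
#' deviation and a stability constant in the denominator; with a single
#' layer (or identical scores) the normalized scores are ~0.
#'
#' @param perLayerProxies list (length L) of per-class proxy vectors, or an
#'   `L x C` matrix.
#' @param epsilon stability constant added to the standard deviation.
#' @return a [LayerScoreTable-class].
#' @export
layerScores <- function(perLayerProxies, epsilon = 1e-8) {
  if (is.matrix(perLayerProxies)) {
    proxy <- perLayerProxies
  } else {
    if (!length(perLayerProxies)) stop("empty proxy map")
    cs <- lengths(perLayerProxies)
    if (length(unique(cs)) != 1L) stop("all layers must share the class set")
    proxy <- do.call(rbind, perLayerProxies)
  }
  if (!nrow(proxy)) stop("empty proxy map")
  raw <- apply(proxy, 1L, max)
  m <- mean(raw)
  s <- sqrt(mean((raw - m)^2))
  new("LayerScoreTable", perClassProxy = proxy, rawScore = raw,
      normScore = (raw - m) / (s + epsilon), scoreMean = m, scoreSD = s,
      epsilon = epsilon)
}

#' Select the top-scoring layers
#'
#' @param table a [LayerScoreTable-class].
#' @param kSelect number of layers K_s to keep.
#' @param seed seed to record in the result (bookkeeping only).
#' @return a [SelectionResult-class] with layers in descending score order,
#'   ties broken toward the lower layer index.
#' @export
selectLayers <- function(table, kSelect, seed = NA_integer_) {
  L <- length(table@rawScore)
  kSelect <- as.integer(kSelect)
  if (kSelect < 1L || kSelect > L)
    stop("kSelect must be between 1 and the number of layers")
  ord <- order(-table@normScore, seq_len(L))
  new("SelectionResult", selected = as.integer(ord[seq_len(kSelect)]),
      table = table, kSelect = kSelect,
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}

#' Probe a frozen backbone and select the most discriminative layers
#'
#' One forward pass over the support set caches every layer's pooled
#' feature. Each layer's features are rescaled to unit mean norm (so scores
#' compare class geometry, not depth-dependent activation scale), a single
#' temporary linear head with fixed seeded standard-normal weights -- shared
#' across all layers and classes -- provides the loss gradients, and layers
#' are ranked by the z-scored maximum class-wise proxy. Backbone weights are
#' never touched.
#'
#' @param backbone a [ViTBackbone-class].
#' @param support an [Episode-class] (its support set is used) or a list
#'   with `images` and `labels`.
#' @param kSelect number of layers to select.
#' @param seed seed of the temporary probe head.
#' @return a [SelectionResult-class].
#' @export
probeBackbone <- function(backbone, support, kSelect = 3L, seed = 1L) {
  if (is(support, "Episode")) support <- episodeSupport(support)
  labels <- as.integer(support$labels)
  if (length(unique(labels)) < 2L)
    stop("support must contain at least two classes")
  L <- backbone@config@nLayers
  kSelect <- as.integer(kSelect)
  if (kSelect < 1L || kSelect > L)
    stop("kSelect must be between 1 and the number of layers")
  C <- max(labels)
  d <- backbone@config@hiddenDim
  images <- standardizeImages(support$images)
  fw <- backboneForward(backbone, images)
  head <- withr::with_seed(as.integer(seed),
                           list(W = matrix(rnorm(C * d), C, d), b = numeric(C)))
  proxy <- matrix(0, L, C)
  for (l in seq_len(L)) {
    f <- fw$pooled[[l]]
    scale <- mean(sqrt(rowSums(f * f)))
    if (scale > 0) f <- f / scale
    proxy[l, ] <- fisherProxy(f, labels, head)
  }
  selectLayers(layerScores(proxy), kSelect, seed = seed)
}

#' Linear-probe evaluation of one layer's representation
#'
#' Fits a multinomial logistic classifier on the support features of the
#' given layer and reports macro one-vs-rest AUROC and accuracy on the
#' query set -- the per-layer discriminative-utility measurement behind
#' layer-wise probe sweeps.
#'
#' @param backbone a [ViTBackbone-class].
#' @param episode an [Episode-class].
#' @param layer layer index to probe.
#' @param decay ridge penalty passed to [nnet::multinom()].
#' @return list with `layer`, `auroc`, `accuracy`.
#' @export
linearProbeEval <- function(backbone, episode, layer, decay = 0.01) {
  L <- backbone@config@nLayers
  layer <- as.integer(layer)
  if (layer < 1L || layer > L) stop("invalid layer index")
  sup <- episodeSupport(episode)
  qry <- episodeQuery(episode)
  fwS <- backboneForward(backbone, standardizeImages(sup$images), upTo = layer)
  fwQ <- backboneForward(backbone, standardizeImages(qry$images), upTo = layer)
  fs <- fwS$pooled[[layer]]
  fq <- fwQ$pooled[[layer]]
  sc <- mean(sqrt(rowSums(fs * fs)))
  if (sc > 0) { fs <- fs / sc; fq <- fq / sc }
  df <- data.frame(y = factor(sup$labels, levels = seq_len(episode@nWay)), fs)
  fit <- nnet::multinom(y ~ ., data = df, decay = decay, trace = FALSE,
                        maxit = 200)
  probs <- stats::predict(fit, newdata = data.frame(fq), type = "probs")
  probs <- matrix(probs, nrow = nrow(fq))
  if (ncol(probs) == 1L) probs <- cbind(1 - probs, probs)  # binary multinom
  metrics <- queryMetrics(probs, as.integer(qry$labels), episode@nWay)
  list(layer = layer, auroc = metrics$auroc, accuracy = metrics$accuracy)
}

#' Layer selection frequencies over repeated probes
#'
#' @param results list of [SelectionResult-class] objects.
#' @param nLayers total number of layers L.
#' @return integer vector of length L; counts sum to `kSelect * length(results)`.
#' @export
selectionFrequencies <- function(results, nLayers) {
  counts <- integer(nLayers)
  for (r in results) {
    sel <- selectedLayers(r)
    counts[sel] <- counts[sel] + 1L
  }
  counts
}
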