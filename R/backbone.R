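# Pre-norm vision-transformer encoder in base matrix algebra, with a cached
# forward pass (every layer's hidden state and pooled feature) and a manual
# backward pass used by the episodic trainer. Block order is
# LN -> attention -> residual, LN -> MLP -> residual; pooled features are
# taken from the block output (after the residual addition, before the final
# norm).

#' Build a randomly initialized frozen backbone
#'
#' Weights are drawn deterministically from `seed`: truncated-normal
#' (Xavier-scaled, clipped at two standard deviations) for all projection
#' matrices, zeros for biases, unit scale / zero shift for the layer norms,
#' and small truncated-normal class-token and positional embeddings. All
#' weights are frozen by convention; only LoRA adapters, the fusion module
#' and the classifier head are ever trained.
#'
#' @param config a [BackboneConfig-class].
#' @param seed integer seed.
#' @return a [ViTBackbone-class].
#' @examples
#' bb <- buildBackbone(backboneConfig(nLayers = 2L), seed = 1)
#' @export
buildBackbone <- function(config, seed = 1L) {
  validObject(config)
  d <- config@hiddenDim
  pdim <- config@patchSize^2 * config@nChannels
  tcount <- nTokens(config)
  withr::with_seed(as.integer(seed), {
    params <- list(
      patchW = matrix(truncNormal(d * pdim, xavierSD(pdim, d)), d, pdim),
      patchB = numeric(d),
      pos = matrix(truncNormal(tcount * d, 0.02), tcount, d)
    )
    if (config@pooling == "cls_token") params$cls <- truncNormal(d, 0.02)
    layers <- vector("list", config@nLayers)
    for (l in seq_len(config@nLayers)) {
      layers[[l]] <- list(
        ln1g = rep(1, d), ln1b = numeric(d),
        Wq = matrix(truncNormal(d * d, xavierSD(d, d)), d, d), bq = numeric(d),
        Wk = matrix(truncNormal(d * d, xavierSD(d, d)), d, d), bk = numeric(d),
        Wv = matrix(truncNormal(d * d, xavierSD(d, d)), d, d), bv = numeric(d),
        Wo = matrix(truncNormal(d * d, xavierSD(d, d)), d, d), bo = numeric(d),
        ln2g = rep(1, d), ln2b = numeric(d),
        W1 = matrix(truncNormal(config@mlpDim * d, xavierSD(d, config@mlpDim)),
                    config@mlpDim, d),
        b1 = numeric(config@mlpDim),
        W2 = matrix(truncNormal(d * config@mlpDim, xavierSD(config@mlpDim, d)),
                    d, config@mlpDim),
        b2 = numeric(d)
      )
    }
    params$layers <- layers
    params$lnFg <- rep(1, d)
    params$lnFb <- numeric(d)
  })
  new("ViTBackbone", config = config, params = params, adapters = list(),
      loraConfig = NULL, merged = FALSE, seed = as.integer(seed))
}

#' Exact scalar parameter count of the encoder
#'
#' Closed-form count over: patch-embedding projection with bias, class token
#' (under `cls_token` pooling), positional embeddings (one per token), per
#' layer two layer norms (scale and shift), the four attention projections
#' with biases, the two-layer MLP with biases, and the final layer norm.
#' Excludes any task head. The ViT-B/16 geometry gives 85,798,656.
#'
#' @param config a [BackboneConfig-class].
#' @return integer (double for counts beyond integer range safety).
#' @examples
#' countParameters(backboneConfig(nLayers = 12L, hiddenDim = 768L,
#'   nHeads = 12L, mlpDim = 3072L, patchSize = 16L, imageSize = 224L,
#'   nChannels = 3L))
#' @export
countParameters <- function(config) {
  validObject(config)
  d <- as.numeric(config@hiddenDim)
  mlp <- as.numeric(config@mlpDim)
  pdim <- as.numeric(config@patchSize)^2 * config@nChannels
  tcount <- as.numeric(nTokens(config))
  hasCls <- config@pooling == "cls_token"
  perLayer <- 2 * (2 * d) +            # two layer norms
    4 * (d * d + d) +                  # q, k, v, out projections + biases
    (mlp * d + mlp) + (d * mlp + d)    # MLP
  total <- (d * pdim + d) + (if (hasCls) d else 0) + tcount * d +
    config@nLayers * perLayer + 2 * d
  total
}

# Enumerated count over instantiated tensors; the independent cross-check of
# the closed form used in tests.
enumerateParameters <- function(backbone) {
  sum(vapply(flattenTensors(backbone@params), length, numeric(1)))
}

# Effective attention projection weight: frozen base plus the low-rank
# branch when an (unmerged) adapter is present.
effectiveWeight <- function(backbone, layer, target) {
  lw <- backbone@params$layers[[layer]]
  W <- switch(target, query = lw$Wq, key = lw$Wk, value = lw$Wv)
  if (length(backbone@adapters) && !backbone@merged) {
    ad <- backbone@adapters[[layer]][[target]]
    if (!is.null(ad)) W <- W + ad$scaling * (ad$B %*% ad$A)
  }
  W
}

# images [B, C, H, W] -> patch matrix [B * nPatch, P^2 * C] with tokens of
# one image contiguous (row-major over patch rows then columns).
patchify <- function(images, config) {
  d <- dim(images)
  P <- config@patchSize
  nb <- config@imageSize %/% P
  x <- images
  dim(x) <- c(d[1L], d[2L], P, nb, P, nb)   # (b, c, pr, rowBlock, pc, colBlock)
  x <- aperm(x, c(4L, 6L, 1L, 2L, 3L, 5L))  # (rowBlock, colBlock, b, c, pr, pc)
  dim(x) <- c(nb * nb * d[1L], d[2L] * P * P)
  # rows: rowBlock fastest, then colBlock, then image -> one image's patch
  # tokens are contiguous; columns enumerate (channel, pr, pc)
  x
}

# Embed images into the token stream H0 [B * T, d]; rows of one image are
# contiguous, the class token (if any) first.
embedImages <- function(backbone, images) {
  cfg <- backbone@config
  if (length(dim(images)) == 3L) dim(images) <- c(1L, dim(images))
  di <- dim(images)
  if (di[2L] != cfg@nChannels || di[3L] != cfg@imageSize || di[4L] != cfg@imageSize)
    stop("image dimensions do not match the backbone configuration")
  B <- di[1L]
  np <- (cfg@imageSize %/% cfg@patchSize)^2
  tcount <- nTokens(cfg)
  Xp <- patchify(images, cfg)
  tok <- addRowVec(Xp %*% t(backbone@params$patchW), backbone@params$patchB)
  H0 <- matrix(0, B * tcount, cfg@hiddenDim)
  hasCls <- cfg@pooling == "cls_token"
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * tcount + 1L):(b * tcount)
    prow <- ((b - 1L) * np + 1L):(b * np)
    if (hasCls) {
      H0[rows[1L], ] <- backbone@params$cls
      H0[rows[-1L], ] <- tok[prow, , drop = FALSE]
    } else {
      H0[rows, ] <- tok[prow, , drop = FALSE]
    }
  }
  H0 + backbone@params$pos[rep(seq_len(tcount), B), , drop = FALSE]
}

poolTokens <- function(H, B, tcount, pooling) {
  if (pooling == "cls_token") {
    H[seq(1L, B * tcount, by = tcount), , drop = FALSE]
  } else {
    grp <- rep(seq_len(B), each = tcount)
    unname(rowsum(H, grp)) / tcount
  }
}

# Forward pass through the encoder. Returns pooled features (and hidden
# states) for layers 1..upTo, plus the cache needed for backprop when
# `cache = TRUE`.
backboneForward <- function(backbone, images, upTo = NULL, cache = FALSE,
                            keepHidden = FALSE) {
  cfg <- backbone@config
  if (length(dim(images)) == 3L) dim(images) <- c(1L, dim(images))
  B <- dim(images)[1L]
  tcount <- nTokens(cfg)
  L <- if (is.null(upTo)) cfg@nLayers else as.integer(upTo)
  d <- cfg@hiddenDim
  nh <- cfg@nHeads
  dk <- d %/% nh
  H <- embedImages(backbone, images)
  pooled <- vector("list", L)
  hidden <- if (keepHidden) vector("list", L) else NULL
  caches <- if (cache) vector("list", L) else NULL
  rowsOf <- function(b) ((b - 1L) * tcount + 1L):(b * tcount)
  for (l in seq_len(L)) {
    lw <- backbone@params$layers[[l]]
    Hin <- H
    ln1 <- layerNormForward(H, lw$ln1g, lw$ln1b)
    X <- ln1$y
    Wq <- effectiveWeight(backbone, l, "query")
    Wk <- effectiveWeight(backbone, l, "key")
    Wv <- effectiveWeight(backbone, l, "value")
    Qm <- addRowVec(X %*% t(Wq), lw$bq)
    Km <- addRowVec(X %*% t(Wk), lw$bk)
    Vm <- addRowVec(X %*% t(Wv), lw$bv)
    O <- matrix(0, nrow(H), d)
    attW <- if (cache) array(0, c(tcount, tcount, nh, B)) else NULL
    for (b in seq_len(B)) {
      rb <- rowsOf(b)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dk + 1L):(h * dk)
        S <- (Qm[rb, ch, drop = FALSE] %*% t(Km[rb, ch, drop = FALSE])) / sqrt(dk)
        A <- softmaxRows(S)
        O[rb, ch] <- A %*% Vm[rb, ch, drop = FALSE]
        if (cache) attW[, , h, b] <- A
      }
    }
    attnOut <- addRowVec(O %*% t(lw$Wo), lw$bo)
    H1 <- Hin + attnOut
    ln2 <- layerNormForward(H1, lw$ln2g, lw$ln2b)
    X2 <- ln2$y
    U <- addRowVec(X2 %*% t(lw$W1), lw$b1)
    G <- gelu(U)
    H <- H1 + addRowVec(G %*% t(lw$W2), lw$b2)
    pooled[[l]] <- poolTokens(H, B, tcount, cfg@pooling)
    if (keepHidden) {
      arr <- array(0, c(B, tcount, d))
      for (b in seq_len(B)) arr[b, , ] <- H[rowsOf(b), ]
      hidden[[l]] <- arr
    }
    if (cache) {
      caches[[l]] <- list(ln1 = ln1, X = X, Qm = Qm, Km = Km, Vm = Vm,
                          attW = attW, O = O, ln2 = ln2, X2 = X2, U = U, G = G,
                          Wq = Wq, Wk = Wk, Wv = Wv)
    }
  }
  list(pooled = pooled, hidden = hidden, caches = caches, B = B,
       tcount = tcount, nLayersRun = L)
}

#' Per-layer hidden states and pooled features
#'
#' Runs one forward pass and returns, for every layer, the hidden token
#' matrix `H_l` and the pooled feature `f_l` (class-token row under
#' `cls_token` pooling, token mean under `mean_tokens`). Evaluation-mode and
#' deterministic: no dropout anywhere in the encoder.
#'
#' @param backbone a [ViTBackbone-class].
#' @param images array `[batch, channels, height, width]`.
#' @return object of class `LayerFeatures`: list with `hidden` (list of
#'   `[batch, T, d]` arrays) and `pooled` (list of `batch x d` matrices),
#'   one entry per layer.
#' @export
forwardFeatures <- function(backbone, images) {
  fw <- backboneForward(backbone, images, keepHidden = TRUE)
  structure(list(hidden = fw$hidden, pooled = fw$pooled), class = "LayerFeatures")
}

# Backward pass. Given `taps` (a named list mapping layer index to a [B x d]
# gradient on that layer's pooled feature), propagates back through layers
# maxLayer..1 and accumulates gradients on the LoRA adapters only (base
# weights are frozen). Returns list(lora = list per layer/target of A/B
# gradients).
backboneBackward <- function(backbone, fw, taps) {
  cfg <- backbone@config
  B <- fw$B
  tcount <- fw$tcount
  d <- cfg@hiddenDim
  nh <- cfg@nHeads
  dk <- d %/% nh
  hasLora <- length(backbone@adapters) > 0L && !backbone@merged
  tapLayers <- as.integer(names(taps))
  Lmax <- max(tapLayers)
  dH <- matrix(0, B * tcount, d)
  rowsOf <- function(b) ((b - 1L) * tcount + 1L):(b * tcount)
  addTap <- function(dH, tap) {
    if (cfg@pooling == "cls_token") {
      idx <- seq(1L, B * tcount, by = tcount)
      dH[idx, ] <- dH[idx, ] + tap
    } else {
      dH <- dH + tap[rep(seq_len(B), each = tcount), , drop = FALSE] / tcount
    }
    dH
  }
  loraGrads <- if (hasLora) vector("list", Lmax) else NULL
  for (l in seq(Lmax, 1L)) {
    if (l %in% tapLayers) dH <- addTap(dH, taps[[as.character(l)]])
    cc <- fw$caches[[l]]
    lw <- backbone@params$layers[[l]]
    # MLP branch
    dM <- dH
    dG <- dM %*% lw$W2
    dU <- dG * geluGrad(cc$U)
    dX2 <- dU %*% lw$W1
    dH1 <- dH + layerNormBackward(dX2, cc$ln2)
    # attention branch
    dO <- dH1 %*% lw$Wo
    dQm <- matrix(0, B * tcount, d)
    dKm <- matrix(0, B * tcount, d)
    dVm <- matrix(0, B * tcount, d)
    for (b in seq_len(B)) {
      rb <- rowsOf(b)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dk + 1L):(h * dk)
        A <- cc$attW[, , h, b]
        dOh <- dO[rb, ch, drop = FALSE]
        dA <- dOh %*% t(cc$Vm[rb, ch, drop = FALSE])
        dVm[rb, ch] <- t(A) %*% dOh
        dS <- A * (dA - rowSums(dA * A))
        dQm[rb, ch] <- (dS %*% cc$Km[rb, ch, drop = FALSE]) / sqrt(dk)
        dKm[rb, ch] <- (t(dS) %*% cc$Qm[rb, ch, drop = FALSE]) / sqrt(dk)
      }
    }
    if (hasLora && l <= length(backbone@adapters)) {
      lg <- list()
      for (target in names(backbone@adapters[[l]])) {
        ad <- backbone@adapters[[l]][[target]]
        dWeff <- switch(target,
                        query = t(dQm) %*% cc$X,
                        key = t(dKm) %*% cc$X,
                        value = t(dVm) %*% cc$X)
        lg[[target]] <- list(
          A = ad$scaling * (t(ad$B) %*% dWeff),
          B = ad$scaling * (dWeff %*% t(ad$A))
        )
      }
      loraGrads[[l]] <- lg
    }
    dX <- dQm %*% cc$Wq + dKm %*% cc$Wk + dVm %*% cc$Wv
    dH <- dH1 + layerNormBackward(dX, cc$ln1)
  }
  list(lora = loraGrads)
}
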