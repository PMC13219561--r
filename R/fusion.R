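# Attention-guided multiscale feature fusion. Selected-layer features are
# aligned by a shared projection (LeakyReLU + L2 normalization), pre-scaled
# by learnable static layer weights, stacked, and aggregated by multi-head
# cross-attention against a learned input-agnostic query; the attended
# vector is activated and re-normalized to the unit sphere so the classifier
# operates on feature direction.

#' Initialize the fusion state
#'
#' The shared projection and key/value projections are Xavier-normal, the
#' fusion query is Xavier-normal (fan-in d, fan-out 1), biases are zero, and
#' the static layer weights start as the evenly spaced descending sequence
#' from 1.5 to 0.5 (a single selected layer takes the start value 1.5). All
#' tensors are trainable members of the fusion partition.
#'
#' @param config a [FusionConfig-class].
#' @param seed integer seed.
#' @return a [FusionState-class].
#' @examples
#' st <- initFusion(fusionConfig(kSelect = 3L, dim = 32L, nHeads = 4L), seed = 1)
#' st@params$w  # 1.5 1.0 0.5
#' @export
initFusion <- function(config, seed = 1L) {
  validObject(config)
  d <- config@dim
  withr::with_seed(as.integer(seed), {
    params <- list(
      P = matrix(rnorm(d * d, sd = xavierSD(d, d)), d, d),
      bp = numeric(d),
      w = if (config@kSelect == 1L) 1.5 else seq(1.5, 0.5, length.out = config@kSelect),
      q = rnorm(d, sd = xavierSD(d, 1)),
      WK = matrix(rnorm(d * d, sd = xavierSD(d, d)), d, d),
      WV = matrix(rnorm(d * d, sd = xavierSD(d, d)), d, d)
    )
  })
  new("FusionState", config = config, params = params, seed = as.integer(seed))
}

#' Align one feature vector into the shared fusion space
#'
#' `LeakyReLU(P f + bp)` followed by L2 normalization. A vector whose
#' activation is exactly zero is returned as zeros with a warning.
#'
#' @param f numeric feature vector of length d.
#' @param state a [FusionState-class].
#' @return unit-norm numeric vector of length d.
#' @export
projectAndNormalize <- function(f, state) {
  a <- leakyRelu(as.vector(state@params$P %*% f) + state@params$bp,
                 state@config@leakySlope)
  l2NormalizeVec(a)
}

# Forward pass for one sample. `features` is a list of K_s length-d vectors
# in stack order. Returns the FusedFeature pieces plus the cache for
# backprop. Dropout (inverted, on the attention weights) uses the current
# RNG stream and is active only when `training`.
fuseForwardOne <- function(features, state, training = FALSE) {
  cfg <- state@config
  p <- state@params
  d <- cfg@dim
  Ks <- cfg@kSelect
  nh <- cfg@nHeads
  dk <- d %/% nh
  slope <- cfg@leakySlope
  fIn <- do.call(rbind, lapply(features, as.vector))    # Ks x d
  U <- addRowVec(fIn %*% t(p$P), p$bp)
  Aact <- leakyRelu(U, slope)
  rA <- sqrt(rowSums(Aact * Aact))
  Tm <- Aact / (rA + 1e-12)
  if (any(rA == 0)) {
    warning("zero-activation feature in fusion; its aligned vector is zero")
    Tm[rA == 0, ] <- 0
  }
  Fhat <- Tm * p$w                                       # static scaling
  K <- Fhat %*% p$WK
  V <- Fhat %*% p$WV
  attn <- matrix(0, nh, Ks)
  mask <- NULL
  if (training && cfg@dropout > 0)
    mask <- matrix(stats::rbinom(nh * Ks, 1L, 1 - cfg@dropout), nh, Ks) /
      (1 - cfg@dropout)
  Fp <- numeric(d)
  for (h in seq_len(nh)) {
    ch <- ((h - 1L) * dk + 1L):(h * dk)
    s <- as.vector(K[, ch, drop = FALSE] %*% p$q[ch]) / sqrt(dk)
    al <- softmaxVec(s)
    attn[h, ] <- al
    alEff <- if (is.null(mask)) al else al * mask[h, ]
    Fp[ch] <- as.vector(t(V[, ch, drop = FALSE]) %*% alEff)
  }
  Z <- leakyRelu(Fp, slope)
  Fout <- l2NormalizeVec(Z)
  list(aligned = Tm, scaled = Fhat, stack = Fhat, attention = attn,
       fused = Fp, out = Fout,
       cache = list(fIn = fIn, U = U, Aact = Aact, rA = rA, Tm = Tm,
                    Fhat = Fhat, K = K, V = V, attn = attn, mask = mask,
                    Fp = Fp, Z = Z))
}

# Backward for one sample given dFout. Returns parameter gradients and the
# gradient on each input feature vector.
fuseBackwardOne <- function(cc, dFout, state) {
  cfg <- state@config
  p <- state@params
  d <- cfg@dim
  Ks <- cfg@kSelect
  nh <- cfg@nHeads
  dk <- d %/% nh
  slope <- cfg@leakySlope
  dZ <- l2NormalizeBackward(dFout, cc$Z)
  dFp <- dZ * leakyReluGrad(cc$Fp, slope)
  dK <- matrix(0, Ks, d)
  dV <- matrix(0, Ks, d)
  dq <- numeric(d)
  for (h in seq_len(nh)) {
    ch <- ((h - 1L) * dk + 1L):(h * dk)
    al <- cc$attn[h, ]
    m <- if (is.null(cc$mask)) rep(1, Ks) else cc$mask[h, ]
    doh <- dFp[ch]
    dalEff <- as.vector(cc$V[, ch, drop = FALSE] %*% doh)
    dV[, ch] <- outer(al * m, doh)
    dal <- dalEff * m
    ds <- al * (dal - sum(dal * al))
    dK[, ch] <- dK[, ch] + outer(ds, p$q[ch]) / sqrt(dk)
    dq[ch] <- as.vector(t(cc$K[, ch, drop = FALSE]) %*% ds) / sqrt(dk)
  }
  dWK <- t(cc$Fhat) %*% dK
  dWV <- t(cc$Fhat) %*% dV
  dFhat <- dK %*% t(p$WK) + dV %*% t(p$WV)
  dw <- rowSums(dFhat * cc$Tm)
  dT <- dFhat * p$w
  dA <- matrix(0, Ks, d)
  for (i in seq_len(Ks)) {
    if (cc$rA[i] == 0) next
    dA[i, ] <- l2NormalizeBackward(dT[i, ], cc$Aact[i, ])
  }
  dU <- dA * leakyReluGrad(cc$U, slope)
  dP <- t(dU) %*% cc$fIn
  dbp <- colSums(dU)
  dfIn <- dU %*% p$P
  list(P = dP, bp = dbp, w = dw, q = dq, WK = dWK, WV = dWV, dFeatures = dfIn)
}

#' Fuse selected-layer features into one unit-norm vector
#'
#' Runs the full fusion pipeline (align, statically scale, stack, multi-head
#' cross-attention with the learned query, activate, normalize) on one
#' sample. Dropout on the attention weights is active only when
#' `training = TRUE`.
#'
#' @param features list of K_s numeric vectors (length d) in stack order,
#'   i.e. descending Fisher score of their source layers.
#' @param state a [FusionState-class].
#' @param training logical; enables attention dropout.
#' @return list with `out` (unit-norm fused feature), `attention`
#'   (`nHeads x K_s` weights, each row summing to 1), `fused` (pre-activation
#'   attended vector), `aligned` and `scaled` feature stacks.
#' @export
fuseFeatures <- function(features, state, training = FALSE) {
  if (length(features) != state@config@kSelect)
    stop("feature list length must equal kSelect")
  if (any(vapply(features, length, 1L) != state@config@dim))
    stop("feature width must equal the fusion dim")
  res <- fuseForwardOne(features, state, training = training)
  res[c("out", "attention", "fused", "aligned", "scaled")]
}
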