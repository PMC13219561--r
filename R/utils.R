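# Internal numerical helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats qnorm runif pnorm dnorm rnorm sd
NULL

# Truncated-normal draws on [-2, 2] standard deviations, via inverse CDF so a
# single runif stream drives everything (cheap, deterministic, no rejection).
truncNormal <- function(n, sd = 1) {
  lo <- pnorm(-2)
  hi <- pnorm(2)
  qnorm(runif(n, lo, hi)) * sd
}

xavierSD <- function(fanIn, fanOut) sqrt(2 / (fanIn + fanOut))

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmaxVec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

leakyRelu <- function(x, slope = 0.1) ifelse(x >= 0, x, slope * x)

leakyReluGrad <- function(x, slope = 0.1) ifelse(x >= 0, 1, slope)

# Exact (erf-based) GELU and its derivative.
gelu <- function(x) x * pnorm(x)

geluGrad <- function(x) pnorm(x) + x * dnorm(x)

# Add a length-d row vector to every row of an n x d matrix.
addRowVec <- function(m, v) m + rep(v, each = nrow(m))

# Multiply every row of an n x d matrix elementwise by a length-d vector.
mulRowVec <- function(m, v) m * rep(v, each = nrow(m))

# Layer normalization over the feature (column) dimension, returning the
# output plus the cache needed for the backward pass.
layerNormForward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = addRowVec(mulRowVec(xhat, g), b), xhat = xhat, inv = inv, g = g)
}

# Gradient with respect to the input only; scale/shift are frozen everywhere
# layer norm is used in this package.
layerNormBackward <- function(dy, cache) {
  dxhat <- mulRowVec(dy, cache$g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  (dxhat - m1 - cache$xhat * m2) * cache$inv
}

l2NormalizeVec <- function(a, eps = 1e-12) {
  r <- sqrt(sum(a * a))
  if (r == 0) {
    warning("zero vector passed to L2 normalization; returning zeros")
    return(a)
  }
  a / (r + eps)
}

# Backward of y = a / (||a|| + eps) given upstream gradient dy.
l2NormalizeBackward <- function(dy, a, eps = 1e-12) {
  r <- sqrt(sum(a * a))
  if (r == 0) return(dy * 0)
  dy / (r + eps) - a * (sum(dy * a) / (r * (r + eps)^2))
}

# Per-image, per-channel standardization to zero mean / unit variance; the
# canonical preprocessing applied before the backbone. Idempotent up to
# floating point.
#' Standardize images to zero mean and unit variance per channel
#'
#' Applies per-image, per-channel standardization, the preprocessing used in
#' front of the backbone throughout the pipeline. Constant channels are left
#' centred at zero.
#'
#' @param images array `[batch, channels, height, width]` (a single
#'   `[channels, height, width]` image is promoted to a batch of one).
#' @return array of the same shape.
#' @export
standardizeImages <- function(images) {
  if (length(dim(images)) == 3L) dim(images) <- c(1L, dim(images))
  stopifnot(length(dim(images)) == 4L)
  d <- dim(images)
  for (b in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      x <- images[b, ch, , ]
      mu <- mean(x)
      s <- stats::sd(as.vector(x))
      if (!is.finite(s) || s == 0) s <- 1
      images[b, ch, , ] <- (x - mu) / s
    }
  }
  images
}

# Flatten a nested list of numeric arrays into a named list of tensors using
# dot-joined paths; used by the optimizer and the gradient checker.
flattenTensors <- function(x, prefix = "") {
  out <- list()
  nms <- names(x) %||% as.character(seq_along(x))
  for (i in seq_along(x)) {
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[i]])) {
      out <- c(out, flattenTensors(x[[i]], key))
    } else {
      out[[key]] <- x[[i]]
    }
  }
  out
}

globalNorm <- function(tensors) {
  sqrt(sum(vapply(tensors, function(t) sum(t * t), numeric(1))))
}
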