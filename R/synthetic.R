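# Seeded synthetic N-way K-shot episodes. Two pattern families emulate the
# shallow-vs-deep discriminability contrast of real imaging tasks: "texture"
# plants class identity in local high-frequency gratings, "shape" in the
# global layout of a smooth blob. Planted tasks label noise images by a
# random projection of a chosen layer's pooled features, giving a ground
# truth for layer-selection recovery.

classPattern <- function(class, family, imageSize) {
  xs <- matrix(seq(0, 1, length.out = imageSize), imageSize, imageSize)
  ys <- t(xs)
  if (family == "texture") {
    # class-specific high-frequency grating: frequency and orientation step
    # with the class index, phase fixed so the signal is linearly decodable
    freq <- 4 + 2 * class
    theta <- pi * (class - 1) / 7
    sin(2 * pi * freq * (cos(theta) * xs + sin(theta) * ys))
  } else {
    # class-specific global blob position on a ring
    ang <- 2 * pi * (class - 1) / 8 + 0.4
    cx <- 0.5 + 0.28 * cos(ang)
    cy <- 0.5 + 0.28 * sin(ang)
    g <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * 0.12^2))
    2 * g - mean(2 * g)
  }
}

#' Generate a seeded synthetic episode
#'
#' Each class owns a fixed spatial pattern from the chosen family; an image
#' is `0.5 + 0.25 * margin * pattern + noise`, clipped to `[0, 1]`, with
#' i.i.d. Gaussian pixel noise of standard deviation `noiseSD`. With
#' `margin = 0` the labels are independent of the pixels. The support holds
#' every class exactly `kShot` times; query labels cycle through the
#' classes (with a warning when `nQuery < nWay` leaves classes unseen).
#'
#' @param nWay,kShot,nQuery episode geometry (query size M).
#' @param imageSize,channels image geometry.
#' @param family `"texture"` (local high-frequency signal) or `"shape"`
#'   (global layout signal).
#' @param noiseSD pixel noise standard deviation (default 0.1).
#' @param margin class-signal amplitude scale (default 1).
#' @param seed integer seed; the episode is a pure function of the
#'   arguments.
#' @return an [Episode-class].
#' @examples
#' ep <- generateEpisode(nWay = 3, kShot = 2, nQuery = 6, seed = 1)
#' table(ep@supportLabels)
#' @export
generateEpisode <- function(nWay = 5L, kShot = 5L, nQuery = 15L,
                            imageSize = 32L, channels = 1L,
                            family = c("texture", "shape"), noiseSD = 0.1,
                            margin = 1, seed = 1L) {
  family <- match.arg(family)
  nWay <- as.integer(nWay); kShot <- as.integer(kShot); nQuery <- as.integer(nQuery)
  stopifnot(nWay >= 2L, kShot >= 1L, nQuery >= 1L, noiseSD >= 0)
  if (nQuery < nWay)
    warning("nQuery < nWay: some classes are absent from the query set")
  patterns <- lapply(seq_len(nWay), classPattern, family = family,
                     imageSize = imageSize)
  supportLabels <- rep(seq_len(nWay), each = kShot)
  queryLabels <- rep_len(seq_len(nWay), nQuery)
  drawImages <- function(labels) {
    arr <- array(0, c(length(labels), channels, imageSize, imageSize))
    for (i in seq_along(labels)) {
      base <- 0.5 + 0.25 * margin * patterns[[labels[i]]]
      for (ch in seq_len(channels)) {
        img <- base + matrix(rnorm(imageSize^2, sd = noiseSD),
                             imageSize, imageSize)
        arr[i, ch, , ] <- pmin(pmax(img, 0), 1)
      }
    }
    arr
  }
  withr::with_seed(as.integer(seed), {
    supportImages <- drawImages(supportLabels)
    queryLabels <- sample(queryLabels)
    queryImages <- drawImages(queryLabels)
  })
  new("Episode", supportImages = supportImages,
      supportLabels = supportLabels, queryImages = queryImages,
      queryLabels = as.integer(queryLabels), nWay = nWay, kShot = kShot)
}

#' Generate a planted-informative-layer task
#'
#' Draws unlabeled noise images, pools their layer-`layer` features on the
#' frozen backbone, and labels each image by the arg-max of a seeded random
#' projection of that feature (columns centred on the pool median so
#' classes are balanced). Samples whose top-two projection gap falls below
#' `margin` pool standard deviations are resampled, so the task is
#' learnably separable at small K; `margin = 0` disables the filter. Labels
#' are therefore a deterministic function of the chosen layer's features,
#' optionally flipped with probability `labelNoise`.
#'
#' @param backbone a frozen [ViTBackbone-class].
#' @param layer the informative layer index.
#' @param nWay,kShot,nQuery episode geometry.
#' @param margin margin-filter width in gap standard deviations.
#' @param labelNoise probability of flipping a label to a random other
#'   class.
#' @param seed integer seed.
#' @param maxTries resampling budget (batches of candidate images).
#' @return list of class `PlantedTask`: `episode` ([Episode-class]),
#'   `layer`, `labelRule` (the projection matrix, column centres and norm
#'   scale that deterministically reproduce the labels from layer-`layer`
#'   pooled features), `seed`.
#' @export
generatePlantedTask <- function(backbone, layer, nWay = 2L, kShot = 5L,
                                nQuery = 20L, margin = 0.1, labelNoise = 0,
                                seed = 1L, maxTries = 400L) {
  cfg <- backbone@config
  layer <- as.integer(layer)
  if (layer < 1L || layer > cfg@nLayers) stop("invalid planted layer index")
  nWay <- as.integer(nWay)
  perClassNeed <- kShot + ceiling(nQuery / nWay) + 2L
  withr::with_seed(as.integer(seed), {
    Wp <- matrix(rnorm(nWay * cfg@hiddenDim), nWay, cfg@hiddenDim)
    keptImages <- list()
    keptLabels <- integer()
    center <- NULL
    gapSD <- NULL
    normScale <- NULL
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("margin filtering exhausted the resampling budget")
      batch <- 64L
      imgs <- array(pmin(pmax(0.5 + 0.2 * rnorm(batch * cfg@nChannels * cfg@imageSize^2), 0), 1),
                    c(batch, cfg@nChannels, cfg@imageSize, cfg@imageSize))
      fw <- backboneForward(backbone, standardizeImages(imgs), upTo = layer)
      f <- fw$pooled[[layer]]
      if (is.null(center)) {
        # calibrate scale, class balance and margin width on the first batch
        normScale <- mean(sqrt(rowSums(f * f)))
        sc <- (f / normScale) %*% t(Wp)
        center <- apply(sc, 2L, stats::median)
        gaps0 <- apply(sweep(sc, 2L, center), 1L, function(z) {
          o <- sort(z, decreasing = TRUE); o[1L] - o[2L]
        })
        gapSD <- stats::sd(gaps0)
      }
      sc <- (f / normScale) %*% t(Wp)
      sc <- sweep(sc, 2L, center)
      lab <- max.col(sc, ties.method = "first")
      gap <- apply(sc, 1L, function(z) {
        o <- sort(z, decreasing = TRUE); o[1L] - o[2L]
      })
      keep <- gap >= margin * gapSD
      for (i in which(keep)) {
        if (sum(keptLabels == lab[i]) < perClassNeed) {
          keptImages[[length(keptImages) + 1L]] <- imgs[i, , , , drop = FALSE]
          keptLabels <- c(keptLabels, lab[i])
        }
      }
      if (all(tabulate(keptLabels, nWay) >= perClassNeed)) break
    }
    if (labelNoise > 0) {
      flip <- runif(length(keptLabels)) < labelNoise
      keptLabels[flip] <- vapply(keptLabels[flip], function(l)
        sample(setdiff(seq_len(nWay), l), 1L), integer(1))
    }
    # split: first kShot of each class to support; query filled class-balanced
    supIdx <- unlist(lapply(seq_len(nWay), function(c)
      which(keptLabels == c)[seq_len(kShot)]))
    restBy <- lapply(seq_len(nWay), function(c)
      setdiff(which(keptLabels == c), supIdx))
    qIdx <- integer()
    round <- 1L
    while (length(qIdx) < nQuery && any(lengths(restBy) >= round)) {
      for (c in seq_len(nWay)) {
        if (length(qIdx) < nQuery && length(restBy[[c]]) >= round)
          qIdx <- c(qIdx, restBy[[c]][round])
      }
      round <- round + 1L
    }
  })
  bind <- function(idx) {
    arr <- array(0, c(length(idx), cfg@nChannels, cfg@imageSize, cfg@imageSize))
    for (j in seq_along(idx)) arr[j, , , ] <- keptImages[[idx[j]]]
    arr
  }
  episode <- new("Episode", supportImages = bind(supIdx),
                 supportLabels = keptLabels[supIdx],
                 queryImages = bind(qIdx), queryLabels = keptLabels[qIdx],
                 nWay = nWay, kShot = as.integer(kShot))
  structure(list(episode = episode, layer = layer,
                 labelRule = list(projection = Wp, center = center,
                                  normScale = normScale),
                 seed = as.integer(seed)), class = "PlantedTask")
}
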