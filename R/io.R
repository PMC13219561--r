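# Episode export/import (PNG directory + CSV manifest) and the YAML run
# configuration.

#' Export an episode as PNG files with a CSV manifest
#'
#' Writes one 8-bit PNG per image under `dir/images/` and a
#' `manifest.csv` with columns `path, split, label`. Pixel values are
#' clipped to `[0, 1]` before quantization, so a round trip through
#' [loadEpisode()] reproduces images to within 1/255.
#'
#' @param episode an [Episode-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
exportEpisode <- function(episode, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  writeOne <- function(images, labels, split) {
    for (i in seq_along(labels)) {
      img <- images[i, , , ]
      if (length(dim(img)) == 3L) img <- aperm(img, c(2L, 3L, 1L))  # H,W,C
      rel <- file.path("images", sprintf("%s_%04d.png", split, i))
      png::writePNG(pmin(pmax(img, 0), 1), file.path(dir, rel))
      rows[[length(rows) + 1L]] <<- data.frame(
        path = rel, split = split, label = labels[i])
    }
  }
  writeOne(episode@supportImages, episode@supportLabels, "support")
  writeOne(episode@queryImages, episode@queryLabels, "query")
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load an episode from a PNG directory with a CSV manifest
#'
#' @param dir directory written by [exportEpisode()] (or hand-assembled
#'   with the same layout: `manifest.csv` with `path, split, label`).
#' @return an [Episode-class].
#' @export
loadEpisode <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("manifest.csv not found in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("path", "split", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns path, split, label")
  readSplit <- function(split) {
    sub <- manifest[manifest$split == split, , drop = FALSE]
    if (!nrow(sub)) return(list(images = array(0, c(0, 1, 1, 1)), labels = integer()))
    imgs <- lapply(seq_len(nrow(sub)), function(i) {
      p <- file.path(dir, sub$path[i])
      if (!file.exists(p))
        stop(sprintf("missing image '%s' (manifest line %d)", sub$path[i], i))
      x <- png::readPNG(p)
      if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
      aperm(x, c(3L, 1L, 2L))  # C,H,W
    })
    d <- dim(imgs[[1L]])
    arr <- array(0, c(length(imgs), d))
    for (i in seq_along(imgs)) arr[i, , , ] <- imgs[[i]]
    list(images = arr, labels = as.integer(sub$label))
  }
  sup <- readSplit("support")
  qry <- readSplit("query")
  nWay <- max(sup$labels)
  kShot <- as.integer(sum(sup$labels == 1L))
  new("Episode", supportImages = sup$images, supportLabels = sup$labels,
      queryImages = qry$images, queryLabels = qry$labels,
      nWay = as.integer(nWay), kShot = kShot)
}

runConfigDefaults <- function() {
  list(
    backbone = list(n_layers = 6L, hidden_dim = 32L, n_heads = 4L,
                    mlp_dim = 64L, patch_size = 8L, image_size = 32L,
                    n_channels = 1L, pooling = "cls_token"),
    lora = list(rank = 8L, targets = c("query", "key", "value"), scaling = 1.0),
    fusion = list(k_select = 3L, n_heads = 8L, dropout = 0.1),
    training = list(steps = 50L, lora_lr = 1e-3, fusion_lr = 1e-2,
                    head_lr = 3e-2, head_lr_ref_n = 5L, clip_norm = 1.0,
                    weight_decay = 1e-4),
    episode = list(source = "synthetic", n_way = 5L, k_shot = 5L,
                   n_query = 15L, family = "texture", noise_sd = 0.1,
                   margin = 1),
    n_tasks = 10L,
    seed = 1L,
    output_dir = "hpfnet-out"
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Unspecified keys take the package defaults (desk-scale backbone, rank-8
#' LoRA on q/k/v, K_s = 3 fusion, 50-step training). Validates early that
#' the selected-layer count does not exceed the layer count.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides optional named list merged over the file values.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- runConfigDefaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  cfg <- mergeConfig(cfg, overrides)
  if (cfg$fusion$k_select > cfg$backbone$n_layers)
    stop("k_select exceeds the number of backbone layers")
  cfg
}

configBackbone <- function(cfg) {
  b <- cfg$backbone
  backboneConfig(b$n_layers, b$hidden_dim, b$n_heads, b$mlp_dim,
                 b$patch_size, b$image_size, b$n_channels, b$pooling)
}

configTraining <- function(cfg, seed) {
  t <- cfg$training
  trainingConfig(loraLR = t$lora_lr, fusionLR = t$fusion_lr,
                 headLR = t$head_lr, headLRRefN = t$head_lr_ref_n,
                 steps = t$steps, clipNorm = t$clip_norm,
                 weightDecay = t$weight_decay, seed = seed)
}

configEpisode <- function(cfg, taskSeed) {
  e <- cfg$episode
  if (identical(e$source, "manifest")) {
    loadEpisode(e$path)
  } else {
    generateEpisode(nWay = e$n_way, kShot = e$k_shot, nQuery = e$n_query,
                    imageSize = cfg$backbone$image_size,
                    channels = cfg$backbone$n_channels,
                    family = e$family, noiseSD = e$noise_sd,
                    margin = e$margin, seed = taskSeed)
  }
}

writeJSONL <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Write and read a flat named-tensor archive
#'
#' Serializes a named list of numeric arrays (adapter state, fusion
#' parameters, or any tensor collection with dot-separated names) as JSON
#' with dimensions and full-precision values, and reads it back.
#'
#' @param tensors named list of numeric vectors/matrices/arrays.
#' @param path file path.
#' @return `writeTensorArchive` returns the path invisibly;
#'   `readTensorArchive` returns the named list of arrays.
#' @export
writeTensorArchive <- function(tensors, path) {
  stopifnot(length(names(tensors)) == length(tensors))
  out <- lapply(tensors, function(t)
    list(dim = if (is.null(dim(t))) length(t) else dim(t),
         data = as.vector(t)))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeTensorArchive
#' @export
readTensorArchive <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(entry) {
    x <- as.numeric(entry$data)
    d <- as.integer(entry$dim)
    if (length(d) > 1L) dim(x) <- d
    x
  })
}

#' Export and import LoRA adapter state
#'
#' `adapterState` flattens the adapters of a backbone into named tensors
#' (`lora.L01.query.A`, ...); `applyAdapterState` writes such a set back,
#' validating names and shapes — the archive round trip for task switching.
#'
#' @param backbone an adapted [ViTBackbone-class].
#' @param state named tensor list as produced by `adapterState` (possibly
#'   read back via [readTensorArchive()]).
#' @return a named tensor list, or the updated backbone.
#' @export
adapterState <- function(backbone) {
  if (!length(backbone@adapters)) stop("no adapters present")
  out <- list()
  for (l in seq_along(backbone@adapters))
    for (target in names(backbone@adapters[[l]]))
      for (mat in c("A", "B"))
        out[[sprintf("lora.L%02d.%s.%s", l, target, mat)]] <-
          backbone@adapters[[l]][[target]][[mat]]
  out
}

#' @rdname adapterState
#' @export
applyAdapterState <- function(backbone, state) {
  current <- adapterState(backbone)
  if (!setequal(names(state), names(current)))
    stop("adapter archive names do not match the injected configuration")
  for (nm in names(state)) {
    if (!identical(dim(current[[nm]]), dim(state[[nm]])))
      stop("shape mismatch for tensor ", nm)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    l <- as.integer(sub("L", "", parts[2L]))
    backbone@adapters[[l]][[parts[3L]]][[parts[4L]]] <- state[[nm]]
  }
  backbone
}
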