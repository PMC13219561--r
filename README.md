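# hpfnet — probe-then-fuse adaptation for few-shot image classification

`hpfnet` adapts a **frozen** vision-transformer backbone to an N-way K-shot
image-classification episode. Full fine-tuning overfits badly when only a
handful of labeled images per class exist (the routine situation in medical
imaging); this package instead trains a small, carefully placed set of
parameters around the frozen encoder:

1. **Fisher-probe layer selection.** Every transformer layer ℓ exposes a
   pooled feature `f_ℓ(x)` (the class-token hidden state). On the support
   set, a fixed random linear head `h` provides loss gradients, and each
   layer is scored by the class-wise gradient Fisher proxy

   `F_c(ℓ) = mean over class-c samples of ‖∇_{f_ℓ(x)} L_CE(h(f_ℓ(x)), y)‖²`,

   aggregated per layer as `score_ℓ = max_c F_c(ℓ)` and z-scored across
   layers. The top `K_s` layers (default 3) form the fusion set.
2. **LoRA adapters.** Each attention projection `W₀ ∈ {W_q, W_k, W_v}` gains
   a low-rank branch `W′ = W₀ + s·BA` with rank `r` (default 8); `B = 0` at
   injection so the adapted model starts exactly at the frozen model, and
   `BA` merges into `W₀` for inference with zero latency overhead.
3. **Attention-guided fusion.** Selected-layer features are aligned by a
   shared projection (LeakyReLU + L2 norm), scaled by learnable static
   layer weights initialized `linspace(1.5, 0.5, K_s)`, and aggregated by
   multi-head cross-attention `softmax(qKᵀ/√d_k)V` against a learned query;
   the output is re-normalized so the classifier operates on feature
   direction.

Only `Θ_lora ∪ Θ_fusion ∪ Θ_head` train (AdamW, cosine annealing, global
gradient clipping, head rate scaled with the class count); the backbone is
bitwise frozen throughout. Everything — transformer forward pass, manual
backward pass, adapters, fusion, trainer, AUROC evaluation and a seeded
synthetic episode generator — is implemented in base R matrix algebra with
no deep-learning framework, and the hand-written gradients are verified
against finite differences in the test suite.

## Worked example

```r
library(hpfnet)

bb <- buildBackbone(backboneConfig(), seed = 7)   # frozen 6-layer, width-32 encoder
bb
#> ViTBackbone (frozen): 6 layers, width 32, 17 tokens, 53,984 parameters

# a synthetic episode whose labels are a margin-separated function of the
# layer-3 pooled features (ground truth for the whole pipeline)
pt <- generatePlantedTask(bb, layer = 3, nWay = 5, kShot = 10,
                          nQuery = 30, margin = 1.0, seed = 41)
pt$episode
#> Episode: 5-way 10-shot, |S|=50, |Q|=30, 32x32 images (1 ch)

rec <- runTask(pt$episode, bb, kSelect = 3, seed = 1)
rec$selected                          # layers chosen by the Fisher probe
#> [1] 5 1 6
c(first = rec$loss[1], final = rec$loss[50])
#> first final
#> 1.610 0.147                         # support loss falls 10x in 50 steps
rec$metrics$auroc                     # held-out query, macro one-vs-rest
#> [1] 0.957
rec$parameters$percentTrainable
#> [1] 23.19                           # trainable share at desk scale
```

At the ViT-B/16 geometry the accounting is exact and matches the published
budgets:

```r
vit <- backboneConfig(nLayers = 12, hiddenDim = 768, nHeads = 12,
                      mlpDim = 3072, patchSize = 16, imageSize = 224,
                      nChannels = 3)
countParameters(vit)                  # 85,798,656  (85.80 M, full tuning)
countLoraParameters(12, 768, 768, 8)  # 442,368     (0.44 M at rank 8)
parameterReport(vit)$coreMillions     # 1.03 M adapters + shared projection
parameterReport(vit)$percentCore      # 1.20 % of the backbone
```

A YAML-driven command surface (`cmdProbe`, `cmdRun`, `cmdParams`,
`cmdGenerate`; thin CLI in `inst/scripts/hpfnet`) writes JSONL task
records, selection-frequency tables and parameter sweeps for batch
experiments.

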