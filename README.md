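# m3seg — hybrid CNN–Transformer segmentation of 2D medical images

`m3seg` is an R implementation of a hybrid U-shaped encoder–decoder for
multi-class 2D medical image segmentation (CT slices, endoscopy frames,
X-rays, dermoscopy). It is aimed at methods researchers who want every piece
of such an architecture — attention biases, gates, losses, metrics — as
inspectable, CPU-trainable R code rather than an opaque GPU framework.

The network combines:

* a residual convolutional stem with skip features at 1/2, 1/4, 1/8
  resolution, patch-embedded into a token grid of `(S/P)²` tokens;
* **MSGA** — grouped multi-scale gate attention applied to the token grid
  before self-attention (depthwise convolution, directional-pooling spatial
  gate, cross-spatial re-weighting; a pure sigmoid gate, so `|Y| ≤ |X|`);
* **ME-MSA** — multi-head self-attention with a learnable Manhattan-distance
  penalty on the logits, per head
  `Softmax(QKᵀ/√d_k − λ·D)V`, `D_ij = (|x_i−x_j| + |y_i−y_j|)/(H+W)`,
  λ initialized to 1 — an explicit locality prior;
* **MKGAG** — skip-connection gates built from three independent 3×3
  group-convolution + batch-norm branches, summed, ReLU6-activated and
  compressed to a single-channel sigmoid map;
* **MSSA** — decoder refinement with four depthwise-separable branches
  (kernels 3/5/7/9 with squeeze-and-excitation) and linear-complexity
  Performer attention, `D⁻¹(ϕ(Q)(ϕ(K)ᵀV))`, over the fused features.

Training minimizes `L = 0.5·CE + 0.5·Dice` (background excluded from the
Dice average) with SGD (lr 0.01, momentum 0.9, weight decay 1e−4,
polynomial decay). Evaluation reports DSC (%), IOU and the 95th-percentile
Hausdorff distance in mm. A seeded phantom generator produces multi-class,
multi-scale, low-contrast "organ-like" fixtures so the full pipeline runs
with no dataset download. The automatic differentiation engine behind all
of this lives in the package itself (R tape + Rcpp/RcppArmadillo kernels).

## A worked example

```r
library(m3seg)

# four synthetic 4-class phantoms at the tiny preset's 64 px
samples <- lapply(1:4, function(i) generate_phantom(seed = 100 + i,
                                                    size = 64, n_classes = 4))
model <- build_model(model_config("tiny"), seed = 1)
count_parameters(model)
#> [1] 177951

fit <- fit_segmentation(model, samples,
                        config = train_config(batch_size = 2,
                                              max_iterations = 2000, seed = 1,
                                              eval_every = 50,
                                              target_dsc = 0.92))
glance(fit)
#> # A tibble: 1 × 6
#>   iterations final_loss final_ce final_dice train_dsc parameters
#>        <int>      <dbl>    <dbl>      <dbl>     <dbl>      <dbl>
#> 1        450     0.0412   0.0149     0.0675     0.994     177951

report <- evaluate_model(fit$model, samples)
summarize_metrics(report)
#> # A tibble: 1 × 5
#>   mean_dsc mean_hd95 mean_iou n_classes n_hd95_undefined
#>      <dbl>     <dbl>    <dbl>     <int>            <int>
#> 1     99.4     0.175    0.988        12                0
```

The run stops once the mean foreground DSC over the training phantoms
reaches the 0.92 target (here after 450 iterations, a few CPU-minutes);
`final_loss = 0.5·final_ce + 0.5·final_dice` holds on every logged row.
`autoplot(fit)` draws the three loss curves; `autoplot(report)` the
per-class DSC.

A command-line interface wraps the same functions
(`inst/cli/m3seg fixtures|train|eval|predict`), with run configuration in
YAML and metric reports written as CSV + JSON.

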