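# stomadet

Small-object detection of stomata in leaf-epidermis micrographs, as a
single self-contained R package: a seeded synthetic micrograph generator,
YOLO-format dataset I/O, a CPU-trainable anchor-free multi-scale detector
with an optional stride-4 small-object scale (P2) and a dynamic
mixture-of-kernels convolution operator, mask-driven multi-task training
that focuses optimization on the stomatal class, masked generative feature
distillation, and standard detection evaluation (precision, recall,
AP/mAP).

## Who it is for

Plant-phenotyping and quantitative-microscopy groups who want a compact,
fully reproducible reference implementation of the "small object inside a
large auxiliary object" detection recipe — and anyone who needs exact,
testable parameter/FLOP accounting for this detector family without a GPU
stack.

## The models in brief

* **Detector.** A YOLO-family one-stage network: CSP backbone (strides
  2–32), SPPF + spatial attention at stride 32, top-down/bottom-up neck,
  decoupled heads with distribution-based box regression (16 bins per box
  side, decoded by softmax expectation) and per-class sigmoid scores.
  Scales P3–P5 by default; adding P2 (stride 4) quadruples the spatial
  resolution available to small objects.
* **Dynamic convolution.** Designated convolutions hold M expert kernels
  `W_1..W_M`; a two-layer router computes
  `alpha = softmax(MLP(GlobalAvgPool(x)))` per sample and the layer applies
  `W' = sum_i alpha_i W_i`. Capacity grows linearly in M at almost no
  FLOP cost.
* **Multi-task masking.** With both classes annotated
  (outer = epidermal cell = 0, inner = stoma = 1), training first
  pretrains on outer-only labels (half of train+val), then formally trains
  with a binary mask `M_ij = 1[label_ij = inner]` so the supervised loss
  `sum(BCE * M) / max(sum(M), 1)` (and the equally masked box terms)
  backpropagates only stomatal error.
* **Distillation.** `L = L_task + alpha * sum (T - G(f_align(S * mask)))^2`
  with a random spatial mask of ratio lambda on the student's neck
  features, a 1x1 channel alignment, and a conv–ReLU–conv generation
  network regenerating the frozen teacher's features.

## Worked example

```r
library(stomadet)

# 1. a synthetic dataset: 200 micrographs, nested outer/inner labels
dir <- file.path(tempdir(), "scenes")
synth_dataset(dir, 200, seed = 1,
              spec = scene_spec(width = 320, height = 320, n_cells = 4))
m <- split_dataset(build_manifest(dir), c(7, 2, 1), seed = 1)
print(m)
#> <dataset_manifest> 200 items; classes: outer, inner
#>  test train   val
#>    20   140    40

# 2. profile the reference architectures
profile_detector(detector_config(scales = c("P3", "P4", "P5")))$parameters
#> [1] 2582542
p <- profile_detector(detector_config(scales = c("P2", "P3", "P4", "P5"),
                                      use_dynamic = TRUE))
p$parameters; round(p$gflops, 2)
#> [1] 4692692
#> [1] 8.31

# 3. train the full recipe at desk scale (about 2.5 min on one CPU)
cfg <- run_config(out_dir = file.path(tempdir(), "run"), data_dir = dir,
                  width = 0.125, input_size = 160, use_dynamic = TRUE,
                  pretrain = TRUE, pretrain_epochs = 4, epochs = 8,
                  batch_size = 10, lr0 = 0.02, seed = 1)
res <- train_pipeline(cfg)
round(res$metrics$map_headline, 2)   # inner-class mAP@0.5 on the val split
#> [1] 0.54

# 4. detect stomata in one image
det <- predict_image(res$model, m$items$image[1], conf_threshold = 0.25)
head(det[det$class == 1, c("conf", "cx", "cy", "w", "h")], 3)
#>   conf   cx    cy     w     h
#> 1    1 0.42 0.813 0.048 0.049
#> 2    1 0.80 0.087 0.051 0.048
#> 3    1 0.71 0.562 0.048 0.046
```

The first number printed in step 2 is the exact trainable-parameter count
of the baseline configuration, obtained by enumerating every stored weight
array; the second pair is the full configuration (P2 + dynamic convolution)
and its forward cost at a 640 px input under the 1 MAC = 2 FLOPs
convention. Step 3's number is the headline metric: mean average precision
of the stomatal class at IoU 0.5 on held-out validation scenes (small
training budget; see the methods vignette for the full protocol).

A thin command-line front end is included at `inst/cli/stomadet`
(subcommands `synth`, `split`, `train`, `eval`, `profile`, `ablate`).

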