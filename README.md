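# nervequant

Quantification of the corneal sub-basal nerve plexus from in-vivo confocal
microscopy (CCM). The package segments nerve fibres with a patch-based
U-Net — optionally a five-member bootstrap ensemble fused by pixel-wise
majority vote — and reduces the segmentation to the clinical nerve
biomarkers used in diabetic-neuropathy screening, together with the
statistics needed to validate an automated reader against manual
annotation.

**Who it is for.** Researchers working with CCM images of the cornea who
need reproducible, scriptable nerve morphometry: total corneal nerve fibre
(CNF) length, branch and tail points, nerve segments, and a fractal
complexity measure — and who need to compare methods (ICC, Bland–Altman,
RMSE/SD) or evaluate diagnostic performance (ROC/AUC, Youden cut-point).

## The method in brief

* **Standardisation.** Images are resampled by bilinear interpolation to
  1.04 μm/px and framed to 384 × 384 px (pitch wins over frame; crop/pad
  as needed).
* **Segmentation.** 128 × 128 px patches anchored every 32 px (81 per
  frame) pass through a U-Net (3 × 3 conv + ReLU blocks, 2 × 2 pooling and
  nearest-neighbour upsampling, skip connections, dropout 0.2, sigmoid
  head) trained with the soft Dice loss 1 − DSC, where
  DSC = (2|A∩B| + s)/(|A| + |B| + s). Patch masks are stitched by majority
  vote over the covering patches. An ensemble of five nets, each trained on
  an image-level bootstrap resample, votes per pixel (threshold 3 of 5).
* **Morphometry.** The mask is thinned to a 1-px skeleton (Zhang–Suen plus
  a redundant-pixel cleanup); tails have one 8-neighbour, branch clusters
  three or more; segments run node-to-node; lengths are geodesic
  (1 / √2 steps × pitch); the fractal number is the box-counting slope of
  log N(ε) vs log(1/ε) on dyadic boxes.
* **Validation statistics.** Per-variable RMSE and SD of the per-image
  error V = v_method − v_manual; ICC(2,1) (two-way random, absolute
  agreement, single measures) with the conventional reliability bands;
  Bland–Altman limits of agreement (mean ± 1.96 SD, 95% CIs); empirical
  ROC with trapezoid AUC and the Youden-optimal cut.

Everything is seeded and deterministic; a synthetic phantom generator
(`generate_phantom()`, `generate_cohort()`) produces CCM-like branching
fibre images with exact ground truth for testing and demonstration.

## Worked example

```r
library(nervequant)

# a phantom with known ground truth
ph <- generate_phantom(phantom_spec(seed = 13))
ph$truth$true_total_length_um
#> [1] 2475.2
ph$truth$true_n_branch
#> [1] 17

# quantify the (here: ground-truth) segmentation
q <- quantify(ph$truth$mask, pixel_size_um = 1.04)
q
#> <morphometry_record> total 2516.0 um | 17 branch, 27 tail, 39 segments | mean seg 64.5 um | fractal 1.122
```

The quantified total length lands within ~2% of the generating truth and
the branch count is exact. Training a segmenter and validating it end to
end:

```r
pairs <- lapply(1:16, function(s) {
  p <- generate_phantom(phantom_spec(image_size = 128L, n_trees = 3L, seed = s))
  list(x = p$image$pixels, y = p$truth$mask)
})
ens <- train_ensemble(pairs,
                      unet_config(depth = 3, base_channels = 8),
                      train_config(epochs = 12, seed = 7),
                      ensemble_config(n_members = 5),
                      patch_px = 128, stride_px = 128)
mask <- predict_ensemble(ens, pairs[[1]]$x)
dice_coefficient(mask, pairs[[1]]$y)
#> [1] 0.8395062
```

A thin command-line front end over these functions lives at
`inst/cli/nervequant.R` (subcommands `simulate`, `split`, `train`,
`segment`, `quantify`, `validate`).

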