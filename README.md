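# mcseg — multi-contrast MRI segmentation by convex TV relaxation

`mcseg` segments deep grey-matter structures — designed around thalamic
nuclear group parcellation — from several co-registered MRI contrasts at
once (e.g. T1-weighted, T2\*-weighted and quantitative susceptibility
maps). No single contrast resolves all internal boundaries of the
thalamus; the package exploits their joint information in two stages:

1. **Supervised posterior estimation.** Every voxel is described by 9
   features per contrast (intensity, 26-neighbourhood mean and standard
   deviation, six face-neighbour intensities; m = 27 for three
   contrasts), standardized with training statistics. A k-nearest
   neighbour (k = 3) or Parzen-window (h = 0.1668) classifier trained on
   a labelled template produces per-voxel class posteriors
   p̂ ∈ ℝ^{n×ℓ}.
2. **Convex multi-label segmentation.** The relaxed labelling
   u : Ω → Δ_ℓ (unit simplex per voxel) minimises

       min_u  Σ_x Σ_l C(x,l) u(x,l) + λ TV(u),
       C = −log((1−w) p̂ + w m)

   where TV is the L¹ total variation of the class channels (slicewise
   2D by default, full 3D optional), λ balances data fidelity against
   interface length, and m is an optional one-hot template prior with
   weight w ∈ [0,1] for robust single-subject segmentation. The problem
   is solved with a first-order primal-dual method and discretized by
   per-voxel argmax.

The package also ships the evaluation metrics used to validate such
segmentations (confusion matrix, global error rate, non-background
true-positive rate, Dice, physical boundary distances) and a synthetic
multi-contrast phantom generator whose class means are engineered so that
each single contrast is ambiguous for one class pair while all contrasts
jointly separate every class — making multi-contrast superiority a
testable property.

## Worked example

```r
library(mcseg)

# a noise-free template with ground-truth labels, and a noisy subject
tmpl  <- generate_subject(phantom_spec(shape = c(32, 32, 32), noise_sd = 0),
                          seed = 1)
model <- run_training(tmpl$volume, tmpl$labels, "knn", k = 3)
subj  <- generate_subject(phantom_spec(shape = c(32, 32, 32), noise_sd = 9),
                          seed = 42)
res   <- run_segmentation(model, subj$volume,
                          config = solver_config(lambda = 1),
                          truth = subj$labels)

round(100 * res$metrics$global_error, 3)
#> [1] 0.012
round(res$metrics$dice, 3)
#> class0 class1 class2 class3
#>  1.000  0.999  0.996  0.997
res$relaxed
#> <relaxed_labeling> 32768 voxels x 4 classes, 11 iterations (converged)
```

The global error is the fraction of all evaluated voxels labelled
incorrectly (here 0.012%); per-class Dice measures the overlap of each
predicted region with its ground truth. Because the background outweighs
the nuclei several-fold, every metrics report also carries the
non-background true-positive rate and the evaluation region it was
computed on.

`run_ablation()` tabulates errors for every contrast subset (the feature
space shrinks to 9·|subset|), `run_w_sweep()` traces the error as the
prior weight w moves from the classifier-only solution (w = 0) to the
prior itself (w = 1), and `inst/cli/mcseg.R` is a command-line front end
(`train`, `segment`, `phantom`) operating on NIfTI files.

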