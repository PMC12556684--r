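# drseg — contrast-agnostic brain segmentation by domain randomization

`drseg` is an R implementation of the domain-randomization recipe for
MRI brain segmentation that is robust to contrast, resolution, and the
strong signal inhomogeneities of ultra-high-field (7 T+) imaging. The idea:
instead of training a network on real images of some particular contrast,
training images are *synthesized* from anatomical label maps — for every
image, each structure's intensity distribution, a bias field, and a gamma
transform are drawn at random. A 3D U-Net trained on such data cannot latch
onto any contrast and generalizes across acquisitions.

The package covers the whole desk-scale pipeline:

* **volio** — NIfTI-1 I/O, FreeSurfer color tables, anatomical reorientation
  (e.g. to LIA), cubic-spline intensity resampling and one-hot linear label
  resampling;
* **labelprep** — extra-cerebral label construction (closing, hole fill,
  4/5-voxel dilation) and skull-strip masking;
* **synthgen** — the generative model: random deformation, per-label Gaussian
  intensities, bias field (amplitude 0.9), gamma, all at native resolution;
* **phantoms** — nested-ellipsoid phantom label maps and fixed-contrast
  renderings so everything is testable without data;
* **network** — configurable 3D U-Net (conv + instance norm + leaky ReLU),
  soft-Dice + cross-entropy loss, poly LR schedule, AdamW, fold training with
  synthetic-train / real-validate splits;
* **inference** — Gaussian-weighted sliding windows, softmax-average
  ensembling over folds, validated largest-component post-processing, and the
  LIA/resolution round trip back to the native grid;
* **evaluate** — DSC and average surface distance with the missing-label
  convention (DSC 0 / ASD NaN), the 27-of-35-label exclusion policy,
  bootstrap cohort summaries, TIV-normalized volumetry with Mann-Whitney U
  tests under Bonferroni correction.

## The statistics at the core

For ground-truth segment $G$ and prediction $P$:

$$\mathrm{DSC} = \frac{2\,|G \cap P|}{|G| + |P|}, \qquad
\mathrm{ASD} = \frac{\sum_{i=1}^{N_G} d_{G\to P,i} + \sum_{i=1}^{N_P} d_{P\to G,i}}{N_G + N_P}$$

with $d$ the Euclidean nearest-point distance between voxel-center surfaces
in mm. Training minimizes soft-Dice plus cross-entropy; the learning rate
follows $\mathrm{lr}(e) = \mathrm{lr}_0 (1 - e/E)^{0.9}$.

## Worked example

```r
library(drseg)

# a phantom "subject": label map + a fixed-contrast rendering
ph   <- make_phantom_labelmap(phantom_spec(seed = 7))
img  <- render_validation_image(ph, phantom_contrast_profile(ph, "t1w"),
                                snr = 25, seed = 7)

# attach the extra-cerebral label and synthesize one training image
pol  <- extracerebral_policy(dilation_voxels = "auto")
lm   <- add_extracerebral_label(ph, extracerebral_mask(ph, pol), pol)
pair <- generate_training_pair(lm, generator_config(seed = 1))
range(pair$image$data)          # synthetic image lives in [0, 1]
#> [1] 0 1
999 %in% vol_labels(pair$target) # extra-cerebral id never a training target
#> [1] FALSE

# evaluate a (here: perfect) segmentation
rep <- evaluate_labelmaps(ph, ph, default_exclusion_policy())
rep$summary
#> $median_dsc
#> [1] 1
#> $median_asd_mm
#> [1] 0
#> $n_labels
#> [1] 10
```

`median_dsc = 1` / `median_asd_mm = 0` are the perfect-overlap values.
`n_labels = 10`: the 12-label phantom loses its ventricle (id 4) and CSF rim
(id 24) to the default exclusion policy; on a full 35-label map the same
policy leaves 27 labels — the conventional "median over 27 labels" summary.

Training and prediction at desk scale:

```r
pairs <- lapply(1:24, function(i) {
  ph <- make_phantom_labelmap(phantom_spec(seed = 100 + i))
  lm <- add_extracerebral_label(ph, extracerebral_mask(ph, pol), pol)
  generate_training_pair(lm, generator_config(seed = 1), seed = 1000 + i)
})
vals <- lapply(1:4, function(i) {
  ph <- make_phantom_labelmap(phantom_spec(seed = 200 + i))
  validation_pair(render_validation_image(
    ph, phantom_contrast_profile(ph, "t1w"), snr = 25, seed = i), ph)
})
model <- train_fold(pairs, vals, net_config(), train_config(), verbose = TRUE)
seg   <- segment_volume(img, list(model), postproc_policy(), train_spacing = 0.7)
```

## Command line

```sh
Rscript -e 'drseg::drseg_cli()' make-phantoms --n 24 --shape 64 --spacing 0.7 --seed 1 --out phantoms/
Rscript -e 'drseg::drseg_cli()' prepare-labels --in labels.nii.gz --dilate auto --ec-id 999 --out-labels prepped.nii.gz
Rscript -e 'drseg::drseg_cli()' generate --labels phantoms/ --out pairs/ --seed 1
Rscript -e 'drseg::drseg_cli()' predict --in t1.nii.gz --models 'models/fold_*.rds' --out seg.nii.gz --train-spacing 0.7
Rscript -e 'drseg::drseg_cli()' evaluate --gt 'gt/*.nii.gz' --pred 'pred/*.nii.gz' --policy default27 --out report.csv
```

## Scope

Dataset acquisition, ground-truth production with external tools, cortical
parcellation, MR physics simulation, and reproduction of any published
real-cohort scores are out of scope; phantom-based tests establish that the
machinery is correct, not that a desk-scale model segments real brains.
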