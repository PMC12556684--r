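# Prediction path: canonical LIA reorientation, resampling to the training
# resolution, Gaussian-weighted sliding-window prediction, softmax-average
# ensembling over folds, validated largest-component post-processing, and the
# round trip back to the native grid and orientation.

#' Stub model for pipeline testing
#'
#' A drop-in replacement for a trained `fold_model` whose prediction is an
#' arbitrary function of the raw intensity patch. Used to test that the
#' inference plumbing itself introduces no error (e.g. a stub decoding a
#' noiseless rendering back to its one-hot labels must reproduce the phantom
#' exactly at matched spacing).
#'
#' @param predict_fn `function(patch_array)` returning a `[dims, K]`
#'   probability array.
#' @param class_ids label id per probability channel (background 0 first).
#' @param patch_size patch shape the stub expects.
#' @return a `stub_model` usable wherever a `fold_model` is.
#' @export
stub_model <- function(predict_fn, class_ids, patch_size = c(24L, 24L, 24L)) {
  structure(list(predict_fn = predict_fn, class_ids = as.integer(class_ids),
                 net = list(patch_size = as.integer(rep(patch_size,
                                                        length.out = 3)))),
            class = "stub_model")
}

model_class_ids <- function(model) model$class_ids

model_normalize_volume <- function(model, data) {
  if (inherits(model, "stub_model")) data else normalize_image(data)
}

model_predict_patch <- function(model, patch) {
  if (inherits(model, "stub_model")) {
    p <- model$predict_fn(patch)
    stopifnot(length(dim(p)) == 4L)
    return(p)
  }
  fw <- unet_forward(model$params, model$net, patch)
  probs <- softmax_rows(fw$logits)
  array(probs, c(fw$dims, ncol(probs)))
}

gaussian_patch_weight <- function(patch) {
  sig <- patch / 8
  w1 <- lapply(1:3, function(a) {
    x <- seq_len(patch[a]) - (patch[a] + 1) / 2
    exp(-x^2 / (2 * sig[a]^2))
  })
  w <- outer(outer(w1[[1]], w1[[2]]), w1[[3]])
  pmax(w, max(w) * 1e-3)
}

tile_starts <- function(n, p, overlap) {
  if (n <= p) return(1L)
  step <- max(1L, as.integer(floor(p * (1 - overlap))))
  s <- seq(1L, n - p + 1L, by = step)
  if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
  s
}

#' Sliding-window probabilistic prediction
#'
#' Tiles the volume with at least `overlap` fractional overlap between
#' neighboring patches, accumulates Gaussian-weighted (sigma = patch/8)
#' softmax outputs and normalizes by the accumulated weight, guaranteeing
#' full coverage and per-voxel probability sums of 1. Volumes smaller than
#' the patch are zero-padded internally and cropped back.
#'
#' @param model `fold_model` or [stub_model()].
#' @param image an [intensity_volume()] already on the model's training grid
#'   spacing and orientation.
#' @param patch patch shape; defaults to the model's training patch.
#' @param overlap fractional overlap in [0, 1).
#' @return a `probability_maps` object: `probs` array `[dims, K]`,
#'   `class_ids`, `affine`.
#' @export
sliding_window_predict <- function(model, image,
                                   patch = model$net$patch_size,
                                   overlap = 0.5) {
  stopifnot(inherits(image, "intensity_volume"), overlap >= 0, overlap < 1)
  patch <- as.integer(rep(patch, length.out = 3))
  d0 <- dim(image$data)
  x <- model_normalize_volume(model, image$data)
  x <- pad_to_patch(x, patch)
  d <- dim(x)
  K <- length(model_class_ids(model))
  bg_channel <- match(0L, model_class_ids(model), nomatch = 0L)
  acc <- array(0, c(d, K))
  wsum <- array(0, d)
  w <- gaussian_patch_weight(patch)
  for (i in tile_starts(d[1], patch[1], overlap))
    for (j in tile_starts(d[2], patch[2], overlap))
      for (k in tile_starts(d[3], patch[3], overlap)) {
        ii <- i:(i + patch[1] - 1L)
        jj <- j:(j + patch[2] - 1L)
        kk <- k:(k + patch[3] - 1L)
        xp <- x[ii, jj, kk, drop = FALSE]
        rngp <- range(xp)
        if (rngp[1] == rngp[2] && bg_channel > 0L) {
          # a strictly constant patch is invisible to a per-patch-normalizing
          # network (instance norm maps every constant to the same features);
          # in a skull-stripped volume it can only be background
          p <- array(0, c(patch, K))
          p[, , , bg_channel] <- 1
        } else {
          p <- model_predict_patch(model, xp)
        }
        for (c_ in seq_len(K))
          acc[ii, jj, kk, c_] <- acc[ii, jj, kk, c_] + p[, , , c_] * w
        wsum[ii, jj, kk] <- wsum[ii, jj, kk] + w
      }
  for (c_ in seq_len(K)) acc[, , , c_] <- acc[, , , c_] / wsum
  probs <- acc[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), , drop = FALSE]
  structure(list(probs = probs, class_ids = model_class_ids(model),
                 affine = image$affine),
            class = "probability_maps")
}

#' Ensemble probability maps into a segmentation
#'
#' Averages the per-class softmax outputs of all models voxel-wise and takes
#' the argmax (ties resolved toward the lowest label id; channels are ordered
#' by increasing id with background first).
#'
#' @param prob_list list of `probability_maps` sharing grid and class map.
#' @param lut optional lookup table for the output [labeled_volume()].
#' @return a [labeled_volume()].
#' @export
ensemble_segment <- function(prob_list, lut = NULL) {
  stopifnot(length(prob_list) >= 1L)
  ref <- prob_list[[1]]
  for (p in prob_list[-1]) {
    if (!identical(dim(p$probs), dim(ref$probs)) ||
        !identical(p$class_ids, ref$class_ids))
      stop("probability maps do not share grid and class mapping")
  }
  mean_probs <- ref$probs
  if (length(prob_list) > 1L) {
    for (p in prob_list[-1]) mean_probs <- mean_probs + p$probs
    mean_probs <- mean_probs / length(prob_list)
  }
  d <- dim(mean_probs)
  m <- matrix(mean_probs, ncol = d[4])
  ord <- order(ref$class_ids)  # ascending id; ties -> first max -> lowest id
  cls <- ord[max.col(m[, ord, drop = FALSE], ties.method = "first")]
  lab <- array(ref$class_ids[cls], d[1:3])
  labeled_volume(lab, ref$affine, lut = lut)
}

#' Post-processing policy
#'
#' Which labels get largest-connected-component filtering, and the
#' connectivity used to define components.
#'
#' @param apply_largest_component integer label ids to filter.
#' @param connectivity 6, 18 or 26 (default 26, the full 3D neighborhood).
#' @return a `postproc_policy`.
#' @export
postproc_policy <- function(apply_largest_component = integer(),
                            connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  structure(list(apply_largest_component = as.integer(apply_largest_component),
                 connectivity = as.integer(connectivity)),
            class = "postproc_policy")
}

#' Keep only the largest connected component of selected labels
#'
#' For each label in the policy's apply set, voxels outside the label's
#' largest component become background (0); removed satellites are not
#' reassigned to neighbors. Labels outside the set are untouched. Idempotent.
#'
#' @param seg a [labeled_volume()].
#' @param policy a [postproc_policy()].
#' @return filtered [labeled_volume()].
#' @export
largest_component_filter <- function(seg, policy) {
  stopifnot(inherits(seg, "labeled_volume"), inherits(policy, "postproc_policy"))
  data <- seg$data
  d <- as.integer(dim(data))
  for (id in intersect(policy$apply_largest_component, vol_labels(seg))) {
    mask <- data == id
    cc <- cpp_connected_components(mask, d, policy$connectivity)
    if (length(cc$sizes) <= 1L) next
    keep <- which.max(cc$sizes)
    data[mask & cc$labels != keep] <- 0L
  }
  out <- seg
  out$data <- data
  out
}

#' Decide the largest-component policy on validation data
#'
#' For each label, compares the mean validation Dice of the ensembled
#' prediction with vs without largest-component filtering of that label; the
#' label enters the apply set only if the mean strictly improves (ties are
#' excluded). Mirrors the production rule of testing the default
#' post-processing against the validation set after training all folds.
#'
#' @param models list of `fold_model`s (ensembled for the decision).
#' @param val_pairs list of [validation_pair()]s on the training grid.
#' @param connectivity component connectivity (26 default).
#' @param overlap sliding-window overlap.
#' @return a [postproc_policy()].
#' @export
decide_postproc_policy <- function(models, val_pairs, connectivity = 26L,
                                   overlap = 0.5) {
  if (length(val_pairs) == 0L) stop("empty validation set")
  gains <- list()
  all_ids <- integer()
  per_subject <- list()
  for (si in seq_along(val_pairs)) {
    vp <- val_pairs[[si]]
    probs <- lapply(models, sliding_window_predict, image = vp$image,
                    overlap = overlap)
    seg <- ensemble_segment(probs, lut = vp$target$lut)
    per_subject[[si]] <- list(seg = seg, gt = vp$target)
    all_ids <- union(all_ids, vol_labels(vp$target))
  }
  apply_set <- integer()
  for (id in sort(all_ids)) {
    with_f <- without_f <- numeric()
    for (ps in per_subject) {
      g <- ps$gt$data == id
      if (!any(g)) next
      p_raw <- ps$seg$data == id
      seg_f <- largest_component_filter(
        ps$seg, postproc_policy(id, connectivity))
      p_f <- seg_f$data == id
      without_f <- c(without_f, dice_coefficient(g, p_raw))
      with_f <- c(with_f, dice_coefficient(g, p_f))
    }
    if (length(with_f) > 0L && mean(with_f) > mean(without_f))
      apply_set <- c(apply_set, id)
  }
  postproc_policy(apply_set, connectivity)
}

#' Segment a volume end to end
#'
#' Reorients to the canonical LIA orientation, resamples to the training
#' spacing (default (0.7 mm)^3) if needed, runs sliding-window prediction for
#' every fold model, averages softmax outputs, applies the largest-component
#' policy, resamples the labels back to the native grid by one-hot linear
#' interpolation and restores the native orientation. The output grid and
#' affine equal the input's exactly.
#'
#' @param image a skull-stripped [intensity_volume()] (contract, not checked).
#' @param models list of `fold_model`s / [stub_model()]s sharing a class map.
#' @param policy a [postproc_policy()] (default: no filtering).
#' @param train_spacing model grid spacing in mm.
#' @param overlap sliding-window overlap fraction.
#' @param lut lookup table for the output map.
#' @return a [labeled_volume()] on the input grid.
#' @export
segment_volume <- function(image, models, policy = postproc_policy(),
                           train_spacing = 0.7, overlap = 0.5, lut = NULL) {
  stopifnot(inherits(image, "intensity_volume"), length(models) >= 1L)
  train_spacing <- rep(as.numeric(train_spacing), length.out = 3)
  native_orient <- orientation_of(image$affine)
  lia <- reorient(image, "LIA")
  lia_dims <- dim(lia$data)
  lia_affine <- lia$affine
  sp <- vol_spacing(lia)
  needs_resample <- any(abs(sp - train_spacing) > 1e-6)
  work <- if (needs_resample) resample_intensity(lia, train_spacing) else lia

  probs <- lapply(models, sliding_window_predict, image = work,
                  overlap = overlap)
  seg <- ensemble_segment(probs, lut = lut)
  seg <- largest_component_filter(seg, policy)

  if (needs_resample)
    seg <- resample_labels_to_grid(seg, lia_dims, lia_affine)
  out <- reorient(seg, native_orient)
  if (max(abs(out$affine - image$affine)) > 1e-6)
    stop("internal error: output affine drifted from the input affine")
  out$affine <- image$affine
  out
}
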