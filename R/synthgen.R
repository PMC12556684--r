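# Domain-randomization generative model: label map -> (deformed label map,
# synthetic intensity image). Contrast agnosticism comes from sampling a
# fresh per-label Gaussian intensity distribution for every synthetic image;
# spatial variability from a random affine + smooth elastic deformation;
# acquisition artifacts from a multiplicative bias field and a random gamma
# transform. No resolution degradation is ever applied: synthetic images stay
# at the native grid of the label map.

#' Generator configuration
#'
#' Priors of the domain-randomization model. Defaults follow the published
#' priors of label-map-to-image synthesis models, with two deltas for the
#' ultra-high-field setting: the bias-field amplitude is raised to 0.9 and
#' resolution randomization does not exist in this implementation at all.
#'
#' @param rotation_deg max |rotation| per axis, degrees (uniform prior).
#' @param scaling scaling range per axis (uniform).
#' @param shearing max |shear| coefficient (uniform).
#' @param translation_mm max |translation| per axis in mm (uniform).
#' @param elastic_grid control-grid size for the smooth elastic field.
#' @param elastic_std_mm range of the elastic displacement std in mm; the
#'   per-sample std is drawn uniformly, then control-point displacements are
#'   Gaussian with that std.
#' @param mean_range per-label intensity mean prior, uniform (arbitrary units).
#' @param std_range per-label intensity std prior, uniform.
#' @param bias_amplitude_max bias-field coefficient std upper bound; the
#'   per-sample std is U(0, max), coefficients are exponentiated so the field
#'   is strictly positive. 0 disables the bias field.
#' @param bias_grid_size control-grid size of the bias field (default 4).
#' @param gamma_log_std std of the log-gamma exponent; 0 disables gamma.
#' @param flip_probability probability of a left/right flip; off by default
#'   (lateralized label ids would require an id-swap table, see `flip_swap`).
#' @param flip_swap optional named integer vector mapping ids under flip.
#' @param drop_from_target label ids synthesized into the image but removed
#'   (set to background) in the returned training target; by default the
#'   extra-cerebral id 999.
#' @param seed integer seed making [generate_training_pair()] deterministic.
#' @return a `generator_config` list.
#' @export
generator_config <- function(rotation_deg = 15,
                             scaling = c(0.85, 1.15),
                             shearing = 0.012,
                             translation_mm = 3,
                             elastic_grid = 5L,
                             elastic_std_mm = c(0, 2.5),
                             mean_range = c(25, 225),
                             std_range = c(5, 25),
                             bias_amplitude_max = 0.9,
                             bias_grid_size = 4L,
                             gamma_log_std = 0.4,
                             flip_probability = 0,
                             flip_swap = NULL,
                             drop_from_target = 999L,
                             seed = 1L) {
  chk_range <- function(x, nm) {
    if (length(x) != 2L || x[1] > x[2]) stop(nm, " must be an ordered range")
    x
  }
  stopifnot(rotation_deg >= 0, shearing >= 0, translation_mm >= 0,
            bias_amplitude_max >= 0, gamma_log_std >= 0,
            flip_probability >= 0, flip_probability <= 1,
            elastic_grid >= 2L, bias_grid_size >= 2L)
  structure(list(
    rotation_deg = rotation_deg,
    scaling = chk_range(scaling, "scaling"),
    shearing = shearing,
    translation_mm = translation_mm,
    elastic_grid = as.integer(elastic_grid),
    elastic_std_mm = chk_range(elastic_std_mm, "elastic_std_mm"),
    mean_range = chk_range(mean_range, "mean_range"),
    std_range = chk_range(std_range, "std_range"),
    bias_amplitude_max = bias_amplitude_max,
    bias_grid_size = as.integer(bias_grid_size),
    gamma_log_std = gamma_log_std,
    flip_probability = flip_probability,
    flip_swap = flip_swap,
    drop_from_target = as.integer(drop_from_target),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# sample a random affine (3x3 matrix + translation in voxels) about the grid
# center; resamples internally until the determinant is positive
sample_affine_transform <- function(cfg, spacing) {
  repeat {
    rot <- runif(3, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
    sc <- runif(3, cfg$scaling[1], cfg$scaling[2])
    sh <- runif(3, -cfg$shearing, cfg$shearing)
    tr_mm <- runif(3, -cfg$translation_mm, cfg$translation_mm)
    cx <- cos(rot[1]); sx <- sin(rot[1])
    cy <- cos(rot[2]); sy <- sin(rot[2])
    cz <- cos(rot[3]); sz <- sin(rot[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
    M <- Rz %*% Ry %*% Rx %*% Sh %*% diag(sc)
    if (det(M) > 0) return(list(M = M, t_vox = tr_mm / spacing))
  }
}

# smooth elastic displacement field (voxel units), trilinearly upsampled from
# a coarse control grid
sample_elastic_field <- function(cfg, dims, spacing) {
  std_mm <- runif(1, cfg$elastic_std_mm[1], cfg$elastic_std_mm[2])
  g <- cfg$elastic_grid
  if (std_mm <= 0) return(NULL)
  coords <- as.matrix(expand.grid(
    x = (seq_len(dims[1]) - 1) * (g - 1) / (dims[1] - 1),
    y = (seq_len(dims[2]) - 1) * (g - 1) / (dims[2] - 1),
    z = (seq_len(dims[3]) - 1) * (g - 1) / (dims[3] - 1)))
  disp <- matrix(0, prod(dims), 3)
  for (ax in 1:3) {
    ctrl <- array(rnorm(g^3, 0, std_mm / spacing[ax]), c(g, g, g))
    disp[, ax] <- cpp_sample_trilinear(as.numeric(ctrl), rep(g, 3L), coords,
                                       TRUE, 0)
  }
  disp
}

#' Randomly deform a label map
#'
#' Samples an affine (rotation, scaling, shearing, translation) and a smooth
#' elastic displacement field from the configured priors and warps the label
#' map by nearest-neighbor interpolation (affine applied first, then the
#' elastic field, both about the grid center; out-of-view voxels become
#' background). Consumes the current RNG stream; seed via
#' [generate_training_pair()] or `set.seed()`.
#'
#' @param labelmap a [labeled_volume()].
#' @param cfg a [generator_config()].
#' @return list with `labelmap` (deformed [labeled_volume()]) and `field`
#'   (sampled affine + elastic components).
#' @export
deform_labelmap <- function(labelmap, cfg = generator_config()) {
  stopifnot(inherits(labelmap, "labeled_volume"),
            inherits(cfg, "generator_config"))
  d <- dim(labelmap$data)
  spacing <- vol_spacing(labelmap)
  aff <- sample_affine_transform(cfg, spacing)
  elastic <- sample_elastic_field(cfg, d, spacing)
  out <- warp_labelmap_nn(labelmap, aff$M, aff$t_vox, elastic)
  list(labelmap = out,
       field = list(M = aff$M, t_vox = aff$t_vox, elastic = elastic))
}

# nearest-neighbor warp; inverse map: source = Minv (v - c) + c - t + elastic
warp_labelmap_nn <- function(labelmap, M, t_vox, elastic = NULL) {
  d <- dim(labelmap$data)
  ctr <- (d - 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                             y = seq_len(d[2]) - 1,
                             z = seq_len(d[3]) - 1))
  Minv <- solve(M)
  src <- sweep(g, 2, ctr) %*% t(Minv)
  src <- sweep(src, 2, ctr - t_vox, `+`)
  if (!is.null(elastic)) src <- src + elastic
  vals <- cpp_sample_nearest(as.integer(labelmap$data), as.integer(d), src, 0L)
  labeled_volume(array(vals, d), labelmap$affine, lut = labelmap$lut)
}

#' Sample per-label Gaussian intensities
#'
#' For each present nonzero label (in increasing id order), draws a mean and
#' a standard deviation from the uniform priors and fills that label's voxels
#' with independent Gaussian draws. Background stays exactly 0.
#'
#' @param labelmap a [labeled_volume()].
#' @param cfg a [generator_config()].
#' @return list with `image` ([intensity_volume()]) and `params`
#'   (`data.frame(id, mean, sd)` of the sampled distributions).
#' @export
sample_label_intensities <- function(labelmap, cfg = generator_config()) {
  stopifnot(inherits(labelmap, "labeled_volume"))
  ids <- vol_labels(labelmap)
  img <- array(0, dim(labelmap$data))
  mus <- sds <- numeric(length(ids))
  for (i in seq_along(ids)) {
    mus[i] <- runif(1, cfg$mean_range[1], cfg$mean_range[2])
    sds[i] <- runif(1, cfg$std_range[1], cfg$std_range[2])
    vox <- which(labelmap$data == ids[i])
    img[vox] <- mus[i] + if (sds[i] > 0) rnorm(length(vox), 0, sds[i]) else 0
  }
  list(image = intensity_volume(img, labelmap$affine),
       params = data.frame(id = ids, mean = mus, sd = sds))
}

#' Corrupt a synthetic image with bias field and gamma
#'
#' Multiplies by a smooth strictly positive bias field (an exponentiated
#' low-resolution Gaussian coefficient field, cubically upsampled; the
#' coefficient std is itself drawn U(0, `bias_amplitude_max`)), min-max
#' rescales to [0, 1], then applies a random gamma exponent `exp(g)` with
#' `g ~ N(0, gamma_log_std^2)`. The output always lies in [0, 1] and no
#' resolution degradation is ever applied.
#'
#' @param image an [intensity_volume()].
#' @param cfg a [generator_config()].
#' @return corrupted [intensity_volume()] in [0, 1].
#' @export
corrupt_intensities <- function(image, cfg = generator_config()) {
  stopifnot(inherits(image, "intensity_volume"))
  d <- dim(image$data)
  x <- image$data
  if (cfg$bias_amplitude_max > 0) {
    x <- x * sample_bias_field(cfg, d)
  }
  rng <- range(x)
  x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  if (cfg$gamma_log_std > 0) {
    gexp <- exp(rnorm(1, 0, cfg$gamma_log_std))
    x <- x^gexp
  }
  intensity_volume(x, image$affine)
}

# strictly positive smooth multiplicative field on the full grid
sample_bias_field <- function(cfg, dims) {
  bstd <- runif(1, 0, cfg$bias_amplitude_max)
  g <- cfg$bias_grid_size
  coeff <- array(rnorm(g^3, 0, bstd), c(g, g, g))
  coords <- as.matrix(expand.grid(
    x = (seq_len(dims[1]) - 1) * (g - 1) / (dims[1] - 1),
    y = (seq_len(dims[2]) - 1) * (g - 1) / (dims[2] - 1),
    z = (seq_len(dims[3]) - 1) * (g - 1) / (dims[3] - 1)))
  field <- cpp_sample_tricubic(as.numeric(coeff), rep(g, 3L), coords)
  array(exp(field), dims)
}

#' Generate one synthetic training pair
#'
#' Composes the full generative model: random deformation of the label map,
#' per-label Gaussian intensity synthesis on the deformed map (the
#' extra-cerebral label, if present, contributes signal), bias-field and
#' gamma corruption. The returned target is the deformed label map with the
#' `drop_from_target` ids replaced by background, so the extra-cerebral label
#' is never a training target. Image and target share the input grid exactly.
#'
#' @param labelmap a [labeled_volume()], typically already carrying the
#'   extra-cerebral label (see [add_extracerebral_label()]).
#' @param cfg a [generator_config()].
#' @param seed overrides `cfg$seed`.
#' @return a `training_pair`: list with `image`, `target`, and `meta` (the
#'   sampled intensity parameters); provenance tag `"synthetic"`.
#' @export
generate_training_pair <- function(labelmap, cfg = generator_config(),
                                   seed = cfg$seed) {
  stopifnot(inherits(labelmap, "labeled_volume"))
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)

  if (cfg$flip_probability > 0 && runif(1) < cfg$flip_probability) {
    labelmap <- flip_labelmap_lr(labelmap, cfg$flip_swap)
  }
  def <- deform_labelmap(labelmap, cfg)
  syn <- sample_label_intensities(def$labelmap, cfg)
  img <- corrupt_intensities(syn$image, cfg)

  target <- def$labelmap
  drop <- intersect(cfg$drop_from_target, vol_labels(target))
  if (length(drop) > 0L) {
    data <- target$data
    data[data %in% drop] <- 0L
    target <- labeled_volume(data, target$affine,
                             lut = target$lut[!target$lut$id %in% cfg$drop_from_target, ,
                                              drop = FALSE])
  }
  structure(list(image = img, target = target,
                 meta = list(intensities = syn$params, seed = seed)),
            class = "training_pair", provenance = "synthetic")
}

flip_labelmap_lr <- function(labelmap, swap) {
  d <- dim(labelmap$data)
  x <- labelmap$data[rev(seq_len(d[1])), , , drop = FALSE]
  if (!is.null(swap)) {
    from <- as.integer(names(swap))
    x2 <- x
    for (i in seq_along(swap)) x2[x == from[i]] <- swap[[i]]
    x <- x2
  }
  labeled_volume(x, labelmap$affine, lut = labelmap$lut)
}

#' Bundle a real validation image with its ground-truth label map
#'
#' Tags the pair with provenance `"real"`; the training loop refuses
#' synthetic validation pairs, mirroring the synthetic-train / real-validate
#' split design.
#'
#' @param image an [intensity_volume()].
#' @param target a [labeled_volume()] on the same grid.
#' @return a `validation_pair`.
#' @export
validation_pair <- function(image, target) {
  stopifnot(inherits(image, "intensity_volume"),
            inherits(target, "labeled_volume"),
            identical(dim(image$data), dim(target$data)))
  prov <- attr(image, "provenance")
  structure(list(image = image, target = target),
            class = "validation_pair",
            provenance = if (is.null(prov)) "real" else prov)
}
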