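# Phantom fixtures: nested-ellipsoid "brains" with analytic ground truth.
# They stand in for a training corpus so the whole chain (label prep ->
# synthesis -> training -> inference -> evaluation) is testable offline.
# Realism of the geometry is irrelevant: the generative model destroys
# intensity realism by construction, and structure locations are kept
# anatomically consistent across phantoms (as they are across real brains)
# so that a network can learn a spatial prior.

PHANTOM_SUBCORTICAL_IDS <- c(10L, 11L, 12L, 13L, 17L, 18L, 26L, 28L,
                             49L, 50L, 51L, 52L, 53L, 54L, 58L, 60L)

#' Phantom specification
#'
#' @param shape voxel count per axis (scalar or length-3, each >= 32).
#' @param spacing isotropic or per-axis voxel size in mm (default 0.7, the
#'   training resolution).
#' @param n_subcortical number of ellipsoidal subcortical blobs (0..16).
#' @param seed integer seed controlling the geometric jitter.
#' @param lut label lookup table; defaults to the packaged 35-label table.
#' @param snr signal-to-noise ratio used when rendering "real" validation
#'   images (per-label noise sd = mean/snr); `Inf` renders noiselessly.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = 64L, spacing = 0.7, n_subcortical = 8L,
                         seed = 1L, lut = NULL, snr = 25) {
  shape <- as.integer(rep(shape, length.out = 3))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(shape < 32L)) stop("phantom shape must be >= 32 per axis")
  stopifnot(n_subcortical >= 0L, n_subcortical <= length(PHANTOM_SUBCORTICAL_IDS),
            all(spacing > 0))
  if (is.null(lut)) lut <- fs_lut35()
  structure(list(shape = shape, spacing = spacing,
                 n_subcortical = as.integer(n_subcortical),
                 seed = as.integer(seed), lut = lut, snr = snr),
            class = "phantom_spec")
}

# voxel-count indicator of an ellipsoid; returns logical array
ellipsoid_mask <- function(shape, center, semiaxes) {
  x <- (seq_len(shape[1]) - 1 - center[1]) / semiaxes[1]
  y <- (seq_len(shape[2]) - 1 - center[2]) / semiaxes[2]
  z <- (seq_len(shape[3]) - 1 - center[3]) / semiaxes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Generate a nested-structure phantom label map
#'
#' Deterministic under `spec$seed`. Structures, outside-in: background (0),
#' an extra-cerebral-like CSF rim (id 24), a cortex-like shell (id 3), a
#' white-matter-like core (id 2), a ventricle-like central cavity (id 4) and
#' `n_subcortical` ellipsoidal blobs with distinct FreeSurfer-convention ids
#' placed on a ring inside the core. All structures are mutually exclusive.
#'
#' @param spec a [phantom_spec()].
#' @return a [labeled_volume()]; attribute `"blobs"` records each blob's
#'   center, semi-axes (voxels) and id for analytic volume checks.
#' @export
make_phantom_labelmap <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(spec$seed)

  d <- spec$shape
  ctr <- (d - 1) / 2 + runif(3, -0.015, 0.015) * d
  jitter <- function() runif(3, 0.93, 1.07)
  rim_ax   <- 0.44 * d * jitter()
  ctx_ax   <- 0.395 * d * jitter()
  wm_ax    <- 0.315 * d * jitter()
  vent_ax  <- 0.085 * d * jitter()
  if (any(vent_ax < 1.5) || any(rim_ax >= d / 2))
    stop("phantom shape too small to nest structures")

  lab <- array(0L, d)
  lab[ellipsoid_mask(d, ctr, rim_ax)] <- 24L
  lab[ellipsoid_mask(d, ctr, ctx_ax)] <- 3L
  lab[ellipsoid_mask(d, ctr, wm_ax)]  <- 2L
  lab[ellipsoid_mask(d, ctr, vent_ax)] <- 4L

  blobs <- list()
  n_sub <- spec$n_subcortical
  if (n_sub > 0L) {
    ids <- PHANTOM_SUBCORTICAL_IDS[seq_len(n_sub)]
    # fixed angular layout on a ring inside the WM core (alternating above /
    # below the equator so neighbors stay disjoint), jittered per phantom.
    # Blob sizes mimic real subcortical ROIs at 0.7 mm: ~7 mm across,
    # hundreds to ~1000 voxels each.
    angles <- 2 * pi * (seq_len(n_sub) - 1) / n_sub
    ring_r <- 0.18 * d
    for (i in seq_len(n_sub)) {
      ang <- angles[i] + runif(1, -0.05, 0.05)
      zsign <- if (i %% 2 == 0) 1 else -1
      zoff <- zsign * 0.07 * d[3] + runif(1, -0.008, 0.008) * d[3]
      cen <- ctr + c(ring_r[1] * cos(ang), ring_r[2] * sin(ang), zoff)
      ax <- (0.075 + 0.015 * (i %% 3) / 2) * d * runif(3, 0.95, 1.05)
      m <- ellipsoid_mask(d, cen, ax)
      m <- m & (lab == 2L) # blobs live strictly inside the WM core
      lab[m] <- ids[i]
      blobs[[i]] <- list(id = ids[i], center = cen, semiaxes = ax,
                         n_inside = sum(ellipsoid_mask(d, cen, ax)))
    }
  }

  affine <- diag(c(spec$spacing, 1))
  out <- labeled_volume(lab, affine, lut = spec$lut)
  attr(out, "blobs") <- blobs
  out
}

#' Named contrast profiles for phantom rendering
#'
#' Per-label mean intensities emulating fixed acquisition contrasts:
#' `"t1w"`-like (WM bright), `"t2w"`-like (fluid bright), `"pdw"`-like (flat
#' tissue contrast) and `"flairlike"` (fluid suppressed). `"random"` draws a
#' fresh profile from the seed.
#'
#' @param labelmap a [labeled_volume()] whose labels the profile must cover.
#' @param type one of `"t1w"`, `"t2w"`, `"pdw"`, `"flairlike"`, `"random"`.
#' @param seed used only for `type = "random"`.
#' @return `data.frame` with columns `id` and `mean`.
#' @export
phantom_contrast_profile <- function(labelmap, type = "t1w", seed = 1L) {
  ids <- vol_labels(labelmap)
  base <- switch(
    type,
    t1w = c(`2` = 0.90, `3` = 0.55, `4` = 0.12, `24` = 0.18),
    t2w = c(`2` = 0.30, `3` = 0.55, `4` = 0.95, `24` = 0.85),
    pdw = c(`2` = 0.65, `3` = 0.72, `4` = 0.80, `24` = 0.70),
    flairlike = c(`2` = 0.45, `3` = 0.75, `4` = 0.05, `24` = 0.10),
    random = NULL,
    stop("unknown contrast profile type: ", type)
  )
  if (identical(type, "random")) {
    old <- .Random.seed_safe()
    on.exit(.restore_seed(old))
    set.seed(seed)
    means <- runif(length(ids), 0.1, 0.95)
    return(data.frame(id = ids, mean = means))
  }
  means <- numeric(length(ids))
  others <- setdiff(ids, as.integer(names(base)))
  for (i in seq_along(ids)) {
    key <- as.character(ids[i])
    if (key %in% names(base)) {
      means[i] <- base[[key]]
    } else {
      # subcortical blobs: gray-matter-like, staggered so every label keeps a
      # distinct (decodable) mean
      gm <- base[["3"]]; wm <- base[["2"]]
      frac <- (match(ids[i], others) - 1) / max(length(others), 1)
      means[i] <- gm + (wm - gm) * (0.2 + 0.6 * frac)
    }
  }
  data.frame(id = ids, mean = means)
}

#' Render a fixed-contrast "real" validation image from a phantom
#'
#' Piecewise-constant image following `profile` means plus Gaussian noise at
#' the stated SNR (per-label sd = mean/snr). One fixed, non-randomized
#' contrast per call, emulating a real acquisition; background stays 0.
#'
#' @param labelmap a [labeled_volume()].
#' @param profile `data.frame(id, mean)` covering all present labels.
#' @param snr scalar signal-to-noise ratio; `Inf` for noiseless.
#' @param seed noise seed.
#' @return an [intensity_volume()] tagged with provenance `"real"`.
#' @export
render_validation_image <- function(labelmap, profile, snr = 25, seed = 1L) {
  stopifnot(inherits(labelmap, "labeled_volume"))
  ids <- vol_labels(labelmap)
  missing <- setdiff(ids, profile$id)
  if (length(missing) > 0L)
    stop("contrast profile missing labels: ", paste(missing, collapse = ", "))
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  img <- array(0, dim(labelmap$data))
  for (i in seq_along(ids)) {
    id <- ids[i]
    mu <- profile$mean[match(id, profile$id)]
    vox <- which(labelmap$data == id)
    noise_sd <- if (is.finite(snr)) mu / snr else 0
    img[vox] <- mu + if (noise_sd > 0) rnorm(length(vox), 0, noise_sd) else 0
  }
  out <- intensity_volume(img, labelmap$affine)
  attr(out, "provenance") <- "real"
  out
}

# RNG bookkeeping: phantom/render functions must not disturb the caller's RNG
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
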