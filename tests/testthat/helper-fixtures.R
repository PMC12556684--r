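# Shared fixtures, built in code (no binary data in the repo). The cache
# avoids regenerating the same phantom across test files.

.fix_cache <- new.env(parent = emptyenv())

fix_phantom <- function(seed = 1L, shape = 64L, spacing = 0.7,
                        n_subcortical = 8L) {
  key <- paste("ph", seed, shape[1], spacing[1], n_subcortical, sep = "_")
  if (is.null(.fix_cache[[key]]))
    .fix_cache[[key]] <- make_phantom_labelmap(
      phantom_spec(shape = shape, spacing = spacing,
                   n_subcortical = n_subcortical, seed = seed))
  .fix_cache[[key]]
}

# phantom with the extra-cerebral label attached (small dilation keeps tests
# fast; the rim only needs to exist, not to be realistic)
fix_phantom_ec <- function(seed = 1L, dilate = 2L) {
  key <- paste("phec", seed, dilate, sep = "_")
  if (is.null(.fix_cache[[key]])) {
    ph <- fix_phantom(seed)
    pol <- extracerebral_policy(dilation_voxels = dilate)
    .fix_cache[[key]] <- add_extracerebral_label(
      ph, extracerebral_mask(ph, pol), pol)
  }
  .fix_cache[[key]]
}

# tiny random labeled volume for metric tests
fix_random_labels <- function(seed, dims = c(8L, 8L, 8L), ids = 0:3,
                              affine = diag(4)) {
  set.seed(seed)
  labeled_volume(array(sample(ids, prod(dims), TRUE), dims), affine)
}

# brute-force one-hot trilinear resampling oracle (independent of the C++
# path): explicit per-label channel interpolation at given input-index coords
oracle_onehot_resample <- function(data, coords) {
  ids <- sort(union(0L, unique(as.integer(data))))
  d <- dim(data)
  interp1 <- function(ch, co) {
    f <- floor(co)
    r <- co - f
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) r[1] else 1 - r[1]) * (if (dy) r[2] else 1 - r[2]) *
        (if (dz) r[3] else 1 - r[3])
      ix <- f + c(dx, dy, dz)
      v <- if (any(ix < 0) || any(ix > d - 1)) 0 else ch[ix[1] + 1, ix[2] + 1, ix[3] + 1]
      acc <- acc + w * v
    }
    acc
  }
  # same FOV convention as the implementation: clamp to the last voxel center
  for (j in 1:3) coords[, j] <- pmin(pmax(coords[, j], 0), d[j] - 1)
  out <- integer(nrow(coords))
  for (q in seq_len(nrow(coords))) {
    wts <- vapply(ids, function(id) {
      ch <- array(0, d)
      ch[data == id] <- 1
      interp1(ch, coords[q, ])
    }, 0)
    # out-of-bounds weight flows to the background channel
    wts[1] <- wts[1] + (1 - sum(wts))
    out[q] <- ids[which.max(wts)] # first max: ties go to the lowest id
  }
  out
}

expect_same_volume <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a$data), dim(b$data))
  expect_lt(max(abs(a$affine - b$affine)), tol)
  expect_true(max(abs(as.numeric(a$data) - as.numeric(b$data))) <= tol)
}
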