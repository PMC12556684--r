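# Stub decoding a noiseless rendering back to its one-hot labels: nearest
# profile mean per voxel, sharp probabilities. Lets the plumbing be tested
# without a trained network.
decoder_stub <- function(profile, class_ids, patch = 24L) {
  means <- c(0, profile$mean[match(class_ids[-1], profile$id)])
  stub_model(function(p) {
    d <- dim(p)
    K <- length(class_ids)
    idx <- vapply(as.numeric(p), function(v) which.min(abs(means - v)), 0L)
    probs <- array(0, c(d[1:3], K))
    flat <- matrix(0, prod(d[1:3]), K)
    flat[cbind(seq_along(idx), idx)] <- 1
    array(flat, c(d[1:3], K))
  }, class_ids = class_ids, patch_size = patch)
}

test_that("sliding window: constant stub is tiling-invariant, sums to one", {
  K <- 3L
  const_stub <- stub_model(function(p) {
    d <- dim(p)[1:3]
    array(rep(c(0.5, 0.3, 0.2), each = prod(d)), c(d, K))
  }, class_ids = c(0L, 2L, 3L), patch_size = 8L)
  img <- intensity_volume(array(rnorm(20^3), c(20, 20, 20)),
                          diag(c(0.7, 0.7, 0.7, 1)))
  pm <- sliding_window_predict(const_stub, img, patch = 8L, overlap = 0.5)
  expect_equal(dim(pm$probs), c(20L, 20L, 20L, 3L))
  expect_true(max(abs(pm$probs[, , , 1] - 0.5)) < 1e-12)
  sums <- pm$probs[, , , 1] + pm$probs[, , , 2] + pm$probs[, , , 3]
  expect_equal(range(sums), c(1, 1), tolerance = 1e-9)
})

test_that("patch covering the whole volume equals a single forward pass", {
  net <- net_config(n_stages = 2L, features_per_stage = c(4L, 6L),
                    patch_size = 16L)
  params <- drseg:::unet_init(net, 4L, seed = 3)
  model <- structure(list(params = params, net = net,
                          class_ids = c(0L, 2L, 3L, 4L), n_classes = 4L,
                          normalization = "zscore-nonzero"),
                     class = "fold_model")
  set.seed(6)
  img <- intensity_volume(array(rexp(16^3), c(16, 16, 16)))
  pm <- sliding_window_predict(model, img, patch = 16L, overlap = 0.5)
  x <- drseg:::normalize_image(img$data)
  fw <- drseg:::unet_forward(params, net, x)
  direct <- array(drseg:::softmax_rows(fw$logits), c(16, 16, 16, 4))
  expect_equal(pm$probs, direct, tolerance = 1e-9)
})

test_that("weighted accumulation normalizes correctly on an overlap case", {
  # stub emitting position-dependent probabilities: overlapping windows then
  # disagree and the Gaussian-weighted average must still sum to one
  K <- 2L
  pos_stub <- stub_model(function(p) {
    d <- dim(p)[1:3]
    a <- array(seq(0.2, 0.8, length.out = prod(d)), d)
    out <- array(0, c(d, K))
    out[, , , 1] <- a
    out[, , , 2] <- 1 - a
    out
  }, class_ids = c(0L, 7L), patch_size = 8L)
  img <- intensity_volume(array(0.5, c(12, 8, 8)))
  pm <- sliding_window_predict(pos_stub, img, patch = 8L, overlap = 0.5)
  sums <- pm$probs[, , , 1] + pm$probs[, , , 2]
  expect_equal(range(sums), c(1, 1), tolerance = 1e-9)
  expect_true(all(pm$probs >= 0 & pm$probs <= 1))
})

test_that("ensemble_segment averages softmaxes and breaks ties low", {
  aff <- diag(4)
  mk <- function(p1) {
    probs <- array(0, c(2, 2, 2, 2))
    probs[, , , 1] <- p1
    probs[, , , 2] <- 1 - p1
    structure(list(probs = probs, class_ids = c(0L, 5L), affine = aff),
              class = "probability_maps")
  }
  single <- ensemble_segment(list(mk(0.6)))
  expect_true(all(single$data == 0L))
  five <- ensemble_segment(rep(list(mk(0.3)), 5))
  expect_true(all(five$data == 5L))
  # (0.6, 0.4) and (0.2, 0.8) -> mean (0.4, 0.6) -> second class
  two <- ensemble_segment(list(mk(0.6), mk(0.2)))
  expect_true(all(two$data == 5L))
  # exact tie -> lowest label id (background 0)
  tie <- ensemble_segment(list(mk(0.5)))
  expect_true(all(tie$data == 0L))
  # permutation invariance
  p_list <- list(mk(0.1), mk(0.5), mk(0.9))
  expect_identical(ensemble_segment(p_list)$data,
                   ensemble_segment(rev(p_list))$data)
  bad <- mk(0.5); bad$class_ids <- c(0L, 9L)
  expect_error(ensemble_segment(list(mk(0.5), bad)), "share")
})

test_that("largest_component_filter keeps the biggest component only", {
  lab <- array(0L, c(12, 12, 12))
  lab[2:6, 2:6, 2:6] <- 3L      # dominant component
  lab[10, 10, 10] <- 3L          # satellite (size 1)
  lab[9:10, 2:3, 2:3] <- 5L      # another label, single component
  seg <- labeled_volume(lab, diag(4))

  f <- largest_component_filter(seg, postproc_policy(3L))
  expect_equal(sum(f$data == 3L), 125L)
  expect_equal(f$data[10, 10, 10], 0L) # satellite removed to background
  expect_equal(sum(f$data == 5L), 8L)  # untouched label

  # single-component label unchanged
  f5 <- largest_component_filter(seg, postproc_policy(5L))
  expect_identical(f5$data, seg$data)

  # label excluded from the policy keeps all components
  f_none <- largest_component_filter(seg, postproc_policy(integer()))
  expect_identical(f_none$data, seg$data)

  # idempotence
  expect_identical(largest_component_filter(f, postproc_policy(3L))$data,
                   f$data)

  # component enumeration oracle: sizes 10 vs 3
  lab2 <- array(0L, c(10, 10, 10))
  lab2[1:10, 1, 1] <- 4L
  lab2[1:3, 5, 5] <- 4L
  s2 <- labeled_volume(lab2, diag(4))
  f2 <- largest_component_filter(s2, postproc_policy(4L))
  expect_equal(sum(f2$data == 4L), 10L)
  expect_true(all(f2$data[1:3, 5, 5] == 0L))
})

test_that("decide_postproc_policy includes exactly strictly-improving labels", {
  ph <- fix_phantom(12, shape = 32L)
  prof <- phantom_contrast_profile(ph, "t1w")
  img <- render_validation_image(ph, prof, snr = Inf)
  class_ids <- c(0L, vol_labels(ph))
  stub <- decoder_stub(prof, class_ids, patch = 32L)

  # inject satellite false positives for label 2 into the *prediction* by
  # corrupting the rendered image in a far corner with label-2 intensity
  img_sat <- img
  img_sat$data[1:2, 1:2, 1:2] <- prof$mean[match(2L, prof$id)]
  vp <- validation_pair(img_sat, ph)
  pol <- decide_postproc_policy(list(stub), list(vp), connectivity = 26L)
  expect_true(2L %in% pol$apply_largest_component)

  # a genuinely two-component truth must be excluded: split label 4 in the
  # ground truth and render it faithfully -> filtering can only hurt
  ph2 <- ph
  ph2$data[ph2$data == 4L & slice.index(ph2$data, 1) > 16] <- 0L
  ph2$data[1:3, 1:3, 14:18] <- 4L # detached second component
  img2 <- render_validation_image(ph2, prof, snr = Inf)
  vp2 <- validation_pair(img2, ph2)
  pol2 <- decide_postproc_policy(list(decoder_stub(prof, class_ids, 32L)),
                                 list(vp2))
  expect_false(4L %in% pol2$apply_largest_component)

  # ties (perfect prediction, single component) are excluded
  vp3 <- validation_pair(img, ph)
  pol3 <- decide_postproc_policy(list(stub), list(vp3))
  expect_false(3L %in% pol3$apply_largest_component)

  expect_error(decide_postproc_policy(list(stub), list()), "empty")
})

test_that("segment_volume with a perfect stub reproduces the phantom exactly", {
  ph <- fix_phantom(14, shape = 32L)
  prof <- phantom_contrast_profile(ph, "t1w")
  img <- render_validation_image(ph, prof, snr = Inf)
  class_ids <- c(0L, vol_labels(ph))
  stub <- decoder_stub(prof, class_ids, patch = 16L)

  # matched spacing, native orientation: the pipeline must add zero error
  seg <- segment_volume(img, list(stub), postproc_policy(),
                        train_spacing = vol_spacing(img), lut = ph$lut)
  expect_identical(seg$data, ph$data)
  expect_equal(seg$affine, img$affine)
  for (id in vol_labels(ph))
    expect_equal(dice_coefficient(ph$data == id, seg$data == id), 1.0)
})

test_that("segment_volume round-trips orientation and resolution", {
  ph <- fix_phantom(15, shape = 32L)
  prof <- phantom_contrast_profile(ph, "t2w")
  img <- render_validation_image(ph, prof, snr = Inf)
  class_ids <- c(0L, vol_labels(ph))
  stub <- decoder_stub(prof, class_ids, patch = 16L)

  # present the image in LPS orientation; output must come back in LPS with
  # the identical affine
  img_lps <- reorient(img, "LPS")
  seg <- segment_volume(img_lps, list(stub),
                        train_spacing = vol_spacing(img), lut = ph$lut)
  expect_equal(seg$affine, img_lps$affine)
  expect_identical(dim(seg$data), dim(img_lps$data))
  # content equals the phantom reoriented to LPS
  expect_identical(seg$data, reorient(ph, "LPS")$data)

  # unseen spacing: resample to the training grid and back; shape preserved
  img08 <- resample_intensity(img, 0.8)
  seg08 <- segment_volume(img08, list(stub),
                          train_spacing = vol_spacing(img), lut = ph$lut)
  expect_identical(dim(seg08$data), dim(img08$data))
  expect_equal(seg08$affine, img08$affine)
  expect_equal(vol_spacing(seg08), rep(0.8, 3), tolerance = 1e-9)
  expect_true(all(vol_labels(seg08) %in% class_ids))
})
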