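test_that("net_config validates the patch/stage contract", {
  expect_error(net_config(n_stages = 3L, features_per_stage = c(8L, 16L, 32L),
                          patch_size = 18L), "divisible")
  expect_error(net_config(n_stages = 2L, features_per_stage = 8L))
  np <- net_config_paper()
  expect_equal(np$features_per_stage, c(32L, 64L, 128L, 256L, 320L, 320L))
  expect_equal(np$patch_size, c(192L, 192L, 160L))
  expect_equal(np$batch_size, 2L)
})

test_that("poly_lr follows base_lr * (1 - epoch/epochs)^exponent", {
  paper <- train_config_paper()
  expect_equal(poly_lr(0L, paper), 3e-4)
  cfg <- train_config(epochs = 100L, base_lr = 1e-2, lr_exponent = 0.9)
  expect_equal(poly_lr(50L, cfg), 1e-2 * 0.5^0.9)
  lrs <- vapply(0:99, poly_lr, 0, cfg = cfg)
  expect_true(all(diff(lrs) < 0))
  expect_lt(poly_lr(99L, cfg), 1e-2 * (1 / 100)^0.9 + 1e-12)
  expect_error(poly_lr(100L, cfg), "range")
  expect_error(poly_lr(-1L, cfg), "range")
})

test_that("dice_ce_loss matches its closed forms", {
  # perfect one-hot prediction: both terms vanish up to smoothing
  t_ids <- array(c(0L, 1L, 2L, 1L, 0L, 2L, 2L, 1L), c(2, 2, 2))
  K <- 3L
  onehot <- array(0, c(2, 2, 2, K))
  for (k in 0:(K - 1)) onehot[, , , k + 1][t_ids == k] <- 1
  # clamp away from exact 0/1 the way a softmax output would look
  eps_p <- 1e-9
  probs <- (onehot + eps_p) / (1 + K * eps_p)
  l <- dice_ce_loss(probs, t_ids, class_ids = 0:2)
  expect_lt(l$total, 1e-4)
  expect_gte(l$dice_term, 0)
  expect_gte(l$ce_term, 0)

  # uniform prediction: cross-entropy is exactly ln K
  unif <- array(1 / K, c(2, 2, 2, K))
  lu <- dice_ce_loss(unif, t_ids, class_ids = 0:2)
  expect_equal(lu$ce_term, log(K), tolerance = 1e-12)
})

test_that("dice_ce_loss agrees with a brute-force per-voxel oracle", {
  set.seed(13)
  K <- 3L
  d <- c(4L, 4L, 4L)
  t_ids <- array(sample(0:(K - 1), prod(d), TRUE), d)
  raw <- array(runif(prod(d) * K), c(d, K))
  s <- apply(raw, 1:3, sum)
  probs <- raw / array(rep(s, K), c(d, K))

  eps <- 1e-5
  # oracle: explicit loops, independent of the vectorized implementation
  ce_acc <- 0
  inter <- pv <- tv <- numeric(K)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    tc <- t_ids[i, j, k] + 1L
    ce_acc <- ce_acc - log(probs[i, j, k, tc])
    for (c_ in 1:K) {
      p <- probs[i, j, k, c_]
      tt <- as.numeric(tc == c_)
      inter[c_] <- inter[c_] + p * tt
      pv[c_] <- pv[c_] + p
      tv[c_] <- tv[c_] + tt
    }
  }
  oracle_ce <- ce_acc / prod(d)
  oracle_dice <- 1 - mean((2 * inter + eps) / (pv + tv + eps))

  got <- dice_ce_loss(probs, t_ids, class_ids = 0:2, eps = eps)
  expect_equal(got$ce_term, oracle_ce, tolerance = 1e-6)
  expect_equal(got$dice_term, oracle_dice, tolerance = 1e-6)
  expect_equal(got$total, oracle_ce + oracle_dice, tolerance = 1e-6)
})

test_that("network gradients match finite differences", {
  set.seed(42)
  net <- net_config(n_stages = 2L, features_per_stage = c(4L, 6L),
                    patch_size = 8L, batch_size = 1L)
  K <- 3L
  params <- drseg:::unet_init(net, K, seed = 7)
  x <- array(rnorm(8^3), c(8, 8, 8))
  tcls <- as.integer(array(sample(0:(K - 1), 8^3, TRUE)))
  eps_d <- 1e-5

  loss_of <- function(p) {
    fw <- drseg:::unet_forward(p, net, x)
    pr <- drseg:::softmax_rows(fw$logits)
    drseg:::soft_dice_ce(pr, tcls, K, eps_d)$total
  }
  fw <- drseg:::unet_forward(params, net, x, keep_cache = TRUE)
  pr <- drseg:::softmax_rows(fw$logits)
  st <- drseg:::soft_dice_ce(pr, tcls, K, eps_d)
  dz <- drseg:::loss_grad_logits(pr, tcls, st, K, eps_d, length(tcls))
  grads <- drseg:::unet_backward(params, net, fw$cache, dz)

  h <- 1e-6
  probes <- list(
    c("enc", 1L, "conv1", "W", 5L),  c("enc", 2L, "conv2", "W", 11L),
    c("dec", 1L, "conv1", "W", 40L), c("dec", 1L, "conv2", "g", 2L),
    c("enc", 1L, "conv2", "be", 3L), c("final", NA, NA, "W", 2L))
  for (pb in probes) {
    get <- function(pp) {
      if (pb[1] == "final") pp$final[[pb[4]]][as.integer(pb[5])]
      else pp[[pb[1]]][[as.integer(pb[2])]][[pb[3]]][[pb[4]]][as.integer(pb[5])]
    }
    set <- function(pp, v) {
      if (pb[1] == "final") pp$final[[pb[4]]][as.integer(pb[5])] <- v
      else pp[[pb[1]]][[as.integer(pb[2])]][[pb[3]]][[pb[4]]][as.integer(pb[5])] <- v
      pp
    }
    num <- (loss_of(set(params, get(params) + h)) -
              loss_of(set(params, get(params) - h))) / (2 * h)
    expect_equal(get(grads), num, tolerance = 1e-4)
  }
})

test_that("softmax output sums to 1 and forward shape matches the patch", {
  net <- net_config(n_stages = 2L, features_per_stage = c(4L, 6L),
                    patch_size = 8L)
  params <- drseg:::unet_init(net, 5L, seed = 2)
  x <- array(rnorm(8^3), c(8, 8, 8))
  fw <- drseg:::unet_forward(params, net, x)
  expect_equal(fw$dims, c(8L, 8L, 8L))
  expect_equal(nrow(fw$logits), 512L)
  expect_equal(ncol(fw$logits), 5L)
  p <- drseg:::softmax_rows(fw$logits)
  expect_equal(rowSums(p), rep(1, 512), tolerance = 1e-6)
})

test_that("train_fold contract: determinism, history, provenance, errors", {
  lm <- fix_phantom_ec(1)
  cfg <- generator_config()
  pairs <- lapply(1:2, function(i) generate_training_pair(lm, cfg, seed = i))
  ph <- fix_phantom(30, shape = 32L)
  img <- render_validation_image(ph, phantom_contrast_profile(ph, "t1w"),
                                 snr = 25, seed = 1)
  vals <- list(validation_pair(img, ph))

  net <- net_config(n_stages = 2L, features_per_stage = c(4L, 6L),
                    patch_size = 16L)
  tc <- train_config(epochs = 2L, batches_per_epoch = 2L, seed = 5L)
  m1 <- train_fold(pairs, vals, net, tc)
  m2 <- train_fold(pairs, vals, net, tc)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 2L)
  expect_true(all(c("loss", "dice_term", "ce_term", "lr", "val_dice") %in%
                    names(m1$history)))
  # loss decomposition holds in the recorded history
  expect_equal(m1$history$loss, m1$history$dice_term + m1$history$ce_term,
               tolerance = 1e-10)
  expect_true(all(m1$history$dice_term >= 0 & m1$history$ce_term >= 0))
  expect_equal(m1$class_ids[1], 0L)

  expect_error(train_fold(list(), vals, net, tc), "empty")
  expect_error(train_fold(pairs, list(), net, tc), "empty")
  fake_val <- structure(list(image = pairs[[1]]$image,
                             target = pairs[[1]]$target),
                        class = "validation_pair", provenance = "synthetic")
  expect_error(train_fold(pairs, list(fake_val), net, tc), "synthetic")
})

test_that("make_folds partitions subjects into disjoint held-out blocks", {
  folds <- make_folds(20L, 5L, seed = 2)
  expect_equal(length(folds), 5L)
  held <- unlist(lapply(folds, `[[`, "val"))
  expect_equal(sort(held), 1:20)
  for (f in folds) {
    expect_equal(length(f$val), 4L)
    expect_equal(sort(c(f$train, f$val)), 1:20)
    expect_length(intersect(f$train, f$val), 0L)
  }
})
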