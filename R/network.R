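# Configurable 3D U-Net with Dice + cross-entropy compound loss, poly
# learning-rate schedule and AdamW, written against small Rcpp kernels
# (im2col/col2im, max pooling) with BLAS matrix products doing the heavy
# lifting. Activations are channels-last arrays [nx, ny, nz, C]; convolution
# weights are (k^3 * C_in) x C_out matrices so a convolution is one GEMM.

#' Network configuration
#'
#' The default is the desk-scale preset used throughout the test suite
#' (3 stages, 24^3 patches); [net_config_paper()] is the full-scale 6-stage
#' topology (32..320 features, 192x192x160 patches, batch 2) that the method
#' uses at production scale. The patch size must be divisible by
#' 2^(n_stages - 1).
#'
#' @param n_stages number of resolution levels.
#' @param features_per_stage integer vector, one entry per stage.
#' @param kernel odd convolution kernel size.
#' @param lrelu_slope negative slope of the leaky rectifier.
#' @param patch_size scalar or length-3 patch shape (voxels).
#' @param batch_size minibatch size.
#' @param n_classes number of output classes incl. background; `NULL` lets
#'   [train_fold()] derive it from the training targets.
#' @return a `net_config` list.
#' @export
net_config <- function(n_stages = 3L, features_per_stage = c(8L, 16L, 32L),
                       kernel = 3L, lrelu_slope = 0.01,
                       patch_size = 24L, batch_size = 2L, n_classes = NULL) {
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  stopifnot(length(features_per_stage) == n_stages,
            kernel %% 2L == 1L, n_stages >= 1L, batch_size >= 1L)
  if (any(patch_size %% 2L^(n_stages - 1L) != 0L))
    stop("patch_size must be divisible by 2^(n_stages-1)")
  structure(list(n_stages = as.integer(n_stages),
                 features_per_stage = as.integer(features_per_stage),
                 kernel = as.integer(kernel), lrelu_slope = lrelu_slope,
                 patch_size = patch_size, batch_size = as.integer(batch_size),
                 n_classes = n_classes),
            class = "net_config")
}

#' @rdname net_config
#' @export
net_config_paper <- function(n_classes = NULL) {
  net_config(n_stages = 6L,
             features_per_stage = c(32L, 64L, 128L, 256L, 320L, 320L),
             patch_size = c(192L, 192L, 160L), batch_size = 2L,
             n_classes = n_classes)
}

#' Training configuration
#'
#' Defaults are the desk-scale preset (20 epochs of 20 minibatches, base LR
#' 1e-3); [train_config_paper()] carries the production values: 500 epochs of
#' 250 random minibatches per fold, AdamW at base LR 3e-4 with poly decay,
#' 5 folds each holding out 20% of subjects.
#'
#' @param epochs training epochs (an epoch is `batches_per_epoch` random
#'   minibatches, not a data pass).
#' @param batches_per_epoch minibatches per epoch.
#' @param base_lr initial learning rate.
#' @param lr_exponent poly-scheduler exponent (0.9 by convention).
#' @param weight_decay decoupled weight decay of AdamW.
#' @param clip_norm global gradient-norm clip.
#' @param n_folds folds for cross-validation ensembling.
#' @param val_fraction held-out subject fraction per fold.
#' @param val_interval validate every this many epochs.
#' @param fg_oversample probability that a sampled patch is centered on a
#'   foreground voxel.
#' @param seed RNG seed for fold assignment, init and patch sampling.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 20L, batches_per_epoch = 20L,
                         base_lr = 1e-3, lr_exponent = 0.9,
                         weight_decay = 3e-5, clip_norm = 12,
                         n_folds = 5L, val_fraction = 0.2,
                         val_interval = 1L, fg_oversample = 1 / 3,
                         seed = 1L) {
  stopifnot(epochs >= 1L, batches_per_epoch >= 1L, base_lr > 0,
            n_folds >= 1L, val_fraction > 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 base_lr = base_lr, lr_exponent = lr_exponent,
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 n_folds = as.integer(n_folds), val_fraction = val_fraction,
                 val_interval = as.integer(val_interval),
                 fg_oversample = fg_oversample, seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @export
train_config_paper <- function(...) {
  train_config(epochs = 500L, batches_per_epoch = 250L, base_lr = 3e-4, ...)
}

#' Poly learning-rate schedule
#'
#' `base_lr * (1 - epoch/epochs)^lr_exponent` for 0-based `epoch`; strictly
#' decreasing, reaching `base_lr * (1/epochs)^lr_exponent` at the last epoch.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param cfg a [train_config()].
#' @return learning rate scalar.
#' @export
poly_lr <- function(epoch, cfg) {
  if (epoch < 0 || epoch >= cfg$epochs) stop("epoch out of range [0, epochs)")
  cfg$base_lr * (1 - epoch / cfg$epochs)^cfg$lr_exponent
}

# ---------------------------------------------------------------------------
# layers

# conv forward; when keep = TRUE the col matrix is cached for the backward
# pass (trades ~150 MB per desk-scale sample for skipping a second im2col)
conv_fwd <- function(x, W, b, k, keep = FALSE) {
  d <- dim(x)
  col <- cpp_im2col(as.numeric(x), as.integer(d), k)
  y <- col %*% W
  y <- y + matrix(b, nrow(y), ncol(W), byrow = TRUE)
  dim(y) <- c(d[1:3], ncol(W))
  if (keep) list(y = y, col = col, d_in = d) else y
}

conv_bwd <- function(dy, fwd, W, k) {
  dmat <- matrix(dy, nrow = prod(dim(dy)[1:3]))
  dW <- crossprod(fwd$col, dmat)
  db <- colSums(dmat)
  dx <- cpp_col2im(tcrossprod(dmat, W), as.integer(fwd$d_in), k)
  list(dx = dx, dW = dW, db = db)
}

lrelu_fwd <- function(x, slope) cpp_lrelu_fwd(x, slope)
lrelu_bwd <- function(dy, y, slope) cpp_lrelu_bwd(dy, y, slope)

# instance normalization (per-sample, per-channel over spatial dims) with a
# learned scale/shift, the convention of the framework family this follows
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  V <- prod(d[1:3])
  m <- matrix(x, V)
  mu <- colMeans(m)
  xc <- m - matrix(mu, V, d[4], byrow = TRUE)
  sig <- sqrt(colMeans(xc^2) + eps)
  xhat <- xc / matrix(sig, V, d[4], byrow = TRUE)
  y <- xhat * matrix(gamma, V, d[4], byrow = TRUE) +
    matrix(beta, V, d[4], byrow = TRUE)
  dim(y) <- d
  list(y = y, xhat = xhat, sig = sig)
}

inorm_bwd <- function(dy, cache, gamma) {
  d <- dim(dy)
  V <- prod(d[1:3])
  dm <- matrix(dy, V)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  g <- dm * matrix(gamma, V, d[4], byrow = TRUE)
  gm <- colMeans(g)
  gx <- colMeans(g * xhat)
  dx <- (g - matrix(gm, V, d[4], byrow = TRUE) -
           xhat * matrix(gx, V, d[4], byrow = TRUE)) /
    matrix(cache$sig, V, d[4], byrow = TRUE)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# conv -> instance norm -> leaky ReLU
block_fwd <- function(x, pp, k, sl, keep = FALSE) {
  cf <- conv_fwd(x, pp$W, pp$b, k, keep = keep)
  nf <- inorm_fwd(if (keep) cf$y else cf, pp$g, pp$be)
  a <- lrelu_fwd(nf$y, sl)
  if (keep)
    list(a = a, conv = cf[c("col", "d_in")], norm = nf[c("xhat", "sig")])
  else list(a = a)
}

block_bwd <- function(da, cache, pp, k, sl) {
  dn <- lrelu_bwd(da, cache$a, sl)
  ni <- inorm_bwd(dn, cache$norm, pp$g)
  cb <- conv_bwd(ni$dx, cache$conv, pp$W, k)
  list(dx = cb$dx,
       grad = list(W = cb$dW, b = cb$db, g = ni$dgamma, be = ni$dbeta))
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  m <- d[1:3] / 2
  out <- array(0, c(m, d[4]))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    out <- out + dy[seq(1 + a, d[1], 2), seq(1 + b, d[2], 2),
                    seq(1 + cc, d[3], 2), , drop = FALSE]
  }
  out
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

unet_init <- function(net, n_classes, seed = 1L) {
  set.seed(seed)
  k3 <- net$kernel^3
  f <- net$features_per_stage
  S <- net$n_stages
  block <- function(cin, cout) {
    list(W = he_init(k3 * cin, cout), b = numeric(cout),
         g = rep(1, cout), be = numeric(cout))
  }
  enc <- vector("list", S)
  cin <- 1L
  for (s in seq_len(S)) {
    enc[[s]] <- list(conv1 = block(cin, f[s]), conv2 = block(f[s], f[s]))
    cin <- f[s]
  }
  dec <- list()
  if (S > 1L) {
    dec <- vector("list", S - 1L)
    for (s in seq(S - 1L, 1L)) {
      # input: upsampled deeper features + skip connection
      dec[[s]] <- list(conv1 = block(f[s + 1L] + f[s], f[s]),
                       conv2 = block(f[s], f[s]))
    }
  }
  final <- list(W = he_init(f[1], n_classes), b = numeric(n_classes))
  list(enc = enc, dec = dec, final = final)
}

# forward pass for one sample; x is [nx, ny, nz] or [nx, ny, nz, 1]
unet_forward <- function(params, net, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  k <- net$kernel
  sl <- net$lrelu_slope
  S <- net$n_stages
  cache <- list(enc = vector("list", S), dec = vector("list", max(S - 1L, 0L)))
  skips <- vector("list", S)
  h <- x
  for (s in seq_len(S)) {
    b1 <- block_fwd(h, params$enc[[s]]$conv1, k, sl, keep_cache)
    b2 <- block_fwd(b1$a, params$enc[[s]]$conv2, k, sl, keep_cache)
    if (keep_cache) cache$enc[[s]] <- list(f1 = b1, f2 = b2)
    skips[[s]] <- b2$a
    if (s < S) {
      mp <- cpp_maxpool_fwd(as.numeric(b2$a), as.integer(dim(b2$a)))
      h <- mp$y
      if (keep_cache) {
        cache$enc[[s]]$argmax <- mp$argmax
        cache$enc[[s]]$pool_in_dim <- dim(b2$a)
      }
    } else {
      h <- b2$a
    }
  }
  if (S > 1L) {
    for (s in seq(S - 1L, 1L)) {
      up <- upsample2_fwd(h)
      xin <- array(c(skips[[s]], up),
                   c(dim(up)[1:3], dim(skips[[s]])[4] + dim(up)[4]))
      b1 <- block_fwd(xin, params$dec[[s]]$conv1, k, sl, keep_cache)
      b2 <- block_fwd(b1$a, params$dec[[s]]$conv2, k, sl, keep_cache)
      if (keep_cache)
        cache$dec[[s]] <- list(f1 = b1, f2 = b2,
                               n_skip = dim(skips[[s]])[4])
      h <- b2$a
    }
  }
  V <- prod(dim(h)[1:3])
  hmat <- matrix(h, nrow = V)
  logits <- sweep(hmat %*% params$final$W, 2, params$final$b, `+`)
  if (keep_cache) cache$final_in <- h
  list(logits = logits, dims = dim(h)[1:3], cache = if (keep_cache) cache)
}

# backward from dlogits (V x K); returns gradients with params' structure
unet_backward <- function(params, net, cache, dlogits) {
  k <- net$kernel
  sl <- net$lrelu_slope
  S <- net$n_stages
  grads <- list(enc = vector("list", S), dec = vector("list", max(S - 1L, 0L)))

  h <- cache$final_in
  V <- prod(dim(h)[1:3])
  hmat <- matrix(h, nrow = V)
  grads$final <- list(W = crossprod(hmat, dlogits), b = colSums(dlogits))
  dh <- dlogits %*% t(params$final$W)
  dim(dh) <- dim(h)

  dskips <- vector("list", S)
  if (S > 1L) {
    for (s in seq_len(S - 1L)) {
      cc <- cache$dec[[s]]
      g2 <- block_bwd(dh, cc$f2, params$dec[[s]]$conv2, k, sl)
      g1 <- block_bwd(g2$dx, cc$f1, params$dec[[s]]$conv1, k, sl)
      grads$dec[[s]] <- list(conv1 = g1$grad, conv2 = g2$grad)
      nsk <- cc$n_skip
      dxin <- g1$dx
      dskips[[s]] <- dxin[, , , seq_len(nsk), drop = FALSE]
      dup <- dxin[, , , nsk + seq_len(dim(dxin)[4] - nsk), drop = FALSE]
      dh <- upsample2_bwd(dup)
    }
  }
  # dh now reaches the bottleneck output (stage S)
  for (s in seq(S, 1L)) {
    cc <- cache$enc[[s]]
    dout <- if (s == S) dh else {
      dd <- cpp_maxpool_bwd(as.numeric(dh), cc$argmax,
                            as.integer(cc$pool_in_dim))
      dd + dskips[[s]]
    }
    g2 <- block_bwd(dout, cc$f2, params$enc[[s]]$conv2, k, sl)
    g1 <- block_bwd(g2$dx, cc$f1, params$enc[[s]]$conv1, k, sl)
    grads$enc[[s]] <- list(conv1 = g1$grad, conv2 = g2$grad)
    dh <- g1$dx
  }
  grads
}

softmax_rows <- function(z) {
  m <- z[, 1]
  for (k in seq_len(ncol(z))[-1]) m <- pmax(m, z[, k])
  e <- exp(z - m)
  e / rowSums(e)
}

#' Compound soft-Dice + cross-entropy loss
#'
#' Soft Dice is batch-summed per class with smoothing `eps` in numerator and
#' denominator, background class included; the Dice term is
#' `1 - mean_c dice_c`. Cross-entropy is the voxel mean of `-log p(target)`.
#' Both terms are non-negative and vanish (up to `eps`) for a perfect one-hot
#' prediction.
#'
#' @param pred_probs per-class probability array `[nx, ny, nz, K]` (must sum
#'   to 1 per voxel) or a `V x K` matrix.
#' @param target a [labeled_volume()] or an integer array of label ids.
#' @param class_ids label id of each probability channel (default: background
#'   0 followed by the sorted nonzero target labels).
#' @param eps Dice smoothing (1e-5).
#' @return list with `total`, `dice_term` and `ce_term`.
#' @export
dice_ce_loss <- function(pred_probs, target, class_ids = NULL, eps = 1e-5) {
  tdata <- if (inherits(target, "labeled_volume")) target$data else target
  if (is.array(pred_probs) && length(dim(pred_probs)) == 4L) {
    if (!identical(dim(pred_probs)[1:3], dim(tdata)))
      stop("prediction and target grids do not match")
    K <- dim(pred_probs)[4]
    p <- matrix(pred_probs, ncol = K)
  } else {
    p <- as.matrix(pred_probs)
    K <- ncol(p)
    if (nrow(p) != length(tdata)) stop("prediction and target sizes differ")
  }
  if (is.null(class_ids)) class_ids <- c(0L, sort(setdiff(unique(as.integer(tdata)), 0L)))
  if (length(class_ids) != K) stop("class_ids length must match channels")
  tclass <- match(as.integer(tdata), class_ids) - 1L
  if (anyNA(tclass)) stop("target contains labels outside class_ids")
  soft_dice_ce(p, tclass, K, eps)[c("total", "dice_term", "ce_term")]
}

# core loss on a V x K probability matrix and 0-based class indices
soft_dice_ce <- function(p, tclass, K, eps = 1e-5) {
  V <- nrow(p)
  t1 <- tclass + 1L
  pt <- p[cbind(seq_len(V), t1)]
  ce <- -mean(log(pmax(pt, 1e-12)))
  S_t <- tabulate(t1, nbins = K)
  S_p <- colSums(p)
  S_pt <- numeric(K)
  agg <- rowsum(pt, t1)
  S_pt[as.integer(rownames(agg))] <- agg[, 1]
  den <- S_p + S_t + eps
  dice_c <- (2 * S_pt + eps) / den
  list(total = (1 - mean(dice_c)) + ce,
       dice_term = 1 - mean(dice_c), ce_term = ce,
       S_p = S_p, S_t = S_t, S_pt = S_pt, den = den, dice_c = dice_c)
}

# gradient of the compound loss wrt logits, given softmax probs (V x K)
loss_grad_logits <- function(p, tclass, stats, K, eps, n_total) {
  V <- nrow(p)
  t1 <- tclass + 1L
  onehot_rows <- cbind(seq_len(V), t1)
  # cross-entropy: (p - onehot)/n_total
  dz <- p / n_total
  dz[onehot_rows] <- dz[onehot_rows] - 1 / n_total
  # dice: dL/dp_c = -(1/K) * (2*t_c*den_c - (2*S_pt_c+eps)) / den_c^2
  gA <- -(1 / K) * 2 / stats$den                      # coefficient of t_c
  gB <- (1 / K) * (2 * stats$S_pt + eps) / stats$den^2 # constant per class
  g <- matrix(gB, V, K, byrow = TRUE)
  g[onehot_rows] <- g[onehot_rows] + gA[t1]
  # chain through softmax: dz_k = p_k * (g_k - sum_c g_c p_c)
  srow <- rowSums(g * p)
  dz + p * (g - srow)
}

# ---------------------------------------------------------------------------
# optimizer

grad_leaves <- function(g) {
  if (is.list(g)) unlist(lapply(g, grad_leaves), recursive = FALSE, use.names = FALSE)
  else list(g)
}

walk2 <- function(a, b, f) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- walk2(a[[i]], b[[i]], f)
    a
  } else f(a, b)
}

adamw_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay, clip_norm,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grad_leaves(grads), function(x) sum(x^2), 0)))
  if (is.finite(clip_norm) && gn > clip_norm) {
    scl <- clip_norm / gn
    grads <- walk2(grads, grads, function(g, ...) g * scl)
  }
  state$t <- state$t + 1L
  state$m <- walk2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- walk2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- walk2(state$m, state$v,
               function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- walk2(params, upd,
                  function(p, u) p - lr * u - lr * weight_decay * p)
  list(params = params, state = state, grad_norm = gn)
}

# ---------------------------------------------------------------------------
# training

normalize_image <- function(data) {
  fg <- data != 0
  if (!any(fg)) return(data)
  mu <- mean(data[fg])
  sd_ <- stats::sd(data[fg])
  if (!is.finite(sd_) || sd_ < 1e-8) sd_ <- 1
  (data - mu) / sd_
}

pad_to_patch <- function(arr, patch, fill = 0) {
  d <- dim(arr)[1:3]
  if (all(d >= patch)) return(arr)
  nd <- pmax(d, patch)
  out <- array(fill, nd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

# class-balanced oversampling: with probability fg_prob, pick a random
# present foreground class and center the patch on one of its voxels, so
# small structures are seen as often as large ones
sample_patch_corner <- function(tdata, patch, fg_prob, cls_idx = NULL) {
  d <- dim(tdata)
  hi <- d - patch
  if (runif(1) < fg_prob) {
    if (is.null(cls_idx)) {
      fg <- which(tdata != 0L)
      cls_idx <- split(fg, tdata[fg])
    }
    if (length(cls_idx) > 0L) {
      vox <- cls_idx[[sample.int(length(cls_idx), 1L)]]
      v <- vox[sample.int(length(vox), 1L)]
      idx <- arrayInd(v, d)
      corner <- pmin(pmax(idx - patch %/% 2, 1L), hi + 1L)
      return(as.integer(corner))
    }
  }
  as.integer(1L + floor(runif(3) * (hi + 1 - 1e-9)))
}

crop_patch <- function(arr, corner, patch) {
  arr[corner[1]:(corner[1] + patch[1] - 1L),
      corner[2]:(corner[2] + patch[2] - 1L),
      corner[3]:(corner[3] + patch[3] - 1L), drop = FALSE]
}

#' Split subjects into cross-validation folds
#'
#' Subject-level shuffling under a fixed seed; fold `k` holds out the `k`-th
#' contiguous block (~`1/n_folds` of subjects) as validation.
#'
#' @param n_subjects subject count.
#' @param n_folds number of folds.
#' @param seed shuffle seed.
#' @return list of `list(train, val)` index vectors.
#' @export
make_folds <- function(n_subjects, n_folds = 5L, seed = 1L) {
  stopifnot(n_subjects >= n_folds, n_folds >= 1L)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed)
  idx <- sample.int(n_subjects)
  bounds <- floor(seq(0, n_subjects, length.out = n_folds + 1))
  lapply(seq_len(n_folds), function(k) {
    val <- idx[(bounds[k] + 1):bounds[k + 1]]
    list(train = setdiff(idx, val), val = val)
  })
}

#' Train one fold of the segmentation U-Net
#'
#' Runs `epochs x batches_per_epoch` random-patch minibatches of AdamW with
#' the poly LR schedule on synthetic training pairs, validating on real
#' (never synthetic) image/label pairs with the mean foreground Dice.
#' Deterministic under `cfg$seed`.
#'
#' @param train_pairs list of training pairs from [generate_training_pair()].
#' @param val_pairs list of [validation_pair()]s; pairs tagged with synthetic
#'   provenance are rejected.
#' @param net a [net_config()].
#' @param cfg a [train_config()].
#' @param fold_index stored on the returned model.
#' @param verbose print per-epoch progress.
#' @return a `fold_model`: parameters, `class_ids` (label id per output
#'   channel, background first), per-epoch `history` (loss terms, lr,
#'   validation Dice) and the configs.
#' @export
train_fold <- function(train_pairs, val_pairs, net = net_config(),
                       cfg = train_config(), fold_index = 1L,
                       verbose = FALSE) {
  if (length(train_pairs) == 0L) stop("empty training split")
  if (length(val_pairs) == 0L) stop("empty validation split")
  for (vp in val_pairs) {
    if (identical(attr(vp, "provenance"), "synthetic"))
      stop("validation pairs must be real images, not synthetic ones")
  }

  class_ids <- sort(unique(c(0L, unlist(lapply(train_pairs, function(p)
    vol_labels(p$target))))))
  n_classes <- if (is.null(net$n_classes)) length(class_ids) else net$n_classes
  if (n_classes < length(class_ids)) stop("n_classes smaller than label set")
  patch <- net$patch_size

  prep <- function(image, target) {
    x <- pad_to_patch(normalize_image(image$data), patch)
    td <- target$data
    tc <- match(as.integer(td), class_ids) - 1L
    if (anyNA(tc)) stop("target labels outside the training class set")
    dim(tc) <- dim(td)
    tpad <- pad_to_patch(tc, patch, fill = 0L)
    fg <- which(tpad != 0L)
    list(x = x, t = tpad, cls_idx = split(fg, tpad[fg]))
  }
  tr <- lapply(train_pairs, function(p) prep(p$image, p$target))
  va <- lapply(val_pairs, function(p) prep(p$image, p$target))

  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  params <- unet_init(net, n_classes, seed = cfg$seed)
  opt <- adamw_init(params)
  eps <- 1e-5
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dice_term = numeric(), ce_term = numeric(),
                        lr = numeric(), val_dice = numeric())

  for (epoch in seq_len(cfg$epochs)) {
    lr <- poly_lr(epoch - 1L, cfg)
    ep_loss <- ep_dice <- ep_ce <- 0
    for (b in seq_len(cfg$batches_per_epoch)) {
      xs <- vector("list", net$batch_size)
      ts <- vector("list", net$batch_size)
      for (i in seq_len(net$batch_size)) {
        j <- sample.int(length(tr), 1L)
        corner <- sample_patch_corner(tr[[j]]$t, patch, cfg$fg_oversample,
                                      tr[[j]]$cls_idx)
        xs[[i]] <- crop_patch(tr[[j]]$x, corner, patch)
        ts[[i]] <- crop_patch(tr[[j]]$t, corner, patch)
      }
      fw <- lapply(xs, function(x) unet_forward(params, net, x, keep_cache = TRUE))
      V <- prod(patch)
      pmat <- do.call(rbind, lapply(fw, function(f) softmax_rows(f$logits)))
      tcls <- unlist(ts, use.names = FALSE)
      st <- soft_dice_ce(pmat, tcls, n_classes, eps)
      n_total <- V * net$batch_size
      grads <- NULL
      for (i in seq_len(net$batch_size)) {
        rows <- (i - 1L) * V + seq_len(V)
        dz <- loss_grad_logits(pmat[rows, , drop = FALSE], tcls[rows],
                               st, n_classes, eps, n_total)
        g <- unet_backward(params, net, fw[[i]]$cache, dz)
        grads <- if (is.null(grads)) g else walk2(grads, g, `+`)
      }
      step <- adamw_step(params, grads, opt, lr, cfg$weight_decay, cfg$clip_norm)
      params <- step$params
      opt <- step$state
      ep_loss <- ep_loss + st$total
      ep_dice <- ep_dice + st$dice_term
      ep_ce <- ep_ce + st$ce_term
    }
    nb <- cfg$batches_per_epoch
    val_dice <- NA_real_
    if (epoch %% cfg$val_interval == 0L || epoch == cfg$epochs) {
      val_dice <- mean(vapply(va, function(v)
        tiled_val_dice(params, net, v$x, v$t, n_classes), 0))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / nb, dice_term = ep_dice / nb,
      ce_term = ep_ce / nb, lr = lr, val_dice = val_dice))
    if (verbose)
      message(sprintf("fold %d epoch %3d  loss %.4f  val dice %s",
                      fold_index, epoch, ep_loss / nb,
                      ifelse(is.na(val_dice), "-", sprintf("%.3f", val_dice))))
  }

  structure(list(params = params, net = net, class_ids = class_ids,
                 n_classes = n_classes, history = history,
                 fold_index = as.integer(fold_index),
                 normalization = "zscore-nonzero"),
            class = "fold_model")
}

# cheap validation: non-overlapping tiling, argmax, mean Dice over the
# foreground labels present in the ground truth
tiled_val_dice <- function(params, net, x, tcls, n_classes) {
  patch <- net$patch_size
  d <- dim(x)
  pred <- array(0L, d)
  starts <- function(n, p) unique(pmin(seq(1L, n, by = p), n - p + 1L))
  for (i in starts(d[1], patch[1]))
    for (j in starts(d[2], patch[2]))
      for (k in starts(d[3], patch[3])) {
        corner <- c(i, j, k)
        xp <- crop_patch(x, corner, patch)
        fwp <- unet_forward(params, net, xp)
        cls <- max.col(fwp$logits, ties.method = "first") - 1L
        pred[corner[1]:(corner[1] + patch[1] - 1L),
             corner[2]:(corner[2] + patch[2] - 1L),
             corner[3]:(corner[3] + patch[3] - 1L)] <- cls
      }
  mean_foreground_dice(pred, tcls)
}

# mean per-class Dice over nonzero classes present in the ground truth
mean_foreground_dice <- function(pred, gt) {
  ids <- setdiff(unique(as.integer(gt)), 0L)
  if (length(ids) == 0L) return(NA_real_)
  mean(vapply(ids, function(id) {
    g <- gt == id
    p <- pred == id
    s <- sum(g) + sum(p)
    if (s == 0) return(NA_real_)
    2 * sum(g & p) / s
  }, 0), na.rm = TRUE)
}

#' @export
print.fold_model <- function(x, ...) {
  cat(sprintf("<fold_model> fold %d, %d classes, %d epochs trained\n",
              x$fold_index, x$n_classes, nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss %.4f, val dice %.3f\n", last$loss,
                last$val_dice))
  }
  invisible(x)
}
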