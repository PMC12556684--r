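mask_of <- function(idx, dims = c(6L, 6L, 6L)) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  m
}

test_that("dice_coefficient: closed-form cases", {
  a <- mask_of(1:8)
  expect_equal(dice_coefficient(a, a), 1.0)
  b <- mask_of(9:16)
  expect_equal(dice_coefficient(a, b), 0.0)
  g <- mask_of(1:8)
  p <- mask_of(5:12) # |G|=8, |P|=8, overlap 4
  expect_equal(dice_coefficient(g, p), 0.5)
  expect_true(is.na(dice_coefficient(mask_of(integer()), mask_of(integer()))))
  expect_equal(dice_coefficient(a, mask_of(integer())), 0)
  expect_error(dice_coefficient(a, array(TRUE, c(2, 2, 2))), "match")
  # symmetry
  expect_equal(dice_coefficient(g, p), dice_coefficient(p, g))
})

test_that("average_surface_distance: hand-computed cases", {
  # identical segments
  a <- array(FALSE, c(5, 5, 5)); a[2:3, 2:3, 2:3] <- TRUE
  expect_equal(average_surface_distance(a, a, 1), 0)

  # two single voxels one step apart at 1 mm
  g <- array(FALSE, c(5, 5, 5)); g[2, 2, 2] <- TRUE
  p <- array(FALSE, c(5, 5, 5)); p[3, 2, 2] <- TRUE
  expect_equal(average_surface_distance(g, p, 1), 1.0)

  # parallel 1-voxel plates k voxels apart scale with spacing
  k <- 3L
  g2 <- array(FALSE, c(8, 6, 6)); g2[2, , ] <- TRUE
  p2 <- array(FALSE, c(8, 6, 6)); p2[2 + k, , ] <- TRUE
  expect_equal(average_surface_distance(g2, p2, 1), k)
  expect_equal(average_surface_distance(g2, p2, 0.7), k * 0.7)

  # missing segment
  expect_true(is.na(average_surface_distance(g, array(FALSE, c(5, 5, 5)), 1)))
  # symmetry
  set.seed(3)
  r1 <- array(runif(216) > 0.7, c(6, 6, 6))
  r2 <- array(runif(216) > 0.7, c(6, 6, 6))
  expect_equal(average_surface_distance(r1, r2, 0.9),
               average_surface_distance(r2, r1, 0.9))
})

test_that("ASD agrees with a brute-force all-pairs oracle on random masks", {
  oracle_asd <- function(G, P, spacing) {
    surf <- function(m) {
      d <- dim(m)
      pts <- list()
      for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
        if (!m[i, j, k]) next
        nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                    c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
        on_surf <- FALSE
        for (q in 1:6) {
          v <- nb[q, ]
          if (any(v < 1) || any(v > d)) on_surf <- TRUE
          else if (!m[v[1], v[2], v[3]]) on_surf <- TRUE
        }
        if (on_surf) pts[[length(pts) + 1]] <- c(i, j, k)
      }
      sweep(do.call(rbind, pts) - 1, 2, spacing, `*`)
    }
    sg <- surf(G); sp <- surf(P)
    dmin <- function(A, B) {
      vapply(seq_len(nrow(A)), function(i)
        sqrt(min(colSums((t(B) - A[i, ])^2))), 0)
    }
    (sum(dmin(sg, sp)) + sum(dmin(sp, sg))) / (nrow(sg) + nrow(sp))
  }
  set.seed(8)
  for (rep in 1:5) {
    G <- array(runif(125) > 0.6, c(5, 5, 5))
    P <- array(runif(125) > 0.6, c(5, 5, 5))
    if (sum(G) == 0 || sum(P) == 0) next
    sp3 <- c(0.7, 0.8, 1.0)
    expect_equal(average_surface_distance(G, P, sp3), oracle_asd(G, P, sp3),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_labelmaps: perfect prediction and missing-label rules", {
  ph <- fix_phantom(5, shape = 32L)
  perfect <- evaluate_labelmaps(ph, ph, exclusion_policy())
  expect_true(all(perfect$per_label$dsc == 1))
  expect_true(all(perfect$per_label$asd_mm == 0))
  expect_equal(perfect$summary$median_dsc, 1)

  # drop one label from the prediction: DSC 0, ASD NaN, flagged missing
  pred <- ph
  pred$data[pred$data == 10L] <- 2L
  rep2 <- evaluate_labelmaps(ph, pred, exclusion_policy())
  row10 <- rep2$per_label[rep2$per_label$label == 10L, ]
  expect_equal(row10$dsc, 0)
  expect_true(is.nan(row10$asd_mm))
  expect_true(row10$missing)
})

test_that("grid mismatch is rejected", {
  a <- fix_phantom(5, shape = 32L)
  b <- labeled_volume(array(0:1, c(4, 4, 4)), diag(4))
  expect_error(evaluate_labelmaps(a, b), "match")
})

test_that("the default exclusion policy summarizes exactly 27 of 35 labels", {
  lut <- fs_lut35()
  # fixture map holding all 35 lut labels
  data <- array(0L, c(7, 7, 7))
  data[seq_len(35)] <- lut$id
  gt <- labeled_volume(data, diag(4), lut)
  rep <- evaluate_labelmaps(gt, gt, default_exclusion_policy())
  expect_equal(nrow(rep$per_label), 35L)
  expect_equal(sum(rep$per_label$excluded), 8L)
  expect_equal(rep$summary$n_labels, 27L)
})

test_that("label volumes use the voxel volume from the affine", {
  data <- array(0L, c(10, 10, 10))
  data[1:100] <- 7L
  seg <- labeled_volume(data, diag(c(0.7, 0.7, 0.7, 1)))
  lv <- label_volumes(seg, ids = 7L)
  expect_equal(lv$volume_mm3, 100 * 0.7^3) # 34.3
  aniso <- labeled_volume(array(c(rep(1L, 10), rep(0L, 54)), c(4, 4, 4)),
                          diag(c(0.5, 0.5, 1.0, 1)))
  expect_equal(label_volumes(aniso, ids = 1L)$volume_mm3, 2.5)
  expect_equal(label_volumes(seg, ids = 99L)$volume_mm3, 0)
})

test_that("volumes are conserved across labels plus background", {
  ph <- fix_phantom(2, shape = 32L)
  lv <- label_volumes(ph, ids = vol_labels(ph))
  voxvol <- abs(det(ph$affine[1:3, 1:3]))
  bg <- sum(ph$data == 0L) * voxvol
  expect_equal(sum(lv$volume_mm3) + bg, prod(dim(ph$data)) * voxvol,
               tolerance = 1e-9)
})

test_that("group_volume_test: degenerate, Bonferroni and exact separated case", {
  rec <- function(subj, grp, v, tiv = 1500) {
    volumetry_record(subj, grp, c(`12` = v), tiv)
  }
  a <- lapply(1:5, function(i) rec(i, "A", 10 + i))
  b <- lapply(1:5, function(i) rec(i + 5, "B", 10 + i))
  same <- group_volume_test(a, b, 12L, 1L)
  expect_gt(same$p, 0.9)
  expect_false(same$significant)

  const <- lapply(1:4, function(i) rec(i, "A", 10))
  deg <- group_volume_test(const, const, 12L, 1L)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  expect_equal(group_volume_test(a, b, 12L, 9L)$threshold, 0.05 / 9)
  expect_equal(round(0.05 / 9, 4), 0.0056)

  # completely separated samples of 5: exact two-sided p = 2/252, U = 0 or 25
  lo <- lapply(1:5, function(i) rec(i, "A", 10 + i))
  hi <- lapply(1:5, function(i) rec(i + 5, "B", 100 + i))
  sep <- group_volume_test(lo, hi, 12L, 1L)
  expect_equal(sep$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(sep$U %in% c(0, 25))
})

test_that("rank-sum p-values match exhaustive permutation enumeration", {
  # independent oracle: enumerate all group-A assignments, two-sided p from
  # the permutation distribution of the U statistic
  perm_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combs <- utils::combn(length(pooled), n)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
    mu <- length(y) * n / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  }
  set.seed(17)
  for (rep in 1:10) {
    na <- sample(3:6, 1)
    nb <- sample(3:6, 1)
    x <- round(rnorm(na, 10, 2), 6)
    y <- round(rnorm(nb, 11, 2), 6)
    recs_a <- lapply(seq_len(na), function(i)
      volumetry_record(i, "A", c(`17` = x[i]), 1000))
    recs_b <- lapply(seq_len(nb), function(i)
      volumetry_record(100 + i, "B", c(`17` = y[i]), 1000))
    got <- group_volume_test(recs_a, recs_b, 17L, 1L)
    expect_equal(got$p, perm_p(x / 1000, y / 1000), tolerance = 1e-9)
  }
})

test_that("summarize_cohort: degenerate CIs and bootstrap reference", {
  ph <- fix_phantom(6, shape = 32L)
  rep1 <- evaluate_labelmaps(ph, ph, exclusion_policy())
  tab1 <- summarize_cohort(list(rep1), n_boot = 50L)
  expect_true(all(tab1$dsc_median == 1))
  expect_true(all(tab1$dsc_lo == tab1$dsc_hi)) # single subject: point CI

  # bootstrap percentile CI against an independent reimplementation on a
  # fixed per-subject fixture (one value per subject)
  vals <- c(0.91, 0.88, 0.95, 0.87, 0.90, 0.93, 0.89, 0.92, 0.86, 0.94,
            0.91, 0.90, 0.88, 0.93, 0.92, 0.89, 0.87, 0.95, 0.90, 0.91)
  reports <- lapply(vals, function(v) {
    structure(list(per_label = data.frame(
      label = 2L, name = "wm", dsc = v, asd_mm = 1 - v,
      gt_vol_mm3 = 1, pred_vol_mm3 = 1, excluded = FALSE, missing = FALSE),
      summary = list()), class = "eval_report")
  })
  got <- summarize_cohort(reports, n_boot = 4000L, seed = 7)
  row <- got[got$label == 2L, ]
  set.seed(1234)
  ref <- replicate(4000, median(sample(vals, replace = TRUE)))
  expect_equal(row$dsc_median, median(vals))
  expect_lt(abs(row$dsc_lo - quantile(ref, 0.025)), 0.02)
  expect_lt(abs(row$dsc_hi - quantile(ref, 0.975)), 0.02)
})
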