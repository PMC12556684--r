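# Quantitative evaluation: Dice overlap, symmetric average surface distance
# with the voxel-center surface convention, missing-label rules (DSC 0 / ASD
# NaN when a label is absent from one map), exclusion policies (the default
# drops 8 of 35 labels, leaving the conventional 27-label summary), cohort
# summaries with bootstrap CIs, and TIV-normalized ROI volumetry with
# Mann-Whitney U group tests under Bonferroni correction.

#' Dice-Sørensen coefficient of two binary masks
#'
#' `2|G∩P| / (|G|+|P|)`; 1 is perfect overlap. If exactly one mask is empty
#' the value is 0; if both are empty the label is "missing" and `NA` is
#' returned for the caller to handle.
#'
#' @param G,P logical arrays on the same grid (ground truth, prediction).
#' @return scalar in [0, 1], or `NA` if both masks are empty.
#' @export
dice_coefficient <- function(G, P) {
  if (!identical(dim(G), dim(P))) stop("mask grids do not match")
  sg <- sum(G)
  sp <- sum(P)
  if (sg == 0 && sp == 0) return(NA_real_)
  2 * sum(G & P) / (sg + sp)
}

#' Average surface distance between two binary masks
#'
#' Surfaces are the centers of foreground voxels with at least one
#' face-adjacent background voxel (volume borders count as background).
#' ASD = (sum of nearest-point distances G->P + P->G) / (N_G + N_P), in mm;
#' symmetric by construction, 0 for identical masks.
#'
#' @param G,P logical arrays on the same grid.
#' @param spacing voxel size in mm (scalar or length-3).
#' @return scalar mm, or `NA` if either mask is empty (missing label).
#' @export
average_surface_distance <- function(G, P, spacing = 1) {
  if (!identical(dim(G), dim(P))) stop("mask grids do not match")
  if (sum(G) == 0 || sum(P) == 0) return(NA_real_)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  d <- as.integer(dim(G))
  sg <- cpp_surface_voxels(G, d)
  sp <- cpp_surface_voxels(P, d)
  wg <- sweep(sg, 2, spacing, `*`)
  wp <- sweep(sp, 2, spacing, `*`)
  (cpp_directed_nn_distance_sum(wg, wp) +
     cpp_directed_nn_distance_sum(wp, wg)) / (nrow(wg) + nrow(wp))
}

#' Label exclusion policy for evaluation
#'
#' The default excludes 8 of the 35 conventional labels: choroid plexus
#' (both hemispheres) and WM-hypointensities (not segmented by the reference
#' contrast-agnostic tool), the lateral and inferior lateral ventricles (both
#' hemispheres, directly impacted by the choroid plexus definition) and CSF
#' (defined differently across tools) — leaving the conventional 27-label
#' summary.
#'
#' @param excluded integer label ids to exclude from summaries.
#' @param rationale character tags, one per id.
#' @return an `exclusion_policy`.
#' @export
exclusion_policy <- function(excluded = integer(), rationale = NULL) {
  excluded <- as.integer(excluded)
  if (is.null(rationale)) rationale <- rep("unspecified", length(excluded))
  stopifnot(length(rationale) == length(excluded))
  structure(list(excluded = excluded,
                 rationale = stats::setNames(rationale,
                                             as.character(excluded))),
            class = "exclusion_policy")
}

#' @rdname exclusion_policy
#' @export
default_exclusion_policy <- function() {
  exclusion_policy(
    excluded = c(31L, 63L, 77L, 4L, 43L, 5L, 44L, 24L),
    rationale = c("choroid-plexus", "choroid-plexus", "wm-hypointensities",
                  "lateral-ventricle", "lateral-ventricle",
                  "inferior-lateral-ventricle", "inferior-lateral-ventricle",
                  "csf-definition"))
}

#' Evaluate a predicted label map against ground truth
#'
#' Per label (union of labels present in either map): DSC and ASD, with the
#' missing-label convention — a label present in only one map scores DSC 0
#' and ASD `NaN`. Labels in the exclusion policy are reported but flagged and
#' left out of the summaries; labels absent from both maps are skipped.
#'
#' @param gt,pred [labeled_volume()]s on the same grid.
#' @param policy an [exclusion_policy()].
#' @return an `eval_report`: `per_label` data frame (label, name, dsc,
#'   asd_mm, gt/pred volumes mm^3, `excluded`/`missing` flags) and `summary`
#'   (medians over included labels, label count).
#' @export
evaluate_labelmaps <- function(gt, pred, policy = default_exclusion_policy()) {
  stopifnot(inherits(gt, "labeled_volume"), inherits(pred, "labeled_volume"))
  if (!identical(dim(gt$data), dim(pred$data)))
    stop("ground-truth and prediction grids do not match")
  spacing <- vol_spacing(gt)
  voxvol <- abs(det(gt$affine[1:3, 1:3]))
  ids <- sort(union(vol_labels(gt), vol_labels(pred)))
  rows <- lapply(ids, function(id) {
    g <- gt$data == id
    p <- pred$data == id
    missing <- xor(any(g), any(p))
    dsc <- dice_coefficient(g, p)
    if (missing) dsc <- 0
    asd <- if (missing) NaN else average_surface_distance(g, p, spacing)
    nm <- gt$lut$name[match(id, gt$lut$id)]
    data.frame(label = id, name = if (is.na(nm)) sprintf("label-%d", id) else nm,
               dsc = dsc, asd_mm = asd,
               gt_vol_mm3 = sum(g) * voxvol, pred_vol_mm3 = sum(p) * voxvol,
               excluded = id %in% policy$excluded, missing = missing)
  })
  per_label <- do.call(rbind, rows)
  inc <- per_label[!per_label$excluded, , drop = FALSE]
  summary <- list(
    median_dsc = if (nrow(inc)) median(inc$dsc) else NA_real_,
    median_asd_mm = if (nrow(inc)) median(inc$asd_mm, na.rm = TRUE) else NA_real_,
    n_labels = nrow(inc))
  structure(list(per_label = per_label, summary = summary),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d labels summarized (of %d scored)\n",
              x$summary$n_labels, nrow(x$per_label)))
  cat(sprintf("  median DSC %.3f, median ASD %.3f mm\n",
              x$summary$median_dsc, x$summary$median_asd_mm))
  invisible(x)
}

#' Per-label volumes of a segmentation
#'
#' `volume(l) = count(l) * |det(A[1:3, 1:3])|`, the voxel count times the
#' voxel volume in mm^3.
#'
#' @param seg a [labeled_volume()].
#' @param ids labels to report (default: lut ids; absent labels report 0).
#' @return data frame with `label`, `name`, `n_voxels`, `volume_mm3`.
#' @export
label_volumes <- function(seg, ids = NULL) {
  stopifnot(inherits(seg, "labeled_volume"))
  if (is.null(ids)) ids <- sort(unique(c(seg$lut$id, vol_labels(seg))))
  voxvol <- abs(det(seg$affine[1:3, 1:3]))
  counts <- vapply(ids, function(id) sum(seg$data == id), 0)
  data.frame(label = as.integer(ids),
             name = ifelse(is.na(match(ids, seg$lut$id)),
                           sprintf("label-%d", ids),
                           seg$lut$name[match(ids, seg$lut$id)]),
             n_voxels = counts, volume_mm3 = counts * voxvol)
}

#' Volumetry record for one subject
#'
#' @param subject subject identifier.
#' @param group group tag (e.g. `"HC"` / `"patient"`).
#' @param volumes named numeric vector of ROI volumes in mm^3 (names are
#'   label ids).
#' @param tiv total intracranial volume in mm^3 (> 0; computed externally —
#'   if unavailable, [tiv_proxy()] gives a labeled fallback).
#' @return a `volumetry_record`.
#' @export
volumetry_record <- function(subject, group, volumes, tiv) {
  stopifnot(tiv > 0, length(volumes) >= 1, !is.null(names(volumes)))
  norm <- volumes / tiv
  if (any(norm <= 0 | norm >= 1))
    stop("normalized volumes must lie in (0, 1); check tiv units")
  structure(list(subject = subject, group = group, volumes = volumes,
                 tiv = tiv, normalized = norm),
            class = "volumetry_record")
}

#' Total-brain-volume proxy for TIV
#'
#' Sum of all nonzero-label volumes. This is a fallback, not a true total
#' intracranial volume (it excludes extra-cerebral CSF); use an externally
#' computed TIV when available.
#'
#' @param seg a [labeled_volume()].
#' @return scalar mm^3.
#' @export
tiv_proxy <- function(seg) {
  voxvol <- abs(det(seg$affine[1:3, 1:3]))
  sum(seg$data != 0L) * voxvol
}

#' Mann-Whitney U test on TIV-normalized ROI volumes
#'
#' Two-sided rank-sum test (exact for small untied samples, tie-corrected
#' normal approximation otherwise) with a Bonferroni-corrected significance
#' threshold `0.05 / n_comparisons`. All-identical pooled values are flagged
#' degenerate with p = 1.
#'
#' @param groupA,groupB lists of [volumetry_record()]s.
#' @param roi label id of the ROI tested.
#' @param n_comparisons number of comparisons in the Bonferroni family.
#' @return list: `U`, `p`, `threshold`, `significant`, `degenerate`, `n`.
#' @export
group_volume_test <- function(groupA, groupB, roi, n_comparisons = 1L) {
  stopifnot(length(groupA) >= 1L, length(groupB) >= 1L, n_comparisons >= 1L)
  pull <- function(recs) vapply(recs, function(r) {
    v <- r$normalized[as.character(roi)]
    if (is.na(v)) stop("roi ", roi, " missing from a volumetry record")
    v
  }, 0)
  a <- pull(groupA)
  b <- pull(groupB)
  threshold <- 0.05 / n_comparisons
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = length(a) * length(b) / 2, p = 1, threshold = threshold,
                significant = FALSE, degenerate = TRUE,
                n = c(length(a), length(b))))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = !any(duplicated(c(a, b)))))
  list(U = unname(wt$statistic), p = wt$p.value, threshold = threshold,
       significant = wt$p.value < threshold, degenerate = FALSE,
       n = c(length(a), length(b)))
}

#' Cohort summary of evaluation reports
#'
#' Per-label and overall medians across subjects with nonparametric bootstrap
#' 95% confidence intervals (percentile interval over subject resamples,
#' fixed seed). The overall row pools all included (subject, label) DSC/ASD
#' values, resampling subjects.
#'
#' @param reports list of `eval_report`s, one per subject.
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return data frame: label (`0` = overall), name, n_subjects, median and CI
#'   for DSC and ASD.
#' @export
summarize_cohort <- function(reports, n_boot = 10000L, conf = 0.95,
                             seed = 1L) {
  stopifnot(length(reports) >= 1L)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed)
  tabs <- lapply(seq_along(reports), function(i) {
    tb <- reports[[i]]$per_label
    tb$subject <- i
    tb[!tb$excluded, , drop = FALSE]
  })
  all_tb <- do.call(rbind, tabs)
  alpha <- (1 - conf) / 2

  boot_median_ci <- function(values_by_subject) {
    point <- median(unlist(values_by_subject), na.rm = TRUE)
    ns <- length(values_by_subject)
    if (ns == 1L) return(c(point, point, point))
    meds <- vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(ns, ns, replace = TRUE)
      median(unlist(values_by_subject[pick]), na.rm = TRUE)
    }, 0)
    c(point, unname(quantile(meds, c(alpha, 1 - alpha), na.rm = TRUE)))
  }

  rows <- list()
  for (id in sort(unique(all_tb$label))) {
    sub <- all_tb[all_tb$label == id, , drop = FALSE]
    dsc <- split(sub$dsc, sub$subject)
    asd <- split(sub$asd_mm, sub$subject)
    cd <- boot_median_ci(dsc)
    ca <- boot_median_ci(asd)
    rows[[length(rows) + 1L]] <- data.frame(
      label = id, name = sub$name[1], n_subjects = length(dsc),
      dsc_median = cd[1], dsc_lo = cd[2], dsc_hi = cd[3],
      asd_median = ca[1], asd_lo = ca[2], asd_hi = ca[3])
  }
  cd <- boot_median_ci(split(all_tb$dsc, all_tb$subject))
  ca <- boot_median_ci(split(all_tb$asd_mm, all_tb$subject))
  rows[[length(rows) + 1L]] <- data.frame(
    label = 0L, name = sprintf("overall (%d labels)",
                               length(unique(all_tb$label))),
    n_subjects = length(reports),
    dsc_median = cd[1], dsc_lo = cd[2], dsc_hi = cd[3],
    asd_median = ca[1], asd_lo = ca[2], asd_hi = ca[3])
  do.call(rbind, rows)
}
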