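#' Volume containers
#'
#' `intensity_volume()` wraps a 3D scalar grid with a 4x4 voxel-to-world
#' affine (mm, 0-based voxel indices, NIfTI convention). `labeled_volume()`
#' wraps a 3D non-negative integer grid with the same affine contract plus a
#' label lookup table. Label id 0 is reserved for background and never appears
#' in the lookup table.
#'
#' @param data 3D array (numeric for intensities, integer-valued for labels).
#' @param affine 4x4 numeric voxel-to-world matrix; must be invertible.
#' @param lut lookup table `data.frame` with columns `id`, `name` and
#'   optionally `r`, `g`, `b`, `a` (0-255); see [read_fs_lut()].
#' @return An object of class `intensity_volume` or `labeled_volume`.
#' @examples
#' iv <- intensity_volume(array(rnorm(8), c(2, 2, 2)), diag(4))
#' vol_spacing(iv)
#' @export
intensity_volume <- function(data, affine = diag(4)) {
  data <- as_grid3d(data, numeric_ok = TRUE)
  check_affine(affine)
  structure(list(data = data, affine = affine),
            class = c("intensity_volume", "drseg_volume"))
}

#' @rdname intensity_volume
#' @export
labeled_volume <- function(data, affine = diag(4), lut = NULL) {
  data <- as_grid3d(data, numeric_ok = FALSE)
  check_affine(affine)
  present <- setdiff(unique(as.integer(data)), 0L)
  if (any(present < 0L)) stop("label maps must be non-negative")
  if (is.null(lut)) lut <- default_lut(present)
  stopifnot(is.data.frame(lut), all(c("id", "name") %in% names(lut)))
  if (any(lut$id == 0L)) stop("label id 0 is reserved for background")
  missing <- setdiff(present, lut$id)
  if (length(missing) > 0L)
    stop("labels present in data but absent from lut: ",
         paste(missing, collapse = ", "))
  structure(list(data = data, affine = affine, lut = lut),
            class = c("labeled_volume", "drseg_volume"))
}

default_lut <- function(ids) {
  ids <- sort(as.integer(ids))
  data.frame(id = ids,
             name = if (length(ids)) sprintf("label-%d", ids) else character(),
             r = integer(length(ids)) + 128L, g = integer(length(ids)) + 128L,
             b = integer(length(ids)) + 128L, a = integer(length(ids)) + 255L)
}

as_grid3d <- function(data, numeric_ok) {
  if (is.null(dim(data))) stop("data must be a 3D array")
  if (length(dim(data)) != 3L) stop("data must have exactly 3 dimensions")
  if (!numeric_ok) {
    storage.mode(data) <- "integer"
  } else {
    storage.mode(data) <- "double"
  }
  data
}

check_affine <- function(affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  invisible(affine)
}

#' @export
print.drseg_volume <- function(x, ...) {
  kind <- if (inherits(x, "labeled_volume")) "labeled_volume" else "intensity_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(vol_spacing(x), 4), collapse = "x")))
  if (inherits(x, "labeled_volume"))
    cat(sprintf("  %d labels in lut\n", nrow(x$lut)))
  invisible(x)
}

#' Voxel spacing of a volume
#'
#' Per-axis voxel size in mm, derived from the column norms of the affine's
#' rotation/scale block.
#'
#' @param vol an `intensity_volume` or `labeled_volume`.
#' @return numeric length-3 vector (mm).
#' @export
vol_spacing <- function(vol) {
  a <- vol$affine[1:3, 1:3, drop = FALSE]
  sqrt(colSums(a^2))
}

#' Labels present in a label map
#' @param vol a `labeled_volume`.
#' @return sorted integer vector of nonzero label ids present in the grid.
#' @export
vol_labels <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  sort(setdiff(unique(as.integer(vol$data)), 0L))
}

# ---------------------------------------------------------------------------
# Orientation

ORIENT_LETTERS <- c("R", "A", "S") # direction of increasing world coordinate
ORIENT_OPPOSITE <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")

#' Validate a 3-letter anatomical orientation code
#'
#' Codes follow the NIfTI axis convention: each letter names the anatomical
#' direction toward which the corresponding voxel axis points (e.g. `"RAS"`:
#' axis 1 to the Right, axis 2 Anterior, axis 3 Superior). The canonical
#' orientation used before inference is `"LIA"`.
#'
#' @param code character scalar, e.g. `"LIA"`.
#' @return the validated upper-case code, invisibly usable downstream.
#' @export
orientation_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  code <- toupper(code)
  letters3 <- strsplit(code, "")[[1]]
  if (length(letters3) != 3L) stop("orientation code must have 3 letters")
  axis_of <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
  if (!all(letters3 %in% names(axis_of))) stop("invalid orientation letter")
  if (anyDuplicated(axis_of[letters3])) stop("duplicated anatomical axis in code")
  code
}

#' Determine the orientation code of an affine
#'
#' Each voxel axis is assigned the cardinal world axis its direction cosine
#' dominates. An axis whose dominant |cosine| is below `tol` makes the affine
#' oblique and raises an error.
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param tol dominance threshold on the normalized direction cosine (0.9).
#' @return 3-letter orientation code.
#' @export
orientation_of <- function(affine, tol = 0.9) {
  check_affine(affine)
  letters3 <- character(3)
  axes <- integer(3)
  for (j in 1:3) {
    col <- affine[1:3, j]
    u <- col / sqrt(sum(col^2))
    k <- which.max(abs(u))
    if (abs(u[k]) <= tol)
      stop("oblique affine: voxel axis ", j,
           " has no dominant cardinal direction (|cos| <= ", tol, ")")
    axes[j] <- k
    letters3[j] <- if (u[k] > 0) ORIENT_LETTERS[k] else ORIENT_OPPOSITE[ORIENT_LETTERS[k]]
  }
  if (anyDuplicated(axes)) stop("oblique affine: two voxel axes map to one world axis")
  paste(letters3, collapse = "")
}

#' Reorient a volume to a target anatomical orientation
#'
#' Pure permutation/flip of the voxel grid: the world coordinate of every
#' voxel center is unchanged and no interpolation happens. Oblique affines
#' (no axis within tolerance of a cardinal direction) raise an error.
#'
#' @param vol `intensity_volume` or `labeled_volume`.
#' @param target 3-letter orientation code, default the `"LIA"` canonical
#'   orientation used before inference.
#' @param tol obliqueness tolerance passed to [orientation_of()].
#' @return a volume of the same class on the reoriented grid.
#' @export
reorient <- function(vol, target = "LIA", tol = 0.9) {
  stopifnot(inherits(vol, "drseg_volume"))
  target <- orientation_code(target)
  current <- orientation_of(vol$affine, tol = tol)
  if (current == target) return(vol)

  cur <- strsplit(current, "")[[1]]
  tgt <- strsplit(target, "")[[1]]
  axis_of <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
  src <- integer(3)
  flip <- logical(3)
  for (j in 1:3) {
    s <- which(axis_of[cur] == axis_of[tgt[j]])
    src[j] <- s
    flip[j] <- cur[s] != tgt[j]
  }

  d <- dim(vol$data)
  x <- vol$data
  for (s in unique(src[flip])) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[s]] <- rev(idx[[s]])
    x <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  x <- aperm(x, src)

  # voxel_old = P %*% voxel_new + q ; new_affine = affine %*% [P q; 0 1]
  tf <- diag(4)
  P <- matrix(0, 3, 3)
  q <- numeric(3)
  for (j in 1:3) {
    P[src[j], j] <- if (flip[j]) -1 else 1
    if (flip[j]) q[src[j]] <- d[src[j]] - 1
  }
  tf[1:3, 1:3] <- P
  tf[1:3, 4] <- q
  new_affine <- vol$affine %*% tf

  out <- vol
  out$data <- x
  out$affine <- new_affine
  out
}

# ---------------------------------------------------------------------------
# Resampling

resample_grid_geometry <- function(vol, target_spacing) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  stopifnot(length(target_spacing) == 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be strictly positive")
  sp <- vol_spacing(vol)
  d <- dim(vol$data)
  n_out <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  scale <- target_spacing / sp
  affine_out <- vol$affine
  for (j in 1:3) affine_out[1:3, j] <- affine_out[1:3, j] * scale[j]
  list(n_out = n_out, affine_out = affine_out, scale = scale)
}

# output voxel centers expressed as continuous 0-based input voxel indices;
# valid for any invertible affines sharing an origin convention
coords_between_grids <- function(affine_in, affine_out, n_out) {
  m <- solve(affine_in) %*% affine_out
  g <- as.matrix(expand.grid(x = seq_len(n_out[1]) - 1,
                             y = seq_len(n_out[2]) - 1,
                             z = seq_len(n_out[3]) - 1))
  coords <- g %*% t(m[1:3, 1:3]) +
    matrix(m[1:3, 4], nrow(g), 3, byrow = TRUE)
  coords
}

#' Resample an intensity volume to a target voxel spacing
#'
#' Tricubic (Catmull-Rom) spline interpolation with mirror boundary handling;
#' the world position of the voxel (0,0,0) center anchors the output grid, so
#' the field of view is preserved within one output voxel.
#'
#' @param vol `intensity_volume`.
#' @param target_spacing scalar or length-3 spacing in mm (> 0).
#' @return `intensity_volume` at the requested spacing.
#' @export
resample_intensity <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "intensity_volume"))
  geo <- resample_grid_geometry(vol, target_spacing)
  if (all(abs(geo$scale - 1) < 1e-9)) return(vol)
  resample_intensity_to_grid(vol, geo$n_out, geo$affine_out)
}

resample_intensity_to_grid <- function(vol, n_out, affine_out) {
  coords <- coords_between_grids(vol$affine, affine_out, n_out)
  # clamp to the edge (replication) before cubic sampling with mirror padding
  d <- dim(vol$data)
  for (j in 1:3) coords[, j] <- pmin(pmax(coords[, j], 0), d[j] - 1)
  vals <- cpp_sample_tricubic(as.numeric(vol$data), as.integer(d), coords)
  intensity_volume(array(vals, n_out), affine_out)
}

#' Resample a label map to a target voxel spacing
#'
#' Each present label is one-hot encoded, channels are interpolated linearly
#' onto the target grid and the output label is the per-voxel argmax (ties
#' broken toward the lowest label id). Out-of-bounds weight goes to
#' background. The output label set is always a subset of the input's.
#'
#' @param vol `labeled_volume`.
#' @param target_spacing scalar or length-3 spacing in mm (> 0).
#' @return `labeled_volume` at the requested spacing.
#' @export
resample_labels <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "labeled_volume"))
  geo <- resample_grid_geometry(vol, target_spacing)
  if (all(abs(geo$scale - 1) < 1e-9)) return(vol)
  resample_labels_to_grid(vol, geo$n_out, geo$affine_out)
}

resample_labels_to_grid <- function(vol, n_out, affine_out) {
  coords <- coords_between_grids(vol$affine, affine_out, n_out)
  # clamp to the last voxel center: edge replication within the field of
  # view; background fill only applies to deformation warps, not resampling
  d <- dim(vol$data)
  for (j in 1:3) coords[, j] <- pmin(pmax(coords[, j], 0), d[j] - 1)
  vals <- cpp_resample_labels_onehot(as.integer(vol$data),
                                     as.integer(dim(vol$data)), coords)
  labeled_volume(array(vals, n_out), affine_out, lut = vol$lut)
}
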