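# Minimal NIfTI-1 I/O (.nii / .nii.gz, single-file). Supports the datatypes
# used in structural neuroimaging (uint8, int16, int32, float32, float64,
# uint16), sform/qform affines and scl slope/intercept. Kept deliberately
# small: no extensions, no 4D, no DICOM.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

read_nifti_header <- function(con) {
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) stop("truncated NIfTI header")
  endian <- "little"
  sz <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  rd <- function(off, what, n, size) {
    readBin(raw_hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  list(
    endian = endian,
    dim = rd(40L, "integer", 8L, 2L),
    datatype = rd(70L, "integer", 1L, 2L),
    bitpix = rd(72L, "integer", 1L, 2L),
    pixdim = rd(76L, "double", 8L, 4L),
    vox_offset = rd(108L, "double", 1L, 4L),
    scl_slope = rd(112L, "double", 1L, 4L),
    scl_inter = rd(116L, "double", 1L, 4L),
    qform_code = rd(252L, "integer", 1L, 2L),
    sform_code = rd(254L, "integer", 1L, 2L),
    quatern = rd(256L, "double", 3L, 4L),
    qoffset = rd(268L, "double", 3L, 4L),
    srow = rbind(rd(280L, "double", 4L, 4L),
                 rd(296L, "double", 4L, 4L),
                 rd(312L, "double", 4L, 4L)),
    magic = magic
  )
}

nifti_affine_from_header <- function(h) {
  if (h$sform_code > 0L) {
    return(rbind(h$srow, c(0, 0, 0, 1)))
  }
  if (h$qform_code > 0L) {
    b <- h$quatern[1]; c_ <- h$quatern[2]; d <- h$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), 3, 3, byrow = TRUE)
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    S <- diag(c(h$pixdim[2], h$pixdim[3], qfac * h$pixdim[4]))
    aff <- diag(4)
    aff[1:3, 1:3] <- R %*% S
    aff[1:3, 4] <- h$qoffset
    return(aff)
  }
  aff <- diag(c(h$pixdim[2:4], 1))
  aff
}

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' `read_nifti()` returns an [intensity_volume()];
#' `read_nifti_labels()` returns a [labeled_volume()] (values are rounded to
#' integers; pass a lookup table read with [read_fs_lut()] or let a generic
#' one be built from the ids present).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param lut optional lookup table `data.frame` for label volumes.
#' @return a volume object with the file's affine (sform preferred, then
#'   qform, then pixdim-diagonal).
#' @export
read_nifti <- function(path) {
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  h <- read_nifti_header(con)
  dt <- NIFTI_DT[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", h$datatype)
  nd <- h$dim[1]
  if (nd < 3L) stop("expected a 3D volume")
  d <- h$dim[2:4]
  if (nd > 3L && any(h$dim[5:(1 + nd)] > 1L)) stop("4D volumes are not supported")
  skip <- h$vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = h$endian)
  if (length(vals) < n) stop("truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0)) {
    vals <- vals * h$scl_slope + h$scl_inter
  }
  intensity_volume(array(vals, d), nifti_affine_from_header(h))
}

#' @rdname read_nifti
#' @export
read_nifti_labels <- function(path, lut = NULL) {
  iv <- read_nifti(path)
  labeled_volume(array(as.integer(round(iv$data)), dim(iv$data)),
                 iv$affine, lut = lut)
}

#' Write a volume to NIfTI-1
#'
#' Intensity volumes are written as float32, label maps as int32. The affine
#' is stored in the sform (code 2); the qform is left unset.
#'
#' @param vol `intensity_volume` or `labeled_volume`.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "drseg_volume"))
  is_labels <- inherits(vol, "labeled_volume")
  datatype <- if (is_labels) 8L else 16L
  bitpix <- 32L
  d <- dim(vol$data)
  sp <- vol_spacing(vol)

  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                       # sizeof_hdr
  wraw(36L)                          # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)   # dim
  wf(c(0, 0, 0)); wi(0L, 2L)         # intent
  wi(datatype, 2L); wi(bitpix, 2L); wi(0L, 2L)
  wf(c(1, sp, 1, 1, 1, 1))           # pixdim (qfac 1)
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope / inter
  wi(0L, 2L); wraw(2L)               # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  wraw(104L)                         # descrip + aux_file
  wi(0L, 2L); wi(2L, 2L)             # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))     # quatern, qoffset
  wf(vol$affine[1, ]); wf(vol$affine[2, ]); wf(vol$affine[3, ])
  wraw(16L)                          # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1L)  # magic
  wraw(4L)                           # extension flag
  if (is_labels) {
    wi(as.integer(vol$data), 4L)
  } else {
    wf(as.numeric(vol$data))
  }
  invisible(path)
}

#' Read a FreeSurfer-style color lookup table
#'
#' Plain-text table with one `id name R G B A` row per label; `#` comments
#' and blank lines are ignored. The 35-label table following the standard
#' FreeSurfer convention ships with the package:
#' `system.file("extdata", "fs_labels35.txt", package = "drseg")`.
#'
#' @param path text file path.
#' @return `data.frame` with columns `id`, `name`, `r`, `g`, `b`, `a`.
#' @export
read_fs_lut <- function(path) {
  tab <- read.table(path, comment.char = "#", stringsAsFactors = FALSE,
                    col.names = c("id", "name", "r", "g", "b", "a"))
  tab$id <- as.integer(tab$id)
  if (anyDuplicated(tab$id)) stop("duplicate label ids in lookup table")
  tab
}

#' The packaged 35-label FreeSurfer-convention lookup table
#' @return `data.frame` as from [read_fs_lut()].
#' @export
fs_lut35 <- function() {
  read_fs_lut(system.file("extdata", "fs_labels35.txt", package = "drseg"))
}
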