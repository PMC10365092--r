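#' Gradient table
#'
#' Pairs each DWI frame with its diffusion-sensitizing direction and b-value.
#' Frames with b below `b0_threshold` (default 50 s/mm^2) are treated as b0
#' frames and keep a zero direction; all other directions are normalized to
#' unit length.
#'
#' @param directions n x 3 matrix of gradient directions (rows).
#' @param bvalues Numeric vector of n non-negative b-values (s/mm^2).
#' @param b0_threshold b-values at or below this are considered b0 frames.
#' @return Object of class `gradient_table`.
#' @export
gradient_table <- function(directions, bvalues, b0_threshold = 50) {
  directions <- .as_direction_matrix(directions)
  if (nrow(directions) != length(bvalues)) {
    stop("gradient table mismatch: ", nrow(directions), " directions but ",
         length(bvalues), " b-values")
  }
  if (any(!is.finite(directions)) || any(!is.finite(bvalues))) {
    stop("non-finite values in gradient table")
  }
  if (any(bvalues < 0)) stop("negative b-values in gradient table")
  is_b0 <- bvalues <= b0_threshold
  nrm <- sqrt(rowSums(directions^2))
  if (any(!is_b0 & nrm < 1e-12)) {
    stop("zero direction for a diffusion-weighted frame")
  }
  directions[!is_b0, ] <- directions[!is_b0, , drop = FALSE] / nrm[!is_b0]
  directions[is_b0, ] <- 0
  structure(list(directions = directions, bvalues = as.numeric(bvalues),
                 b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  tab <- table(round(x$bvalues, -1))
  cat("gradient_table:", length(x$bvalues), "frames; b-values:",
      paste(sprintf("%s (x%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

n_frames <- function(gtab) length(gtab$bvalues)

b0_frames <- function(gtab) which(gtab$bvalues <= gtab$b0_threshold)

#' Subset a gradient table by frame index
#' @param gtab A [gradient_table()].
#' @param idx Frame indices to keep (order preserved or permuted as given).
#' @return A new `gradient_table`.
#' @export
subset_gradients <- function(gtab, idx) {
  gradient_table(gtab$directions[idx, , drop = FALSE], gtab$bvalues[idx],
                 gtab$b0_threshold)
}

#' DWI volume container
#'
#' @param data 4D non-negative array (X, Y, Z, G).
#' @param affine 4x4 voxel-to-world transform (mm).
#' @param gradients [gradient_table()] with G entries.
#' @param brain_mask Optional 3D logical/0-1 array of the same spatial shape.
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, affine = diag(4), gradients, brain_mask = NULL) {
  stopifnot(length(dim(data)) == 4L)
  if (dim(data)[4] != n_frames(gradients)) {
    stop("frame mismatch: image has ", dim(data)[4], " frames but gradient ",
         "table has ", n_frames(gradients))
  }
  if (any(!is.finite(data))) stop("non-finite values in DWI data")
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  if (!is.null(brain_mask)) {
    stopifnot(all(dim(brain_mask) == dim(data)[1:3]))
    brain_mask <- array(brain_mask != 0, dim(brain_mask))
  }
  structure(list(data = data, affine = affine, gradients = gradients,
                 brain_mask = brain_mask),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dwi_volume: %d x %d x %d, %d frames\n", d[1], d[2], d[3], d[4]))
  print(x$gradients)
  invisible(x)
}

#' Voxel volume in mm^3 from an affine
#' @param affine 4x4 voxel-to-world transform.
#' @return Scalar voxel volume, `abs(det(affine[1:3, 1:3]))`.
#' @export
voxel_volume <- function(affine) abs(det(affine[1:3, 1:3]))

#' Read a DWI volume with FSL-style gradient files
#'
#' @param image_path Path to a 4D NIfTI image.
#' @param bval_path Path to a whitespace-separated b-value file (one row).
#' @param bvec_path Path to a whitespace-separated b-vector file
#'   (3 rows x G columns).
#' @param b0_threshold Passed to [gradient_table()].
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, b0_threshold = 50) {
  for (p in c(image_path, bval_path, bvec_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  img <- RNifti::readNifti(image_path)
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L) stop("bvec file must have 3 rows: ", bvec_path)
  g <- dim(dat)[4]
  if (length(bvals) != g) {
    stop("bval count mismatch in ", bval_path, ": ", length(bvals),
         " values for ", g, " frames")
  }
  if (ncol(bvecs) != g) {
    stop("bvec count mismatch in ", bvec_path, ": ", ncol(bvecs),
         " columns for ", g, " frames")
  }
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) diag(4))
  dwi_volume(dat, affine = aff,
             gradients = gradient_table(t(bvecs), bvals, b0_threshold))
}

#' Write a DWI volume with FSL-style gradient files
#'
#' @param dwi A [dwi_volume()].
#' @param image_path Output NIfTI path (.nii or .nii.gz).
#' @param bval_path,bvec_path Output gradient file paths; defaults replace
#'   the image extension with .bval/.bvec.
#' @return Invisibly, the image path.
#' @export
write_dwi <- function(dwi, image_path,
                      bval_path = sub("\\.nii(\\.gz)?$", ".bval", image_path),
                      bvec_path = sub("\\.nii(\\.gz)?$", ".bvec", image_path)) {
  .write_nifti(dwi$data, dwi$affine, image_path)
  writeLines(paste(format(dwi$gradients$bvalues, trim = TRUE),
                   collapse = " "), bval_path)
  bv <- t(dwi$gradients$directions)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(image_path)
}

.write_nifti <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  sf <- structure(affine, code = 2L)
  RNifti::sform(img) <- sf
  RNifti::qform(img) <- sf
  RNifti::writeNifti(img, path)
  invisible(path)
}

.read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = tryCatch(unclass(RNifti::xform(img)), error = function(e) diag(4)))
}
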