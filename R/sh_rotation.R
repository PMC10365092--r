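#' Rotation specification for augmentation
#'
#' Extrinsic rotations about the grid axes, applied in the fixed order
#' x, then y, then z.
#'
#' @param angles Numeric length-3 vector of angles in degrees.
#' @return Object of class `rotation_spec`.
#' @export
rotation_spec <- function(angles = c(0, 0, 0)) {
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  structure(list(angles = as.numeric(angles), order = "xyz_extrinsic"),
            class = "rotation_spec")
}

#' Draw a random rotation for data augmentation
#'
#' Three angles i.i.d. uniform on [-range_deg, +range_deg], drawn from the
#' current R random stream (seed with `set.seed()` for reproducibility).
#'
#' @param range_deg Non-negative half-width of the angle range in degrees
#'   (the training default is 20).
#' @return A [rotation_spec()].
#' @export
sample_rotation <- function(range_deg = 20) {
  if (length(range_deg) != 1 || !is.finite(range_deg) || range_deg < 0) {
    stop("range_deg must be a non-negative scalar")
  }
  if (range_deg == 0) return(rotation_spec(c(0, 0, 0)))
  rotation_spec(stats::runif(3, -range_deg, range_deg))
}

#' 3x3 rotation matrix of a rotation spec
#' @param rot A [rotation_spec()].
#' @return 3x3 orthogonal matrix R = Rz Ry Rx (extrinsic x, y, z order).
#' @export
rotation_matrix <- function(rot) {
  a <- rot$angles * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' SH-coefficient rotation operator
#'
#' Builds the block-diagonal operator that rotates an even-degree real SH
#' coefficient vector consistently with a spatial rotation R: if c' = D c
#' then the synthesized function satisfies f'(u) = f(R^-1 u). Each degree is
#' an invariant subspace, so D has one orthogonal (2l+1) x (2l+1) block per
#' even degree.
#'
#' The blocks are obtained by collocation: the basis is evaluated on a fixed
#' quasi-uniform direction set and the (exactly consistent, overdetermined)
#' linear system Y(R^-1 u) = Y(u) D_l is solved per degree by least squares.
#' This is exact to numerical precision because rotated spherical harmonics
#' of degree l stay inside the degree-l subspace.
#'
#' @param rot A [rotation_spec()] or a 3x3 rotation matrix.
#' @param lmax Even maximum degree.
#' @param n_collocation Number of collocation directions (must comfortably
#'   exceed 2*lmax+1).
#' @return Object of class `sh_rotation_operator` with one matrix per even
#'   degree in `$blocks`.
#' @export
build_sh_rotation <- function(rot, lmax, n_collocation = 60) {
  R <- if (inherits(rot, "rotation_spec")) rotation_matrix(rot) else rot
  stopifnot(all(dim(R) == c(3, 3)))
  u <- fibonacci_directions(n_collocation)
  u_back <- u %*% R  # rows: R^-1 u (R orthogonal => R^-1 = t(R); u R = t(t(R) t(u)))
  blocks <- list()
  for (l in seq(0L, lmax, by = 2L)) {
    if (l == 0L) {
      blocks[[paste0("l", l)]] <- matrix(1, 1, 1)
      next
    }
    A <- .sh_degree_block(u, l)
    Bm <- .sh_degree_block(u_back, l)
    blocks[[paste0("l", l)]] <- qr.solve(A, Bm)
  }
  structure(list(blocks = blocks, lmax = lmax, R = R),
            class = "sh_rotation_operator")
}

# Evaluate only the degree-l real SH functions at unit directions.
.sh_degree_block <- function(dirs, l) {
  B <- sh_basis(dirs, l)
  idx <- sh_index_table(l)
  B[, idx$l == l, drop = FALSE]
}

#' Rotate SH coefficient vectors
#'
#' Applies the block-diagonal operator per degree. Accepts a single
#' coefficient vector or a matrix of row vectors (voxels x M).
#'
#' @param coeffs Length-M vector or (V x M) matrix.
#' @param op An [build_sh_rotation()] operator.
#' @return Rotated coefficients, same shape as the input.
#' @export
rotate_sh_coeffs <- function(coeffs, op) {
  vec <- is.null(dim(coeffs))
  cm <- if (vec) matrix(coeffs, nrow = 1L) else coeffs
  m <- sh_n_coeffs(op$lmax)
  if (ncol(cm) != m) {
    stop("coefficient length ", ncol(cm), " does not match operator lmax ",
         op$lmax, " (", m, " channels)")
  }
  idx <- sh_index_table(op$lmax)
  out <- cm
  for (l in seq(0L, op$lmax, by = 2L)) {
    cols <- which(idx$l == l)
    D <- op$blocks[[paste0("l", l)]]
    out[, cols] <- cm[, cols, drop = FALSE] %*% t(D)
  }
  if (vec) drop(out) else out
}

# --- spatial resampling -----------------------------------------------------

# Source voxel coordinates (0-based) for resampling a volume rotated by R
# about the grid center: target voxel v takes its value from R^-1 (v - c) + c.
.rotation_source_coords <- function(dims, R) {
  i <- rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3])
  j <- rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3])
  k <- rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  ctr <- (dims - 1) / 2
  v <- cbind(i - ctr[1], j - ctr[2], k - ctr[3])
  sweep(v %*% R, 2, ctr, "+")  # v R = t(R^-1 t(v)) since R^-1 = t(R)
}

# Trilinear sampling of a (V x C) channel matrix over grid `dims` at
# fractional 0-based coords (n x 3). Out-of-bounds -> 0.
.trilinear_sample <- function(chan, dims, coords) {
  n <- nrow(coords)
  inb <- coords[, 1] >= 0 & coords[, 1] <= dims[1] - 1 &
    coords[, 2] >= 0 & coords[, 2] <= dims[2] - 1 &
    coords[, 3] >= 0 & coords[, 3] <= dims[3] - 1
  out <- matrix(0, n, ncol(chan))
  if (!any(inb)) return(out)
  p <- coords[inb, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), dims[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(p[, 2]), dims[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(p[, 3]), dims[3] - 2); k0 <- pmax(k0, 0)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  s1 <- dims[1]; s2 <- dims[1] * dims[2]
  base <- i0 + j0 * s1 + k0 * s2 + 1
  acc <- matrix(0, sum(inb), ncol(chan))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    idx <- base + dx + dy * s1 + dz * s2
    acc <- acc + chan[idx, , drop = FALSE] * w
  }
  out[inb, ] <- acc
  out
}

# Nearest-neighbor sampling (for label masks). Out-of-bounds -> 0.
.nearest_sample <- function(chan, dims, coords) {
  n <- nrow(coords)
  p <- round(coords)
  inb <- p[, 1] >= 0 & p[, 1] <= dims[1] - 1 &
    p[, 2] >= 0 & p[, 2] <= dims[2] - 1 &
    p[, 3] >= 0 & p[, 3] <= dims[3] - 1
  out <- matrix(0, n, ncol(chan))
  if (!any(inb)) return(out)
  idx <- p[inb, 1] + p[inb, 2] * dims[1] + p[inb, 3] * dims[1] * dims[2] + 1
  out[inb, ] <- chan[idx, , drop = FALSE]
  out
}

#' Rotate a scalar (or multi-channel) volume spatially
#'
#' Resamples about the grid center with zero fill outside; no SH coefficient
#' handling. Used to map stochastic-pass probability maps back to subject
#' space (probabilities are orientation scalars).
#'
#' @param arr 3D array, or 4D array whose 4th dimension is channels.
#' @param R 3x3 rotation matrix (content is rotated by R).
#' @param interpolation "linear" or "nearest".
#' @return Array of the same shape.
#' @export
rotate_scalar_volume <- function(arr, R, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(arr)
  dims <- dm[1:3]
  nc <- if (length(dm) == 4L) dm[4] else 1L
  chan <- matrix(arr, prod(dims), nc)
  coords <- .rotation_source_coords(dims, R)
  out <- if (interpolation == "linear") .trilinear_sample(chan, dims, coords)
         else .nearest_sample(chan, dims, coords)
  array(out, dm)
}

#' Rotate an SH volume: spatial grid and coefficients together
#'
#' Applies one 3D rotation consistently: the voxel grid is resampled under
#' the rotation (trilinear for coefficients, nearest for masks, zero fill
#' outside) and every voxel's coefficient vector is multiplied by the SH
#' rotation operator of the same rotation, so fiber orientations follow the
#' anatomy. An identity rotation returns the input unchanged.
#'
#' @param sh An [sh_volume()].
#' @param masks Optional named list of 3D/4D label arrays to co-rotate with
#'   nearest-neighbor interpolation.
#' @param rot A [rotation_spec()].
#' @return List with rotated `sh` and `masks`.
#' @export
rotate_volume_and_sh <- function(sh, masks = NULL, rot) {
  R <- rotation_matrix(rot)
  if (max(abs(R - diag(3))) < 1e-14) {
    return(list(sh = sh, masks = masks))
  }
  dm <- dim(sh$coeffs)
  dims <- dm[1:3]
  chan <- matrix(sh$coeffs, prod(dims), dm[4])
  coords <- .rotation_source_coords(dims, R)
  res <- .trilinear_sample(chan, dims, coords)
  op <- build_sh_rotation(rot, sh$lmax)
  res <- rotate_sh_coeffs(res, op)
  out_masks <- NULL
  if (!is.null(masks)) {
    out_masks <- lapply(masks, function(mk) {
      md <- dim(mk)
      nc <- if (length(md) == 4L) md[4] else 1L
      r <- .nearest_sample(matrix(mk, prod(dims), nc), dims, coords)
      array(r, md)
    })
  }
  list(sh = sh_volume(array(res, dm), sh$lmax, sh$affine, sh$basis),
       masks = out_masks)
}
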