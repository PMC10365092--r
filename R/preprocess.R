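#' SH coefficient volume
#'
#' 4D grid holding, per voxel, the even-degree real SH coefficients of the
#' b0-normalized diffusion signal. This is the network input representation.
#'
#' @param coeffs 4D array (X, Y, Z, M).
#' @param lmax Even maximum degree; M must equal [sh_n_coeffs()].
#' @param affine 4x4 voxel-to-world transform.
#' @param basis Identifier of the real-SH convention in use.
#' @return Object of class `sh_volume`.
#' @export
sh_volume <- function(coeffs, lmax, affine = diag(4),
                      basis = "real_even_descriptive") {
  stopifnot(length(dim(coeffs)) == 4L)
  if (dim(coeffs)[4] != sh_n_coeffs(lmax)) {
    stop("channel mismatch: lmax ", lmax, " needs ", sh_n_coeffs(lmax),
         " channels, got ", dim(coeffs)[4])
  }
  if (any(!is.finite(coeffs))) stop("non-finite SH coefficients")
  structure(list(coeffs = coeffs, lmax = lmax, affine = affine, basis = basis),
            class = "sh_volume")
}

#' @export
print.sh_volume <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("sh_volume: %d x %d x %d, lmax=%d (%d channels), basis=%s\n",
              d[1], d[2], d[3], x$lmax, d[4], x$basis))
  invisible(x)
}

#' Split a DWI volume into a single shell and its b0 frames
#'
#' @param dwi A [dwi_volume()].
#' @param b_target Target shell b-value (s/mm^2), e.g. 2000.
#' @param tolerance Frames with |b - b_target| <= tolerance belong to the
#'   shell.
#' @return List with elements `shell` and `b0` (both `dwi_volume`), frame
#'   order preserved.
#' @export
extract_shell <- function(dwi, b_target, tolerance = 100) {
  b <- dwi$gradients$bvalues
  sel <- which(abs(b - b_target) <= tolerance & b > dwi$gradients$b0_threshold)
  b0 <- b0_frames(dwi$gradients)
  if (length(sel) == 0L) {
    stop("no frames within ", tolerance, " of b=", b_target,
         "; available b-values: ", paste(sort(unique(b)), collapse = ", "))
  }
  if (length(b0) == 0L) {
    stop("no b0 frames (b <= ", dwi$gradients$b0_threshold,
         "); available b-values: ", paste(sort(unique(b)), collapse = ", "))
  }
  pick <- function(idx) dwi_volume(dwi$data[, , , idx, drop = FALSE],
                                   dwi$affine,
                                   subset_gradients(dwi$gradients, idx),
                                   dwi$brain_mask)
  list(shell = pick(sel), b0 = pick(b0))
}

#' Normalize shell signal by the mean b0 signal
#'
#' Divides every shell frame voxelwise by the voxel's mean b0 intensity.
#' Voxels whose mean b0 does not exceed `epsilon` get output 0; their count
#' is reported via `message()` and attached as attribute `n_zero_b0`.
#'
#' @param shell,b0 `dwi_volume`s with matching spatial shape.
#' @param epsilon Mean-b0 values at or below this are treated as empty.
#' @return Normalized shell `dwi_volume`.
#' @export
normalize_by_b0 <- function(shell, b0, epsilon = 1e-6) {
  stopifnot(all(dim(shell$data)[1:3] == dim(b0$data)[1:3]))
  mb0 <- apply(b0$data, 1:3, mean)
  if (all(mb0 <= epsilon)) stop("all-zero b0 volume; cannot normalize")
  bad <- mb0 <= epsilon
  mb0[bad] <- 1
  dat <- shell$data / as.vector(mb0)
  if (any(bad)) {
    dat <- dat * as.vector(!bad)
    message(sum(bad), " voxels with zero mean b0 set to 0")
  }
  out <- dwi_volume(dat, shell$affine, shell$gradients, shell$brain_mask)
  attr(out, "n_zero_b0") <- sum(bad)
  out
}

#' Project a single-shell signal onto even-degree real SH
#'
#' Per voxel, solves the least-squares problem B c = s where B is the SH
#' design matrix at the shell directions ([sh_basis()]) and s the voxel's
#' shell signal. No diffusion model is fitted; this is a linear change of
#' representation.
#'
#' @param shell Normalized single-shell [dwi_volume()].
#' @param lmax Even maximum degree (default 4, giving 15 channels).
#' @param max_condition Largest acceptable condition number of the design
#'   matrix.
#' @return An [sh_volume()].
#' @export
fit_sh <- function(shell, lmax = 4, max_condition = 1e6) {
  dirs <- shell$gradients$directions
  m <- sh_n_coeffs(lmax)
  g <- nrow(dirs)
  if (g < m) {
    stop("underdetermined SH fit: ", g, " directions for ", m,
         " coefficients (lmax=", lmax, ")")
  }
  B <- sh_basis(dirs, lmax)
  sv <- svd(B, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > max_condition) {
    stop("ill-conditioned SH design matrix (condition number ",
         format(cond, digits = 4), "); directions may be coplanar")
  }
  dm <- dim(shell$data)
  smat <- matrix(shell$data, prod(dm[1:3]), dm[4])
  coefs <- t(qr.coef(qr(B), t(smat)))  # voxels x M
  sh_volume(array(coefs, c(dm[1:3], m)), lmax = lmax, affine = shell$affine)
}

#' Clamp SH outlier values to per-channel percentiles
#'
#' Percentiles are computed per coefficient channel over in-mask voxels
#' (linear interpolation between order statistics); in-mask values outside
#' the band are set to the band edge. Out-of-mask voxels are untouched.
#'
#' @param sh An [sh_volume()].
#' @param low_pct,high_pct Percentile bounds in [0, 100].
#' @param mask Optional 3D brain mask; default uses every voxel.
#' @return Clamped [sh_volume()].
#' @export
clamp_outliers <- function(sh, low_pct = 5, high_pct = 99, mask = NULL) {
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  dm <- dim(sh$coeffs)
  if (is.null(mask)) {
    keep <- rep(TRUE, prod(dm[1:3]))
  } else {
    stopifnot(all(dim(mask) == dm[1:3]))
    keep <- as.vector(mask != 0)
    if (!any(keep)) stop("empty mask: no voxels to compute percentiles over")
  }
  cm <- matrix(sh$coeffs, prod(dm[1:3]), dm[4])
  for (ch in seq_len(dm[4])) {
    q <- stats::quantile(cm[keep, ch], c(low_pct, high_pct) / 100,
                         type = 7, names = FALSE)
    cm[keep, ch] <- pmin(pmax(cm[keep, ch], q[1]), q[2])
  }
  sh_volume(array(cm, dm), sh$lmax, sh$affine, sh$basis)
}

# Electrostatic-repulsion energy a candidate direction adds against a chosen
# set, with antipodal symmetry: sum over chosen d_j of 1/|d - d_j| + 1/|d + d_j|.
.pair_energy <- function(cand, chosen) {
  if (nrow(chosen) == 0L) return(0)
  dif <- sqrt(colSums((t(chosen) - cand)^2))
  sm <- sqrt(colSums((t(chosen) + cand)^2))
  sum(1 / pmax(dif, 1e-12)) + sum(1 / pmax(sm, 1e-12))
}

#' Reorder gradient directions for truncation robustness
#'
#' Greedily permutes the diffusion-weighted directions so that every prefix
#' is approximately optimally spread on the half-sphere: each step appends
#' the direction that adds the least electrostatic-repulsion energy
#' (antipodally symmetric pairwise 1/distance). b0 frames are interleaved
#' evenly through the sequence. A scan truncated after any number of frames
#' then retains a near-uniform angular coverage.
#'
#' @param gtab A [gradient_table()].
#' @return Reordered `gradient_table` with attribute `permutation` giving,
#'   per output frame, the index of the input frame it came from.
#' @export
reorder_gradients <- function(gtab) {
  dwi_idx <- setdiff(seq_len(n_frames(gtab)), b0_frames(gtab))
  b0_idx <- b0_frames(gtab)
  if (length(dwi_idx) < 2L) stop("need at least 2 diffusion-weighted directions")
  dirs <- gtab$directions[dwi_idx, , drop = FALSE]
  n <- nrow(dirs)
  # duplicate (antipodally identical) directions make the energy infinite
  dup <- FALSE
  for (i in seq_len(n - 1L)) {
    d <- pmin(sqrt(colSums((t(dirs[-(1:i), , drop = FALSE]) - dirs[i, ])^2)),
              sqrt(colSums((t(dirs[-(1:i), , drop = FALSE]) + dirs[i, ])^2)))
    if (any(d < 1e-9)) dup <- TRUE
  }
  if (dup) warning("duplicate (antipodally identical) directions; ",
                   "ties broken by input index")
  remaining <- seq_len(n)
  order_local <- integer(0)
  for (k in seq_len(n)) {
    chosen <- dirs[order_local, , drop = FALSE]
    e <- vapply(remaining, function(i) .pair_energy(dirs[i, ], chosen),
                numeric(1))
    best <- remaining[which.min(e)]  # which.min: lowest index on ties
    order_local <- c(order_local, best)
    remaining <- setdiff(remaining, best)
  }
  dwi_perm <- dwi_idx[order_local]
  # interleave b0 frames evenly: b0 i goes before dwi frame ceil(i * n / (nb0+1))
  nb0 <- length(b0_idx)
  if (nb0 > 0L) {
    slots <- floor(seq_len(nb0) * n / (nb0 + 1L))
    perm <- integer(0)
    last <- 0L
    for (i in seq_len(nb0)) {
      perm <- c(perm, dwi_perm[seq_len(slots[i])[seq_len(slots[i]) > last]],
                b0_idx[i])
      last <- slots[i]
    }
    perm <- c(perm, dwi_perm[seq_len(n) > last])
  } else {
    perm <- dwi_perm
  }
  out <- subset_gradients(gtab, perm)
  attr(out, "permutation") <- perm
  out
}

#' Prefix electrostatic energies of a direction ordering
#'
#' Total antipodally-symmetric repulsion energy of each prefix of the
#' diffusion-weighted directions, in table order. Used to verify that a
#' reordering keeps prefixes well spread.
#'
#' @param gtab A [gradient_table()].
#' @return Numeric vector; element k is the energy of the first k directions.
#' @export
prefix_energies <- function(gtab) {
  dwi_idx <- setdiff(seq_len(n_frames(gtab)), b0_frames(gtab))
  dirs <- gtab$directions[dwi_idx, , drop = FALSE]
  n <- nrow(dirs)
  e <- numeric(n)
  acc <- 0
  for (k in seq_len(n)) {
    if (k > 1L) acc <- acc + .pair_energy(dirs[k, ], dirs[seq_len(k - 1L), , drop = FALSE])
    e[k] <- acc
  }
  e
}

#' Truncate a DWI acquisition to the first n directions
#'
#' Emulates a clinically short scan: keeps the first `n_directions`
#' diffusion-weighted frames (in current table order -- reorder first with
#' [reorder_gradients()]) plus a proportional number of b0 frames (at least
#' one), preserving frame order.
#'
#' @param dwi A [dwi_volume()].
#' @param n_directions Number of diffusion-weighted directions to keep.
#' @return Truncated [dwi_volume()].
#' @export
truncate_gradients <- function(dwi, n_directions = 45) {
  dwi_idx <- setdiff(seq_len(n_frames(dwi$gradients)), b0_frames(dwi$gradients))
  b0_idx <- b0_frames(dwi$gradients)
  if (n_directions < 1L || n_directions > length(dwi_idx)) {
    stop("cannot keep ", n_directions, " directions: ", length(dwi_idx),
         " available")
  }
  keep_dwi <- dwi_idx[seq_len(n_directions)]
  nb0_keep <- max(1L, round(length(b0_idx) * n_directions / length(dwi_idx)))
  keep_b0 <- b0_idx[seq_len(min(nb0_keep, length(b0_idx)))]
  keep <- sort(c(keep_dwi, keep_b0))
  dwi_volume(dwi$data[, , , keep, drop = FALSE], dwi$affine,
             subset_gradients(dwi$gradients, keep), dwi$brain_mask)
}

#' Full preprocessing pipeline: shell selection to clamped SH volume
#'
#' Convenience wrapper: [extract_shell()], [normalize_by_b0()], [fit_sh()],
#' [clamp_outliers()].
#'
#' @param dwi A [dwi_volume()].
#' @param b_target Shell b-value.
#' @param lmax Even maximum SH degree.
#' @param low_pct,high_pct Clamping percentiles.
#' @param tolerance Shell selection tolerance.
#' @return An [sh_volume()].
#' @export
preprocess_dwi <- function(dwi, b_target = 2000, lmax = 4,
                           low_pct = 5, high_pct = 99, tolerance = 100) {
  parts <- extract_shell(dwi, b_target, tolerance)
  norm <- normalize_by_b0(parts$shell, parts$b0)
  sh <- fit_sh(norm, lmax)
  clamp_outliers(sh, low_pct, high_pct, mask = dwi$brain_mask)
}
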