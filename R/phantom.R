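#' Phantom specification
#'
#' Parameters of the synthetic "subjects" used to exercise the pipeline
#' without external data: tube-shaped tract masks around smooth curves
#' (straight, C- and S-shaped templates echoing CST-, UF- and ILF-like
#' geometries), plus a single-shell DWI signal consistent with the local
#' fiber direction. In-tract voxels follow an axially symmetric
#' single-tensor attenuation `S0 * exp(-b * (l_perp + (l_par - l_perp)
#' (g . d)^2))`; background is isotropic; b0 frames carry the unattenuated
#' signal. Default diffusivities (l_par = 1.5e-3, l_perp = 0.3e-3 mm^2/s,
#' ratio 5) at b = 2000 s/mm^2 put the degree-2 SH energy of tract voxels
#' well above the noise floor at the default noise SD, so segmentation is
#' learnable at desk scale.
#'
#' @param grid_size Cubic grid side in voxels.
#' @param voxel_size_mm Isotropic voxel size.
#' @param n_tracts Number of tract classes (templates cycle through
#'   straight / C / S shapes).
#' @param radius_vox Tube radius in voxels.
#' @param n_directions Diffusion-weighted directions (half-sphere scheme).
#' @param n_b0 Number of b0 frames, interleaved through the acquisition.
#' @param bvalue Shell b-value (s/mm^2).
#' @param s0 Unattenuated signal level.
#' @param lambda_par,lambda_perp Axial/radial diffusivities (mm^2/s).
#' @param background_adc Isotropic background diffusivity (mm^2/s).
#' @param noise_sd Noise standard deviation on the signal scale.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of
#'   complex Gaussian noise).
#' @param jitter_vox SD-free uniform control-point jitter between subjects
#'   (voxels).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 32, voxel_size_mm = 1, n_tracts = 3,
                         radius_vox = 2.4, n_directions = 60, n_b0 = 6,
                         bvalue = 2000, s0 = 100, lambda_par = 1.5e-3,
                         lambda_perp = 3e-4, background_adc = 7e-4,
                         noise_sd = 2, noise_model = c("gaussian", "rician"),
                         jitter_vox = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(radius_vox >= 1, noise_sd >= 0, n_tracts >= 1,
            n_directions >= 15, grid_size >= 16)
  structure(list(grid_size = as.integer(grid_size),
                 voxel_size_mm = voxel_size_mm, n_tracts = n_tracts,
                 radius_vox = radius_vox, n_directions = n_directions,
                 n_b0 = n_b0, bvalue = bvalue, s0 = s0,
                 lambda_par = lambda_par, lambda_perp = lambda_perp,
                 background_adc = background_adc, noise_sd = noise_sd,
                 noise_model = noise_model, jitter_vox = jitter_vox),
            class = "phantom_spec")
}

# Sampled centerline (n x 3, 1-based voxel coords) and tangents for tract
# template `which` on a grid of side g, with additive control jitter.
# The three templates mimic the shape *and* orientation classes of real
# bundles: a straight inferior-superior tract (CST-like, along z), a
# C-shaped tract curving in the y-z plane (UF-like), and an S-shaped
# anterior-posterior tract (ILF-like, along y). Distinct principal
# orientation planes keep the per-voxel SH signatures of different tracts
# locally distinguishable, as anatomy does for real bundles.
.tract_curve <- function(which, g, jitter) {
  t_ <- seq(0, 1, length.out = 160)
  margin <- 5
  span <- g - 2 * margin
  ctr <- g / 2
  shape <- (which - 1L) %% 3L
  if (shape == 0L) {            # straight, z-aligned (CST-like)
    pts <- cbind(ctr - span / 4 + jitter[1],
                 ctr - span / 4 + jitter[2],
                 margin + span * t_)
  } else if (shape == 1L) {     # "C" curve in the y-z plane (UF-like)
    r <- span / 2.2
    pts <- cbind(ctr + span / 4 + jitter[1],
                 ctr + r * cos(pi * (0.15 + 0.7 * t_)) - r / 2 + 2 + jitter[2],
                 ctr + r * sin(pi * (0.15 + 0.7 * t_)) - r / 3 + jitter[3])
  } else {                      # "S" curve along y (ILF-like)
    amp <- span / 5
    pts <- cbind(ctr + amp * sin(2 * pi * t_) - span / 4 + jitter[1],
                 margin + span * t_,
                 ctr + span / 4 + jitter[2])
  }
  if (any(pts < 1.5) || any(pts > g - 0.5)) {
    stop("tract curve leaves the grid; reduce jitter or curvature")
  }
  tang <- rbind(pts[2, ] - pts[1, ],
                (pts[-(1:2), ] - pts[seq_len(nrow(pts) - 2L), ]) / 2,
                pts[nrow(pts), ] - pts[nrow(pts) - 1L, ])
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = pts, tangents = tang)
}

#' Generate tract masks and the fiber direction field
#'
#' Each tract is the set of voxels within `radius_vox` of its centerline;
#' the local fiber direction is the tangent at the nearest centerline
#' point. Tracts may overlap (multi-label masks).
#'
#' @param spec A [phantom_spec()].
#' @param jitter Optional (n_tracts x 3) matrix of control-point offsets;
#'   zero when NULL.
#' @return List with `masks` (4D 0/1 array X, Y, Z, N) and `directions`
#'   (4D array X, Y, Z, 3; unit tangents inside tracts, zero outside;
#'   overlaps keep the lowest tract index).
#' @export
make_tract_masks <- function(spec, jitter = NULL) {
  g <- spec$grid_size
  n <- spec$n_tracts
  if (is.null(jitter)) jitter <- matrix(0, n, 3)
  masks <- array(0L, c(g, g, g, n))
  dirs <- array(0, c(g, g, g, 3))
  assigned <- array(FALSE, c(g, g, g))
  for (tr in seq_len(n)) {
    cv <- .tract_curve(tr, g, jitter[tr, ])
    lo <- pmax(1L, floor(apply(cv$points, 2, min) - spec$radius_vox - 1))
    hi <- pmin(g, ceiling(apply(cv$points, 2, max) + spec$radius_vox + 1))
    bx <- lo[1]:hi[1]; by <- lo[2]:hi[2]; bz <- lo[3]:hi[3]
    vox <- as.matrix(expand.grid(x = bx, y = by, z = bz))
    # squared distance from every box voxel to every centerline sample
    cross <- outer(rowSums(vox^2), rowSums(cv$points^2), "+") -
      2 * vox %*% t(cv$points)
    nearest <- max.col(-cross, ties.method = "first")
    mind <- sqrt(pmax(cross[cbind(seq_len(nrow(vox)), nearest)], 0))
    inside <- mind <= spec$radius_vox
    idx <- vox[inside, , drop = FALSE]
    lin <- idx[, 1] + (idx[, 2] - 1L) * g + (idx[, 3] - 1L) * g * g
    masks[lin + (tr - 1L) * g^3] <- 1L
    new_vox <- lin[!assigned[lin]]
    tang <- cv$tangents[nearest[inside], , drop = FALSE][!assigned[lin], ,
                                                         drop = FALSE]
    for (a in 1:3) dirs[new_vox + (a - 1L) * g^3] <- tang[, a]
    assigned[new_vox] <- TRUE
  }
  list(masks = masks, directions = dirs)
}

# Gradient scheme for a phantom acquisition: half-sphere directions with
# b0 frames interleaved evenly.
.phantom_gradients <- function(spec) {
  d <- fibonacci_directions(spec$n_directions, hemisphere = TRUE)
  nb0 <- spec$n_b0
  n <- spec$n_directions
  dirs <- matrix(0, n + nb0, 3)
  bvals <- numeric(n + nb0)
  b0_slots <- if (nb0 > 0) round(seq(1, n + nb0, length.out = nb0)) else integer(0)
  di <- 1L
  for (i in seq_len(n + nb0)) {
    if (i %in% b0_slots) next
    dirs[i, ] <- d[di, ]
    bvals[i] <- spec$bvalue
    di <- di + 1L
  }
  gradient_table(dirs, bvals)
}

#' Synthesize the DWI signal of a phantom subject
#'
#' @param tracts A [make_tract_masks()] result.
#' @param brain 3D brain mask.
#' @param spec A [phantom_spec()].
#' @return A [dwi_volume()] (noise drawn from the current R random stream).
#' @export
make_dwi <- function(tracts, brain, spec) {
  g <- spec$grid_size
  gtab <- .phantom_gradients(spec)
  nf <- n_frames(gtab)
  v <- g^3
  dirfield <- matrix(tracts$directions, v, 3)
  in_tract <- rowSums(dirfield^2) > 0.5
  in_brain <- as.vector(brain != 0)
  dat <- matrix(0, v, nf)
  b0s <- b0_frames(gtab)
  for (f in seq_len(nf)) {
    if (f %in% b0s) {
      s <- numeric(v)
      s[in_brain] <- spec$s0
    } else {
      gdir <- gtab$directions[f, ]
      s <- numeric(v)
      s[in_brain] <- spec$s0 * exp(-spec$bvalue * spec$background_adc)
      if (any(in_tract)) {
        ct <- dirfield[in_tract, , drop = FALSE] %*% gdir
        s[in_tract] <- spec$s0 * exp(-spec$bvalue *
          (spec$lambda_perp + (spec$lambda_par - spec$lambda_perp) * ct^2))
      }
    }
    dat[, f] <- s
  }
  if (spec$noise_sd > 0) {
    if (spec$noise_model == "gaussian") {
      dat <- dat + matrix(stats::rnorm(v * nf, 0, spec$noise_sd), v, nf)
      dat[dat < 0] <- 0
    } else {
      dat <- sqrt((dat + matrix(stats::rnorm(v * nf, 0, spec$noise_sd),
                                v, nf))^2 +
                  matrix(stats::rnorm(v * nf, 0, spec$noise_sd), v, nf)^2)
    }
  }
  aff <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  dwi_volume(array(dat, c(g, g, g, nf)), aff, gtab, brain_mask = brain)
}

#' Generate one phantom subject
#'
#' @param spec A [phantom_spec()].
#' @param seed Subject seed (controls jitter and noise).
#' @return Object of class `phantom_subject`: `dwi`, `brain`, `tracts`
#'   (4D mask array), `directions`.
#' @export
make_phantom_subject <- function(spec, seed = 1) {
  set.seed(seed)
  jit <- matrix(stats::runif(spec$n_tracts * 3, -spec$jitter_vox,
                             spec$jitter_vox), spec$n_tracts, 3)
  tr <- make_tract_masks(spec, jit)
  g <- spec$grid_size
  ctr <- (g + 1) / 2
  ax <- seq_len(g) - ctr
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  brain <- array(r2 <= (g / 2 - 1)^2, c(g, g, g))
  # intracranial mask must contain every tract voxel
  brain <- brain | (apply(tr$masks, 1:3, max) > 0)
  dwi <- make_dwi(tr, brain, spec)
  structure(list(dwi = dwi, brain = array(as.integer(brain), c(g, g, g)),
                 tracts = tr$masks, directions = tr$directions,
                 spec = spec, seed = seed),
            class = "phantom_subject")
}

#' Generate a reproducible phantom dataset
#'
#' Per-subject seeds are derived deterministically from the master seed;
#' subjects differ by control-point jitter and noise realization. An
#' optional per-subject noise sweep overrides the spec's noise SD.
#'
#' @param n_subjects Number of subjects.
#' @param spec A [phantom_spec()].
#' @param seed Master seed.
#' @param noise_sds Optional length-`n_subjects` vector of noise SDs.
#' @return List of [make_phantom_subject()] results.
#' @export
make_dataset <- function(n_subjects, spec, seed = 1, noise_sds = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(noise_sds)) stopifnot(length(noise_sds) == n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    sp <- spec
    if (!is.null(noise_sds)) sp$noise_sd <- noise_sds[i]
    make_phantom_subject(sp, seed = (seed * 10007 + i * 97) %% 2147483629)
  })
}

#' Preprocess a phantom subject into network-ready form
#'
#' Runs the standard preprocessing chain on the subject's DWI and bundles
#' the result with its masks, in the layout [train_model()] expects.
#'
#' @param subject A [make_phantom_subject()] result.
#' @param lmax Even maximum SH degree.
#' @return List with `sh`, `masks`, `brain`.
#' @export
prepare_subject <- function(subject, lmax = 4) {
  sh <- preprocess_dwi(subject$dwi, b_target = subject$spec$bvalue,
                       lmax = lmax)
  # restrict the input to the intracranial space: outside the brain the b0
  # normalization divides noise by noise and the coefficients carry no signal
  sh$coeffs <- sh$coeffs * as.vector(subject$brain != 0)
  list(sh = sh, masks = subject$tracts, brain = subject$brain)
}

#' Write a phantom subject to disk in the real-data layout
#'
#' @param subject A [make_phantom_subject()] result.
#' @param dir Output directory (created if needed).
#' @param id Subject identifier used in file names.
#' @return Invisibly, the directory.
#' @export
write_phantom_subject <- function(subject, dir, id = "sub-01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dwi(subject$dwi, file.path(dir, paste0(id, "_dwi.nii.gz")))
  .write_nifti(subject$brain, subject$dwi$affine,
               file.path(dir, paste0(id, "_brain.nii.gz")))
  .write_nifti(subject$tracts, subject$dwi$affine,
               file.path(dir, paste0(id, "_tracts.nii.gz")))
  invisible(dir)
}
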