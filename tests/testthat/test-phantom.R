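test_that("tract masks are tubes around the template curves", {
  spec <- phantom_spec(grid_size = 32, n_tracts = 1, radius_vox = 1,
                       noise_sd = 0)
  # offset keeps the tube centerline between voxel rows (the tightest
  # discretization of a radius-1 tube)
  jit <- matrix(c(0.5, 0, 0), 1)
  tr <- make_tract_masks(spec, jitter = jit)
  # tract 1 is straight and z-aligned: brute-force distance-to-curve count
  g <- 32
  count <- sum(tr$masks[, , , 1])
  cv <- tractuq:::.tract_curve(1, g, jit[1, ])
  vox <- as.matrix(expand.grid(1:g, 1:g, 1:g))
  brute <- 0
  for (i in seq_len(nrow(vox))) {
    d <- sqrt(min(colSums((t(cv$points) - vox[i, ])^2)))
    if (d <= 1) brute <- brute + 1
  }
  expect_equal(count, brute)
  # voxel count within the discretization band [L, 3L] for radius 1
  L <- diff(range(cv$points[, 3]))  # straight template runs along z
  expect_gte(count, L)
  expect_lte(count, 3 * L)
  # straight template: symmetric under reflection across the tube axis plane
  zs <- round(mean(which(apply(tr$masks[, , , 1], 3, sum) > 0)))
  sl <- apply(tr$masks[, , , 1], c(1, 2), max)
  ys <- which(apply(sl, 2, sum) > 0)
  expect_equal(sl[, ys], sl[, rev(ys)])
})

test_that("direction field is unit norm inside tracts and tracts stay in the brain", {
  sub <- tiny_subject()
  df <- matrix(sub$directions, length(sub$brain), 3)
  any_tract <- as.vector(apply(sub$tracts, 1:3, max) > 0)
  nrm <- sqrt(rowSums(df^2))
  expect_true(all(abs(nrm[any_tract] - 1) < 1e-9))
  expect_true(all(nrm[!any_tract] == 0))
  expect_true(all(sub$brain[apply(sub$tracts, 1:3, max) > 0] == 1))
})

test_that("signal model: anisotropy only inside tracts, monotone in alignment", {
  spec <- phantom_spec(grid_size = 20, n_tracts = 1, radius_vox = 2,
                       noise_sd = 0, n_directions = 30, n_b0 = 2)
  set.seed(1)
  tr <- make_tract_masks(spec)
  g <- spec$grid_size
  brain <- array(1L, c(g, g, g))
  dwi <- make_dwi(tr, brain, spec)
  # pick an in-tract voxel with known (x-aligned) direction
  vi <- which(tr$masks[, , , 1] == 1, arr.ind = TRUE)[10, ]
  sig <- dwi$data[vi[1], vi[2], vi[3], ]
  dirs <- dwi$gradients$directions
  dwi_frames <- dwi$gradients$bvalues > 50
  align <- abs(dirs[dwi_frames, ] %*% c(0, 0, 1))  # straight template runs along z
  # signal decreases with alignment to the fiber (exp monotonicity)
  expect_lt(spearman(as.vector(align), sig[dwi_frames]), -0.9)
  expect_gt(max(sig[dwi_frames]) / min(sig[dwi_frames]), 2)
  # isotropic spec (ratio 1): no direction dependence
  spec_iso <- spec
  spec_iso$lambda_perp <- spec_iso$lambda_par
  dwi_iso <- make_dwi(tr, brain, spec_iso)
  sig_iso <- dwi_iso$data[vi[1], vi[2], vi[3], dwi_frames]
  expect_lt(diff(range(sig_iso)), 1e-9)
  # b0 frames carry the unattenuated signal
  expect_equal(as.vector(dwi$data[vi[1], vi[2], vi[3], !dwi_frames]),
               rep(spec$s0, 2))
})

test_that("noiseless tract voxels carry degree-2 SH energy, background none", {
  spec <- phantom_spec(grid_size = 20, n_tracts = 1, radius_vox = 2,
                       noise_sd = 0, n_directions = 30, n_b0 = 2)
  sub <- make_phantom_subject(spec, seed = 3)
  # probe the SH fit itself (no percentile clamping: with a zero-noise
  # background the band edges sit inside the tract value range)
  parts <- extract_shell(sub$dwi, spec$bvalue)
  norm <- suppressMessages(normalize_by_b0(parts$shell, parts$b0))
  sh <- fit_sh(norm, lmax = 4)
  idx <- sh_index_table(4)
  cm <- matrix(sh$coeffs, 20^3, 15)
  e2 <- rowSums(cm[, idx$l == 2]^2)
  in_tract <- as.vector(sub$tracts[, , , 1] != 0)
  in_bg <- as.vector(sub$brain != 0) & !in_tract
  expect_gt(min(e2[in_tract]), 1e-3)
  expect_lt(max(e2[in_bg]), 1e-10)
})

test_that("datasets are seeded, jittered, and degrade with noise", {
  spec <- tiny_spec()
  d1 <- make_dataset(2, spec, seed = 5)
  d2 <- make_dataset(2, spec, seed = 5)
  expect_identical(d1[[1]]$dwi$data, d2[[1]]$dwi$data)
  expect_identical(d1[[2]]$tracts, d2[[2]]$tracts)
  # subjects differ by jitter
  expect_false(identical(d1[[1]]$tracts, d1[[2]]$tracts))
  # increasing noise -> increasing SH fit residual
  sds <- c(0.5, 2, 4, 8, 12)
  subs <- make_dataset(5, spec, seed = 9, noise_sds = sds)
  resid <- vapply(subs, function(s) {
    parts <- extract_shell(s$dwi, s$spec$bvalue)
    norm <- suppressMessages(normalize_by_b0(parts$shell, parts$b0))
    sh <- fit_sh(norm)
    B <- sh_basis(norm$gradients$directions, 4)
    v <- sum(s$brain)
    cm <- matrix(sh$coeffs, length(s$brain), 15)[s$brain != 0, ]
    sm <- matrix(norm$data, length(s$brain), dim(norm$data)[4])[s$brain != 0, ]
    sqrt(mean((sm - cm %*% t(B))^2))
  }, numeric(1))
  expect_true(all(diff(resid) > 0))
})

test_that("phantom subjects serialize to byte-identical NIfTI given a seed", {
  sub <- tiny_subject()
  td <- withr::local_tempdir()
  write_phantom_subject(sub, file.path(td, "a"), "s1")
  write_phantom_subject(sub, file.path(td, "b"), "s1")
  fa <- file.path(td, "a", "s1_dwi.nii.gz")
  fb <- file.path(td, "b", "s1_dwi.nii.gz")
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  # and read back loss-free up to float storage
  back <- read_dwi(fa, file.path(td, "a", "s1_dwi.bval"),
                   file.path(td, "a", "s1_dwi.bvec"))
  expect_equal(back$data, sub$dwi$data, tolerance = 1e-6)
})
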