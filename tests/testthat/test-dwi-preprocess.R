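make_test_dwi <- function(bvals, dims = c(4, 4, 4), data = NULL) {
  g <- length(bvals)
  dirs <- matrix(0, g, 3)
  dwi_frames <- bvals > 50
  if (any(dwi_frames)) {
    dirs[dwi_frames, ] <- fibonacci_directions(sum(dwi_frames),
                                               hemisphere = TRUE)
  }
  if (is.null(data)) data <- array(runif(prod(dims) * g) + 1, c(dims, g))
  dwi_volume(data, diag(4), gradient_table(dirs, bvals))
}

test_that("gradient files round-trip through disk and mismatches are caught", {
  set.seed(7)
  dwi <- make_test_dwi(c(0, rep(1000, 20)))
  td <- withr::local_tempdir()
  img <- file.path(td, "sub_dwi.nii.gz")
  write_dwi(dwi, img)
  back <- read_dwi(img, file.path(td, "sub_dwi.bval"), file.path(td, "sub_dwi.bvec"))
  expect_equal(dim(back$data), dim(dwi$data))
  expect_equal(back$gradients$bvalues, dwi$gradients$bvalues)
  expect_equal(back$gradients$directions, dwi$gradients$directions,
               tolerance = 1e-7, ignore_attr = TRUE)
  # b0 frame keeps its zero direction
  expect_equal(back$gradients$directions[1, ], c(0, 0, 0))
  # 9 bvals for 21 frames -> format error naming the file
  bad <- file.path(td, "bad.bval")
  writeLines(paste(rep(0, 9), collapse = " "), bad)
  expect_error(read_dwi(img, bad, file.path(td, "sub_dwi.bvec")),
               "bval count mismatch")
})

test_that("extract_shell partitions frames by b-value with a tolerance", {
  dwi <- make_test_dwi(c(0, 1000, 2000, 2000))
  parts <- extract_shell(dwi, 2000, tolerance = 100)
  expect_equal(n_frames(parts$shell$gradients), 2L)
  expect_equal(parts$shell$gradients$bvalues, c(2000, 2000))
  expect_equal(n_frames(parts$b0$gradients), 1L)
  expect_equal(parts$shell$data, dwi$data[, , , 3:4, drop = FALSE])

  dwi2 <- make_test_dwi(c(0, 995, 1005))
  parts2 <- extract_shell(dwi2, 1000, tolerance = 10)
  expect_equal(parts2$shell$gradients$bvalues, c(995, 1005))

  dwi3 <- make_test_dwi(c(0, 3000))
  expect_error(extract_shell(dwi3, 2000, tolerance = 100), "available b-values")
})

test_that("b0 normalization divides by the mean b0 and guards empty voxels", {
  dims <- c(3, 3, 3)
  shell_dat <- array(4, c(dims, 2))
  b0_dat <- array(2, c(dims, 1))
  b0_dat[1, 1, 1, 1] <- 0  # degenerate voxel
  shell <- make_test_dwi(c(1000, 1000), dims, shell_dat)
  b0 <- make_test_dwi(0, dims, b0_dat)
  norm <- suppressMessages(normalize_by_b0(shell, b0))
  expect_equal(norm$data[2, 2, 2, 1], 2)
  expect_equal(norm$data[1, 1, 1, 1], 0)
  expect_equal(attr(norm, "n_zero_b0"), 1L)
  # shell equal to b0 everywhere -> all ones (away from the degenerate voxel)
  shell_eq <- make_test_dwi(c(1000, 1000), dims,
                            array(rep(b0_dat, 2), c(dims, 2)))
  norm_eq <- suppressMessages(normalize_by_b0(shell_eq, b0))
  # the degenerate voxel is zeroed in both frames (linear indices 1 and 28)
  expect_equal(norm_eq$data[-c(1, 28)], rep(1, prod(dims) * 2 - 2),
               tolerance = 1e-12)
  expect_error(normalize_by_b0(shell, make_test_dwi(0, dims, array(0, c(dims, 1)))),
               "all-zero b0")
})

test_that("fit_sh solves the per-voxel least-squares problem", {
  set.seed(11)
  dirs <- fibonacci_directions(30, hemisphere = TRUE)
  B <- sh_basis(dirs, 4)
  cc <- rnorm(15)
  sig <- drop(B %*% cc)
  dat <- array(rep(sig, each = 8), c(2, 2, 2, 30))
  shell <- dwi_volume(dat, diag(4), gradient_table(dirs, rep(2000, 30)))
  sh <- fit_sh(shell, lmax = 4)
  expect_s3_class(sh, "sh_volume")
  expect_equal(dim(sh$coeffs)[4], 15L)
  expect_lt(max(abs(sh$coeffs[1, 1, 1, ] - cc)), 1e-6)
  # underdetermined: 10 directions for 15 coefficients
  shell10 <- dwi_volume(dat[, , , 1:10, drop = FALSE], diag(4),
                        gradient_table(dirs[1:10, ], rep(2000, 10)))
  expect_error(fit_sh(shell10, lmax = 4), "underdetermined")
  # coplanar directions are ill-conditioned
  flat <- dirs; flat[, 3] <- 0
  flat <- flat / sqrt(rowSums(flat^2))
  shell_flat <- dwi_volume(dat, diag(4), gradient_table(flat, rep(2000, 30)))
  expect_error(fit_sh(shell_flat, lmax = 4), "condition")
})

test_that("percentile clamping matches the interpolated order statistics", {
  vals <- sample(1:100)
  sh <- sh_volume(array(rep(vals, 15), c(100, 1, 1, 15)), lmax = 4)
  out <- clamp_outliers(sh, 5, 99)
  p <- quantile(1:100, c(0.05, 0.99), type = 7, names = FALSE)
  expect_equal(min(out$coeffs[, , , 1]), p[1])
  expect_equal(max(out$coeffs[, , , 1]), p[2])
  # idempotent up to re-interpolation within one order-statistic gap
  twice <- clamp_outliers(out, 5, 99)
  expect_equal(twice$coeffs, out$coeffs, tolerance = 0.01)
  # constant channel unchanged; 0/100 bounds are the identity
  shc <- sh_volume(array(2, c(10, 1, 1, 15)), lmax = 4)
  expect_equal(clamp_outliers(shc, 5, 99)$coeffs, shc$coeffs)
  expect_equal(clamp_outliers(sh, 0, 100)$coeffs, sh$coeffs)
  expect_error(clamp_outliers(sh, 5, 99, mask = array(0, c(100, 1, 1))),
               "empty mask")
})

test_that("greedy reordering keeps every prefix well spread", {
  # icosahedral-ish half-sphere set, deliberately badly ordered
  dirs <- fibonacci_directions(6, hemisphere = TRUE)
  bad_order <- c(1, 2, 3, 4, 5, 6)
  gt <- gradient_table(rbind(0, dirs[bad_order, ]), c(0, rep(1000, 6)))
  re <- reorder_gradients(gt)
  # permutation: same multiset of directions and bvalues
  perm <- attr(re, "permutation")
  expect_setequal(perm, 1:7)
  expect_equal(sort(re$bvalues), sort(gt$bvalues))
  # greedy prefix energies never exceed the input-order prefix energies
  e_greedy <- prefix_energies(re)
  e_input <- prefix_energies(gt)
  expect_true(all(e_greedy <= e_input + 1e-9))
  # idempotent on its own output
  re2 <- reorder_gradients(re)
  expect_equal(prefix_energies(re2), e_greedy, tolerance = 1e-12)
  # two orthogonal directions: both kept in the only unordered outcome
  gt2 <- gradient_table(rbind(0, c(1, 0, 0), c(0, 1, 0)), c(0, 1000, 1000))
  re2d <- reorder_gradients(gt2)
  expect_equal(sort(attr(re2d, "permutation")), 1:3)
  # duplicate directions warn and fall back to input order
  gtd <- gradient_table(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)),
                        rep(1000, 3))
  expect_warning(reorder_gradients(gtd), "duplicate")
})

test_that("truncation keeps the leading directions plus proportional b0s", {
  set.seed(5)
  bvals <- c(0, rep(1000, 90), 0)
  dwi <- make_test_dwi(bvals, dims = c(3, 3, 3))
  tr <- truncate_gradients(dwi, 45)
  expect_equal(sum(tr$gradients$bvalues > 50), 45L)
  expect_equal(sum(tr$gradients$bvalues <= 50), 1L)
  expect_equal(dim(tr$data)[4], n_frames(tr$gradients))
  # identity when keeping everything
  all_tr <- truncate_gradients(dwi, 90)
  expect_equal(dim(all_tr$data)[4], 92L)
  expect_error(truncate_gradients(dwi, 0), "cannot keep")
  expect_error(truncate_gradients(dwi, 91), "cannot keep")
})
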