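test_that("voxel quantiles interpolate order statistics per voxel", {
  # constant stack: every level equals the constant
  probs <- array(0.37, c(4, 2, 2, 1, 1))
  q <- voxel_quantiles(as_stack(probs), levels = c(0, 0.3, 1))
  expect_equal(as.vector(q), rep(0.37, 3 * 4))
  # known samples: [0.2, 0.4, 0.6, 0.8] at levels {0, 0.5, 1}
  probs2 <- array(c(0.6, 0.2, 0.8, 0.4), c(4, 1, 1, 1, 1))
  q2 <- voxel_quantiles(as_stack(probs2), levels = c(0, 0.5, 1))
  expect_equal(as.vector(q2), c(0.2, 0.5, 0.8))
  # matches stats::quantile type 7 on random data, any level
  set.seed(66)
  probs3 <- array(runif(7 * 3^3 * 2), c(7, 3, 3, 3, 2))
  lv <- c(0, 0.12, 0.5, 0.87, 1)
  q3 <- voxel_quantiles(as_stack(probs3), levels = lv)
  for (i in seq_along(lv)) {
    expect_equal(as.vector(q3[i, , , , ]),
                 as.vector(apply(probs3, 2:5, quantile, probs = lv[i],
                                 type = 7, names = FALSE)),
                 tolerance = 1e-12)
  }
  # non-decreasing in level at every voxel
  expect_true(all(apply(q3, 2:5, function(v) all(diff(v) >= -1e-12))))
  expect_error(voxel_quantiles(as_stack(probs3), levels = c(0.5, 0.2)),
               "non-decreasing")
})

test_that("quantile-volume curves sum soft volumes per level", {
  qm <- array(c(0.1, 0.5, 0.9), c(3, 1, 1, 1, 1))
  cv <- quantile_volume_curve(qm, tract = 1, levels = c(0, 0.5, 1))
  expect_equal(cv$volumes, c(0.1, 0.5, 0.9))
  # all-zero stack -> all-zero volumes
  z <- voxel_quantiles(as_stack(array(0, c(3, 2, 2, 2, 1))))
  expect_equal(quantile_volume_curve(z)$volumes, rep(0, 4))
  # two voxels at 0.5 with voxel volume 2 mm^3 -> 2.0 mm^3
  qm2 <- array(0.5, c(1, 2, 1, 1, 1))
  cv2 <- quantile_volume_curve(qm2, levels = 0.5, voxel_vol = 2)
  expect_equal(cv2$volumes, 2)
})

test_that("coverage level inverts the curve piecewise-linearly with clipping", {
  cv <- structure(list(levels = c(0, 0.5, 1), volumes = c(10, 20, 30),
                       tract = 1L, voxel_volume = 1),
                  class = "quantile_volume_curve")
  expect_equal(coverage_level(cv, 20), 0.5)
  expect_equal(coverage_level(cv, 15), 0.25)
  expect_equal(coverage_level(cv, 5), 0)
  expect_equal(coverage_level(cv, 35), 1)
  # ties resolve to the lowest crossing level
  cvt <- structure(list(levels = c(0, 0.25, 0.5, 1),
                        volumes = c(10, 20, 20, 30), tract = 1L,
                        voxel_volume = 1),
                   class = "quantile_volume_curve")
  expect_equal(coverage_level(cvt, 20), 0.25)
})

test_that("curve volumes are non-decreasing for random stacks", {
  set.seed(77)
  for (rep in 1:20) {
    probs <- array(runif(20 * 4^3), c(20, 4, 4, 4, 1))
    q <- voxel_quantiles(as_stack(probs))
    cv <- quantile_volume_curve(q)
    expect_true(all(diff(cv$volumes) >= -1e-9))
    # curve endpoints bracket the soft volume of the mean prediction
    mean_vol <- sum(apply(probs, 2:5, mean))
    expect_lte(cv$volumes[1], mean_vol + 1e-9)
    expect_gte(cv$volumes[21], mean_vol - 1e-9)
  }
})

make_curve <- function(vols, levels = seq(0, 1, length.out = length(vols)),
                       tract = 1L) {
  structure(list(levels = levels, volumes = vols, tract = tract,
                 voxel_volume = 1),
            class = "quantile_volume_curve")
}

test_that("calibration fitting inverts the empirical coverage distribution", {
  base <- make_curve(seq(50, 150, length.out = 21))
  # coverage levels on a uniform grid -> map close to the identity
  u_grid <- seq(0.1, 0.9, by = 0.1)
  val <- lapply(u_grid, function(u) {
    list(curve = base, v_gt = approx(base$levels, base$volumes, u)$y)
  })
  map <- fit_calibration(val)
  qs <- seq(0, 1, by = 0.05)
  expect_lt(max(abs(evaluate_calibration(map, qs) - qs)),
            1 / (length(u_grid) + 1) + 1e-9)
  # symmetric two-subject case: map(0.5) = 0.5
  val2 <- lapply(c(0.25, 0.75), function(u) {
    list(curve = base, v_gt = approx(base$levels, base$volumes, u)$y)
  })
  expect_equal(evaluate_calibration(fit_calibration(val2), 0.5), 0.5,
               tolerance = 1e-12)
  # saturation: ground truth above every curve
  val3 <- lapply(1:3, function(i) list(curve = base, v_gt = 500))
  expect_warning(map3 <- fit_calibration(val3), "identical")
  expect_equal(evaluate_calibration(map3, 0.5), 1)
})

test_that("applying calibration remaps levels monotonically", {
  cv <- make_curve(seq(10, 30, length.out = 11))
  ident <- structure(list(nominal = c(0, 0.5, 1), calibrated = c(0, 0.5, 1),
                          tract = 1L, n_validation = 2,
                          coverage_levels = c(0.25, 0.75)),
                     class = "calibration_map")
  out <- apply_calibration(cv, ident)
  expect_equal(out$volumes, cv$volumes, tolerance = 1e-12)
  # compressing map shrinks the spread of the calibrated curve
  compress <- structure(list(nominal = c(0, 0.5, 1),
                             calibrated = c(0.3, 0.5, 0.7), tract = 1L,
                             n_validation = 2, coverage_levels = c(0.3, 0.7)),
                        class = "calibration_map")
  out2 <- apply_calibration(cv, compress)
  expect_lt(diff(range(out2$volumes)), diff(range(cv$volumes)))
  expect_true(all(diff(out2$volumes) >= -1e-12))
  expect_error(apply_calibration(make_curve(1:3, tract = 2L), ident),
               "tract mismatch")
})

test_that("minimum volume difference matches the exhaustive search", {
  cv <- make_curve(c(10, 20))
  expect_equal(min_volume_difference(cv, 25), 5)
  expect_equal(min_volume_difference(cv, 20), 0)
  set.seed(3)
  vols <- sort(runif(21, 0, 100))
  cv2 <- make_curve(vols)
  for (gt in c(-5, 12.3, 50, 120)) {
    expect_equal(min_volume_difference(cv2, gt),
                 min(vapply(vols, function(v) abs(v - gt), numeric(1))))
  }
})

test_that("calibration maps serialize to JSON and back", {
  base <- make_curve(seq(50, 150, length.out = 21))
  val <- lapply(c(0.2, 0.5, 0.9), function(u) {
    list(curve = base, v_gt = approx(base$levels, base$volumes, u)$y)
  })
  map <- fit_calibration(val)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_maps(list(map), path)
  back <- read_calibration_maps(path)[[1]]
  expect_equal(back$nominal, map$nominal)
  expect_equal(back$calibrated, map$calibrated)
  expect_equal(back$tract, map$tract)
})
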