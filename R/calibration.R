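#' Per-voxel quantiles of a probability stack
#'
#' For every voxel and class, the empirical quantile (linear interpolation
#' between order statistics) of the T pass probabilities at each requested
#' level; level 0 is the per-voxel minimum and level 1 the maximum.
#'
#' @param stack A [run_stochastic()] result.
#' @param levels Non-decreasing quantile levels in [0, 1]; default is the
#'   T+1 grid `{0, 1/T, ..., 1}`.
#' @return 5D array (L, X, Y, Z, N), one probability volume per level.
#' @export
voxel_quantiles <- function(stack, levels = NULL) {
  d <- dim(stack$probs)
  t_ <- d[1]
  if (is.null(levels)) levels <- seq(0, 1, length.out = t_ + 1L)
  if (any(!is.finite(levels)) || any(levels < 0) || any(levels > 1) ||
      is.unsorted(levels)) {
    stop("levels must be non-decreasing values in [0, 1]")
  }
  pm <- matrix(stack$probs, t_, prod(d[-1]))
  srt <- apply(pm, 2, sort.int, method = "quick")
  if (t_ == 1L) srt <- matrix(srt, nrow = 1L)
  out <- array(0, c(length(levels), d[-1]))
  om <- matrix(out, length(levels), prod(d[-1]))
  h <- (t_ - 1) * levels
  lo <- pmin(floor(h), t_ - 1)
  fr <- h - lo
  for (i in seq_along(levels)) {
    v <- srt[lo[i] + 1L, ]
    if (fr[i] > 0) v <- v + fr[i] * (srt[lo[i] + 2L, ] - v)
    om[i, ] <- v
  }
  array(om, c(length(levels), d[-1]))
}

#' Quantile-volume curve of one tract
#'
#' The soft volume at quantile level k is the sum over voxels of the
#' level-k quantile probability, scaled by the voxel volume. Because order
#' statistics are monotone in the level, the curve is non-decreasing; it
#' summarizes the predicted volume distribution of the tract across the
#' stochastic passes.
#'
#' @param qmaps Output of [voxel_quantiles()].
#' @param tract Class index the curve is computed for.
#' @param levels The levels the quantile maps were computed at.
#' @param voxel_vol Voxel volume in mm^3 (1 reports voxel counts).
#' @return Object of class `quantile_volume_curve` with `$levels`,
#'   `$volumes`, `$tract`, `$voxel_volume`.
#' @export
quantile_volume_curve <- function(qmaps, tract = 1L, levels = NULL,
                                  voxel_vol = 1) {
  d <- dim(qmaps)
  if (is.null(levels)) levels <- seq(0, 1, length.out = d[1])
  stopifnot(length(levels) == d[1], tract >= 1, tract <= d[5])
  qm <- matrix(qmaps, d[1], prod(d[-1]))
  n_vox <- prod(d[2:4])
  cols <- ((tract - 1L) * n_vox + 1L):(tract * n_vox)
  vols <- rowSums(qm[, cols, drop = FALSE]) * voxel_vol
  structure(list(levels = levels, volumes = vols, tract = tract,
                 voxel_volume = voxel_vol),
            class = "quantile_volume_curve")
}

#' @export
print.quantile_volume_curve <- function(x, ...) {
  cat(sprintf(
    "quantile_volume_curve (tract %d): %d levels, V in [%.2f, %.2f] mm^3\n",
    x$tract, length(x$levels), min(x$volumes), max(x$volumes)))
  invisible(x)
}

#' Coverage level of a reference volume on a quantile-volume curve
#'
#' The quantile level at which the piecewise-linear interpolation of
#' (levels, volumes) crosses the reference volume; clipped to 0 below the
#' curve and 1 above it, ties (flat segments) resolved to the lowest
#' crossing level. For a validation subject with known ground-truth volume,
#' this is the nominal confidence level at which the prediction covers the
#' truth.
#'
#' @param curve A [quantile_volume_curve()].
#' @param v_ref Reference (e.g. ground-truth) volume.
#' @return Level in [0, 1].
#' @export
coverage_level <- function(curve, v_ref) {
  if (length(curve$volumes) == 0L) stop("empty quantile-volume curve")
  v <- curve$volumes
  lv <- curve$levels
  if (v_ref <= v[1]) {
    return(if (v_ref < v[1]) 0 else lv[min(which(v == v[1]))])
  }
  if (v_ref > v[length(v)]) return(1)
  i <- max(which(v < v_ref))
  # lowest crossing: first knot at/above v_ref, or linear interpolation
  j <- i + 1L
  if (v[j] == v_ref) return(lv[min(which(v == v_ref))])
  lv[i] + (lv[j] - lv[i]) * (v_ref - v[i]) / (v[j] - v[i])
}

#' Fit a per-tract calibration map on validation subjects
#'
#' Computes the coverage level of each validation subject's ground-truth
#' volume on its quantile-volume curve, then builds the monotone map that
#' sends a nominal level q to the empirical quantile of those coverage
#' levels (piecewise-linear empirical-CDF inverse, anchored at (0,0) and
#' (1,1)). Remapped coverage levels of subjects from the validation
#' distribution are then approximately uniform on [0, 1] -- the correct
#' proportion of ground-truth volumes falls inside each nominal confidence
#' interval.
#'
#' @param validation List of entries, each a list with `curve`
#'   (a [quantile_volume_curve()]) and `v_gt` (ground-truth volume).
#' @return Object of class `calibration_map` with monotone knots
#'   `$nominal` -> `$calibrated`.
#' @export
fit_calibration <- function(validation) {
  stopifnot(length(validation) >= 2)
  tract <- validation[[1]]$curve$tract
  u <- vapply(validation, function(s) {
    stopifnot(s$curve$tract == tract)
    coverage_level(s$curve, s$v_gt)
  }, numeric(1))
  if (max(u) - min(u) < 1e-12) {
    warning("all validation coverage levels identical (", round(u[1], 4),
            "); calibration map degenerates to a step")
  }
  n <- length(u)
  nominal <- c(0, seq_len(n) / (n + 1), 1)
  calibrated <- pmin(pmax(c(0, sort(u), 1), 0), 1)
  structure(list(nominal = nominal, calibrated = cummax(calibrated),
                 tract = tract, n_validation = n,
                 coverage_levels = sort(u)),
            class = "calibration_map")
}

#' Evaluate a calibration map at nominal levels
#'
#' @param map A [fit_calibration()] result.
#' @param q Nominal levels in [0, 1].
#' @return Calibrated levels in [0, 1].
#' @export
evaluate_calibration <- function(map, q) {
  stats::approx(map$nominal, map$calibrated, xout = pmin(pmax(q, 0), 1),
                ties = "ordered")$y
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("calibration_map (tract %d): fitted on %d subjects\n",
              x$tract, x$n_validation))
  invisible(x)
}

#' Apply a calibration map to a quantile-volume curve
#'
#' The calibrated curve reports, at nominal level k, the volume of the
#' original curve at the remapped level map(k) (piecewise-linear
#' interpolation). Monotone maps preserve curve monotonicity.
#'
#' @param curve A [quantile_volume_curve()].
#' @param map A [fit_calibration()] result for the same tract.
#' @return Calibrated `quantile_volume_curve`.
#' @export
apply_calibration <- function(curve, map) {
  if (curve$tract != map$tract) {
    stop("tract mismatch: curve is tract ", curve$tract, ", map is tract ",
         map$tract)
  }
  q_cal <- evaluate_calibration(map, curve$levels)
  v_cal <- stats::approx(curve$levels, curve$volumes, xout = q_cal,
                         ties = "ordered", rule = 2)$y
  structure(list(levels = curve$levels, volumes = v_cal,
                 tract = curve$tract, voxel_volume = curve$voxel_volume),
            class = "quantile_volume_curve")
}

#' Smallest volume error achievable on a curve
#'
#' Minimum over quantile levels of the absolute difference between the
#' curve volume and a reference volume; quantifies how close the predicted
#' volume distribution comes to the truth.
#'
#' @param curve A [quantile_volume_curve()].
#' @param v_gt Reference (ground-truth) volume.
#' @return Non-negative scalar.
#' @export
min_volume_difference <- function(curve, v_gt) {
  if (length(curve$volumes) == 0L) stop("empty quantile-volume curve")
  min(abs(curve$volumes - v_gt))
}

#' Save / load calibration maps as JSON
#'
#' @param maps A named list of [fit_calibration()] results (or one map).
#' @param path JSON file path.
#' @return `write_calibration_maps` returns the path invisibly;
#'   `read_calibration_maps` returns the list of maps.
#' @export
write_calibration_maps <- function(maps, path) {
  if (inherits(maps, "calibration_map")) maps <- list(maps)
  payload <- lapply(maps, function(m) {
    list(tract = m$tract, nominal = m$nominal, calibrated = m$calibrated,
         n_validation = m$n_validation, coverage_levels = m$coverage_levels)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_maps
#' @export
read_calibration_maps <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow_or_len(raw)), function(i) {
    m <- if (is.data.frame(raw)) lapply(raw, `[[`, i) else raw[[i]]
    structure(list(nominal = unlist(m$nominal),
                   calibrated = unlist(m$calibrated),
                   tract = m$tract, n_validation = m$n_validation,
                   coverage_levels = unlist(m$coverage_levels)),
              class = "calibration_map")
  })
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Read / write quantile-volume curves as CSV
#'
#' The CSV has columns `level` and `volume_mm3`; the tract id and voxel
#' volume travel in comment-free extra columns `tract` and `voxel_volume`.
#'
#' @param curve A [quantile_volume_curve()].
#' @param path CSV file path.
#' @return `write_curve_csv` returns the path invisibly; `read_curve_csv`
#'   the curve.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(level = curve$levels,
                              volume_mm3 = curve$volumes,
                              tract = curve$tract,
                              voxel_volume = curve$voxel_volume),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(levels = df$level, volumes = df$volume_mm3,
                 tract = df$tract[1], voxel_volume = df$voxel_volume[1]),
            class = "quantile_volume_curve")
}
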