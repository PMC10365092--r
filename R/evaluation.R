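#' Voxelwise confusion counts between binary masks
#'
#' @param pred,truth Binary arrays of equal shape.
#' @param eval_mask Optional mask restricting which voxels are counted
#'   (default: whole grid).
#' @return Object of class `confusion_counts` with tp, fp, tn, fn.
#' @export
confusion <- function(pred, truth, eval_mask = NULL) {
  if (!all(dim(pred) == dim(truth))) {
    stop("shape mismatch: pred ", paste(dim(pred), collapse = "x"),
         " vs truth ", paste(dim(truth), collapse = "x"))
  }
  p <- as.vector(pred != 0)
  t_ <- as.vector(truth != 0)
  if (!is.null(eval_mask)) {
    keep <- as.vector(eval_mask != 0)
    p <- p[keep]
    t_ <- t_[keep]
  }
  structure(list(tp = sum(p & t_), fp = sum(p & !t_),
                 tn = sum(!p & !t_), fn = sum(!p & t_)),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' `dice` is `2 tp / (2 tp + fp + fn)`; two empty masks give Dice 1 by
#' convention (attribute `degenerate` set). Sensitivity and specificity
#' support two conventions: `"standard"` gives the usual recall
#' `tp / (tp + fn)` and true-negative rate `tn / (tn + fp)`;
#' `"as_printed"` divides by the predicted counts instead
#' (`tp / (tp + fp)`, i.e. precision, and `tn / (tn + fn)`), a wording
#' sometimes found in the tract-segmentation literature. The default is
#' `"standard"`.
#'
#' @param counts A [confusion()] result.
#' @param convention `"standard"` or `"as_printed"`.
#' @return Scalar in [0, 1]; NA with attribute `degenerate` when the
#'   denominator is zero.
#' @export
dice <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(structure(1, degenerate = TRUE))
  2 * counts$tp / den
}

#' @rdname dice
#' @export
sensitivity <- function(counts, convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  den <- if (convention == "standard") counts$tp + counts$fn
         else counts$tp + counts$fp
  if (den == 0) return(structure(NA_real_, degenerate = TRUE))
  counts$tp / den
}

#' @rdname dice
#' @export
specificity <- function(counts, convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  den <- if (convention == "standard") counts$tn + counts$fp
         else counts$tn + counts$fn
  if (den == 0) return(structure(NA_real_, degenerate = TRUE))
  counts$tn / den
}

# Boundary voxels: foreground with at least one background face neighbor
# (6-connectivity); voxels on the grid edge count as boundary.
.boundary_voxels <- function(mask) {
  m <- array(mask != 0, dim(mask))
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  nb <- array(TRUE, d)
  sl <- function(off) pad[(2:(d[1] + 1L)) + off[1], (2:(d[2] + 1L)) + off[2],
                          (2:(d[3] + 1L)) + off[3]]
  all_nb <- sl(c(-1, 0, 0)) & sl(c(1, 0, 0)) & sl(c(0, -1, 0)) &
    sl(c(0, 1, 0)) & sl(c(0, 0, -1)) & sl(c(0, 0, 1))
  which(m & !all_nb, arr.ind = TRUE)
}

#' Directed surface distances between binary masks
#'
#' Boundaries are foreground voxels with a background face neighbor
#' (6-connectivity). Distances are Euclidean nearest-boundary distances in
#' mm, with voxel coordinates scaled by the axis spacing; both directions
#' (prediction to truth and truth to prediction) are returned.
#'
#' @param pred,truth Non-empty binary arrays of equal shape.
#' @param spacing mm per voxel along each axis (length 1 or 3).
#' @return Object of class `surface_distance_set` with `$pred_to_truth`
#'   and `$truth_to_pred`.
#' @export
surface_distances <- function(pred, truth, spacing = c(1, 1, 1)) {
  stopifnot(all(dim(pred) == dim(truth)))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!any(pred != 0) || !any(truth != 0)) {
    stop("surface distances undefined for an empty mask")
  }
  bp <- sweep(.boundary_voxels(pred), 2, spacing, "*")
  bt <- sweep(.boundary_voxels(truth), 2, spacing, "*")
  d2 <- function(a, b) {
    # rows of a to nearest row of b
    cross <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(pmax(apply(cross, 1, min), 0))
  }
  structure(list(pred_to_truth = d2(bp, bt), truth_to_pred = d2(bt, bp)),
            class = "surface_distance_set")
}

#' Hausdorff and average symmetric surface distance
#'
#' `hausdorff` is the maximum over both directed distance sets; `assd` is
#' the mean over the union of both sets.
#'
#' @param sd_set A [surface_distances()] result.
#' @return Distance in mm.
#' @export
hausdorff <- function(sd_set) {
  max(c(sd_set$pred_to_truth, sd_set$truth_to_pred))
}

#' @rdname hausdorff
#' @export
assd <- function(sd_set) {
  mean(c(sd_set$pred_to_truth, sd_set$truth_to_pred))
}

#' Volume variation coefficient of a stochastic stack
#'
#' Each pass is thresholded into a binary mask; the per-pass foreground
#' volumes V = [v_1, ..., v_T] summarize the structure-wise spread of the
#' prediction. VVC = sigma_V / mu_V (population SD). Scale-free: doubling
#' all volumes leaves it unchanged.
#'
#' @param stack A [run_stochastic()] result.
#' @param tract Class index.
#' @param threshold Binarization threshold (inclusive).
#' @return List with `volumes`, `mu`, `sigma` and `vvc` (NA when mu = 0).
#' @export
vvc <- function(stack, tract = 1L, threshold = 0.5) {
  d <- dim(stack$probs)
  stopifnot(d[1] >= 2, tract >= 1, tract <= d[5])
  v <- vapply(seq_len(d[1]), function(t_) {
    sum(stack$probs[t_, , , , tract] >= threshold)
  }, numeric(1))
  mu <- mean(v)
  sg <- sqrt(mean((v - mu)^2))
  structure(list(volumes = v, mu = mu, sigma = sg,
                 vvc = if (mu > 0) sg / mu else NA_real_),
            class = "volume_series")
}

#' Mean per-pass Dice of a stochastic stack
#'
#' Dice of each thresholded pass against the ground truth, averaged over
#' the T passes. Together with VVC this yields the uncertainty-vs-error
#' relation: across subjects, VVC is expected to rank with 1 - mean Dice.
#'
#' @param stack A [run_stochastic()] result.
#' @param truth 3D binary ground-truth mask of the tract.
#' @param tract Class index.
#' @param threshold Binarization threshold.
#' @return Mean Dice in [0, 1].
#' @export
mean_pass_dice <- function(stack, truth, tract = 1L, threshold = 0.5) {
  d <- dim(stack$probs)
  mean(vapply(seq_len(d[1]), function(t_) {
    dice(confusion(stack$probs[t_, , , , tract] >= threshold, truth))
  }, numeric(1)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' Strictly monotone tie-free pairs give exactly +1 or -1. Returns NA when
#' either sequence has zero rank variance.
#'
#' @param x,y Numeric sequences of equal length >= 3.
#' @return Correlation in [-1, 1], or NA.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  # perfect monotone tie-free relations are exactly +/-1 by definition;
  # the general correlation formula only reaches them up to rounding
  if (identical(rx, ry)) return(1)
  if (identical(rx, length(ry) + 1 - ry)) return(-1)
  stats::cor(rx, ry)
}

#' Residual map: truth minus mean probability
#'
#' Signed voxelwise residual in [-1, 1]; positive where the model
#' under-segments, negative where it over-segments.
#'
#' @param truth Binary array.
#' @param mean_prob Probability array of the same shape.
#' @return Numeric array of residuals.
#' @export
residual_map <- function(truth, mean_prob) {
  if (!all(dim(truth) == dim(mean_prob))) {
    stop("shape mismatch between truth and probability map")
  }
  (truth != 0) - mean_prob
}

#' Per-tract metric report for one subject
#'
#' @param pred 4D binary prediction (X, Y, Z, N).
#' @param truth 4D binary ground truth (X, Y, Z, N).
#' @param spacing mm per voxel (length 1 or 3).
#' @param stack Optional [run_stochastic()] result to add VVC and mean
#'   per-pass Dice.
#' @param convention Sensitivity/specificity convention, see [dice()].
#' @param subject Subject identifier recorded in the table.
#' @return data.frame, one row per tract: dice, sensitivity, specificity,
#'   assd_mm, hausdorff_mm and (if `stack` given) vvc, mean_pass_dice.
#' @export
metric_report <- function(pred, truth, spacing = c(1, 1, 1), stack = NULL,
                          convention = "standard", subject = NA) {
  stopifnot(length(dim(pred)) == 4L, all(dim(pred) == dim(truth)))
  n_class <- dim(pred)[4]
  rows <- lapply(seq_len(n_class), function(n) {
    cc <- confusion(pred[, , , n], truth[, , , n])
    hd <- NA_real_
    as_ <- NA_real_
    if (any(pred[, , , n] != 0) && any(truth[, , , n] != 0)) {
      sds <- surface_distances(pred[, , , n], truth[, , , n], spacing)
      hd <- hausdorff(sds)
      as_ <- assd(sds)
    }
    out <- data.frame(subject = subject, tract = n,
                      dice = as.numeric(dice(cc)),
                      sensitivity = as.numeric(sensitivity(cc, convention)),
                      specificity = as.numeric(specificity(cc, convention)),
                      assd_mm = as_, hausdorff_mm = hd,
                      convention = convention)
    if (!is.null(stack)) {
      out$vvc <- vvc(stack, n)$vvc
      out$mean_pass_dice <- mean_pass_dice(stack, truth[, , , n], n)
    }
    out
  })
  do.call(rbind, rows)
}

#' Aggregate a metric table into mean (SD) per metric
#'
#' @param report data.frame from [metric_report()] (possibly row-bound over
#'   subjects).
#' @return data.frame with one row per metric: mean and sd across rows.
#' @export
aggregate_metrics <- function(report) {
  num <- report[vapply(report, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("tract", "subject"))]
  data.frame(metric = names(num),
             mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1)),
             sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE),
                         numeric(1)),
             row.names = NULL)
}
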