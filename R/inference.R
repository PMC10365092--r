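#' Inference configuration
#'
#' @param mode One of "deterministic", "ttd" (test-time dropout), "tta"
#'   (test-time augmentation) or "hybrid" (both per pass).
#' @param passes Number of stochastic forward passes T (full-scale protocol:
#'   20); ignored for deterministic mode.
#' @param aug_range_deg Rotation range for TTA/hybrid passes (degrees).
#' @param window Sliding-window side; NULL fits the whole (padded) volume
#'   in one window of the training patch size supplied at call time.
#' @param overlap Fractional window overlap in [0, 1).
#' @param seed Master seed; each pass uses an independently derived stream,
#'   so pass t of a T-pass run equals pass t of any longer run.
#' @return Object of class `inference_config`.
#' @export
inference_config <- function(mode = c("deterministic", "ttd", "tta", "hybrid"),
                             passes = 20, aug_range_deg = 20, window = 16,
                             overlap = 0.5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(passes >= 1, overlap >= 0, overlap < 1, aug_range_deg >= 0)
  structure(list(mode = mode, passes = as.integer(passes),
                 aug_range_deg = aug_range_deg, window = as.integer(window),
                 overlap = overlap, seed = as.integer(seed)),
            class = "inference_config")
}

.pass_seed <- function(master, t) {
  as.integer((as.numeric(master) * 7919 + t * 104729) %% 2147483629)
}

.window_starts <- function(extent, window, overlap) {
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  s <- seq(1L, max(1L, extent - window + 1L), by = stride)
  if (s[length(s)] + window - 1L < extent) s <- c(s, extent - window + 1L)
  unique(s)
}

#' Whole-volume prediction by sliding-window aggregation
#'
#' Overlapping cubic windows cover the volume; per-voxel probabilities are
#' averaged with uniform weights over all windows containing the voxel.
#' Volumes smaller than the window are zero padded and cropped back.
#'
#' @param model A `unet3d_model`.
#' @param sh An [sh_volume()] (or bare 4D array of SH channels).
#' @param window Window side (divisible by `2^depth`).
#' @param overlap Fractional overlap in [0, 1).
#' @param dropout_active Enable encoder dropout (stochastic pass).
#' @return 4D array (X, Y, Z, N) of probabilities.
#' @export
predict_volume <- function(model, sh, window = 16, overlap = 0.5,
                           dropout_active = FALSE) {
  coeffs <- if (inherits(sh, "sh_volume")) sh$coeffs else sh
  dm <- dim(coeffs)
  if (dm[4] != model$config$in_channels) {
    stop("volume has ", dm[4], " channels; model expects ",
         model$config$in_channels)
  }
  if (window %% 2L^model$config$depth != 0L) {
    stop("window ", window, " not divisible by 2^depth = ",
         2L^model$config$depth)
  }
  pad_dims <- pmax(dm[1:3], window)
  padded <- array(0, c(pad_dims, dm[4]))
  padded[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]), ] <- coeffs
  n_class <- model$config$out_channels
  acc <- array(0, c(pad_dims, n_class))
  cnt <- array(0, pad_dims)
  sx <- .window_starts(pad_dims[1], window, overlap)
  sy <- .window_starts(pad_dims[2], window, overlap)
  sz <- .window_starts(pad_dims[3], window, overlap)
  for (x0 in sx) for (y0 in sy) for (z0 in sz) {
    rx <- x0:(x0 + window - 1L)
    ry <- y0:(y0 + window - 1L)
    rz <- z0:(z0 + window - 1L)
    patch <- padded[rx, ry, rz, , drop = FALSE]
    probs <- unet_forward(model, patch, dropout_active = dropout_active)
    acc[rx, ry, rz, ] <- acc[rx, ry, rz, , drop = FALSE] + probs
    cnt[rx, ry, rz] <- cnt[rx, ry, rz] + 1
  }
  out <- acc / as.vector(cnt)
  out[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]), , drop = FALSE]
}

#' Run stochastic inference (TTD, TTA or Hybrid)
#'
#' Executes T forward passes. TTD: encoder dropout is kept active. TTA: per
#' pass, a random rotation is applied to the input (grid and SH
#' coefficients together), the rotated volume is predicted, and the
#' probability maps are mapped back to subject space with the inverse
#' spatial rotation so voxelwise statistics over passes are aligned.
#' Hybrid: both. Per-pass random streams are derived from `cfg$seed`, so
#' results are reproducible and the first T passes of a longer run match a
#' shorter run.
#'
#' @param model A `unet3d_model`.
#' @param sh An [sh_volume()].
#' @param cfg An [inference_config()] with mode "ttd", "tta" or "hybrid".
#' @return Object of class `probability_stack`: `$probs` is a 5D array
#'   (T, X, Y, Z, N); `$transforms` records the per-pass rotation.
#' @export
run_stochastic <- function(model, sh, cfg) {
  if (cfg$mode == "deterministic") {
    stop("mode 'deterministic' has a single pass; use predict_volume()")
  }
  use_tta <- cfg$mode %in% c("tta", "hybrid")
  use_ttd <- cfg$mode %in% c("ttd", "hybrid")
  dm <- dim(sh$coeffs)
  n_class <- model$config$out_channels
  probs <- array(0, c(cfg$passes, dm[1:3], n_class))
  transforms <- vector("list", cfg$passes)
  for (t in seq_len(cfg$passes)) {
    set.seed(.pass_seed(cfg$seed, t))
    rot <- NULL
    input <- sh
    if (use_tta) {
      rot <- sample_rotation(cfg$aug_range_deg)
      input <- rotate_volume_and_sh(sh, NULL, rot)$sh
    }
    pred <- predict_volume(model, input, window = cfg$window,
                           overlap = cfg$overlap,
                           dropout_active = use_ttd)
    if (use_tta && max(abs(rot$angles)) > 0) {
      pred <- rotate_scalar_volume(pred, t(rotation_matrix(rot)),
                                   interpolation = "linear")
      pred <- pmin(pmax(pred, 0), 1)
    }
    probs[t, , , , ] <- pred
    transforms[[t]] <- rot
  }
  structure(list(probs = probs, mode = cfg$mode, transforms = transforms,
                 seed = cfg$seed),
            class = "probability_stack")
}

#' @export
print.probability_stack <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("probability_stack: %d passes (%s), %d x %d x %d, %d classes\n",
              d[1], x$mode, d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Mean prediction and uncertainty map of a stochastic stack
#'
#' The final segmentation probability is the voxelwise mean over the T
#' passes; the epistemic/aleatoric uncertainty map is the voxelwise SD
#' (population convention, divisor T).
#'
#' @param stack A [run_stochastic()] result.
#' @return List with `mean_prob` and `sd_map`, both (X, Y, Z, N) arrays.
#' @export
summarize_stack <- function(stack) {
  d <- dim(stack$probs)
  t_ <- d[1]
  pm <- matrix(stack$probs, t_, prod(d[-1]))
  mu <- colMeans(pm)
  sdv <- sqrt(colMeans(pm^2) - mu^2)
  sdv[sdv < 0 | !is.finite(sdv)] <- 0
  list(mean_prob = array(mu, d[-1]), sd_map = array(sdv, d[-1]))
}

#' Threshold probabilities into a binary tract mask
#'
#' Foreground where probability is greater than or equal to the threshold
#' (inclusive at 0.5, matching the evaluation convention).
#'
#' @param prob Probability array.
#' @param threshold Inclusive foreground threshold.
#' @return Integer 0/1 array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  array(as.integer(prob >= threshold), dim(prob))
}
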