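#' Desk-scale end-to-end study profile
#'
#' The package's scaled-down analog of the full training protocol: the tiny
#' network profile (depth 2, 16^3 patches) trained on a handful of 32^3
#' phantom subjects, evaluated with Hybrid stochastic inference on held-out
#' phantoms, plus a noise-sweep ensemble probing whether structure-wise
#' uncertainty (VVC) tracks segmentation error. All sizes are chosen so the
#' study runs on a single CPU in minutes; the vignette discusses what this
#' does and does not show about the full-scale protocol.
#'
#' @param seed Master seed for phantom generation, initialization, training
#'   and stochastic inference.
#' @param n_train Training subjects.
#' @param n_heldout Held-out evaluation subjects.
#' @param n_sweep Subjects in the noise sweep.
#' @param epochs Training epochs.
#' @param passes Stochastic passes T for Hybrid inference.
#' @return A list of configuration pieces consumed by [run_desk_study()].
#' @export
desk_study_profile <- function(seed = 7, n_train = 6, n_heldout = 2,
                               n_sweep = 8, epochs = 50, passes = 10) {
  list(seed = as.integer(seed), n_train = n_train, n_heldout = n_heldout,
       n_sweep = n_sweep,
       phantom = phantom_spec(),
       # from near-noiseless to severely degraded (b0 SNR 100 down to 2.5):
       # the uncertainty-vs-error association can only be measured if the
       # ensemble actually spans low to high segmentation error
       sweep_noise_sds = seq(1, 40, length.out = n_sweep),
       model = unet_config(in_channels = 15, out_channels = 3, depth = 2,
                           base_filters = 8, dropout_rate = 0.25,
                           head_bias = -2.5),
       train = train_config(epochs = epochs, initial_lr = 5e-3,
                            lr_halving_period = 20, weight_decay = 1e-6,
                            optimizer = "adam", patch_size = 16,
                            patches_per_subject = 10, aug_range_deg = 15,
                            seed = seed),
       infer = inference_config(mode = "hybrid", passes = passes,
                                aug_range_deg = 15, window = 32,
                                overlap = 0.5, seed = seed))
}

#' Run the desk-scale end-to-end study
#'
#' Generates phantoms, preprocesses them to clamped SH volumes, trains the
#' tiny U-Net profile, runs Hybrid stochastic inference on held-out
#' phantoms, and evaluates: per-tract Dice of the thresholded mean
#' prediction, the Spearman correlation between VVC and 1 - mean-pass Dice
#' across a noise sweep, and quantile-volume curves for the held-out
#' subjects.
#'
#' @param profile A [desk_study_profile()].
#' @param verbose Print progress.
#' @return List with `model`, `loss`, `heldout` (per-subject metric tables,
#'   stacks summarized), `mean_dice`, `sweep` (per-subject VVC and mean-pass
#'   Dice), `spearman_vvc_error`.
#' @export
run_desk_study <- function(profile = desk_study_profile(), verbose = FALSE) {
  seed <- profile$seed
  say <- function(...) if (verbose) message(...)
  say("generating phantoms")
  train_subjects <- make_dataset(profile$n_train, profile$phantom,
                                 seed = seed)
  heldout_subjects <- make_dataset(profile$n_heldout, profile$phantom,
                                   seed = seed + 1000L)
  sweep_subjects <- make_dataset(profile$n_sweep, profile$phantom,
                                 seed = seed + 2000L,
                                 noise_sds = profile$sweep_noise_sds)
  say("preprocessing")
  prep <- function(s) suppressMessages(prepare_subject(s))
  train_prep <- lapply(train_subjects, prep)
  held_prep <- lapply(heldout_subjects, prep)
  sweep_prep <- lapply(sweep_subjects, prep)

  say("training")
  model <- build_model(profile$model, seed = seed)
  fit <- train_model(model, train_prep, profile$train)
  model <- fit$model

  say("hybrid inference on held-out phantoms")
  n_class <- profile$model$out_channels
  heldout <- list()
  dices <- c()
  for (i in seq_along(held_prep)) {
    cfg <- profile$infer
    cfg$seed <- seed + 100L + i
    stack <- run_stochastic(model, held_prep[[i]]$sh, cfg)
    sm <- summarize_stack(stack)
    pred_bin <- binarize(sm$mean_prob)
    report <- metric_report(pred_bin, held_prep[[i]]$masks, stack = stack,
                            subject = i)
    qmaps <- voxel_quantiles(stack)
    curves <- lapply(seq_len(n_class), function(n) {
      quantile_volume_curve(qmaps, tract = n,
                            voxel_vol = voxel_volume(held_prep[[i]]$sh$affine))
    })
    gt_vols <- vapply(seq_len(n_class), function(n) {
      sum(held_prep[[i]]$masks[, , , n] != 0) *
        voxel_volume(held_prep[[i]]$sh$affine)
    }, numeric(1))
    heldout[[i]] <- list(report = report, curves = curves, gt_vols = gt_vols,
                         sd_mean = mean(sm$sd_map))
    dices <- c(dices, report$dice)
  }

  say("noise sweep for uncertainty vs error")
  sweep <- data.frame(subject = seq_along(sweep_prep),
                      noise_sd = profile$sweep_noise_sds,
                      vvc = NA_real_, mean_pass_dice = NA_real_)
  for (i in seq_along(sweep_prep)) {
    cfg <- profile$infer
    cfg$seed <- seed + 500L + i
    stack <- run_stochastic(model, sweep_prep[[i]]$sh, cfg)
    vv <- vapply(seq_len(n_class), function(n) vvc(stack, n)$vvc, numeric(1))
    md <- vapply(seq_len(n_class), function(n) {
      mean_pass_dice(stack, sweep_prep[[i]]$masks[, , , n], n)
    }, numeric(1))
    sweep$vvc[i] <- mean(vv, na.rm = TRUE)
    sweep$mean_pass_dice[i] <- mean(md)
  }
  rho <- spearman(sweep$vvc, 1 - sweep$mean_pass_dice)

  list(model = model, loss = fit$loss, heldout = heldout,
       mean_dice = mean(dices), sweep = sweep, spearman_vvc_error = rho)
}
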