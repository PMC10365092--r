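#' Per-class weights from positive-voxel counts
#'
#' Counts positive voxels of every tract class over all training subjects
#' and weights each class by `max(C) / c_n`, so rare tracts contribute as
#' much to the loss as common ones. The largest class gets weight 1.
#'
#' @param masks A single 4D tract mask array (X, Y, Z, N) or a list of them
#'   (one per subject).
#' @return Object of class `class_weights` with `$counts` and `$weights`.
#' @export
compute_class_weights <- function(masks) {
  if (!is.list(masks)) masks <- list(masks)
  stopifnot(length(masks) >= 1)
  counts <- Reduce(`+`, lapply(masks, function(m) {
    stopifnot(length(dim(m)) == 4L)
    apply(m != 0, 4, sum)
  }))
  if (any(counts == 0)) {
    stop("class with no positive voxels in the training set: class ",
         paste(which(counts == 0), collapse = ", "))
  }
  structure(list(counts = counts, weights = max(counts) / counts),
            class = "class_weights")
}

#' Weighted binary cross-entropy loss
#'
#' `-(1/N) * sum_n w_n * sum_j [y log(p) + (1-y) log(1-p)]` over voxels j
#' and classes n, with predictions clipped to `[eps, 1-eps]`. With
#' `voxel_mean = TRUE` the result is additionally divided by the voxel
#' count J, decoupling the loss scale (and hence the learning rate) from
#' the patch size; the training loop uses that form.
#'
#' @param pred Predicted probabilities, (J x N) matrix or array with class
#'   as last dimension.
#' @param target Binary targets of the same shape.
#' @param weights A [compute_class_weights()] object, a numeric vector of N
#'   weights, or NULL for unit weights.
#' @param voxel_mean Divide by the number of voxels J.
#' @param eps Clipping bound keeping the logs finite.
#' @return Non-negative scalar loss.
#' @export
wbce_loss <- function(pred, target, weights = NULL, voxel_mean = FALSE,
                      eps = 1e-7) {
  pred <- .as_class_matrix(pred)
  target <- .as_class_matrix(target)
  if (!all(dim(pred) == dim(target))) {
    stop("shape mismatch: pred ", paste(dim(pred), collapse = "x"),
         " vs target ", paste(dim(target), collapse = "x"))
  }
  n_class <- ncol(pred)
  w <- .weights_vector(weights, n_class)
  p <- pmin(pmax(pred, eps), 1 - eps)
  per_class <- -colSums(target * log(p) + (1 - target) * log(1 - p))
  loss <- sum(w * per_class) / n_class
  if (voxel_mean) loss <- loss / nrow(pred)
  loss
}

.as_class_matrix <- function(x) {
  if (is.null(dim(x))) return(matrix(x, ncol = 1L))
  d <- dim(x)
  if (length(d) == 2L) x else matrix(x, prod(d[-length(d)]), d[length(d)])
}

.weights_vector <- function(weights, n_class) {
  if (is.null(weights)) return(rep(1, n_class))
  w <- if (inherits(weights, "class_weights")) weights$weights else weights
  stopifnot(length(w) == n_class)
  w
}

#' Sample training patches from within the brain mask
#'
#' Patch centers are uniform draws (with replacement) from in-mask voxels;
#' patches crossing the volume border are zero padded. Reproducible from
#' the current R random stream.
#'
#' @param sh An [sh_volume()].
#' @param masks 4D tract mask array (X, Y, Z, N).
#' @param brain 3D brain mask.
#' @param n Number of patches.
#' @param size Patch side length.
#' @return List with `inputs` (n, S, S, S, M), `targets` (n, S, S, S, N)
#'   and `centers` (n x 3 voxel indices).
#' @export
sample_patches <- function(sh, masks, brain, n, size) {
  dm <- dim(sh$coeffs)
  stopifnot(all(dim(brain) == dm[1:3]), length(dim(masks)) == 4L)
  in_mask <- which(brain != 0)
  if (length(in_mask) == 0L) stop("empty brain mask: no voxels to sample")
  m <- dm[4]
  n_class <- dim(masks)[4]
  inputs <- array(0, c(n, size, size, size, m))
  targets <- array(0, c(n, size, size, size, n_class))
  centers <- matrix(0L, n, 3L)
  if (n == 0L) return(list(inputs = inputs, targets = targets,
                           centers = centers))
  picks <- in_mask[sample.int(length(in_mask), n, replace = TRUE)]
  ijk <- arrayInd(picks, dm[1:3])
  half <- size %/% 2L
  for (b in seq_len(n)) {
    centers[b, ] <- ijk[b, ]
    lo <- ijk[b, ] - half
    src <- lapply(1:3, function(a) {
      r <- lo[a] + seq_len(size) - 1L
      r[r < 1L | r > dm[a]] <- NA_integer_
      r
    })
    ok <- lapply(src, function(r) which(!is.na(r)))
    inputs[b, ok[[1]], ok[[2]], ok[[3]], ] <-
      sh$coeffs[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]], ]
    targets[b, ok[[1]], ok[[2]], ok[[3]], ] <-
      masks[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]], ]
  }
  list(inputs = inputs, targets = targets, centers = centers)
}

#' Training configuration
#'
#' Defaults follow the full-scale training protocol: 400 epochs, initial
#' learning rate 1e-3 halved every 50 epochs, weight decay 1e-6, encoder
#' dropout 0.25, rotation augmentation range 20 degrees. The desk-scale
#' profile overrides epochs, patch size and patches per subject.
#'
#' @param epochs Number of epochs (each subject visited once per epoch).
#' @param initial_lr Initial learning rate.
#' @param lr_halving_period Epochs between learning-rate halvings.
#' @param weight_decay L2 weight decay coefficient.
#' @param optimizer `"adam"` (default; adaptive steps converge within a
#'   desk-scale epoch budget) or `"sgd"` (momentum SGD).
#' @param momentum SGD momentum (ignored by adam).
#' @param patch_size Cubic patch side.
#' @param patches_per_subject Patches sampled per subject visit.
#' @param aug_range_deg Rotation augmentation half-range in degrees
#'   (0 disables augmentation).
#' @param seed Master seed for sampling, augmentation and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 400, initial_lr = 1e-3,
                         lr_halving_period = 50, weight_decay = 1e-6,
                         optimizer = c("adam", "sgd"), momentum = 0.9,
                         patch_size = 64, patches_per_subject = 50,
                         aug_range_deg = 20, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 0, initial_lr > 0, lr_halving_period >= 1,
            weight_decay >= 0, patch_size >= 4, patches_per_subject >= 1)
  structure(list(epochs = epochs, initial_lr = initial_lr,
                 lr_halving_period = lr_halving_period,
                 weight_decay = weight_decay, optimizer = optimizer,
                 momentum = momentum, patch_size = patch_size,
                 patches_per_subject = patches_per_subject,
                 aug_range_deg = aug_range_deg, seed = seed),
            class = "train_config")
}

#' Learning rate at an epoch
#'
#' Step schedule: `initial_lr * 0.5 ^ floor(epoch / period)` with epochs
#' counted from 0.
#'
#' @param epoch Zero-based epoch index.
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  cfg$initial_lr * 0.5^(epoch %/% cfg$lr_halving_period)
}

# Optimizer state and updates over the nested parameter/gradient lists.
# Leaves are visited with a closure so SGD-momentum and Adam share the
# traversal.
.walk_params <- function(params, grads, state, fn) {
  for (nm in names(grads)) {
    for (sub in names(grads[[nm]])) {
      gg <- grads[[nm]][[sub]]
      if (is.list(gg)) {
        for (k in seq_along(gg)) {
          r <- fn(params[[nm]][[sub]][[k]], gg[[k]],
                  lapply(state, function(s) s[[nm]][[sub]][[k]]))
          params[[nm]][[sub]][[k]] <- r$p
          for (sn in names(r$state)) state[[sn]][[nm]][[sub]][[k]] <- r$state[[sn]]
        }
      } else {
        r <- fn(params[[nm]][[sub]], gg,
                lapply(state, function(s) s[[nm]][[sub]]))
        params[[nm]][[sub]] <- r$p
        for (sn in names(r$state)) state[[sn]][[nm]][[sub]] <- r$state[[sn]]
      }
    }
  }
  list(params = params, state = state)
}

.sgd_update <- function(params, grads, state, lr, momentum, wd) {
  .walk_params(params, grads, state, function(p, g, st) {
    v <- momentum * st$v - lr * (g + wd * p)
    list(p = p + v, state = list(v = v))
  })
}

.adam_update <- function(params, grads, state, lr, wd, step,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^step
  c2 <- 1 - beta2^step
  .walk_params(params, grads, state, function(p, g, st) {
    g <- g + wd * p
    m <- beta1 * st$m + (1 - beta1) * g
    v <- beta2 * st$v + (1 - beta2) * g^2
    list(p = p - lr * (m / c1) / (sqrt(v / c2) + eps),
         state = list(m = m, v = v))
  })
}

.zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

#' Train the segmentation network
#'
#' Per epoch, every subject is visited once in random order; per visit a
#' fresh random rotation augments the subject (grid and SH coefficients
#' together) and a fresh set of patches is sampled from the brain mask. The
#' class-weighted binary cross-entropy (voxel-mean form) is minimized with
#' SGD (momentum, weight decay, halving learning-rate schedule). Fully
#' reproducible given `cfg$seed`.
#'
#' @param model A [build_model()] result.
#' @param subjects List of subjects, each a list with elements `sh`
#'   ([sh_volume()]), `masks` (4D tract array) and `brain` (3D mask).
#' @param cfg A [train_config()].
#' @param weights Optional precomputed [compute_class_weights()]; computed
#'   from `subjects` when NULL.
#' @param verbose Print per-epoch loss.
#' @return List with the trained `model`, per-epoch `loss` vector and the
#'   class `weights` used.
#' @export
train_model <- function(model, subjects, cfg, weights = NULL,
                        verbose = FALSE) {
  stopifnot(length(subjects) >= 1)
  if (is.null(weights)) {
    weights <- compute_class_weights(lapply(subjects, `[[`, "masks"))
  }
  if (cfg$epochs == 0) {
    return(list(model = model, loss = numeric(0), weights = weights))
  }
  set.seed(cfg$seed)
  n_class <- model$config$out_channels
  w <- weights$weights
  opt_state <- if (cfg$optimizer == "adam") {
    list(m = .zero_like(model$params), v = .zero_like(model$params))
  } else {
    list(v = .zero_like(model$params))
  }
  opt_step <- 0L
  loss_log <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at(ep - 1L, cfg)
    ep_loss <- 0
    n_batches <- 0L
    for (si in sample(length(subjects))) {
      sub <- subjects[[si]]
      if (cfg$aug_range_deg > 0) {
        rot <- sample_rotation(cfg$aug_range_deg)
        rr <- rotate_volume_and_sh(sub$sh, list(masks = sub$masks,
                                                brain = sub$brain), rot)
        sub <- list(sh = rr$sh, masks = rr$masks$masks,
                    brain = rr$masks$brain)
      }
      batch <- sample_patches(sub$sh, sub$masks, sub$brain,
                              cfg$patches_per_subject, cfg$patch_size)
      np <- cfg$patches_per_subject
      grads_acc <- NULL
      batch_loss <- 0
      for (b in seq_len(np)) {
        dims <- rep(cfg$patch_size, 3L)
        x <- matrix(batch$inputs[b, , , , ], prod(dims),
                    model$config$in_channels)
        y <- matrix(batch$targets[b, , , , ], prod(dims), n_class)
        fwd <- .unet_forward_mat(model, x, dims, dropout_active = TRUE,
                                 want_cache = TRUE)
        p <- nn_sigmoid(fwd$logits)
        batch_loss <- batch_loss + wbce_loss(p, y, w, voxel_mean = TRUE)
        dlogits <- sweep(p - y, 2, w, "*") / (n_class * nrow(p) * np)
        g <- .unet_backward_mat(model, fwd, dlogits)
        grads_acc <- if (is.null(grads_acc)) g else .add_grads(grads_acc, g)
      }
      if (!is.finite(batch_loss)) {
        stop("non-finite training loss at epoch ", ep, ", subject ", si,
             " (lr = ", lr, ")")
      }
      opt_step <- opt_step + 1L
      upd <- if (cfg$optimizer == "adam") {
        .adam_update(model$params, grads_acc, opt_state, lr,
                     cfg$weight_decay, opt_step)
      } else {
        .sgd_update(model$params, grads_acc, opt_state, lr, cfg$momentum,
                    cfg$weight_decay)
      }
      model$params <- upd$params
      opt_state <- upd$state
      ep_loss <- ep_loss + batch_loss / np
      n_batches <- n_batches + 1L
    }
    loss_log[ep] <- ep_loss / n_batches
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.5f", ep, lr, loss_log[ep]))
    }
  }
  list(model = model, loss = loss_log, weights = weights)
}

.add_grads <- function(a, b) {
  for (nm in names(a)) for (sub in names(a[[nm]])) {
    if (is.list(a[[nm]][[sub]])) {
      for (k in seq_along(a[[nm]][[sub]])) {
        a[[nm]][[sub]][[k]] <- a[[nm]][[sub]][[k]] + b[[nm]][[sub]][[k]]
      }
    } else {
      a[[nm]][[sub]] <- a[[nm]][[sub]] + b[[nm]][[sub]]
    }
  }
  a
}

#' Seeded subject-level train/validation split
#'
#' @param n_subjects Total number of subjects.
#' @param val_fraction Fraction held out for validation (full-scale protocol:
#'   0.1).
#' @param seed Split seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_subjects <- function(n_subjects, val_fraction = 0.1, seed = 1) {
  stopifnot(n_subjects >= 2, val_fraction > 0, val_fraction < 1)
  set.seed(seed)
  n_val <- max(1L, round(n_subjects * val_fraction))
  val <- sort(sample.int(n_subjects, n_val))
  list(train = setdiff(seq_len(n_subjects), val), validation = val)
}
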