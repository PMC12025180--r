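# Training: Adam optimization, augmentation, single-condition training,
# multi-condition distillation with condition cycling, photocoagulation
# pretraining, and two-annotator target interpolation.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size images per optimization step (default 10).
#' @param epochs training epochs (default 500); an epoch is one full pass
#'   over a condition's training split.
#' @param augmentation list with `shift` (max |pixels|), `rotation` (max
#'   |degrees|), `flip_prob`, `jitter` (max relative brightness/contrast
#'   change), `noise_sd`; all zero disables augmentation.
#' @param seed training seed (shuffling, augmentation draws).
#' @param condition_cycling cycle conditions one epoch at a time
#'   (multi-condition training).
#' @param two_annotations train on interpolated two-annotator targets with
#'   expanded condition-annotator codes.
#' @param pretrain_checkpoint optional checkpoint path loaded before
#'   training (inter-modality pretraining).
#' @param eval_every evaluate the test split every this many epochs (the
#'   trace still records one row per epoch, carrying the last evaluation
#'   forward).
#' @return an object of class `faz_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 10L, epochs = 500L,
                         augmentation = list(shift = 8, rotation = 15,
                                             flip_prob = 0.5, jitter = 0.1,
                                             noise_sd = 0.02),
                         seed = 0L, condition_cycling = TRUE,
                         two_annotations = FALSE, pretrain_checkpoint = NULL,
                         eval_every = 1L) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augmentation = augmentation,
                 seed = as.integer(seed), condition_cycling = isTRUE(condition_cycling),
                 two_annotations = isTRUE(two_annotations),
                 pretrain_checkpoint = pretrain_checkpoint,
                 eval_every = as.integer(eval_every)),
            class = "faz_train_config")
}

## ---- Adam ------------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

# Lazy Adam: parameters that received no gradient in this step (e.g. inactive
# teacher decoders) are left bit-identical, so gradient routing is exact.
adam_step <- function(store, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state$m[[nm]]
    if (is.null(m)) m <- g * 0
    v <- state$v[[nm]]
    if (is.null(v)) v <- g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    store$params[[nm]] <- store$params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  invisible(NULL)
}

## ---- augmentation ----------------------------------------------------------

rotate_nn <- function(mat, angle_deg, bilinear = FALSE) {
  n <- nrow(mat)
  th <- angle_deg * pi / 180
  c0 <- (n + 1) / 2
  xs <- rep(seq_len(n), each = n) - c0   # x (col)
  ys <- rep(seq_len(n), times = n) - c0  # y (row)
  sx <- cos(th) * xs + sin(th) * ys + c0
  sy <- -sin(th) * xs + cos(th) * ys + c0
  out <- matrix(0, n, n)
  if (bilinear) {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    val <- function(yy, xx) {
      ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= n
      v <- numeric(length(yy))
      v[ok] <- mat[cbind(yy[ok], xx[ok])]
      v
    }
    v <- (1 - fx) * (1 - fy) * val(y0, x0) + fx * (1 - fy) * val(y0, x0 + 1) +
      (1 - fx) * fy * val(y0 + 1, x0) + fx * fy * val(y0 + 1, x0 + 1)
  } else {
    xr <- round(sx); yr <- round(sy)
    ok <- xr >= 1 & xr <= n & yr >= 1 & yr <= n
    v <- numeric(length(xs))
    v[ok] <- mat[cbind(yr[ok], xr[ok])]
  }
  out[cbind(rep(seq_len(n), times = n), rep(seq_len(n), each = n))] <- v
  out
}

shift_mat <- function(mat, dy, dx) {
  n <- nrow(mat); m <- ncol(mat)
  out <- matrix(0, n, m)
  ys <- seq_len(n) - dy; xs <- seq_len(m) - dx
  oky <- ys >= 1 & ys <= n; okx <- xs >= 1 & xs <= m
  out[which(oky), which(okx)] <- mat[ys[oky], xs[okx]]
  out
}

#' Augment an image/mask batch
#'
#' Identical geometric transforms (integer shifts, rotations, flips) are
#' applied to image and mask (nearest-neighbour resampling keeps the mask
#' binary); photometric transforms (brightness/contrast jitter, additive
#' zero-mean Gaussian noise) touch the image only.
#'
#' @param batch list with `images` and `masks` (lists of matrices; masks may
#'   be soft interpolation targets).
#' @param config a [train_config()]; magnitudes come from
#'   `config$augmentation`.
#' @param rng_seed integer seed.
#' @return batch of the same shape.
#' @export
augment <- function(batch, config, rng_seed) {
  a <- config$augmentation
  with_seed(derive_seed(rng_seed, "augment"), {
    for (i in seq_along(batch$images)) {
      img <- batch$images[[i]]
      msk <- batch$masks[[i]]
      if ((a$shift %||% 0) > 0) {
        dy <- sample(-a$shift:a$shift, 1); dx <- sample(-a$shift:a$shift, 1)
        if (dy != 0 || dx != 0) {
          img <- shift_mat(img, dy, dx)
          msk <- shift_mat(msk, dy, dx)
        }
      }
      if ((a$rotation %||% 0) > 0) {
        ang <- stats::runif(1, -a$rotation, a$rotation)
        img <- rotate_nn(img, ang, bilinear = TRUE)
        msk <- rotate_nn(msk, ang, bilinear = FALSE)
      }
      if ((a$flip_prob %||% 0) > 0) {
        if (stats::runif(1) < a$flip_prob) {
          img <- img[, rev(seq_len(ncol(img)))]
          msk <- msk[, rev(seq_len(ncol(msk)))]
        }
        if (stats::runif(1) < a$flip_prob) {
          img <- img[rev(seq_len(nrow(img))), ]
          msk <- msk[rev(seq_len(nrow(msk))), ]
        }
      }
      if ((a$jitter %||% 0) > 0) {
        img <- img * (1 + stats::runif(1, -a$jitter, a$jitter)) +
          stats::runif(1, -a$jitter, a$jitter) * 0.5
      }
      if ((a$noise_sd %||% 0) > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, a$noise_sd), nrow(img))
      }
      batch$images[[i]] <- pmin(pmax(img, 0), 1)
      batch$masks[[i]] <- msk
    }
    batch
  })
}

#' Interpolate two annotators' masks into a soft target
#'
#' `target = lambda * mask1 + (1 - lambda) * mask2`, paired with the
#' expanded condition-annotator code `lambda * e(cond, ann1) + (1 - lambda) *
#' e(cond, ann2)`. Interpolation effectively expands the dataset and
#' averages out systematic annotator biases; the endpoints reproduce
#' single-annotator training exactly.
#'
#' @param masks list of exactly 2 binary masks.
#' @param condition_index condition slot (1-based).
#' @param n_conditions number of conditions.
#' @param lambda mixing weight in `[0, 1]`; `NULL` draws Uniform(0, 1).
#' @param rng_seed seed used when `lambda` is `NULL`.
#' @return list with `target` (values in `{0, lambda, 1 - lambda, 1}`),
#'   `code` (length `2 * n_conditions`), and `lambda`.
#' @export
interpolate_annotations <- function(masks, condition_index, n_conditions,
                                    lambda = NULL, rng_seed = 0L) {
  if (length(masks) != 2L) stop("exactly 2 annotator masks are required")
  if (is.null(lambda)) {
    lambda <- with_seed(derive_seed(rng_seed, "lambda"), stats::runif(1))
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  target <- lambda * masks[[1]] + (1 - lambda) * masks[[2]]
  code <- numeric(2L * n_conditions)
  code[2L * (condition_index - 1L) + 1L] <- lambda
  code[2L * (condition_index - 1L) + 2L] <- 1 - lambda
  list(target = target, code = condition_code(code, 2L * n_conditions), lambda = lambda)
}

## ---- dataset plumbing ------------------------------------------------------

#' Slice a dataset into a training/evaluation view
#'
#' Selects manifest rows and pins one annotator's mask as the target,
#' producing the `images`/`masks` list structure the training functions
#' consume.
#'
#' @param ds in-memory dataset from [generate_dataset()] or [load_dataset()].
#' @param rows integer manifest row indices.
#' @param annotator annotator index whose mask becomes the target.
#' @return list with `images`, `masks`, `all_masks`, `manifest`.
#' @export
dataset_view <- function(ds, rows, annotator = 1L) {
  list(images = ds$images[rows], masks = lapply(ds$masks[rows], `[[`, annotator),
       all_masks = ds$masks[rows], manifest = ds$manifest[rows, , drop = FALSE])
}

stack_images <- function(lst) {
  n <- nrow(lst[[1]])
  out <- array(0, c(length(lst), n, ncol(lst[[1]])))
  for (i in seq_along(lst)) out[i, , ] <- lst[[i]]
  out
}

eval_dice <- function(model, view, condition = NULL, chunk = 10L) {
  n <- length(view$images)
  ds <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    X <- stack_images(view$images[i:j])
    pb <- faz_predict(model, X, condition = condition)
    for (k in i:j) {
      ds[k] <- dice_index(pb[k - i + 1L, , ] >= 0.5, view$masks[[k]] > 0.5)
    }
    i <- j + 1L
  }
  mean(ds)
}

make_batches <- function(n, batch_size, shuffle_seed) {
  ord <- with_seed(shuffle_seed, sample.int(n))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train a single-condition model
#'
#' Optimizes the hybrid Dice + BCE loss plus the L1 sparsity penalties with
#' Adam on the base encoder-decoder (no teachers, no condition code).
#'
#' @param dataset in-memory dataset (from [generate_dataset()] or
#'   [load_dataset()]) restricted to one condition; or any list with
#'   `images` and `masks`.
#' @param model a `faz_model`.
#' @param config a [train_config()].
#' @param weights a [loss_weights()].
#' @param test optional held-out view evaluated each epoch (Dice trace).
#' @param annotator annotator index used as training target.
#' @return list with `model`, `trace` (data.frame: epoch, split, dice, loss
#'   and its components), and `optimizer` state.
#' @export
train_single_condition <- function(dataset, model, config = train_config(),
                                   weights = loss_weights(model$config$n_stages),
                                   test = NULL, annotator = 1L) {
  view <- if (!is.null(dataset$manifest) && length(dataset$masks) > 0 &&
              is.list(dataset$masks[[1]])) {
    dataset_view(dataset, seq_len(nrow(dataset$manifest)), annotator)
  } else dataset
  n <- length(view$images)
  if (n == 0L) stop("empty training split")
  opt <- adam_state()
  rows <- list()
  last_test <- NA_real_
  for (ep in seq_len(config$epochs)) {
    batches <- make_batches(n, config$batch_size, derive_seed(config$seed, "shuffle", ep))
    ep_loss <- 0; ep_l1 <- 0
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      batch <- list(images = view$images[b], masks = view$masks[b])
      batch <- augment(batch, config, derive_seed(config$seed, "aug", ep, bi))
      X <- stack_images(batch$images)
      yf <- flatten_images(stack_images(batch$masks))
      tape <- ag_tape()
      rec <- new.env(parent = emptyenv())
      enc <- encoder_forward(model, X, tape = tape, record = rec,
                             lambda_attn = weights$lambda_l1_attn,
                             lambda_sae = weights$lambda_l1_sae)
      pr <- decoder_forward(model, enc, condition = NULL, tape = tape, record = rec,
                            lambda_attn = weights$lambda_l1_attn,
                            lambda_sae = weights$lambda_l1_sae)
      loss <- ag_attach_penalties(tape, ag_hybrid(tape, pr$y_hat, yf, weights), rec)
      grads <- ag_backward(tape, loss)
      adam_step(model$store, grads, opt, config$learning_rate)
      ep_loss <- ep_loss + ag_val(loss)
      ep_l1 <- ep_l1 + (rec$l1_attn %||% 0) + (rec$l1_sae %||% 0)
    }
    if (!is.null(test) && (ep %% config$eval_every == 0L || ep == config$epochs)) {
      last_test <- eval_dice(model, test)
    }
    rows[[ep]] <- data.frame(epoch = ep, split = "train",
                             loss = ep_loss / length(batches),
                             l1 = ep_l1 / length(batches),
                             test_dice = last_test)
  }
  list(model = model, trace = do.call(rbind, rows), optimizer = opt)
}

#' Train the multi-condition model by knowledge distillation
#'
#' The base and teacher models are trained simultaneously and end-to-end:
#' training cycles through the conditions, one condition-epoch (a full pass
#' over that condition's training split) at a time, optimizing the
#' depth-masked distillation loss with that condition's teacher. One Adam
#' optimizer covers all parameters; parameters outside the active graph
#' (other teachers) receive no gradient and are left bit-identical.
#'
#' @param datasets named list of per-condition training views (each with
#'   `images`, `masks`), in cycling order.
#' @param model a `faz_model` with teachers built (see [build_teachers()]);
#'   `n_conditions` must be at least `length(datasets)`.
#' @param config a [train_config()].
#' @param weights a [loss_weights()].
#' @param tests optional named list of held-out views (per condition).
#' @param detach_teacher stop-gradient variant of the comparison term.
#' @return list with `model`, `trace` (epoch, condition, split, dice, loss),
#'   and `optimizer`.
#' @export
train_multi_condition <- function(datasets, model, config = train_config(),
                                  weights = loss_weights(model$config$n_stages),
                                  tests = NULL, detach_teacher = FALSE) {
  if (length(datasets) < 2L) stop("multi-condition training needs >= 2 conditions")
  if (!model$has_teachers) stop("model has no teachers; call build_teachers()")
  if (length(datasets) > model$config$n_conditions) {
    stop("more conditions than teacher decoders")
  }
  conds <- names(datasets)
  if (is.null(conds)) stop("datasets must be a named list (condition names)")
  opt <- adam_state()
  rows <- list()
  last_test <- stats::setNames(rep(NA_real_, length(conds)), conds)
  for (ep in seq_len(config$epochs)) {
    for (j in seq_along(conds)) {
      view <- datasets[[j]]
      n <- length(view$images)
      if (n == 0L) stop("empty training split for condition ", conds[j])
      batches <- make_batches(n, config$batch_size,
                              derive_seed(config$seed, "shuffle", ep, j))
      ep_loss <- 0
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        batch <- list(images = view$images[b], masks = view$masks[b])
        batch <- augment(batch, config, derive_seed(config$seed, "aug", ep, j, bi))
        X <- stack_images(batch$images)
        y <- stack_images(batch$masks)
        tape <- ag_tape()
        cond <- if (!is.null(view$codes)) view$codes[[b[1]]] else j
        loss <- depth_masked_total_loss(model, X, y, cond, weights, tape = tape,
                                        detach_teacher = detach_teacher)
        grads <- ag_backward(tape, loss)
        adam_step(model$store, grads, opt, config$learning_rate)
        ep_loss <- ep_loss + ag_val(loss)
      }
      if (!is.null(tests) && !is.null(tests[[conds[j]]]) &&
          (ep %% config$eval_every == 0L || ep == config$epochs)) {
        last_test[conds[j]] <- eval_dice(model, tests[[conds[j]]],
                                         condition = condition_code(j, model$config$n_slots))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = ep, condition = conds[j], split = "train",
        loss = ep_loss / length(batches), test_dice = last_test[conds[j]])
    }
  }
  list(model = model, trace = do.call(rbind, rows), optimizer = opt)
}

#' Pretrain on the photocoagulation segmentation set
#'
#' Plain supervised segmentation (hybrid loss) of treatment-region blobs in
#' fundus-style single-channel images, used as an inter-modality warm start:
#' the resulting checkpoint is loaded before FAZ fine-tuning. Color inputs
#' are reduced to luminance by the documented fixed weights at read time.
#'
#' @param pc_dataset list with `images` and `masks` (from
#'   [generate_pc_set()]).
#' @param model a `faz_model`.
#' @param config a [train_config()].
#' @param weights a [loss_weights()].
#' @param checkpoint_path where to save the pretrained checkpoint (`NULL` to
#'   skip saving).
#' @return list with `model`, `trace`, and `checkpoint_path`.
#' @export
pretrain_pc <- function(pc_dataset, model, config = train_config(),
                        weights = loss_weights(model$config$n_stages),
                        checkpoint_path = NULL) {
  view <- list(images = pc_dataset$images, masks = pc_dataset$masks)
  fit <- train_single_condition(view, model, config, weights)
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, trace = fit$trace, checkpoint_path = checkpoint_path)
}
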