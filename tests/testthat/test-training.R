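# Training mechanics: augmentation, optimizer behavior, annotation
# interpolation, condition cycling, checkpoint-resume determinism.

test_that("augmentation with zero magnitudes is the identity", {
  ds <- micro_dataset()
  batch <- list(images = ds$images[1:2], masks = lapply(ds$masks[1:2], `[[`, 1))
  cfg <- micro_train_config()
  out <- augment(batch, cfg, 1)
  expect_identical(out$images, batch$images)
  expect_identical(out$masks, batch$masks)
})

test_that("geometric transforms move image and mask together; noise leaves masks alone", {
  ds <- micro_dataset()
  img <- ds$images[[1]]
  msk <- ds$masks[[1]][[1]]
  # pure horizontal flip (probability 1): centroid x reflects about center
  cfg <- train_config(augmentation = list(shift = 0, rotation = 0, flip_prob = 1,
                                          jitter = 0, noise_sd = 0))
  found_flip <- FALSE
  for (s in 1:10) {
    out <- augment(list(images = list(img), masks = list(msk)), cfg, s)
    fm <- out$masks[[1]]
    expect_equal(sum(fm), sum(msk))
    cx0 <- mean(which(msk > 0, arr.ind = TRUE)[, 2])
    cx1 <- mean(which(fm > 0, arr.ind = TRUE)[, 2])
    cy1 <- mean(which(fm > 0, arr.ind = TRUE)[, 1])
    cy0 <- mean(which(msk > 0, arr.ind = TRUE)[, 1])
    if (isTRUE(all.equal(cx1, ncol(msk) + 1 - cx0)) ||
        isTRUE(all.equal(cy1, nrow(msk) + 1 - cy0))) found_flip <- TRUE
  }
  expect_true(found_flip)

  # rotation keeps the mask strictly binary (nearest-neighbour resampling)
  cfg <- train_config(augmentation = list(shift = 0, rotation = 15, flip_prob = 0,
                                          jitter = 0, noise_sd = 0))
  out <- augment(list(images = list(img), masks = list(msk)), cfg, 3)
  expect_true(all(out$masks[[1]] %in% c(0, 1)))

  # noise perturbs the image but the mask is bit-identical
  cfg <- train_config(augmentation = list(shift = 0, rotation = 0, flip_prob = 0,
                                          jitter = 0, noise_sd = 0.1))
  out <- augment(list(images = list(img), masks = list(msk)), cfg, 4)
  expect_false(identical(out$images[[1]], img))
  expect_identical(out$masks[[1]], msk)
})

test_that("a zero learning rate leaves parameters unchanged", {
  m <- build_base_model(micro_config(), seed = 10)
  before <- m$store$params
  ds <- micro_dataset()
  tc <- micro_train_config(epochs = 2)
  tc$learning_rate <- 0
  fit <- train_single_condition(view_rows(ds, 1:4), m, tc, loss_weights(n_stages = 2))
  expect_identical(m$store$params, before)
})

test_that("training reduces the loss and is reproducible from the seed", {
  ds <- micro_dataset()
  tr <- view_rows(ds, 1:8)
  w <- loss_weights(n_stages = 2)
  m1 <- build_base_model(micro_config(), seed = 0)
  f1 <- train_single_condition(tr, m1, micro_train_config(epochs = 8), w)
  expect_lt(utils::tail(f1$trace$loss, 1), f1$trace$loss[1])
  m2 <- build_base_model(micro_config(), seed = 0)
  f2 <- train_single_condition(tr, m2, micro_train_config(epochs = 8), w)
  expect_identical(f1$trace, f2$trace)
  expect_error(train_single_condition(view_rows(ds, integer(0)), m1,
                                      micro_train_config()), "empty")
})

test_that("EMA training loss at a later step is below the early loss for several seeds", {
  ds <- micro_dataset()
  tr <- view_rows(ds, 1:8)
  w <- loss_weights(n_stages = 2)
  for (sd in 0:2) {
    m <- build_base_model(micro_config(), seed = sd)
    fit <- train_single_condition(tr, m, micro_train_config(epochs = 25, seed = sd), w)
    ema <- Reduce(function(a, x) 0.7 * a + 0.3 * x, fit$trace$loss, accumulate = TRUE)
    expect_lt(utils::tail(ema, 1), ema[2])
  }
})

test_that("condition cycling trains every condition once per outer epoch", {
  ds <- micro_multi_dataset()
  man <- ds$manifest
  views <- list(Healthy = view_rows(ds, which(man$condition == "Healthy")),
                DR = view_rows(ds, which(man$condition == "DR")))
  m <- build_base_model(micro_config(n_conditions = 2L), seed = 1)
  build_teachers(m)
  w <- loss_weights(n_stages = 2)
  fit <- train_multi_condition(views, m, micro_train_config(epochs = 3), w)
  counts <- table(fit$trace$condition)
  expect_equal(as.numeric(counts), c(3, 3))
  expect_equal(fit$trace$condition[1:2], c("Healthy", "DR"))
  expect_error(train_multi_condition(views[1], m, micro_train_config()), ">= 2")
})

test_that("a step on one condition leaves the other teacher bit-unchanged", {
  ds <- micro_multi_dataset()
  man <- ds$manifest
  m <- build_base_model(micro_config(n_conditions = 2L), seed = 2)
  build_teachers(m)
  w <- loss_weights(n_stages = 2)
  snap <- m$store$params
  X <- stack_imgs(ds$images[which(man$condition == "Healthy")[1:2]])
  y <- stack_imgs(lapply(ds$masks[which(man$condition == "Healthy")[1:2]], `[[`, 1))
  tape <- fazkd:::ag_tape()
  loss <- depth_masked_total_loss(m, X, y, 1L, w, tape = tape)
  grads <- fazkd:::ag_backward(tape, loss)
  opt <- fazkd:::adam_state()
  fazkd:::adam_step(m$store, grads, opt, 1e-3)
  nms <- names(m$store$params)
  t2 <- grep("^t2\\.", nms, value = TRUE)
  expect_true(all(vapply(t2, function(n) identical(m$store$params[[n]], snap[[n]]),
                         logical(1))))
  enc <- grep("^enc\\.", nms, value = TRUE)
  expect_true(any(vapply(enc, function(n) !identical(m$store$params[[n]], snap[[n]]),
                         logical(1))))
  t1 <- grep("^t1\\.", nms, value = TRUE)
  expect_true(any(vapply(t1, function(n) !identical(m$store$params[[n]], snap[[n]]),
                         logical(1))))
})

test_that("annotation interpolation hits its endpoints and marks disagreement", {
  m1 <- matrix(0, 8, 8); m1[3:6, 3:6] <- 1
  m2 <- matrix(0, 8, 8); m2[4:7, 4:7] <- 1
  r1 <- interpolate_annotations(list(m1, m2), condition_index = 2, n_conditions = 4,
                                lambda = 1)
  expect_identical(r1$target, m1)
  expect_equal(as.numeric(r1$code), c(0, 0, 1, 0, 0, 0, 0, 0))
  r0 <- interpolate_annotations(list(m1, m2), 2, 4, lambda = 0)
  expect_identical(r0$target, m2)
  rh <- interpolate_annotations(list(m1, m2), 1, 4, lambda = 0.5)
  dis <- xor(m1 > 0, m2 > 0)
  expect_true(all(rh$target[dis] == 0.5))
  expect_true(all(rh$target[m1 > 0 & m2 > 0] == 1))
  expect_true(all(rh$target[!dis & m1 == 0] == 0))
  expect_error(interpolate_annotations(list(m1), 1, 4), "exactly 2")
  # unspecified lambda draws reproducibly from the seed
  ra <- interpolate_annotations(list(m1, m2), 1, 4, rng_seed = 9)
  rb <- interpolate_annotations(list(m1, m2), 1, 4, rng_seed = 9)
  expect_equal(ra$lambda, rb$lambda)
  expect_gte(ra$lambda, 0)
  expect_lte(ra$lambda, 1)
})

test_that("checkpoint save/load/resume reproduces the next-step loss exactly", {
  ds <- micro_dataset()
  tr <- view_rows(ds, 1:4)
  w <- loss_weights(n_stages = 2)
  m <- build_base_model(micro_config(), seed = 3)
  train_single_condition(tr, m, micro_train_config(epochs = 1), w)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  f_next <- train_single_condition(tr, m, micro_train_config(epochs = 1, seed = 99), w)
  m2 <- build_base_model(micro_config(), seed = 3)
  load_checkpoint(m2, ck)
  f_next2 <- train_single_condition(tr, m2, micro_train_config(epochs = 1, seed = 99), w)
  expect_equal(f_next$trace$loss, f_next2$trace$loss, tolerance = 1e-6)
  unlink(ck)
})

test_that("photocoagulation pretraining learns and warm-starts fine-tuning", {
  spec <- synth_dataset_spec(image_size = 32, seed = 4)
  pc <- generate_pc_set(16, spec)
  w <- loss_weights(n_stages = 2)
  m <- build_base_model(micro_config(), seed = 4)
  ck <- tempfile(fileext = ".rds")
  fit <- pretrain_pc(pc, m, micro_train_config(epochs = 8), w, checkpoint_path = ck)
  expect_lt(utils::tail(fit$trace$loss, 1), fit$trace$loss[1])

  # checkpoint round-trip: identical forward outputs
  set.seed(20)
  X <- array(runif(32 * 32), c(1, 32, 32))
  m3 <- build_base_model(micro_config(), seed = 99)
  load_checkpoint(m3, ck)
  expect_identical(faz_predict(m3, X, condition = 1), faz_predict(m, X, condition = 1))

  # warm start: after an identical short fine-tuning budget on FAZ data the
  # pretrained model reaches a lower training loss than random init (median
  # over 3 seeds; at step 0 the binarized Dice is degenerate because the
  # photocoagulation task has opposite polarity to the dark FAZ)
  ds <- micro_dataset()
  tr2 <- view_rows(ds, 1:8)
  diffs <- vapply(0:2, function(sd) {
    mp <- build_base_model(micro_config(), seed = sd)
    load_checkpoint(mp, ck)
    mr <- build_base_model(micro_config(), seed = sd)
    fp <- train_single_condition(tr2, mp, micro_train_config(epochs = 3, seed = sd), w)
    fr <- train_single_condition(tr2, mr, micro_train_config(epochs = 3, seed = sd), w)
    utils::tail(fr$trace$loss, 1) - utils::tail(fp$trace$loss, 1)
  }, numeric(1))
  expect_gte(stats::median(diffs), 0)
  unlink(ck)
})
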