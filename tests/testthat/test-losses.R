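# Loss constructions: hand-computed values, schedule properties, and
# structural invariants.

test_that("dice loss matches hand-computed values", {
  y <- c(1, 0, 1, 1)
  expect_equal(dice_loss(y, y), 0)                       # perfect binary match
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)     # empty-empty smoothing
  expect_equal(dice_loss(c(0, 1), c(1, 0)), 2 / 3)       # 1 - 1/3
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("bce loss matches hand-computed values", {
  expect_lte(bce_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_equal(bce_loss(rep(0.5, 7), c(1, 0, 1, 0, 1, 1, 0)), log(2))
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), (-log(0.9) - log(0.8)) / 2,
               tolerance = 1e-12)
})

test_that("hybrid loss weights BCE and Dice as configured", {
  w <- loss_weights()
  expect_equal(w$c1, 1)
  expect_equal(w$c2, 0.5)
  y <- c(1, 0, 1)
  yh <- c(0.8, 0.3, 0.9)
  expect_equal(hybrid_loss(yh, y, w),
               bce_loss(yh, y) + 0.5 * dice_loss(yh, y))
  w0 <- loss_weights(c2 = 0)
  expect_equal(hybrid_loss(yh, y, w0), bce_loss(yh, y))
  expect_lt(hybrid_loss(c(1, 0, 1), y), 1e-5)
})

test_that("distillation loss is the weighted three-term sum", {
  w <- loss_weights()
  expect_equal(c(w$alpha, w$beta, w$gamma), c(1, 0.5, 0.25))
  y <- matrix(c(1, 0, 0, 1), 2)
  yb <- matrix(c(0.9, 0.2, 0.1, 0.7), 2)
  yt <- matrix(c(0.8, 0.1, 0.3, 0.9), 2)
  manual <- w$alpha * hybrid_loss(yb, y, w) + w$beta * hybrid_loss(yt, y, w) +
    w$gamma * (w$c1 * bce_loss(yb, yt) + w$c2 * dice_loss(yb, yt))
  expect_equal(distill_loss(yb, yt, y, w), manual, tolerance = 1e-12)
  expect_lt(distill_loss(y, y, y, w), 1e-5)
  # degenerate weighting: beta, gamma -> 0 approaches the plain hybrid loss
  w2 <- loss_weights(alpha = 1, beta = 1e-12, gamma = 1e-13)
  expect_equal(distill_loss(yb, yt, y, w2), hybrid_loss(yb, y, w2), tolerance = 1e-9)
  expect_error(loss_weights(alpha = 0.1, beta = 0.5, gamma = 0.25), "alpha > beta")
})

test_that("geometric depth schedule dominates its tail", {
  for (n in 1:8) {
    a <- a_schedule(n)
    expect_equal(a, 2^-(0:n))
    for (i in seq_len(n)) {
      expect_gt(a[i], sum(a[(i + 1):(n + 1)]))
    }
  }
})

test_that("L1 penalties are linear in their activations", {
  w <- loss_weights(lambda_l1_attn = 2, lambda_l1_sae = 3)
  expect_equal(l1_penalties(list(matrix(0, 2, 2)), list(rep(0, 5)), w), 0)
  expect_equal(l1_penalties(list(matrix(1, 2, 2)), list(), loss_weights(
    lambda_l1_attn = 0, lambda_l1_sae = 0)), 0)
  a <- list(matrix(rnorm(9), 3))
  h <- list(abs(rnorm(7)))
  p1 <- l1_penalties(a, h, w)
  p2 <- l1_penalties(lapply(a, `*`, 2), lapply(h, `*`, 2), w)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
})

test_that("dice loss is symmetric, bounded, and monotone at a single pixel", {
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(16, 1, 0.4)
    yh <- rbinom(16, 1, 0.4)
    expect_equal(dice_loss(yh, y), dice_loss(y, yh))
    r <- runif(16)
    d <- dice_loss(r, y)
    expect_gte(d, 0)
    expect_lt(d, 1)
    expect_true(is.finite(hybrid_loss(r, y)))
  }
  # one-pixel mask: raising the prediction at the true pixel lowers the loss
  y <- c(1, rep(0, 8))
  vals <- sapply(seq(0.1, 0.9, 0.2), function(p) dice_loss(c(p, rep(0, 8)), y))
  expect_true(all(diff(vals) < 0))
})

test_that("distillation gradients flow end-to-end, including into the teacher", {
  cfg <- micro_config(n_conditions = 2L)
  m <- build_base_model(cfg, seed = 31)
  build_teachers(m)
  set.seed(32)
  X <- array(runif(32 * 32), c(1, 32, 32))
  y <- array(rbinom(32 * 32, 1, 0.15), c(1, 32, 32))
  w <- loss_weights(n_stages = 2, lambda_l1_attn = 0, lambda_l1_sae = 0)
  tape <- fazkd:::ag_tape()
  loss <- depth_masked_total_loss(m, X, y, 1L, w, tape = tape)
  grads <- fazkd:::ag_backward(tape, loss)
  lf <- function() depth_masked_total_loss(m, X, y, 1L, w)
  # the gamma comparison term must reach the teacher's own parameters
  expect_false(is.null(grads[["t1.head.W"]]))
  for (nm in c("t1.head.W", "t1.s1.up.W", "enc.s1.conv.W", "dec.s2.cond.W")) {
    for (i in sample(length(m$store$params[[nm]]), 2)) {
      num <- numeric_grad(lf, m$store, nm, i)
      anl <- if (is.null(grads[[nm]])) 0 else grads[[nm]][i]
      expect_lt(abs(num - anl) / max(1e-6, abs(num), abs(anl)), 1e-3)
    }
  }
  # detaching the teacher removes the gamma path but keeps the beta path
  tape2 <- fazkd:::ag_tape()
  loss2 <- depth_masked_total_loss(m, X, y, 1L, w, tape = tape2,
                                   detach_teacher = TRUE)
  grads2 <- fazkd:::ag_backward(tape2, loss2)
  expect_false(is.null(grads2[["t1.head.W"]]))
})

test_that("depth-masked total equals a loop-and-sum oracle over mask depths", {
  cfg <- micro_config(n_conditions = 2L)
  m <- build_base_model(cfg, seed = 3)
  build_teachers(m)
  set.seed(8)
  X <- array(runif(2 * 32 * 32), c(2, 32, 32))
  y <- array(rbinom(2 * 32 * 32, 1, 0.15), c(2, 32, 32))
  w <- loss_weights(n_stages = 2, lambda_l1_attn = 0, lambda_l1_sae = 0)

  total <- depth_masked_total_loss(m, X, y, 2L, w)

  # oracle: manual per-depth forward passes and hand-weighted hybrid sums
  enc <- encoder_forward(m, X)
  yf <- fazkd:::flatten_images(y)
  teach <- decoder_forward(m, enc, decoder = 2L)$y_hat
  cond <- condition_code(2L, cfg$n_slots)
  a <- a_schedule(2)
  acc <- 0
  for (i in 0:2) {
    bi <- decoder_forward(m, enc, condition = cond, mask_depth = i)$y_hat
    acc <- acc + a[i + 1] * w$alpha * hybrid_loss(bi, yf, w)
    if (i == 0) {
      acc <- acc + w$beta * hybrid_loss(teach, yf, w) +
        w$gamma * (w$c1 * bce_loss(bi, teach) +
                     w$c2 * (1 - (2 * sum(teach * bi) + 1) / (sum(teach + bi) + 1)))
    }
  }
  expect_equal(total, acc, tolerance = 1e-9)

  # truncated schedule (weights at depth 0 only) reduces to the plain
  # distillation loss
  base0 <- decoder_forward(m, enc, condition = cond, mask_depth = 0)$y_hat
  d0 <- w$alpha * hybrid_loss(base0, yf, w) + w$beta * hybrid_loss(teach, yf, w) +
    w$gamma * (w$c1 * bce_loss(base0, teach) +
                 w$c2 * (1 - (2 * sum(teach * base0) + 1) / (sum(teach + base0) + 1)))
  expect_lt(abs(d0 - (acc - sum(a[2:3] * sapply(1:2, function(i) {
    w$alpha * hybrid_loss(decoder_forward(m, enc, condition = cond,
                                          mask_depth = i)$y_hat, yf, w)
  })))), 1e-9)
})
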