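# Architecture contracts: shapes, determinism, masking, condition pathway,
# encoder sharing, checkpoints.

test_that("configuration invariants are enforced at construction", {
  expect_error(model_config(n_stages = 2, embed_dims = c(16L, 16L), image_size = 64),
               "strictly increasing")
  expect_error(model_config(n_stages = 2, embed_dims = c(16L, 32L), image_size = 50),
               "divisible")
  expect_error(model_config(n_stages = 2, embed_dims = c(6L, 9L), n_heads = 4,
                            patch_size = c(1L, 1L), image_size = 64),
               "divisible by n_heads")
  expect_error(model_config(n_conditions = 0), "n_conditions")
  cfg <- tiny_model_config()
  expect_equal(cfg$n_slots, 4L)
  cfg2 <- tiny_model_config(condition_agnostic_slot = TRUE)
  expect_equal(cfg2$n_slots, 5L)
})

test_that("encoder produces halved-resolution skips and is deterministic", {
  cfg <- model_config(n_stages = 3, embed_dims = c(8L, 16L, 32L), n_heads = 2,
                      patch_size = c(2L, 1L, 1L), sae_expansion = 2,
                      pos_rank = 2, n_conditions = 2, image_size = 64)
  m <- build_base_model(cfg, seed = 1)
  set.seed(9)
  X <- array(runif(2 * 64 * 64), c(2, 64, 64))
  enc <- encoder_forward(m, X)
  expect_equal(vapply(enc$skips, nrow, numeric(1)), 2 * c(32, 16, 8)^2)
  expect_equal(vapply(enc$skips, ncol, numeric(1)), c(8, 16, 32))
  enc2 <- encoder_forward(m, X)
  expect_identical(enc$bottleneck, enc2$bottleneck)

  # batch equivariance: permuting inputs permutes outputs
  p1 <- faz_predict(m, X, condition = 1)
  Xr <- X[c(2, 1), , ]
  p2 <- faz_predict(m, Xr, condition = 1)
  expect_equal(p2[1, , ], p1[2, , ], tolerance = 1e-12)
  expect_equal(p2[2, , ], p1[1, , ], tolerance = 1e-12)
})

test_that("predictions are probabilities at input resolution for several sizes", {
  for (sz in c(32L, 64L)) {
    cfg <- micro_config()
    cfg <- model_config(n_stages = 2, embed_dims = c(8L, 16L), n_heads = 2,
                        patch_size = c(2L, 1L), sae_expansion = 2, pos_rank = 2,
                        n_conditions = 2, image_size = sz)
    m <- build_base_model(cfg, seed = 2)
    X <- array(runif(sz * sz), c(1, sz, sz))
    pb <- faz_predict(m, X, condition = 1)
    expect_equal(dim(pb), c(1L, sz, sz))
    expect_true(all(pb >= 0 & pb <= 1))
  }
  # full-scale input resolution with a slim model
  cfg <- model_config(n_stages = 3, embed_dims = c(8L, 16L, 32L), n_heads = 2,
                      patch_size = c(8L, 4L, 2L), sae_expansion = 2, pos_rank = 2,
                      n_conditions = 2, image_size = 256)
  m <- build_base_model(cfg, seed = 2)
  X <- array(runif(256 * 256), c(1, 256, 256))
  pb <- faz_predict(m, X, condition = 1)
  expect_equal(dim(pb), c(1L, 256L, 256L))
  expect_true(all(pb >= 0 & pb <= 1))
})

test_that("depth masking removes exactly the shallow skip pathways", {
  cfg <- micro_config()
  m <- build_base_model(cfg, seed = 4)
  set.seed(10)
  X <- array(runif(32 * 32), c(1, 32, 32))
  enc <- encoder_forward(m, X)
  cond <- condition_code(1, cfg$n_slots)
  full <- decoder_forward(m, enc, condition = cond, mask_depth = 0)$y_hat
  m1 <- decoder_forward(m, enc, condition = cond, mask_depth = 1)$y_hat
  expect_false(isTRUE(all.equal(full, m1)))

  # at mask_depth = n_stages the output depends only on the bottleneck:
  # perturbing every skip tensor leaves it unchanged
  enc_pert <- enc
  enc_pert$skips <- lapply(enc$skips, function(s) s + matrix(rnorm(length(s)), nrow(s)))
  out_a <- decoder_forward(m, enc, condition = cond, mask_depth = 2)$y_hat
  out_b <- decoder_forward(m, enc_pert, condition = cond, mask_depth = 2)$y_hat
  expect_identical(out_a, out_b)
  expect_error(decoder_forward(m, enc, condition = cond, mask_depth = 3), "mask_depth")
})

test_that("the condition pathway is live in the base decoder", {
  cfg <- micro_config()
  m <- build_base_model(cfg, seed = 5)
  set.seed(11)
  X <- array(runif(32 * 32), c(1, 32, 32))
  p1 <- faz_predict(m, X, condition = 1)
  p2 <- faz_predict(m, X, condition = 2)
  expect_gt(max(abs(p1 - p2)), 0)
  mix <- condition_code(c(0.5, 0.5), cfg$n_slots)
  pm <- faz_predict(m, X, condition = mix)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_error(condition_code(c(0.5, 0.2), 2), "sum to 1")
})

test_that("teachers share the encoder and drop only the condition pathway", {
  cfg <- micro_config(n_conditions = 4L)
  m <- build_base_model(cfg, seed = 6)
  enc_before <- param_count(m, "enc.")
  build_teachers(m)
  expect_equal(param_count(m, "enc."), enc_before)  # sharing: one encoder
  nms <- names(m$store$params)
  expect_length(unique(sub("\\..*", "", grep("^t", nms, value = TRUE))), 4L)
  cond_params <- sum(vapply(grep("^dec\\..*\\.cond\\.", nms, value = TRUE),
                            function(n) length(m$store$params[[n]]), numeric(1)))
  expect_equal(param_count(m, "t1."), param_count(m, "dec.") - cond_params)
  # the same store object backs base and teachers (parameter sharing by identity)
  set.seed(12)
  X <- array(runif(32 * 32), c(1, 32, 32))
  pt <- faz_predict(m, X, decoder = 1L)
  expect_true(all(pt >= 0 & pt <= 1))
  expect_error(decoder_forward(m, encoder_forward(m, X), decoder = 9L), "teacher")
})

test_that("Gaussian scales stay positive through optimization", {
  cfg <- micro_config()
  m <- build_base_model(cfg, seed = 7)
  ds <- micro_dataset()
  view <- view_rows(ds, 1:4)
  fit <- train_single_condition(view, m, micro_train_config(epochs = 2),
                                loss_weights(n_stages = 2))
  rho <- m$store$params[["enc.s1.blk.attn.rx"]]
  expect_true(all(is.finite(rho)))
  expect_true(all(fazkd:::softplus(rho) > 0))
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  cfg <- micro_config()
  m <- build_base_model(cfg, seed = 8)
  set.seed(13)
  X <- array(runif(32 * 32), c(1, 32, 32))
  p0 <- faz_predict(m, X, condition = 1)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- faz_load_model(ck)
  expect_identical(faz_predict(m2, X, condition = 1), p0)
  other <- build_base_model(model_config(n_stages = 2, embed_dims = c(8L, 16L),
                                         n_heads = 2, patch_size = c(2L, 1L),
                                         sae_expansion = 2, pos_rank = 2,
                                         n_conditions = 3, image_size = 32),
                            seed = 0)
  expect_error(load_checkpoint(other, ck), "hash")
  unlink(ck)
})
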