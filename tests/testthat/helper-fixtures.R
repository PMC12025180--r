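# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

# 32 x 32 micro config: exercises every architectural component at minimal cost.
micro_config <- function(n_conditions = 2L) {
  model_config(n_stages = 2L, embed_dims = c(8L, 16L), n_heads = 2L,
               patch_size = c(2L, 1L), sae_expansion = 2, pos_rank = 2L,
               n_conditions = n_conditions, image_size = 32L)
}

micro_train_config <- function(epochs = 5L, seed = 0L, ...) {
  train_config(learning_rate = 2e-3, batch_size = 4L, epochs = epochs,
               augmentation = list(shift = 0, rotation = 0, flip_prob = 0,
                                   jitter = 0, noise_sd = 0),
               seed = seed, ...)
}

# Tiny synthetic single-condition dataset at 32 px, in memory.
micro_dataset <- function(n_eyes = 12L, seed = 5L) {
  memo(paste0("micro_ds_", n_eyes, "_", seed), function() {
    prof <- condition_profile("Healthy", 4.5, 0.4, 0.1, 0.9, n_eyes = n_eyes)
    spec <- synth_dataset_spec(image_size = 32L, profiles = list(prof),
                               noise_sd = 0.03, seed = seed)
    generate_dataset(spec)
  })
}

# Two-condition 32 px dataset for distillation tests.
micro_multi_dataset <- function(seed = 6L) {
  memo(paste0("micro_multi_", seed), function() {
    profs <- list(condition_profile("Healthy", 4.5, 0.4, 0.1, 0.9, n_eyes = 8L),
                  condition_profile("DR", 6.0, 0.5, 0.4, 0.6, n_eyes = 8L))
    spec <- synth_dataset_spec(image_size = 32L, profiles = profs,
                               noise_sd = 0.03, seed = seed)
    generate_dataset(spec)
  })
}

view_rows <- function(ds, rows, annotator = 1L) {
  fazkd:::dataset_view(ds, rows, annotator)
}

stack_imgs <- function(lst) fazkd:::stack_images(lst)

# Numerical gradient by central differences on a named parameter entry.
numeric_grad <- function(loss_fn, store, name, i, h = 1e-6) {
  p0 <- store$params[[name]][i]
  store$params[[name]][i] <- p0 + h
  up <- loss_fn()
  store$params[[name]][i] <- p0 - h
  dn <- loss_fn()
  store$params[[name]][i] <- p0
  (up - dn) / (2 * h)
}
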