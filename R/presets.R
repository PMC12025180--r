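#' Model and data presets
#'
#' `paper_model_config()` is the full-scale architecture (256 x 256 inputs,
#' three stages with embedding dimensions 128/256/512, 8 attention heads);
#' training it is a GPU-scale undertaking. `tiny_model_config()` is the
#' desk-scale preset used throughout the tests and examples: 64 x 64 inputs,
#' two stages with dimensions 16/32, 4 heads, patch sizes (4, 2) and SAE
#' expansion 2, which trains in minutes on one CPU while exercising every
#' architectural component.
#'
#' @param n_conditions number of conditions (teacher decoders).
#' @param n_heads attention heads (the multi-condition variant is sometimes
#'   run wider, e.g. 16).
#' @param image_size square input size in pixels.
#' @param ... passed through to [model_config()].
#' @return a [model_config()].
#' @export
paper_model_config <- function(n_conditions = 4L, n_heads = 8L, image_size = 256L, ...) {
  model_config(n_stages = 3L, embed_dims = c(128L, 256L, 512L), n_heads = n_heads,
               n_conditions = n_conditions, image_size = image_size, ...)
}

#' @rdname paper_model_config
#' @export
tiny_model_config <- function(n_conditions = 4L, n_heads = 4L, image_size = 64L, ...) {
  model_config(n_stages = 2L, embed_dims = c(16L, 32L), n_heads = n_heads,
               patch_size = c(4L, 2L), sae_expansion = 2, pos_rank = 4L,
               n_conditions = n_conditions, image_size = image_size, ...)
}

#' Desk-scale training configuration
#'
#' Training settings matched to [tiny_model_config()]: Adam at 2e-3 (the
#' full-scale protocol uses 1e-4 over 500 epochs; the tiny model tolerates
#' and needs a larger step for few-hundred-step runs), batch 10, and mild
#' augmentation (shifts up to 3 px, rotations up to 10 degrees, flips,
#' 5% intensity jitter, noise sd 0.02).
#'
#' @param epochs training epochs.
#' @param seed training seed.
#' @param batch_size images per optimization step.
#' @param ... passed through to [train_config()].
#' @return a [train_config()].
#' @export
tiny_train_config <- function(epochs = 50L, seed = 0L, batch_size = 10L, ...) {
  train_config(learning_rate = 2e-3, batch_size = batch_size, epochs = epochs,
               augmentation = list(shift = 3, rotation = 10, flip_prob = 0.5,
                                   jitter = 0.05, noise_sd = 0.02),
               seed = seed, ...)
}
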