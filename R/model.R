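# Hybrid CNN/transformer encoder-decoder with Gaussian-locality and
# positional attention biases, sparse-autoencoder feed-forwards, optional
# per-condition teacher decoders sharing the encoder, and depth-masked
# decoding for the layerwise distillation loss.

#' Model configuration
#'
#' @param n_stages number of encoder/decoder stages (each halves resolution).
#' @param embed_dims channels per stage, strictly increasing.
#' @param n_heads attention heads; every stage's token dimension
#'   (`embed_dims[s] * patch_size[s]^2`) must be divisible by it.
#' @param patch_size per-stage token patch size over the downsampled grid;
#'   `NULL` chooses, per stage, the smallest power of two keeping the token
#'   grid at most 16 x 16.
#' @param sae_expansion hidden-width multiplier of the sparse-autoencoder
#'   feed-forward (overcomplete hidden layer).
#' @param n_conditions number of disease conditions (teacher decoders).
#' @param condition_agnostic_slot add an extra one-hot slot for
#'   condition-agnostic prediction.
#' @param image_size square input size in pixels; must be divisible by
#'   `2^n_stages` and by each stage's patch size after downsampling.
#' @param pos_rank rank of the low-rank positional score factorization.
#' @param sigma_per_patch if `TRUE`, the Gaussian kernel scales are learned
#'   per head and query patch rather than per head only.
#' @param downsample `"conv"` (strided convolution, default) or `"pool"`
#'   (stride-1 convolution followed by 2 x 2 max pooling).
#' @return an object of class `faz_model_config`.
#' @export
model_config <- function(n_stages = 3L, embed_dims = c(128L, 256L, 512L),
                         n_heads = 8L, patch_size = NULL, sae_expansion = 4,
                         n_conditions = 4L, condition_agnostic_slot = FALSE,
                         image_size = 256L, pos_rank = 8L,
                         sigma_per_patch = FALSE, downsample = c("conv", "pool")) {
  downsample <- match.arg(downsample)
  n_stages <- as.integer(n_stages)
  embed_dims <- as.integer(embed_dims)
  if (length(embed_dims) != n_stages) stop("length(embed_dims) must equal n_stages")
  if (n_stages > 1 && any(diff(embed_dims) <= 0)) stop("embed_dims must be strictly increasing")
  if (n_conditions < 1) stop("n_conditions must be >= 1")
  if (image_size %% (2^n_stages) != 0) {
    stop("image_size must be divisible by the total downsampling factor 2^n_stages")
  }
  grids <- image_size / 2^seq_len(n_stages)
  if (is.null(patch_size)) {
    patch_size <- vapply(grids, function(g) 2^max(0, ceiling(log2(g / 16))), numeric(1))
  }
  patch_size <- as.integer(rep_len(patch_size, n_stages))
  if (any(grids %% patch_size != 0)) stop("each stage grid must be divisible by its patch size")
  token_dims <- embed_dims * patch_size^2
  if (any(token_dims %% n_heads != 0)) {
    stop("each stage token dimension (embed_dim * patch_size^2) must be divisible by n_heads")
  }
  if (sae_expansion < 1) stop("sae_expansion must be >= 1")
  structure(list(
    n_stages = n_stages, embed_dims = embed_dims, n_heads = as.integer(n_heads),
    patch_size = patch_size, sae_expansion = sae_expansion,
    n_conditions = as.integer(n_conditions),
    condition_agnostic_slot = isTRUE(condition_agnostic_slot),
    image_size = as.integer(image_size), pos_rank = as.integer(pos_rank),
    sigma_per_patch = isTRUE(sigma_per_patch), downsample = downsample,
    head_channels = max(4L, embed_dims[1] %/% 2L),
    n_slots = as.integer(n_conditions + isTRUE(condition_agnostic_slot))
  ), class = "faz_model_config")
}

config_hash <- function(config) {
  s <- paste(vapply(config, function(x) paste(format(x), collapse = ","), character(1)),
             collapse = ";")
  derive_seed(0L, s)
}

#' Condition code vector
#'
#' One-hot (or convex-combination, for annotator-interpolated targets)
#' encoding of the disease condition fed to the base decoder.
#'
#' @param x an integer slot index, or a numeric vector of non-negative
#'   entries summing to 1.
#' @param n_slots total number of slots.
#' @return a numeric vector of length `n_slots` (class `faz_condition_code`).
#' @export
condition_code <- function(x, n_slots) {
  if (length(x) == 1L && x == round(x)) {
    stopifnot(x >= 1, x <= n_slots)
    v <- numeric(n_slots)
    v[x] <- 1
  } else {
    v <- as.numeric(x)
    if (length(v) != n_slots) stop("condition code has wrong length")
    if (any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      stop("condition code entries must be >= 0 and sum to 1")
    }
  }
  structure(v, class = "faz_condition_code")
}

## ---- geometry (index maps, cached per batch size) --------------------------

conv_idx <- function(H, W, k = 3L, stride = 1L, pad = 1L) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  oy <- rep(seq_len(Ho) - 1L, each = Wo)
  ox <- rep(seq_len(Wo) - 1L, times = Ho)
  idx <- matrix(0L, Ho * Wo, k * k)
  col <- 0L
  for (ky in 0:(k - 1L)) for (kx in 0:(k - 1L)) {
    col <- col + 1L
    y <- oy * stride - pad + ky
    x <- ox * stride - pad + kx
    ok <- y >= 0L & y < H & x >= 0L & x < W
    idx[, col] <- ifelse(ok, y * W + x + 1L, 0L)
  }
  idx
}

patchify_idx <- function(H, W, p) {
  Hp <- H %/% p; Wp <- W %/% p
  idx <- matrix(0L, Hp * Wp, p * p)
  col <- 0L
  for (dy in 0:(p - 1L)) for (dx in 0:(p - 1L)) {
    col <- col + 1L
    py <- rep(seq_len(Hp) - 1L, each = Wp)
    px <- rep(seq_len(Wp) - 1L, times = Hp)
    idx[, col] <- (py * p + dy) * W + (px * p + dx) + 1L
  }
  idx
}

upsample_idx <- function(H, W) {
  # nearest-neighbour x2: output grid (2H x 2W), single-column gather
  oy <- rep(seq_len(2L * H) - 1L, each = 2L * W)
  ox <- rep(seq_len(2L * W) - 1L, times = 2L * H)
  matrix((oy %/% 2L) * W + (ox %/% 2L) + 1L, ncol = 1L)
}

pool_idx <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  idx <- matrix(0L, Ho * Wo, 4L)
  col <- 0L
  for (dy in 0:1) for (dx in 0:1) {
    col <- col + 1L
    py <- rep(seq_len(Ho) - 1L, each = Wo)
    px <- rep(seq_len(Wo) - 1L, times = Ho)
    idx[, col] <- (py * 2L + dy) * W + (px * 2L + dx) + 1L
  }
  idx
}

batch_offset_idx <- function(idx, B, n_in) {
  if (B == 1L) return(idx)
  blocks <- vector("list", B)
  for (b in seq_len(B)) {
    bl <- idx
    bl[bl > 0L] <- bl[bl > 0L] + (b - 1L) * n_in
    blocks[[b]] <- bl
  }
  do.call(rbind, blocks)
}

# 2x2 max pool with argmax routing.
ag_maxpool <- function(tape, x, idx, C) {
  xv <- ag_val(x)
  n_out <- nrow(idx)
  v <- xv[idx[, 1L], , drop = FALSE]
  amax <- matrix(1L, n_out, C)
  for (k in 2:4) {
    cand <- xv[idx[, k], , drop = FALSE]
    upd <- cand > v
    v[upd] <- cand[upd]
    amax[upd] <- k
  }
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    dx <- matrix(0, nrow(xv), C)
    for (k in 1:4) {
      m <- amax == k
      gk <- g * m
      dx <- ag_scatter_add(dx, idx[, k], gk)
    }
    ag_acc(x, dx)
  })
}

model_geom <- function(model, B) {
  key <- paste0("B", B)
  g <- model$geom[[key]]
  if (!is.null(g)) return(g)
  cfg <- model$config
  S <- cfg$image_size
  st <- vector("list", cfg$n_stages)
  Hprev <- S
  for (s in seq_len(cfg$n_stages)) {
    Hs <- Hprev %/% 2L
    p <- cfg$patch_size[s]
    Hp <- Hs %/% p
    grid <- patch_grid(Hp, Hp)
    dx2 <- outer(grid$coords[, 1], grid$coords[, 1], "-")^2
    dy2 <- outer(grid$coords[, 2], grid$coords[, 2], "-")^2
    st[[s]] <- list(
      H = Hs, Hp = Hp, p = p,
      conv = if (cfg$downsample == "conv") {
        batch_offset_idx(conv_idx(Hprev, Hprev, stride = 2L), B, Hprev^2)
      } else {
        batch_offset_idx(conv_idx(Hprev, Hprev, stride = 1L), B, Hprev^2)
      },
      pool = if (cfg$downsample == "pool") batch_offset_idx(pool_idx(Hprev, Hprev), B, Hprev^2) else NULL,
      patch = if (p > 1L) batch_offset_idx(patchify_idx(Hs, Hs, p), B, Hs^2) else NULL,
      # 2x2 stride-2 transposed convolution realized as 4 parity matmuls +
      # interleave: chunk k of (z %*% Wup) lands on output parity class k.
      deconv = batch_offset_idx(patchify_idx(Hprev, Hprev, 2L), B, Hprev^2),
      dx2 = dx2, dy2 = dy2
    )
    Hprev <- Hs
  }
  g <- list(stages = st)
  model$geom[[key]] <- g
  g
}

## ---- parameter initialization ---------------------------------------------

init_block_params <- function(p, prefix, D, Np, cfg, rnorm_) {
  hd <- cfg$n_heads
  r <- cfg$pos_rank
  Dh <- as.integer(round(cfg$sae_expansion * D))
  sig0 <- max(2, Np^0.5 / 2)^2
  rho0 <- log(expm1(sig0))
  nsig <- if (cfg$sigma_per_patch) Np else 1L
  p[[paste0(prefix, ".ln1.g")]] <- matrix(1, 1, D)
  p[[paste0(prefix, ".ln1.b")]] <- matrix(0, 1, D)
  for (w in c("Wq", "Wk", "Wv", "Wo")) {
    p[[paste0(prefix, ".attn.", w)]] <- rnorm_(D, D, sqrt(1 / D))
  }
  p[[paste0(prefix, ".attn.U")]] <- rnorm_(Np, r * hd, 0.1)
  p[[paste0(prefix, ".attn.V")]] <- matrix(0, Np, r * hd)
  p[[paste0(prefix, ".attn.rx")]] <- matrix(rho0, hd, nsig)
  p[[paste0(prefix, ".attn.ry")]] <- matrix(rho0, hd, nsig)
  p[[paste0(prefix, ".ln2.g")]] <- matrix(1, 1, D)
  p[[paste0(prefix, ".ln2.b")]] <- matrix(0, 1, D)
  p[[paste0(prefix, ".sae.W1")]] <- rnorm_(D, Dh, sqrt(2 / D))
  p[[paste0(prefix, ".sae.b1")]] <- matrix(0, 1, Dh)
  p[[paste0(prefix, ".sae.W2")]] <- rnorm_(Dh, D, sqrt(1 / Dh))
  p[[paste0(prefix, ".sae.b2")]] <- matrix(0, 1, D)
  p
}

init_decoder_params <- function(p, pfx, cfg, rnorm_, with_condition) {
  S <- cfg$image_size
  dims <- cfg$embed_dims
  for (s in seq_len(cfg$n_stages)) {
    Hs <- S %/% 2L^s
    D <- dims[s] * cfg$patch_size[s]^2
    Np <- (Hs %/% cfg$patch_size[s])^2
    if (with_condition) {
      p[[paste0(pfx, ".s", s, ".cond.W")]] <- rnorm_(cfg$n_slots, dims[s], 0.1)
      p[[paste0(pfx, ".s", s, ".cond.b")]] <- matrix(0, 1, dims[s])
    }
    p[[paste0(pfx, ".s", s, ".xattn.lnq.g")]] <- matrix(1, 1, D)
    p[[paste0(pfx, ".s", s, ".xattn.lnq.b")]] <- matrix(0, 1, D)
    p[[paste0(pfx, ".s", s, ".xattn.lnkv.g")]] <- matrix(1, 1, D)
    p[[paste0(pfx, ".s", s, ".xattn.lnkv.b")]] <- matrix(0, 1, D)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0(pfx, ".s", s, ".xattn.", w)]] <- rnorm_(D, D, sqrt(1 / D))
    }
    p <- init_block_params(p, paste0(pfx, ".s", s, ".blk"), D, Np, cfg, rnorm_)
    cout <- if (s == 1L) cfg$head_channels else dims[s - 1L]
    p[[paste0(pfx, ".s", s, ".up.W")]] <- rnorm_(dims[s], 4L * cout, sqrt(2 / dims[s]))
    p[[paste0(pfx, ".s", s, ".up.b")]] <- matrix(0, 1, cout)
  }
  p[[paste0(pfx, ".head.W")]] <- rnorm_(cfg$head_channels, 1L, sqrt(2 / cfg$head_channels))
  p[[paste0(pfx, ".head.b")]] <- matrix(-2, 1, 1)
  p
}

init_params <- function(cfg, seed) {
  with_seed(derive_seed(seed, "init"), {
    rnorm_ <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)
    p <- list()
    S <- cfg$image_size
    dims <- cfg$embed_dims
    cin <- 1L
    for (s in seq_len(cfg$n_stages)) {
      Hs <- S %/% 2L^s
      p[[paste0("enc.s", s, ".conv.W")]] <- rnorm_(9L * cin, dims[s], sqrt(2 / (9 * cin)))
      p[[paste0("enc.s", s, ".conv.b")]] <- matrix(0, 1, dims[s])
      D <- dims[s] * cfg$patch_size[s]^2
      Np <- (Hs %/% cfg$patch_size[s])^2
      p <- init_block_params(p, paste0("enc.s", s, ".blk"), D, Np, cfg, rnorm_)
      cin <- dims[s]
    }
    Dn <- dims[cfg$n_stages]
    p[["bot.fc1.W"]] <- rnorm_(Dn, Dn, sqrt(2 / Dn))
    p[["bot.fc1.b"]] <- matrix(0, 1, Dn)
    p[["bot.fc2.W"]] <- rnorm_(Dn, Dn, sqrt(1 / Dn))
    p[["bot.fc2.b"]] <- matrix(0, 1, Dn)
    init_decoder_params(p, "dec", cfg, rnorm_, with_condition = TRUE)
  })
}

#' Build the base model (shared encoder + base decoder)
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `faz_model` (an environment holding the
#'   configuration and one shared parameter store).
#' @export
build_base_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "faz_model_config"))
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$store <- new.env(parent = emptyenv())
  m$store$params <- init_params(config, seed)
  m$geom <- new.env(parent = emptyenv())
  m$has_teachers <- FALSE
  m$seed <- as.integer(seed)
  class(m) <- "faz_model"
  m
}

#' Add per-condition teacher decoders
#'
#' Teacher decoders are architecture-identical to the base decoder minus the
#' condition-embedding pathway, and share the encoder (the same parameter
#' store) with the base model. At inference only the base model is used.
#'
#' @param model a `faz_model` from [build_base_model()].
#' @return the same model (environment), with `n_conditions` teacher decoders.
#' @export
build_teachers <- function(model) {
  stopifnot(inherits(model, "faz_model"))
  cfg <- model$config
  if (cfg$n_conditions < 1) stop("n_conditions must be >= 1")
  if (!model$has_teachers) {
    with_seed(derive_seed(model$seed, "teachers"), {
      rnorm_ <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)
      p <- model$store$params
      for (j in seq_len(cfg$n_conditions)) {
        p <- init_decoder_params(p, paste0("t", j), cfg, rnorm_, with_condition = FALSE)
      }
      model$store$params <- p
    })
    model$has_teachers <- TRUE
  }
  invisible(model)
}

#' Count parameters by name prefix
#'
#' @param model a `faz_model`.
#' @param prefix name prefix (`"enc."`, `"dec."`, `"t1."`, ...); `NULL`
#'   counts everything.
#' @return total number of scalar parameters.
#' @export
param_count <- function(model, prefix = NULL) {
  nms <- names(model$store$params)
  if (!is.null(prefix)) nms <- nms[startsWith(nms, prefix)]
  sum(vapply(model$store$params[nms], length, numeric(1)))
}

## ---- forward passes --------------------------------------------------------

# Flatten (B, H, W) array to row-major (B*H*W) x 1 matrix.
flatten_images <- function(X) {
  if (is.matrix(X)) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  B <- dim(X)[1]
  matrix(as.numeric(aperm(X, c(3L, 2L, 1L))), ncol = 1L)
}

unflatten_maps <- function(v, B, H, W) {
  aperm(array(as.numeric(v), dim = c(W, H, B)), c(3L, 2L, 1L))
}

transformer_block <- function(tape, t, pf, geo, B, model, record, lambda_attn, lambda_sae) {
  p <- function(nm) ag_param(tape, model$store, paste0(pf, ".", nm))
  cfg <- model$config
  Np <- geo$Hp^2
  a_in <- ag_layernorm(tape, t, p("ln1.g"), p("ln1.b"))
  a <- ag_mha(tape, a_in, a_in, p("attn.Wq"), p("attn.Wk"), p("attn.Wv"), p("attn.Wo"),
              cfg$n_heads, B, Np, Np,
              pos_u = p("attn.U"), pos_v = p("attn.V"),
              rho_x = p("attn.rx"), rho_y = p("attn.ry"),
              dx2 = geo$dx2, dy2 = geo$dy2,
              lambda_attn = lambda_attn, record = record)
  t <- ag_add(tape, t, a)
  s_in <- ag_layernorm(tape, t, p("ln2.g"), p("ln2.b"))
  s <- ag_sae(tape, s_in, p("sae.W1"), p("sae.b1"), p("sae.W2"), p("sae.b2"),
              lambda_sae = lambda_sae, record = record)
  ag_add(tape, t, s)
}

#' Encoder forward pass
#'
#' Alternating convolution (stride-2, or stride-1 plus max pooling) and
#' transformer stages; a token-wise fully connected network forms the
#' bottleneck. Returns per-stage skip features for cross-attention in the
#' decoder.
#'
#' @param model a `faz_model`.
#' @param X image batch: `(B, H, W)` array or a single `H x W` matrix, values
#'   in `[0, 1]`.
#' @param tape optional autodiff tape (training); `NULL` for inference.
#' @param record optional environment collecting attention/SAE activation
#'   statistics for the L1 penalties.
#' @param lambda_attn,lambda_sae L1 penalty coefficients applied during this
#'   pass (0 at inference).
#' @return list with `bottleneck` tokens, `skips` (one token matrix per
#'   stage), and the batch size `B`.
#' @export
encoder_forward <- function(model, X, tape = NULL, record = NULL,
                            lambda_attn = 0, lambda_sae = 0) {
  cfg <- model$config
  if (is.matrix(X)) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  B <- dim(X)[1]
  if (dim(X)[2] != cfg$image_size || dim(X)[3] != cfg$image_size) {
    stop("input spatial size does not match the model's image_size")
  }
  geom <- model_geom(model, B)
  p <- function(nm) ag_param(tape, model$store, nm)
  x <- flatten_images(X)
  skips <- vector("list", cfg$n_stages)
  for (s in seq_len(cfg$n_stages)) {
    geo <- geom$stages[[s]]
    x <- ag_regroup(tape, x, geo$conv)
    x <- ag_add_rowvec(tape, ag_matmul(tape, x, p(paste0("enc.s", s, ".conv.W"))),
                       p(paste0("enc.s", s, ".conv.b")))
    x <- ag_relu(tape, x)
    if (cfg$downsample == "pool") x <- ag_maxpool(tape, x, geo$pool, cfg$embed_dims[s])
    t <- if (geo$p > 1L) ag_regroup(tape, x, geo$patch) else x
    t <- transformer_block(tape, t, paste0("enc.s", s, ".blk"), geo, B, model,
                           record, lambda_attn, lambda_sae)
    x <- if (geo$p > 1L) {
      ag_ungroup(tape, t, geo$patch, B * geo$H^2, cfg$embed_dims[s])
    } else t
    skips[[s]] <- x
  }
  h <- ag_relu(tape, ag_add_rowvec(tape, ag_matmul(tape, x, p("bot.fc1.W")), p("bot.fc1.b")))
  z <- ag_add_rowvec(tape, ag_matmul(tape, h, p("bot.fc2.W")), p("bot.fc2.b"))
  z <- ag_add(tape, x, z)
  list(bottleneck = z, skips = skips, B = B)
}

#' Decoder forward pass
#'
#' Upsampling decoder with cross-attention over encoder skip features,
#' condition-embedding injection (base decoder only) and depth masking: with
#' `mask_depth = i`, the skip connections into the `i` shallowest
#' (highest-resolution) decoder stages are removed, forcing the deeper layers
#' to carry the representation.
#'
#' @param model a `faz_model`.
#' @param enc output of [encoder_forward()].
#' @param condition a [condition_code()] (base decoder; ignored by teachers).
#' @param mask_depth integer in `[0, n_stages]`; 0 = unmasked.
#' @param decoder `"base"` or a teacher index `1..n_conditions`.
#' @param tape,record,lambda_attn,lambda_sae see [encoder_forward()].
#' @return an object of class `faz_prediction`: list with `y_hat`
#'   (`(B*H*W) x 1` per-pixel probabilities, autodiff node under a tape),
#'   `source`, `mask_depth`, and `B`.
#' @export
decoder_forward <- function(model, enc, condition = NULL, mask_depth = 0L,
                            decoder = "base", tape = NULL, record = NULL,
                            lambda_attn = 0, lambda_sae = 0) {
  cfg <- model$config
  n <- cfg$n_stages
  if (mask_depth < 0L || mask_depth > n) stop("mask_depth must be in [0, n_stages]")
  is_base <- identical(decoder, "base")
  pfx <- if (is_base) "dec" else {
    j <- as.integer(decoder)
    if (!model$has_teachers || j < 1L || j > cfg$n_conditions) {
      stop("no such teacher decoder: ", decoder)
    }
    paste0("t", j)
  }
  if (is_base && !is.null(condition)) {
    condition <- as.numeric(condition)
    if (length(condition) != cfg$n_slots) stop("condition code has wrong length for this model")
  }
  B <- enc$B
  geom <- model_geom(model, B)
  p <- function(nm) ag_param(tape, model$store, paste0(pfx, ".", nm))
  z <- enc$bottleneck
  for (s in seq.int(n, 1L)) {
    geo <- geom$stages[[s]]
    if (is_base && !is.null(condition)) {
      ce <- ag_matmul(tape, matrix(condition, nrow = 1L), p(paste0("s", s, ".cond.W")))
      ce <- ag_add(tape, ce, p(paste0("s", s, ".cond.b")))
      z <- ag_add_rowvec(tape, z, ce)
    }
    zp <- if (geo$p > 1L) ag_regroup(tape, z, geo$patch) else z
    Np <- geo$Hp^2
    if (s > mask_depth) {
      kv <- if (geo$p > 1L) ag_regroup(tape, enc$skips[[s]], geo$patch) else enc$skips[[s]]
      qn <- ag_layernorm(tape, zp, p(paste0("s", s, ".xattn.lnq.g")), p(paste0("s", s, ".xattn.lnq.b")))
      kn <- ag_layernorm(tape, kv, p(paste0("s", s, ".xattn.lnkv.g")), p(paste0("s", s, ".xattn.lnkv.b")))
      ca <- ag_mha(tape, qn, kn,
                   p(paste0("s", s, ".xattn.Wq")), p(paste0("s", s, ".xattn.Wk")),
                   p(paste0("s", s, ".xattn.Wv")), p(paste0("s", s, ".xattn.Wo")),
                   cfg$n_heads, B, Np, Np,
                   lambda_attn = lambda_attn, record = record)
      zp <- ag_add(tape, zp, ca)
    }
    zp <- transformer_block(tape, zp, paste0(pfx, ".s", s, ".blk"), geo, B, model,
                            record, lambda_attn, lambda_sae)
    z <- if (geo$p > 1L) ag_ungroup(tape, zp, geo$patch, B * geo$H^2, cfg$embed_dims[s]) else zp
    cout <- if (s == 1L) cfg$head_channels else cfg$embed_dims[s - 1L]
    z <- ag_matmul(tape, z, p(paste0("s", s, ".up.W")))
    z <- ag_ungroup(tape, z, geo$deconv, B * (2L * geo$H)^2, cout)
    z <- ag_add_rowvec(tape, z, p(paste0("s", s, ".up.b")))
    z <- ag_relu(tape, z)
  }
  logits <- ag_add_rowvec(tape, ag_matmul(tape, z, p("head.W")), p("head.b"))
  y_hat <- ag_sigmoid(tape, logits)
  structure(list(y_hat = y_hat, source = if (is_base) "base" else paste0("teacher_", pfx),
                 mask_depth = as.integer(mask_depth), B = B),
            class = "faz_prediction")
}

#' Predict FAZ probability maps
#'
#' Full inference pass through the base model (teachers are never used at
#' test time).
#'
#' @param model a `faz_model`.
#' @param X image batch (`(B, H, W)` array or `H x W` matrix).
#' @param condition a [condition_code()] or slot index; `NULL` for models
#'   trained without conditioning.
#' @param decoder `"base"` or a teacher index.
#' @return `(B, H, W)` array of probabilities in `[0, 1]`.
#' @export
faz_predict <- function(model, X, condition = NULL, decoder = "base") {
  cfg <- model$config
  if (!is.null(condition) && length(condition) == 1L) {
    condition <- condition_code(condition, cfg$n_slots)
  }
  enc <- encoder_forward(model, X, tape = NULL)
  pred <- decoder_forward(model, enc, condition = condition, decoder = decoder, tape = NULL)
  unflatten_maps(pred$y_hat, enc$B, cfg$image_size, cfg$image_size)
}

#' Activation statistics of a forward pass
#'
#' Runs the base model on a batch and summarizes the recorded activations:
#' the mean absolute pre-softmax content attention score and the fraction of
#' SAE hidden activations below a threshold. These are the quantities the L1
#' penalties act on, so they quantify the sparsity response to
#' `lambda_l1_attn` and `lambda_l1_sae`.
#'
#' @param model a `faz_model`.
#' @param X image batch.
#' @param condition optional condition (slot index or [condition_code()]).
#' @return list with `mean_abs_content_score` and `frac_sae_near_zero` (an
#'   SAE hidden activation counts as inactive below 1e-3).
#' @export
activation_stats <- function(model, X, condition = NULL) {
  if (!is.null(condition) && length(condition) == 1L) {
    condition <- condition_code(condition, model$config$n_slots)
  }
  rec <- new.env(parent = emptyenv())
  enc <- encoder_forward(model, X, tape = NULL, record = rec, lambda_attn = 1e-12)
  invisible(decoder_forward(model, enc, condition = condition, tape = NULL,
                            record = rec, lambda_attn = 1e-12))
  list(mean_abs_content_score = rec$attn_abs_sum / rec$attn_n,
       frac_sae_near_zero = rec$sae_near_zero / rec$sae_n)
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding the parameter arrays together with
#' the model configuration serialized as JSON text and its hash; loading into
#' a model with a different configuration is refused.
#'
#' @param model a `faz_model`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model invisibly; `faz_load_model` returns a new `faz_model`.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$config
  obj <- list(
    config_json = jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
    config_hash = config_hash(cfg),
    params = model$store$params,
    seed = model$seed,
    has_teachers = model$has_teachers
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  obj <- readRDS(path)
  if (obj$config_hash != config_hash(model$config)) {
    stop("checkpoint configuration hash does not match this model's configuration")
  }
  keep <- intersect(names(obj$params), names(model$store$params))
  if (length(keep) == 0L) stop("checkpoint shares no parameters with this model")
  model$store$params[keep] <- obj$params[keep]
  invisible(model)
}

#' @rdname save_checkpoint
#' @export
faz_load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- as.list(jsonlite::fromJSON(obj$config_json))
  cfg$embed_dims <- as.integer(cfg$embed_dims)
  cfg$patch_size <- as.integer(cfg$patch_size)
  config <- do.call(model_config, cfg[c("n_stages", "embed_dims", "n_heads", "patch_size",
                                        "sae_expansion", "n_conditions",
                                        "condition_agnostic_slot", "image_size",
                                        "pos_rank", "sigma_per_patch", "downsample")])
  m <- build_base_model(config, seed = obj$seed %||% 0L)
  if (isTRUE(obj$has_teachers)) build_teachers(m)
  m$store$params <- obj$params
  m
}
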