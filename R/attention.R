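#' Rectangular patch grid
#'
#' Coordinates of image patches laid out row-major on an `h x w` grid, in
#' patch units. These coordinates feed the Gaussian locality kernel, which
#' scores patch pairs by their spatial displacement.
#'
#' @param h,w grid height and width in patches.
#' @return an object of class `faz_patch_grid` with fields `coords`
#'   (`n_patches x 2` matrix of (x, y)) and `n_patches`.
#' @export
patch_grid <- function(h, w = h) {
  stopifnot(h >= 1, w >= 1)
  coords <- cbind(
    x = rep(seq_len(w), times = h),
    y = rep(seq_len(h), each = w)
  )
  structure(list(coords = coords, n_patches = h * w, h = h, w = w),
            class = "faz_patch_grid")
}

#' Attention bias parameters
#'
#' Holds the learnable scales of the elliptical Gaussian locality kernel
#' (`sigma_x`, `sigma_y`, one per head, in squared patch units: the kernel is
#' `exp(-dx^2/sigma_x - dy^2/sigma_y)`) and the low-rank factors of the
#' content-independent positional score matrix (`P_h = U_h V_h^T`).
#'
#' @param n_heads number of attention heads.
#' @param n_patches number of patches in the grid.
#' @param sigma_x,sigma_y numeric vectors (length `n_heads` or 1, recycled) of
#'   positive Gaussian scales.
#' @param rank rank of the positional factorization.
#' @param pos_u,pos_v optional `n_patches x (rank * n_heads)` factor matrices;
#'   default zero (no positional bias).
#' @return an object of class `faz_attention_params`.
#' @export
attention_params <- function(n_heads, n_patches, sigma_x = 1, sigma_y = 1,
                             rank = 8, pos_u = NULL, pos_v = NULL) {
  sigma_x <- rep_len(sigma_x, n_heads)
  sigma_y <- rep_len(sigma_y, n_heads)
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) {
    stop("sigma_x and sigma_y must be strictly positive")
  }
  if (is.null(pos_u)) pos_u <- matrix(0, n_patches, rank * n_heads)
  if (is.null(pos_v)) pos_v <- matrix(0, n_patches, rank * n_heads)
  stopifnot(nrow(pos_u) == n_patches, ncol(pos_u) == rank * n_heads,
            nrow(pos_v) == n_patches, ncol(pos_v) == rank * n_heads)
  structure(list(n_heads = n_heads, n_patches = n_patches,
                 sigma_x = sigma_x, sigma_y = sigma_y, rank = rank,
                 pos_u = pos_u, pos_v = pos_v),
            class = "faz_attention_params")
}

#' Gaussian locality attention scores
#'
#' Pre-softmax additive scores of the elliptical Gaussian locality kernel in
#' log form: `score[i, j] = -(x_i - x_j)^2 / sigma_x - (y_i - y_j)^2 / sigma_y`.
#' Exponentiating a score recovers the kernel value, so the diagonal is 0
#' (kernel 1) and all scores are non-positive.
#'
#' @param grid a [patch_grid()].
#' @param params a [attention_params()]; `sigma_x[h]`, `sigma_y[h]` are used
#'   for head `h`.
#' @return a list of `n_patches x n_patches` score matrices, one per head.
#' @export
gaussian_local_scores <- function(grid, params) {
  stopifnot(inherits(grid, "faz_patch_grid"),
            inherits(params, "faz_attention_params"),
            params$n_patches == grid$n_patches)
  dx2 <- outer(grid$coords[, 1], grid$coords[, 1], "-")^2
  dy2 <- outer(grid$coords[, 2], grid$coords[, 2], "-")^2
  lapply(seq_len(params$n_heads), function(h) {
    -(dx2 / params$sigma_x[h] + dy2 / params$sigma_y[h])
  })
}

#' Positional attention scores
#'
#' Content-independent attention scores determined purely by the absolute
#' patch locations: a learnable low-rank matrix `P_h = U_h V_h^T` per head.
#' Identical for every input batch by construction.
#'
#' @param params a [attention_params()].
#' @return a list of `n_patches x n_patches` score matrices, one per head.
#' @export
positional_scores <- function(params) {
  stopifnot(inherits(params, "faz_attention_params"))
  r <- params$rank
  lapply(seq_len(params$n_heads), function(h) {
    cols <- ((h - 1L) * r + 1L):(h * r)
    tcrossprod(params$pos_u[, cols, drop = FALSE],
               params$pos_v[, cols, drop = FALSE])
  })
}

#' Combine content, positional and locality scores into attention weights
#'
#' The three score matrices are added pre-softmax and a row-wise softmax
#' produces a row-stochastic attention matrix. Adding the Gaussian kernel in
#' log form keeps rows normalized and is numerically stable.
#'
#' @param content_scores,positional_scores,local_scores matrices of equal
#'   shape (a single head).
#' @return a row-stochastic matrix of the same shape.
#' @export
combined_attention <- function(content_scores, positional_scores, local_scores) {
  if (!all(dim(content_scores) == dim(positional_scores)) ||
      !all(dim(content_scores) == dim(local_scores))) {
    stop("score matrices must have identical shapes")
  }
  s <- content_scores + positional_scores + local_scores
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

#' Sparse-autoencoder feed-forward block (functional form)
#'
#' The transformer feed-forward is replaced by a sparse autoencoder: an
#' overcomplete hidden layer (`expansion` times the embedding dimension) with
#' ReLU activations, projected back to the embedding dimension. The hidden
#' activations are returned so an L1 activity penalty can be applied to them.
#'
#' @param x `n x d` matrix of patch embeddings.
#' @param W1 `d x (expansion * d)` encoder weights; `b1` hidden bias.
#' @param W2 `(expansion * d) x d` decoder weights; `b2` output bias.
#' @return list with `output` (`n x d`) and `hidden` (`n x (expansion * d)`).
#' @export
sae_ffn <- function(x, W1, b1, W2, b2) {
  stopifnot(ncol(x) == nrow(W1), ncol(W1) == nrow(W2), ncol(W2) == ncol(x))
  pre <- sweep(x %*% W1, 2L, as.numeric(b1), "+")
  h <- pre * (pre > 0)
  out <- sweep(h %*% W2, 2L, as.numeric(b2), "+")
  list(output = out, hidden = h)
}
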