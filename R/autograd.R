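# Compact reverse-mode automatic differentiation over dense matrices.
#
# Every tensor in the network is a plain numeric matrix; a "node" is an
# environment holding the value, an accumulated gradient, and a backward
# closure. Ops come in a single implementation that runs in two modes:
# with tape == NULL they compute values only (cheap inference path); with a
# tape they additionally register a backward closure. Backward passes are
# hand-derived; the test suite checks them against central finite differences.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e$pcache <- new.env(parent = emptyenv())
  e
}

ag_is_node <- function(x) is.environment(x)

ag_val <- function(x) if (is.environment(x)) x$value else x

ag_acc <- function(x, g) {
  if (is.environment(x)) x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

ag_node <- function(tape, value, backward = NULL, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$name <- name
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# Parameter leaf; cached per tape so gradients from all uses accumulate in one node.
ag_param <- function(tape, store, name) {
  if (is.null(tape)) return(store$params[[name]])
  nd <- tape$pcache[[name]]
  if (is.null(nd)) {
    nd <- ag_node(tape, store$params[[name]], backward = NULL, name = name)
    tape$pcache[[name]] <- nd
  }
  nd
}

# Seed the root (a scalar loss node) with gradient 1 and sweep the tape in
# reverse. Returns a named list of parameter gradients.
ag_backward <- function(tape, root) {
  root$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  grads <- list()
  for (nm in ls(tape$pcache)) {
    nd <- tape$pcache[[nm]]
    if (!is.null(nd$grad)) grads[[nm]] <- nd$grad
  }
  grads
}

# Scatter-add rows of g into target at positions idx (0 = discard), handling
# duplicate indices via rowsum().
ag_scatter_add <- function(target, idx, g) {
  sel <- idx > 0L
  if (!all(sel)) {
    idx <- idx[sel]
    g <- g[sel, , drop = FALSE]
  }
  if (length(idx) == 0L) return(target)
  rs <- rowsum(g, group = idx)
  rows <- as.integer(rownames(rs))
  target[rows, ] <- target[rows, , drop = FALSE] + rs
  target
}

## ---- elementwise / linear ops -------------------------------------------

ag_matmul <- function(tape, a, b) {
  v <- ag_val(a) %*% ag_val(b)
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    ag_acc(a, g %*% t(ag_val(b)))
    ag_acc(b, crossprod(ag_val(a), g))
  })
}

ag_add <- function(tape, a, b) {
  v <- ag_val(a) + ag_val(b)
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    ag_acc(a, g)
    ag_acc(b, g)
  })
}

# x: (N x C); v: (1 x C) bias/embedding broadcast over rows.
ag_add_rowvec <- function(tape, x, v) {
  xv <- ag_val(x)
  out <- sweep(xv, 2L, as.numeric(ag_val(v)), "+")
  if (is.null(tape)) return(out)
  ag_node(tape, out, backward = function(g) {
    ag_acc(x, g)
    ag_acc(v, matrix(colSums(g), nrow = 1L))
  })
}

ag_scale <- function(tape, x, k) {
  v <- ag_val(x) * k
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) ag_acc(x, g * k))
}

ag_relu <- function(tape, x) {
  xv <- ag_val(x)
  v <- xv * (xv > 0)
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) ag_acc(x, g * (xv > 0)))
}

ag_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-ag_val(x)))
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) ag_acc(x, g * v * (1 - v)))
}

## ---- gather / regroup (convolution im2col, patchify, upsampling) ---------

# idx: integer matrix (Nout x K); out[i, ] = concat_k x[idx[i, k], ], with
# idx == 0 contributing a zero row (zero padding). Compiled kernel.
ag_regroup <- function(tape, x, idx) {
  xv <- ag_val(x)
  n_in <- nrow(xv)
  v <- cpp_gather(xv, idx)
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    ag_acc(x, cpp_scatter(g, idx, n_in))
  })
}

# Inverse of ag_regroup for a partition index (each target row appears exactly
# once across idx): writes chunk k of x back to rows idx[, k].
ag_ungroup <- function(tape, x, idx, n_rows, C) {
  xv <- ag_val(x)
  v <- cpp_ungroup_fwd(xv, idx, n_rows, C)
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    ag_acc(x, cpp_ungroup_bwd(g, idx, nrow(xv), ncol(xv)))
  })
}

## ---- layer norm -----------------------------------------------------------

ag_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- ag_val(x)
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  s <- sqrt(va + eps)
  z <- xc / s
  gv <- as.numeric(ag_val(gamma))
  bv <- as.numeric(ag_val(beta))
  v <- sweep(sweep(z, 2L, gv, "*"), 2L, bv, "+")
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    dz <- sweep(g, 2L, gv, "*")
    ag_acc(gamma, matrix(colSums(g * z), nrow = 1L))
    ag_acc(beta, matrix(colSums(g), nrow = 1L))
    m1 <- rowMeans(dz)
    m2 <- rowMeans(dz * z)
    ag_acc(x, (dz - m1 - z * m2) / s)
  })
}

## ---- losses ---------------------------------------------------------------

ag_bce <- function(tape, y_hat, y, eps = 1e-7) {
  yh <- ag_val(y_hat)
  p <- pmin(pmax(yh, eps), 1 - eps)
  n <- length(p)
  v <- -sum(y * log(p) + (1 - y) * log(1 - p)) / n
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    d <- (p - y) / (p * (1 - p)) / n
    d[yh < eps | yh > 1 - eps] <- 0
    ag_acc(y_hat, g * d)
  })
}

# BCE against a soft target node: gradients flow into both the prediction
# and the target (d/dy of the pixel term is -logit(p)).
ag_bce_soft <- function(tape, y_hat, y_t, eps = 1e-7) {
  yh <- ag_val(y_hat)
  yt <- ag_val(y_t)
  p <- pmin(pmax(yh, eps), 1 - eps)
  n <- length(p)
  v <- -sum(yt * log(p) + (1 - yt) * log(1 - p)) / n
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    d <- (p - yt) / (p * (1 - p)) / n
    d[yh < eps | yh > 1 - eps] <- 0
    ag_acc(y_hat, g * d)
    ag_acc(y_t, g * (-log(p / (1 - p)) / n))
  })
}

ag_dice <- function(tape, y_hat, y, delta1 = 1, delta2 = 1) {
  yh <- ag_val(y_hat)
  num <- 2 * sum(y * yh) + delta1
  den <- sum(y + yh) + delta2
  v <- 1 - num / den
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    ag_acc(y_hat, g * (-2 * y / den + num / den^2))
  })
}

# Weighted sum of scalar nodes.
ag_lincomb <- function(tape, nodes, coefs) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + coefs[i] * ag_val(nodes[[i]])
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    for (i in seq_along(nodes)) ag_acc(nodes[[i]], g * coefs[i])
  })
}

## ---- fused multi-head attention -------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Multi-head attention over a batch of token grids, with optional additive
# pre-softmax biases: a low-rank positional score matrix (U_h V_h^T, a
# function of parameters only) and the Gaussian locality log-kernel
# -(dx^2/sigma_x + dy^2/sigma_y) with sigma = softplus(rho) > 0 per head
# (or per head and query patch). An L1 penalty on the pre-softmax content
# scores can be attached; its value is accumulated in `record` and its
# gradient is injected during the backward sweep.
#
# xq: (B*Nq x D), xkv: (B*Nk x D). pos_u/pos_v: (Nq x r*heads). rho_x/rho_y:
# (heads x 1) or (heads x Nq). dx2/dy2: constant (Nq x Nk) squared
# displacements in patch units.
ag_mha <- function(tape, xq, xkv, Wq, Wk, Wv, Wo, n_heads, B, Nq, Nk,
                   pos_u = NULL, pos_v = NULL,
                   rho_x = NULL, rho_y = NULL, dx2 = NULL, dy2 = NULL,
                   lambda_attn = 0, record = NULL, tag = "attn") {
  xqv <- ag_val(xq)
  xkvv <- ag_val(xkv)
  use_pos <- !is.null(pos_u)
  use_gauss <- !is.null(rho_x)
  empty <- matrix(0, 0, 0)
  uv <- if (use_pos) ag_val(pos_u) else empty
  vv <- if (use_pos) ag_val(pos_v) else empty
  rx <- if (use_gauss) ag_val(rho_x) else empty
  ry <- if (use_gauss) ag_val(rho_y) else empty
  sig_x <- if (use_gauss) softplus(rx) else empty
  sig_y <- if (use_gauss) softplus(ry) else empty
  per_patch <- use_gauss && ncol(rx) > 1L
  if (!use_gauss) { dx2 <- empty; dy2 <- empty }
  need_abs <- lambda_attn > 0 || !is.null(record)

  fw <- cpp_mha_fwd(xqv, xkvv, ag_val(Wq), ag_val(Wk), ag_val(Wv), ag_val(Wo),
                    n_heads, B, Nq, Nk, uv, vv, use_pos,
                    sig_x, sig_y, dx2, dy2, use_gauss, per_patch, need_abs)
  n_scores <- B * n_heads * Nq * Nk
  if (!is.null(record)) {
    record$attn_abs_sum <- (record$attn_abs_sum %||% 0) + fw$abs_sum
    record$attn_n <- (record$attn_n %||% 0) + n_scores
    record$l1_attn <- (record$l1_attn %||% 0) + lambda_attn * fw$abs_sum / n_scores
  }
  if (is.null(tape)) return(fw$out)

  ag_node(tape, fw$out, backward = function(g) {
    bw <- cpp_mha_bwd(g, fw$A, fw$Q, fw$K, fw$V, xqv, xkvv,
                      ag_val(Wq), ag_val(Wk), ag_val(Wv), ag_val(Wo),
                      n_heads, B, Nq, Nk, uv, vv, use_pos,
                      rx, ry, sig_x, sig_y, dx2, dy2,
                      use_gauss, per_patch, lambda_attn)
    ag_acc(Wq, bw$dWq)
    ag_acc(Wk, bw$dWk)
    ag_acc(Wv, bw$dWv)
    ag_acc(Wo, bw$dWo)
    ag_acc(xq, bw$dxq)
    ag_acc(xkv, bw$dxkv)
    if (use_pos) { ag_acc(pos_u, bw$dU); ag_acc(pos_v, bw$dV) }
    if (use_gauss) { ag_acc(rho_x, bw$drx); ag_acc(rho_y, bw$dry) }
  })
}

## ---- fused sparse-autoencoder feed-forward --------------------------------

# Overcomplete hidden layer (width = expansion * embed dim), ReLU, projection
# back to the embed dim. Hidden activations are recorded so the L1 activity
# penalty can be reported and measured; the penalty subgradient is injected
# during backward.
ag_sae <- function(tape, x, W1, b1, W2, b2, lambda_sae = 0, record = NULL) {
  xv <- ag_val(x)
  pre <- sweep(xv %*% ag_val(W1), 2L, as.numeric(ag_val(b1)), "+")
  h <- pre * (pre > 0)
  out <- sweep(h %*% ag_val(W2), 2L, as.numeric(ag_val(b2)), "+")
  nh <- length(h)
  if (!is.null(record)) {
    record$sae_abs_sum <- (record$sae_abs_sum %||% 0) + sum(h)
    record$sae_n <- (record$sae_n %||% 0) + nh
    record$sae_near_zero <- (record$sae_near_zero %||% 0) + sum(h < 1e-3)
    record$l1_sae <- (record$l1_sae %||% 0) + lambda_sae * sum(h) / nh
  }
  if (is.null(tape)) return(out)
  ag_node(tape, out, backward = function(g) {
    dh <- g %*% t(ag_val(W2))
    ag_acc(W2, crossprod(h, g))
    ag_acc(b2, matrix(colSums(g), nrow = 1L))
    if (lambda_sae > 0) dh <- dh + lambda_sae * (h > 0) / nh
    dpre <- dh * (pre > 0)
    ag_acc(W1, crossprod(xv, dpre))
    ag_acc(b1, matrix(colSums(dpre), nrow = 1L))
    ag_acc(x, dpre %*% t(ag_val(W1)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
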