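# Loss constructions: the hybrid Dice + BCE segmentation loss, the
# three-term distillation loss, the depth-masked total loss with the
# geometric 2^-i schedule, and the L1 sparsity penalties.

#' Loss weights
#'
#' @param c1,c2 hybrid weights of the BCE and Dice terms (defaults 1, 1/2).
#' @param delta1,delta2 Dice smoothing constants (defaults 1, 1).
#' @param alpha,beta,gamma distillation weights (defaults 1, 1/2, 1/4);
#'   must satisfy `alpha > beta > gamma > 0` so the base model and the
#'   ground truth are prioritized over the teacher comparison.
#' @param n_stages depth of the `a_i = 2^-i` schedule (coefficients for
#'   `i = 0..n_stages`).
#' @param lambda_l1_attn,lambda_l1_sae L1 coefficients on pre-softmax content
#'   attention scores and on SAE hidden activations.
#' @return an object of class `faz_loss_weights`.
#' @export
loss_weights <- function(c1 = 1, c2 = 0.5, delta1 = 1, delta2 = 1,
                         alpha = 1, beta = 0.5, gamma = 0.25,
                         n_stages = 3L,
                         lambda_l1_attn = 1e-4, lambda_l1_sae = 1e-4) {
  if (!(alpha > beta && beta > gamma && gamma > 0)) {
    stop("distillation weights must satisfy alpha > beta > gamma > 0")
  }
  a <- a_schedule(n_stages)
  structure(list(c1 = c1, c2 = c2, delta1 = delta1, delta2 = delta2,
                 alpha = alpha, beta = beta, gamma = gamma,
                 a_schedule = a,
                 lambda_l1_attn = lambda_l1_attn, lambda_l1_sae = lambda_l1_sae),
            class = "faz_loss_weights")
}

#' Depth-coefficient schedule a_i = 2^-i
#'
#' Geometric coefficients for the depth-masked loss, `i = 0..n_stages`
#' (i = 0 is the unmasked model). Each coefficient exceeds the sum of all
#' subsequent ones, so the loss prioritizes more complete models.
#'
#' @param n_stages number of maskable decoder stages.
#' @return numeric vector of length `n_stages + 1`.
#' @export
a_schedule <- function(n_stages) 2^-(0:n_stages)

#' Soft Dice loss
#'
#' `1 - (2 * sum(y * y_hat) + delta1) / (sum(y + y_hat) + delta2)`. With
#' `delta1 = delta2 = 1` the loss lies in `[0, 1)` and is 0 for a perfect
#' binary match, including the empty-vs-empty case.
#'
#' @param y_hat predicted probabilities in `[0, 1]`.
#' @param y binary ground-truth mask (same shape).
#' @param delta1,delta2 smoothing constants.
#' @return scalar loss.
#' @export
dice_loss <- function(y_hat, y, delta1 = 1, delta2 = 1) {
  if (!identical(dim(y_hat), dim(y)) && length(y_hat) != length(y)) {
    stop("y_hat and y must have the same shape")
  }
  1 - (2 * sum(y * y_hat) + delta1) / (sum(y + y_hat) + delta2)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log(y_hat) + (1 - y) log(1 - y_hat)]`, with
#' `y_hat` clipped to `[eps, 1 - eps]`.
#'
#' @param y_hat predicted probabilities; `y` binary mask; `eps` clip.
#' @inheritParams dice_loss
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(y_hat, y, eps = 1e-7) {
  if (!identical(dim(y_hat), dim(y)) && length(y_hat) != length(y)) {
    stop("y_hat and y must have the same shape")
  }
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Hybrid segmentation loss
#'
#' `c1 * BCE + c2 * Dice` — BCE stabilizes training while the Dice term
#' targets overlap directly.
#'
#' @inheritParams dice_loss
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
hybrid_loss <- function(y_hat, y, weights = loss_weights()) {
  weights$c1 * bce_loss(y_hat, y) +
    weights$c2 * dice_loss(y_hat, y, weights$delta1, weights$delta2)
}

#' Three-term distillation loss
#'
#' `alpha * L(y_base, y) + beta * L(y_teacher, y) + gamma * L(y_base,
#' y_teacher)`, each `L` the hybrid loss. The third term treats the teacher's
#' real-valued probability map as the target of the base output; teachers
#' carry richer information than the binary masks alone.
#'
#' @param y_base,y_teacher_j predicted probability maps of the base model and
#'   of the teacher matched to the batch's condition.
#' @param y binary ground-truth mask.
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
distill_loss <- function(y_base, y_teacher_j, y, weights = loss_weights()) {
  weights$alpha * hybrid_loss(y_base, y, weights) +
    weights$beta * hybrid_loss(y_teacher_j, y, weights) +
    weights$gamma * hybrid_loss(y_base, y_teacher_j, weights)
}

#' L1 sparsity penalties
#'
#' `lambda_l1_attn * mean(|pre-softmax content scores|) + lambda_l1_sae *
#' mean(|SAE hidden activations|)`. Penalizing content scores (rather than
#' the row-stochastic post-softmax weights, whose L1 norm is constant) pushes
#' the model toward the cheap positional and locality attention pathways;
#' penalizing hidden activations keeps few SAE units active.
#'
#' @param attention_scores list or array of pre-softmax content scores.
#' @param sae_hidden_activations list or array of SAE hidden activations.
#' @param weights a [loss_weights()].
#' @return scalar penalty.
#' @export
l1_penalties <- function(attention_scores, sae_hidden_activations,
                         weights = loss_weights()) {
  a <- unlist(attention_scores, use.names = FALSE)
  h <- unlist(sae_hidden_activations, use.names = FALSE)
  pa <- if (length(a)) mean(abs(a)) else 0
  ph <- if (length(h)) mean(abs(h)) else 0
  weights$lambda_l1_attn * pa + weights$lambda_l1_sae * ph
}

## ---- tape-side loss graph builders (training path) ------------------------

ag_hybrid <- function(tape, y_hat, y, w) {
  ag_lincomb(tape,
             list(ag_bce(tape, y_hat, y),
                  ag_dice(tape, y_hat, y, w$delta1, w$delta2)),
             c(w$c1, w$c2))
}

ag_distill <- function(tape, y_base, y_teacher, y, w) {
  ag_lincomb(tape,
             list(ag_hybrid(tape, y_base, y, w),
                  ag_hybrid(tape, y_teacher, y, w),
                  ag_hybrid_soft(tape, y_base, y_teacher, w)),
             c(w$alpha, w$beta, w$gamma))
}

# Hybrid loss against a soft (teacher) target node: BCE and Dice generalize
# directly to y in [0,1]; gradients flow into both arguments unless the
# teacher is detached.
ag_hybrid_soft <- function(tape, y_hat, y_t, w) {
  bce <- ag_bce_soft(tape, y_hat, y_t)
  dce <- ag_dice_soft(tape, y_hat, y_t, w$delta1, w$delta2)
  ag_lincomb(tape, list(bce, dce), c(w$c1, w$c2))
}

ag_dice_soft <- function(tape, y_hat, y_t, delta1, delta2) {
  yh <- ag_val(y_hat)
  yt <- ag_val(y_t)
  num <- 2 * sum(yt * yh) + delta1
  den <- sum(yt + yh) + delta2
  v <- 1 - num / den
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) {
    ag_acc(y_hat, g * (-2 * yt / den + num / den^2))
    ag_acc(y_t, g * (-2 * yh / den + num / den^2))
  })
}

# Attach recorded L1 penalty values (whose gradients were injected inside the
# fused ops) to a scalar task-loss node, so the reported loss value includes
# them while the gradient path stays consistent.
ag_attach_penalties <- function(tape, task, record) {
  pen <- (record$l1_attn %||% 0) + (record$l1_sae %||% 0)
  v <- ag_val(task) + pen
  if (is.null(tape)) return(v)
  ag_node(tape, v, backward = function(g) ag_acc(task, g))
}

#' Depth-masked total distillation loss
#'
#' Runs the shared encoder once, the base decoder at every mask depth
#' `i = 0..n_stages`, and the condition's teacher decoder at full depth, and
#' combines them as `sum_i a_i * [alpha * L(base_i, y)]` plus the teacher and
#' base-teacher comparison terms at `i = 0` (`a_0 = 1`), with `a_i = 2^-i`.
#' Masking progressively removes the shallow skip connections, forcing the
#' deeper layers to produce compressed representations that already explain
#' the output.
#'
#' @param model a `faz_model` with teachers built.
#' @param X image batch `(B, H, W)`.
#' @param y binary masks, same shape as `X`.
#' @param condition condition slot index (selects the teacher) or a
#'   [condition_code()]; the teacher index is the argmax slot.
#' @param weights a [loss_weights()].
#' @param tape optional autodiff tape; `NULL` evaluates the value only.
#' @param record optional environment for activation statistics.
#' @param detach_teacher if `TRUE`, stop gradients through the teacher output
#'   in the comparison term (default `FALSE`: trained end-to-end).
#' @return scalar loss (autodiff node under a tape).
#' @export
depth_masked_total_loss <- function(model, X, y, condition,
                                    weights = loss_weights(), tape = NULL,
                                    record = NULL, detach_teacher = FALSE) {
  cfg <- model$config
  if (!model$has_teachers) stop("model has no teacher decoders; call build_teachers()")
  if (length(condition) == 1L) {
    j <- as.integer(condition)
    cond <- condition_code(j, cfg$n_slots)
  } else {
    cond <- condition_code(condition, cfg$n_slots)
    j <- which.max(as.numeric(cond))
  }
  if (j > cfg$n_conditions) stop("condition ", j, " has no teacher decoder")
  if (is.null(record)) record <- new.env(parent = emptyenv())
  la <- weights$lambda_l1_attn
  ls <- weights$lambda_l1_sae
  yv <- flatten_images(y)
  enc <- encoder_forward(model, X, tape = tape, record = record,
                         lambda_attn = la, lambda_sae = ls)
  a <- a_schedule(cfg$n_stages)
  teacher <- decoder_forward(model, enc, condition = NULL, mask_depth = 0L,
                             decoder = j, tape = tape, record = record,
                             lambda_attn = la, lambda_sae = ls)
  y_t <- teacher$y_hat
  if (detach_teacher && !is.null(tape)) {
    y_t <- ag_node(tape, ag_val(y_t), backward = NULL)
  }
  terms <- vector("list", cfg$n_stages + 2L)
  coefs <- numeric(cfg$n_stages + 2L)
  for (i in 0:cfg$n_stages) {
    base_i <- decoder_forward(model, enc, condition = cond, mask_depth = i,
                              decoder = "base", tape = tape, record = record,
                              lambda_attn = la, lambda_sae = ls)
    terms[[i + 1L]] <- ag_hybrid(tape, base_i$y_hat, yv, weights)
    coefs[i + 1L] <- a[i + 1L] * weights$alpha
    if (i == 0L) base_full <- base_i
  }
  # beta: teacher vs ground truth (always trained); gamma: base vs teacher,
  # with the teacher side optionally detached as the distillation target
  terms[[cfg$n_stages + 2L]] <- ag_lincomb(
    tape,
    list(ag_hybrid(tape, teacher$y_hat, yv, weights),
         ag_hybrid_soft(tape, base_full$y_hat, y_t, weights)),
    c(weights$beta, weights$gamma))
  coefs[cfg$n_stages + 2L] <- a[1L]
  task <- ag_lincomb(tape, terms, coefs)
  ag_attach_penalties(tape, task, record)
}
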