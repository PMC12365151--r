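## Training objective: symmetric CLIP-style contrastive losses for the two
## image-clinical pairs, a class-weighted focal loss on the classifier
## logits, and a dynamic weight that balances the two groups by their
## current (detached) magnitudes.

#' Symmetric contrastive loss over a similarity-logit matrix
#'
#' Cross-entropy of each row of `l` against its own index (image -> clinical
#' matching) plus cross-entropy of each row of `t(l)` against its own index
#' (clinical -> image), halved and averaged over the batch. With
#' `targets = "class"`, positives are all batch items sharing the anchor's
#' label (soft uniform targets) instead of only the matching pair.
#'
#' @param l Square N x N logit matrix ([similarity_logits()]).
#' @param targets `"pair"` (CLIP matching-pair targets, default) or
#'   `"class"` (supervised-contrastive style).
#' @param labels Class labels, required for `targets = "class"`.
#' @return Non-negative scalar loss.
#' @export
clip_contrastive_loss <- function(l, targets = c("pair", "class"),
                                  labels = NULL) {
  targets <- match.arg(targets)
  if (!is.matrix(l) || nrow(l) != ncol(l)) {
    stop("clip_contrastive_loss(): logits must be a square matrix")
  }
  n <- nrow(l)
  tmat <- contrastive_target_matrix(n, targets, labels)
  ce <- function(logits) {
    lse <- log(rowSums(exp(logits - apply(logits, 1, max)))) +
      apply(logits, 1, max)
    mean(rowSums(tmat * (lse - logits)))
  }
  (ce(l) + ce(t(l))) / 2
}

contrastive_target_matrix <- function(n, targets, labels) {
  if (targets == "pair") return(diag(n))
  if (is.null(labels) || length(labels) != n) {
    stop("class-level contrastive targets need one label per batch item")
  }
  same <- outer(labels, labels, `==`) * 1
  same / rowSums(same)
}

## Gradient of clip_contrastive_loss w.r.t. the logit matrix.
contrastive_grad <- function(l, targets = "pair", labels = NULL) {
  n <- nrow(l)
  tmat <- contrastive_target_matrix(n, targets, labels)
  (softmax_rows(l) - tmat) / (2 * n) +
    t(softmax_rows(t(l)) - tmat) / (2 * n)
}

#' Inverse-frequency focal-loss class weights
#'
#' `alpha[c] = N_total / (n_classes * count[c])`: a balanced dataset yields
#' all-ones; rarer classes get proportionally larger weights. Invariant to
#' rescaling all counts.
#'
#' @param label_counts Positive integer count per class.
#' @return Numeric weight vector.
#' @export
class_alpha_weights <- function(label_counts) {
  if (any(label_counts <= 0)) {
    stop("class_alpha_weights(): every class needs a positive count")
  }
  sum(label_counts) / (length(label_counts) * label_counts)
}

#' Focal loss for multi-class logits
#'
#' `mean( alpha_t * (1 - p_t)^gamma * (-log p_t) )` with `p_t` the softmax
#' probability of the true class. `gamma = 0` with unit weights reduces to
#' the mean cross-entropy.
#'
#' @param logits N x C matrix of class logits.
#' @param labels 0-based integer class labels, length N.
#' @param alpha_t Per-class weights (default all ones).
#' @param gamma Focusing parameter (default 0.25).
#' @return Non-negative scalar loss.
#' @export
focal_loss <- function(logits, labels, alpha_t = rep(1, ncol(logits)),
                       gamma = 0.25) {
  if (!is.matrix(logits) || nrow(logits) == 0L) {
    stop("focal_loss(): empty batch")
  }
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(logits))) {
    stop("focal_loss(): label outside 0..", ncol(logits) - 1L)
  }
  if (length(alpha_t) != ncol(logits) || any(alpha_t <= 0)) {
    stop("focal_loss(): alpha_t must be positive, one weight per class")
  }
  p <- softmax_rows(logits)
  pt <- pmin(pmax(p[cbind(seq_len(nrow(p)), labels + 1L)], 1e-12), 1 - 1e-12)
  mean(alpha_t[labels + 1L] * (1 - pt)^gamma * (-log(pt)))
}

## Gradient of focal_loss w.r.t. the logits.
focal_grad <- function(logits, labels, alpha_t = rep(1, ncol(logits)),
                       gamma = 0.25) {
  n <- nrow(logits)
  labels <- as.integer(labels)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  pt <- pmin(pmax(p[idx], 1e-12), 1 - 1e-12)
  a <- alpha_t[labels + 1L]
  # dL/dp_t, then through the softmax Jacobian (only the true-class prob
  # enters the per-sample loss)
  dpt <- a * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  onehot <- matrix(0, n, ncol(logits))
  onehot[idx] <- 1
  (dpt * pt / n) * (onehot - p)
}

#' Dynamic weight between contrastive and focal losses
#'
#' `omega = Lc / (Lc + Lf)` with `Lc` the summed contrastive losses and `Lf`
#' the focal loss: the larger group is down-weighted in the total objective.
#' Computed from detached values (no gradient flows through `omega`). When
#' both are zero the initial weight 0.5 is returned with a warning.
#'
#' @param l_contrastive_sum Non-negative summed contrastive loss.
#' @param l_focal Non-negative focal loss.
#' @return `omega` in `[0, 1]`.
#' @export
dynamic_weight <- function(l_contrastive_sum, l_focal) {
  if (l_contrastive_sum < 0 || l_focal < 0) {
    stop("dynamic_weight(): losses must be non-negative")
  }
  total <- l_contrastive_sum + l_focal
  if (total == 0) {
    warning("dynamic_weight(): both losses are zero; using omega = 0.5")
    return(0.5)
  }
  l_contrastive_sum / total
}

#' Combine the loss terms into the training objective
#'
#' `L_total = omega * (L_SC + L_LC) + (1 - omega) * L_focal` with `omega`
#' from [dynamic_weight()] (0.5, the initial weight, when every term
#' is zero). Substituting the weight gives the closed form
#' `(Lc^2 + Lf^2) / (Lc + Lf)`.
#'
#' @param l_sc,l_lc Contrastive losses for the small-CT/clinical and
#'   large-CT/clinical pairs.
#' @param l_focal Focal loss.
#' @return A `loss_bundle` list with `L_SC`, `L_LC`, `L_focal`, `omega`,
#'   `L_total`.
#' @export
total_loss <- function(l_sc, l_lc, l_focal) {
  if (any(c(l_sc, l_lc, l_focal) < 0)) {
    stop("total_loss(): losses must be non-negative")
  }
  lc <- l_sc + l_lc
  omega <- if (lc + l_focal == 0) 0.5 else dynamic_weight(lc, l_focal)
  structure(list(L_SC = l_sc, L_LC = l_lc, L_focal = l_focal,
                 omega = omega,
                 L_total = omega * lc + (1 - omega) * l_focal),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf(
    "<loss_bundle> L_SC %.4f  L_LC %.4f  L_focal %.4f  omega %.3f  L_total %.4f\n",
    x$L_SC, x$L_LC, x$L_focal, x$omega, x$L_total))
  invisible(x)
}
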