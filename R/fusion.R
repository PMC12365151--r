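## Feature alignment and fusion.
##
## The contrastive pathway L2-normalizes each modality feature and forms
## temperature-scaled cosine-similarity logits between image and clinical
## features. The classification pathway stacks the raw (un-normalized)
## features into F (batch x modalities x D) and refines them in two phases:
## Phase 1 is an n-layer transformer over the modality tokens (plain
## residual blocks: attention + FFN, no internal layer norms)
## followed by a per-token normalization; Phase 2 is channel attention that
## rescales each modality row by the sum of two sigmoid gates computed from
## average- and max-pooled channel statistics through a shared two-layer
## map. A linear head on the flattened stack produces class logits.

CLIP_LOG_SCALE_INIT <- log(1 / 0.07)

#' L2-normalize feature vectors
#'
#' @param f Numeric vector, or matrix whose rows are feature vectors.
#' @return Unit-norm vector / matrix of the same shape.
#' @export
l2_normalize <- function(f) {
  if (is.matrix(f)) {
    nrm <- sqrt(rowSums(f * f))
    if (any(nrm <= 0)) stop("l2_normalize(): zero-norm feature vector")
    f / nrm
  } else {
    nrm <- sqrt(sum(f * f))
    if (nrm <= 0) stop("l2_normalize(): zero-norm feature vector")
    f / nrm
  }
}

#' Temperature-scaled cosine-similarity logits
#'
#' `l[i, j] = exp(log_scale) * <z_a[i], z_b[j]>` for unit-norm feature rows.
#' At the standard initialization `log_scale = log(1 / 0.07)`, an identical
#' pair scores `1 / 0.07`.
#'
#' @param z_a,z_b Matrices of unit-norm rows (N x D each).
#' @param log_scale Log temperature scale (default `log(1 / 0.07)`).
#' @return N x N logit matrix.
#' @export
similarity_logits <- function(z_a, z_b, log_scale = CLIP_LOG_SCALE_INIT) {
  if (!is.matrix(z_a)) z_a <- matrix(z_a, nrow = 1L)
  if (!is.matrix(z_b)) z_b <- matrix(z_b, nrow = 1L)
  if (ncol(z_a) != ncol(z_b)) {
    stop("similarity_logits(): feature dimensions differ")
  }
  if (max(abs(c(rowSums(z_a^2), rowSums(z_b^2)) - 1)) > 1e-6) {
    stop("similarity_logits(): rows must be unit-norm (see l2_normalize())")
  }
  exp(log_scale) * tcrossprod(z_a, z_b)
}

## --- stack <-> array conversion -------------------------------------------
## F is stored sample-major as a (B*k) x D matrix; the user-facing shape is
## a B x k x D array.

stack_from_array <- function(arr) {
  d <- dim(arr)
  X <- aperm(arr, c(3, 2, 1))
  dim(X) <- c(d[3], d[2] * d[1])
  t(X)
}

array_from_stack <- function(X, n_batch, k) {
  arr <- t(X)
  dim(arr) <- c(ncol(X), k, n_batch)
  aperm(arr, c(3, 2, 1))
}

#' One fusion transformer block over the modality tokens
#'
#' Residual multi-head self-attention over the k modality tokens of each
#' sample, followed (when `ffn = TRUE`) by a residual feed-forward
#' sub-block.
#'
#' @param F_arr Array `batch x k x D`.
#' @param params Block parameters from [plain_block_init()].
#' @param n_heads Attention heads (must divide D).
#' @return Array of the same shape.
#' @export
transformer_block <- function(F_arr, params, n_heads) {
  d <- dim(F_arr)
  if (length(d) != 3L) stop("transformer_block(): expected batch x k x D")
  X <- stack_from_array(F_arr)
  if (any(!is.finite(X))) stop("transformer_block(): non-finite input")
  out <- plain_block_fwd(X, params, n_heads, d[2], d[1])$out
  array_from_stack(out, d[1], d[2])
}

phase1_norm_fwd <- function(X, kind) {
  if (kind == "layernorm") {
    layernorm_fwd(X, NULL)
  } else {
    nrm <- sqrt(rowSums(X * X))
    if (any(nrm <= 0)) stop("phase-1 norm: zero-norm token")
    list(out = X / nrm, cache = list(nrm = nrm, out = X / nrm))
  }
}

phase1_norm_bwd <- function(dY, st, kind) {
  if (kind == "layernorm") {
    layernorm_bwd(dY, st$cache, NULL)$dX
  } else {
    z <- st$cache$out
    (dY - z * rowSums(z * dY)) / st$cache$nrm
  }
}

#' Phase-1 fusion: transformer layers plus final per-token normalization
#'
#' @param F_arr Array `batch x k x D`.
#' @param config A [cmmf_config()] (uses `dff_layers`, `dff_heads`,
#'   `phase1_norm`).
#' @param params List of block parameter lists (`dff$blocks` of a model).
#' @return Array of the same shape, per-token normalized.
#' @export
dff_phase1 <- function(F_arr, config, params) {
  if (config$dff_layers < 1L) stop("dff_phase1(): need at least one layer")
  d <- dim(F_arr)
  X <- stack_from_array(F_arr)
  for (i in seq_len(config$dff_layers)) {
    X <- plain_block_fwd(X, params[[i]], config$dff_heads, d[2], d[1])$out
  }
  array_from_stack(phase1_norm_fwd(X, config$phase1_norm)$out, d[1], d[2])
}

## --- channel attention ------------------------------------------------------

ca_fwd <- function(X, params, n_batch, k) {
  ap <- matrix(rowMeans(X), k, n_batch)
  rmax_idx <- max.col(X, ties.method = "first")
  mp <- matrix(X[cbind(seq_len(nrow(X)), rmax_idx)], k, n_batch)
  h1_pre <- params$W1 %*% ap
  h1 <- pmax(h1_pre, 0)
  g1 <- 1 / (1 + exp(-(params$W2 %*% h1)))
  h2_pre <- params$W1 %*% mp
  h2 <- pmax(h2_pre, 0)
  g2 <- 1 / (1 + exp(-(params$W2 %*% h2)))
  mult <- as.vector(g1 + g2)   # column-major: modality fastest, sample-major
  list(out = X * mult,
       cache = list(X = X, ap = ap, mp = mp, rmax_idx = rmax_idx,
                    h1_pre = h1_pre, h1 = h1, g1 = g1,
                    h2_pre = h2_pre, h2 = h2, g2 = g2, mult = mult,
                    n_batch = n_batch, k = k))
}

ca_bwd <- function(dOut, cache, params) {
  k <- cache$k; n_batch <- cache$n_batch
  X <- cache$X
  dX <- dOut * cache$mult
  dmult <- matrix(rowSums(dOut * X), k, n_batch)
  gW1 <- matrix(0, nrow(params$W1), ncol(params$W1))
  gW2 <- matrix(0, nrow(params$W2), ncol(params$W2))
  pool_grad <- function(g, h, h_pre, pooled) {
    dz <- dmult * g * (1 - g)
    gW2 <<- gW2 + tcrossprod(dz, h)
    dh <- crossprod(params$W2, dz)
    dh[h_pre <= 0] <- 0
    gW1 <<- gW1 + tcrossprod(dh, pooled)
    crossprod(params$W1, dh)   # k x n_batch gradient at the pooled stats
  }
  dap <- pool_grad(cache$g1, cache$h1, cache$h1_pre, cache$ap)
  dmp <- pool_grad(cache$g2, cache$h2, cache$h2_pre, cache$mp)
  dX <- dX + as.vector(dap) / ncol(X)
  idx <- cbind(seq_len(nrow(X)), cache$rmax_idx)
  dX[idx] <- dX[idx] + as.vector(dmp)
  list(dX = dX, grads = list(W1 = gW1, W2 = gW2))
}

#' Phase-2 fusion: channel attention over modality rows
#'
#' Pools each modality row of `F_p1` to its mean and max over D, passes both
#' statistics through a shared two-layer map (ReLU between, sigmoid after),
#' and rescales each row by the sum of the two gates (a multiplier in
#' `(0, 2)`; zero weights give exactly 1, the identity).
#'
#' @param F_arr Array `batch x k x D` (Phase-1 output).
#' @param params List with `W1` ((k/r) x k) and `W2` (k x (k/r)).
#' @return Array of the same shape.
#' @export
channel_attention <- function(F_arr, params) {
  d <- dim(F_arr)
  if (length(d) != 3L) stop("channel_attention(): expected batch x k x D")
  if (ncol(params$W1) != d[2] || nrow(params$W2) != d[2]) {
    stop("channel_attention(): weight shapes do not match channel count")
  }
  X <- stack_from_array(F_arr)
  array_from_stack(ca_fwd(X, params, d[1], d[2])$out, d[1], d[2])
}

## --- classification head ----------------------------------------------------

flatten_stack <- function(X, n_batch, k) {
  D <- ncol(X)
  out <- matrix(0, n_batch, k * D)
  for (m in seq_len(k)) {
    out[, ((m - 1L) * D + 1L):(m * D)] <-
      X[seq(m, n_batch * k, by = k), , drop = FALSE]
  }
  out
}

unflatten_stack <- function(Fl, n_batch, k) {
  D <- ncol(Fl) %/% k
  X <- matrix(0, n_batch * k, D)
  for (m in seq_len(k)) {
    X[seq(m, n_batch * k, by = k), ] <-
      Fl[, ((m - 1L) * D + 1L):(m * D), drop = FALSE]
  }
  X
}

#' Linear classification head on the fused stack
#'
#' Flattens `batch x k x D` to `batch x (k*D)` (modality-major) and applies
#' a linear map to class logits.
#'
#' @param F_arr Array `batch x k x D`.
#' @param params Linear parameters (`W` of shape (k*D) x n_classes, `b`).
#' @return Matrix `batch x n_classes` of logits.
#' @export
classify <- function(F_arr, params) {
  d <- dim(F_arr)
  if (length(d) != 3L) stop("classify(): expected batch x k x D")
  if (any(!is.finite(F_arr))) stop("classify(): non-finite input")
  linear_fwd(flatten_stack(stack_from_array(F_arr), d[1], d[2]), params)
}
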