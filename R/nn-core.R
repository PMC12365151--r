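## Neural-network primitives with explicit forward/backward passes.
##
## Token sequences for a batch are stored sample-major as a (B*T) x D
## matrix (rows 1..T are sample 1's tokens, and so on); all dense algebra
## then runs as single BLAS calls across the whole batch, while attention
## softmaxes loop over (sample, head) pairs on small matrices. Parameters
## are nested named lists of numeric arrays; gradients mirror the same
## structure.

trunc_normal <- function(n, sd = 0.02) {
  pmin(pmax(rnorm(n, sd = sd), -2 * sd), 2 * sd)
}

init_matrix <- function(d_in, d_out, sd = NULL) {
  if (is.null(sd)) sd <- 1 / sqrt(d_in)  # fan-in scaling
  matrix(rnorm(d_in * d_out, sd = sd), d_in, d_out)
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

linear_init <- function(d_in, d_out, sd = NULL) {
  list(W = init_matrix(d_in, d_out, sd), b = numeric(d_out))
}

linear_fwd <- function(X, p) add_bias(X %*% p$W, p$b)

linear_bwd <- function(dY, X, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

gelu_fwd <- function(x) x * pnorm(x)
gelu_bwd <- function(dy, x) dy * (pnorm(x) + x * dnorm(x))

softmax_rows <- function(M) {
  rmax <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - rmax)
  E / rowSums(E)
}

## --- layer normalization (per row over D), optional affine ----------------

layernorm_init <- function(D) list(g = rep(1, D), b = numeric(D))

layernorm_fwd <- function(X, p = NULL, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  out <- if (is.null(p)) xhat else add_bias(xhat * rep(p$g, each = nrow(X)), p$b)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dY, cache, p = NULL) {
  xhat <- cache$xhat
  dxhat <- if (is.null(p)) dY else dY * rep(p$g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  grads <- if (is.null(p)) NULL else
    list(g = colSums(dY * xhat), b = colSums(dY))
  list(dX = dX, grads = grads)
}

## --- multi-head self-attention over per-sample token blocks ---------------

mha_init <- function(D) {
  list(Wq = init_matrix(D, D), bq = numeric(D),
       Wk = init_matrix(D, D), bk = numeric(D),
       Wv = init_matrix(D, D), bv = numeric(D),
       Wo = init_matrix(D, D), bo = numeric(D))
}

mha_fwd <- function(X, p, n_heads, t_len, n_batch) {
  D <- ncol(X)
  if (D %% n_heads != 0) stop("mha_fwd(): head count must divide embed dim")
  dk <- D %/% n_heads
  Q <- add_bias(X %*% p$Wq, p$bq)
  K <- add_bias(X %*% p$Wk, p$bk)
  V <- add_bias(X %*% p$Wv, p$bv)
  ctx <- matrix(0, nrow(X), D)
  attn <- vector("list", n_batch * n_heads)
  for (b in seq_len(n_batch)) {
    rows <- ((b - 1L) * t_len + 1L):(b * t_len)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      A <- softmax_rows(tcrossprod(Qh, Kh) / sqrt(dk))
      ctx[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      attn[[(b - 1L) * n_heads + h]] <- A
    }
  }
  out <- add_bias(ctx %*% p$Wo, p$bo)
  list(out = out,
       cache = list(X = X, Q = Q, K = K, V = V, ctx = ctx, attn = attn,
                    n_heads = n_heads, t_len = t_len, n_batch = n_batch))
}

mha_bwd <- function(dOut, cache, p) {
  n_heads <- cache$n_heads; t_len <- cache$t_len; n_batch <- cache$n_batch
  D <- ncol(cache$X)
  dk <- D %/% n_heads
  dctx <- dOut %*% t(p$Wo)
  dQ <- matrix(0, nrow(dOut), D)
  dK <- matrix(0, nrow(dOut), D)
  dV <- matrix(0, nrow(dOut), D)
  for (b in seq_len(n_batch)) {
    rows <- ((b - 1L) * t_len + 1L):(b * t_len)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$attn[[(b - 1L) * n_heads + h]]
      dctx_h <- dctx[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dctx_h, Vh)
      dV[rows, cols] <- crossprod(A, dctx_h)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dk)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) /
        sqrt(dk)
    }
  }
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(
    Wq = crossprod(cache$X, dQ), bq = colSums(dQ),
    Wk = crossprod(cache$X, dK), bk = colSums(dK),
    Wv = crossprod(cache$X, dV), bv = colSums(dV),
    Wo = crossprod(cache$ctx, dOut), bo = colSums(dOut))
  list(dX = dX, grads = grads)
}

## --- MLP sub-block (linear -> GELU -> linear) ------------------------------

mlp_init <- function(D, hidden) {
  list(fc1 = linear_init(D, hidden), fc2 = linear_init(hidden, D))
}

mlp_fwd <- function(X, p) {
  h_pre <- linear_fwd(X, p$fc1)
  h <- gelu_fwd(h_pre)
  list(out = linear_fwd(h, p$fc2),
       cache = list(X = X, h_pre = h_pre, h = h))
}

mlp_bwd <- function(dOut, cache, p) {
  b2 <- linear_bwd(dOut, cache$h, p$fc2)
  dh <- gelu_bwd(b2$dX, cache$h_pre)
  b1 <- linear_bwd(dh, cache$X, p$fc1)
  list(dX = b1$dX, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}

## --- pre-norm ViT block (encoders) -----------------------------------------

vit_block_init <- function(D, n_heads, mlp_ratio = 4) {
  list(ln1 = layernorm_init(D), attn = mha_init(D),
       ln2 = layernorm_init(D), mlp = mlp_init(D, round(mlp_ratio * D)))
}

vit_block_fwd <- function(X, p, n_heads, t_len, n_batch) {
  n1 <- layernorm_fwd(X, p$ln1)
  a <- mha_fwd(n1$out, p$attn, n_heads, t_len, n_batch)
  X1 <- X + a$out
  n2 <- layernorm_fwd(X1, p$ln2)
  m <- mlp_fwd(n2$out, p$mlp)
  list(out = X1 + m$out,
       cache = list(n1 = n1, a = a, X1 = X1, n2 = n2, m = m))
}

vit_block_bwd <- function(dOut, cache, p) {
  mb <- mlp_bwd(dOut, cache$m$cache, p$mlp)
  n2b <- layernorm_bwd(mb$dX, cache$n2$cache, p$ln2)
  dX1 <- dOut + n2b$dX
  ab <- mha_bwd(dX1, cache$a$cache, p$attn)
  n1b <- layernorm_bwd(ab$dX, cache$n1$cache, p$ln1)
  list(dX = dX1 + n1b$dX,
       grads = list(ln1 = n1b$grads, attn = ab$grads,
                    ln2 = n2b$grads, mlp = mb$grads))
}

## --- plain residual block (fusion module) ----------------------------------

plain_block_init <- function(D, n_heads, mlp_ratio = 4, ffn = TRUE) {
  p <- list(attn = mha_init(D))
  if (ffn) p$mlp <- mlp_init(D, round(mlp_ratio * D))
  p
}

plain_block_fwd <- function(X, p, n_heads, t_len, n_batch) {
  a <- mha_fwd(X, p$attn, n_heads, t_len, n_batch)
  X1 <- X + a$out
  if (is.null(p$mlp)) {
    return(list(out = X1, cache = list(a = a, X1 = NULL)))
  }
  m <- mlp_fwd(X1, p$mlp)
  list(out = X1 + m$out, cache = list(a = a, X1 = X1, m = m))
}

plain_block_bwd <- function(dOut, cache, p) {
  if (is.null(p$mlp)) {
    ab <- mha_bwd(dOut, cache$a$cache, p$attn)
    return(list(dX = dOut + ab$dX, grads = list(attn = ab$grads)))
  }
  mb <- mlp_bwd(dOut, cache$m$cache, p$mlp)
  dX1 <- dOut + mb$dX
  ab <- mha_bwd(dX1, cache$a$cache, p$attn)
  list(dX = dX1 + ab$dX, grads = list(attn = ab$grads, mlp = mb$grads))
}

## --- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    by_name <- !is.null(names(a)) && !is.null(names(b)) &&
      all(nzchar(names(a)))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[names(a)[i]]] else b[[i]]
      out[[i]] <- if (is.null(bi)) a[[i]] else tree_map2(f, a[[i]], bi)
    }
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

#' @keywords internal
tree_leaf_sizes <- function(tree, prefix = "") {
  if (is.list(tree)) {
    nm <- names(tree)
    if (is.null(nm)) nm <- as.character(seq_along(tree))
    out <- integer(0)
    for (i in seq_along(tree)) {
      out <- c(out, tree_leaf_sizes(
        tree[[i]], if (prefix == "") nm[i] else paste0(prefix, ".", nm[i])))
    }
    out
  } else {
    stats::setNames(length(tree), prefix)
  }
}

tree_accumulate <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(`+`, a, b)
}
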