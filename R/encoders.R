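## Modality encoders.
##
## CT encoder (CTE): a 3D ViT. The crop is cut into non-overlapping
## patch_size^3 blocks, each flattened and linearly embedded; the lesion
## bounding box (6 crop-relative coordinates) is linearly embedded as an
## extra token occupying position 0; a learnable positional table is added;
## the sequence runs through `depth` pre-norm transformer blocks, and the
## token mean is the modality feature (1 x D).
##
## Clinical encoder (CLE): each scalar of the encoded record scales a
## learned D-dimensional embedding row (plus a learned bias row and a
## positional row), giving an l x D sheet that is flattened and linearly
## projected to 1 x D.

#' Encoder configuration
#'
#' @param embed_dim Embedding size D (default 768).
#' @param depth Number of transformer blocks (default 12).
#' @param n_heads Attention heads; must divide `embed_dim` (default 12).
#' @param patch_size Cubic patch edge in voxels (default 8).
#' @param mlp_ratio MLP hidden width as a multiple of D (default 4).
#' @param ehr_len Encoded clinical vector length l.
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(embed_dim = 768L, depth = 12L, n_heads = 12L,
                           patch_size = 8L, mlp_ratio = 4, ehr_len = NULL) {
  if (embed_dim %% n_heads != 0) {
    stop("encoder_config(): n_heads must divide embed_dim")
  }
  if (patch_size < 1L || depth < 1L) {
    stop("encoder_config(): depth and patch_size must be >= 1")
  }
  structure(list(embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 n_heads = as.integer(n_heads),
                 patch_size = as.integer(patch_size),
                 mlp_ratio = mlp_ratio,
                 ehr_len = if (is.null(ehr_len)) NULL else as.integer(ehr_len)),
            class = "encoder_config")
}

#' Number of ViT patches for a crop shape
#' @param crop_shape Integer length-3 crop shape.
#' @param patch_size Patch edge.
#' @return `prod(ceiling(crop_shape / patch_size))`.
#' @export
n_patches <- function(crop_shape, patch_size) {
  prod(ceiling(crop_shape / patch_size))
}

## Cut a grid into non-overlapping p^3 blocks (zero-padded up to multiples
## of p) and return an N x p^3 matrix; rows are ordered lexicographically
## over (x-block, y-block, z-block).
patchify_slow <- function(grid, p) {
  d <- dim(grid)
  dp <- as.integer(ceiling(d / p) * p)
  if (any(dp != d)) {
    padded <- array(0, dp)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- grid
    grid <- padded
  }
  nb <- dp %/% p
  dim(grid) <- c(p, nb[1], p, nb[2], p, nb[3])
  # fastest-varying: within-block (px, py, pz); block order bz, by, bx slowest
  grid <- aperm(grid, c(1, 3, 5, 6, 4, 2))
  dim(grid) <- c(p^3, prod(nb))
  t(grid)
}

## Fast path: the block permutation only depends on (shape, p), so it is
## computed once via the array route and reused as a single index gather.
.patchify_cache <- new.env(parent = emptyenv())

patchify <- function(grid, p) {
  d <- dim(grid)
  if (is.null(d) || length(d) != 3L || any(d == 0)) {
    stop("patchify(): grid must be a non-empty rank-3 array")
  }
  if (any(d %% p != 0)) return(patchify_slow(grid, p))
  key <- paste(d[1], d[2], d[3], p, sep = "_")
  idx <- .patchify_cache[[key]]
  if (is.null(idx)) {
    idx <- as.vector(patchify_slow(array(seq_len(prod(d)), d), p))
    .patchify_cache[[key]] <- idx
  }
  matrix(grid[idx], prod(d %/% p), p^3)
}

#' Linear 3D patch embedding
#'
#' @param grid Normalized crop (rank-3 array with finite values).
#' @param params A linear map (`W` of shape p^3 x D, bias `b`), e.g. the
#'   `patch` group of [init_cte_params()].
#' @param patch_size Patch edge.
#' @return An N x D matrix of patch tokens.
#' @export
patch_embed_3d <- function(grid, params, patch_size) {
  if (any(!is.finite(grid))) stop("patch_embed_3d(): non-finite grid")
  linear_fwd(patchify(grid, patch_size), params)
}

#' Embed a crop-relative bounding box as a token
#'
#' @param bbox Crop-relative [bbox3d()] or a length-6 vector
#'   `(x, y, z, w, h, d)` with all entries in `[0, 1]`.
#' @param params A linear map (`W` of shape 6 x D, bias `b`).
#' @return A 1 x D matrix.
#' @export
embed_bbox <- function(bbox, params) {
  v <- bbox_as_vector(bbox)
  linear_fwd(matrix(v, 1L, 6L), params)
}

bbox_as_vector <- function(bbox) {
  v <- if (inherits(bbox, "bbox3d")) {
    if (bbox$frame != "relative") stop("bbox must be crop-relative")
    c(bbox$center, bbox$size)
  } else {
    as.double(bbox)
  }
  if (length(v) != 6L) stop("bounding-box vector must have length 6")
  if (any(v < -1e-9 | v > 1 + 1e-9)) {
    stop("crop-relative bounding-box coordinates must lie in [0, 1]")
  }
  pmin(pmax(v, 0), 1)
}

#' Initialize CT-encoder parameters for a crop shape
#'
#' @param config An [encoder_config()].
#' @param crop_shape Crop shape the encoder will consume (fixes the length
#'   of the positional table).
#' @return Parameter list with groups `patch`, `bbox`, `pos` and `blocks`.
#' @export
init_cte_params <- function(config, crop_shape) {
  D <- config$embed_dim
  p <- config$patch_size
  N <- n_patches(crop_shape, p)
  list(
    patch = linear_init(p^3, D),
    bbox = linear_init(6L, D),
    pos = matrix(trunc_normal((N + 1L) * D), N + 1L, D),
    blocks = lapply(seq_len(config$depth), function(i) {
      vit_block_init(D, config$n_heads, config$mlp_ratio)
    })
  )
}

## Batched CTE forward over stacked patch matrices.
##  p_stack: (B*N) x p^3, bbox_mat: B x 6.
cte_fwd_batch <- function(p_stack, bbox_mat, params, config, n_tok, n_batch) {
  D <- config$embed_dim
  t_len <- n_tok + 1L
  if (nrow(params$pos) != t_len) {
    stop("cte_fwd_batch(): positional table length ", nrow(params$pos),
         " does not match token count ", t_len)
  }
  tok <- linear_fwd(p_stack, params$patch)
  btok <- linear_fwd(bbox_mat, params$bbox)
  X <- matrix(0, n_batch * t_len, D)
  brow <- (seq_len(n_batch) - 1L) * t_len + 1L
  prow <- setdiff(seq_len(n_batch * t_len), brow)
  X[brow, ] <- btok
  X[prow, ] <- tok
  X <- X + params$pos[rep(seq_len(t_len), n_batch), ]
  caches <- vector("list", config$depth)
  for (i in seq_len(config$depth)) {
    st <- vit_block_fwd(X, params$blocks[[i]], config$n_heads, t_len, n_batch)
    X <- st$out
    caches[[i]] <- st$cache
  }
  pooled <- rowsum(X, group = rep(seq_len(n_batch), each = t_len)) / t_len
  list(out = pooled,
       cache = list(p_stack = p_stack, bbox_mat = bbox_mat, tok = tok,
                    brow = brow, prow = prow, blocks = caches,
                    t_len = t_len, n_batch = n_batch))
}

cte_bwd_batch <- function(dF, cache, params, config) {
  t_len <- cache$t_len
  n_batch <- cache$n_batch
  dX <- dF[rep(seq_len(n_batch), each = t_len), , drop = FALSE] / t_len
  grads <- list(blocks = vector("list", config$depth))
  for (i in rev(seq_len(config$depth))) {
    bb <- vit_block_bwd(dX, cache$blocks[[i]], params$blocks[[i]])
    dX <- bb$dX
    grads$blocks[[i]] <- bb$grads
  }
  grads$pos <- rowsum(dX, group = rep(seq_len(t_len), n_batch))
  dbtok <- dX[cache$brow, , drop = FALSE]
  dtok <- dX[cache$prow, , drop = FALSE]
  pb <- linear_bwd(dtok, cache$p_stack, params$patch)
  bbx <- linear_bwd(dbtok, cache$bbox_mat, params$bbox)
  grads$patch <- pb$grads
  grads$bbox <- bbx$grads
  grads[c("patch", "bbox", "pos", "blocks")]
}

#' CT-encoder forward pass for one crop
#'
#' Runs the full CT encoder (patch embedding, bounding-box token, learnable
#' positions, `depth` pre-norm transformer blocks, final layer norm, token
#' mean) on one normalized crop.
#'
#' @param grid Normalized crop (rank-3 array).
#' @param bbox Crop-relative [bbox3d()] or length-6 vector.
#' @param config An [encoder_config()].
#' @param params Parameters from [init_cte_params()] for this crop shape.
#' @return Numeric feature vector of length `config$embed_dim`.
#' @export
cte_forward <- function(grid, bbox, config, params) {
  p_stack <- patchify(grid, config$patch_size)
  out <- cte_fwd_batch(p_stack, matrix(bbox_as_vector(bbox), 1L, 6L),
                       params, config, nrow(p_stack), 1L)
  drop(out$out)
}

#' Initialize clinical-encoder parameters
#'
#' @param config An [encoder_config()] with `ehr_len` set.
#' @return Parameter list with groups `emb`, `emb_b`, `pos`, `proj`.
#' @export
init_cle_params <- function(config) {
  D <- config$embed_dim
  l <- config$ehr_len
  if (is.null(l)) stop("init_cle_params(): config$ehr_len is not set")
  list(
    emb = matrix(trunc_normal(l * D), l, D),
    emb_b = matrix(0, l, D),
    pos = matrix(trunc_normal(l * D), l, D),
    proj = linear_init(l * D, D)
  )
}

## Batched CLE forward; E is B x l.
cle_fwd_batch <- function(E, params, config) {
  l <- nrow(params$emb)
  D <- ncol(params$emb)
  if (ncol(E) != l) {
    stop("cle_fwd_batch(): clinical vector length ", ncol(E),
         " does not match encoder (", l, ")")
  }
  n_batch <- nrow(E)
  wvec <- as.vector(t(params$emb))            # entry (j-1)*D + d = emb[j, d]
  cvec <- as.vector(t(params$emb_b + params$pos))
  Erep <- E[, rep(seq_len(l), each = D), drop = FALSE]
  flat <- Erep * rep(wvec, each = n_batch) + rep(cvec, each = n_batch)
  out <- linear_fwd(flat, params$proj)
  list(out = out, cache = list(Erep = Erep, flat = flat))
}

cle_bwd_batch <- function(dY, cache, params) {
  l <- nrow(params$emb)
  D <- ncol(params$emb)
  pb <- linear_bwd(dY, cache$flat, params$proj)
  dflat <- pb$dX
  dwvec <- colSums(dflat * cache$Erep)
  dcvec <- colSums(dflat)
  list(emb = matrix(dwvec, l, D, byrow = TRUE),
       emb_b = matrix(dcvec, l, D, byrow = TRUE),
       pos = matrix(dcvec, l, D, byrow = TRUE),
       proj = pb$grads)
}

#' Clinical-encoder forward pass for one record
#'
#' @param ehr_vec Encoded clinical vector (length `config$ehr_len`).
#' @param config An [encoder_config()] with `ehr_len` set.
#' @param params Parameters from [init_cle_params()].
#' @return Numeric feature vector of length `config$embed_dim`.
#' @export
cle_forward <- function(ehr_vec, config, params) {
  drop(cle_fwd_batch(matrix(as.double(ehr_vec), 1L), params, config)$out)
}
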