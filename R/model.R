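## Model assembly: configuration, parameter initialization, the end-to-end
## forward pass (encoders -> contrastive logits + fused stack -> two-phase
## fusion -> class logits), and the matching backward pass used by training.

MODALITY_ORDER <- c("small", "clinical", "large")

#' Model configuration
#'
#' Collects every architectural switch of the network. Defaults follow the
#' reference CMMFNet configuration (embedding 768, 12 layers, 12 heads, patch 8,
#' two dual-scale crops); ablation variants are expressed as `modalities`
#' subsets and `use_dff = FALSE` (plain concatenation + linear head).
#'
#' @param embed_dim,depth,n_heads,patch_size,mlp_ratio CT/clinical encoder
#'   settings (see [encoder_config()]).
#' @param ehr_len Encoded clinical vector length (required when the
#'   clinical modality is used).
#' @param dff_layers Fusion transformer layers (default 2).
#' @param dff_heads Fusion attention heads (default `n_heads`).
#' @param reduction_ratio Channel-attention reduction ratio r; must divide
#'   the modality count (default 1).
#' @param crop_small,crop_large The two crop shapes.
#' @param n_classes Number of target classes (default 3).
#' @param modalities Subset of `c("small", "clinical", "large")`.
#' @param use_dff Use the two-phase fusion module (`FALSE` = concatenation
#'   plus linear head).
#' @param bbox_token With `FALSE`, the lesion-box token degrades to the
#'   trivial whole-crop box (center 0.5, size 1) for every sample — the
#'   "raw CT" ablation variant without lesion-location conditioning.
#' @param share_cte Share CT-encoder weights between the two scales (each
#'   scale keeps its own positional table).
#' @param freeze_temperature Keep the contrastive temperature fixed at its
#'   initialization instead of learning it.
#' @param ffn Include the feed-forward sub-block in fusion blocks.
#' @param phase1_norm `"layernorm"` (per token, no affine) or `"l2"`.
#' @param contrastive_targets `"pair"` (CLIP) or `"class"`.
#' @return A `cmmf_config` object.
#' @export
cmmf_config <- function(embed_dim = 768L, depth = 12L, n_heads = 12L,
                        patch_size = 8L, mlp_ratio = 4, ehr_len = NULL,
                        dff_layers = 2L, dff_heads = n_heads,
                        reduction_ratio = 1L,
                        crop_small = c(32L, 32L, 32L),
                        crop_large = c(128L, 128L, 32L),
                        n_classes = 3L,
                        modalities = c("small", "clinical", "large"),
                        use_dff = TRUE, bbox_token = TRUE, share_cte = FALSE,
                        freeze_temperature = FALSE, ffn = TRUE,
                        phase1_norm = c("layernorm", "l2"),
                        contrastive_targets = c("pair", "class")) {
  phase1_norm <- match.arg(phase1_norm)
  contrastive_targets <- match.arg(contrastive_targets)
  modalities <- MODALITY_ORDER[MODALITY_ORDER %in% modalities]
  if (length(modalities) == 0L) stop("cmmf_config(): no modalities selected")
  if (embed_dim %% n_heads != 0) {
    stop("cmmf_config(): n_heads must divide embed_dim")
  }
  if (embed_dim %% dff_heads != 0) {
    stop("cmmf_config(): dff_heads must divide embed_dim")
  }
  k <- length(modalities)
  if (use_dff) {
    if (dff_layers < 1L) stop("cmmf_config(): dff_layers must be >= 1")
    if (k %% reduction_ratio != 0 || k %/% reduction_ratio < 1L) {
      stop("cmmf_config(): reduction_ratio must divide the modality count")
    }
  }
  # ehr_len may stay NULL here: fold training fills it in from the fitted
  # clinical encoder; cmmf_model() requires it when the modality is active
  structure(list(
    embed_dim = as.integer(embed_dim), depth = as.integer(depth),
    n_heads = as.integer(n_heads), patch_size = as.integer(patch_size),
    mlp_ratio = mlp_ratio,
    ehr_len = if (is.null(ehr_len)) NULL else as.integer(ehr_len),
    dff_layers = as.integer(dff_layers), dff_heads = as.integer(dff_heads),
    reduction_ratio = as.integer(reduction_ratio),
    crop_small = as.integer(crop_small), crop_large = as.integer(crop_large),
    n_classes = as.integer(n_classes), modalities = modalities,
    use_dff = use_dff, bbox_token = bbox_token, share_cte = share_cte,
    freeze_temperature = freeze_temperature, ffn = ffn,
    phase1_norm = phase1_norm, contrastive_targets = contrastive_targets),
    class = "cmmf_config")
}

#' @export
print.cmmf_config <- function(x, ...) {
  cat("<cmmf_config> D=", x$embed_dim, " depth=", x$depth,
      " heads=", x$n_heads, " patch=", x$patch_size,
      " modalities=", paste(x$modalities, collapse = "+"),
      if (x$use_dff) " +DFF" else " (no DFF)", "\n", sep = "")
  invisible(x)
}

encoder_cfg_of <- function(config) {
  encoder_config(config$embed_dim, config$depth, config$n_heads,
                 config$patch_size, config$mlp_ratio, config$ehr_len)
}

#' Build a model with freshly initialized parameters
#'
#' @param config A [cmmf_config()].
#' @param seed Seed for the initialization.
#' @return A `cmmf_model` list with `config` and `params`.
#' @export
cmmf_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cmmf_config"))
  set.seed(seed)
  ecfg <- encoder_cfg_of(config)
  k <- length(config$modalities)
  D <- config$embed_dim
  params <- list()
  if ("small" %in% config$modalities) {
    params$cte_small <- init_cte_params(ecfg, config$crop_small)
  }
  if ("large" %in% config$modalities) {
    if (config$share_cte && "small" %in% config$modalities) {
      n_large <- n_patches(config$crop_large, config$patch_size)
      params$cte_large <- list(
        pos = matrix(trunc_normal((n_large + 1L) * D), n_large + 1L, D))
    } else {
      params$cte_large <- init_cte_params(ecfg, config$crop_large)
    }
  }
  if ("clinical" %in% config$modalities) {
    params$cle <- init_cle_params(ecfg)
  }
  if (has_contrastive(config)) {
    params$clip <- list(log_scale = CLIP_LOG_SCALE_INIT)
  }
  if (config$use_dff) {
    hidden <- k %/% config$reduction_ratio
    # channel-attention weights stored as left-multiplying maps:
    # W1 (hidden x k) reduces, W2 (k x hidden) expands
    params$dff <- list(
      blocks = lapply(seq_len(config$dff_layers), function(i) {
        plain_block_init(D, config$dff_heads, config$mlp_ratio, config$ffn)
      }),
      ca = list(
        W1 = matrix(rnorm(hidden * k, sd = 1 / sqrt(k)), hidden, k),
        W2 = matrix(rnorm(k * hidden, sd = 1 / sqrt(hidden)), k, hidden)))
  }
  params$head <- linear_init(k * D, config$n_classes)
  structure(list(config = config, params = params), class = "cmmf_model")
}

#' @export
print.cmmf_model <- function(x, ...) {
  print(x$config)
  cp <- count_parameters(x)
  cat("  parameters: ", format(cp$total, big.mark = ","), " (",
      paste(names(cp$by_group), format(cp$by_group, trim = TRUE),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

has_contrastive <- function(config) {
  "clinical" %in% config$modalities &&
    any(c("small", "large") %in% config$modalities)
}

## Resolve the effective CT-encoder parameter set for one scale (handles
## weight sharing, where the large scale only owns its positional table).
get_cte_params <- function(params, config, scale) {
  own <- params[[paste0("cte_", scale)]]
  if (scale == "large" && config$share_cte && !is.null(params$cte_small)) {
    shared <- params$cte_small
    shared$pos <- own$pos
    shared
  } else {
    own
  }
}

#' Count learnable parameters
#'
#' Exact count of learnable scalars, itemized per named parameter group.
#' A frozen contrastive temperature is excluded.
#'
#' @param model A [cmmf_model()].
#' @return List with `total` and named vector `by_group`.
#' @export
count_parameters <- function(model) {
  params <- model$params
  if (isTRUE(model$config$freeze_temperature)) params$clip <- NULL
  by_group <- vapply(params, function(g) sum(tree_leaf_sizes(g)), numeric(1))
  list(total = sum(by_group), by_group = by_group)
}

## ---------------------------------------------------------------------------
## Forward pass

prepare_batch <- function(batch, config) {
  n_batch <- length(batch)
  if (n_batch == 0L) stop("model_forward(): empty batch")
  out <- list(n_batch = n_batch,
              labels = vapply(batch, function(s) as.integer(s$label),
                              integer(1)))
  # the "raw CT" ablation removes lesion-location conditioning: every box
  # token sees the trivial whole-crop box
  box_of <- function(bb) {
    if (config$bbox_token) bbox_as_vector(bb) else c(0.5, 0.5, 0.5, 1, 1, 1)
  }
  if ("small" %in% config$modalities) {
    out$p_small <- do.call(rbind, lapply(batch, function(s) {
      patchify(s$roi_small, config$patch_size)
    }))
    out$bb_small <- t(vapply(batch, function(s) box_of(s$bbox_small),
                             numeric(6)))
    out$n_tok_small <- n_patches(dim(batch[[1]]$roi_small), config$patch_size)
  }
  if ("large" %in% config$modalities) {
    out$p_large <- do.call(rbind, lapply(batch, function(s) {
      patchify(s$roi_large, config$patch_size)
    }))
    out$bb_large <- t(vapply(batch, function(s) box_of(s$bbox_large),
                             numeric(6)))
    out$n_tok_large <- n_patches(dim(batch[[1]]$roi_large), config$patch_size)
  }
  if ("clinical" %in% config$modalities) {
    out$ehr <- t(vapply(batch, function(s) as.double(s$ehr_vec),
                        numeric(length(batch[[1]]$ehr_vec))))
  }
  out
}

#' Full model forward pass on a batch of preprocessed samples
#'
#' Each sample is a list with `roi_small`, `roi_large` (normalized crops),
#' `bbox_small`, `bbox_large` (crop-relative), `ehr_vec` and `label`
#' (0-based) — the output of [preprocess_case()] plus the encoded record.
#' Only the fields of active modalities are required.
#'
#' @param model A [cmmf_model()].
#' @param batch List of samples.
#' @param keep_cache Keep intermediate activations (for the backward pass).
#' @return List with `logits` (batch x n_classes), contrastive logit
#'   matrices `l1` (small-CT vs clinical) and `l2` (large-CT vs clinical)
#'   when defined, the fused stack `F` (batch x k x D), and per-modality
#'   `features`.
#' @export
model_forward <- function(model, batch, keep_cache = FALSE) {
  config <- model$config
  params <- model$params
  ecfg <- encoder_cfg_of(config)
  prep <- prepare_batch(batch, config)
  n_batch <- prep$n_batch
  D <- config$embed_dim
  k <- length(config$modalities)
  cache <- list(prep = prep)

  feats <- list()
  if ("small" %in% config$modalities) {
    st <- cte_fwd_batch(prep$p_small, prep$bb_small,
                        get_cte_params(params, config, "small"), ecfg,
                        prep$n_tok_small, n_batch)
    feats$small <- st$out
    cache$cte_small <- st$cache
  }
  if ("clinical" %in% config$modalities) {
    st <- cle_fwd_batch(prep$ehr, params$cle, ecfg)
    feats$clinical <- st$out
    cache$cle <- st$cache
  }
  if ("large" %in% config$modalities) {
    st <- cte_fwd_batch(prep$p_large, prep$bb_large,
                        get_cte_params(params, config, "large"), ecfg,
                        prep$n_tok_large, n_batch)
    feats$large <- st$out
    cache$cte_large <- st$cache
  }

  l1 <- l2 <- NULL
  if (has_contrastive(config)) {
    zc <- l2_normalize(feats$clinical)
    if (!is.null(feats$small)) {
      l1 <- similarity_logits(l2_normalize(feats$small), zc,
                              params$clip$log_scale)
    }
    if (!is.null(feats$large)) {
      l2 <- similarity_logits(l2_normalize(feats$large), zc,
                              params$clip$log_scale)
    }
  }

  # raw (un-normalized) features enter the fusion stack
  X <- matrix(0, n_batch * k, D)
  for (m in seq_len(k)) {
    X[seq(m, n_batch * k, by = k), ] <- feats[[config$modalities[m]]]
  }
  cache$F_raw <- X

  if (config$use_dff) {
    blk_caches <- vector("list", config$dff_layers)
    Xi <- X
    for (i in seq_len(config$dff_layers)) {
      st <- plain_block_fwd(Xi, params$dff$blocks[[i]], config$dff_heads,
                            k, n_batch)
      Xi <- st$out
      blk_caches[[i]] <- st$cache
    }
    nrm <- phase1_norm_fwd(Xi, config$phase1_norm)
    ca <- ca_fwd(nrm$out, params$dff$ca, n_batch, k)
    cache$dff <- list(blocks = blk_caches, nrm = nrm, ca = ca)
    Xhead <- ca$out
  } else {
    Xhead <- X
  }
  Fl <- flatten_stack(Xhead, n_batch, k)
  logits <- linear_fwd(Fl, params$head)
  cache$Fl <- Fl

  out <- list(logits = logits, l1 = l1, l2 = l2,
              F = array_from_stack(X, n_batch, k), features = feats,
              labels = prep$labels)
  if (keep_cache) out$cache <- cache
  out
}

## ---------------------------------------------------------------------------
## Loss + gradients (the training step's core)

#' Compute the training objective and all parameter gradients on a batch
#'
#' Runs the forward pass, evaluates the contrastive and focal losses, forms
#' the dynamically weighted total (the weight is detached), and
#' backpropagates through the whole network.
#'
#' @param model A [cmmf_model()].
#' @param batch List of samples (see [model_forward()]).
#' @param alpha_t Focal per-class weights.
#' @param gamma Focal focusing parameter.
#' @param compute_grads Set `FALSE` for evaluation-only use.
#' @return List with `bundle` (a [total_loss()] result), `logits`, and
#'   `grads` (a tree matching `model$params`).
#' @export
model_loss <- function(model, batch, alpha_t = rep(1, model$config$n_classes),
                       gamma = 0.25, compute_grads = TRUE) {
  config <- model$config
  params <- model$params
  ecfg <- encoder_cfg_of(config)
  fw <- model_forward(model, batch, keep_cache = TRUE)
  cache <- fw$cache
  labels <- fw$labels
  n_batch <- length(batch)
  k <- length(config$modalities)
  D <- config$embed_dim
  ctg <- config$contrastive_targets

  l_sc <- if (!is.null(fw$l1)) {
    clip_contrastive_loss(fw$l1, ctg, labels)
  } else 0
  l_lc <- if (!is.null(fw$l2)) {
    clip_contrastive_loss(fw$l2, ctg, labels)
  } else 0
  l_f <- focal_loss(fw$logits, labels, alpha_t, gamma)
  bundle <- total_loss(l_sc, l_lc, l_f)
  if (!is.finite(bundle$L_total)) {
    stop("model_loss(): non-finite objective (L_SC=", l_sc, ", L_LC=", l_lc,
         ", L_focal=", l_f, ")")
  }
  if (!compute_grads) {
    return(list(bundle = bundle, logits = fw$logits, grads = NULL))
  }

  omega <- bundle$omega
  grads <- list()

  ## classification pathway
  dlogits <- (1 - omega) * focal_grad(fw$logits, labels, alpha_t, gamma)
  hb <- linear_bwd(dlogits, cache$Fl, params$head)
  grads$head <- hb$grads
  dXhead <- unflatten_stack(hb$dX, n_batch, k)
  if (config$use_dff) {
    cab <- ca_bwd(dXhead, cache$dff$ca$cache, params$dff$ca)
    dX <- phase1_norm_bwd(cab$dX, cache$dff$nrm, config$phase1_norm)
    dff_grads <- list(blocks = vector("list", config$dff_layers),
                      ca = cab$grads)
    for (i in rev(seq_len(config$dff_layers))) {
      bb <- plain_block_bwd(dX, cache$dff$blocks[[i]],
                            params$dff$blocks[[i]])
      dX <- bb$dX
      dff_grads$blocks[[i]] <- bb$grads
    }
    grads$dff <- dff_grads[c("blocks", "ca")]
    dF <- dX
  } else {
    dF <- dXhead
  }

  ## split the stack gradient into per-modality feature gradients
  dfeat <- list()
  for (m in seq_len(k)) {
    dfeat[[config$modalities[m]]] <-
      dF[seq(m, n_batch * k, by = k), , drop = FALSE]
  }

  ## contrastive pathway (through the L2 normalization, scaled by omega)
  dlog_scale <- 0
  if (has_contrastive(config)) {
    fc <- fw$features$clinical
    zc <- l2_normalize(fc)
    dzc <- matrix(0, n_batch, D)
    add_norm_grad <- function(df, f, z, dz) {
      nrm <- sqrt(rowSums(f * f))
      df + (dz - z * rowSums(z * dz)) / nrm
    }
    alpha <- exp(params$clip$log_scale)
    if (!is.null(fw$l1)) {
      dl1 <- omega * contrastive_grad(fw$l1, ctg, labels)
      dlog_scale <- dlog_scale + sum(dl1 * fw$l1)
      fs <- fw$features$small
      zs <- l2_normalize(fs)
      dfeat$small <- add_norm_grad(dfeat$small, fs, zs, alpha * dl1 %*% zc)
      dzc <- dzc + alpha * crossprod(dl1, zs)
    }
    if (!is.null(fw$l2)) {
      dl2 <- omega * contrastive_grad(fw$l2, ctg, labels)
      dlog_scale <- dlog_scale + sum(dl2 * fw$l2)
      fl <- fw$features$large
      zl <- l2_normalize(fl)
      dfeat$large <- add_norm_grad(dfeat$large, fl, zl, alpha * dl2 %*% zc)
      dzc <- dzc + alpha * crossprod(dl2, zl)
    }
    dfeat$clinical <- add_norm_grad(dfeat$clinical, fc, zc, dzc)
    grads$clip <- list(
      log_scale = if (config$freeze_temperature) 0 else dlog_scale)
  }

  ## encoder backward passes
  if ("small" %in% config$modalities) {
    grads$cte_small <- cte_bwd_batch(dfeat$small, cache$cte_small,
                                     get_cte_params(params, config, "small"),
                                     ecfg)
  }
  if ("large" %in% config$modalities) {
    g_large <- cte_bwd_batch(dfeat$large, cache$cte_large,
                             get_cte_params(params, config, "large"), ecfg)
    if (config$share_cte && !is.null(params$cte_small)) {
      pos_large <- g_large$pos
      g_large$pos <- NULL
      grads$cte_small <- tree_accumulate(grads$cte_small, g_large)
      grads$cte_large <- list(pos = pos_large)
    } else {
      grads$cte_large <- g_large
    }
  }
  if ("clinical" %in% config$modalities) {
    grads$cle <- cle_bwd_batch(dfeat$clinical, cache$cle, params$cle)
  }

  list(bundle = bundle, logits = fw$logits, grads = grads[names(params)])
}

#' Predict class probabilities for a list of samples
#'
#' @param model A [cmmf_model()].
#' @param samples List of preprocessed samples.
#' @param batch_size Forward-pass batch size.
#' @return List with `probs` (n x n_classes) and `pred` (0-based labels).
#' @export
predict_cmmf <- function(model, samples, batch_size = 24L) {
  idx <- split(seq_along(samples),
               ceiling(seq_along(samples) / batch_size))
  probs <- do.call(rbind, lapply(idx, function(i) {
    softmax_rows(model_forward(model, samples[i])$logits)
  }))
  list(probs = probs, pred = max.col(probs) - 1L)
}
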