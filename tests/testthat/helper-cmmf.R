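# Shared fixtures: everything is generated in code at test time.

# Small phantom world for unit tests: isotropic 1 mm so preprocessing is
# cheap, noise-free unless asked otherwise.
tiny_spec <- function(noise_sd = 0, seed = 101L, spacing = c(1, 1, 1),
                      shape = c(64L, 64L, 48L)) {
  phantom_spec(noise_sd = noise_sd, volume_shape_vox = shape,
               spacing_mm = spacing, seed = seed)
}

# Reduced model: D = 16, 2 layers, 2 heads, 16^3 / 32x32x16 crops.
tiny_config <- function(ehr_len = NULL, ...) {
  args <- list(embed_dim = 16L, depth = 2L, n_heads = 2L, patch_size = 8L,
               dff_layers = 1L, dff_heads = 2L, ehr_len = ehr_len,
               crop_small = c(16L, 16L, 16L), crop_large = c(32L, 32L, 16L))
  args[names(list(...))] <- list(...)
  do.call(cmmf_config, args)
}

# Generate, preprocess and clinically encode n cases for the tiny model.
# (Encoder fit on all records: fine for unit tests; fold training fits its
# own encoder on the training split.)
tiny_samples <- function(n, spec = tiny_spec(), seed = 5L) {
  cases <- build_dataset_memory(spec, n, seed = seed)
  samples <- preprocess_cases(cases, crop_small = c(16, 16, 16),
                              crop_large = c(32, 32, 16))
  records <- do.call(rbind, lapply(samples, function(s) {
    as.data.frame(s$ehr, stringsAsFactors = FALSE)
  }))
  enc <- fit_ehr_encoder(records, phantom_ehr_fields(spec))
  samples <- lapply(samples, function(s) {
    s$ehr_vec <- encode_ehr(s$ehr, enc)
    s
  })
  attr(samples, "encoder") <- enc
  samples
}

# Independent brute-force multi-head attention: per-head loop with an
# explicit softmax, concatenation, then the output projection.
brute_force_mha <- function(X, p, n_heads) {
  D <- ncol(X)
  dk <- D / n_heads
  ctx <- matrix(0, nrow(X), D)
  Q <- X %*% p$Wq + matrix(p$bq, nrow(X), D, byrow = TRUE)
  K <- X %*% p$Wk + matrix(p$bk, nrow(X), D, byrow = TRUE)
  V <- X %*% p$Wv + matrix(p$bv, nrow(X), D, byrow = TRUE)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    A <- matrix(0, nrow(S), ncol(S))
    for (i in seq_len(nrow(S))) {
      e <- exp(S[i, ] - max(S[i, ]))
      A[i, ] <- e / sum(e)
    }
    ctx[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  ctx %*% p$Wo + matrix(p$bo, nrow(X), D, byrow = TRUE)
}

# Set every array in a parameter subtree to zero.
zero_tree <- function(tree) {
  cmmfnet:::tree_map(function(x) x * 0, tree)
}
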