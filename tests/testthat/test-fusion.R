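test_that("L2 normalization produces unit vectors and is idempotent", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(0.6, 0.8)
  expect_equal(l2_normalize(u), u)
  set.seed(1)
  Z <- l2_normalize(matrix(rnorm(1000 * 8), 1000, 8))
  expect_equal(sqrt(rowSums(Z^2)), rep(1, 1000), tolerance = 1e-12)
  expect_error(l2_normalize(c(0, 0)), "zero-norm")
})

test_that("similarity logits are temperature-scaled cosines", {
  z <- l2_normalize(matrix(c(1, 2, 2, -1), 2, 2, byrow = TRUE))
  l <- similarity_logits(z, z)
  expect_equal(diag(l), rep(1 / 0.07, 2), tolerance = 1e-9)
  expect_equal(l[1, 2], 0, tolerance = 1e-9)            # orthogonal pair
  expect_equal(similarity_logits(z[1, , drop = FALSE],
                                 -z[1, , drop = FALSE])[1, 1],
               -1 / 0.07, tolerance = 1e-9)             # antiparallel
  # cosine bound at any learned scale
  set.seed(2)
  za <- l2_normalize(matrix(rnorm(40), 5, 8))
  zb <- l2_normalize(matrix(rnorm(40), 5, 8))
  l2 <- similarity_logits(za, zb, log_scale = 1.3)
  expect_true(all(abs(l2) <= exp(1.3) + 1e-6))
  expect_error(similarity_logits(za, zb[, 1:4]), "dimension")
  expect_error(similarity_logits(za * 2, zb), "unit-norm")
})

test_that("fusion block with zeroed projections is the identity", {
  set.seed(3)
  D <- 8
  p <- cmmfnet:::plain_block_init(D, 2)
  p$attn$Wo <- p$attn$Wo * 0; p$attn$bo <- p$attn$bo * 0
  p$mlp$fc2$W <- p$mlp$fc2$W * 0; p$mlp$fc2$b <- p$mlp$fc2$b * 0
  F_arr <- array(rnorm(4 * 3 * D), c(4, 3, D))
  expect_equal(transformer_block(F_arr, p, 2), F_arr, tolerance = 1e-12)
})

test_that("fusion attention matches the brute-force reference on a toy input", {
  set.seed(4)
  X <- matrix(rnorm(12), 3, 4)    # 3 modality tokens, D = 4, 2 heads
  p <- cmmfnet:::plain_block_init(4, 2, ffn = FALSE)
  got <- transformer_block(array(X, c(1, 3, 4)), p, 2)
  expect_equal(matrix(got[1, , ], 3, 4),
               X + brute_force_mha(X, p$attn, 2), tolerance = 1e-6)
  # rows of each attention map over the 3 tokens sum to 1
  st <- cmmfnet:::mha_fwd(X, p$attn, 2, 3L, 1L)
  for (A in st$cache$attn) expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-9)
})

test_that("phase-1 output is per-token normalized", {
  cfg <- cmmf_config(embed_dim = 8, depth = 1, n_heads = 2, patch_size = 8,
                     dff_layers = 1, dff_heads = 2, modalities = c("small", "large"))
  set.seed(5)
  blocks <- list(cmmfnet:::plain_block_init(8, 2))
  F_arr <- array(rnorm(6 * 2 * 8, sd = 3), c(6, 2, 8))
  out <- dff_phase1(F_arr, cfg, blocks)
  for (i in 1:6) for (m in 1:2) {
    tok <- out[i, m, ]
    expect_equal(mean(tok), 0, tolerance = 1e-5)
    expect_equal(mean(tok^2), 1, tolerance = 1e-5)   # population variance
  }
  # with zeroed output projections phase 1 is layer-norm of the input
  zp <- blocks
  zp[[1]]$attn$Wo <- zp[[1]]$attn$Wo * 0; zp[[1]]$attn$bo <- zp[[1]]$attn$bo * 0
  zp[[1]]$mlp$fc2$W <- zp[[1]]$mlp$fc2$W * 0; zp[[1]]$mlp$fc2$b <- zp[[1]]$mlp$fc2$b * 0
  out2 <- dff_phase1(F_arr, cfg, zp)
  X <- cmmfnet:::stack_from_array(F_arr)
  ln <- cmmfnet:::layernorm_fwd(X, NULL)$out
  expect_equal(out2, cmmfnet:::array_from_stack(ln, 6, 2), tolerance = 1e-12)
  # the layer count is validated at configuration time
  expect_error(cmmf_config(embed_dim = 8, n_heads = 2, dff_layers = 0,
                           modalities = c("small", "large")), "dff_layers")
})

test_that("channel attention is the identity at zero weights and bounded in (0,2)", {
  set.seed(6)
  F_arr <- array(rnorm(5 * 3 * 8), c(5, 3, 8))
  zero <- list(W1 = matrix(0, 3, 3), W2 = matrix(0, 3, 3))
  expect_identical(channel_attention(F_arr, zero), F_arr)
  p <- list(W1 = matrix(rnorm(9), 3, 3), W2 = matrix(rnorm(9), 3, 3))
  out <- channel_attention(F_arr, p)
  mult <- out / F_arr
  expect_true(all(mult > 0 & mult < 2))
  # a constant modality row has AP = MP, so both gates coincide and the
  # multiplier is 2 * sigmoid(W2 relu(W1 c))
  Fc <- F_arr
  Fc[2, 1, ] <- 0.7
  out_c <- channel_attention(Fc, p)
  g_from_out <- out_c[2, 1, 1] / Fc[2, 1, 1]
  ap <- sapply(1:3, function(m) mean(Fc[2, m, ]))
  mp <- sapply(1:3, function(m) max(Fc[2, m, ]))
  sig <- function(x) 1 / (1 + exp(-x))
  g_direct <- sig(p$W2 %*% pmax(p$W1 %*% ap, 0)) + sig(p$W2 %*% pmax(p$W1 %*% mp, 0))
  expect_equal(g_from_out, g_direct[1], tolerance = 1e-9)
})

test_that("classification head is affine with shift-invariant argmax", {
  set.seed(7)
  F_arr <- array(rnorm(4 * 3 * 8), c(4, 3, 8))
  G_arr <- array(rnorm(4 * 3 * 8), c(4, 3, 8))
  p <- cmmfnet:::linear_init(24, 3)
  zero_p <- list(W = p$W * 0, b = c(1.5, -0.5, 2))
  lz <- classify(F_arr, zero_p)
  expect_true(all(apply(lz, 1, function(r) all(r == c(1.5, -0.5, 2)))))
  expect_equal(classify(F_arr + G_arr, p) - classify(G_arr, p),
               classify(F_arr, p) - classify(array(0, dim(F_arr)), p),
               tolerance = 1e-10)
  shifted <- classify(F_arr, p) + 3.2
  expect_equal(max.col(shifted), max.col(classify(F_arr, p)))
})

test_that("model forward has the contracted shapes and no cross-sample coupling", {
  samples <- tiny_samples(4)
  enc <- attr(samples, "encoder")
  cfg <- tiny_config(ehr_len = enc$length)
  m <- cmmf_model(cfg, seed = 11)
  fw <- model_forward(m, samples)
  expect_equal(dim(fw$logits), c(4L, 3L))
  expect_equal(dim(fw$l1), c(4L, 4L))
  expect_equal(dim(fw$l2), c(4L, 4L))
  expect_equal(dim(fw$F), c(4L, 3L, 16L))
  # duplicating a sample duplicates its logits row exactly
  fw2 <- model_forward(m, samples[c(1, 2, 2, 3)])
  expect_equal(fw2$logits[2, ], fw2$logits[3, ], tolerance = 1e-12)
  expect_equal(fw2$logits[1, ], fw$logits[1, ], tolerance = 1e-12)
  # deterministic in inference mode
  fw3 <- model_forward(m, samples)
  expect_identical(fw$logits, fw3$logits)
  expect_error(model_forward(m, list()), "empty")
})

test_that("ablation variants produce consistent stacks and logits", {
  samples <- tiny_samples(3)
  enc <- attr(samples, "encoder")
  variants <- list(
    list(modalities = "small"),
    list(modalities = "large"),
    list(modalities = c("small", "large")),
    list(modalities = "clinical"),
    list(modalities = c("small", "large"), bbox_token = FALSE),
    list(modalities = c("small", "clinical", "large"), use_dff = FALSE))
  for (v in variants) {
    cfg <- do.call(tiny_config, c(list(ehr_len = enc$length), v))
    m <- cmmf_model(cfg, seed = 2)
    fw <- model_forward(m, samples)
    expect_equal(dim(fw$logits), c(3L, 3L))
    expect_equal(dim(fw$F)[2], length(cfg$modalities))
    has_clin <- "clinical" %in% cfg$modalities
    expect_equal(is.null(fw$l1), !(has_clin && "small" %in% cfg$modalities))
    expect_equal(is.null(fw$l2), !(has_clin && "large" %in% cfg$modalities))
  }
})

test_that("shared CT encoders reuse weights but keep their own positions", {
  samples <- tiny_samples(2)
  enc <- attr(samples, "encoder")
  cfg <- tiny_config(ehr_len = enc$length, share_cte = TRUE)
  m <- cmmf_model(cfg, seed = 4)
  expect_named(m$params$cte_large, "pos")
  fw <- model_forward(m, samples)
  expect_equal(dim(fw$logits), c(2L, 3L))
  ml <- model_loss(m, samples)
  expect_named(ml$grads$cte_large, "pos")
  expect_true(all(is.finite(ml$grads$cte_small$patch$W)))
})
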