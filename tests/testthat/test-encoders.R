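test_that("patch counts follow the ceiling formula for both crop scales", {
  expect_equal(n_patches(c(32, 32, 32), 8), 64)
  expect_equal(n_patches(c(128, 128, 32), 8), 1024)
  expect_equal(nrow(cmmfnet:::patchify(array(0, c(32, 32, 32)), 8)), 64L)
  expect_equal(nrow(cmmfnet:::patchify(array(0, c(128, 128, 32)), 8)), 1024L)
  # non-divisible shapes are zero-padded up
  expect_equal(nrow(cmmfnet:::patchify(array(1, c(20, 20, 12)), 8)), 3L * 3L * 2L)
})

test_that("patchify partitions the grid without loss", {
  set.seed(1)
  g <- array(rnorm(16 * 24 * 8), c(16, 24, 8))
  P <- cmmfnet:::patchify(g, 8)
  expect_equal(dim(P), c(2L * 3L * 1L, 512L))
  expect_equal(sort(as.vector(P)), sort(as.vector(g)))
  # first block is the (0,0,0) corner block
  expect_equal(sort(P[1, ]), sort(as.vector(g[1:8, 1:8, 1:8])))
})

test_that("patch embedding is linear and zero maps to zero", {
  cfg <- encoder_config(embed_dim = 16, depth = 1, n_heads = 2, patch_size = 8)
  set.seed(2)
  params <- cmmfnet:::linear_init(512, 16)
  params$b <- numeric(16)
  z <- patch_embed_3d(array(0, c(16, 16, 16)), params, 8)
  expect_equal(dim(z), c(8L, 16L))
  expect_true(all(z == 0))
  g1 <- array(rnorm(16^3), c(16, 16, 16))
  g2 <- array(rnorm(16^3), c(16, 16, 16))
  expect_equal(patch_embed_3d(g1 + g2, params, 8),
               patch_embed_3d(g1, params, 8) + patch_embed_3d(g2, params, 8),
               tolerance = 1e-12)
  expect_error(patch_embed_3d(array(NA_real_, c(8, 8, 8)), params, 8),
               "finite")
})

test_that("bounding-box token is linear in the box coordinates", {
  set.seed(3)
  params <- cmmfnet:::linear_init(6, 16)
  zero <- list(W = params$W * 0, b = params$b * 0)
  expect_true(all(embed_bbox(c(0.5, 0.5, 0.5, 0.2, 0.2, 0.2), zero) == 0))
  b1 <- c(0.3, 0.5, 0.5, 0.2, 0.2, 0.2)
  b2 <- b1; b2[1] <- 0.4
  expect_equal(drop(embed_bbox(b2, params) - embed_bbox(b1, params)),
               0.1 * params$W[1, ], tolerance = 1e-12)
  # reflection x -> 1 - x acts as the corresponding linear substitution
  bf <- b1; bf[1] <- 1 - b1[1]
  expect_equal(drop(embed_bbox(bf, params) - embed_bbox(b1, params)),
               (1 - 2 * b1[1]) * params$W[1, ], tolerance = 1e-12)
  expect_error(embed_bbox(c(1.5, 0, 0, 0.1, 0.1, 0.1), params), "\\[0, 1\\]")
})

test_that("CT encoder returns a length-D feature for both crop shapes", {
  cfg <- encoder_config(embed_dim = 16, depth = 2, n_heads = 2, patch_size = 8)
  set.seed(4)
  bb <- c(0.5, 0.5, 0.5, 0.3, 0.3, 0.3)
  for (shape in list(c(16, 16, 16), c(32, 32, 16))) {
    params <- init_cte_params(cfg, shape)
    f <- cte_forward(array(runif(prod(shape)), shape), bb, cfg, params)
    expect_length(f, 16)
    expect_true(all(is.finite(f)))
  }
})

test_that("with zeroed output projections the encoder reduces to the residual path", {
  cfg <- encoder_config(embed_dim = 16, depth = 2, n_heads = 2, patch_size = 8)
  set.seed(5)
  shape <- c(16, 16, 16)
  params <- init_cte_params(cfg, shape)
  for (i in seq_along(params$blocks)) {
    params$blocks[[i]]$attn$Wo <- params$blocks[[i]]$attn$Wo * 0
    params$blocks[[i]]$attn$bo <- params$blocks[[i]]$attn$bo * 0
    params$blocks[[i]]$mlp$fc2$W <- params$blocks[[i]]$mlp$fc2$W * 0
    params$blocks[[i]]$mlp$fc2$b <- params$blocks[[i]]$mlp$fc2$b * 0
  }
  g <- array(runif(prod(shape)), shape)
  bb <- c(0.5, 0.5, 0.5, 0.4, 0.4, 0.4)
  f <- cte_forward(g, bb, cfg, params)
  tokens <- rbind(embed_bbox(bb, params$bbox),
                  patch_embed_3d(g, params$patch, 8)) + params$pos
  expect_equal(f, colMeans(tokens), tolerance = 1e-12)
})

test_that("multi-head attention matches the brute-force per-head reference", {
  set.seed(6)
  for (i in 1:10) {
    D <- sample(c(4, 8, 16), 1)
    heads <- sample(c(1, 2, 4), 1)
    if (D %% heads != 0) heads <- 1
    T_len <- sample(3:6, 1)
    X <- matrix(rnorm(T_len * D), T_len, D)
    p <- cmmfnet:::mha_init(D)
    got <- cmmfnet:::mha_fwd(X, p, heads, T_len, 1L)
    expect_equal(got$out, brute_force_mha(X, p, heads), tolerance = 1e-6)
    # every attention row is a probability vector
    for (A in got$cache$attn) {
      expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    }
  }
})

test_that("hand-set single-head attention matches softmax(QK'/sqrt(dk))V", {
  # 3 tokens, 2-dim embedding, hand-chosen weights; fully independent
  # computation below
  X <- matrix(c(1, 0, -1, 2, 1, 0), 3, 2)
  p <- list(Wq = matrix(c(1, 0, 0, 1), 2), bq = c(0, 0),
            Wk = matrix(c(0, 1, 1, 0), 2), bk = c(0, 0),
            Wv = matrix(c(1, 1, 0, 1), 2), bv = c(0, 0),
            Wo = diag(2), bo = c(0, 0))
  S <- (X %*% p$Wq) %*% t(X %*% p$Wk) / sqrt(2)
  A <- exp(S) / rowSums(exp(S))
  expected <- A %*% (X %*% p$Wv)
  got <- cmmfnet:::mha_fwd(X, p, 1L, 3L, 1L)$out
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("token-mean pooling is invariant to patch permutations without positions", {
  cfg <- encoder_config(embed_dim = 8, depth = 2, n_heads = 2, patch_size = 8)
  set.seed(7)
  params <- init_cte_params(cfg, c(16, 16, 16))
  params$pos <- params$pos * 0
  P <- matrix(rnorm(8 * 512), 8, 512)
  bb <- matrix(c(0.5, 0.5, 0.5, 0.2, 0.2, 0.2), 1)
  f1 <- cmmfnet:::cte_fwd_batch(P, bb, params, cfg, 8L, 1L)$out
  perm <- sample(8)
  f2 <- cmmfnet:::cte_fwd_batch(P[perm, ], bb, params, cfg, 8L, 1L)$out
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("activations stay finite on a full-length (1025-token) sequence", {
  cfg <- encoder_config(embed_dim = 16, depth = 2, n_heads = 2, patch_size = 8)
  set.seed(8)
  params <- init_cte_params(cfg, c(128, 128, 32))
  expect_equal(nrow(params$pos), 1025L)
  g <- array(runif(128 * 128 * 32), c(128, 128, 32))
  f <- cte_forward(g, c(0.5, 0.5, 0.5, 0.1, 0.1, 0.2), cfg, params)
  expect_true(all(is.finite(f)))
})

test_that("clinical encoder output has length D and is built from per-field rows", {
  set.seed(9)
  for (l in c(3L, 8L)) {
    cfg <- encoder_config(embed_dim = 16, depth = 1, n_heads = 2, ehr_len = l)
    params <- init_cle_params(cfg)
    e <- rnorm(l)
    expect_length(cle_forward(e, cfg, params), 16)
    # perturbing entry j moves the pre-projection sheet by delta * emb[j, ]
    j <- l
    delta <- 0.7
    e2 <- e; e2[j] <- e[j] + delta
    dflat <- numeric(l * 16)
    dflat[((j - 1) * 16 + 1):(j * 16)] <- delta * params$emb[j, ]
    expect_equal(cle_forward(e2, cfg, params) - cle_forward(e, cfg, params),
                 drop(matrix(dflat, 1) %*% params$proj$W), tolerance = 1e-10)
  }
  # zero input with all additive parameters zeroed gives the zero feature
  cfg <- encoder_config(embed_dim = 16, depth = 1, n_heads = 2, ehr_len = 4L)
  params <- init_cle_params(cfg)
  params$emb_b <- params$emb_b * 0
  params$pos <- params$pos * 0
  params$proj$b <- params$proj$b * 0
  expect_true(all(cle_forward(numeric(4), cfg, params) == 0))
  expect_error(cle_forward(numeric(3), cfg, params), "length")
})
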