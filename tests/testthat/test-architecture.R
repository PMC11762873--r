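test_that("patch embedding maps 224x224x3 to 56x56x96 for the Tiny layout", {
  cfg <- model_config()   # Tiny defaults
  m <- build_model(cfg, seed = 0)
  set.seed(1)
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  fm <- patch_embed(img, m$params$embed, cfg$patch_size)
  expect_equal(dim(fm), c(56, 56, 96))
})

test_that("patch embedding is linear (zero image, zero bias -> zero pre-norm) and matches the gather oracle", {
  set.seed(2)
  C <- 6L
  wts <- list(W = matrix(rnorm(48 * C, sd = 0.1), 48, C), b = rnorm(C),
              norm_g = runif(C, 0.5, 1.5), norm_b = rnorm(C))
  # zero image with zero bias: projection output is zero before the norm
  wz <- wts; wz$b <- numeric(C)
  p <- dattn:::patch_embed_forward(array(0, c(8, 8, 3)), wz, 4L)
  expect_true(all(abs(sweep(sweep(p$out, 2, wz$norm_b, "-"), 2,
                            wz$norm_g, "/")) < 1e-12))
  # 8 x 8 x 3 toy against the scalar patch-gather oracle
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(patch_embed(img, wts, 4L), oracle_patch_embed(img, wts, 4L),
               tolerance = 1e-10)
})

test_that("patch embedding handles grayscale and rejects odd channel counts", {
  set.seed(3)
  wts <- list(W = matrix(rnorm(48 * 4), 48, 4), b = numeric(4),
              norm_g = rep(1, 4), norm_b = numeric(4))
  g <- matrix(runif(64), 8, 8)
  expect_warning(patch_embed(g, wts, 4L), "grayscale")
  expect_error(suppressWarnings(patch_embed(array(0, c(8, 8, 2)), wts, 4L)),
               "3 input channels")
})

test_that("patch merging halves resolution, doubles channels, and matches the index oracle", {
  set.seed(4)
  C <- 2L
  wts <- list(norm_g = runif(4 * C, 0.5, 1.5), norm_b = rnorm(4 * C),
              W = matrix(rnorm(8 * C * C), 4 * C, 2 * C))
  fm <- rand_fm(4, 4, C, seed = 5)
  out <- patch_merging(fm, wts)
  expect_equal(dim(out), c(2, 2, 4))
  expect_equal(out, oracle_patch_merging(fm, wts), tolerance = 1e-10)

  # constant map stays constant across positions
  cm <- patch_merging(feature_map(array(2, c(6, 6, 2))), wts)
  expect_equal(cm[1, 1, ], cm[3, 2, ])

  expect_error(patch_merging(rand_fm(5, 4, 2, seed = 1), wts), "even sides")
})

test_that("transformer block is the identity under zero weights and reduces DA to WMSA", {
  acfg <- attention_config(C = 8L, num_heads = 2L, M = 7L, variant = "DA")
  set.seed(6)
  blk <- list(norm1_g = rep(1, 8), norm1_b = numeric(8),
              attn = init_attention_weights(acfg),
              norm2_g = rep(1, 8), norm2_b = numeric(8),
              mlp_W1 = matrix(rnorm(8 * 32, sd = 0.05), 8, 32), mlp_b1 = numeric(32),
              mlp_W2 = matrix(rnorm(32 * 8, sd = 0.05), 32, 8), mlp_b2 = numeric(8))
  x <- rand_fm(14, 14, 8, seed = 7)

  # all attention and MLP weights zero: pure residual identity
  zblk <- blk
  for (nm in c("mlp_W1", "mlp_W2")) zblk[[nm]][] <- 0
  zblk$attn <- dattn:::tree_map(function(v) v * 0, blk$attn)
  expect_equal(transformer_block(x, zblk, acfg), x, tolerance = 1e-12)

  # W_K2 = 0 equals the WMSA block output bit-for-bit
  rblk <- blk
  rblk$attn$W_K2[] <- 0
  rblk$attn$b_K2[] <- 0
  wblk <- rblk
  wblk$attn$W_K2 <- NULL
  wblk$attn$b_K2 <- NULL
  wcfg <- attention_config(C = 8L, num_heads = 2L, M = 7L, variant = "WMSA")
  expect_identical(transformer_block(x, rblk, acfg),
                   transformer_block(x, wblk, wcfg))

  # composition against the attention oracle: block = x + attn(LN(x)), etc.
  ln1 <- dattn:::layernorm_forward(dattn:::fm_to_tokens(x), blk$norm1_g, blk$norm1_b)
  a_or <- oracle_attention_forward(dattn:::tokens_to_fm(ln1$out, 14, 14),
                                   blk$attn, acfg)
  y <- x + a_or
  ln2 <- dattn:::layernorm_forward(dattn:::fm_to_tokens(y), blk$norm2_g, blk$norm2_b)
  mlp <- dattn:::mlp_forward(ln2$out, blk$mlp_W1, blk$mlp_b1, blk$mlp_W2, blk$mlp_b2)
  want <- y + dattn:::tokens_to_fm(mlp$out, 14, 14)
  expect_equal(transformer_block(x, blk, acfg), want, tolerance = 1e-6)
})

test_that("build_model is seed-deterministic and counts match the audits", {
  cfg <- mini_cfg()
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 10)
  expect_false(identical(m3$params$head_W, m1$params$head_W))
  expect_equal(n_params(m1), count_params(cfg))
})

test_that("stage geometry follows (56,96) -> (28,192) -> (14,384) -> (7,768) for Tiny", {
  cfg <- model_config()
  shapes <- dattn:::stage_shapes(cfg)
  expect_equal(vapply(shapes, `[[`, numeric(1), "h"), c(56, 28, 14, 7))
  expect_equal(vapply(shapes, `[[`, numeric(1), "C"), c(96, 192, 384, 768))
})

test_that("classify returns normalised, batch-invariant probabilities", {
  cfg <- mini_cfg(depths = 1L, heads = 2L, embed_dim = 8L)
  m <- build_model(cfg, seed = 11)
  set.seed(12)
  img <- array(runif(56 * 56 * 3), c(56, 56, 3))
  p1 <- classify(m, list(img))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  # duplicates give identical rows; batch order does not matter
  img2 <- array(runif(56 * 56 * 3), c(56, 56, 3))
  pb <- classify(m, list(img, img2, img))
  expect_equal(pb[1, ], pb[3, ])
  expect_equal(pb[1, ], p1[1, ])
  expect_equal(classify(m, list(img2, img))[2, ], p1[1, ])
  # empty batch
  expect_equal(nrow(classify(m, list())), 0)
})

test_that("checkpoints round-trip and the loader skips mismatched entries with a log", {
  cfg <- mini_cfg(depths = 1L, heads = 2L, embed_dim = 8L)
  m <- build_model(cfg, seed = 13)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)

  # a WMSA target model skips the stored K2 entries, logging each name
  wcfg <- mini_cfg(variant = "WMSA", depths = 1L, heads = 2L, embed_dim = 8L)
  wm <- build_model(wcfg, seed = 14)
  msgs <- capture_messages(wm2 <- load_checkpoint(path, wm))
  expect_true(any(grepl("skipped.*W_K2", msgs)))
  expect_equal(wm2$params$stages[[1]]$blocks[[1]]$attn$W_Q,
               m$params$stages[[1]]$blocks[[1]]$attn$W_Q)
})

test_that("invalid configurations are rejected with the offending values named", {
  expect_error(model_config(embed_dim = 96, heads = c(5, 6, 12, 24)),
               "heads = 5 does not divide C = 96")
  expect_error(model_config(input_hw = c(225, 224)), "not divisible by patch_size")
  expect_error(model_config(num_classes = 1), "num_classes")
})
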