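test_that("standard scores: uniform rows for zero queries, scalar softmax case, shift invariance", {
  # zero Q: every row uniform at 1/M^2
  A <- standard_scores(matrix(0, 4, 2), matrix(rnorm(8), 4, 2))
  expect_equal(A, matrix(0.25, 4, 4))

  # M^2 = 2, d_k = 1: softmax([[1,0],[0,0]]) first row = (e, 1)/(e + 1)
  A <- standard_scores(matrix(c(1, 0), 2, 1), matrix(c(1, 0), 2, 1), d_k = 1)
  expect_equal(A[1, ], c(exp(1), 1) / (exp(1) + 1))
  expect_equal(A[2, ], c(0.5, 0.5))

  # shifting one row of the score matrix leaves that row unchanged: realise
  # by adding a constant vector to one query's contribution via tied keys
  set.seed(8)
  Qw <- matrix(rnorm(8), 4, 2)
  Kw <- matrix(rnorm(8), 4, 2)
  A1 <- standard_scores(Qw, Kw)
  S <- tcrossprod(Qw, Kw) / sqrt(2)
  S[2, ] <- S[2, ] + 7.3
  A2 <- dattn:::softmax_rows(S)
  expect_equal(A2[2, ], A1[2, ], tolerance = 1e-12)

  expect_true(all(abs(rowSums(A1) - 1) < 1e-6))
  expect_true(all(A1 >= 0 & A1 <= 1))
})

test_that("DA scores reduce correctly and match the scalar-loop oracle", {
  set.seed(9)
  Qw <- matrix(rnorm(8), 4, 2)
  K1 <- matrix(rnorm(8), 4, 2)
  K2 <- matrix(rnorm(8), 4, 2)

  # zero second key: identical to the single-key score
  expect_equal(da_scores(Qw, K1, matrix(0, 4, 2)), standard_scores(Qw, K1))
  # tied keys: softmax of the doubled score
  expect_equal(da_scores(Qw, K1, K1),
               dattn:::softmax_rows(2 * tcrossprod(Qw, K1) / sqrt(2)))
  # element-by-element brute force
  expect_equal(da_scores(Qw, K1, K2), oracle_scores(Qw, K1, K2),
               tolerance = 1e-6)
  expect_true(all(abs(rowSums(da_scores(Qw, K1, K2)) - 1) < 1e-6))

  expect_error(da_scores(Qw, K1, matrix(0, 2, 2)), "identical shapes")
  expect_error(standard_scores(matrix(c(1, Inf), 1, 2), matrix(0, 1, 2)), "finite")
})

test_that("DA forward with zero K2 weights is bit-identical to WMSA (and DA_N ties give doubled scores)", {
  for (variant in c("DA", "DA_N")) {
    case <- oracle_case(variant = variant, seed = 21)
    wts0 <- case$wts
    wts0$W_K2[] <- 0
    wts0$b_K2[] <- 0
    wcfg <- attention_config(C = 8L, num_heads = 2L, M = 7L, variant = "WMSA")
    wwts <- wts0
    wwts$W_K2 <- NULL
    wwts$b_K2 <- NULL
    expect_identical(attention_forward(case$x, wts0, case$cfg),
                     attention_forward(case$x, wwts, wcfg))
  }

  # DA_N with W_K2 = W_K1 gives per-window scores softmax(2 Q K1^T / sqrt(dk))
  case <- oracle_case(variant = "DA_N", seed = 22, use_relpos = FALSE)
  wts <- case$wts
  wts$W_K2 <- wts$W_K1
  wts$b_K2 <- wts$b_K1
  X <- dattn:::fm_to_tokens(case$x)
  Q <- dattn:::add_bias(X %*% wts$W_Q, wts$b_Q)
  K1 <- dattn:::add_bias(X %*% wts$W_K1, wts$b_K1)
  perm <- dattn:::window_perm(14, 14, 7)
  rows <- perm[1:49]
  A <- dattn:::softmax_rows(2 * tcrossprod(Q[rows, 1:4], K1[rows, 1:4]) / sqrt(4))
  res <- dattn:::attn_tokens_forward(X, 14, 14, wts, case$cfg, want_cache = TRUE)
  expect_equal(res$cache$A[, , 1, 1], A, tolerance = 1e-12)
})

test_that("attention_forward agrees with the brute-force oracle on 14x14x8 maps", {
  for (variant in c("WMSA", "DA_N", "DA")) {
    case <- oracle_case(variant = variant, seed = 31)
    got <- attention_forward(case$x, case$wts, case$cfg)
    want <- oracle_attention_forward(case$x, case$wts, case$cfg)
    expect_equal(got, want, tolerance = 1e-5)
    expect_equal(dim(got), dim(case$x))
  }
})

test_that("attention_forward validates variant/weight consistency and divisibility", {
  case <- oracle_case(variant = "DA", seed = 41)
  wcfg <- attention_config(C = 8L, num_heads = 2L, M = 7L, variant = "WMSA")
  expect_error(attention_forward(case$x, case$wts, wcfg), "W_K2 present")
  x_bad <- rand_fm(10, 14, 8, seed = 42)
  expect_error(attention_forward(x_bad, case$wts, case$cfg), "M = 7.*h = 10")
  dacfg <- case$cfg
  wts <- case$wts
  wts$W_K2 <- NULL
  expect_error(attention_forward(case$x, wts, dacfg), "requires W_K2")
})

test_that("score rows are stochastic across random cases", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(2:9, 1)
    dk <- sample(1:4, 1)
    A <- da_scores(matrix(rnorm(n * dk, sd = 3), n, dk),
                   matrix(rnorm(n * dk, sd = 3), n, dk),
                   matrix(rnorm(n * dk, sd = 3), n, dk))
    expect_true(all(abs(rowSums(A) - 1) < 1e-6))
    expect_true(all(A >= 0 & A <= 1))
  }
})

test_that("relative-position bias indexing depends only on the coordinate offset", {
  M <- 3L
  idx <- dattn:::relpos_index(M)
  coord <- function(p) c((p - 1) %/% M, (p - 1) %% M)   # 0-based row-major
  seen <- list()
  for (i in 1:(M * M)) for (j in 1:(M * M)) {
    key <- paste(coord(i) - coord(j), collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- idx[i, j]
    } else {
      expect_equal(idx[i, j], seen[[key]])   # same offset, same table row
    }
  }
  # all (2M-1)^2 distinct offsets map to distinct table rows
  expect_equal(sort(unique(as.vector(idx))), 1:(2 * M - 1)^2)
  expect_equal(length(seen), (2 * M - 1)^2)
})
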