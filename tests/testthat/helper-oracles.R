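# Independent scalar-loop oracles. These deliberately avoid the package's
# vectorised index machinery: everything is written as plain loops over
# rows, columns, windows, heads and positions, so agreement with the package
# is a genuine dual-route check.

oracle_shift <- function(fm, dr, dc) {
  d <- dim(fm)
  out <- array(0, d)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    out[r, c, ] <- fm[((r - 1 + dr) %% d[1]) + 1, ((c - 1 + dc) %% d[2]) + 1, ]
  }
  out
}

# window k (1-based, row-major), position p (1-based, row-major) -> (r, c)
oracle_window_rc <- function(k, p, h, w, M) {
  nwc <- w %/% M
  wr <- (k - 1) %/% nwc
  wc <- (k - 1) %% nwc
  pr <- (p - 1) %/% M
  pc <- (p - 1) %% M
  c(wr * M + pr + 1, wc * M + pc + 1)
}

oracle_softmax_row <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Scalar evaluation of the fused attention score for one window/head:
# softmax over rows of (Q K1^T + Q K2^T) / sqrt(d_k)  (K2 = NULL gives the
# single-Key score).
oracle_scores <- function(Qw, K1w, K2w = NULL, d_k = ncol(Qw)) {
  n <- nrow(Qw)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (t in seq_len(ncol(Qw))) {
      s <- s + Qw[i, t] * K1w[j, t]
      if (!is.null(K2w)) s <- s + Qw[i, t] * K2w[j, t]
    }
    S[i, j] <- s / sqrt(d_k)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, ] <- oracle_softmax_row(S[i, ])
  A
}

# Brute-force multi-head window attention on an (h x w x C) array: loops over
# windows, heads and positions, gathering Q/K1/K2/V with explicit index
# arithmetic and applying the fused score formula scalar-wise.
oracle_attention_forward <- function(x, wts, cfg) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; C <- d[3]
  M <- cfg$M; nh <- cfg$num_heads; dk <- C %/% nh
  bias_of <- function(b) if (is.null(b)) numeric(C) else b
  proj <- function(src, W, b) {
    out <- array(0, dim(src))
    b <- bias_of(b)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      out[r, c, ] <- as.numeric(src[r, c, ] %*% W) + b
    }
    out
  }
  Q <- proj(x, wts$W_Q, wts$b_Q)
  K1 <- proj(x, wts$W_K1, wts$b_K1)
  V <- proj(x, wts$W_V, wts$b_V)
  K2 <- NULL
  if (cfg$variant != "WMSA") {
    src <- if (cfg$variant == "DA") oracle_shift(x, M %/% 2, M %/% 2) else x
    K2 <- proj(src, wts$W_K2, wts$b_K2)
  }
  relidx <- if (cfg$use_relpos) dattn:::relpos_index(M) else NULL
  nW <- (h %/% M) * (w %/% M)
  P <- M * M
  O <- array(0, c(h, w, C))
  for (k in seq_len(nW)) {
    for (hd in seq_len(nh)) {
      cols <- ((hd - 1) * dk + 1):(hd * dk)
      Qw <- matrix(0, P, dk); K1w <- matrix(0, P, dk)
      K2w <- if (!is.null(K2)) matrix(0, P, dk) else NULL
      Vw <- matrix(0, P, dk)
      for (p in seq_len(P)) {
        rc <- oracle_window_rc(k, p, h, w, M)
        Qw[p, ] <- Q[rc[1], rc[2], cols]
        K1w[p, ] <- K1[rc[1], rc[2], cols]
        if (!is.null(K2w)) K2w[p, ] <- K2[rc[1], rc[2], cols]
        Vw[p, ] <- V[rc[1], rc[2], cols]
      }
      # pre-softmax scores with optional relative-position bias
      S <- matrix(0, P, P)
      for (i in seq_len(P)) for (j in seq_len(P)) {
        s <- sum(Qw[i, ] * K1w[j, ]) / sqrt(dk)
        if (!is.null(K2w)) s <- s + sum(Qw[i, ] * K2w[j, ]) / sqrt(dk)
        if (cfg$use_relpos) s <- s + wts$relpos[relidx[i, j], hd]
        S[i, j] <- s
      }
      for (i in seq_len(P)) {
        a <- oracle_softmax_row(S[i, ])
        rc <- oracle_window_rc(k, i, h, w, M)
        acc <- numeric(dk)
        for (j in seq_len(P)) acc <- acc + a[j] * Vw[j, ]
        O[rc[1], rc[2], cols] <- acc
      }
    }
  }
  out <- array(0, c(h, w, C))
  bout <- bias_of(wts$b_out)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    out[r, c, ] <- as.numeric(O[r, c, ] %*% wts$W_out) + bout
  }
  out
}

# Scalar patch-embedding oracle: gathers each patch with explicit loops in
# the documented feature order (patch row fastest, then patch col, then
# channel) and applies the projection + LayerNorm directly.
oracle_patch_embed <- function(image, wts, p) {
  d <- dim(image)
  hp <- d[1] %/% p; wp <- d[2] %/% p
  C <- ncol(wts$W)
  out <- array(0, c(hp, wp, C))
  for (R in seq_len(hp)) for (Cc in seq_len(wp)) {
    feat <- numeric(p * p * d[3])
    i <- 0
    for (ch in seq_len(d[3])) for (pc in seq_len(p)) for (pr in seq_len(p)) {
      i <- i + 1
      feat[i] <- image[(R - 1) * p + pr, (Cc - 1) * p + pc, ch]
    }
    v <- as.numeric(feat %*% wts$W) + wts$b
    mu <- mean(v)
    sd2 <- mean((v - mu)^2)
    out[R, Cc, ] <- ((v - mu) / sqrt(sd2 + 1e-5)) * wts$norm_g + wts$norm_b
  }
  out
}

# Scalar patch-merging oracle: gathers the 2x2 neighbourhood in the
# documented group order, LayerNorm, then bias-free projection.
oracle_patch_merging <- function(fm, wts) {
  d <- dim(fm)
  C <- d[3]
  out <- array(0, c(d[1] / 2, d[2] / 2, 2 * C))
  for (R in seq_len(d[1] / 2)) for (Cc in seq_len(d[2] / 2)) {
    v <- c(fm[2 * R - 1, 2 * Cc - 1, ], fm[2 * R, 2 * Cc - 1, ],
           fm[2 * R - 1, 2 * Cc, ], fm[2 * R, 2 * Cc, ])
    mu <- mean(v)
    sd2 <- mean((v - mu)^2)
    vn <- ((v - mu) / sqrt(sd2 + 1e-5)) * wts$norm_g + wts$norm_b
    out[R, Cc, ] <- as.numeric(vn %*% wts$W)
  }
  out
}
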