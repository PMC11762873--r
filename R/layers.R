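# Non-attention layers of the backbone, each with a hand-written backward
# pass (verified against finite differences by the gradcheck module).

#' @noRd
layernorm_forward <- function(X, g, b, eps = 1e-5, want_cache = FALSE) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, "*")
  Y <- sweep(Y, 2L, b, "+")
  if (!want_cache) return(list(out = Y))
  list(out = Y, cache = list(xhat = xhat, inv = inv, g = g))
}

#' @noRd
layernorm_backward <- function(dY, cache) {
  xhat <- cache$xhat
  n <- ncol(xhat)
  dxhat <- sweep(dY, 2L, cache$g, "*")
  t1 <- rowSums(dxhat)
  t2 <- rowSums(dxhat * xhat)
  dX <- (cache$inv / n) * (n * dxhat - t1 - xhat * t2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

#' @noRd
mlp_forward <- function(X, W1, b1, W2, b2, want_cache = FALSE) {
  H0 <- add_bias(X %*% W1, b1)
  H <- gelu(H0)
  Y <- add_bias(H %*% W2, b2)
  if (!want_cache) return(list(out = Y))
  list(out = Y, cache = list(X = X, H0 = H0, H = H, W1 = W1, W2 = W2))
}

#' @noRd
mlp_backward <- function(dY, cache) {
  dH <- dY %*% t(cache$W2)
  dH0 <- dH * gelu_grad(cache$H0)
  list(dX = dH0 %*% t(cache$W1),
       dW1 = crossprod(cache$X, dH0), db1 = colSums(dH0),
       dW2 = crossprod(cache$H, dY), db2 = colSums(dY))
}

# Gather non-overlapping p x p x ch patches of an (h x w x ch) image into a
# (h/p * w/p) x (p*p*ch) matrix, tokens row-major, features ordered
# (patch row fastest, then patch col, then channel).
#' @noRd
extract_patches <- function(img, p) {
  d <- dim(img)
  hp <- d[1] %/% p; wp <- d[2] %/% p
  b <- array(img, dim = c(p, hp, p, wp, d[3]))
  b <- aperm(b, c(4L, 2L, 1L, 3L, 5L))  # (wp, hp, pr, pc, ch)
  matrix(b, nrow = wp * hp, ncol = p * p * d[3])
}

#' Embed an image into the token grid
#'
#' Splits the image into non-overlapping `patch_size` x `patch_size` patches,
#' maps each patch through a learned linear projection to `C` channels, and
#' normalises. Grayscale (single-channel) input is replicated to three
#' channels with a warning; sides not divisible by the patch size are
#' reflect-padded and the padding is reported via `message()`.
#'
#' @param image Numeric array (h x w x 3), or (h x w) / (h x w x 1) grayscale.
#' @param wts List with `W` ((patch^2 * 3) x C), `b` (C), `norm_g`, `norm_b`.
#' @param patch_size Patch edge length in pixels.
#' @return Feature map array (h/patch x w/patch x C).
#' @export
patch_embed <- function(image, wts, patch_size = 4L) {
  res <- patch_embed_forward(image, wts, patch_size)
  tokens_to_fm(res$out, res$hp, res$wp)
}

#' @noRd
pad_reflect <- function(img, p) {
  d <- dim(img)
  ph <- (p - d[1] %% p) %% p
  pw <- (p - d[2] %% p) %% p
  if (ph == 0 && pw == 0) return(img)
  message(sprintf("patch_embed: reflect-padding %d x %d image by (%d, %d)",
                  d[1], d[2], ph, pw))
  ri <- c(seq_len(d[1]), d[1] - seq_len(ph))
  ci <- c(seq_len(d[2]), d[2] - seq_len(pw))
  img[ri, ci, , drop = FALSE]
}

#' @noRd
patch_embed_forward <- function(image, wts, patch_size, want_cache = FALSE) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (d[3] == 1L) {
    warning("grayscale input replicated to 3 channels", call. = FALSE)
    image <- array(rep(image, 3L), dim = c(d[1], d[2], 3L))
    d <- dim(image)
  }
  if (d[3] != 3L) {
    stop(sprintf("expected 3 input channels, got %d", d[3]), call. = FALSE)
  }
  image <- pad_reflect(image, patch_size)
  d <- dim(image)
  P <- extract_patches(image, patch_size)
  X0 <- add_bias(P %*% wts$W, wts$b)
  ln <- layernorm_forward(X0, wts$norm_g, wts$norm_b, want_cache = want_cache)
  out <- list(out = ln$out, hp = d[1] %/% patch_size, wp = d[2] %/% patch_size)
  if (want_cache) out$cache <- list(P = P, ln = ln$cache)
  out
}

#' @noRd
patch_embed_backward <- function(dY, cache) {
  lb <- layernorm_backward(dY, cache$ln)
  list(dW = crossprod(cache$P, lb$dX), db = colSums(lb$dX),
       dnorm_g = lb$dg, dnorm_b = lb$db)
}

# Index vectors of the four 2x2 sub-lattices in row-major token order at the
# output resolution; group order matches Swin (x0 = even-even in 0-based
# coordinates, x1 = odd-even, x2 = even-odd, x3 = odd-odd).
#' @noRd
merge_indices <- function(h, w) {
  R <- rep(seq_len(h %/% 2L), each = w %/% 2L)
  Cc <- rep(seq_len(w %/% 2L), times = h %/% 2L)
  at <- function(r, c) (r - 1L) * w + c
  list(at(2L * R - 1L, 2L * Cc - 1L), at(2L * R, 2L * Cc - 1L),
       at(2L * R - 1L, 2L * Cc), at(2L * R, 2L * Cc))
}

#' Merge 2x2 token neighbourhoods
#'
#' Concatenates each 2x2 neighbourhood of the token grid to 4C channels,
#' normalises, and projects (bias-free) to 2C channels, halving the spatial
#' resolution. This is the downsampling step between backbone stages.
#'
#' @param fm Feature map array (h x w x C); h and w must be even.
#' @param wts List with `norm_g`, `norm_b` (length 4C) and `W` (4C x 2C).
#' @return Feature map array (h/2 x w/2 x 2C).
#' @export
patch_merging <- function(fm, wts) {
  fm <- feature_map(fm)
  d <- dim(fm)
  res <- patch_merging_forward(fm_to_tokens(fm), d[1], d[2], wts)
  tokens_to_fm(res$out, d[1] %/% 2L, d[2] %/% 2L)
}

#' @noRd
patch_merging_forward <- function(X, h, w, wts, want_cache = FALSE) {
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop_dim("patch merging needs even sides, got %d x %d", h, w)
  }
  idx <- merge_indices(h, w)
  Xcat <- cbind(X[idx[[1]], , drop = FALSE], X[idx[[2]], , drop = FALSE],
                X[idx[[3]], , drop = FALSE], X[idx[[4]], , drop = FALSE])
  ln <- layernorm_forward(Xcat, wts$norm_g, wts$norm_b, want_cache = want_cache)
  Y <- ln$out %*% wts$W
  if (!want_cache) return(list(out = Y))
  list(out = Y, cache = list(idx = idx, C = ncol(X), L = nrow(X),
                             Xn = ln$out, ln = ln$cache, W = wts$W))
}

#' @noRd
patch_merging_backward <- function(dY, cache) {
  dXn <- dY %*% t(cache$W)
  dW <- crossprod(cache$Xn, dY)
  lb <- layernorm_backward(dXn, cache$ln)
  C <- cache$C
  dX <- matrix(0, cache$L, C)
  for (j in 1:4) {
    dX[cache$idx[[j]], ] <- lb$dX[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  list(dX = dX, dW = dW, dnorm_g = lb$dg, dnorm_b = lb$db)
}

#' Transformer block forward pass
#'
#' Pre-norm residual block: `y = x + Attention(LN(x))` followed by
#' `out = y + MLP(LN(y))`, where the MLP is linear C -> mlp_ratio*C, GELU,
#' linear back. The attention layer follows `cfg$variant`.
#'
#' @param fm Feature map array (h x w x C), window-divisible.
#' @param blk Block weights: `norm1_g/b`, attention weights `attn`,
#'   `norm2_g/b`, `mlp_W1/b1/W2/b2`.
#' @param cfg An [attention_config()].
#' @return Feature map of identical shape.
#' @export
transformer_block <- function(fm, blk, cfg) {
  fm <- feature_map(fm)
  d <- dim(fm)
  res <- block_forward(fm_to_tokens(fm), d[1], d[2], blk, cfg)
  tokens_to_fm(res$out, d[1], d[2])
}

# `attn_scale` / `mlp_scale` implement stochastic depth: a dropped residual
# branch has scale 0, a kept one under drop probability p has scale 1/(1-p);
# at inference both are 1.
#' @noRd
block_forward <- function(X, h, w, blk, cfg, want_cache = FALSE,
                          attn_scale = 1, mlp_scale = 1) {
  ln1 <- layernorm_forward(X, blk$norm1_g, blk$norm1_b, want_cache = want_cache)
  at <- attn_tokens_forward(ln1$out, h, w, blk$attn, cfg, want_cache = want_cache)
  Y <- X + attn_scale * at$out
  ln2 <- layernorm_forward(Y, blk$norm2_g, blk$norm2_b, want_cache = want_cache)
  ml <- mlp_forward(ln2$out, blk$mlp_W1, blk$mlp_b1, blk$mlp_W2, blk$mlp_b2,
                    want_cache = want_cache)
  out <- Y + mlp_scale * ml$out
  if (!want_cache) return(list(out = out))
  list(out = out, cache = list(ln1 = ln1$cache, attn = at$cache,
                               ln2 = ln2$cache, mlp = ml$cache,
                               attn_scale = attn_scale, mlp_scale = mlp_scale))
}

#' @noRd
block_backward <- function(dOut, cache) {
  g <- list()
  mb <- mlp_backward(cache$mlp_scale * dOut, cache$mlp)
  g$mlp_W1 <- mb$dW1; g$mlp_b1 <- mb$db1
  g$mlp_W2 <- mb$dW2; g$mlp_b2 <- mb$db2
  lb2 <- layernorm_backward(mb$dX, cache$ln2)
  g$norm2_g <- lb2$dg; g$norm2_b <- lb2$db
  dY <- dOut + lb2$dX
  ab <- attn_tokens_backward(cache$attn_scale * dY, cache$attn)
  g$attn <- ab$grads
  lb1 <- layernorm_backward(ab$dX, cache$ln1)
  g$norm1_g <- lb1$dg; g$norm1_b <- lb1$db
  list(dX = dY + lb1$dX, grads = g)
}
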