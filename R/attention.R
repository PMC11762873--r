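# Double-Attention core.
#
# Standard window attention scores one window's Queries against that window's
# Keys: A = softmax(Q K^T / sqrt(d_k)). Double Attention (DA) adds a second
# Key matrix K2, projected from a cyclically shifted copy of the feature map,
# and fuses the two score terms before the softmax:
#
#   A_DA = softmax(Q K1^T / sqrt(d_k) + Q K2^T / sqrt(d_k))
#
# Because K2 carries neighbouring windows' content into each window, cross-
# window correlations are available in a single pass and no alternating
# shifted-window layer is needed. The DA_N ablation projects K2 from the
# unshifted map (extra width, no cross-window flow); WMSA drops K2 entirely.

#' Attention layer configuration
#'
#' @param C Channel count of the layer input.
#' @param num_heads Number of attention heads; must divide `C`.
#' @param M Window edge length in tokens (default 7).
#' @param variant One of `"DA"` (K2 from the shifted map), `"DA_N"` (K2 from
#'   the unshifted map) or `"WMSA"` (no K2).
#' @param use_bias Add learnable biases to the Q/K1/K2/V and output
#'   projections.
#' @param use_relpos Add a learned relative-position bias (one
#'   `(2M-1)^2 x num_heads` table) to the pre-softmax score sum.
#' @return A list of class `"attention_config"` with the validated fields plus
#'   `d_k = C / num_heads`.
#' @export
attention_config <- function(C, num_heads, M = 7L,
                             variant = c("DA", "DA_N", "WMSA"),
                             use_bias = TRUE, use_relpos = TRUE) {
  variant <- match.arg(variant)
  C <- as.integer(C); num_heads <- as.integer(num_heads); M <- as.integer(M)
  if (C < 1L || num_heads < 1L || M < 1L) {
    stop("C, num_heads and M must be positive", call. = FALSE)
  }
  if (C %% num_heads != 0L) {
    stop(sprintf("num_heads = %d must divide C = %d", num_heads, C), call. = FALSE)
  }
  structure(list(C = C, num_heads = num_heads, M = M, d_k = C %/% num_heads,
                 variant = variant, use_bias = use_bias, use_relpos = use_relpos),
            class = "attention_config")
}

# Swin-style relative-position index: an M^2 x M^2 integer matrix mapping each
# (query position, key position) pair to a row of the (2M-1)^2 bias table.
#' @noRd
relpos_index <- function(M) {
  pr <- rep(seq_len(M) - 1L, each = M)
  pc <- rep(seq_len(M) - 1L, times = M)
  dr <- outer(pr, pr, "-") + (M - 1L)
  dc <- outer(pc, pc, "-") + (M - 1L)
  dr * (2L * M - 1L) + dc + 1L
}

#' Initialise attention weights
#'
#' Projections are drawn truncated-normal (sd 0.02, clipped at two sd), biases
#' start at zero, and the relative-position table is drawn truncated-normal.
#' K2 weights are present only for variants `DA` and `DA_N`. Uses the current
#' RNG stream; seed with `set.seed()` for reproducible draws.
#'
#' @param cfg An [attention_config()].
#' @return Named list of class `"attention_weights"`: `W_Q`, `W_K1`, `W_K2`
#'   (or `NULL`), `W_V`, `W_out` (C x C matrices), matching `b_*` vectors when
#'   `use_bias`, and `relpos` when `use_relpos`.
#' @export
init_attention_weights <- function(cfg) {
  stopifnot(inherits(cfg, "attention_config"))
  C <- cfg$C
  mat <- function() matrix(trunc_normal(C * C), C, C)
  wts <- list(
    W_Q  = mat(),
    W_K1 = mat(),
    W_K2 = if (cfg$variant != "WMSA") mat() else NULL,
    W_V  = mat(),
    W_out = mat()
  )
  if (cfg$use_bias) {
    wts$b_Q <- numeric(C); wts$b_K1 <- numeric(C)
    wts$b_K2 <- if (cfg$variant != "WMSA") numeric(C) else NULL
    wts$b_V <- numeric(C); wts$b_out <- numeric(C)
  }
  if (cfg$use_relpos) {
    wts$relpos <- matrix(trunc_normal((2L * cfg$M - 1L)^2 * cfg$num_heads),
                         (2L * cfg$M - 1L)^2, cfg$num_heads)
  }
  structure(wts, class = "attention_weights")
}

#' @noRd
check_score_inputs <- function(...) {
  args <- list(...)
  for (a in args) {
    if (!is.matrix(a) || !all(is.finite(a))) {
      stop("score inputs must be finite numeric matrices", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Standard window attention scores
#'
#' Row-wise softmax of `Q K^T / sqrt(d_k)` for one window and head. Every row
#' of the result sums to one.
#'
#' @param Qw,Kw Per-window, per-head matrices (M^2 x d_k).
#' @param d_k Per-head key dimension used in the scale (defaults to
#'   `ncol(Qw)`).
#' @return Row-stochastic (M^2 x M^2) matrix.
#' @export
standard_scores <- function(Qw, Kw, d_k = ncol(Qw)) {
  check_score_inputs(Qw, Kw)
  if (ncol(Qw) != ncol(Kw)) stop_dim("Qw and Kw must share the key dimension")
  if (d_k <= 0) stop("d_k must be positive", call. = FALSE)
  softmax_rows(tcrossprod(Qw, Kw) / sqrt(d_k))
}

#' Double-Attention scores
#'
#' Row-wise softmax of the fused score `Q K1^T / sqrt(d_k) +
#' Q K2^T / sqrt(d_k)`; both terms share the single `1/sqrt(d_k)` scale before
#' addition.
#'
#' @param Qw,K1w,K2w Per-window, per-head matrices (M^2 x d_k).
#' @param d_k Per-head key dimension (defaults to `ncol(Qw)`).
#' @return Row-stochastic (M^2 x M^2) matrix.
#' @export
da_scores <- function(Qw, K1w, K2w, d_k = ncol(Qw)) {
  check_score_inputs(Qw, K1w, K2w)
  if (!identical(dim(K1w), dim(K2w))) {
    stop_dim("K1w (%d x %d) and K2w (%d x %d) must have identical shapes",
             nrow(K1w), ncol(K1w), nrow(K2w), ncol(K2w))
  }
  if (ncol(Qw) != ncol(K1w)) stop_dim("Qw and K1w must share the key dimension")
  if (d_k <= 0) stop("d_k must be positive", call. = FALSE)
  softmax_rows((tcrossprod(Qw, K1w) + tcrossprod(Qw, K2w)) / sqrt(d_k))
}

# ---------------------------------------------------------------------------
# Token-level forward/backward. The model keeps feature maps as row-major
# (L x C) token matrices; the public attention_forward() wraps these in the
# array form. `score_transform = "identity"` is a gradcheck hook that removes
# the softmax so the whole layer is multilinear.
# ---------------------------------------------------------------------------

#' @noRd
attn_tokens_forward <- function(X, h, w, wts, cfg, want_cache = FALSE,
                                score_transform = "softmax") {
  C <- cfg$C; M <- cfg$M; nh <- cfg$num_heads; dk <- cfg$d_k
  s <- sqrt(dk)
  if (cfg$variant == "WMSA" && !is.null(wts$W_K2)) {
    stop("variant WMSA does not take K2 weights (W_K2 present)", call. = FALSE)
  }
  if (cfg$variant != "WMSA" && is.null(wts$W_K2)) {
    stop(sprintf("variant %s requires W_K2", cfg$variant), call. = FALSE)
  }
  perm <- window_perm(h, w, M)
  nW <- (h %/% M) * (w %/% M)
  P <- M * M

  Q  <- add_bias(X %*% wts$W_Q, wts$b_Q)
  K1 <- add_bias(X %*% wts$W_K1, wts$b_K1)
  V  <- add_bias(X %*% wts$W_V, wts$b_V)
  Xs <- NULL
  K2 <- NULL
  if (cfg$variant == "DA") {
    sp <- shift_perm(h, w, M %/% 2L, M %/% 2L)
    Xs <- X[sp, , drop = FALSE]
    K2 <- add_bias(Xs %*% wts$W_K2, wts$b_K2)
  } else if (cfg$variant == "DA_N") {
    Xs <- X
    K2 <- add_bias(X %*% wts$W_K2, wts$b_K2)
  }

  Qp <- Q[perm, , drop = FALSE]
  K1p <- K1[perm, , drop = FALSE]
  Vp <- V[perm, , drop = FALSE]
  K2p <- if (!is.null(K2)) K2[perm, , drop = FALSE] else NULL

  relidx <- if (cfg$use_relpos) relpos_index(M) else NULL
  A_all <- if (want_cache) array(0, c(P, P, nh, nW)) else NULL
  Op <- matrix(0, nrow(X), C)
  for (k in seq_len(nW)) {
    rows <- ((k - 1L) * P + 1L):(k * P)
    for (hd in seq_len(nh)) {
      cols <- ((hd - 1L) * dk + 1L):(hd * dk)
      Qw <- Qp[rows, cols, drop = FALSE]
      S <- tcrossprod(Qw, K1p[rows, cols, drop = FALSE]) / s
      if (!is.null(K2p)) {
        S <- S + tcrossprod(Qw, K2p[rows, cols, drop = FALSE]) / s
      }
      if (cfg$use_relpos) {
        S <- S + matrix(wts$relpos[relidx, hd], P, P)
      }
      A <- if (score_transform == "softmax") softmax_rows(S) else S
      if (want_cache) A_all[, , hd, k] <- A
      Op[rows, cols] <- A %*% Vp[rows, cols, drop = FALSE]
    }
  }
  O <- matrix(0, nrow(X), C)
  O[perm, ] <- Op
  out <- add_bias(O %*% wts$W_out, wts$b_out)
  if (!want_cache) return(list(out = out))
  list(out = out,
       cache = list(X = X, Xs = Xs, Q = Qp, K1 = K1p, K2 = K2p, V = Vp, O = O,
                    A = A_all, perm = perm, relidx = relidx, h = h, w = w,
                    wts = wts, cfg = cfg, score_transform = score_transform))
}

#' @noRd
attn_tokens_backward <- function(dOut, cache) {
  cfg <- cache$cfg; wts <- cache$wts
  C <- cfg$C; M <- cfg$M; nh <- cfg$num_heads; dk <- cfg$d_k
  s <- sqrt(dk)
  P <- M * M
  perm <- cache$perm
  nW <- length(perm) %/% P

  g <- list()
  g$W_out <- crossprod(cache$O, dOut)
  if (!is.null(wts$b_out)) g$b_out <- colSums(dOut)
  dO <- dOut %*% t(wts$W_out)
  dOp <- dO[perm, , drop = FALSE]

  dQp <- matrix(0, nrow(dO), C)
  dK1p <- matrix(0, nrow(dO), C)
  dK2p <- if (!is.null(cache$K2)) matrix(0, nrow(dO), C) else NULL
  dVp <- matrix(0, nrow(dO), C)
  drel <- if (cfg$use_relpos) matrix(0, (2L * M - 1L)^2, nh) else NULL

  for (hd in seq_len(nh)) {
    cols <- ((hd - 1L) * dk + 1L):(hd * dk)
    dShead <- matrix(0, P, P)  # accumulated over windows for the shared bias
    for (k in seq_len(nW)) {
      rows <- ((k - 1L) * P + 1L):(k * P)
      A <- cache$A[, , hd, k]
      dOw <- dOp[rows, cols, drop = FALSE]
      Vw <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOw, Vw)             # dOw %*% t(Vw)
      dVp[rows, cols] <- crossprod(A, dOw)  # t(A) %*% dOw
      dS <- if (cache$score_transform == "softmax") {
        softmax_rows_backward(A, dA)
      } else dA
      if (cfg$use_relpos) dShead <- dShead + dS
      Qw <- cache$Q[rows, cols, drop = FALSE]
      K1w <- cache$K1[rows, cols, drop = FALSE]
      dQp[rows, cols] <- dQp[rows, cols] + (dS %*% K1w) / s
      dK1p[rows, cols] <- crossprod(dS, Qw) / s
      if (!is.null(dK2p)) {
        K2w <- cache$K2[rows, cols, drop = FALSE]
        dQp[rows, cols] <- dQp[rows, cols] + (dS %*% K2w) / s
        dK2p[rows, cols] <- crossprod(dS, Qw) / s
      }
    }
    if (cfg$use_relpos) {
      drel[, hd] <- rowsum(as.vector(dShead), group = as.vector(cache$relidx))
    }
  }
  if (cfg$use_relpos) g$relpos <- drel

  unperm <- function(Zp) {
    Z <- matrix(0, nrow(Zp), ncol(Zp))
    Z[perm, ] <- Zp
    Z
  }
  dQ <- unperm(dQp); dK1 <- unperm(dK1p); dV <- unperm(dVp)

  X <- cache$X
  g$W_Q <- crossprod(X, dQ)
  g$W_K1 <- crossprod(X, dK1)
  g$W_V <- crossprod(X, dV)
  if (!is.null(wts$b_Q)) {
    g$b_Q <- colSums(dQ); g$b_K1 <- colSums(dK1); g$b_V <- colSums(dV)
  }
  dX <- dQ %*% t(wts$W_Q) + dK1 %*% t(wts$W_K1) + dV %*% t(wts$W_V)
  if (!is.null(dK2p)) {
    dK2 <- unperm(dK2p)
    g$W_K2 <- crossprod(cache$Xs, dK2)
    if (!is.null(wts$b_K2)) g$b_K2 <- colSums(dK2)
    dXs <- dK2 %*% t(wts$W_K2)
    if (cfg$variant == "DA") {
      sp <- shift_perm(cache$h, cache$w, M %/% 2L, M %/% 2L)
      dXshift <- matrix(0, nrow(dXs), ncol(dXs))
      dXshift[sp, ] <- dXs   # scatter through the gather Xs = X[sp, ]
      dX <- dX + dXshift
    } else {
      dX <- dX + dXs
    }
  }
  list(dX = dX, grads = g)
}

#' Multi-head window attention forward pass
#'
#' Projects Q, K1 and V from the input map; for variant `"DA"`, K2 is
#' projected from the map cyclically shifted by `floor(M/2)` in both axes, for
#' `"DA_N"` from the unshifted map, and for `"WMSA"` no K2 exists. Heads are
#' split to `d_k = C / num_heads` columns, per-window scores are fused and
#' normalised by [da_scores()] (or [standard_scores()]), a learned
#' relative-position bias is added to the pre-softmax score sum when
#' configured, and the weighted Values are merged and passed through the
#' output projection. Shape is preserved.
#'
#' @param x Feature map array (h x w x C); h and w must be multiples of
#'   `cfg$M`.
#' @param wts [init_attention_weights()] list matching `cfg`.
#' @param cfg An [attention_config()].
#' @return Feature map array (h x w x C).
#' @export
attention_forward <- function(x, wts, cfg) {
  stopifnot(inherits(cfg, "attention_config"))
  x <- feature_map(x)
  d <- dim(x)
  if (d[3] != cfg$C) stop_dim("input has %d channels but cfg$C = %d", d[3], cfg$C)
  X <- fm_to_tokens(x)
  res <- attn_tokens_forward(X, d[1], d[2], wts, cfg)
  tokens_to_fm(res$out, d[1], d[2])
}
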