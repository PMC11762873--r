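# Feature maps and window bookkeeping.
#
# A feature map is an (h x w x C) numeric array of token activations. Window
# attention operates on non-overlapping M x M tiles of the map; both the tiles
# and the positions inside a tile are ordered row-major, so window k = 0.. fills
# left-to-right then top-to-bottom, and position p = 0.. scans a tile the same
# way. All indexing below is 1-based at the R surface.

#' Construct a feature map
#'
#' A feature map is a rank-3 numeric array indexed (row, col, channel). The
#' constructor validates finiteness and positivity of the dimensions; matrices
#' are promoted to single-channel maps.
#'
#' @param values Numeric array (h x w x C), or a matrix (h x w) for C = 1.
#' @return The validated array with class `"feature_map"` retained as a plain
#'   array (no attributes beyond `dim`).
#' @export
feature_map <- function(values) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_dim("a feature map must be an (h x w x C) array")
  }
  d <- dim(values)
  if (any(d < 1L)) stop_dim("feature map dimensions must all be >= 1")
  if (!all(is.finite(values))) stop("feature map values must all be finite", call. = FALSE)
  storage.mode(values) <- "double"
  values
}

#' Cyclically shift a feature map
#'
#' Rolls the spatial grid so that `out[r, c, ] = x[(r + dr) mod h, (c + dc) mod
#' w, ]`. This is the shift that sources the second Key matrix: content from
#' neighbouring windows is wrapped into each window before the K2 projection,
#' so attention scores can compare a window's Queries against its neighbours'
#' content. Applying the negated offsets restores the input exactly.
#'
#' @param fm Feature map array (h x w x C).
#' @param dr,dc Integer row/column offsets (any integers; taken modulo h, w).
#' @return Shifted feature map of identical shape.
#' @examples
#' x <- feature_map(array(1:32, c(4, 4, 2)))
#' y <- cyclic_shift(x, 2, 2)
#' identical(cyclic_shift(y, -2, -2), x)
#' @export
cyclic_shift <- function(fm, dr, dc) {
  fm <- feature_map(fm)
  d <- dim(fm)
  ri <- ((seq_len(d[1]) - 1 + dr) %% d[1]) + 1
  ci <- ((seq_len(d[2]) - 1 + dc) %% d[2]) + 1
  fm[ri, ci, , drop = FALSE]
}

# Permutation sending token index t (row-major over an h x w grid) to the index
# of the token that lands at t after a cyclic shift by (dr, dc); used on the
# (L x C) token matrix form, where Xs <- X[shift_perm(h, w, dr, dc), ].
#' @noRd
shift_perm <- function(h, w, dr, dc) {
  r <- rep(seq_len(h), each = w)
  c <- rep(seq_len(w), times = h)
  r2 <- ((r - 1 + dr) %% h) + 1
  c2 <- ((c - 1 + dc) %% w) + 1
  (r2 - 1L) * w + c2
}

# Permutation that reorders row-major tokens into (window, position) order:
# entry (k-1)*M^2 + p holds the token index of position p in window k.
#' @noRd
window_perm <- function(h, w, M) {
  if (h %% M != 0 || w %% M != 0) {
    stop_dim("window size M = %d must divide both h = %d and w = %d", M, h, w)
  }
  nwr <- h %/% M
  nwc <- w %/% M
  wr <- rep(seq_len(nwr) - 1L, each = nwc * M * M)
  wc <- rep(rep(seq_len(nwc) - 1L, each = M * M), times = nwr)
  pr <- rep(rep(seq_len(M) - 1L, each = M), times = nwr * nwc)
  pc <- rep(seq_len(M) - 1L, times = nwr * nwc * M)
  r <- wr * M + pr + 1L
  c <- wc * M + pc + 1L
  (r - 1L) * w + c
}

# Row-major (h*w x C) token matrix from an (h x w x C) array and back.
#' @noRd
fm_to_tokens <- function(fm) {
  d <- dim(fm)
  matrix(aperm(fm, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
}

#' @noRd
tokens_to_fm <- function(X, h, w) {
  aperm(array(X, dim = c(w, h, ncol(X))), c(2L, 1L, 3L))
}

#' Partition a feature map into non-overlapping windows
#'
#' Tiles the (h x w) grid into (h/M)(w/M) windows of M^2 positions each, both
#' ordered row-major. Values are copied, never aggregated; `window_reverse()`
#' inverts the operation exactly.
#'
#' @param fm Feature map array (h x w x C); h and w must be multiples of M.
#' @param M Window edge length in tokens.
#' @return A `window_set`: list with `windows` (n_windows x M^2 x C array),
#'   `M`, `h`, `w`.
#' @export
window_partition <- function(fm, M) {
  fm <- feature_map(fm)
  d <- dim(fm)
  perm <- window_perm(d[1], d[2], M)
  X <- fm_to_tokens(fm)[perm, , drop = FALSE]
  nw <- (d[1] %/% M) * (d[2] %/% M)
  windows <- aperm(array(X, dim = c(M * M, nw, d[3])), c(2L, 1L, 3L))
  structure(list(windows = windows, M = M, h = d[1], w = d[2]),
            class = "window_set")
}

#' Reassemble a feature map from a window set
#'
#' Exact inverse of [window_partition()].
#'
#' @param ws A `window_set` as returned by [window_partition()].
#' @param h,w Target spatial extent; `n_windows * M^2` must equal `h * w`.
#' @return Feature map array (h x w x C).
#' @export
window_reverse <- function(ws, h, w) {
  stopifnot(inherits(ws, "window_set"))
  d <- dim(ws$windows)
  if (d[1] * d[2] != h * w) {
    stop_dim("window set holds %d values per channel but target is %d x %d",
             d[1] * d[2], h, w)
  }
  M <- ws$M
  if (h %% M != 0 || w %% M != 0) {
    stop_dim("window size M = %d must divide both h = %d and w = %d", M, h, w)
  }
  X <- matrix(aperm(ws$windows, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  perm <- window_perm(h, w, M)
  Y <- matrix(0, nrow = nrow(X), ncol = ncol(X))
  Y[perm, ] <- X
  tokens_to_fm(Y, h, w)
}
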