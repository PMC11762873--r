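# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
softmax_rows <- function(S) {
  # max-subtraction keeps exp() finite; softmax is invariant to row shifts
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# Backward of row-softmax: given A = softmax_rows(S) and upstream dA,
# dS = A * (dA - rowSums(dA * A)).
#' @noRd
softmax_rows_backward <- function(A, dA) {
  A * (dA - rowSums(dA * A))
}

# Truncated-normal init (mean 0, sd `sd`, truncated at +-2 sd) by rejection;
# consumes the current RNG stream so builds are reproducible under set.seed().
#' @noRd
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  bad <- which(abs(x) > 2 * sd)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), sd = sd)
    bad <- bad[abs(x[bad]) > 2 * sd]
  }
  x
}

# Round half away from zero at `digits` decimals (the convention used for the
# printed M-parameter and G-MAC figures).
#' @noRd
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
add_bias <- function(X, b) {
  if (is.null(b)) X else sweep(X, 2L, b, "+")
}

#' @noRd
gelu <- function(x) x * stats::pnorm(x)

#' @noRd
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' @noRd
stop_dim <- function(...) stop(sprintf(...), call. = FALSE)

# Exact-integer guard: all complexity arithmetic stays below 2^53 so doubles
# represent every intermediate integer exactly.
#' @noRd
check_exact_int <- function(x, what = "count") {
  if (any(x >= 2^53)) {
    stop(sprintf("%s exceeds 2^53; exact integer arithmetic not guaranteed", what),
         call. = FALSE)
  }
  x
}
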