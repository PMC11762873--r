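# Finite-difference verification of the analytic gradients.
#
# The scalar loss is the sum of the operation's outputs. For every parameter
# entry the central difference  (L(p + eps) - L(p - eps)) / (2 eps)  is
# compared with the analytic gradient; the report carries the maximum relative
# deviation  |analytic - numeric| / (|analytic| + eps)  over all entries.
# For the DA variant the report additionally confirms the dual gradient path:
# the loss gradient with respect to the Query projection stays nonzero when
# either Key path is blocked (its projection zeroed), because the score sum
# feeds Q through both Q K1^T and Q K2^T.

#' @noRd
gradcheck_ops <- c("standard_scores", "da_scores", "attention_forward")

# Build seeded inputs + closures for one op. Each case returns:
#  params: named list of numeric arrays the check perturbs
#  loss(params): scalar forward loss
#  grad(params): analytic gradient list matching params
#' @noRd
gradcheck_case <- function(op_id, seed, score_transform = "softmax") {
  ident <- score_transform == "identity"
  fused_loss <- function(Qw, Ks, d_k) {
    S <- Reduce(`+`, lapply(Ks, function(K) tcrossprod(Qw, K))) / sqrt(d_k)
    A <- if (ident) S else softmax_rows(S)
    list(A = A, loss = sum(A))
  }
  fused_grad <- function(Qw, Ks, d_k) {
    s <- sqrt(d_k)
    fw <- fused_loss(Qw, Ks, d_k)
    dA <- matrix(1, nrow(fw$A), ncol(fw$A))
    dS <- if (ident) dA else softmax_rows_backward(fw$A, dA)
    out <- list(Qw = Reduce(`+`, lapply(Ks, function(K) (dS %*% K) / s)))
    for (nm in names(Ks)) out[[nm]] <- crossprod(dS, Qw) / s
    out
  }
  if (op_id == "standard_scores") {
    with_seed(seed, {
      Qw <- matrix(stats::rnorm(8), 4, 2)
      Kw <- matrix(stats::rnorm(8), 4, 2)
      list(params = list(Qw = Qw, Kw = Kw),
           loss = function(p) fused_loss(p$Qw, list(Kw = p$Kw), 2)$loss,
           grad = function(p) fused_grad(p$Qw, list(Kw = p$Kw), 2))
    })
  } else if (op_id == "da_scores") {
    with_seed(seed, {
      Qw <- matrix(stats::rnorm(8), 4, 2)
      K1w <- matrix(stats::rnorm(8), 4, 2)
      K2w <- matrix(stats::rnorm(8), 4, 2)
      list(params = list(Qw = Qw, K1w = K1w, K2w = K2w),
           loss = function(p) fused_loss(p$Qw, list(K1w = p$K1w, K2w = p$K2w), 2)$loss,
           grad = function(p) fused_grad(p$Qw, list(K1w = p$K1w, K2w = p$K2w), 2))
    })
  } else if (op_id == "attention_forward") {
    cfg <- attention_config(C = 4L, num_heads = 2L, M = 2L, variant = "DA")
    with_seed(seed, {
      wts <- init_attention_weights(cfg)
      X <- matrix(stats::rnorm(16 * 4), 16, 4)   # 4 x 4 grid, M = 2
      run <- function(p) {
        w <- wts
        for (nm in setdiff(names(p), "X")) w[[nm]] <- p[[nm]]
        attn_tokens_forward(p$X, 4L, 4L, w, cfg, want_cache = TRUE,
                            score_transform = score_transform)
      }
      flat <- c(list(X = X),
                wts[c("W_Q", "b_Q", "W_K1", "b_K1", "W_K2", "b_K2",
                      "W_V", "b_V", "W_out", "b_out", "relpos")])
      list(params = flat,
           loss = function(p) sum(run(p)$out),
           grad = function(p) {
             res <- run(p)
             bw <- attn_tokens_backward(matrix(1, nrow(p$X), ncol(p$X)), res$cache)
             c(list(X = bw$dX), bw$grads)
           })
    })
  } else {
    stop(sprintf("unknown gradcheck op '%s'", op_id), call. = FALSE)
  }
}

#' Finite-difference gradient check
#'
#' Verifies the analytic gradients of the score and attention operations
#' against central finite differences on seeded inputs. If the seeded scores
#' contain exact ties (a degenerate input for the relative check), the case is
#' re-seeded with a warning.
#'
#' @param op_id One of `"standard_scores"`, `"da_scores"`,
#'   `"attention_forward"`.
#' @param seed Integer seed for the input draws.
#' @param eps Finite-difference step, in `[1e-6, 1e-3]`.
#' @param score_transform `"softmax"`, or `"identity"` to remove the softmax
#'   so the map is multilinear (exactness hook: deviation collapses to
#'   rounding error).
#' @return List of class `"gradcheck_report"`: `op`, `max_rel_dev`, `per_param`
#'   named vector, and for the DA forward `dual_path` with the norms of
#'   dL/dW_Q when the K1 or K2 path is blocked.
#' @export
gradcheck <- function(op_id, seed = 0L, eps = 1e-4,
                      score_transform = c("softmax", "identity")) {
  score_transform <- match.arg(score_transform)
  if (!op_id %in% gradcheck_ops) {
    stop(sprintf("op_id must be one of: %s", paste(gradcheck_ops, collapse = ", ")),
         call. = FALSE)
  }
  if (eps < 1e-6 || eps > 1e-3) stop("eps must lie in [1e-6, 1e-3]", call. = FALSE)

  case <- gradcheck_case(op_id, seed, score_transform)
  # degenerate-input guard: exact ties in any pairwise score matrix
  has_ties <- function(p) {
    sc <- tcrossprod(p[[1]], p[[2]])
    anyDuplicated(as.vector(sc)) > 0
  }
  if (op_id %in% c("standard_scores", "da_scores") && has_ties(case$params)) {
    warning(sprintf("tied scores at seed %d; re-seeding with %d", seed, seed + 1L),
            call. = FALSE)
    case <- gradcheck_case(op_id, seed + 1L, score_transform)
  }

  analytic <- case$grad(case$params)
  per_param <- numeric(0)
  for (nm in names(case$params)) {
    p <- case$params
    a <- analytic[[nm]]
    num <- array(0, dim = dim_or_len(p[[nm]]))
    for (j in seq_along(p[[nm]])) {
      pp <- p; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- p; pm[[nm]][j] <- pm[[nm]][j] - eps
      num[j] <- (case$loss(pp) - case$loss(pm)) / (2 * eps)
    }
    dev <- max(abs(a - num) / (abs(a) + eps))
    per_param[nm] <- dev
  }

  report <- list(op = op_id, seed = seed, eps = eps,
                 score_transform = score_transform,
                 max_rel_dev = max(per_param), per_param = per_param)

  if (op_id == "attention_forward") {
    # dual gradient path: block one Key path by zeroing its projection and
    # bias; dL/dW_Q must stay nonzero through the other.
    block <- function(which) {
      p <- case$params
      p[[paste0("W_", which)]][] <- 0
      p[[paste0("b_", which)]][] <- 0
      sqrt(sum(case$grad(p)$W_Q^2))
    }
    report$dual_path <- c(dQ_norm_K1_blocked = block("K1"),
                          dQ_norm_K2_blocked = block("K2"))
  }
  class(report) <- "gradcheck_report"
  report
}
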