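# Four-stage hierarchical backbone: patch embedding, window-attention blocks,
# patch merging between stages, global average pooling and a linear head.
# Stage s runs at resolution (input/patch)/2^(s-1) with C * 2^(s-1) channels.

#' Model configuration
#'
#' Defaults are the "Tiny" configuration: patch 4, embed dim 96, depths
#' (2, 2, 6, 2), heads (3, 6, 12, 24), window 7, MLP ratio 4, 224 x 224 input
#' and a 1000-class reference head (the head used when quoting backbone
#' complexity figures; set `num_classes` to the task's class count for
#' training). Every block in every stage uses the same attention `variant`;
#' there is no alternating shifted-window layer — cross-window flow is carried
#' by the K2 pathway.
#'
#' @param patch_size Patch edge length in pixels.
#' @param embed_dim Stage-1 channel count C.
#' @param depths Integer vector, blocks per stage.
#' @param heads Integer vector, attention heads per stage (same length as
#'   `depths`); `embed_dim * 2^(s-1)` must be divisible by `heads[s]`.
#' @param window Window edge length M in tokens.
#' @param mlp_ratio Hidden width of the block MLP as a multiple of C.
#' @param num_classes Output classes (>= 2).
#' @param variant `"DA"`, `"DA_N"` or `"WMSA"`.
#' @param input_hw Length-2 integer vector, input image size in pixels.
#' @param use_relpos,use_bias Attention layer flags, see [attention_config()].
#' @param drop_path Stochastic-depth rate in [0, 1) applied to residual
#'   branches during training (default 0).
#' @return List of class `"model_config"`.
#' @export
model_config <- function(patch_size = 4L, embed_dim = 96L,
                         depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                         window = 7L, mlp_ratio = 4, num_classes = 1000L,
                         variant = c("DA", "DA_N", "WMSA"),
                         input_hw = c(224L, 224L),
                         use_relpos = TRUE, use_bias = TRUE, drop_path = 0) {
  variant <- match.arg(variant)
  cfg <- list(patch_size = as.integer(patch_size), embed_dim = as.integer(embed_dim),
              depths = as.integer(depths), heads = as.integer(heads),
              window = as.integer(window), mlp_ratio = mlp_ratio,
              num_classes = as.integer(num_classes), variant = variant,
              input_hw = as.integer(input_hw), use_relpos = isTRUE(use_relpos),
              use_bias = isTRUE(use_bias), drop_path = drop_path)
  class(cfg) <- "model_config"
  validate_model_config(cfg)
  cfg
}

#' @noRd
validate_model_config <- function(cfg) {
  probs <- character(0)
  ns <- length(cfg$depths)
  if (length(cfg$heads) != ns) {
    probs <- c(probs, sprintf("depths has %d stages but heads has %d", ns,
                              length(cfg$heads)))
  }
  if (cfg$num_classes < 2L) probs <- c(probs, "num_classes must be >= 2")
  if (cfg$mlp_ratio <= 0) probs <- c(probs, "mlp_ratio must be positive")
  if (cfg$drop_path < 0 || cfg$drop_path >= 1) {
    probs <- c(probs, "drop_path must lie in [0, 1)")
  }
  for (s in seq_len(min(ns, length(cfg$heads)))) {
    C <- cfg$embed_dim * 2L^(s - 1L)
    if (C %% cfg$heads[s] != 0L) {
      probs <- c(probs, sprintf("stage %d: heads = %d does not divide C = %d",
                                s, cfg$heads[s], C))
    }
  }
  if (any(cfg$input_hw %% cfg$patch_size != 0L)) {
    probs <- c(probs, sprintf("input %d x %d not divisible by patch_size %d",
                              cfg$input_hw[1], cfg$input_hw[2], cfg$patch_size))
  } else {
    hw <- cfg$input_hw %/% cfg$patch_size
    for (s in seq_len(ns)) {
      if (any(hw %% cfg$window != 0L)) {
        probs <- c(probs, sprintf(
          "stage %d token grid %d x %d not divisible by window %d",
          s, hw[1], hw[2], cfg$window))
      }
      if (s < ns && any(hw %% 2L != 0L)) {
        probs <- c(probs, sprintf("stage %d grid %d x %d not even for merging",
                                  s, hw[1], hw[2]))
      }
      hw <- hw %/% 2L
    }
  }
  if (length(probs) > 0L) {
    stop(paste0("invalid model configuration:\n  - ",
                paste(probs, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(cfg)
}

#' @noRd
stage_attention_config <- function(cfg, s, variant = cfg$variant) {
  attention_config(C = cfg$embed_dim * 2L^(s - 1L), num_heads = cfg$heads[s],
                   M = cfg$window, variant = variant,
                   use_bias = cfg$use_bias, use_relpos = cfg$use_relpos)
}

#' Build a model
#'
#' Deterministic construction for a given seed: projections are drawn
#' truncated-normal (sd 0.02), biases and LayerNorm offsets start at zero,
#' LayerNorm gains at one. The RNG draw order is variant-independent (the K2
#' projection is always drawn, then discarded for `"WMSA"`), so models of
#' different variants built from the same seed share bit-identical common
#' weights — the controlled-comparison setup used by [compare_variants()].
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the weight draws.
#' @return List of class `"dattn_model"` with `cfg`, per-stage attention
#'   configs, and the parameter tree.
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, {
    C0 <- cfg$embed_dim
    pdim <- cfg$patch_size^2 * 3L
    params <- list(
      embed = list(W = matrix(trunc_normal(pdim * C0), pdim, C0),
                   b = numeric(C0),
                   norm_g = rep(1, C0), norm_b = numeric(C0))
    )
    ns <- length(cfg$depths)
    stages <- vector("list", ns)
    for (s in seq_len(ns)) {
      C <- cfg$embed_dim * 2L^(s - 1L)
      acfg_da <- stage_attention_config(cfg, s, variant = "DA")
      blocks <- vector("list", cfg$depths[s])
      for (b in seq_len(cfg$depths[s])) {
        attn <- init_attention_weights(acfg_da)
        if (cfg$variant == "WMSA") {
          attn$W_K2 <- NULL
          attn$b_K2 <- NULL
        }
        hidden <- round(cfg$mlp_ratio * C)
        blocks[[b]] <- list(
          norm1_g = rep(1, C), norm1_b = numeric(C),
          attn = attn,
          norm2_g = rep(1, C), norm2_b = numeric(C),
          mlp_W1 = matrix(trunc_normal(C * hidden), C, hidden),
          mlp_b1 = numeric(hidden),
          mlp_W2 = matrix(trunc_normal(hidden * C), hidden, C),
          mlp_b2 = numeric(C)
        )
      }
      merge <- NULL
      if (s < ns) {
        merge <- list(norm_g = rep(1, 4L * C), norm_b = numeric(4L * C),
                      W = matrix(trunc_normal(4L * C * 2L * C), 4L * C, 2L * C))
      }
      stages[[s]] <- list(blocks = blocks, merge = merge)
    }
    Cf <- cfg$embed_dim * 2L^(ns - 1L)
    params$stages <- stages
    params$norm_g <- rep(1, Cf)
    params$norm_b <- numeric(Cf)
    params$head_W <- matrix(trunc_normal(Cf * cfg$num_classes), Cf, cfg$num_classes)
    params$head_b <- numeric(cfg$num_classes)
    structure(list(cfg = cfg,
                   stage_cfgs = lapply(seq_len(ns), function(s)
                     stage_attention_config(cfg, s)),
                   params = params, seed = seed),
              class = "dattn_model")
  })
}

#' Number of learnable scalars in a built model
#'
#' @param model A [build_model()] result.
#' @return Exact integer count of all parameter entries.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "dattn_model"))
  count <- function(x) {
    if (is.null(x)) return(0)
    if (is.numeric(x)) return(length(x))
    if (is.list(x)) return(sum(vapply(x, count, numeric(1))))
    0
  }
  count(model$params)
}

# ---------------------------------------------------------------------------
# Full-model forward/backward for a single image.
# ---------------------------------------------------------------------------

#' @noRd
model_forward <- function(model, image, want_cache = FALSE, training = FALSE) {
  cfg <- model$cfg
  pe <- patch_embed_forward(image, model$params$embed, cfg$patch_size,
                            want_cache = want_cache)
  X <- pe$out
  h <- pe$hp; w <- pe$wp
  ns <- length(cfg$depths)
  caches <- list(embed = pe$cache, stages = vector("list", ns))
  for (s in seq_len(ns)) {
    st <- model$params$stages[[s]]
    acfg <- model$stage_cfgs[[s]]
    bl_caches <- vector("list", length(st$blocks))
    for (b in seq_along(st$blocks)) {
      sc <- c(1, 1)
      if (training && cfg$drop_path > 0) {
        keep <- stats::runif(2) >= cfg$drop_path
        sc <- ifelse(keep, 1 / (1 - cfg$drop_path), 0)
      }
      bf <- block_forward(X, h, w, st$blocks[[b]], acfg,
                          want_cache = want_cache,
                          attn_scale = sc[1], mlp_scale = sc[2])
      X <- bf$out
      if (want_cache) bl_caches[[b]] <- bf$cache
    }
    mg_cache <- NULL
    if (!is.null(st$merge)) {
      mf <- patch_merging_forward(X, h, w, st$merge, want_cache = want_cache)
      X <- mf$out
      if (want_cache) mg_cache <- mf$cache
      h <- h %/% 2L; w <- w %/% 2L
    }
    caches$stages[[s]] <- list(blocks = bl_caches, merge = mg_cache, h = h, w = w)
  }
  ln <- layernorm_forward(X, model$params$norm_g, model$params$norm_b,
                          want_cache = want_cache)
  z <- colMeans(ln$out)
  logits <- as.numeric(z %*% model$params$head_W) + model$params$head_b
  if (!want_cache) return(list(logits = logits))
  caches$final_ln <- ln$cache
  caches$z <- z
  caches$L_final <- nrow(ln$out)
  list(logits = logits, cache = caches)
}

#' @noRd
model_backward <- function(model, cache, dlogits) {
  g <- list()
  g$head_W <- outer(cache$z, dlogits)
  g$head_b <- dlogits
  Lf <- cache$L_final
  dz <- as.numeric(model$params$head_W %*% dlogits)
  dLN <- matrix(rep(dz / Lf, each = Lf), nrow = Lf)
  lb <- layernorm_backward(dLN, cache$final_ln)
  g$norm_g <- lb$dg; g$norm_b <- lb$db
  dX <- lb$dX
  ns <- length(model$cfg$depths)
  g$stages <- vector("list", ns)
  for (s in rev(seq_len(ns))) {
    stc <- cache$stages[[s]]
    sg <- list()
    if (!is.null(stc$merge)) {
      mb <- patch_merging_backward(dX, stc$merge)
      sg$merge <- list(norm_g = mb$dnorm_g, norm_b = mb$dnorm_b, W = mb$dW)
      dX <- mb$dX
    }
    nb <- length(stc$blocks)
    sg$blocks <- vector("list", nb)
    for (b in rev(seq_len(nb))) {
      bb <- block_backward(dX, stc$blocks[[b]])
      sg$blocks[[b]] <- bb$grads
      dX <- bb$dX
    }
    g$stages[[s]] <- sg
  }
  eb <- patch_embed_backward(dX, cache$embed)
  g$embed <- list(W = eb$dW, b = eb$db, norm_g = eb$dnorm_g, norm_b = eb$dnorm_b)
  g
}

#' Class probabilities for a batch of images
#'
#' Runs the model on each image independently (per-image results are
#' batch-order invariant) and softmax-normalises the logits.
#'
#' @param model A [build_model()] result.
#' @param images List of image arrays, or a single image array, or an
#'   (n x h x w) / (n x h x w x ch) batch array.
#' @return (n x num_classes) matrix of probabilities; each row sums to one.
#'   An empty batch yields a 0-row matrix.
#' @export
classify <- function(model, images) {
  stopifnot(inherits(model, "dattn_model"))
  images <- as_image_list(images)
  ncls <- model$cfg$num_classes
  if (length(images) == 0L) return(matrix(numeric(0), 0L, ncls))
  logits <- t(vapply(images, function(im) model_forward(model, im)$logits,
                     numeric(ncls)))
  softmax_rows(logits)
}

#' @noRd
as_image_list <- function(images) {
  if (is.list(images)) return(images)
  if (!is.array(images)) stop("images must be a list or an array", call. = FALSE)
  d <- dim(images)
  if (length(d) == 2L || length(d) == 3L && d[3] %in% c(1L, 3L)) {
    return(list(images))
  }
  lapply(seq_len(d[1]), function(i) {
    if (length(d) == 3L) images[i, , ] else images[i, , , ]
  })
}

# ---------------------------------------------------------------------------
# Checkpoints: a versioned flat map of named parameter arrays plus the config.
# ---------------------------------------------------------------------------

#' @noRd
flatten_params <- function(x, prefix = "") {
  if (is.null(x)) return(list())
  if (is.numeric(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  out <- list()
  nms <- names(x)
  for (i in seq_along(x)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    child <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    out <- c(out, flatten_params(x[[i]], child))
  }
  out
}

#' Save a model checkpoint
#'
#' Writes a versioned file holding the configuration record and a flat map of
#' named parameter arrays.
#'
#' @param model A [build_model()] result.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dattn_model"))
  saveRDS(list(format = "dattn-checkpoint", version = 1L,
               cfg = unclass(model$cfg), seed = model$seed,
               params = flatten_params(model$params)),
          path)
  invisible(path)
}

#' Load a checkpoint into a model
#'
#' Copies every stored parameter whose name and shape match the target model;
#' mismatched or unknown entries are skipped and every skipped name is logged
#' via `message()`. This mirrors the protocol of initialising a modified
#' attention architecture from weights whose attention parameters have been
#' removed.
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param model Target model; when `NULL`, a model is rebuilt from the stored
#'   config (and seed) before loading.
#' @return The model with loaded weights.
#' @export
load_checkpoint <- function(path, model = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, "dattn-checkpoint")) {
    stop("not a dattn checkpoint file", call. = FALSE)
  }
  if (is.null(model)) {
    cfg <- ck$cfg; class(cfg) <- "model_config"
    model <- build_model(cfg, seed = if (is.null(ck$seed)) 0L else ck$seed)
  }
  have <- flatten_params(model$params)
  skipped <- character(0)
  for (nm in names(ck$params)) {
    src <- ck$params[[nm]]
    if (nm %in% names(have) && identical(dim_or_len(have[[nm]]), dim_or_len(src))) {
      model$params <- assign_path(model$params, strsplit(nm, ".", fixed = TRUE)[[1]], src)
    } else {
      skipped <- c(skipped, nm)
    }
  }
  missing <- setdiff(names(have), names(ck$params))
  for (nm in skipped) message(sprintf("load_checkpoint: skipped stored entry '%s'", nm))
  for (nm in missing) message(sprintf("load_checkpoint: model entry '%s' kept at init", nm))
  model
}

#' @noRd
dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @noRd
assign_path <- function(tree, path, value) {
  key <- path[1]
  idx <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
  if (length(path) == 1L) {
    tree[[idx]] <- value
  } else {
    tree[[idx]] <- assign_path(tree[[idx]], path[-1], value)
  }
  tree
}

# ---------------------------------------------------------------------------
# Parameter-tree arithmetic used by the optimisers and gradcheck.
# ---------------------------------------------------------------------------

# Apply f elementwise to the numeric leaves of two same-shaped trees, matching
# children by name where names exist.
#' @noRd
tree_map2 <- function(f, x, y) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(f(x, y))
  nms <- names(x)
  out <- x
  for (i in seq_along(x)) {
    yi <- if (!is.null(nms) && nzchar(nms[i]) && !is.null(names(y))) y[[nms[i]]] else y[[i]]
    out[i] <- list(tree_map2(f, x[[i]], yi))  # [i] <- list(): keep NULL slots
  }
  out
}

#' @noRd
tree_map <- function(f, x) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(f(x))
  out <- x
  for (i in seq_along(x)) out[i] <- list(tree_map(f, x[[i]]))
  out
}
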