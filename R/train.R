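# Desk-scale supervised training.
#
# The loss is cross-entropy over softmax logits. The `sgd` optimizer is the
# literal per-parameter update  p(t+1) = p(t) - eta * dL/dp  — the closed form
# the dual-gradient-path analysis is stated in — while `adamw` (with optional
# cosine schedule and warmup) is the practical default. After every epoch the
# validation accuracy is measured and the best checkpoint retained; ties are
# broken toward the earliest epoch.

#' Training configuration
#'
#' @param eta Learning rate (> 0 unless `epochs = 0`).
#' @param optimizer `"adamw"` (default) or `"sgd"` (the plain
#'   gradient-descent update, no momentum).
#' @param epochs Number of passes over the training split (>= 0).
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled weight decay (adamw only).
#' @param seed Seed controlling shuffling, augmentation and stochastic depth.
#' @param augment Apply random 90-degree rotations and horizontal/vertical
#'   flips (probability 0.5 each) to training images.
#' @param schedule `"constant"` or `"cosine"` (cosine decay with 10% linear
#'   warmup, adamw only).
#' @return List of class `"train_config"`.
#' @export
train_config <- function(eta = 1e-3, optimizer = c("adamw", "sgd"), epochs = 10L,
                         batch_size = 8L, weight_decay = 0.05, seed = 0L,
                         augment = FALSE, schedule = c("constant", "cosine")) {
  optimizer <- match.arg(optimizer)
  schedule <- match.arg(schedule)
  if (eta < 0) stop("eta must be >= 0", call. = FALSE)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  structure(list(eta = eta, optimizer = optimizer, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), weight_decay = weight_decay,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 schedule = schedule),
            class = "train_config")
}

#' @noRd
cross_entropy_grad <- function(logits, label) {
  # label is 0-based; returns list(loss, dlogits)
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  p <- exp(logits - lse)
  d <- p
  d[label + 1L] <- d[label + 1L] - 1
  list(loss = lse - logits[label + 1L], dlogits = d)
}

#' @noRd
augment_image <- function(img) {
  k <- sample(0:3, 1L)
  if (k > 0) for (j in seq_len(k)) img <- t(img[nrow(img):1, , drop = FALSE])
  if (stats::runif(1) < 0.5) img <- img[, ncol(img):1, drop = FALSE]
  if (stats::runif(1) < 0.5) img <- img[nrow(img):1, , drop = FALSE]
  img
}

# Grayscale (n x h x w slice) -> h x w x 3 model input.
#' @noRd
to_model_input <- function(img) {
  if (is.matrix(img)) {
    array(rep(img, 3L), dim = c(dim(img), 3L))
  } else img
}

#' @noRd
lr_at <- function(tc, step, total_steps) {
  if (tc$schedule == "constant" || total_steps <= 1) return(tc$eta)
  warm <- max(1, floor(0.1 * total_steps))
  if (step <= warm) return(tc$eta * step / warm)
  frac <- (step - warm) / max(1, total_steps - warm)
  tc$eta * 0.5 * (1 + cos(pi * min(1, frac)))
}

#' @noRd
adamw_step <- function(params, grads, state, lr, tc) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u - lr * tc$weight_decay * p,
                      params, upd)
  list(params = params, state = state)
}

#' One plain gradient-descent step
#'
#' Updates every parameter by `p - eta * grad`, the closed-form update the
#' optimizer fidelity tests check against.
#'
#' @param params Parameter tree.
#' @param grads Matching gradient tree.
#' @param eta Learning rate.
#' @return Updated parameter tree.
#' @export
sgd_step <- function(params, grads, eta) {
  tree_map2(function(p, g) p - eta * g, params, grads)
}

# Mean loss + mean gradient tree over a minibatch of (image, label) pairs.
#' @noRd
batch_grad <- function(model, images, labels, training = TRUE) {
  n <- length(labels)
  total <- NULL
  loss <- 0
  correct <- 0L
  for (i in seq_len(n)) {
    fw <- model_forward(model, to_model_input(images[[i]]), want_cache = TRUE,
                        training = training)
    ce <- cross_entropy_grad(fw$logits, labels[i])
    if (!is.finite(ce$loss)) {
      stop(sprintf("non-finite loss at sample %d", i), call. = FALSE)
    }
    loss <- loss + ce$loss
    correct <- correct + (which.max(fw$logits) - 1L == labels[i])
    g <- model_backward(model, fw$cache, ce$dlogits / n)
    total <- if (is.null(total)) g else tree_map2(`+`, total, g)
  }
  list(grads = total, loss = loss / n, correct = correct)
}

#' Train a model
#'
#' Runs minibatch training under `tc`, recording per-epoch training accuracy,
#' validation accuracy and mean loss, and retaining the weights of the epoch
#' with the best validation accuracy (earliest epoch on ties). Deterministic
#' for a fixed (seed, config, data) triple. A non-finite loss aborts with the
#' epoch and step recorded in the error.
#'
#' @param model A [build_model()] result.
#' @param images n x h x w (or n x h x w x 3) array, or list of images.
#' @param labels Integer class labels, 0-based.
#' @param split [split_622()]-style list with `train` and `val` index vectors.
#' @param tc A [train_config()].
#' @return List with `history` (`data.frame`: epoch, train_acc, val_acc,
#'   loss), `best_model`, `best_epoch`, `best_val_acc`, `final_model`.
#' @export
train_model <- function(model, images, labels, split, tc) {
  stopifnot(inherits(model, "dattn_model"), inherits(tc, "train_config"))
  images <- as_image_list(images)
  if (tc$epochs > 0L && (length(split$train) == 0L || length(split$val) == 0L)) {
    stop("train and val splits must be non-empty", call. = FALSE)
  }
  history <- data.frame(epoch = integer(0), train_acc = numeric(0),
                        val_acc = numeric(0), loss = numeric(0))
  best <- list(model = model, epoch = 0L, val_acc = -Inf)
  if (tc$epochs == 0L) {
    best$val_acc <- NA_real_
    return(list(history = history, best_model = model, best_epoch = 0L,
                best_val_acc = NA_real_, final_model = model))
  }
  n_train <- length(split$train)
  steps_per_epoch <- ceiling(n_train / tc$batch_size)
  total_steps <- steps_per_epoch * tc$epochs
  opt_state <- NULL
  if (tc$optimizer == "adamw") {
    opt_state <- list(t = 0L, m = tree_map(function(x) x * 0, model$params),
                      v = tree_map(function(x) x * 0, model$params))
  }
  step <- 0L
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      order <- split$train[sample.int(n_train)]
      ep_loss <- 0
      ep_correct <- 0L
      for (b0 in seq(1L, n_train, by = tc$batch_size)) {
        step <- step + 1L
        idx <- order[b0:min(b0 + tc$batch_size - 1L, n_train)]
        imgs <- lapply(images[idx], function(im) {
          if (tc$augment && is.matrix(im)) augment_image(im) else im
        })
        bg <- tryCatch(
          batch_grad(model, imgs, labels[idx]),
          error = function(e) stop(sprintf("epoch %d step %d: %s",
                                           epoch, step, conditionMessage(e)),
                                   call. = FALSE))
        if (tc$optimizer == "sgd") {
          model$params <- sgd_step(model$params, bg$grads, tc$eta)
        } else {
          res <- adamw_step(model$params, bg$grads, opt_state,
                            lr_at(tc, step, total_steps), tc)
          model$params <- res$params
          opt_state <- res$state
        }
        ep_loss <- ep_loss + bg$loss * length(idx)
        ep_correct <- ep_correct + bg$correct
      }
      val_acc <- evaluate(model, images[split$val], labels[split$val])
      history <- rbind(history, data.frame(
        epoch = epoch, train_acc = ep_correct / n_train,
        val_acc = val_acc, loss = ep_loss / n_train))
      if (val_acc > best$val_acc) {
        best <- list(model = model, epoch = epoch, val_acc = val_acc)
      }
    }
  })
  list(history = history, best_model = best$model, best_epoch = best$epoch,
       best_val_acc = best$val_acc, final_model = model)
}

#' Classification accuracy on a split
#'
#' Fraction of argmax-correct predictions; order-invariant.
#'
#' @param model A [build_model()] result.
#' @param images Images (list or batch array).
#' @param labels Integer labels, 0-based.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate <- function(model, images, labels) {
  images <- as_image_list(images)
  if (length(labels) == 0L) {
    stop("accuracy is undefined on an empty split", call. = FALSE)
  }
  probs <- classify(model, lapply(images, to_model_input))
  mean(max.col(probs, ties.method = "first") - 1L == labels)
}

#' Best-on-validation epoch selection
#'
#' Returns the epoch with the highest validation accuracy; ties are broken
#' toward the earliest epoch.
#'
#' @param history `data.frame` with columns `epoch` and `val_acc`.
#' @return The selected epoch (integer).
#' @export
select_best_epoch <- function(history) {
  if (nrow(history) == 0L) return(0L)
  history$epoch[which.max(history$val_acc)]
}

#' Controlled comparison of attention variants
#'
#' Generates the task dataset, and for each seed builds the variants from a
#' shared initialisation (identical non-attention and shared attention
#' weights; see [build_model()]), trains each under the identical budget, and
#' reports the comparison table (method, test accuracy of the
#' best-on-validation checkpoint, FLOPs, parameters) plus the accuracy
#' histories.
#'
#' @param spec A [synth_spec()]; its seed is re-derived per comparison seed.
#' @param cfg A [model_config()]; the `variant` field is overridden per run.
#' @param tc A [train_config()]; its seed is re-derived per comparison seed.
#' @param variants Variants to compare.
#' @param seeds Integer vector of comparison seeds.
#' @return List with `table` (`data.frame`: method, acc, flops_G, params_M
#'   averaged over seeds), `per_seed` test-accuracy matrix, `per_seed_val`
#'   best-validation-accuracy matrix, and `histories`.
#' @export
compare_variants <- function(spec, cfg, tc, variants = c("WMSA", "DA_N", "DA"),
                             seeds = 0:2) {
  accs <- matrix(NA_real_, length(seeds), length(variants),
                 dimnames = list(paste0("seed", seeds), variants))
  vaccs <- accs
  histories <- list()
  for (si in seq_along(seeds)) {
    sd <- seeds[si]
    dspec <- spec
    dspec$seed <- spec$seed + sd
    ds <- generate_dataset(dspec)
    split <- split_622(length(ds$labels), seed = dspec$seed)
    for (v in variants) {
      vcfg <- cfg
      vcfg$variant <- v
      validate_model_config(vcfg)
      model <- build_model(vcfg, seed = sd)
      vtc <- tc
      vtc$seed <- tc$seed + sd
      fit <- train_model(model, ds$images, ds$labels, split, vtc)
      accs[si, v] <- evaluate(fit$best_model, as_image_list(ds$images)[split$test],
                              ds$labels[split$test])
      vaccs[si, v] <- fit$best_val_acc
      histories[[sprintf("%s_seed%d", v, sd)]] <- fit$history
    }
  }
  mean_acc <- colMeans(accs)
  tab <- complexity_table(cfg, variants = variants,
                          acc = as.list(round(100 * mean_acc, 1)))
  list(table = tab, per_seed = accs, per_seed_val = vaccs, histories = histories)
}

#' Write a training history as CSV
#'
#' @param history History `data.frame` from [train_model()].
#' @param path Output CSV path (columns epoch, train_acc, val_acc, loss).
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Plot train/validation accuracy curves
#'
#' Draws the per-epoch accuracy trend of one or more training runs to a PNG
#' file, one panel per run.
#'
#' @param histories Named list of history `data.frame`s (or a single one).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_history <- function(histories, path) {
  if (is.data.frame(histories)) histories <- list(run = histories)
  grDevices::png(path, width = 640 * length(histories), height = 480)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(histories)))
  for (nm in names(histories)) {
    h <- histories[[nm]]
    graphics::plot(h$epoch, h$train_acc, type = "l", col = "steelblue",
                   ylim = c(0, 1), xlab = "epoch", ylab = "accuracy", main = nm)
    graphics::lines(h$epoch, h$val_acc, col = "firebrick")
    graphics::legend("bottomright", legend = c("train", "val"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  }
  invisible(path)
}
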