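# Fast training-harness checks on a deliberately small geometry: 28 x 28
# inputs give a 7 x 7 token grid (one attention window).

micro_setup <- function(n = 8, seed = 1) {
  spec <- synth_spec(n, image_hw = c(28, 28), window_px = 14L, shift_px = 7L,
                     seed = seed)
  ds <- gen_cross_window(spec)
  cfg <- model_config(embed_dim = 8L, depths = 1L, heads = 2L, window = 7L,
                      input_hw = c(28, 28), num_classes = 2L, variant = "DA")
  list(ds = ds, model = build_model(cfg, seed = seed),
       split = list(train = seq_len(n), val = seq_len(n), test = integer(0)))
}

test_that("zero epochs is a no-op and eta = 0 sgd leaves weights bit-identical", {
  su <- micro_setup()
  tc0 <- train_config(epochs = 0L)
  fit <- train_model(su$model, su$ds$images, su$ds$labels, su$split, tc0)
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$best_model$params, su$model$params)

  tc <- train_config(eta = 0, optimizer = "sgd", epochs = 2L, batch_size = 4L,
                     seed = 5)
  fit0 <- train_model(su$model, su$ds$images, su$ds$labels, su$split, tc)
  expect_identical(fit0$final_model$params, su$model$params)
})

test_that("the sgd update is the literal closed form p - eta * grad", {
  # hand-computed toy: L = 2 w  =>  dL/dw = 2; one step from w = 5, eta = 0.1
  upd <- sgd_step(list(w = 5), list(w = 2), 0.1)
  expect_identical(upd$w, 5 - 0.1 * 2)

  # one real step: the parameter delta equals -eta times the batch gradient
  su <- micro_setup(n = 4)
  bg <- dattn:::batch_grad(su$model, dattn:::as_image_list(su$ds$images),
                           su$ds$labels, training = FALSE)
  eta <- 0.01
  new_params <- sgd_step(su$model$params, bg$grads, eta)
  dW <- new_params$head_W - su$model$params$head_W
  expect_equal(dW, -eta * bg$grads$head_W, tolerance = 1e-7)
  w0 <- su$model$params$stages[[1]]$blocks[[1]]$attn$W_K2
  w1 <- new_params$stages[[1]]$blocks[[1]]$attn$W_K2
  expect_equal(w1 - w0, -eta * bg$grads$stages[[1]]$blocks[[1]]$attn$W_K2,
               tolerance = 1e-7)
})

test_that("best-on-validation selection returns the argmax epoch, earliest on ties", {
  h <- data.frame(epoch = 1:5, val_acc = c(0.4, 0.8, 0.6, 0.8, 0.7))
  expect_equal(select_best_epoch(h), 2)
  expect_equal(select_best_epoch(h[0, ]), 0)
  h2 <- data.frame(epoch = 1:3, val_acc = c(0.9, 0.9, 0.9))
  expect_equal(select_best_epoch(h2), 1)

  # trained run: the retained checkpoint scores the recorded best accuracy
  su <- micro_setup()
  tc <- train_config(eta = 1e-3, epochs = 3L, batch_size = 4L, seed = 2)
  fit <- train_model(su$model, su$ds$images, su$ds$labels, su$split, tc)
  expect_equal(fit$best_epoch, select_best_epoch(fit$history))
  expect_equal(evaluate(fit$best_model, dattn:::as_image_list(su$ds$images),
                        su$ds$labels),
               fit$best_val_acc)
})

test_that("evaluate is the argmax-correct fraction with sane bounds", {
  su <- micro_setup(n = 16)
  imgs <- dattn:::as_image_list(su$ds$images)
  # untrained 2-class model on balanced labels: near chance
  acc <- evaluate(su$model, imgs, su$ds$labels)
  expect_gte(acc, 0.0)
  expect_lte(acc, 1.0)
  # scoring the model against its own predictions gives exactly 1
  own <- max.col(classify(su$model, lapply(imgs, dattn:::to_model_input)),
                 ties.method = "first") - 1L
  expect_equal(evaluate(su$model, imgs, own), 1.0)
  # order invariance
  perm <- rev(seq_along(imgs))
  expect_equal(evaluate(su$model, imgs[perm], su$ds$labels[perm]), acc)
  expect_error(evaluate(su$model, list(), integer(0)), "empty split")
})

test_that("training is bit-reproducible for a fixed seed and aborts on non-finite loss", {
  su <- micro_setup()
  tc <- train_config(eta = 1e-3, epochs = 2L, batch_size = 4L, seed = 11)
  f1 <- train_model(su$model, su$ds$images, su$ds$labels, su$split, tc)
  f2 <- train_model(su$model, su$ds$images, su$ds$labels, su$split, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$final_model$params, f2$final_model$params)

  bad <- su$model
  bad$params$head_W[1, 1] <- NaN
  expect_error(train_model(bad, su$ds$images, su$ds$labels, su$split, tc),
               "epoch 1 step 1.*non-finite loss")
})

test_that("adamw with cosine schedule trains without drift in the history contract", {
  su <- micro_setup(n = 8)
  tc <- train_config(eta = 3e-3, epochs = 4L, batch_size = 4L, seed = 3,
                     schedule = "cosine", augment = TRUE)
  fit <- train_model(su$model, su$ds$images, su$ds$labels, su$split, tc)
  expect_equal(nrow(fit$history), 4)
  expect_equal(fit$history$epoch, 1:4)
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(all(fit$history$train_acc >= 0 & fit$history$train_acc <= 1))
})
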