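#' Training configuration
#'
#' Optimization protocol for PVNet regression: mean squared error loss with
#' the Adam optimizer, validation-based early stopping. Defaults follow the
#' standard protocol for this task (initial learning rate 1e-4, batch size
#' 128, up to 200 epochs, patience 15).
#'
#' @param lr Initial learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience, epochs without validation-loss
#'   improvement.
#' @param val_frac Fraction of pairs held out for validation.
#' @param seed Seed governing the split, initialization and shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(lr = 1e-4, batch_size = 128, max_epochs = 200,
                            patience = 15, val_frac = 0.2, seed = 0) {
  stopifnot(lr >= 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
            patience < max_epochs || max_epochs == 1,
            val_frac > 0, val_frac < 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "training_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

as_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("image", "v_true") %in% names(pairs)))
    list(images = pairs$image, targets = pairs$v_true)
  } else {
    stopifnot(all(c("images", "targets") %in% names(pairs)))
    pairs
  }
}

#' Train PVNet on labelled phase images
#'
#' Splits the pairs into disjoint training and validation sets, standardizes
#' the targets on the training split, and optimizes the MSE with Adam.
#' Training stops when the validation loss has not improved for
#' `patience` epochs (or at `max_epochs`); the parameters of the best
#' validation epoch are returned. Fully deterministic given the seeds.
#'
#' @param pairs A tibble from [make_training_set()] (columns `image`,
#'   `v_true`) or a `list(images =, targets =)`. Images are resized to the
#'   model input size here, as an explicit preprocessing step.
#' @param tcfg A [training_config()].
#' @param mcfg A [pvnet_config()].
#' @return A `pvnet_fit`: list with the trained `model` (best-validation
#'   checkpoint), `history` (per-epoch tibble), `best_epoch`, and the
#'   configurations.
#' @export
train_pvnet <- function(pairs, tcfg = training_config(),
                        mcfg = pvnet_config("tiny")) {
  pr <- as_pairs(pairs)
  n <- length(pr$images)
  if (n < 2) stop_sawoce("need at least 2 labelled pairs", "sawoce_config")
  stopifnot(length(pr$targets) == n)
  model <- pvnet(mcfg, seed = tcfg$seed)
  input_size <- mcfg$input_size
  imgs <- lapply(pr$images, function(im) {
    if (all(dim(im) == input_size)) im else resize_bilinear(im, input_size[1],
                                                            input_size[2])
  })
  y <- as.numeric(pr$targets)

  split <- with_seed(tcfg$seed + 1L, {
    n_val <- max(1L, round(tcfg$val_frac * n))
    val <- sample.int(n, n_val)
    list(train = setdiff(seq_len(n), val), val = val)
  })
  if (!length(split$train) || !length(split$val)) {
    stop_sawoce("empty train or validation split", "sawoce_config")
  }
  model$target_center <- mean(y[split$train])
  model$target_scale <- max(sd(y[split$train]), 1e-8)
  ys <- (y - model$target_center) / model$target_scale

  x_val <- pvnet_input(imgs[split$val], input_size)
  y_val <- ys[split$val]
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params,
               run_stats = as.list(model$run_stats), epoch = 0L)
  since <- 0L
  history <- vector("list", tcfg$max_epochs)

  # lr = 0 means a fully frozen model: no parameter updates and no batch-
  # statistic drift, so repeated epochs are bit-identical.
  learning <- tcfg$lr > 0
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- with_seed(tcfg$seed + 1000L + epoch, sample(split$train))
    tr_loss <- 0
    nb <- 0
    for (start in seq(1, length(ord), by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1, length(ord))]
      xb <- pvnet_input(imgs[idx], input_size)
      fwd <- pvnet_fwd(model, xb, training = learning, keep_cache = TRUE)
      err <- fwd$pred - ys[idx]
      loss <- mean(err^2)
      grads <- pvnet_bwd(model, fwd$cache, 2 * err / length(err))
      upd <- adam_step(model$params, grads, opt, tcfg$lr)
      model$params <- upd$params
      opt <- upd$state
      tr_loss <- tr_loss + loss
      nb <- nb + 1
    }
    val_pred <- pvnet_fwd(model, x_val, training = FALSE)$pred
    val_loss <- mean((val_pred - y_val)^2)
    val_mae <- mean(abs(val_pred - y_val)) * model$target_scale
    history[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss / nb,
                               val_loss = val_loss, val_mae = val_mae)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = model$params,
                   run_stats = as.list(model$run_stats), epoch = epoch)
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= tcfg$patience) break
    }
  }
  model$params <- best$params
  model$run_stats <- list2env(best$run_stats, parent = emptyenv())
  structure(list(model = model,
                 history = dplyr::bind_rows(history[!vapply(history, is.null,
                                                            logical(1))]),
                 best_epoch = best$epoch, tcfg = tcfg, mcfg = mcfg,
                 split = split),
            class = "pvnet_fit")
}

#' @export
print.pvnet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<pvnet_fit> %d epochs (best %d), val loss %.4g, val MAE %.3g m/s\n",
    nrow(h), x$best_epoch, min(h$val_loss), h$val_mae[x$best_epoch]))
  invisible(x)
}

#' @export
predict.pvnet_fit <- function(object, images, ...) {
  predict(object$model, images, ...)
}

#' @describeIn train_pvnet Per-epoch loss history as a tibble.
#' @param x A `pvnet_fit`.
#' @param ... Unused.
#' @export
tidy.pvnet_fit <- function(x, ...) x$history

#' @describeIn train_pvnet One-row training summary.
#' @export
glance.pvnet_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_loss = min(x$history$val_loss),
         best_val_mae = x$history$val_mae[x$best_epoch],
         n_train = length(x$split$train), n_val = length(x$split$val),
         n_parameters = n_parameters(x$model))
}

#' Mean absolute error of a model on labelled pairs
#'
#' @param model A `pvnet` or `pvnet_fit`.
#' @param pairs Labelled pairs as in [train_pvnet()].
#' @return List with `mae` and `sd`: mean and standard deviation of the
#'   absolute errors `|prediction - target|`, m/s.
#' @export
evaluate_mae <- function(model, pairs) {
  if (inherits(model, "pvnet_fit")) model <- model$model
  pr <- as_pairs(pairs)
  if (!length(pr$images)) {
    stop_sawoce("cannot evaluate on an empty set", "sawoce_config")
  }
  input_size <- model$config$input_size
  imgs <- lapply(pr$images, function(im) {
    if (all(dim(im) == input_size)) im else resize_bilinear(im, input_size[1],
                                                            input_size[2])
  })
  err <- abs(predict(model, imgs) - as.numeric(pr$targets))
  list(mae = mean(err), sd = if (length(err) > 1) sd(err) else 0)
}
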