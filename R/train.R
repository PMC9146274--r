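#' Training protocol configuration
#'
#' Mirrors the reference protocol: ADAM with standard moment decays,
#' an initial learning rate of 0.01 dropped by a factor of 0.2 every 25
#' epochs (piecewise constant), mini-batches of 50 frames, 200 maximum
#' epochs, and a least-squares loss augmented with an l2 penalty
#' (lambda = 0.1) on convolution and transposed-convolution weights only
#' (biases and batch-norm parameters are not penalised).
#'
#' @param initial_lr initial learning rate (default 0.01).
#' @param drop_factor multiplicative learning-rate drop (default 0.2).
#' @param drop_period_epochs epochs between drops (default 25).
#' @param batch_size mini-batch size (default 50).
#' @param max_epochs number of epochs (default 200; 60 is used for the
#'   largest frames).
#' @param l2_lambda weight-penalty coefficient (default 0.1).
#' @param beta1,beta2,adam_eps ADAM first/second moment decays and
#'   epsilon (defaults 0.9, 0.999, 1e-8).
#' @param seed seed driving initial shuffling order and any stochastic
#'   layer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, drop_factor = 0.2,
                         drop_period_epochs = 25, batch_size = 50,
                         max_epochs = 200, l2_lambda = 0.1,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1) {
  stopifnot(initial_lr > 0, drop_factor > 0, drop_factor <= 1,
            drop_period_epochs >= 1, batch_size >= 1, max_epochs >= 1,
            l2_lambda >= 0)
  structure(list(initial_lr = initial_lr, drop_factor = drop_factor,
                 drop_period_epochs = as.integer(drop_period_epochs),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), l2_lambda = l2_lambda,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Piecewise-constant learning-rate schedule
#'
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch number.
#' @return `initial_lr * drop_factor^floor((epoch - 1) / drop_period)`.
#' @examples
#' cfg <- train_config()
#' lr_at_epoch(cfg, 1)   # 0.01
#' lr_at_epoch(cfg, 26)  # 0.002
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(all(epoch >= 1))
  cfg$initial_lr * cfg$drop_factor^floor((epoch - 1) / cfg$drop_period_epochs)
}

# names of penalised parameter tensors: conv / transposed-conv weights
.penalized <- function(params) {
  nm <- names(params)
  nm[grepl("_w$", nm) | grepl("up_w$", nm)]
}

#' Penalised least-squares training loss
#'
#' `(1 / (2 * B * P)) * sum((prediction - target)^2) + lambda * sum(w^2)`
#' where `B` is the number of frames in the batch, `P` the pixels per
#' frame and the weight sum runs over convolution and
#' transposed-convolution weights only.
#'
#' @param prediction,target (H, W, 1, B) arrays or matrices of equal
#'   shape.
#' @param params named parameter list (or NULL for the bare data term).
#' @param lambda penalty coefficient.
#' @return Scalar loss.
#' @export
training_loss <- function(prediction, target, params = NULL, lambda = 0) {
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(target) %||% length(target)))
    stop("prediction and target shapes differ")
  B <- if (is.null(dim(prediction)) || length(dim(prediction)) < 4) 1
       else dim(prediction)[4]
  P <- length(prediction) / B
  data_term <- sum((prediction - target)^2) / (2 * B * P)
  pen <- 0
  if (!is.null(params) && lambda > 0)
    pen <- lambda * sum(vapply(.penalized(params),
                               function(nm) sum(params[[nm]]^2), numeric(1)))
  data_term + pen
}

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

.adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * gmat
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

.stack_batch <- function(pairs, idx, field) {
  H <- nrow(pairs[[idx[1]]][[field]])
  W <- ncol(pairs[[idx[1]]][[field]])
  out <- array(0, c(H, W, 1L, length(idx)))
  for (k in seq_along(idx)) out[, , 1, k] <- pairs[[idx[k]]][[field]]
  out
}

#' Train a restoration network
#'
#' Runs seeded mini-batch ADAM optimisation of the penalised
#' least-squares loss for `cfg$max_epochs` epochs with per-epoch
#' shuffling; the last incomplete mini-batch of an epoch is kept.  There
#' is no early stopping: validation loss is recorded for monitoring
#' only and the final-epoch weights are returned.  A non-finite loss
#' aborts with a diagnostic.
#'
#' @param net a network from [build_upunet()] or [build_baseline_unet()].
#' @param dataset a `bead_dataset` with non-empty train and validation
#'   splits (or a list with `pairs` and `split`).
#' @param cfg a [train_config()].
#' @param verbose print one log line per epoch.
#' @return An object of class `upunet_fit`: `net` (trained), `history`
#'   (data frame: epoch, lr, train_loss, val_loss, seconds), `cfg`.
#' @export
train_model <- function(net, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "restoration_net"))
  pairs <- dataset$pairs
  tr <- dataset$split$train
  va <- dataset$split$val
  if (length(tr) == 0) stop("empty training split")
  if (cfg$batch_size > length(tr))
    stop("batch_size exceeds the training-set size")
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0),
                        seconds = numeric(0))
  state <- .adam_init(net$params)
  val_in <- if (length(va)) .stack_batch(pairs, va, "input") else NULL
  val_tg <- if (length(va)) .stack_batch(pairs, va, "target") else NULL
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      t0 <- proc.time()[["elapsed"]]
      lr <- lr_at_epoch(cfg, epoch)
      order_idx <- sample(tr)
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / cfg$batch_size))
      epoch_loss <- 0
      for (b in batches) {
        xb <- .stack_batch(pairs, b, "input")
        yb <- .stack_batch(pairs, b, "target")
        fw <- net_forward(net, xb, training = TRUE, cache = TRUE)
        net <- fw$net
        loss <- training_loss(fw$y, yb, net$params, cfg$l2_lambda)
        if (!is.finite(loss))
          stop("training diverged at epoch ", epoch, " (non-finite loss)")
        dy <- (fw$y - yb) / (length(b) * prod(dim(fw$y)[1:2]))
        grads <- net_backward(net, fw$cache, dy)
        if (cfg$l2_lambda > 0)
          for (nm in .penalized(net$params))
            grads[[nm]] <- grads[[nm]] + 2 * cfg$l2_lambda * net$params[[nm]]
        st <- .adam_step(net$params, grads, state, lr, cfg)
        net$params <- st$params
        state <- st$state
        epoch_loss <- epoch_loss + loss * length(b)
      }
      epoch_loss <- epoch_loss / length(tr)
      val_loss <- NA_real_
      if (!is.null(val_in)) {
        pv <- net_forward(net, val_in, training = FALSE)$y
        val_loss <- training_loss(pv, val_tg, net$params, cfg$l2_lambda)
      }
      secs <- proc.time()[["elapsed"]] - t0
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = lr,
                                  train_loss = epoch_loss,
                                  val_loss = val_loss, seconds = secs))
      if (verbose)
        message(sprintf("epoch %3d  lr %.5f  train %.4f  val %.4f  (%.1fs)",
                        epoch, lr, epoch_loss, val_loss, secs))
    }
  })
  structure(list(net = net, history = history, cfg = cfg),
            class = "upunet_fit")
}

#' @export
print.upunet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained restoration network: %d epochs, final train loss %.4f, val loss %.4f\n",
              nrow(h), h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  print(x$net)
  invisible(x)
}

#' @export
coef.upunet_fit <- function(object, ...) object$net$params

#' @export
predict.upunet_fit <- function(object, newdata, ...)
  predict(object$net, newdata, ...)

#' Training and validation loss curves
#'
#' @param x an `upunet_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.upunet_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1:2, col = c("black", "red3"), xlab = "epoch",
                    ylab = "loss", log = "y", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Restoration residuals on held-out pairs
#'
#' @param object an `upunet_fit`.
#' @param dataset a `bead_dataset`; defaults must be supplied by the
#'   caller (the fit does not retain the training data).
#' @param which split to evaluate (default `"test"`).
#' @param ... unused.
#' @return Data frame with per-frame restored-vs-target and
#'   input-vs-target mean squared errors.
#' @export
residuals.upunet_fit <- function(object, dataset, which = "test", ...) {
  idx <- dataset$split[[which]]
  out <- lapply(idx, function(i) {
    pr <- pairs_mse(object$net, dataset$pairs[[i]])
    data.frame(id = i, mse_restored = pr[1], mse_input = pr[2])
  })
  do.call(rbind, out)
}

pairs_mse <- function(net, pair) {
  rest <- restore_frame(net, pair$input)
  c(mean((rest - pair$target)^2), mean((pair$input - pair$target)^2))
}
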