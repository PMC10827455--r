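#' Learning-rate scheduler configuration
#'
#' Exponential decay with a floor, used for the block-wise fine-tuning
#' phase: the rate starts at `lr_max` and is multiplied by `decay` each
#' epoch until it reaches `lr_min`, where it stays.
#'
#' @param lr_max starting (maximum) learning rate.
#' @param lr_min floor learning rate.
#' @param decay per-epoch multiplicative decay in (0, 1).
#' @return An object of class `scheduler_config`.
#' @export
scheduler_config <- function(lr_max = 5e-5, lr_min = 1e-5, decay = 0.8) {
  if (lr_min > lr_max) abort("`lr_min` must not exceed `lr_max`")
  if (decay <= 0 || decay >= 1) abort("`decay` must be in (0, 1)")
  structure(list(lr_max = lr_max, lr_min = lr_min, decay = decay),
            class = "scheduler_config")
}

#' Learning rate at a given epoch
#'
#' `lr(e) = max(lr_min, lr_max * decay^e)`: non-increasing in `e` and
#' always within `[lr_min, lr_max]`.
#'
#' @param epoch non-negative integer (0 = first epoch).
#' @param cfg `scheduler_config`.
#' @return The learning rate.
#' @export
lr_schedule <- function(epoch, cfg = scheduler_config()) {
  if (any(epoch < 0)) abort("`epoch` must be >= 0")
  pmax(cfg$lr_min, cfg$lr_max * cfg$decay^epoch)
}

#' Training configuration
#'
#' @param batch_size minibatch size (>= 1).
#' @param base_lr Adam learning rate used when no scheduler is given.
#' @param epochs number of epochs (>= 1).
#' @param seed integer seed controlling shuffling, augmentation and mixup.
#' @param scheduler optional `scheduler_config`; when present the per-epoch
#'   rate is `lr_schedule(epoch - 1, scheduler)`.
#' @param freeze optional `freeze_config` (applied by [fine_tune()]).
#' @param augment optional `augment_config`; when present each training
#'   image is augmented (seeded) every epoch.
#' @param mixup logical; mix each batch with [mixup_batch()] (using
#'   `augment$mixup_alpha`, default 0.2). Never applied at evaluation or
#'   pseudo-labeling time.
#' @param class_weights optional named vector (`benign`, `malignant`) of
#'   loss weights.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, base_lr = 1e-3, epochs = 1L,
                         seed = 1L, scheduler = NULL, freeze = NULL,
                         augment = NULL, mixup = FALSE, class_weights = NULL) {
  if (batch_size < 1L) abort("`batch_size` must be >= 1")
  if (epochs < 1L) abort("`epochs` must be >= 1 (zero-epoch training is not a run)")
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = "adam", loss = "cross-entropy",
                 scheduler = scheduler, freeze = freeze, augment = augment,
                 mixup = isTRUE(mixup), class_weights = class_weights),
            class = "train_config")
}

adam_init <- function() new.env(parent = emptyenv())

adam_step <- function(model, opt, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- (opt$t %||% 0) + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    for (pn in intersect(names(grads[[nm]]), c("W", "b", "gamma", "beta"))) {
      g <- grads[[nm]][[pn]]
      if (is.null(g)) next
      key <- paste0(nm, ".", pn)
      st <- opt[[key]] %||% list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      model$nodes[[nm]]$params[[pn]] <- model$nodes[[nm]]$params[[pn]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
      opt[[key]] <- st
    }
    if (!is.null(grads[[nm]]$batch_mean)) {
      p <- model$nodes[[nm]]$params
      model$nodes[[nm]]$params$moving_mean <- 0.9 * p$moving_mean + 0.1 * grads[[nm]]$batch_mean
      model$nodes[[nm]]$params$moving_var <- 0.9 * p$moving_var + 0.1 * grads[[nm]]$batch_var
    }
  }
  model
}

augment_batch <- function(xb, aug, seed) {
  for (i in seq_len(dim(xb)[4])) {
    xb[, , , i] <- standard_augment(image_tensor(xb[, , , i]), aug,
                                    seed = derive_seed(seed, i))$pixels
  }
  xb
}

#' Train a model on labeled images
#'
#' Minibatch Adam on (categorical) cross-entropy. Only parameters whose
#' node is flagged trainable change; frozen batch-norm layers keep their
#' moving statistics and run in inference mode. Fully deterministic given
#' `cfg$seed` (single-threaded BLAS assumed for bitwise identity).
#'
#' @param model `model_graph` with trainable flags already applied.
#' @param x `(H, W, 3, N)` training images.
#' @param y class labels (character/factor) or an `N x 2` one-hot matrix.
#' @param cfg `train_config`.
#' @param opt optional Adam state (to continue an optimizer across calls,
#'   as the self-training loop does).
#' @return A list: `model` (updated), `history` (tibble with one row per
#'   epoch: epoch, lr, loss, accuracy), `opt` (Adam state).
#' @export
train_model <- function(model, x, y, cfg = train_config(), opt = NULL) {
  n <- dim(x)[4]
  if (is.null(n) || n == 0L) abort("training data is empty")
  yh <- if (is.matrix(y)) y else one_hot(y)
  if (nrow(yh) != n) abort("`x` and `y` sizes must agree")
  opt <- opt %||% adam_init()
  hist <- vector("list", cfg$epochs)
  wts <- if (!is.null(cfg$class_weights)) cfg$class_weights[CLASS_LEVELS] else c(1, 1)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (!is.null(cfg$scheduler)) lr_schedule(epoch - 1L, cfg$scheduler) else cfg$base_lr
    ord <- with_seed(derive_seed(cfg$seed, 104729, epoch), sample.int(n))
    tot_loss <- 0; tot_correct <- 0
    starts <- seq.int(1L, n, by = cfg$batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- yh[idx, , drop = FALSE]
      if (!is.null(cfg$augment))
        xb <- augment_batch(xb, cfg$augment, derive_seed(cfg$seed, epoch, bi))
      yb_hard <- yb
      if (cfg$mixup && length(idx) >= 2L) {
        alpha <- if (!is.null(cfg$augment)) cfg$augment$mixup_alpha else 0.2
        mx <- mixup_batch(xb, yb, alpha = alpha,
                          seed = derive_seed(cfg$seed, epoch, bi, 7L))
        xb <- mx$x; yb <- mx$y
      }
      fwd <- forward_graph(model, xb, training = TRUE)
      p <- fwd$prob
      w <- as.vector(yb_hard %*% wts)
      loss <- -sum(w * rowSums(yb * log(pmax(p, 1e-12)))) / sum(w)
      if (!is.finite(loss))
        abort(sprintf("non-finite loss at epoch %d, batch %d; try a lower learning rate",
                      epoch, bi))
      dlogits <- t((p - yb) * (w / sum(w)))
      grads <- backward_graph(model, fwd, dlogits)
      model <- adam_step(model, opt, grads, lr)
      tot_loss <- tot_loss + loss * length(idx)
      tot_correct <- tot_correct +
        sum(max.col(p, ties.method = "first") == max.col(yb_hard, ties.method = "first"))
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                    loss = tot_loss / n, accuracy = tot_correct / n)
  }
  history <- dplyr::bind_rows(hist)
  class(history) <- c("train_history", class(history))
  list(model = model, history = history, opt = opt)
}

#' Fine-tune under a freeze configuration and learning-rate schedule
#'
#' Applies the freeze configuration, then trains with the scheduler driving
#' the per-epoch learning rate (starting at `lr_max`).
#'
#' @inheritParams train_model
#' @param cfg `train_config` with non-null `freeze` and `scheduler`.
#' @return As [train_model()].
#' @export
fine_tune <- function(model, x, y, cfg) {
  if (is.null(cfg$freeze)) abort("fine_tune requires `cfg$freeze`")
  if (is.null(cfg$scheduler)) abort("fine_tune requires `cfg$scheduler`")
  model <- apply_freeze_config(model, cfg$freeze)
  train_model(model, x, y, cfg)
}

#' Accuracy of a model on labeled images
#'
#' @param model `model_graph`.
#' @param x `(H, W, 3, N)` images.
#' @param labels true class labels.
#' @return Proportion correct.
#' @export
model_accuracy <- function(model, x, labels) {
  mean(predict_proba(model, x)$predicted_label == as.character(labels))
}
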