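#' Optimization recipe
#'
#' Record of the training hyper-parameters: Adam with an epoch-granularity
#' cosine warm-restart schedule, label smoothing on top of the loss, an
#' explicit L2 penalty over all parameters (weights and biases), and
#' global-norm gradient clipping. No dropout is used anywhere.
#'
#' @param learning_rate Peak learning rate at every (re)start (default 1e-4).
#' @param batch_size Mini-batch size (default 64).
#' @param epochs Training epochs (default 100).
#' @param weight_l2 Coefficient of the L2 penalty `weight_l2 * sum(w^2)`
#'   added to the loss over all network parameters (default 0.01).
#' @param clip_max_norm Global gradient-norm ceiling (default 1.0).
#' @param label_smoothing Smoothing mass `epsilon` in `[0, 1)` (default 0.1).
#' @param restart_period First cosine cycle length T0 in epochs (default 10).
#' @param restart_mult Cycle-length multiplier at each restart (default 2).
#' @param eta_min Learning-rate floor of the cosine (default 0).
#' @param seed RNG seed controlling shuffling (default 1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64L,
                         epochs = 100L, weight_l2 = 0.01,
                         clip_max_norm = 1.0, label_smoothing = 0.1,
                         restart_period = 10L, restart_mult = 2L,
                         eta_min = 0, seed = 1L) {
  if (label_smoothing < 0 || label_smoothing >= 1)
    stop("'label_smoothing' must lie in [0, 1)", call. = FALSE)
  if (eta_min > learning_rate)
    stop("'eta_min' must not exceed 'learning_rate'", call. = FALSE)
  if (weight_l2 < 0) stop("'weight_l2' must be >= 0", call. = FALSE)
  if (clip_max_norm <= 0) stop("'clip_max_norm' must be > 0", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_l2 = weight_l2,
                 clip_max_norm = clip_max_norm,
                 label_smoothing = label_smoothing,
                 restart_period = as.integer(restart_period),
                 restart_mult = as.integer(restart_mult),
                 eta_min = eta_min, seed = as.integer(seed)),
            class = "train_config")
}

log_softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  s - m - log(rowSums(exp(s - m)))
}

#' Label-smoothed categorical cross entropy
#'
#' `(1 - eps) * CE(scores, labels) + eps * CE(scores, uniform)`, averaged
#' over the batch, with CE computed from the softmax of the raw scores.
#' With all-equal scores the loss is `log(K)` for any `eps`; with `eps = 0`
#' it is the plain categorical cross entropy.
#'
#' @param scores Numeric `[N, K]` matrix of raw scores.
#' @param labels Integer vector of length N with classes in `1..K`.
#' @param eps Smoothing mass in `[0, 1)`.
#' @return Scalar mean loss.
#' @export
smoothed_cross_entropy <- function(scores, labels, eps = 0.1) {
  if (!is.matrix(scores) || ncol(scores) < 2L)
    stop("'scores' must be an [N, K] matrix with K >= 2", call. = FALSE)
  labels <- as.integer(labels)
  K <- ncol(scores); N <- nrow(scores)
  if (length(labels) != N) stop("length(labels) must equal nrow(scores)", call. = FALSE)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > K))
    stop(sprintf("labels must lie in 1..%d", K), call. = FALSE)
  if (eps < 0 || eps >= 1) stop("'eps' must lie in [0, 1)", call. = FALSE)
  lp <- log_softmax_rows(scores)
  ce_label <- -lp[cbind(seq_len(N), labels)]
  ce_unif <- -rowMeans(lp)
  mean((1 - eps) * ce_label + eps * ce_unif)
}

# gradient wrt scores of smoothed_cross_entropy (mean over batch)
smoothed_ce_grad <- function(scores, labels, eps) {
  N <- nrow(scores); K <- ncol(scores)
  p <- softmax_rows(scores)
  q <- matrix(eps / K, N, K)
  q[cbind(seq_len(N), as.integer(labels))] <-
    q[cbind(seq_len(N), as.integer(labels))] + (1 - eps)
  (p - q) / N
}

softplus <- function(s) pmax(s, 0) + log1p(exp(-abs(s)))

#' Binary / multilabel cross entropy with smoothed targets
#'
#' Mean element-wise binary cross entropy on the sigmoid of raw scores.
#' With smoothing `eps > 0` the 0/1 targets are relaxed to
#' `eps/2` and `1 - eps/2`. Columns may index multiple labels (multilabel
#' head).
#'
#' @param scores Numeric vector or `[N, L]` matrix of raw scores.
#' @param labels 0/1 vector or matrix of the same shape.
#' @param eps Smoothing mass in `[0, 1)`.
#' @return Scalar mean loss.
#' @export
binary_loss <- function(scores, labels, eps = 0.1) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  if (length(s) != length(y))
    stop("'scores' and 'labels' must have the same shape", call. = FALSE)
  if (any(is.na(y)) || any(y != 0 & y != 1))
    stop("'labels' must be 0/1", call. = FALSE)
  if (eps < 0 || eps >= 1) stop("'eps' must lie in [0, 1)", call. = FALSE)
  yt <- y * (1 - eps) + eps / 2
  mean(softplus(s) - yt * s)
}

binary_loss_grad <- function(scores, labels, eps) {
  yt <- labels * (1 - eps) + eps / 2
  (1 / (1 + exp(-scores)) - yt) / length(scores)
}

#' Cosine-annealed learning rate with warm restarts
#'
#' Cycle j has length `restart_period * restart_mult^j` epochs; within a
#' cycle, `lr(t) = eta_min + (lr_max - eta_min) * (1 + cos(pi t / T_j)) / 2`
#' with `t` the time since the last restart. At every restart the rate
#' returns exactly to `learning_rate`.
#'
#' @param epoch_fraction Non-negative epoch position(s), possibly fractional.
#' @param cfg A [train_config()].
#' @return Learning rate(s), same length as `epoch_fraction`.
#' @export
warm_restart_lr <- function(epoch_fraction, cfg) {
  vapply(epoch_fraction, function(t) {
    if (t < 0) stop("'epoch_fraction' must be >= 0", call. = FALSE)
    Tj <- cfg$restart_period
    while (t >= Tj) {
      t <- t - Tj
      Tj <- Tj * cfg$restart_mult
    }
    cfg$eta_min + (cfg$learning_rate - cfg$eta_min) * (1 + cos(pi * t / Tj)) / 2
  }, numeric(1))
}

param_sq_sum <- function(params) sum(vapply(params, function(p) sum(p * p), numeric(1)))

grad_global_norm <- function(grads) sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))

batch_data_loss <- function(head, scores, y, eps) {
  switch(head,
    "multiclass-softmax" = smoothed_cross_entropy(scores, y, eps),
    "binary" = binary_loss(scores[, 1L], y, eps),
    "multilabel-sigmoid" = binary_loss(scores, y, eps))
}

batch_data_grad <- function(head, scores, y, eps) {
  switch(head,
    "multiclass-softmax" = smoothed_ce_grad(scores, y, eps),
    "binary" = matrix(binary_loss_grad(scores[, 1L], y, eps), ncol = 1L),
    "multilabel-sigmoid" = matrix(binary_loss_grad(scores, as.numeric(y), eps),
                                  nrow = nrow(scores)))
}

batch_accuracy <- function(head, scores, y) {
  if (head == "multiclass-softmax")
    return(mean(max.col(scores, ties.method = "first") == as.integer(y)))
  pr <- 1 / (1 + exp(-scores))
  mean((pr > 0.5) == (as.numeric(y) > 0.5))
}

slice_y <- function(y, idx) if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx]

#' Train a model
#'
#' Runs mini-batch Adam over the dataset: per epoch, the learning rate is
#' set by [warm_restart_lr()], the data loss (smoothed cross entropy or
#' binary cross entropy, per the model head) is augmented by
#' `weight_l2 * sum(w^2)` over every parameter, gradients are clipped to a
#' global norm of `clip_max_norm`, and an epoch row (lr, train loss/acc,
#' validation loss/acc) is appended to the history. Fully reproducible for
#' a fixed `cfg$seed`.
#'
#' @param model A [build_model()] result.
#' @param train_data List with `x` (`[C, T, N]` array) and `y` (integer
#'   labels `1..K` for the multiclass head, 0/1 vector for the binary head,
#'   0/1 `[N, L]` matrix for the multilabel head).
#' @param valid_data Optional list like `train_data` for per-epoch
#'   validation metrics.
#' @param cfg A [train_config()].
#' @param grad_hook Optional function called after clipping with the
#'   post-clip global gradient norm (monitoring hook for diagnostics).
#' @return An object of class `ddx_fit`: `model` (trained), `history`
#'   (data.frame epoch/lr/train_loss/train_acc/valid_loss/valid_acc),
#'   `config`.
#' @export
fit <- function(model, train_data, valid_data = NULL, cfg = train_config(),
                grad_hook = NULL) {
  if (!inherits(model, "ddx_model")) stop("'model' must be a ddx_model", call. = FALSE)
  if (!inherits(cfg, "train_config")) stop("'cfg' must be a train_config", call. = FALSE)
  x <- train_data$x; y <- train_data$y
  if (is.null(x) || length(dim(x)) != 3L || dim(x)[3L] < 1L)
    stop("'train_data$x' must be a non-empty [C, T, N] array", call. = FALSE)
  N <- dim(x)[3L]
  head <- model$config$head
  params <- model$params
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  hist <- vector("list", cfg$epochs)
  mdl <- model
  for (epoch in seq_len(cfg$epochs)) {
    lr <- warm_restart_lr(epoch - 1L, cfg)
    ord <- sample.int(N)
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
      xb <- x[, , idx, drop = FALSE]
      yb <- slice_y(y, idx)
      mdl$params <- params
      fwd <- model_forward(mdl, xb, need_cache = TRUE)
      dloss <- batch_data_loss(head, fwd$scores, yb, cfg$label_smoothing)
      loss <- dloss + cfg$weight_l2 * param_sq_sum(params)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
      grads <- model_backward(mdl, fwd$caches, batch_data_grad(head, fwd$scores, yb,
                                                               cfg$label_smoothing))
      for (nm in names(grads))
        grads[[nm]] <- grads[[nm]] + 2 * cfg$weight_l2 * params[[nm]]
      gn <- grad_global_norm(grads)
      if (gn > cfg$clip_max_norm) {
        sc <- cfg$clip_max_norm / gn
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] * sc
      }
      if (!is.null(grad_hook)) grad_hook(grad_global_norm(grads))
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in names(params)) {
        g <- grads[[nm]]
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g * g
        params[[nm]] <- params[[nm]] -
          lr * (m_state[[nm]] / bc1) / (sqrt(v_state[[nm]] / bc2) + adam_eps)
      }
      nb <- length(idx)
      ep_loss <- ep_loss + loss * nb
      ep_acc <- ep_acc + batch_accuracy(head, fwd$scores, yb) * nb
      ep_n <- ep_n + nb
    }
    mdl$params <- params
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = ep_loss / ep_n, train_acc = ep_acc / ep_n,
                      valid_loss = NA_real_, valid_acc = NA_real_)
    if (!is.null(valid_data)) {
      vs <- model_forward(mdl, valid_data$x)$scores
      row$valid_loss <- batch_data_loss(head, vs, valid_data$y, cfg$label_smoothing) +
        cfg$weight_l2 * param_sq_sum(params)
      row$valid_acc <- batch_accuracy(head, vs, valid_data$y)
    }
    hist[[epoch]] <- row
  }
  structure(list(model = mdl, history = do.call(rbind, hist), config = cfg),
            class = "ddx_fit")
}

#' @export
print.ddx_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("ddx_fit: %d epochs, final train loss %.4f, train acc %.3f",
              n, x$history$train_loss[n], x$history$train_acc[n]))
  if (!is.na(x$history$valid_acc[n]))
    cat(sprintf(", valid acc %.3f", x$history$valid_acc[n]))
  cat("\n")
  invisible(x)
}
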