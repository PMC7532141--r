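test_that("smoothed cross entropy matches closed forms and a hand oracle", {
  set.seed(1)
  scores <- matrix(rnorm(12), 4, 3)
  labels <- c(1, 3, 2, 1)
  # eps = 0 is the plain categorical cross entropy
  p <- t(apply(scores, 1, function(s) exp(s - max(s)) / sum(exp(s - max(s)))))
  plain <- -mean(log(p[cbind(1:4, labels)]))
  expect_equal(smoothed_cross_entropy(scores, labels, 0), plain,
               tolerance = 1e-13)
  # all-equal scores give log K for every eps
  flat <- matrix(1.7, 5, 4)
  for (eps in c(0, 0.1, 0.5, 0.9))
    expect_equal(smoothed_cross_entropy(flat, c(1, 2, 3, 4, 1), eps), log(4),
                 tolerance = 1e-13)
  # N = 1, K = 2, scores (2, 0), label 1, eps = 0.1: hand evaluation
  p2 <- exp(c(2, 0)) / sum(exp(c(2, 0)))
  expected <- 0.9 * (-log(p2[1])) + 0.1 * mean(-log(p2))
  expect_equal(smoothed_cross_entropy(matrix(c(2, 0), 1, 2), 1L, 0.1),
               expected, tolerance = 1e-13)
  expect_error(smoothed_cross_entropy(scores, c(1, 2, 5, 1), 0.1), "labels")
})

test_that("smoothed cross entropy is minimized by the smoothed target itself", {
  # direct optimization on a 3-class toy with one-hot label 2, eps = 0.2
  eps <- 0.2
  obj <- function(s) smoothed_cross_entropy(matrix(s, 1, 3), 2L, eps)
  opt <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  p_opt <- exp(opt$par - max(opt$par)) / sum(exp(opt$par - max(opt$par)))
  target <- c(eps / 3, 1 - eps + eps / 3, eps / 3)
  expect_equal(p_opt, target, tolerance = 1e-5)
})

test_that("binary loss matches scalar oracles and supports multilabel shapes", {
  expect_equal(binary_loss(0, 1, 0), log(2), tolerance = 1e-13)
  expect_equal(binary_loss(0, 0, 0), log(2), tolerance = 1e-13)
  expect_equal(binary_loss(1.0, 1, 0), -log(1 / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_lt(binary_loss(c(50, -50), c(1, 0), 0), 1e-20)
  s <- matrix(rnorm(6), 2, 3)
  y <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3)
  manual <- mean(-(y * log(plogis(s)) + (1 - y) * log(1 - plogis(s))))
  expect_equal(binary_loss(s, y, 0), manual, tolerance = 1e-12)
  expect_error(binary_loss(c(0, 0), c(0, 2), 0), "0/1")
})

test_that("warm-restart schedule hits lr_max at restarts and lr_max/2 at midpoints", {
  cfg <- train_config(learning_rate = 1e-4, restart_period = 10,
                      restart_mult = 2, eta_min = 0)
  # cycles: [0,10), [10,30), [30,70)
  expect_identical(warm_restart_lr(c(0, 10, 30, 70), cfg), rep(1e-4, 4))
  expect_equal(warm_restart_lr(5, cfg), 1e-4 / 2, tolerance = 1e-15)
  expect_equal(warm_restart_lr(20, cfg), 1e-4 / 2, tolerance = 1e-15)
  expect_equal(warm_restart_lr(50, cfg), 1e-4 / 2, tolerance = 1e-15)
  # monotone decay within a cycle
  lrs <- warm_restart_lr(seq(0, 9.5, by = 0.5), cfg)
  expect_true(all(diff(lrs) < 0))
})

test_that("fit is reproducible, clips gradients and records the schedule", {
  data <- separable_dataset(n = 32, t_len = 48, seed = 2)
  cfg_m <- model_config(1, 2, blocks_per_stage = c(1), growth_rate = 4)
  tc <- train_config(learning_rate = 1e-3, batch_size = 16, epochs = 12,
                     clip_max_norm = 0.05, restart_period = 5,
                     restart_mult = 2, seed = 7)
  norms <- c()
  f1 <- fit(build_model(cfg_m, 1), data, cfg = tc,
            grad_hook = function(n) norms <<- c(norms, n))
  f2 <- fit(build_model(cfg_m, 1), data, cfg = tc)
  expect_identical(f1$history, f2$history)
  expect_true(all(norms <= 0.05 + 1e-6))
  # lr is exactly lr_max at epochs 1, 6, 16 (restarts at 0, 5, 15)
  expect_equal(f1$history$lr[1], 1e-3)
  expect_equal(f1$history$lr[6], 1e-3)
  expect_true(all(f1$history$lr <= 1e-3))
})

test_that("the L2 penalty in the reported loss equals direct parameter summation", {
  data <- separable_dataset(n = 16, t_len = 48, seed = 3)
  cfg_m <- model_config(1, 2, blocks_per_stage = c(1), growth_rate = 4)
  tc <- train_config(learning_rate = 1e-3, batch_size = 16, epochs = 1,
                     weight_l2 = 0.01, seed = 1)
  f <- fit(build_model(cfg_m, 1), data, valid_data = data, cfg = tc)
  sq <- sum(vapply(f$model$params, function(p) sum(p^2), numeric(1)))
  sc <- model_forward(f$model, data$x)$scores
  expected <- smoothed_cross_entropy(sc, data$y, tc$label_smoothing) + 0.01 * sq
  expect_equal(f$history$valid_loss[1], expected, tolerance = 1e-12)
})

test_that("a vanishingly small clip norm freezes training", {
  data <- separable_dataset(n = 16, t_len = 48, seed = 4)
  cfg_m <- model_config(1, 2, blocks_per_stage = c(1), growth_rate = 4)
  tc <- train_config(learning_rate = 1e-4, batch_size = 16, epochs = 4,
                     clip_max_norm = 1e-8, weight_l2 = 0, seed = 1)
  f <- fit(build_model(cfg_m, 1), data, cfg = tc)
  expect_lt(max(abs(diff(f$history$train_loss))), 1e-3)
})

test_that("a tiny model fits a linearly separable two-class set", {
  for (seed in 1:3) {
    data <- separable_dataset(n = 64, t_len = 64, seed = seed)
    cfg_m <- model_config(1, 2, blocks_per_stage = c(1), growth_rate = 4)
    tc <- train_config(learning_rate = 1e-2, batch_size = 16, epochs = 20,
                       seed = seed)
    f <- fit(build_model(cfg_m, seed), data, cfg = tc)
    expect_gte(tail(f$history$train_acc, 1), 0.99)
  }
})

test_that("empty datasets and invalid configs are rejected", {
  cfg_m <- model_config(1, 2, blocks_per_stage = c(1), growth_rate = 4)
  m <- build_model(cfg_m, 1)
  expect_error(fit(m, list(x = NULL, y = NULL), cfg = train_config()),
               "non-empty")
  expect_error(train_config(label_smoothing = 1), "0, 1")
  expect_error(train_config(eta_min = 1, learning_rate = 1e-4), "eta_min")
})

test_that("binary and multilabel heads train and score sensibly", {
  set.seed(31)
  n <- 48; t_len <- 64
  x <- array(0, c(1, t_len, n))
  yb <- rep(c(0, 1), length.out = n)
  for (i in seq_len(n)) x[1, , i] <- (2 * yb[i] - 1) + 0.1 * rnorm(t_len)
  cfg_b <- model_config(1, 1, head = "binary", blocks_per_stage = 1L,
                        growth_rate = 4)
  fb <- fit(build_model(cfg_b, 1), list(x = x, y = yb),
            cfg = train_config(learning_rate = 1e-2, batch_size = 16,
                               epochs = 15, seed = 1))
  expect_gte(tail(fb$history$train_acc, 1), 0.95)
  pr <- predict(fb$model, x, type = "prob")
  expect_gt(auroc(pr[, 1], yb), 0.95)

  # two independent labels, each tied to the signal level in one half
  ym <- cbind(yb, rep(c(0, 0, 1, 1), length.out = n))
  for (i in seq_len(n))
    x[1, 1:32, i] <- (2 * ym[i, 2] - 1) + 0.1 * rnorm(32)
  cfg_m <- model_config(1, 2, head = "multilabel-sigmoid",
                        blocks_per_stage = 1L, growth_rate = 4)
  fm <- fit(build_model(cfg_m, 2), list(x = x, y = ym),
            cfg = train_config(learning_rate = 1e-2, batch_size = 16,
                               epochs = 15, seed = 2))
  prm <- predict(fm$model, x, type = "prob")
  expect_gt(auroc(prm, ym, "micro"), 0.9)
  expect_gt(auroc(prm, ym, "macro"), 0.9)
  expect_identical(dim(predict(fm$model, x, type = "class")), dim(ym))
})
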