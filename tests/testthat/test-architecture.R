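test_that("dilation schedule follows min(cap, 2^(i+2)) with per-stage reset", {
  expect_identical(dilation_schedule(2, 128), c(4L, 8L))
  expect_identical(dilation_schedule(8, 128),
                   c(4L, 8L, 16L, 32L, 64L, 128L, 128L, 128L))
  expect_identical(dilation_schedule(1, 4), 4L)
  expect_error(dilation_schedule(0, 128), "positive")
  expect_error(dilation_schedule(3, 2), ">= 4")
})

test_that("channel plan reproduces the concatenative-growth arithmetic", {
  cp <- channel_plan(model_config(1, 2))
  expect_identical(cp$entry_out, 64L)
  expect_identical(cp$stage_pre, c(128L, 256L, 384L, 320L))
  expect_identical(cp$stage_post, c(64L, 128L, 192L, 160L))
  expect_identical(cp$head_in, 160L)

  # no compression, single block
  cp2 <- channel_plan(model_config(1, 2, blocks_per_stage = 1L,
                                   growth_rate = 8, compression = 1.0))
  expect_identical(cp2$entry_out, 16L)
  expect_identical(cp2$stage_pre, 24L)
  expect_identical(cp2$stage_post, 24L)

  # floor in the compression: floor(0.5 * 3) = 1
  cp3 <- channel_plan(model_config(1, 2, blocks_per_stage = 1L,
                                   growth_rate = 1, compression = 0.5))
  expect_identical(cp3$entry_out, 2L)
  expect_identical(cp3$stage_pre, 3L)
  expect_identical(cp3$stage_post, 1L)
})

test_that("default build has 20 dense blocks, 4 transitions, max dilation 128", {
  cfg <- model_config(2, 2)
  m <- build_model(cfg, seed = 1)
  roles <- names(m$params)
  expect_length(grep("\\.bottleneck\\.W$", roles), 20L)
  expect_length(grep("\\.conv\\.W$", roles), 20L)
  expect_length(grep("transition\\.W$", roles), 4L)
  expect_length(grep("^entry\\.W$", roles), 1L)
  expect_length(grep("^head\\.W$", roles), 1L)
  dil <- vapply(m$plan$layers, function(l) l$spec$dilation, integer(1))
  expect_identical(max(dil), 128L)
})

test_that("same seed gives bit-identical parameters; different seed differs", {
  cfg <- model_config(1, 3, blocks_per_stage = c(1, 2), growth_rate = 4)
  m1 <- build_model(cfg, seed = 99)
  m2 <- build_model(cfg, seed = 99)
  m3 <- build_model(cfg, seed = 100)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("the default dilation multiset matches the per-stage schedule", {
  m <- build_model(model_config(1, 2), seed = 1)
  per_stage <- lapply(1:4, function(s) {
    idx <- grep(sprintf("^s%d\\.b\\d+\\.conv$", s),
                vapply(m$plan$layers, `[[`, "", "role"))
    vapply(m$plan$layers[idx], function(l) l$spec$dilation, integer(1))
  })
  expect_identical(per_stage[[1]], c(4L, 8L))
  expect_identical(per_stage[[2]], c(4L, 8L, 16L, 32L, 64L, 128L))
  expect_identical(per_stage[[3]], c(4L, 8L, 16L, 32L, 64L, 128L, 128L, 128L))
  expect_identical(per_stage[[4]], c(4L, 8L, 16L, 32L))
  # bottlenecks are undilated
  bidx <- grep("bottleneck", vapply(m$plan$layers, `[[`, "", "role"))
  expect_true(all(vapply(m$plan$layers[bidx], function(l) l$spec$dilation,
                         integer(1)) == 1L))
})

test_that("parameter count is a deterministic integer matching direct arithmetic", {
  cfg <- model_config(3, 5, blocks_per_stage = c(1, 2), growth_rate = 4)
  m <- build_model(cfg, seed = 1)
  expected <- sum(vapply(m$plan$layers, function(l)
    l$spec$out_channels * (l$spec$in_channels * l$spec$kernel_size + 1L),
    numeric(1))) + cfg$num_classes * (m$plan$head_in + 1L)
  expect_identical(num_parameters(m), as.integer(expected))
  expect_identical(num_parameters(build_model(cfg, seed = 7)), as.integer(expected))
})

test_that("forward emits [N, K] scores; zeroed head gives uniform softmax", {
  cfg <- model_config(1, 4, blocks_per_stage = c(1), growth_rate = 4)
  m <- build_model(cfg, seed = 1)
  x <- array(rnorm(1 * 64 * 3), c(1, 64, 3))
  sc <- model_forward(m, x)$scores
  expect_identical(dim(sc), c(3L, 4L))
  m$params$head.W[] <- 0
  m$params$head.b[] <- 0
  pr <- predict(m, x, type = "prob")
  expect_equal(pr, matrix(0.25, 3, 4), ignore_attr = TRUE)
  expect_equal(rowSums(predict(build_model(cfg, 2), x, type = "prob")),
               rep(1, 3))
})

test_that("channel mismatch and too-short inputs raise errors", {
  m <- build_model(model_config(2, 2, blocks_per_stage = c(1), growth_rate = 4), 1)
  expect_error(model_forward(m, array(0, c(3, 64, 1))), "channels")
  expect_error(model_forward(m, array(0, c(2, 4, 1))), "minimum supported length")
})

test_that("measured concatenated widths match channel_plan over random configs", {
  set.seed(11)
  for (rep in 1:20) {
    cfg <- random_small_config()
    m <- build_model(cfg, seed = rep)
    cp <- channel_plan(cfg)
    x <- array(rnorm(cfg$input_channels * 140), c(cfg$input_channels, 140, 1))
    acts <- model_forward(m, x, collect = TRUE)$activations
    for (s in seq_along(cfg$blocks_per_stage)) {
      last_block <- sprintf("s%d.b%d", s, cfg$blocks_per_stage[s])
      expect_identical(dim(acts[[last_block]])[1L], cp$stage_pre[s])
      tr_W <- m$params[[sprintf("s%d.transition.W", s)]]
      expect_identical(nrow(tr_W), cp$stage_post[s])
      expect_identical(ncol(tr_W), cp$stage_pre[s])
    }
    expect_identical(ncol(m$params$head.W), cp$head_in)
  }
})

test_that("dense connectivity is concatenative: ablating a block changes later blocks", {
  cfg <- model_config(1, 2, blocks_per_stage = c(3), growth_rate = 4)
  m <- build_model(cfg, seed = 5)
  x <- array(rnorm(1 * 96), c(1, 96, 1))
  base <- model_forward(m, x, collect = TRUE)
  m2 <- m
  m2$params[["s1.b2.conv.W"]][] <- 0      # silence block 2's contribution
  m2$params[["s1.b2.conv.b"]][] <- 0
  abl <- model_forward(m2, x, collect = TRUE)
  # block 1 precedes the ablation and is untouched
  expect_identical(base$activations[["s1.b1"]], abl$activations[["s1.b1"]])
  # block 3 consumes the concatenation, so its appended channels change
  g <- cfg$growth_rate
  b3 <- dim(base$activations[["s1.b3"]])[1L]
  new3_base <- base$activations[["s1.b3"]][(b3 - g + 1):b3, , 1]
  new3_abl <- abl$activations[["s1.b3"]][(b3 - g + 1):b3, , 1]
  expect_false(isTRUE(all.equal(new3_base, new3_abl)))
})

test_that("dense-block activations respect causality through the entry downsampling", {
  cfg <- model_config(1, 2, blocks_per_stage = c(1, 2), growth_rate = 4)
  m <- build_model(cfg, seed = 3)
  T_len <- 256L
  tstar <- 128L
  set.seed(21)
  x1 <- array(rnorm(T_len), c(1, T_len, 1))
  x2 <- x1
  x2[1, (tstar + 1):T_len, 1] <- rnorm(T_len - tstar)
  a1 <- model_forward(m, x1, collect = TRUE)$activations
  a2 <- model_forward(m, x2, collect = TRUE)$activations
  for (nm in names(a1)) {
    stage <- as.integer(sub("^s(\\d)\\..*", "\\1", nm))
    T_ds <- dim(a1[[nm]])[2L]
    safe <- which(vapply(seq_len(T_ds), stage_input_reach, integer(1),
                         stage = stage, entry_kernel = cfg$entry_kernel) <= tstar)
    expect_gt(length(safe), 0L)
    expect_identical(a1[[nm]][, safe, , drop = FALSE],
                     a2[[nm]][, safe, , drop = FALSE])
  }
})
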