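#' Architectural configuration
#'
#' Hyper-parameter record for the densely connected dilated causal network.
#' The model is an entry block (same-padded conv, kernel `entry_kernel`,
#' stride 2, to `2 * growth_rate` channels, then max pool window 3 stride 2),
#' a sequence of processing stages of densely connected blocks, a transition
#' block after every stage (average pool window 2 stride 2, then a k = 1
#' channel-compressing conv), and a head (global average pool over time plus
#' a single affine layer). Each dense block appends `growth_rate` channels by
#' concatenation; its dilation follows `min(dilation_cap, 2^(i+2))` with `i`
#' the 0-based block index within the stage. There is no batch normalization
#' and no dropout anywhere.
#'
#' @param input_channels Positive integer, channels of the input sequence.
#' @param num_classes Positive integer; number of classes (multiclass head),
#'   labels (multilabel head) or 1 (binary head).
#' @param head One of `"multiclass-softmax"`, `"binary"`,
#'   `"multilabel-sigmoid"`. The model always emits raw scores; the
#'   softmax/sigmoid lives in the loss and in `predict(type = "prob")`.
#' @param blocks_per_stage Integer vector, dense blocks per stage
#'   (default `c(2, 6, 8, 4)`).
#' @param growth_rate Channels appended by each dense block (default 32).
#' @param bottleneck_mult Width of the in-block bottleneck conv as a
#'   multiple of `growth_rate` (default 4).
#' @param dilation_cap Maximum dilation, a power of two `>= 4` (default 128).
#' @param entry_kernel Kernel of the entry conv (default 7).
#' @param block_kernel Kernel of both in-block convs (default 3).
#' @param compression Transition compression factor in `(0, 1]`
#'   (default 0.5).
#' @return An object of class `ddx_config`.
#' @export
model_config <- function(input_channels, num_classes,
                         head = c("multiclass-softmax", "binary",
                                  "multilabel-sigmoid"),
                         blocks_per_stage = c(2L, 6L, 8L, 4L),
                         growth_rate = 32L, bottleneck_mult = 4L,
                         dilation_cap = 128L, entry_kernel = 7L,
                         block_kernel = 3L, compression = 0.5) {
  head <- match.arg(head)
  pint <- function(x, nm) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x))
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
    as.integer(x)
  }
  blocks_per_stage <- as.integer(blocks_per_stage)
  if (length(blocks_per_stage) == 0L || any(blocks_per_stage < 1L))
    stop("'blocks_per_stage' must be non-empty with all entries >= 1", call. = FALSE)
  dilation_cap <- pint(dilation_cap, "dilation_cap")
  if (dilation_cap < 4L || bitwAnd(dilation_cap, dilation_cap - 1L) != 0L)
    stop("'dilation_cap' must be a power of two >= 4", call. = FALSE)
  if (!is.numeric(compression) || length(compression) != 1L ||
      compression <= 0 || compression > 1)
    stop("'compression' must lie in (0, 1]", call. = FALSE)
  cfg <- list(
    input_channels = pint(input_channels, "input_channels"),
    num_classes = pint(num_classes, "num_classes"),
    head = head,
    blocks_per_stage = blocks_per_stage,
    growth_rate = pint(growth_rate, "growth_rate"),
    bottleneck_mult = pint(bottleneck_mult, "bottleneck_mult"),
    dilation_cap = dilation_cap,
    entry_kernel = pint(entry_kernel, "entry_kernel"),
    block_kernel = pint(block_kernel, "block_kernel"),
    compression = compression
  )
  structure(cfg, class = "ddx_config")
}

#' @export
print.ddx_config <- function(x, ...) {
  cat("ddx_config\n")
  cat(sprintf("  input channels: %d   classes: %d   head: %s\n",
              x$input_channels, x$num_classes, x$head))
  cat(sprintf("  stages: [%s] blocks, growth rate %d, dilation cap %d\n",
              paste(x$blocks_per_stage, collapse = ", "),
              x$growth_rate, x$dilation_cap))
  cat(sprintf("  entry k=%d, block k=%d, bottleneck %dx, compression %.2f\n",
              x$entry_kernel, x$block_kernel, x$bottleneck_mult, x$compression))
  invisible(x)
}

#' Per-stage dilation schedule
#'
#' Dilation of the i-th dense block of a stage (0-based index, resetting at
#' every stage): `min(cap, 2^(i+2))`, so the sequence runs 4, 8, 16, ... and
#' saturates at `cap`.
#'
#' @param num_blocks Positive integer, blocks in the stage.
#' @param cap Positive integer `>= 4`, the dilation ceiling.
#' @return Integer vector of length `num_blocks`.
#' @examples
#' dilation_schedule(8, 128)  # 4 8 16 32 64 128 128 128
#' @export
dilation_schedule <- function(num_blocks, cap = 128L) {
  if (length(num_blocks) != 1L || !is.numeric(num_blocks) || is.na(num_blocks) ||
      num_blocks < 1 || num_blocks != floor(num_blocks))
    stop("'num_blocks' must be a positive integer", call. = FALSE)
  if (length(cap) != 1L || !is.numeric(cap) || is.na(cap) || cap < 4)
    stop("'cap' must be a positive integer >= 4", call. = FALSE)
  as.integer(pmin(cap, 2^((0:(num_blocks - 1L)) + 2L)))
}

#' Resolve the channel bookkeeping of a configuration
#'
#' Walks the concatenative growth of the architecture without building any
#' parameters: the entry block emits `2 * growth_rate` channels; a stage
#' entered at `C` channels with `B` blocks leaves at `C + B * growth_rate`;
#' the following transition compresses to `floor(compression * width)`. The
#' head sees the post-transition width of the final stage.
#'
#' @param config A [model_config()].
#' @return An object of class `ddx_plan`: `entry_out`, vectors `stage_pre`
#'   and `stage_post` (pre-/post-transition widths per stage), `head_in`,
#'   per-stage `dilations` (list), and `layers`, the ordered list of
#'   [conv_spec()]s and pooling descriptors of the full network.
#' @examples
#' channel_plan(model_config(1, 2))$head_in  # 160 with the defaults
#' @export
channel_plan <- function(config) {
  if (!inherits(config, "ddx_config")) stop("'config' must be a ddx_config", call. = FALSE)
  g <- config$growth_rate
  entry_out <- 2L * g
  pools <- list(list(role = "entry_pool", kind = "max", window = 3L, stride = 2L))
  layers <- list(list(role = "entry",
                      spec = conv_spec(config$input_channels, entry_out,
                                       config$entry_kernel, dilation = 1L,
                                       stride = 2L, causal = FALSE)))
  C <- entry_out
  n_stages <- length(config$blocks_per_stage)
  stage_pre <- integer(n_stages)
  stage_post <- integer(n_stages)
  dilations <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    B <- config$blocks_per_stage[s]
    ds <- dilation_schedule(B, config$dilation_cap)
    dilations[[s]] <- ds
    for (b in seq_len(B)) {
      width <- config$bottleneck_mult * g
      layers[[length(layers) + 1L]] <- list(
        role = sprintf("s%d.b%d.bottleneck", s, b),
        spec = conv_spec(C, width, config$block_kernel, dilation = 1L,
                         stride = 1L, causal = TRUE))
      layers[[length(layers) + 1L]] <- list(
        role = sprintf("s%d.b%d.conv", s, b),
        spec = conv_spec(width, g, config$block_kernel, dilation = ds[b],
                         stride = 1L, causal = TRUE))
      C <- C + g
    }
    stage_pre[s] <- C
    C <- max(1L, as.integer(floor(config$compression * C)))
    stage_post[s] <- C
    pools[[length(pools) + 1L]] <- list(role = sprintf("s%d.pool", s),
                                        kind = "avg", window = 2L, stride = 2L)
    layers[[length(layers) + 1L]] <- list(
      role = sprintf("s%d.transition", s),
      spec = conv_spec(stage_pre[s], C, 1L, dilation = 1L, stride = 1L,
                       causal = FALSE))
  }
  structure(list(entry_out = entry_out, stage_pre = stage_pre,
                 stage_post = stage_post, head_in = C,
                 dilations = dilations, layers = layers, pools = pools),
            class = "ddx_plan")
}

#' @export
print.ddx_plan <- function(x, ...) {
  cat("ddx_plan\n")
  cat(sprintf("  entry out: %d\n", x$entry_out))
  for (s in seq_along(x$stage_pre))
    cat(sprintf("  stage %d: pre %d -> post %d, dilations [%s]\n",
                s, x$stage_pre[s], x$stage_post[s],
                paste(x$dilations[[s]], collapse = ", ")))
  cat(sprintf("  head in: %d\n", x$head_in))
  invisible(x)
}

he_init <- function(n_out, fan_in_elems) {
  lim <- sqrt(6 / fan_in_elems)
  matrix(stats::runif(n_out * fan_in_elems, -lim, lim), n_out, fan_in_elems)
}

#' Build a model from a configuration
#'
#' Instantiates all parameters of the network described by `config`.
#' Initialization is uniform He-style (limit `sqrt(6 / fan_in)`) drawn in a
#' fixed order from the seeded RNG, so identical seeds give bit-identical
#' parameter vectors; biases start at zero.
#'
#' @param config A [model_config()].
#' @param seed Integer RNG seed for initialization.
#' @return An object of class `ddx_model`: `config`, `plan`
#'   ([channel_plan()] output), `params` (named list of matrices/vectors),
#'   and `seed`. The minimum supported input length is reported by
#'   `min_input_length()`.
#' @export
build_model <- function(config, seed = 1L) {
  plan <- channel_plan(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  params <- list()
  for (ly in plan$layers) {
    sp <- ly$spec
    params[[paste0(ly$role, ".W")]] <-
      he_init(sp$out_channels, sp$in_channels * sp$kernel_size)
    params[[paste0(ly$role, ".b")]] <- numeric(sp$out_channels)
  }
  params[["head.W"]] <- he_init(config$num_classes, plan$head_in)
  params[["head.b"]] <- numeric(config$num_classes)
  structure(list(config = config, plan = plan, params = params,
                 seed = as.integer(seed)),
            class = "ddx_model")
}

#' @export
print.ddx_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d parameters, init seed %d, min input length %d\n",
              num_parameters(x), x$seed, min_input_length(x)))
  invisible(x)
}

#' Total number of parameters of a built model
#' @param model A [build_model()] result.
#' @return Integer count of scalar parameters.
#' @export
num_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Minimum input length a model supports
#'
#' Shortest time axis for which every pooling window still fits after the
#' cumulative downsampling of the entry block and transitions.
#'
#' @param model A [build_model()] result.
#' @return Integer minimal `T`.
#' @export
min_input_length <- function(model) {
  # invert the length recurrences: need >= 1 time-step after the last pool
  need <- 1L
  n_stages <- length(model$config$blocks_per_stage)
  for (s in rev(seq_len(n_stages)))
    need <- (need - 1L) * 2L + 2L          # avg pool w=2 s=2
  need <- (need - 1L) * 2L + 3L            # entry max pool w=3 s=2
  need <- (need - 1L) * 2L + 1L            # entry conv stride 2, same padding
  as.integer(need)
}

lookup_spec <- function(plan, role) {
  for (ly in plan$layers) if (ly$role == role) return(ly$spec)
  stop("internal: unknown layer role ", role)
}

conv_by_role <- function(model, x, role, need_cache) {
  sp <- lookup_spec(model$plan, role)
  conv1d_fwd(x, model$params[[paste0(role, ".W")]],
             model$params[[paste0(role, ".b")]],
             sp$kernel_size, sp$dilation, sp$stride, sp$causal,
             need_cache = need_cache)
}

#' Forward pass
#'
#' Runs a batch through the network and returns raw class scores. Inputs are
#' channel-major: a `[C, T]` matrix (one sample) or a `[C, T, N]` array.
#'
#' @param model A [build_model()] result.
#' @param x Numeric `[C, T]` matrix or `[C, T, N]` array with
#'   `C = config$input_channels`.
#' @param collect If `TRUE`, also return every dense-block activation (the
#'   concatenated stage tensors) for inspection.
#' @param need_cache Internal; retain backward-pass caches.
#' @return A list: `scores` (`[N, num_classes]` matrix), and if requested
#'   `activations` (named list of `[C, T', N]` arrays, one per dense block)
#'   and `caches`.
#' @export
model_forward <- function(model, x, collect = FALSE, need_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L)
    stop("'x' must be a [C, T] matrix or [C, T, N] array", call. = FALSE)
  if (dim(x)[1L] != model$config$input_channels)
    stop(sprintf("input has %d channels but the model expects %d",
                 dim(x)[1L], model$config$input_channels), call. = FALSE)
  if (dim(x)[2L] < min_input_length(model))
    stop(sprintf("input length %d is below the minimum supported length %d",
                 dim(x)[2L], min_input_length(model)), call. = FALSE)
  caches <- list()
  acts <- list()
  keep <- function(nm, cache) if (need_cache) caches[[nm]] <<- cache

  r <- conv_by_role(model, x, "entry", need_cache)
  keep("entry", r$cache)
  h <- relu_fwd(r$out)
  keep("entry.relu", h > 0)
  p <- maxpool_fwd(h, 3L, 2L, need_cache)
  keep("entry.pool", p$cache)
  h <- p$out

  n_stages <- length(model$config$blocks_per_stage)
  for (s in seq_len(n_stages)) {
    B <- model$config$blocks_per_stage[s]
    for (b in seq_len(B)) {
      role_bn <- sprintf("s%d.b%d.bottleneck", s, b)
      role_cv <- sprintf("s%d.b%d.conv", s, b)
      r1 <- conv_by_role(model, h, role_bn, need_cache)
      keep(role_bn, r1$cache)
      a1 <- relu_fwd(r1$out)
      keep(paste0(role_bn, ".relu"), a1 > 0)
      r2 <- conv_by_role(model, a1, role_cv, need_cache)
      keep(role_cv, r2$cache)
      a2 <- relu_fwd(r2$out)
      keep(paste0(role_cv, ".relu"), a2 > 0)
      dm <- dim(h)
      hb <- array(0, c(dm[1L] + dim(a2)[1L], dm[2L], dm[3L]))
      hb[seq_len(dm[1L]), , ] <- h
      hb[dm[1L] + seq_len(dim(a2)[1L]), , ] <- a2
      if (need_cache) caches[[sprintf("s%d.b%d.split", s, b)]] <- dm[1L]
      h <- hb
      if (collect) acts[[sprintf("s%d.b%d", s, b)]] <- h
    }
    p <- avgpool_fwd(h, 2L, 2L, need_cache)
    keep(sprintf("s%d.pool", s), p$cache)
    r <- conv_by_role(model, p$out, sprintf("s%d.transition", s), need_cache)
    keep(sprintf("s%d.transition", s), r$cache)
    h <- r$out
  }

  T_fin <- dim(h)[2L]
  pooled <- apply(h, c(1L, 3L), mean)      # [C, N] global average over time
  if (need_cache) caches[["gap.T"]] <- T_fin
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = dim(h)[1L])
  scores <- model$params[["head.W"]] %*% pooled + model$params[["head.b"]]
  if (need_cache) caches[["head.in"]] <- pooled
  out <- list(scores = t(scores))
  if (collect) out$activations <- acts
  if (need_cache) out$caches <- caches
  out
}

# Backward pass: dscores [N, K] -> named gradient list matching params.
model_backward <- function(model, caches, dscores) {
  grads <- list()
  dS <- t(dscores)                              # [K, N]
  pooled <- caches[["head.in"]]
  grads[["head.W"]] <- dS %*% t(pooled)
  grads[["head.b"]] <- rowSums(dS)
  dpooled <- crossprod(model$params[["head.W"]], dS)  # [C, N]
  T_fin <- caches[["gap.T"]]
  C_fin <- nrow(dpooled); N <- ncol(dpooled)
  dh <- array(rep(dpooled / T_fin, each = 1L), c(C_fin, 1L, N))
  dh <- array(dh[, rep(1L, T_fin), , drop = FALSE], c(C_fin, T_fin, N))

  n_stages <- length(model$config$blocks_per_stage)
  for (s in rev(seq_len(n_stages))) {
    r <- conv1d_bwd(dh, caches[[sprintf("s%d.transition", s)]])
    grads[[sprintf("s%d.transition.W", s)]] <- r$dW
    grads[[sprintf("s%d.transition.b", s)]] <- r$db
    dh <- avgpool_bwd(r$dx, caches[[sprintf("s%d.pool", s)]])
    B <- model$config$blocks_per_stage[s]
    for (b in rev(seq_len(B))) {
      role_bn <- sprintf("s%d.b%d.bottleneck", s, b)
      role_cv <- sprintf("s%d.b%d.conv", s, b)
      Cin <- caches[[sprintf("s%d.b%d.split", s, b)]]
      Ctot <- dim(dh)[1L]
      dprev <- dh[seq_len(Cin), , , drop = FALSE]
      da2 <- dh[(Cin + 1L):Ctot, , , drop = FALSE]
      da2[!caches[[paste0(role_cv, ".relu")]]] <- 0
      r2 <- conv1d_bwd(da2, caches[[role_cv]])
      grads[[paste0(role_cv, ".W")]] <- r2$dW
      grads[[paste0(role_cv, ".b")]] <- r2$db
      da1 <- r2$dx
      da1[!caches[[paste0(role_bn, ".relu")]]] <- 0
      r1 <- conv1d_bwd(da1, caches[[role_bn]])
      grads[[paste0(role_bn, ".W")]] <- r1$dW
      grads[[paste0(role_bn, ".b")]] <- r1$db
      dh <- dprev + r1$dx
    }
  }
  dh <- maxpool_bwd(dh, caches[["entry.pool"]])
  dh[!caches[["entry.relu"]]] <- 0
  r <- conv1d_bwd(dh, caches[["entry"]])
  grads[["entry.W"]] <- r$dW
  grads[["entry.b"]] <- r$db
  grads
}

#' Predict from a built or trained model
#'
#' @param object A `ddx_model`.
#' @param x `[C, T]` matrix or `[C, T, N]` array.
#' @param type `"score"` for raw scores, `"prob"` for softmax (multiclass
#'   head) or sigmoid (binary/multilabel heads) probabilities, `"class"` for
#'   hard labels (argmax, or 0/1 at probability 0.5).
#' @param ... Unused.
#' @return `[N, K]` matrix of scores or probabilities, or a label vector /
#'   0-1 matrix for `type = "class"`.
#' @export
predict.ddx_model <- function(object, x,
                              type = c("score", "prob", "class"), ...) {
  type <- match.arg(type)
  scores <- model_forward(object, x)$scores
  if (type == "score") return(scores)
  if (object$config$head == "multiclass-softmax") {
    pr <- softmax_rows(scores)
    if (type == "prob") return(pr)
    return(max.col(pr, ties.method = "first"))
  }
  pr <- 1 / (1 + exp(-scores))
  if (type == "prob") return(pr)
  cls <- (pr > 0.5) * 1L
  if (ncol(cls) == 1L) as.integer(cls[, 1L]) else cls
}

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}
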