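#' Convolution layer specification
#'
#' Describes a single 1-D convolution layer: channel widths, kernel size,
#' dilation, stride, and whether the layer is causal. Causal layers left-pad
#' the input by `(kernel_size - 1) * dilation` zeros so that, at stride 1,
#' the output has the same length as the input and the activation at time
#' `t` depends only on inputs at times `<= t`. Non-causal layers use
#' symmetric ("same") zero padding.
#'
#' @param in_channels,out_channels Positive integers, channel widths.
#' @param kernel_size Positive integer, number of taps `k`.
#' @param dilation Positive integer tap spacing `d`; taps of a causal kernel
#'   sit at offsets `-(k-1)d, ..., -d, 0` relative to the output time-step.
#' @param stride Positive integer temporal stride.
#' @param causal Logical; left-padded causal convolution if `TRUE`.
#' @return An object of class `conv_spec`.
#' @examples
#' conv_spec(1, 8, kernel_size = 3, dilation = 4)
#' @export
conv_spec <- function(in_channels, out_channels, kernel_size,
                      dilation = 1L, stride = 1L, causal = TRUE) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x))
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
    as.integer(x)
  }
  spec <- list(
    in_channels  = chk_count(in_channels, "in_channels"),
    out_channels = chk_count(out_channels, "out_channels"),
    kernel_size  = chk_count(kernel_size, "kernel_size"),
    dilation     = chk_count(dilation, "dilation"),
    stride       = chk_count(stride, "stride"),
    causal       = isTRUE(causal)
  )
  structure(spec, class = "conv_spec")
}

#' @export
print.conv_spec <- function(x, ...) {
  cat(sprintf("conv_spec: %d -> %d, k=%d, d=%d, stride=%d, %s\n",
              x$in_channels, x$out_channels, x$kernel_size, x$dilation,
              x$stride, if (x$causal) "causal" else "same-padded"))
  invisible(x)
}

# Internal padded im2col convolution over a batch array [C, T, N].
# Returns list(out [C_out, T', N], cache) where cache carries what the
# backward pass needs. `W` is the flattened kernel [C_out, C_in * k] with
# rows of the column matrix grouped tap-major: tap j occupies rows
# j*C_in + (1:C_in), tap j = k-1 being the current time-step for causal
# layers (offset -(k-1-j)*d).
conv1d_fwd <- function(x, W, b, k, d, stride, causal, need_cache = FALSE) {
  dm <- dim(x)
  C <- dm[1L]; T_in <- dm[2L]; N <- dm[3L]
  span <- (k - 1L) * d
  if (causal) {
    pl <- span; pr <- 0L
  } else {
    pl <- span %/% 2L; pr <- span - pl
  }
  Tp <- T_in + pl + pr
  T_out <- (Tp - span - 1L) %/% stride + 1L
  if (T_out < 1L)
    stop("input too short for this convolution", call. = FALSE)
  xp <- array(0, c(C, Tp, N))
  xp[, (pl + 1L):(pl + T_in), ] <- x
  starts <- (0:(T_out - 1L)) * stride + 1L
  cols <- array(0, c(C * k, T_out, N))
  for (j in 0:(k - 1L))
    cols[(j * C + 1L):((j + 1L) * C), , ] <- xp[, starts + j * d, , drop = FALSE]
  cm <- matrix(cols, nrow = C * k)
  out <- W %*% cm + b
  out <- array(out, c(nrow(W), T_out, N))
  cache <- NULL
  if (need_cache)
    cache <- list(cm = cm, W = W, C = C, T_in = T_in, N = N, k = k, d = d,
                  stride = stride, pl = pl, Tp = Tp, T_out = T_out,
                  starts = starts)
  list(out = out, cache = cache)
}

conv1d_bwd <- function(dout, cache) {
  C <- cache$C; k <- cache$k; N <- cache$N
  C_out <- dim(dout)[1L]
  dmat <- matrix(dout, nrow = C_out)
  dW <- dmat %*% t(cache$cm)
  db <- rowSums(dmat)
  dcols <- crossprod(cache$W, dmat)
  dcols <- array(dcols, c(C * k, cache$T_out, N))
  dxp <- array(0, c(C, cache$Tp, N))
  for (j in 0:(k - 1L)) {
    idx <- cache$starts + j * cache$d
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] +
      dcols[(j * C + 1L):((j + 1L) * C), , , drop = FALSE]
  }
  dx <- dxp[, (cache$pl + 1L):(cache$pl + cache$T_in), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# Max pooling, window w, stride s, no padding.
maxpool_fwd <- function(x, w, s, need_cache = FALSE) {
  dm <- dim(x); T_in <- dm[2L]
  if (T_in < w) stop("input too short for max pooling", call. = FALSE)
  T_out <- (T_in - w) %/% s + 1L
  starts <- (0:(T_out - 1L)) * s + 1L
  out <- x[, starts, , drop = FALSE]
  arg <- array(0L, dim(out))
  for (o in 1:(w - 1L)) {
    cand <- x[, starts + o, , drop = FALSE]
    gt <- cand > out
    out[gt] <- cand[gt]
    arg[gt] <- o
  }
  cache <- NULL
  if (need_cache)
    cache <- list(arg = arg, starts = starts, w = w, T_in = T_in, dm = dm)
  list(out = out, cache = cache)
}

maxpool_bwd <- function(dout, cache) {
  dx <- array(0, cache$dm)
  for (o in 0:(cache$w - 1L)) {
    mask <- cache$arg == o
    if (!any(mask)) next
    contrib <- dout
    contrib[!mask] <- 0
    idx <- cache$starts + o
    dx[, idx, ] <- dx[, idx, , drop = FALSE] + contrib
  }
  dx
}

# Average pooling, window w, stride s, no padding.
avgpool_fwd <- function(x, w, s, need_cache = FALSE) {
  dm <- dim(x); T_in <- dm[2L]
  if (T_in < w) stop("input too short for average pooling", call. = FALSE)
  T_out <- (T_in - w) %/% s + 1L
  starts <- (0:(T_out - 1L)) * s + 1L
  out <- x[, starts, , drop = FALSE]
  for (o in 1:(w - 1L)) out <- out + x[, starts + o, , drop = FALSE]
  out <- out / w
  cache <- NULL
  if (need_cache) cache <- list(starts = starts, w = w, dm = dm)
  list(out = out, cache = cache)
}

avgpool_bwd <- function(dout, cache) {
  dx <- array(0, cache$dm)
  g <- dout / cache$w
  for (o in 0:(cache$w - 1L)) {
    idx <- cache$starts + o
    dx[, idx, ] <- dx[, idx, , drop = FALSE] + g
  }
  dx
}

relu_fwd <- function(x) {
  out <- x
  out[out < 0] <- 0
  out
}

#' Causal (or same-padded) dilated 1-D convolution
#'
#' Applies a single dilated convolution to a multichannel sequence. With
#' `spec$causal = TRUE` and stride 1 the output has the same length as the
#' input and the value at time `t` is a function only of `x[, 1:t]`: the
#' input is left-padded by `(k - 1) * d` zeros and the kernel taps read
#' offsets `-(k-1)d, ..., -d, 0`. Non-causal layers use symmetric zero
#' padding, preserving length at stride 1.
#'
#' @param x Numeric matrix `[C_in, T]`, channel-major, time along columns.
#' @param spec A [conv_spec()].
#' @param weights Numeric array `[C_out, C_in, k]`; `weights[, , k]` is the
#'   tap applied to the current time-step of a causal layer, `weights[, , 1]`
#'   the oldest tap.
#' @param bias Numeric vector of length `C_out` (default all zero).
#' @return Numeric matrix `[C_out, T']`; `T' = T` when stride is 1.
#' @examples
#' x <- matrix(rnorm(32), 1, 32)
#' w <- array(c(0, 0, 1), c(1, 1, 3))   # identity at the current tap
#' all.equal(causal_conv1d(x, conv_spec(1, 1, 3), w), x, check.attributes = FALSE)
#' @export
causal_conv1d <- function(x, spec, weights, bias = NULL) {
  if (!inherits(spec, "conv_spec")) stop("'spec' must be a conv_spec", call. = FALSE)
  if (!is.matrix(x)) stop("'x' must be a [channels, time] matrix", call. = FALSE)
  if (nrow(x) != spec$in_channels)
    stop(sprintf("x has %d channels but spec expects %d", nrow(x), spec$in_channels),
         call. = FALSE)
  if (ncol(x) < 1L) stop("'x' must have at least one time-step", call. = FALSE)
  wd <- dim(weights)
  if (length(wd) != 3L || wd[1L] != spec$out_channels ||
      wd[2L] != spec$in_channels || wd[3L] != spec$kernel_size)
    stop("'weights' must be an array [out_channels, in_channels, kernel_size] matching spec",
         call. = FALSE)
  if (is.null(bias)) bias <- numeric(spec$out_channels)
  if (length(bias) != spec$out_channels)
    stop("'bias' must have length out_channels", call. = FALSE)
  W <- flatten_kernel(weights)
  xb <- array(x, c(dim(x), 1L))
  res <- conv1d_fwd(xb, W, bias, spec$kernel_size, spec$dilation,
                    spec$stride, spec$causal)
  matrix(res$out, dim(res$out)[1L], dim(res$out)[2L])
}

# [C_out, C_in, k] -> [C_out, C_in * k], tap-major columns matching conv1d_fwd.
flatten_kernel <- function(weights) {
  wd <- dim(weights)
  matrix(weights, wd[1L], wd[2L] * wd[3L])
}

#' Receptive field of a stack of convolution layers
#'
#' Number of input time-steps that can influence a single output time-step
#' of the stacked network: `1 + sum_i (k_i - 1) * d_i * prod_{j<i} s_j`.
#' Strides enlarge the input span of every later layer's tap spacing.
#'
#' @param layers A list of [conv_spec()] objects, input-first.
#' @return A positive integer.
#' @examples
#' receptive_field(list(conv_spec(1, 1, 3),
#'                      conv_spec(1, 1, 3, dilation = 2),
#'                      conv_spec(1, 1, 3, dilation = 4)))  # 15
#' @export
receptive_field <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("'layers' must be a non-empty list of conv_spec objects", call. = FALSE)
  rf <- 1
  jump <- 1
  for (sp in layers) {
    if (!inherits(sp, "conv_spec"))
      stop("every element of 'layers' must be a conv_spec", call. = FALSE)
    rf <- rf + (sp$kernel_size - 1L) * sp$dilation * jump
    jump <- jump * sp$stride
  }
  as.integer(rf)
}
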