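# Independent oracles and small fixtures used across the suite.

# Naive triple-loop dilated convolution, written directly from the
# definition; deliberately shares no code with the package implementation.
naive_conv1d <- function(x, spec, weights, bias = NULL) {
  k <- spec$kernel_size; d <- spec$dilation; s <- spec$stride
  C_in <- spec$in_channels; C_out <- spec$out_channels
  if (is.null(bias)) bias <- numeric(C_out)
  T_in <- ncol(x)
  span <- (k - 1L) * d
  if (spec$causal) { pl <- span; pr <- 0L } else { pl <- span %/% 2L; pr <- span - pl }
  xp <- cbind(matrix(0, C_in, pl), x, matrix(0, C_in, pr))
  T_out <- (ncol(xp) - span - 1L) %/% s + 1L
  out <- matrix(0, C_out, T_out)
  for (oc in seq_len(C_out)) {
    for (t in seq_len(T_out)) {
      acc <- bias[oc]
      for (ic in seq_len(C_in)) {
        for (j in 0:(k - 1L)) {
          acc <- acc + weights[oc, ic, j + 1L] * xp[ic, (t - 1L) * s + 1L + j * d]
        }
      }
      out[oc, t] <- acc
    }
  }
  out
}

# Brute-force AUROC: concordance probability over all positive-negative
# pairs, ties counted one half.
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Largest raw-input index that can influence a dense-block activation at
# (downsampled) index tau in stage `stage`: walks the lookahead of the
# entry block (same-padded stride-2 conv + window-3 max pool) and the
# average-pooling transitions; causal block convolutions add nothing.
stage_input_reach <- function(tau, stage, entry_kernel = 7L) {
  for (s in rev(seq_len(stage - 1L))) tau <- 2L * tau        # avg pool w2 s2
  tau <- 2L * tau + 1L                                       # entry max pool w3 s2
  pr <- ((entry_kernel - 1L) - (entry_kernel - 1L) %/% 2L)   # right pad of same conv
  2L * (tau - 1L) + 1L + pr                                  # entry conv stride 2
}

# Random small architectural configuration for property sweeps.
random_small_config <- function() {
  n_stages <- sample(1:3, 1)
  model_config(
    input_channels = sample(1:3, 1),
    num_classes = sample(2:4, 1),
    blocks_per_stage = sample(1:3, n_stages, replace = TRUE),
    growth_rate = sample(2:6, 1),
    bottleneck_mult = sample(2:4, 1),
    dilation_cap = sample(c(4L, 8L, 16L), 1),
    entry_kernel = sample(c(3L, 5L, 7L), 1),
    compression = sample(c(0.5, 0.75, 1.0), 1))
}

# Linearly separable two-class set: constant +1 vs -1 level plus small noise.
separable_dataset <- function(n = 64, t_len = 64, seed = 1) {
  set.seed(seed)
  y <- rep(1:2, length.out = n)
  x <- array(0, c(1, t_len, n))
  for (i in seq_len(n))
    x[1, , i] <- ifelse(y[i] == 1, 1, -1) + 0.05 * rnorm(t_len)
  list(x = x, y = y)
}
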