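#' Class table of the multi-scale synthetic task
#'
#' Each class is the sum of one short-period and one long-period sinusoid;
#' the table fixes the two periods (in samples) per class. Classes share
#' single scales pairwise (a 2 x 2 grid for 4 classes), so no single scale
#' separates all classes — both must be used. Every long/short ratio is at
#' least 8.
#'
#' @param n_classes Number of classes, at most 8.
#' @return Data.frame with columns `class`, `short_period`, `long_period`.
#' @export
multiscale_class_table <- function(n_classes = 4L) {
  if (n_classes < 1L || n_classes > 8L)
    stop("'n_classes' must be between 1 and 8", call. = FALSE)
  shorts <- c(8, 12, 8, 12, 6, 10, 6, 10)
  longs  <- c(96, 96, 128, 128, 96, 96, 128, 128)
  data.frame(class = seq_len(n_classes),
             short_period = shorts[seq_len(n_classes)],
             long_period = longs[seq_len(n_classes)])
}

#' Generate the multi-scale classification benchmark
#'
#' Balanced single-channel sequences; class `c` is
#' `sin(2 pi t / short_c + phi1) + sin(2 pi t / long_c + phi2)` with
#' per-sample uniform random phases plus i.i.d. Gaussian noise. Because the
#' class periods form a grid (see [multiscale_class_table()]), the classes
#' are distinguishable only by combining the short- and long-scale content —
#' the regime the adaptively dilated architecture targets. Byte-identical
#' re-generation for a fixed seed.
#'
#' @param n_samples Number of sequences.
#' @param n_classes Number of classes (at most 8, default 4).
#' @param sequence_length Time-steps per sequence (default 256); must be at
#'   least the longest class period.
#' @param noise_sigma Gaussian noise s.d. (default 0.3).
#' @param seed RNG seed.
#' @return An object of class `ddx_dataset`: `x` (`[1, T, N]` array), `y`
#'   (integer labels `1..K`, balanced), `class_table`, `modality`.
#' @export
gen_multiscale <- function(n_samples, n_classes = 4L, sequence_length = 256L,
                           noise_sigma = 0.3, seed = 1L) {
  tab <- multiscale_class_table(n_classes)
  if (n_samples < n_classes)
    stop("'n_samples' must be at least 'n_classes'", call. = FALSE)
  if (sequence_length < max(tab$long_period))
    stop(sprintf("'sequence_length' must be >= the longest class period (%d)",
                 max(tab$long_period)), call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  y <- rep(seq_len(n_classes), length.out = n_samples)
  tt <- 0:(sequence_length - 1L)
  x <- array(0, c(1L, sequence_length, n_samples))
  for (i in seq_len(n_samples)) {
    ph <- stats::runif(2L, 0, 2 * pi)
    x[1L, , i] <- sin(2 * pi * tt / tab$short_period[y[i]] + ph[1L]) +
      sin(2 * pi * tt / tab$long_period[y[i]] + ph[2L]) +
      noise_sigma * stats::rnorm(sequence_length)
  }
  structure(list(x = x, y = y, class_table = tab, modality = "multiscale"),
            class = "ddx_dataset")
}

#' @export
print.ddx_dataset <- function(x, ...) {
  dm <- dim(x$x)
  cat(sprintf("ddx_dataset (%s): %d samples, %d channel(s) x %d time-steps\n",
              x$modality, dm[3L], dm[1L], dm[2L]))
  invisible(x)
}

#' Generate ECG-like single-lead signals with planted R-peaks
#'
#' Each class has a base heart rate and a Gaussian-bump R-peak morphology
#' width; inter-beat intervals are jittered multiplicatively. The planted
#' peak sample indices are returned as annotations, so detector recall can
#' be measured exactly.
#'
#' @param n_samples Number of records.
#' @param n_classes Number of classes (at most 4, default 2).
#' @param rate Sampling rate in Hz (default 125).
#' @param duration_s Record length in seconds (default 10; at least 10).
#' @param noise_sigma Additive Gaussian noise s.d. (default 0.02).
#' @param jitter Relative s.d. of the inter-beat interval (default 0.05;
#'   0 gives strictly periodic beats).
#' @param seed RNG seed.
#' @return An object of class `ddx_ecg_set`: `signals` (list of numeric
#'   vectors), `peaks` (list of 1-based planted peak indices), `y` (labels),
#'   `rate`.
#' @export
gen_ecg_like <- function(n_samples, n_classes = 2L, rate = 125,
                         duration_s = 10, noise_sigma = 0.02,
                         jitter = 0.05, seed = 1L) {
  if (duration_s < 10) stop("'duration_s' must be at least 10 s", call. = FALSE)
  if (n_classes < 1L || n_classes > 4L)
    stop("'n_classes' must be between 1 and 4", call. = FALSE)
  bpm <- c(60, 90, 75, 110)[seq_len(n_classes)]
  width_s <- c(0.020, 0.030, 0.025, 0.035)[seq_len(n_classes)]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  n_t <- as.integer(round(duration_s * rate))
  tgrid <- (0:(n_t - 1L)) / rate
  y <- rep(seq_len(n_classes), length.out = n_samples)
  signals <- vector("list", n_samples)
  peaks <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    interval <- 60 / bpm[y[i]]
    t0 <- stats::runif(1L, 0.1, 0.9 * interval)
    times <- numeric(0)
    t_cur <- t0
    while (t_cur < duration_s) {
      times <- c(times, t_cur)
      gap <- interval * (1 + jitter * stats::rnorm(1L))
      t_cur <- t_cur + max(gap, 0.25)      # physiologic floor on the gap
    }
    sig <- noise_sigma * stats::rnorm(n_t)
    w <- width_s[y[i]]
    for (tp in times) sig <- sig + exp(-(tgrid - tp)^2 / (2 * w^2))
    signals[[i]] <- sig
    peaks[[i]] <- as.integer(round(times * rate)) + 1L
  }
  structure(list(signals = signals, peaks = peaks, y = y, rate = rate),
            class = "ddx_ecg_set")
}

#' Generate multi-label EHR episodes
#'
#' Labels are drawn independently at the stated prevalences; label `l`
#' shifts the mean of its own disjoint triplet of features (features
#' `3l-2 .. 3l`) by `effect_size` from a random onset inside the episode.
#' Observation times follow an independent Poisson process per feature, so
#' the episodes are irregularly sampled; [ehr_tensorize()] grids them to
#' the `[76, 256]` model input.
#'
#' @param n_samples Number of episodes.
#' @param n_labels Number of binary conditions (at most 25, default 25).
#' @param prevalence Scalar or length-`n_labels` vector of label
#'   probabilities (default 0.3).
#' @param effect_size Mean shift applied to affected features (default 1).
#' @param num_steps,bin_hours Grid the episodes are meant for; the horizon
#'   is `num_steps * bin_hours` hours (defaults 256 and 2).
#' @param obs_gap_hours Mean gap of the per-feature observation process
#'   (default 16 h).
#' @param seed RNG seed.
#' @return An object of class `ddx_ehr_set`: `episodes` (list of
#'   data.frames with columns timestamp/feature/value, timestamps in
#'   hours), `labels` (`[n_samples, n_labels]` 0/1 matrix), `catalog`.
#' @export
gen_ehr_multilabel <- function(n_samples, n_labels = 25L, prevalence = 0.3,
                               effect_size = 1.0, num_steps = 256L,
                               bin_hours = 2, obs_gap_hours = 16,
                               seed = 1L) {
  if (n_labels < 1L || n_labels > 25L)
    stop("'n_labels' must be between 1 and 25", call. = FALSE)
  prev <- rep_len(prevalence, n_labels)
  if (any(prev < 0 | prev > 1)) stop("'prevalence' must lie in [0, 1]", call. = FALSE)
  catalog <- ehr_feature_catalog(76L)
  horizon <- num_steps * bin_hours
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  labels <- matrix(0L, n_samples, n_labels)
  episodes <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    yl <- stats::rbinom(n_labels, 1L, prev)
    labels[i, ] <- yl
    onset <- stats::runif(n_labels, 0.25, 0.75) * horizon
    shift <- numeric(76L)
    rows <- vector("list", 76L)
    for (f in seq_len(76L)) {
      lab <- if (f <= 3L * n_labels) (f - 1L) %/% 3L + 1L else NA_integer_
      gaps <- stats::rexp(ceiling(horizon / obs_gap_hours * 3) + 5L,
                          rate = 1 / obs_gap_hours)
      ts <- cumsum(gaps)
      ts <- ts[ts < horizon]
      if (length(ts) == 0L) ts <- stats::runif(1L, 0, horizon)
      mu <- numeric(length(ts))
      if (!is.na(lab) && yl[lab] == 1L)
        mu[ts >= onset[lab]] <- effect_size
      rows[[f]] <- data.frame(timestamp = ts, feature = catalog[f],
                              value = mu + stats::rnorm(length(ts)),
                              stringsAsFactors = FALSE)
    }
    ep <- do.call(rbind, rows)
    episodes[[i]] <- ep[order(ep$timestamp), , drop = FALSE]
  }
  structure(list(episodes = episodes, labels = labels, catalog = catalog),
            class = "ddx_ehr_set")
}
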