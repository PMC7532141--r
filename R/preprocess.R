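#' Standard 22-pair TCP montage
#'
#' The transverse central parietal (TCP) bipolar derivation commonly used
#' for EEG abnormality screening, as electrode-name pairs in the 10-20
#' scheme. Shipped as an editable data frame so site-specific montages can
#' be substituted.
#'
#' @return A data.frame with character columns `anode` and `cathode`
#'   (22 rows).
#' @export
tcp_montage_pairs <- function() {
  data.frame(
    anode   = c("FP1", "F7", "T3", "T5", "FP2", "F8", "T4", "T6",
                "A1", "T3", "C3", "CZ", "C4", "T4",
                "FP1", "F3", "C3", "P3", "FP2", "F4", "C4", "P4"),
    cathode = c("F7", "T3", "T5", "O1", "F8", "T4", "T6", "O2",
                "T3", "C3", "CZ", "C4", "T4", "A2",
                "F3", "C3", "P3", "O1", "F4", "C4", "P4", "O2"),
    stringsAsFactors = FALSE)
}

#' Apply a bipolar TCP montage to a referential EEG recording
#'
#' Each montage channel is the difference between its anode and cathode
#' electrode traces: row p of the output is
#' `recording[anode_p, ] - recording[cathode_p, ]`.
#'
#' @param recording Numeric `[E, T]` matrix with electrode names as row
#'   names (10-20 scheme; case-insensitive match).
#' @param pairs Data.frame with columns `anode`, `cathode`
#'   (default [tcp_montage_pairs()]).
#' @return Numeric `[P, T]` matrix, one row per pair, row names
#'   `"ANODE-CATHODE"`.
#' @export
tcp_montage <- function(recording, pairs = tcp_montage_pairs()) {
  if (!is.matrix(recording) || is.null(rownames(recording)))
    stop("'recording' must be a matrix with electrode row names", call. = FALSE)
  electrodes <- toupper(rownames(recording))
  find <- function(nm) {
    i <- match(toupper(nm), electrodes)
    if (is.na(i)) stop(sprintf("electrode '%s' not present in the recording", nm),
                       call. = FALSE)
    i
  }
  ai <- vapply(pairs$anode, find, integer(1))
  ci <- vapply(pairs$cathode, find, integer(1))
  out <- recording[ai, , drop = FALSE] - recording[ci, , drop = FALSE]
  rownames(out) <- paste0(toupper(pairs$anode), "-", toupper(pairs$cathode))
  out
}

# triangular mel filter bank [n_mels, n_fft/2 + 1], HTK mel scale
mel_filterbank <- function(n_mels, n_fft, sr, fmin = 0, fmax = sr / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (0:(n_fft %/% 2L)) * sr / n_fft
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# orthonormal DCT-II matrix [n_out, n_in]
dct_matrix <- function(n_out, n_in) {
  mat <- outer(0:(n_out - 1L), 0:(n_in - 1L),
               function(u, m) cos(pi * (m + 0.5) * u / n_in))
  mat <- mat * sqrt(2 / n_in)
  mat[1L, ] <- mat[1L, ] / sqrt(2)
  mat
}

#' MFCC featurization of a montaged EEG snapshot
#'
#' Per channel: polyphase resampling to 100 Hz, centred short-time analysis
#' with a 2000-sample Hann window hopped by 100 samples (the signal is
#' zero-padded by half a window on both sides, so the frame count is
#' `1 + floor(T/hop)` at the resampled rate), 2000-point FFT power spectrum,
#' a 40-filter triangular mel bank over 0..Nyquist, log (floored at 1e-10),
#' and an orthonormal DCT-II retaining all 40 cepstral coefficients.
#' Channel-wise stacking yields `P * 40` feature rows; a 22-channel,
#' 5-minute, 250 Hz recording maps to a 880 x 301 tensor.
#'
#' @param montaged Numeric `[P, T]` matrix of montage channels.
#' @param source_rate Sampling rate of `montaged` in Hz (default 250).
#' @param target_rate Analysis rate in Hz (default 100).
#' @param n_fft FFT/window size in samples at `target_rate` (default 2000).
#' @param hop Hop between frames in samples (default 100).
#' @param n_mels Mel filters = retained cepstral coefficients (default 40).
#' @return Numeric `[P * n_mels, frames]` matrix; all values finite.
#' @export
eeg_mfcc_features <- function(montaged, source_rate = 250,
                              target_rate = 100, n_fft = 2000L,
                              hop = 100L, n_mels = 40L) {
  if (!is.matrix(montaged)) stop("'montaged' must be a [P, T] matrix", call. = FALSE)
  P <- nrow(montaged)
  t_len <- ceiling(ncol(montaged) * target_rate / source_rate)
  if (t_len < hop)
    stop("signal shorter than one analysis hop after resampling", call. = FALSE)
  n_frames <- 1L + t_len %/% hop
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n_fft - 1L)) / n_fft)   # periodic Hann
  fb <- mel_filterbank(n_mels, n_fft, target_rate)
  dct <- dct_matrix(n_mels, n_mels)
  half <- n_fft %/% 2L
  out <- matrix(0, P * n_mels, n_frames)
  for (p in seq_len(P)) {
    xr <- if (source_rate == target_rate) montaged[p, ] else
      as.numeric(signal::resample(montaged[p, ], target_rate, source_rate))
    xr <- xr[seq_len(min(length(xr), t_len))]
    xp <- c(numeric(half), xr, numeric(half + n_fft))  # generous right pad
    frames <- vapply(seq_len(n_frames), function(f) {
      s <- (f - 1L) * hop + 1L
      xp[s:(s + n_fft - 1L)] * win
    }, numeric(n_fft))
    spec <- stats::mvfft(frames)
    pow <- Mod(spec[1:(half + 1L), , drop = FALSE])^2
    mel_e <- log(pmax(fb %*% pow, 1e-10))
    out[((p - 1L) * n_mels + 1L):(p * n_mels), ] <- dct %*% mel_e
  }
  stopifnot(all(is.finite(out)))
  out
}

min_max_normalize <- function(x) {
  r <- range(x)
  if (r[2L] - r[1L] <= 0) return(NULL)
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Extract normalized heartbeat vectors from a single-lead ECG
#'
#' Implements the heartbeat-representation protocol: resample the lead to
#' 125 Hz; split into non-overlapping 10 s windows; min-max normalize each
#' window to `[0, 1]` (zero-dynamic-range windows are skipped with a
#' warning); detect R-peaks as local maxima at or above `threshold` with a
#' refractory gap; per window, compute the median R-R interval and cut a
#' beat from each peak spanning `1.2 x` the median R-R, zero-padded or
#' truncated to `beat_length` samples.
#'
#' @param lead Numeric vector, a single ECG lead.
#' @param source_rate Sampling rate of `lead` in Hz.
#' @param beat_length Output beat length in samples (default 187).
#' @param target_rate Analysis rate in Hz (default 125).
#' @param window_s Window length in seconds (default 10).
#' @param threshold R-peak threshold on the normalized amplitude
#'   (default 0.9).
#' @param refractory_s Minimum gap between accepted peaks in seconds
#'   (default 0.36).
#' @param smooth_samples Width (odd, in samples) of the moving-average
#'   smoother applied before peak picking (default 7, i.e. 56 ms at
#'   125 Hz — narrower than a QRS complex). Thresholding happens on the
#'   smoothed trace's own normalized range, which suppresses isolated
#'   noise extrema; each accepted peak is then refined to the local
#'   maximum of the unsmoothed window within half a smoother width.
#' @return An object of class `ddx_beats`: `beats` (list of numeric vectors
#'   of length `beat_length`, values in `[0, 1]`), `peaks` (absolute sample
#'   indices of accepted R-peaks in the resampled signal, 1-based),
#'   `n_windows`, `skipped` (count of flat windows).
#' @export
extract_beats <- function(lead, source_rate, beat_length = 187L,
                          target_rate = 125, window_s = 10,
                          threshold = 0.9, refractory_s = 0.36,
                          smooth_samples = 7L) {
  if (length(lead) < window_s * source_rate)
    stop(sprintf("'lead' must span at least %g s at %g Hz", window_s, source_rate),
         call. = FALSE)
  x <- if (source_rate == target_rate) as.numeric(lead) else
    as.numeric(signal::resample(lead, target_rate, source_rate))
  wlen <- as.integer(round(window_s * target_rate))
  refr <- as.integer(round(refractory_s * target_rate))
  n_win <- length(x) %/% wlen
  beats <- list()
  peaks <- integer(0)
  skipped <- 0L
  for (w in seq_len(n_win)) {
    seg <- x[((w - 1L) * wlen + 1L):(w * wlen)]
    segn <- min_max_normalize(seg)
    if (is.null(segn)) {
      warning(sprintf("window %d has zero dynamic range; skipped", w), call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    # smooth, re-normalize, pick local maxima at/above threshold with a
    # greedy refractory sweep, then refine peaks on the unsmoothed trace
    n <- length(segn)
    half <- smooth_samples %/% 2L
    sm <- as.numeric(stats::filter(segn, rep(1 / smooth_samples, smooth_samples),
                                   sides = 2))
    sm[is.na(sm)] <- 0
    smn <- min_max_normalize(sm)
    if (is.null(smn)) { skipped <- skipped + 1L; next }
    cand <- which(smn >= threshold)
    cand <- cand[cand > 1L & cand < n]
    cand <- cand[smn[cand] >= smn[cand - 1L] & smn[cand] > smn[cand + 1L]]
    kept <- integer(0)
    last <- -refr
    for (i in cand) {
      if (i - last >= refr) {
        lo <- max(1L, i - half)
        kept <- c(kept, lo + which.max(segn[lo:min(n, i + half)]) - 1L)
        last <- i
      }
    }
    if (length(kept) < 2L) next                 # no R-R interval defined
    med_rr <- stats::median(diff(kept))
    span <- as.integer(round(1.2 * med_rr))
    for (i in kept) {
      stop_at <- min(i + span - 1L, n)
      beat <- segn[i:stop_at]
      if (length(beat) >= beat_length) beat <- beat[seq_len(beat_length)]
      else beat <- c(beat, numeric(beat_length - length(beat)))
      beats[[length(beats) + 1L]] <- beat
      peaks <- c(peaks, (w - 1L) * wlen + i)
    }
  }
  structure(list(beats = beats, peaks = peaks, n_windows = n_win,
                 skipped = skipped),
            class = "ddx_beats")
}

#' @export
print.ddx_beats <- function(x, ...) {
  cat(sprintf("ddx_beats: %d beats from %d window(s) (%d skipped)\n",
              length(x$beats), x$n_windows, x$skipped))
  invisible(x)
}

#' Default EHR feature catalog
#'
#' Ordered list of the 76 per-time-step measurement channels of the ICU
#' episode representation. Generic names are used; any 76-name character
#' vector (e.g. real chart-event names) can be passed to [ehr_tensorize()]
#' instead.
#'
#' @param n Number of features (default 76).
#' @return Character vector of length `n`.
#' @export
ehr_feature_catalog <- function(n = 76L) sprintf("feature_%02d", seq_len(n))

forward_fill <- function(v, default = 0) {
  ok <- !is.na(v)
  if (!any(ok)) return(rep(default, length(v)))
  idx <- cummax(ifelse(ok, seq_along(v), 0L))
  out <- ifelse(idx == 0L, default, v[pmax(idx, 1L)])
  out
}

#' Grid an irregular EHR episode onto a fixed measurement tensor
#'
#' Buckets timestamped (feature, value) observations onto a uniform grid of
#' `num_steps` bins of `bin_hours` each, anchored at the episode's first
#' timestamp. Within a bin the last observation wins; gaps are
#' forward-filled from the most recent observation; leading gaps take the
#' per-feature default (0, i.e. the standardized mean). Observations beyond
#' the grid horizon are ignored.
#'
#' @param episode Data.frame with columns `timestamp` (numeric hours, or
#'   POSIXct / ISO-8601 strings), `feature` (names from the catalog), and
#'   `value` (numeric).
#' @param feature_catalog Ordered character vector of feature names
#'   (default [ehr_feature_catalog()], 76 names).
#' @param num_steps Grid length (default 256).
#' @param bin_hours Bin width in hours (default 2).
#' @param default Leading-gap fill value (default 0).
#' @return Numeric `[length(feature_catalog), num_steps]` matrix with the
#'   catalog as row names.
#' @export
ehr_tensorize <- function(episode, feature_catalog = ehr_feature_catalog(),
                          num_steps = 256L, bin_hours = 2, default = 0) {
  if (!is.data.frame(episode) || nrow(episode) == 0L)
    stop("'episode' must be a non-empty data.frame", call. = FALSE)
  req <- c("timestamp", "feature", "value")
  if (!all(req %in% names(episode)))
    stop("'episode' needs columns timestamp, feature, value", call. = FALSE)
  ts <- episode$timestamp
  if (inherits(ts, "POSIXt")) {
    ts <- as.numeric(difftime(ts, min(ts), units = "hours"))
  } else if (is.character(ts)) {
    tp <- as.POSIXct(ts, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                    "%Y-%m-%d %H:%M:%S"))
    if (any(is.na(tp))) stop("unparseable ISO-8601 timestamp", call. = FALSE)
    ts <- as.numeric(difftime(tp, min(tp), units = "hours"))
  } else {
    ts <- as.numeric(ts)
  }
  fi <- match(episode$feature, feature_catalog)
  if (any(is.na(fi)))
    stop(sprintf("unknown feature name(s): %s",
                 paste(unique(episode$feature[is.na(fi)]), collapse = ", ")),
         call. = FALSE)
  bins <- floor((ts - min(ts)) / bin_hours) + 1L
  keep <- bins >= 1L & bins <= num_steps
  ord <- order(ts[keep])
  fi <- fi[keep][ord]; bins <- bins[keep][ord]
  vals <- as.numeric(episode$value)[keep][ord]
  mat <- matrix(NA_real_, length(feature_catalog), num_steps)
  mat[cbind(fi, bins)] <- vals            # increasing time: last wins
  out <- t(apply(mat, 1L, forward_fill, default = default))
  rownames(out) <- feature_catalog
  out
}
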