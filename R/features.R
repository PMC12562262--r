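#' Feature extraction configuration
#'
#' Parameters of the MFCC image front end. A heart-sound recording is cut
#' into non-overlapping 1024-sample windows, each window is turned into 64
#' MFCCs (mel filter bank + log + orthonormal DCT-II), and the coefficient
#' track plus its delta and double-delta form a 64 x 64 x 3 "image" that the
#' two transformer branches consume.
#'
#' @param window_length Analysis window in samples (default 1024).
#' @param hop_length Hop between windows in samples; equal to
#'   `window_length` by default, i.e. non-overlapping frames.
#' @param n_mels Number of triangular mel filters (default 64).
#' @param n_coeffs Number of DCT coefficients kept (default 64; must be
#'   `<= n_mels`).
#' @param target_frames Number of frames in the fitted image (default 64).
#' @param delta_width Half-width of the delta regression window in frames
#'   (default 2, i.e. a 5-frame regression).
#' @param log_floor Constant added to mel energies before the log
#'   (default 1e-10).
#' @param fmin,fmax Mel filter bank frequency range in Hz. `fmax = NULL`
#'   means the Nyquist frequency of the recording.
#' @param window_fun Analysis window shape: `"hann"`, `"hamming"` or
#'   `"rect"`.
#' @param rate Expected sample rate in Hz (default 2000).
#' @return A list of class `pcg_feature_config`.
#' @export
feature_config <- function(window_length = 1024L, hop_length = window_length,
                           n_mels = 64L, n_coeffs = 64L, target_frames = 64L,
                           delta_width = 2L, log_floor = 1e-10,
                           fmin = 0, fmax = NULL,
                           window_fun = c("hann", "hamming", "rect"),
                           rate = 2000) {
  window_fun <- match.arg(window_fun)
  if (n_coeffs > n_mels) {
    stop("n_coeffs must be <= n_mels", call. = FALSE)
  }
  if (window_length <= 0 || hop_length <= 0) {
    stop("window_length and hop_length must be positive", call. = FALSE)
  }
  if (!is.null(fmax) && fmax > rate / 2) {
    stop("fmax must not exceed the Nyquist frequency rate/2", call. = FALSE)
  }
  structure(
    list(window_length = as.integer(window_length),
         hop_length = as.integer(hop_length),
         n_mels = as.integer(n_mels), n_coeffs = as.integer(n_coeffs),
         target_frames = as.integer(target_frames),
         delta_width = as.integer(delta_width), log_floor = log_floor,
         fmin = fmin, fmax = if (is.null(fmax)) rate / 2 else fmax,
         window_fun = window_fun, rate = rate),
    class = "pcg_feature_config"
  )
}

#' Cut a signal into frames
#'
#' Frame `i` (1-based) holds samples `[(i-1)*hop + 1, (i-1)*hop + window]`;
#' a trailing partial window is discarded. With the default non-overlapping
#' hop the frame count is `floor(length(samples) / hop)`.
#'
#' @param samples Amplitude vector.
#' @param cfg A [feature_config()].
#' @return A `frames x window_length` matrix (possibly 0 rows).
#' @export
frame_signal <- function(samples, cfg = feature_config()) {
  if (length(samples) == 0) stop("empty signal", call. = FALSE)
  w <- cfg$window_length
  h <- cfg$hop_length
  n_frames <- if (length(samples) < w) 0L else (length(samples) - w) %/% h + 1L
  if (n_frames == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = w))
  }
  idx <- outer(seq_len(w), (seq_len(n_frames) - 1L) * h, `+`)
  t(matrix(samples[idx], nrow = w))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filter bank matrix
#'
#' Triangular filters with centres equally spaced on the mel scale between
#' `fmin` and `fmax`, evaluated on the non-negative FFT bin frequencies.
#'
#' @param n_fft FFT size (the window length).
#' @param rate Sample rate in Hz.
#' @param n_mels Number of filters.
#' @param fmin,fmax Frequency range in Hz.
#' @return An `n_mels x (n_fft/2 + 1)` matrix of filter weights.
#' @export
mel_filterbank <- function(n_fft, rate, n_mels, fmin = 0, fmax = rate / 2) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * rate / n_fft
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Orthonormal DCT-II matrix
#'
#' Returns the `n x n` type-II discrete cosine transform with orthonormal
#' scaling, so the matrix is orthogonal (its transpose is its inverse).
#'
#' @param n Transform size.
#' @return An `n x n` matrix `M` such that `coeffs = M %*% x`.
#' @export
dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  m <- outer(k, k + 0.5, function(i, j) cos(pi * i * j / n))
  m <- m * sqrt(2 / n)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

mel_energies <- function(frames, rate, cfg) {
  w <- cfg$window_length
  win <- switch(cfg$window_fun,
    hann    = 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1L) / (w - 1L)),
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(w) - 1L) / (w - 1L)),
    rect    = rep(1, w)
  )
  fb <- mel_filterbank(w, rate, cfg$n_mels, cfg$fmin, cfg$fmax)
  # |FFT|^2 of each windowed frame, non-negative frequencies only
  spec <- stats::mvfft(t(frames * rep(win, each = nrow(frames))))
  power <- Mod(spec[seq_len(w %/% 2L + 1L), , drop = FALSE])^2
  t(fb %*% power)           # frames x n_mels
}

#' MFCCs of framed audio
#'
#' Per frame: power spectrum (FFT size = window length) -> mel filter bank
#' energies -> `log(energy + log_floor)` -> orthonormal DCT-II -> first
#' `n_coeffs` coefficients. Coefficient 0 (the energy-like term) is kept.
#'
#' @param frames A `frames x window_length` matrix from [frame_signal()].
#' @param rate Sample rate in Hz; must match `cfg$rate`.
#' @param cfg A [feature_config()].
#' @return A `frames x n_coeffs` matrix.
#' @export
mfcc_frames <- function(frames, rate, cfg = feature_config()) {
  if (!is.matrix(frames) || ncol(frames) != cfg$window_length) {
    stop("frames must have window_length columns", call. = FALSE)
  }
  if (rate != cfg$rate) {
    stop("sample rate ", rate, " does not match the filter-bank design rate ",
         cfg$rate, call. = FALSE)
  }
  if (nrow(frames) == 0L) return(matrix(numeric(0), 0, cfg$n_coeffs))
  loge <- log(mel_energies(frames, rate, cfg) + cfg$log_floor)
  dct <- dct_matrix(cfg$n_mels)[seq_len(cfg$n_coeffs), , drop = FALSE]
  loge %*% t(dct)
}

#' Delta (regression slope) of a coefficient track
#'
#' The standard regression delta over a window of `2*width + 1` frames:
#' `d_t = sum_n n * (c_{t+n} - c_{t-n}) / (2 * sum_n n^2)`, `n = 1..width`,
#' with edge frames replicated. A single-frame input yields zeros.
#'
#' @param coeffs A `frames x n_coeffs` matrix.
#' @param width Regression half-width in frames (>= 1).
#' @return A matrix of the same shape.
#' @export
delta <- function(coeffs, width = 2L) {
  stopifnot(is.matrix(coeffs), width >= 1)
  n <- nrow(coeffs)
  if (n == 0L) return(coeffs)
  denom <- 2 * sum((seq_len(width))^2)
  out <- matrix(0, n, ncol(coeffs))
  idx <- function(i) pmin(pmax(i, 1L), n)   # edge replication
  for (k in seq_len(width)) {
    out <- out + k * (coeffs[idx(seq_len(n) + k), , drop = FALSE] -
                      coeffs[idx(seq_len(n) - k), , drop = FALSE])
  }
  out / denom
}

#' Build the 64 x 64 x 3 feature image of one recording
#'
#' The MFCC track is fitted to exactly `target_frames` frames (short
#' recordings are zero-padded at the tail of the coefficient matrix, long
#' ones truncated to the first `target_frames` frames), the delta and
#' double-delta channels are computed from the fitted track, and the three
#' channels are stacked as `frames x coefficients x 3`.
#'
#' @param samples Amplitude vector of one recording.
#' @param rate Sample rate in Hz.
#' @param cfg A [feature_config()].
#' @return A numeric array `target_frames x n_coeffs x 3` with channels
#'   (MFCC, delta, double-delta).
#' @export
make_feature_image <- function(samples, rate, cfg = feature_config()) {
  if (any(!is.finite(samples))) {
    stop("signal contains non-finite samples", call. = FALSE)
  }
  frames <- frame_signal(samples, cfg)
  co <- mfcc_frames(frames, rate, cfg)
  tf <- cfg$target_frames
  if (nrow(co) < tf) {
    co <- rbind(co, matrix(0, tf - nrow(co), ncol(co)))
  } else if (nrow(co) > tf) {
    co <- co[seq_len(tf), , drop = FALSE]
  }
  d1 <- delta(co, cfg$delta_width)
  d2 <- delta(d1, cfg$delta_width)
  img <- array(0, dim = c(tf, cfg$n_coeffs, 3L))
  img[, , 1] <- co
  img[, , 2] <- d1
  img[, , 3] <- d2
  img
}

#' Feature images for a whole manifest
#'
#' Maps [make_feature_image()] over a dataset manifest, reading WAV files
#' (resampled to `cfg$rate` if needed) or using an in-memory `samples`
#' list-column when present. Images can be cached as RDS files keyed by
#' `record_id`.
#'
#' @param manifest A tibble with columns `record_id` and either `samples`
#'   (+ `rate`) or `path`.
#' @param cfg A [feature_config()].
#' @param cache_dir Optional directory for an RDS image cache
#'   (`<cache_dir>/<record_id>.rds`).
#' @return The manifest with a list-column `image` added.
#' @export
extract_features <- function(manifest, cfg = feature_config(),
                             cache_dir = NULL) {
  stopifnot(is.data.frame(manifest), "record_id" %in% names(manifest))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  get_samples <- function(row) {
    if (!is.null(row$samples[[1]])) {
      list(samples = row$samples[[1]], rate = row$rate[[1]])
    } else {
      read_wav(row$path, target_rate = cfg$rate)
    }
  }
  imgs <- purrr::map(seq_len(nrow(manifest)), function(i) {
    rid <- manifest$record_id[i]
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, paste0(rid, ".rds"))
      if (file.exists(f)) return(readRDS(f))
    }
    row <- manifest[i, ]
    if (!"samples" %in% names(row)) row$samples <- list(NULL)
    x <- get_samples(row)
    img <- make_feature_image(x$samples, x$rate, cfg)
    if (!is.null(cache_dir)) {
      saveRDS(img, file.path(cache_dir, paste0(rid, ".rds")))
    }
    img
  })
  out <- tibble::as_tibble(manifest)
  out$image <- imgs
  out
}

#' Per-channel standardization statistics
#'
#' Mean and standard deviation of each of the three channels, pooled over a
#' set of feature images (normally the training split only, so no test
#' information leaks into the normalization).
#'
#' @param images List of `frames x coeffs x 3` arrays.
#' @return A list with numeric vectors `mean` and `sd` of length 3.
#' @export
channel_stats <- function(images) {
  stopifnot(length(images) > 0)
  ch <- lapply(1:3, function(c) unlist(lapply(images, function(im) im[, , c])))
  list(mean = vapply(ch, mean, numeric(1)),
       sd = vapply(ch, function(x) max(stats::sd(x), 1e-8), numeric(1)))
}

#' Apply per-channel standardization
#'
#' @param image A `frames x coeffs x 3` array.
#' @param stats A list from [channel_stats()].
#' @return The standardized array.
#' @export
standardize_image <- function(image, stats) {
  for (c in 1:3) image[, , c] <- (image[, , c] - stats$mean[c]) / stats$sd[c]
  image
}
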