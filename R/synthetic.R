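#' Synthetic phonocardiogram dataset configuration
#'
#' Controls the generator used for end-to-end testing without real
#' recordings. Signals mimic the gross structure of a phonocardiogram: a
#' periodic S1/S2 double transient at a subject-specific heart rate (damped
#' sinusoids near 30-80 Hz for S1 and 80-150 Hz for S2), pink background
#' noise, and - for the positive classes - band-limited "murmur" noise
#' injected during systole. `murmur_snr_db` is the separability knob: the
#' murmur power relative to the background noise power.
#'
#' @param n_subjects Number of subjects.
#' @param records_per_subject Recordings per subject (default 2).
#' @param rate Sample rate in Hz (fixed at 2000 for this corpus style).
#' @param duration_range Recording durations in seconds, uniform per record
#'   (default 5-35 s; must stay within 5-120 s).
#' @param heart_rate_range Subject heart rate in beats/min (default 55-95).
#' @param murmur_band Murmur noise band in Hz (default 150-400).
#' @param murmur_snr_db Murmur-to-background power ratio in dB for the
#'   "abnormal"/"present" class (default +10).
#' @param class_mode `"binary"` (normal/abnormal) or `"three_class"`
#'   (present/absent/unknown).
#' @param unknown_fraction Fraction of subjects labeled "unknown" in
#'   three-class mode (default 0.2); unknowns get a low-SNR ambiguous
#'   murmur.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of class `pcg_synth_config`.
#' @export
synth_config <- function(n_subjects = 40L, records_per_subject = 2L,
                         rate = 2000, duration_range = c(5, 35),
                         heart_rate_range = c(55, 95),
                         murmur_band = c(150, 400), murmur_snr_db = 10,
                         class_mode = c("binary", "three_class"),
                         unknown_fraction = 0.2, seed = 1L) {
  class_mode <- match.arg(class_mode)
  if (duration_range[1] < 5 || duration_range[2] > 120) {
    stop("duration_range must lie within [5, 120] seconds", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         records_per_subject = as.integer(records_per_subject),
         rate = rate, duration_range = duration_range,
         heart_rate_range = heart_rate_range, murmur_band = murmur_band,
         murmur_snr_db = murmur_snr_db, class_mode = class_mode,
         unknown_fraction = unknown_fraction, seed = as.integer(seed)),
    class = "pcg_synth_config"
  )
}

# 1/f ("pink") noise via spectral shaping of white noise; the FFT length is
# rounded up to a highly composite size and the result truncated, keeping the
# transform fast for arbitrary durations
pink_noise <- function(n) {
  nf <- stats::nextn(n, 2)
  white <- stats::rnorm(nf)
  spec <- stats::fft(white)
  f <- c(1, seq_len(nf - 1))                      # avoid div by zero at DC
  shaped <- spec / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE))[seq_len(n)] / nf
  x / stats::sd(x)
}

# band-pass noise (frequency-domain brick wall; adequate for synthesis)
band_noise <- function(n, rate, band) {
  nf <- stats::nextn(n, 2)
  white <- stats::rnorm(nf)
  spec <- stats::fft(white)
  freqs <- (seq_len(nf) - 1) * rate / nf
  freqs <- pmin(freqs, rate - freqs)              # fold to [0, rate/2]
  keep <- freqs >= band[1] & freqs <= band[2]
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / nf
  x / max(stats::sd(x), 1e-12)
}

# one damped-sinusoid heart sound transient
transient <- function(rate, freq, dur = 0.08, decay = 30) {
  t <- seq(0, dur, by = 1 / rate)
  sin(2 * pi * freq * t) * exp(-decay * t)
}

#' Generate one synthetic heart-sound recording
#'
#' Deterministic given `seed`. The subject profile fixes heart rate, S1/S2
#' frequencies and amplitude; systole occupies a fixed 0.35 fraction of each
#' cardiac cycle, and murmur noise (when the label calls for it) is confined
#' to the systolic intervals.
#'
#' @param profile A list with `heart_rate` (bpm), `s1_freq`, `s2_freq` (Hz),
#'   `amplitude`.
#' @param label Class label string.
#' @param cfg A [synth_config()].
#' @param seed Integer seed for this recording.
#' @return A list with `samples` and `rate`.
#' @export
generate_recording <- function(profile, label, cfg = synth_config(), seed = 1L) {
  set.seed(seed)
  rate <- cfg$rate
  dur <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
  n <- round(dur * rate)
  x <- 0.05 * pink_noise(n)

  cycle <- 60 / profile$heart_rate             # seconds per beat
  systole <- 0.35 * cycle
  s1 <- transient(rate, profile$s1_freq)
  s2 <- transient(rate, profile$s2_freq)
  beat_starts <- seq(0, dur, by = cycle)
  sys_mask <- rep(FALSE, n)
  for (b in beat_starts) {
    i1 <- round(b * rate) + 1L
    i2 <- round((b + systole) * rate) + 1L
    add_at <- function(sig, pos, amp) {
      j <- pos + seq_along(sig) - 1L
      ok <- j <= n
      sig_ok <- sig[ok]
      if (length(sig_ok)) x[j[ok]] <<- x[j[ok]] + amp * sig_ok
    }
    if (i1 <= n) add_at(s1, i1, profile$amplitude)
    if (i2 <= n) add_at(s2, i2, 0.8 * profile$amplitude)
    sys_mask[i1:min(i2, n)] <- TRUE
  }

  murmur_snr <- switch(label,
    abnormal = , present = cfg$murmur_snr_db,
    unknown = cfg$murmur_snr_db - 12,          # ambiguous low-SNR murmur
    NA_real_                                   # normal / absent: none
  )
  if (!is.na(murmur_snr)) {
    noise_power <- 0.05^2         # background pink noise is sd-normalized
    amp <- sqrt(noise_power * 10^(murmur_snr / 10))
    m <- band_noise(n, rate, cfg$murmur_band) * amp
    x[sys_mask] <- x[sys_mask] + m[sys_mask]
  }
  list(samples = x, rate = rate)
}

#' Generate a labeled synthetic phonocardiogram dataset
#'
#' Subjects are assigned a class and a physiological profile; each subject
#' contributes several recordings so subject-wise splitting is exercised.
#'
#' @param cfg A [synth_config()].
#' @return A tibble manifest with columns `record_id`, `subject_id`,
#'   `label`, `rate` and a list-column `samples`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  classes <- if (cfg$class_mode == "binary") {
    c("normal", "abnormal")
  } else {
    c("present", "absent", "unknown")
  }
  n_unknown <- if (cfg$class_mode == "three_class") {
    round(cfg$unknown_fraction * cfg$n_subjects)
  } else 0L
  n_rest <- cfg$n_subjects - n_unknown
  if (n_rest < 2L * (length(classes) - (n_unknown > 0))) {
    stop("too few subjects for at least 2 per class", call. = FALSE)
  }
  set.seed(cfg$seed)
  main <- setdiff(classes, "unknown")
  subj_labels <- c(rep(main, length.out = n_rest),
                   rep("unknown", n_unknown))
  subj_labels <- sample(subj_labels)
  profiles <- lapply(seq_len(cfg$n_subjects), function(i) {
    list(heart_rate = stats::runif(1, cfg$heart_rate_range[1],
                                   cfg$heart_rate_range[2]),
         s1_freq = stats::runif(1, 30, 80),
         s2_freq = stats::runif(1, 80, 150),
         amplitude = stats::runif(1, 0.7, 1.3))
  })
  seeds <- sample.int(.Machine$integer.max %/% 2L,
                      cfg$n_subjects * cfg$records_per_subject)

  rows <- list()
  k <- 0L
  for (i in seq_len(cfg$n_subjects)) {
    for (r in seq_len(cfg$records_per_subject)) {
      k <- k + 1L
      rec <- generate_recording(profiles[[i]], subj_labels[i], cfg,
                                seed = seeds[k])
      rows[[k]] <- tibble::tibble(
        record_id = sprintf("s%03d_r%02d", i, r),
        subject_id = sprintf("s%03d", i),
        label = subj_labels[i],
        rate = rec$rate,
        samples = list(rec$samples)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic dataset to WAV files plus a manifest CSV
#'
#' The manifest schema (`record_id, subject_id, path, label`) matches the
#' one [load_manifest()] reads, so synthetic and real corpora flow through
#' the same pipeline.
#'
#' @param dataset A manifest tibble from [generate_dataset()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    paths[i] <- file.path(dir, paste0(dataset$record_id[i], ".wav"))
    write_wav(dataset$samples[[i]], dataset$rate[i], paths[i])
  }
  man <- dplyr::tibble(record_id = dataset$record_id,
                       subject_id = dataset$subject_id,
                       path = paths, label = dataset$label)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}
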