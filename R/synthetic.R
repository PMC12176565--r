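#' Synthetic phonocardiogram generator configuration
#'
#' Defines the conditions for the seeded synthetic heart-sound simulator.
#' Each cardiac cycle places a Gaussian-enveloped S1 tone burst at cycle
#' start and an S2 burst at 55% of the cycle (systole shorter than diastole).
#' Abnormal recordings add band-limited "murmur" noise shaped by a half-sine
#' envelope across each systolic S1-to-S2 interval. A white noise floor is
#' added to every recording.
#'
#' @param n_normal,n_abnormal number of recordings per class
#' @param seed integer seed; recording `i` uses sub-seed `seed + i`, so a
#'   dataset can be extended without changing earlier recordings
#' @param sampling_rate sampling rate in Hz
#' @param bpm_range heart-rate range (beats per minute), drawn uniformly
#' @param duration_range_s recording duration range in seconds
#' @param s1_freq_hz,s2_freq_hz centre frequencies of the S1/S2 tone bursts
#' @param burst_width_ms approximate width of each heart-sound burst (ms)
#' @param murmur_band_hz frequency band of the murmur noise (Hz)
#' @param murmur_snr_db murmur strength in dB relative to the RMS of the
#'   clean S1/S2 signal; larger values make classes easier to separate
#' @param noise_floor_db white-noise floor in dB relative to clean signal RMS
#' @param amplitude_jitter relative standard deviation of per-burst amplitude
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_normal, n_abnormal, seed = 0L,
                         sampling_rate = 2000,
                         bpm_range = c(60, 100),
                         duration_range_s = c(5, 122),
                         s1_freq_hz = 60, s2_freq_hz = 110,
                         burst_width_ms = 40,
                         murmur_band_hz = c(150, 400),
                         murmur_snr_db = 0,
                         noise_floor_db = -30,
                         amplitude_jitter = 0.1) {
  stopifnot(n_normal >= 0, n_abnormal >= 0,
            sampling_rate > 0,
            duration_range_s[1] > 0, duration_range_s[1] <= duration_range_s[2],
            bpm_range[1] > 0, bpm_range[1] <= bpm_range[2],
            murmur_band_hz[1] > 0, murmur_band_hz[2] < sampling_rate / 2)
  structure(list(
    n_normal = as.integer(n_normal), n_abnormal = as.integer(n_abnormal),
    seed = as.integer(seed), sampling_rate = sampling_rate,
    bpm_range = bpm_range, duration_range_s = duration_range_s,
    s1_freq_hz = s1_freq_hz, s2_freq_hz = s2_freq_hz,
    burst_width_ms = burst_width_ms, murmur_band_hz = murmur_band_hz,
    murmur_snr_db = murmur_snr_db, noise_floor_db = noise_floor_db,
    amplitude_jitter = amplitude_jitter
  ), class = "synth_config")
}

#' Preset matching the class balance of the CinC 2016 training corpus
#'
#' Returns a generator configuration with 2,575 normal and 665 abnormal
#' recordings at `scale = 1`; `scale` shrinks both counts proportionally
#' (rounding half up, minimum one recording per class) for desk-scale runs.
#'
#' @param scale positive scaling factor for the class counts
#' @param ... further arguments passed to [synth_config()]
#' @return an object of class `synth_config`
#' @export
table1_preset <- function(scale = 1, ...) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("`scale` must be a positive number")
  }
  half_up <- function(x) floor(x + 0.5)
  synth_config(n_normal = max(1, half_up(2575 * scale)),
               n_abnormal = max(1, half_up(665 * scale)), ...)
}

new_pcg_recording <- function(id, samples, sampling_rate, label,
                              source = c("synthetic", "file")) {
  source <- match.arg(source)
  stopifnot(sampling_rate > 0, length(samples) > 0)
  label <- match.arg(label, c("normal", "abnormal"))
  structure(list(id = id, samples = samples, sampling_rate = sampling_rate,
                 label = label, source = source),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording %s: %s, %.1f s @ %g Hz, %s>\n",
              x$id, x$label, length(x$samples) / x$sampling_rate,
              x$sampling_rate, x$source))
  invisible(x)
}

gauss_burst <- function(t, t0, freq, amp, width_s) {
  env <- exp(-0.5 * ((t - t0) / (width_s / 2.5))^2)
  amp * env * sin(2 * pi * freq * (t - t0))
}

synth_one <- function(cfg, label, index) {
  set.seed((cfg$seed + index) %% .Machine$integer.max)
  fs <- cfg$sampling_rate
  duration <- runif(1, cfg$duration_range_s[1], cfg$duration_range_s[2])
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  bpm <- runif(1, cfg$bpm_range[1], cfg$bpm_range[2])
  cycle <- 60 / bpm
  width_s <- cfg$burst_width_ms / 1000
  starts <- seq(width_s, duration - cycle, by = cycle)
  clean <- numeric(n)
  for (t0 in starts) {
    a1 <- 0.5 * (1 + cfg$amplitude_jitter * rnorm(1))
    a2 <- 0.35 * (1 + cfg$amplitude_jitter * rnorm(1))
    clean <- clean + gauss_burst(t, t0, cfg$s1_freq_hz, a1, width_s)
    clean <- clean + gauss_burst(t, t0 + 0.55 * cycle, cfg$s2_freq_hz, a2, width_s)
  }
  rms_clean <- sqrt(mean(clean^2))
  x <- clean
  if (label == "abnormal") {
    bf <- signal::butter(4, cfg$murmur_band_hz / (fs / 2), type = "pass")
    raw <- signal::filtfilt(bf, rnorm(n))
    env <- numeric(n)
    for (t0 in starts) {
      lo <- t0 + width_s
      hi <- t0 + 0.55 * cycle - width_s
      if (hi <= lo) next
      in_sys <- t >= lo & t <= hi
      env[in_sys] <- sin(pi * (t[in_sys] - lo) / (hi - lo))
    }
    murmur <- raw * env
    rms_m <- sqrt(mean(murmur[env > 0]^2))
    if (is.finite(rms_m) && rms_m > 0) {
      murmur <- murmur * (10^(cfg$murmur_snr_db / 20) * rms_clean / rms_m)
    }
    x <- x + murmur
  }
  x <- x + rnorm(n, sd = 10^(cfg$noise_floor_db / 20) * rms_clean)
  x <- pmax(pmin(x, 0.999), -0.999)
  new_pcg_recording(sprintf("synth-%s-%04d", label, index), x, fs, label,
                    source = "synthetic")
}

#' Generate a labelled synthetic heart-sound dataset
#'
#' @param cfg a [synth_config()]
#' @return list of `pcg_recording` (normals first, then abnormals); an empty
#'   request returns an empty list
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- vector("list", cfg$n_normal + cfg$n_abnormal)
  labels <- c(rep("normal", cfg$n_normal), rep("abnormal", cfg$n_abnormal))
  for (i in seq_along(recs)) {
    recs[[i]] <- synth_one(cfg, labels[i], i)
  }
  recs
}

#' Write recordings as WAV files plus a CSV manifest
#'
#' Produces the exact layout consumed by [load_recordings()]: one 16-bit PCM
#' mono WAV per recording and a `manifest.csv` with columns `id,path,label`
#' (paths relative to `dir`).
#'
#' @param recordings list of `pcg_recording`
#' @param dir output directory (created if missing)
#' @return path to the manifest, invisibly
#' @export
write_dataset <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(recordings, function(r) {
    fname <- paste0(r$id, ".wav")
    write_wav(r$samples, r$sampling_rate, file.path(dir, fname))
    data.frame(id = r$id, path = fname, label = r$label)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(manifest)) {
    manifest <- data.frame(id = character(), path = character(),
                           label = character())
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
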