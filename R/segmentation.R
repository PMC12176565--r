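#' Load heart-sound recordings from a manifest
#'
#' Reads a CSV manifest with columns `id`, `path` (WAV path relative to
#' `audio_dir`), and `label` (`normal` or `abnormal`). Amplitudes are scaled
#' by the PCM full-scale value so they lie in \[-1, 1). Stereo files are
#' rejected. Files whose sampling rate differs from `sampling_rate` are
#' resampled (polyphase) with a warning.
#'
#' An unknown label token is a hard error naming the offending row. A missing
#' or unreadable file is recorded as a per-record error entry and loading
#' continues; the entries are attached as the `"errors"` attribute
#' (a data frame with columns `id`, `message`).
#'
#' @param manifest_path path to the manifest CSV
#' @param audio_dir directory the manifest paths are relative to
#' @param sampling_rate target sampling rate in Hz (default 2000)
#' @return list of `pcg_recording`, with attribute `"errors"`
#' @export
load_recordings <- function(manifest_path, audio_dir,
                            sampling_rate = 2000) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("id", "path", "label")
  if (!all(required %in% names(manifest))) {
    stop("manifest must have columns id, path, label")
  }
  bad <- !manifest$label %in% c("normal", "abnormal")
  if (any(bad)) {
    stop("unknown label token in manifest row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(manifest$label[bad]), collapse = ", "))
  }
  recs <- list()
  errors <- data.frame(id = character(), message = character())
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(audio_dir, manifest$path[i])
    res <- tryCatch(read_wav(path), error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(id = manifest$id[i],
                                         message = conditionMessage(res)))
      next
    }
    samples <- res$samples
    if (res$sampling_rate != sampling_rate) {
      warning(sprintf("resampling %s from %g Hz to %g Hz",
                      manifest$id[i], res$sampling_rate, sampling_rate))
      samples <- signal::resample(samples, sampling_rate, res$sampling_rate)
    }
    recs[[length(recs) + 1L]] <- new_pcg_recording(
      manifest$id[i], samples, sampling_rate, manifest$label[i],
      source = "file")
  }
  attr(recs, "errors") <- errors
  recs
}

new_pcg_segment <- function(parent_id, index, samples, label) {
  structure(list(parent_id = parent_id, index = as.integer(index),
                 samples = samples, label = label),
            class = "pcg_segment")
}

#' Cut a recording into fixed, non-overlapping windows
#'
#' Returns `floor(duration / window_seconds)` segments of exactly
#' `window_seconds * sampling_rate` samples each, covering a prefix of the
#' recording; the trailing remainder is discarded and never padded.
#' Recordings shorter than one window return an empty list (callers should
#' count these in a skip log; see [segment_dataset()]).
#'
#' @param rec a `pcg_recording`
#' @param window_seconds window length in seconds (default 5)
#' @return list of `pcg_segment` (possibly empty)
#' @export
segment_recording <- function(rec, window_seconds = 5) {
  stopifnot(inherits(rec, "pcg_recording"))
  wn <- window_seconds * rec$sampling_rate
  if (abs(wn - round(wn)) > 1e-9) {
    stop(sprintf(paste0("window of %g s at %g Hz is not an integer number of",
                        " samples; adjust the window or the sampling rate"),
                 window_seconds, rec$sampling_rate))
  }
  wn <- as.integer(round(wn))
  k <- length(rec$samples) %/% wn
  if (k == 0L) return(list())
  lapply(seq_len(k) - 1L, function(i) {
    new_pcg_segment(rec$id, i, rec$samples[(i * wn + 1L):((i + 1L) * wn)],
                    rec$label)
  })
}

#' Segment a set of recordings, keeping a skip log
#'
#' @param recordings list of `pcg_recording`
#' @param window_seconds window length in seconds
#' @return list with `segments` (flat list of `pcg_segment`) and `skipped`
#'   (data frame of recordings shorter than one window: `id`, `duration_s`)
#' @export
segment_dataset <- function(recordings, window_seconds = 5) {
  segments <- list()
  skipped <- data.frame(id = character(), duration_s = numeric())
  for (rec in recordings) {
    segs <- segment_recording(rec, window_seconds)
    if (length(segs) == 0L) {
      skipped <- rbind(skipped, data.frame(
        id = rec$id, duration_s = length(rec$samples) / rec$sampling_rate))
    } else {
      segments <- c(segments, segs)
    }
  }
  list(segments = segments, skipped = skipped)
}
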