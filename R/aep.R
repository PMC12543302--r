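#' Epoch, clean and average stimulus-locked responses
#'
#' Band-pass filters the recording (zero-phase, 4th-order Butterworth),
#' cuts epochs around stimulus onsets, drops epochs containing voltage
#' excursions beyond `reject_uv` (checked on the unfiltered data), averages
#' the surviving trials, and subtracts the prestimulus mean per channel.
#'
#' @param recording A recording object or channels x samples matrix (uV).
#' @param events Stimulus onsets: integer sample indices, or a data frame
#'   with a column `onset_sample`.
#' @param band Band-pass edges in Hz (default 3-300).
#' @param reject_uv Epoch rejection threshold (uV, default 400).
#' @param window_ms Epoch window relative to stimulus (default -50..400 ms).
#' @param baseline Subtract the prestimulus mean (default `TRUE`).
#' @param rate Sampling rate, for matrix input.
#' @return An `evoked_waveform`: list with `times` (ms), `amplitude`
#'   (time x channel, uV), `n_trials`, `n_trials_retained`, `channel_ids`.
#' @export
preprocess_epochs <- function(recording, events, band = c(3, 300),
                              reject_uv = 400, window_ms = c(-50, 400),
                              baseline = TRUE, rate = NULL) {
  rec <- resolve_recording(recording, rate)
  fs <- rec$rate
  if (fs < 2 * band[2]) {
    abort_invalid("Sampling rate must be at least twice the filter upper edge.")
  }
  onsets <- if (is.data.frame(events)) events$onset_sample else events
  if (length(onsets) < 1) abort_insufficient("At least one event is required.")

  x <- rec$samples
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filt <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))

  span <- round(window_ms / 1000 * fs)
  idx_rel <- span[1]:span[2]
  times <- idx_rel / fs * 1000
  keep_onsets <- onsets[onsets + span[1] >= 1 & onsets + span[2] <= ncol(x)]
  n_trials <- length(keep_onsets)
  if (n_trials < 1) abort_insufficient("No event window fits the recording.")

  retained <- list()
  for (on in keep_onsets) {
    cols <- on + idx_rel
    if (max(abs(x[, cols])) > reject_uv) next
    retained[[length(retained) + 1L]] <- t(filt[, cols, drop = FALSE])
  }
  if (length(retained) == 0) {
    abort_insufficient("All epochs exceeded the rejection threshold.")
  }
  avg <- Reduce(`+`, retained) / length(retained)
  if (baseline) {
    pre <- times < 0
    if (any(pre)) avg <- sweep(avg, 2, colMeans(avg[pre, , drop = FALSE]))
  }
  colnames(avg) <- rec$node_ids
  structure(
    list(times = times, amplitude = avg, n_trials = n_trials,
         n_trials_retained = length(retained), channel_ids = rec$node_ids,
         rate = fs),
    class = "evoked_waveform"
  )
}

#' @export
print.evoked_waveform <- function(x, ...) {
  cat(sprintf(
    "<evoked_waveform> %d channels, %.0f..%.0f ms, %d/%d trials retained\n",
    ncol(x$amplitude), min(x$times), max(x$times), x$n_trials_retained,
    x$n_trials
  ))
  invisible(x)
}

#' Detect the N1 component of an evoked waveform
#'
#' Per channel, finds the largest-magnitude negative local extremum inside
#' the search window (default 15-100 ms post-stimulus); ties are broken by
#' the earlier latency. Channels without a negative local extremum in the
#' window are flagged `found = FALSE`.
#'
#' @param evoked An `evoked_waveform`.
#' @param window_ms Search window (ms post-stimulus).
#' @return A tibble with columns `channel`, `latency_ms`, `amplitude_uv`,
#'   `found`.
#' @export
detect_n1 <- function(evoked, window_ms = c(15, 100)) {
  stopifnot(inherits(evoked, "evoked_waveform"))
  tm <- evoked$times
  if (window_ms[1] < min(tm) || window_ms[2] > max(tm)) {
    abort_invalid("Evoked waveform does not cover the search window.")
  }
  purrr::map_dfr(seq_along(evoked$channel_ids), function(ch) {
    y <- evoked$amplitude[, ch]
    n <- length(y)
    interior <- 2:(n - 1)
    is_min <- y[interior] < y[interior - 1] & y[interior] <= y[interior + 1]
    cand <- interior[is_min & y[interior] < 0]
    cand <- cand[tm[cand] >= window_ms[1] & tm[cand] <= window_ms[2]]
    if (length(cand) == 0) {
      tibble::tibble(channel = evoked$channel_ids[ch],
                     latency_ms = NA_real_, amplitude_uv = NA_real_,
                     found = FALSE)
    } else {
      best <- cand[order(y[cand], tm[cand])][1]
      tibble::tibble(channel = evoked$channel_ids[ch],
                     latency_ms = tm[best], amplitude_uv = y[best],
                     found = TRUE)
    }
  })
}

#' Simulate a stimulus-locked recording with an N1-like response
#'
#' Builds a continuous multichannel recording in which every stimulus evokes
#' a negative deflection (Gaussian trough) at a fixed latency followed by a
#' smaller positive deflection, on top of white noise — enough structure to
#' exercise epoching, rejection and N1 detection end to end.
#'
#' @param n_channels Number of channels.
#' @param n_trials Number of stimuli.
#' @param rate Sampling rate (Hz).
#' @param isi_ms Inter-stimulus interval (ms).
#' @param n1_amp N1 amplitude (uV, negative).
#' @param n1_lat_ms N1 latency (ms).
#' @param noise_sd Additive noise SD (uV).
#' @param seed Integer seed.
#' @return A list with `recording` (list with `samples`, `rate`,
#'   `node_ids`) and `events` (tibble with `onset_sample`, `label`).
#' @export
simulate_aep_recording <- function(n_channels = 4, n_trials = 200,
                                   rate = 2000, isi_ms = 500, n1_amp = -8,
                                   n1_lat_ms = 40, noise_sd = 4, seed = 1) {
  set.seed(seed)
  isi <- round(isi_ms / 1000 * rate)
  onsets <- seq(2 * isi, by = isi, length.out = n_trials)
  n_samples <- max(onsets) + 2 * isi
  tmpl_t <- seq(0, 0.25, by = 1 / rate) * 1000          # ms
  template <- n1_amp * exp(-((tmpl_t - n1_lat_ms) / 10)^2) +
    (-n1_amp / 2) * exp(-((tmpl_t - 2.5 * n1_lat_ms) / 25)^2)
  x <- matrix(rnorm(n_channels * n_samples, sd = noise_sd),
              nrow = n_channels)
  for (on in onsets) {
    cols <- on + seq_along(template) - 1L
    x[, cols] <- x[, cols] + matrix(template, nrow = n_channels,
                                    ncol = length(template), byrow = TRUE)
  }
  ids <- sprintf("E%02d", seq_len(n_channels))
  rownames(x) <- ids
  list(
    recording = list(samples = x, rate = rate, node_ids = ids),
    events = tibble::tibble(onset_sample = onsets, label = "click")
  )
}

#' Read stimulus events from a delimited table
#'
#' @param path Tab-delimited file with columns `onset_sample` and optional
#'   `label`.
#' @return A tibble of events.
#' @export
read_events <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!"onset_sample" %in% names(tab)) {
    abort_invalid("Events file must have a column `onset_sample`.",
                  class = "gammanet_format_error")
  }
  tibble::as_tibble(tab)
}
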