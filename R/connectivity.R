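#' Spectral estimation settings for connectome construction
#'
#' Recordings are segmented into non-overlapping epochs; within each epoch,
#' Welch-style tapered segments with the configured overlap provide the
#' cross-spectral densities. Frequency resolution is `1 / csd_window_s`.
#'
#' @param epoch_s Epoch length (s).
#' @param csd_window_s Welch segment length (s), at most `epoch_s`.
#' @param overlap_frac Segment overlap fraction in \[0, 1).
#' @param band_hz Frequency band of interest (Hz), default gamma 25-80.
#' @param taper Taper family: `"hamming"`, `"hanning"` or `"rectangular"`.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(epoch_s = 3, csd_window_s = 1.5,
                            overlap_frac = 0.5, band_hz = c(25, 80),
                            taper = c("hamming", "hanning", "rectangular")) {
  check_scalar_number(epoch_s, "epoch_s", lower = 0, strict_lower = TRUE)
  check_scalar_number(csd_window_s, "csd_window_s", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(overlap_frac, "overlap_frac", lower = 0)
  if (overlap_frac >= 1) abort_invalid("`overlap_frac` must be < 1.")
  if (csd_window_s > epoch_s) {
    abort_invalid("`csd_window_s` must not exceed `epoch_s`.")
  }
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1]) {
    abort_invalid("`band_hz` must be an increasing positive interval.")
  }
  taper <- match.arg(taper)
  structure(list(epoch_s = epoch_s, csd_window_s = csd_window_s,
                 overlap_frac = overlap_frac, band_hz = band_hz,
                 taper = taper),
            class = "spectral_config")
}

taper_window <- function(kind, n) {
  switch(kind,
    hamming = signal::hamming(n),
    hanning = signal::hanning(n),
    rectangular = rep(1, n)
  )
}

resolve_recording <- function(recording, rate = NULL) {
  if (inherits(recording, "synthetic_recording") ||
      (is.list(recording) && !is.null(recording$samples))) {
    list(samples = recording$samples, rate = recording$rate,
         node_ids = recording$node_ids %||% rownames(recording$samples))
  } else if (is.matrix(recording)) {
    if (is.null(rate)) abort_invalid("`rate` is required for matrix input.")
    list(samples = recording, rate = rate,
         node_ids = rownames(recording) %||%
           sprintf("E%02d", seq_len(nrow(recording))))
  } else {
    abort_invalid("`recording` must be a recording object or channels x samples matrix.")
  }
}

#' Per-pair, per-segment cross-spectral densities
#'
#' Cuts the recording into epochs, applies tapered Welch segments within
#' each, and returns the complex cross-spectral density of every channel
#' pair at every retained frequency bin for every segment (segments pooled
#' across epochs). Frequencies are restricted to `freq_limits` (default: the
#' configured band) to bound memory.
#'
#' @param recording A `synthetic_recording`, a list with `samples` and
#'   `rate`, or a channels x samples matrix (then supply `rate`).
#' @param cfg A [spectral_config()].
#' @param rate Sampling rate in Hz, for matrix input.
#' @param freq_limits Length-2 interval of frequencies to retain (Hz).
#' @param reject_uv Optional amplitude threshold: segments containing any
#'   sample with `|x| > reject_uv` are dropped (default `NULL`, off).
#' @return A `cross_spectra` object: complex array `csd` with dimensions
#'   (frequency, segment, pair), plus `freqs`, `pairs`, `node_ids`, `cfg`.
#' @export
cross_spectra <- function(recording, cfg = spectral_config(), rate = NULL,
                          freq_limits = NULL, reject_uv = NULL) {
  rec <- resolve_recording(recording, rate)
  x <- rec$samples
  if (nrow(x) < 2) abort_insufficient("At least two channels are required.")
  fs <- rec$rate
  epoch_len <- round(cfg$epoch_s * fs)
  seg_len <- round(cfg$csd_window_s * fs)
  if (ncol(x) < epoch_len) {
    abort_insufficient("Recording is shorter than one epoch.")
  }
  step <- max(1L, round(seg_len * (1 - cfg$overlap_frac)))
  n_epochs <- floor(ncol(x) / epoch_len)
  seg_starts_within <- seq(1L, epoch_len - seg_len + 1L, by = step)

  freqs_all <- (seq_len(seg_len) - 1) / seg_len * fs
  keep_f <- seq_len(floor(seg_len / 2) + 1L)
  freq_limits <- freq_limits %||% cfg$band_hz
  keep_f <- keep_f[freqs_all[keep_f] >= freq_limits[1] &
                     freqs_all[keep_f] <= freq_limits[2]]
  if (length(keep_f) == 0) {
    abort_invalid("No frequency bins fall inside `freq_limits`.")
  }
  freqs <- freqs_all[keep_f]

  n_chan <- nrow(x)
  pairs <- upper_pairs(n_chan)
  win <- taper_window(cfg$taper, seg_len)

  # FFT of every tapered segment, then outer cross-products per pair
  seg_ffts <- list()
  s <- 0L
  for (e in seq_len(n_epochs)) {
    off <- (e - 1L) * epoch_len
    for (st in seg_starts_within) {
      seg <- t(x[, off + st + 0:(seg_len - 1L), drop = FALSE])
      if (!is.null(reject_uv) && max(abs(seg)) > reject_uv) next
      seg <- sweep(seg, 2, colMeans(seg))    # per-segment demeaning
      seg <- seg * win
      s <- s + 1L
      seg_ffts[[s]] <- stats::mvfft(seg)[keep_f, , drop = FALSE]
    }
  }
  if (s == 0L) abort_insufficient("All segments were rejected.")
  csd <- array(complex(real = 0), dim = c(length(keep_f), s, nrow(pairs)))
  ii <- pairs[, 1]
  jj <- pairs[, 2]
  for (k in seq_len(s)) {
    Xf <- seg_ffts[[k]]
    csd[, k, ] <- Xf[, ii, drop = FALSE] * Conj(Xf[, jj, drop = FALSE])
  }
  structure(
    list(csd = csd, freqs = freqs, pairs = pairs, node_ids = rec$node_ids,
         cfg = cfg, n_epochs = n_epochs, n_segments = s),
    class = "cross_spectra"
  )
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf(
    "<cross_spectra> %d pairs x %d bins (%.3g-%.3g Hz) x %d segments\n",
    nrow(x$pairs), length(x$freqs), min(x$freqs), max(x$freqs), x$n_segments
  ))
  invisible(x)
}

#' Debiased weighted phase-lag index per pair and frequency
#'
#' For each pair and frequency bin, with imaginary cross-spectrum parts
#' `I_k` over segments `k`, the debiased WPLI-square estimator is
#' `((sum I)^2 - sum I^2) / ((sum |I|)^2 - sum I^2)`. Phase differences are
#' thus weighted by magnitude, discarding zero-phase (volume-conducted)
#' coupling. A zero denominator — no lagged signal at all — yields 0, and
#' negative estimates (estimator noise around zero coupling) are clipped to
#' 0 so downstream graph algorithms receive non-negative weights.
#'
#' @param cs A `cross_spectra` object.
#' @return A `dwpli_spectrum`: matrix `values` (frequency x pair) in
#'   \[0, 1\] plus `freqs`, `pairs`, `node_ids`, `band`.
#' @export
dwpli <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  dims <- dim(cs$csd)
  n_seg <- dims[2]
  if (n_seg < 2) {
    abort_insufficient("dwPLI needs at least 2 segments per pair-frequency.")
  }
  I <- Im(cs$csd)
  collapse <- function(a) {   # sum over the segment dimension
    m <- matrix(aperm(a, c(2, 1, 3)), nrow = n_seg)
    matrix(colSums(m), nrow = dims[1], ncol = dims[3])
  }
  s1 <- collapse(I)
  s2 <- collapse(I^2)
  sa <- collapse(abs(I))
  num <- s1^2 - s2
  den <- sa^2 - s2
  v <- ifelse(den > 0, num / den, 0)
  v <- pmin(pmax(v, 0), 1)
  structure(
    list(values = v, freqs = cs$freqs, pairs = cs$pairs,
         node_ids = cs$node_ids, band = cs$cfg$band_hz),
    class = "dwpli_spectrum"
  )
}

#' Collapse a dwPLI spectrum to a band-averaged connectome
#'
#' Per-pair mean over frequency bins whose center lies inside the band
#' (inclusive).
#'
#' @param dw A `dwpli_spectrum`.
#' @param band Length-2 interval (Hz); defaults to the configured band.
#' @return A `connectome` of band-mean dwPLI values.
#' @export
band_connectome <- function(dw, band = NULL) {
  stopifnot(inherits(dw, "dwpli_spectrum"))
  band <- band %||% dw$band
  if (length(band) != 2 || band[2] < band[1]) {
    abort_invalid("`band` must be a non-decreasing length-2 interval.")
  }
  in_band <- dw$freqs >= band[1] & dw$freqs <= band[2]
  if (!any(in_band)) {
    abort_invalid("No frequency bins available inside the requested band.")
  }
  mean_vals <- colMeans(dw$values[in_band, , drop = FALSE])
  n <- length(dw$node_ids)
  w <- matrix(0, n, n)
  w[dw$pairs] <- mean_vals
  w <- w + t(w)
  connectome(w, node_ids = dw$node_ids, band = band)
}

#' Gamma-band dwPLI connectome from a recording
#'
#' Convenience wrapper chaining [cross_spectra()], [dwpli()] and
#' [band_connectome()].
#'
#' @inheritParams cross_spectra
#' @return A `connectome`.
#' @export
dwpli_connectome <- function(recording, cfg = spectral_config(), rate = NULL,
                             reject_uv = NULL) {
  band_connectome(dwpli(cross_spectra(recording, cfg, rate = rate,
                                      reject_uv = reject_uv)))
}
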