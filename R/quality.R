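#' Welch power spectral density
#'
#' Hann-windowed segment-averaged periodogram (60 s segments, 50% overlap by
#' default), the estimator behind all band-power metrics in this package.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_seconds Segment length in seconds.
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, seg_seconds = 60, overlap = 0.5) {
  n <- length(x)
  seg <- min(n, max(8, round(seg_seconds * fs)))
  step <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  u <- sum(win^2)
  nf <- floor(seg / 2)
  acc <- numeric(nf)
  for (s in starts) {
    v <- x[s:(s + seg - 1)]
    v <- (v - mean(v)) * win
    sp <- abs(stats::fft(v))^2
    acc <- acc + sp[2:(nf + 1)]
  }
  psd <- 2 * acc / (length(starts) * u * fs)
  list(freq = (1:nf) * fs / seg, psd = psd)
}

#' Band power from the Welch estimate
#'
#' @inheritParams welch_psd
#' @param band `c(low, high)` in Hz, half-open `[low, high)`.
#' @return Scalar band power.
#' @export
band_power <- function(x, fs, band, seg_seconds = 60, overlap = 0.5) {
  w <- welch_psd(x, fs, seg_seconds, overlap)
  sel <- w$freq >= band[1] & w$freq < band[2]
  df <- w$freq[2] - w$freq[1]
  sum(w$psd[sel]) * df
}

#' Raw signal strength and SNR
#'
#' Per-channel mean raw intensity and SNR (20 log10(mean/sd)) over a rest
#' window, averaged across wavelengths, plus the subject-level screening flag
#' (mean raw intensity at or above 0.06 V, the level corresponding to the
#' 40 dB SNR benchmark of the device class). The subject-level aggregates use
#' the long channels -- the ones carrying the cortical measurement that the
#' screening protects -- since short channels run at much higher light
#' levels.
#'
#' @param rec A [nirs_recording()].
#' @param window Rest window `c(start, end)` in seconds.
#' @param intensity_threshold Screening threshold in volts (default 0.06).
#' @return List with `channel` (data.frame: mean_intensity, snr_db),
#'   `mean_intensity` (subject level), `snr_db` (subject level) and
#'   `screening_pass`.
#' @export
signal_strength <- function(rec, window = c(0, 120),
                            intensity_threshold = 0.06) {
  n <- dim(rec$intensities)[1]
  i0 <- max(1, floor(window[1] * rec$fs) + 1)
  i1 <- min(n, ceiling(window[2] * rec$fs))
  if (i1 <= i0) stop("window outside recording")
  nch <- dim(rec$intensities)[2]; nwl <- dim(rec$intensities)[3]
  mi <- snr <- matrix(0, nch, nwl)
  for (c in seq_len(nch)) {
    for (w in seq_len(nwl)) {
      seg <- rec$intensities[i0:i1, c, w]
      mi[c, w] <- mean(seg)
      s <- stats::sd(seg)
      snr[c, w] <- if (s == 0) Inf else 20 * log10(mi[c, w] / s)
    }
  }
  if (any(is.infinite(snr))) {
    warning("zero variance in rest window; SNR reported as +Inf")
  }
  ch <- data.frame(mean_intensity = rowMeans(mi), snr_db = rowMeans(snr))
  li <- long_channels(rec$montage)
  list(channel = ch,
       mean_intensity = mean(ch$mean_intensity[li]),
       snr_db = mean(ch$snr_db[li]),
       screening_pass = mean(ch$mean_intensity[li]) >= intensity_threshold)
}

#' Short-channel signal quality
#'
#' Quality of a short channel is judged by its physiological content rather
#' than raw SNR: the ratio (dB) of cardiac band power (0.6-2 Hz) to the
#' residual background power (2-4 Hz) of the unfiltered O2Hb series. A
#' channel passes at or above 12 dB.
#'
#' @param hemo Unfiltered [hemo_series()] (the cardiac band must be intact,
#'   i.e. computed before the 0.35 Hz low-pass).
#' @param channel Index of a short channel.
#' @param threshold_db Pass threshold (default 12 dB).
#' @param cardiac_band,background_band Frequency bands in Hz.
#' @return List with `quality_db` and `pass`.
#' @export
short_channel_quality <- function(hemo, channel, threshold_db = 12,
                                  cardiac_band = c(0.6, 2),
                                  background_band = c(2, 4)) {
  if (hemo$montage$channels$role[channel] != "short") {
    stop("channel ", channel, " is not a short channel")
  }
  if (nrow(hemo$o2hb) < 60 * hemo$fs) stop("recording shorter than 60 s")
  x <- hemo$o2hb[, channel]
  p_card <- band_power(x, hemo$fs, cardiac_band)
  p_bg <- band_power(x, hemo$fs, background_band)
  q <- 10 * log10(p_card / p_bg)
  list(quality_db = q, pass = q >= threshold_db)
}

#' Mayer-wave amplitude
#'
#' Subject-level Mayer-wave oscillation strength: per long channel, the O2Hb
#' band power in 0.07-0.14 Hz normalized by the pulse band power (0.6-2 Hz);
#' the median over long channels is returned. Being a power ratio, it is
#' invariant to overall signal scaling.
#'
#' @param hemo Unfiltered [hemo_series()] (must retain the pulse band).
#' @param mayer_band,pulse_band Frequency bands in Hz.
#' @return Scalar Mayer-wave amplitude (dimensionless).
#' @export
mayer_wave_amplitude <- function(hemo, mayer_band = c(0.07, 0.14),
                                 pulse_band = c(0.6, 2)) {
  li <- long_channels(hemo$montage)
  ratios <- vapply(li, function(c) {
    x <- hemo$o2hb[, c]
    p_pulse <- band_power(x, hemo$fs, pulse_band)
    if (p_pulse <= 0) stop("zero pulse band power; signal must retain pulse")
    band_power(x, hemo$fs, mayer_band) / p_pulse
  }, numeric(1))
  stats::median(ratios)
}

#' Per-recording quality report
#'
#' @param rec A [nirs_recording()].
#' @param hemo_raw Unfiltered [hemo_series()] of the same recording.
#' @param sc_threshold_db Short-channel pass threshold (dB).
#' @param intensity_threshold Screening threshold (V).
#' @return List of class `quality_report`: signal strength summary, per-short
#'   channel quality table, Mayer-wave amplitude, screening flag.
#' @export
quality_report <- function(rec, hemo_raw, sc_threshold_db = 12,
                           intensity_threshold = 0.06) {
  ss <- signal_strength(rec, intensity_threshold = intensity_threshold)
  si <- short_channels(rec$montage)
  scq <- do.call(rbind, lapply(si, function(c) {
    q <- short_channel_quality(hemo_raw, c, sc_threshold_db)
    data.frame(channel = c, quality_db = q$quality_db, pass = q$pass)
  }))
  structure(list(signal = ss, short_channels = scq,
                 mayer_amplitude = mayer_wave_amplitude(hemo_raw),
                 screening_pass = ss$screening_pass),
            class = "quality_report")
}
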