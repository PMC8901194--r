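#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass of the given order, applied zero-phase
#' by forward-backward convolution on reflection-padded signals. The default
#' 0.015-0.35 Hz band removes drift and cardiac pulsation while keeping the
#' task-locked hemodynamic response.
#'
#' @param hemo A [hemo_series()] (or a plain numeric matrix/vector with `fs`
#'   supplied).
#' @param low,high Cutoff frequencies in Hz.
#' @param order FIR order (default 1000).
#' @param fs Sampling rate; taken from `hemo` when it is a `hemo_series`.
#' @return Filtered object of the same shape/class as the input.
#' @export
bandpass_fir <- function(hemo, low = 0.015, high = 0.35, order = 1000,
                         fs = NULL) {
  if (inherits(hemo, "hemo_series")) {
    out <- hemo
    out$o2hb <- bandpass_fir(hemo$o2hb, low, high, order, fs = hemo$fs)
    out$hhb <- bandpass_fir(hemo$hhb, low, high, order, fs = hemo$fs)
    return(out)
  }
  stopifnot(!is.null(fs))
  x <- as.matrix(hemo)
  if (order >= nrow(x) / 3) {
    stop("recording too short for FIR order ", order,
         "; reduce the order to below n_samples/3")
  }
  b <- fir_bandpass_kernel(order, low, high, fs)
  y <- apply(x, 2, apply_zero_phase, b = b)
  if (is.vector(hemo)) as.vector(y) else y
}

fir_bandpass_kernel <- function(order, low, high, fs) {
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  b - mean(b)    # exact null at DC (the ideal kernel's sum, truncated, is not 0)
}

# forward-backward convolution (zero net phase, squared magnitude response)
# with reflection padding to suppress edge transients; FFT-based
apply_zero_phase <- function(x, b) {
  nb <- length(b)
  n <- length(x)
  pad <- min(n - 1, 3 * nb)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  g <- fast_conv(b, b)                 # combined kernel, 2*nb-1
  yf <- fast_conv(xp, g)               # delayed by nb-1
  as.numeric(yf[(nb - 1) + pad + seq_len(n)])
}

# linear convolution via FFT on a highly composite padded length
fast_conv <- function(x, k) {
  nout <- length(x) + length(k) - 1
  n2 <- stats::nextn(nout, c(2, 3, 5))
  fx <- stats::fft(c(x, numeric(n2 - length(x))))
  fk <- stats::fft(c(k, numeric(n2 - length(k))))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(nout)] / n2
}

#' Spline motion-artifact correction
#'
#' Detects artifact segments where the moving-window standard deviation
#' exceeds `threshold` times a robust baseline (the median moving sd), then,
#' within each segment, subtracts a smoothing-spline trend and re-anchors the
#' segment and all subsequent data to the preceding clean level, so both
#' spikes and persistent baseline shifts are removed while clean segments are
#' left untouched.
#'
#' @param series Numeric vector (one channel).
#' @param fs Sampling rate (Hz).
#' @param window Moving-window length in seconds (default 1 s).
#' @param threshold Detection multiplier on the robust baseline sd (default 3).
#' @param spar Smoothing parameter handed to [stats::smooth.spline()]
#'   (default 0.4; low enough that the spline tracks the artifact).
#' @return List with `signal` (corrected series) and `mask` (logical artifact
#'   mask).
#' @export
remove_motion_spline <- function(series, fs, window = 1, threshold = 3,
                                 spar = 0.4) {
  stopifnot(fs > 0)
  n <- length(series)
  w <- max(3L, round(window * fs))
  movsd <- moving_sd(series, w)
  base_sd <- stats::median(movsd)
  if (base_sd == 0) {
    return(list(signal = series, mask = rep(FALSE, n)))
  }
  mask <- movsd > threshold * base_sd
  # widen by half a window so segment edges cover the disturbance
  if (any(mask)) {
    idx <- which(mask)
    half <- ceiling(w / 2)
    for (i in idx) mask[max(1, i - half):min(n, i + half)] <- TRUE
  }
  if (!any(mask)) {
    return(list(signal = series, mask = mask))
  }
  if (all(mask)) {
    warning("entire series flagged as artifact; returning de-trended signal")
    trend <- stats::fitted(stats::smooth.spline(seq_len(n), series,
                                                spar = spar))
    return(list(signal = series - trend + mean(series), mask = mask))
  }
  segs <- mask_segments(mask)
  x <- series
  offset <- 0
  out <- series
  for (s in seq_len(nrow(segs))) {
    i1 <- segs[s, 1]; i2 <- segs[s, 2]
    prev_end <- i1 - 1
    anchor <- if (prev_end >= 1) {
      mean(out[max(1, prev_end - w + 1):prev_end])
    } else {
      mean(x[(i2 + 1):min(n, i2 + w)]) + offset
    }
    seg <- x[i1:i2] + offset
    if (i2 - i1 + 1 >= 8) {
      fitsp <- stats::smooth.spline(i1:i2, seg, spar = spar)
      trend <- stats::fitted(fitsp)
    } else {
      trend <- rep(mean(seg), i2 - i1 + 1)
    }
    seg_corr <- seg - trend + anchor
    out[i1:i2] <- seg_corr
    if (i2 < n) {
      # shift subsequent data so it continues from the corrected level
      tail_len <- min(w, i2 - i1 + 1)
      target <- mean(seg_corr[(length(seg_corr) - tail_len + 1):
                                length(seg_corr)])
      lead_len <- min(w, n - i2)
      actual <- mean(x[(i2 + 1):(i2 + lead_len)]) + offset
      offset <- offset + (target - actual)
      out[(i2 + 1):n] <- x[(i2 + 1):n] + offset
    }
  }
  list(signal = out, mask = mask)
}

moving_sd <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  half <- floor(w / 2)
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo
  m <- (cs[hi + 1] - cs[lo + 1]) / cnt
  v <- pmax(0, (cs2[hi + 1] - cs2[lo + 1]) / cnt - m^2)
  sqrt(v * cnt / pmax(1, cnt - 1))
}

mask_segments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(starts, ends)[r$values, , drop = FALSE]
}

#' Raw recording to band-limited hemoglobin series
#'
#' The full offline preprocessing chain: optional spline motion correction
#' (on optical density, per channel and wavelength), modified Beer-Lambert
#' inversion, then the zero-phase 0.015-0.35 Hz FIR band-pass. Also returns
#' the unfiltered hemoglobin series, which the quality metrics need (they
#' read the cardiac band that the low-pass removes).
#'
#' @param rec A [nirs_recording()].
#' @param params Optional [mbll_params()].
#' @param reference_window OD reference window, seconds.
#' @param motion_correct Apply [remove_motion_spline()]? Default TRUE.
#' @param low,high,order Band-pass settings.
#' @return List with `hemo` (filtered, tag NR), `hemo_raw` (unfiltered) and
#'   `artifact_fraction` (fraction of flagged samples).
#' @export
preprocess_recording <- function(rec, params = NULL,
                                 reference_window = c(0, 120),
                                 motion_correct = TRUE,
                                 low = 0.015, high = 0.35, order = 1000) {
  od <- intensity_to_od(rec, reference_window)
  art <- 0
  if (motion_correct) {
    for (c in seq_len(dim(od$od)[2])) {
      for (w in seq_len(dim(od$od)[3])) {
        mc <- remove_motion_spline(od$od[, c, w], od$fs)
        od$od[, c, w] <- mc$signal
        art <- art + mean(mc$mask)
      }
    }
    art <- art / (dim(od$od)[2] * dim(od$od)[3])
  }
  hemo_raw <- od_to_hemoglobin(od, params)
  hemo <- bandpass_fir(hemo_raw, low = low, high = high, order = order)
  list(hemo = hemo, hemo_raw = hemo_raw, artifact_fraction = art)
}
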