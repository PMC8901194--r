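#' Event block table
#'
#' @param condition Character vector in `{"left","right","rest"}`.
#' @param onset,duration Numeric vectors (seconds). Events must not overlap.
#' @return `data.frame` with one row per block, sorted by onset.
#' @export
event_blocks <- function(condition, onset, duration) {
  stopifnot(length(condition) == length(onset),
            length(onset) == length(duration))
  if (length(onset) == 0) {
    return(data.frame(condition = character(0), onset = numeric(0),
                      duration = numeric(0)))
  }
  stopifnot(all(condition %in% c("left", "right", "rest")),
            all(onset >= 0), all(duration > 0))
  ev <- data.frame(condition = condition, onset = onset, duration = duration)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  if (any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)])) {
    stop("events overlap")
  }
  ev
}

#' Construct a raw multi-wavelength recording
#'
#' @param intensities Array `[n_samples x n_channels x n_wavelengths]`, volts.
#' @param fs Sampling frequency in Hz.
#' @param montage A [nirs_montage()].
#' @param events Event table as from [event_blocks()].
#' @param meta List with `subject`, `session` (1 or 2), `run` (1 or 2).
#' @return Object of class `nirs_recording`.
#' @export
nirs_recording <- function(intensities, fs, montage, events,
                           meta = list(subject = 1L, session = 1L, run = 1L)) {
  stopifnot(fs > 0, length(dim(intensities)) == 3)
  if (dim(intensities)[2] != nrow(montage$channels)) {
    stop("intensity channel count does not match montage")
  }
  if (dim(intensities)[3] != length(montage$wavelengths)) {
    stop("intensity wavelength count does not match montage")
  }
  bad <- which(!is.finite(intensities), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite intensity at sample %d, channel %d",
                 bad[1, 1], bad[1, 2]))
  }
  dur <- dim(intensities)[1] / fs
  if (nrow(events) > 0 && max(events$onset + events$duration) > dur) {
    stop("last event ends after the recording end")
  }
  structure(list(intensities = intensities, fs = fs, montage = montage,
                 events = events, meta = meta),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "fNIRS recording: %d samples (%.1f s) x %d channels x %d wavelengths @ %.2f Hz, %d events\n",
    d[1], d[1] / x$fs, d[2], d[3], x$fs, nrow(x$events)))
  invisible(x)
}

#' Construct a hemoglobin concentration-change series
#'
#' @param o2hb,hhb Matrices `[n_samples x n_channels]` of concentration
#'   changes in micromolar.
#' @param fs Sampling frequency (Hz).
#' @param montage A [nirs_montage()].
#' @param events Event table.
#' @param tag Processing tag: `"NR"` (no regression) or `"SCR"`.
#' @return Object of class `hemo_series`.
#' @export
hemo_series <- function(o2hb, hhb, fs, montage, events,
                        tag = c("NR", "SCR")) {
  tag <- match.arg(tag)
  stopifnot(identical(dim(o2hb), dim(hhb)), fs > 0,
            all(is.finite(o2hb)), all(is.finite(hhb)),
            ncol(o2hb) == nrow(montage$channels))
  structure(list(o2hb = o2hb, hhb = hhb, fs = fs, montage = montage,
                 events = events, tag = tag),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("hemoglobin series [%s]: %d samples x %d channels @ %.2f Hz\n",
              x$tag, nrow(x$o2hb), ncol(x$o2hb), x$fs))
  invisible(x)
}
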