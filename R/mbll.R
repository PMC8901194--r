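#' Default hemoglobin extinction coefficients
#'
#' Base-10 molar extinction coefficients (cm^-1 M^-1) for oxy- and
#' deoxyhemoglobin at the four source wavelengths, linearly interpolated from
#' the standard compiled hemoglobin absorption spectra (OMLC compilation,
#' Prahl). Override via [mbll_params()] if your device calibration differs.
#'
#' @return Matrix `[4 x 2]`, columns `o2hb`, `hhb`; rownames are wavelengths.
#' @export
extinction_default <- function() {
  e <- rbind(`774` = c(672, 1180),
             `817` = c(901, 704),
             `865` = c(1108, 730),
             `892` = c(1180, 753))
  colnames(e) <- c("o2hb", "hhb")
  e
}

#' Parameters of the modified Beer-Lambert law
#'
#' @param wavelengths Wavelengths in nm (must match the extinction rownames).
#' @param dpf Differential pathlength factors, one per wavelength. Defaults to
#'   the adult values 6.2, 6.2, 5.9, 5.5 for 774/817/865/892 nm.
#' @param extinction Matrix `[n_wavelengths x 2]` of base-10 molar extinction
#'   coefficients (cm^-1 M^-1) for (O2Hb, HHb).
#' @param separations_mm Per-channel source-detector separations (mm).
#' @return List of class `mbll_params`.
#' @export
mbll_params <- function(wavelengths = c(774, 817, 865, 892),
                        dpf = c(6.2, 6.2, 5.9, 5.5),
                        extinction = extinction_default(),
                        separations_mm) {
  stopifnot(length(dpf) == length(wavelengths),
            nrow(extinction) == length(wavelengths), all(dpf > 0))
  if (qr(extinction)$rank < 2) {
    stop("configuration error: extinction matrix is rank-deficient")
  }
  structure(list(wavelengths = wavelengths, dpf = dpf,
                 extinction = extinction,
                 separations_cm = separations_mm / 10),
            class = "mbll_params")
}

mbll_params_for <- function(montage) {
  mbll_params(wavelengths = montage$wavelengths,
              separations_mm = montage$channels$separation_mm)
}

# [n_wavelengths x 2] sensitivity matrix for one channel: OD per microM
mbll_matrix <- function(params, channel) {
  params$extinction * params$dpf * params$separations_cm[channel] * 1e-6
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes to optical-density changes; used by
#' the simulator. The inversion [od_to_hemoglobin()] shares the same
#' extinction table and DPFs, so forward-then-invert is exact.
#'
#' @param o2hb,hhb Matrices `[n_samples x n_channels]` in micromolar.
#' @param params [mbll_params()].
#' @return Array `[n_samples x n_channels x n_wavelengths]` of OD changes.
#' @export
forward_mbll <- function(o2hb, hhb, params) {
  n <- nrow(o2hb); nch <- ncol(o2hb)
  nwl <- length(params$wavelengths)
  od <- array(0, c(n, nch, nwl))
  for (c in seq_len(nch)) {
    a <- mbll_matrix(params, c)
    od[, c, ] <- cbind(o2hb[, c], hhb[, c]) %*% t(a)
  }
  od
}

#' Convert raw intensities to optical density
#'
#' OD = -log10(I / I_ref) per channel and wavelength, with the reference the
#' mean intensity over a rest window (default: the 120 s leading baseline).
#' Windows are half-open `[start, end)`.
#'
#' @param rec A [nirs_recording()].
#' @param reference_window `c(start, end)` in seconds.
#' @return List of class `optical_density` with fields `od`, `fs`,
#'   `reference`, plus the recording's montage/events/meta.
#' @export
intensity_to_od <- function(rec, reference_window = c(0, 120)) {
  n <- dim(rec$intensities)[1]
  i0 <- max(1, floor(reference_window[1] * rec$fs) + 1)
  i1 <- min(n, ceiling(reference_window[2] * rec$fs))
  if (i1 <= i0) stop("reference window outside recording")
  bad <- which(rec$intensities <= 0, arr.ind = TRUE)
  if (length(bad) > 0) {
    stop(sprintf("non-positive intensity at sample %d, channel %d",
                 bad[1, 1], bad[1, 2]))
  }
  nch <- dim(rec$intensities)[2]; nwl <- dim(rec$intensities)[3]
  reference <- matrix(0, nch, nwl)
  od <- array(0, dim(rec$intensities))
  for (c in seq_len(nch)) {
    for (w in seq_len(nwl)) {
      r <- mean(rec$intensities[i0:i1, c, w])
      reference[c, w] <- r
      od[, c, w] <- -log10(rec$intensities[, c, w] / r)
    }
  }
  structure(list(od = od, fs = rec$fs, reference = reference,
                 montage = rec$montage, events = rec$events, meta = rec$meta),
            class = "optical_density")
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per sample and channel, the overdetermined system
#' `od(lambda) = extinction(lambda, .) %*% dC * dpf(lambda) * L` in the
#' least-squares sense (4 wavelengths, 2 chromophores).
#'
#' @param od An `optical_density` object from [intensity_to_od()].
#' @param params [mbll_params()]; defaults to the montage's geometry with the
#'   shipped extinction table.
#' @return A [hemo_series()] in micromolar, tagged `"NR"`.
#' @export
od_to_hemoglobin <- function(od, params = NULL) {
  if (is.null(params)) params <- mbll_params_for(od$montage)
  n <- dim(od$od)[1]; nch <- dim(od$od)[2]
  o2hb <- hhb <- matrix(0, n, nch)
  for (c in seq_len(nch)) {
    a <- mbll_matrix(params, c)
    pinv <- solve(crossprod(a), t(a))          # 2 x n_wavelengths
    dc <- od$od[, c, ] %*% t(pinv)
    o2hb[, c] <- dc[, 1]
    hhb[, c] <- dc[, 2]
  }
  hemo_series(o2hb, hhb, od$fs, od$montage, od$events, tag = "NR")
}
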