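#' Activation analysis of one recording
#'
#' Runs the offline chain on a raw recording (motion correction, MBLL, FIR
#' band-pass), then fits the GLM per long channel and chromophore twice: once
#' on the unregressed data (`NR`) and once with all quality-passing short
#' channels as non-negative nuisance regressors (`SCR`, the multichannel
#' short-channel regression). Task regressors are band-passed like the data.
#' Channel t-values and canonical-amplitude estimates are returned in tidy
#' form; ROI values are the mean of each ROI's two channels.
#'
#' @param rec A [nirs_recording()].
#' @param tags Which fits to run: subset of `c("NR", "SCR")`.
#' @param motion_correct Passed to [preprocess_recording()].
#' @param low,high,order Band-pass settings.
#' @param sc_threshold_db Short-channel quality threshold (dB).
#' @param quality Compute the [quality_report()] and use it to screen short
#'   channels (default TRUE; disable for noise-free simulations whose
#'   spectral quality metrics are degenerate).
#' @return List of class `activation_fit`: `channel` (tidy data.frame with
#'   one row per tag x chromophore x condition x long channel: `t`, `beta`),
#'   `roi` (same aggregated to ROIs), `quality` ([quality_report()] or NULL).
#' @export
fit_activation <- function(rec, tags = c("NR", "SCR"), motion_correct = TRUE,
                           low = 0.015, high = 0.35, order = 1000,
                           sc_threshold_db = 12, quality = TRUE) {
  pre <- preprocess_recording(rec, motion_correct = motion_correct,
                              low = low, high = high, order = order)
  qr_ <- if (quality) quality_report(rec, pre$hemo_raw, sc_threshold_db)
  hemo <- pre$hemo
  montage <- rec$montage
  li <- long_channels(montage)
  si <- short_channels(montage)
  n <- nrow(hemo$o2hb)
  filt <- function(x) bandpass_fir(x, low, high, order, fs = rec$fs)
  rows <- list()
  for (tag in tags) {
    for (chrom in c("o2hb", "hhb")) {
      shorts <- NULL
      qdb <- NULL
      if (tag == "SCR") {
        shorts <- hemo[[chrom]][, si, drop = FALSE]
        qdb <- if (quality) qr_$short_channels$quality_db
      }
      des <- build_design(rec$events, n, rec$fs, short_channels = shorts,
                          short_quality_db = qdb,
                          quality_threshold = sc_threshold_db,
                          filter_fn = filt, tag = tag)
      for (ch in li) {
        fit <- fit_glm_nnls(hemo[[chrom]][, ch], des)
        for (cond in names(des$canonical_cols)) {
          rows[[length(rows) + 1]] <- data.frame(
            subject = rec$meta$subject, session = rec$meta$session,
            run = rec$meta$run, tag = tag, chromophore = chrom,
            condition = cond, channel = ch,
            roi = montage$channels$roi_id[ch],
            t = t_value(fit, des, cond),
            beta = fit$beta[[des$canonical_cols[[cond]]]])
        }
      }
    }
  }
  channel <- do.call(rbind, rows)
  rownames(channel) <- NULL
  roi <- stats::aggregate(cbind(t, beta) ~ subject + session + run + tag +
                            chromophore + condition + roi,
                          data = channel, FUN = mean)
  structure(list(channel = channel, roi = roi, quality = qr_),
            class = "activation_fit")
}

#' Activation table for a whole study
#'
#' Applies [fit_activation()] to every recording of a simulated (or loaded)
#' study. For the default 15-subject study the channelwise table has
#' 1920 rows per chromophore and tag (15 subjects x 16 channels x 2 hands x
#' 2 runs x 2 sessions).
#'
#' @param study A `nirs_study` from [simulate_study()], or a list of
#'   recordings.
#' @param ... Passed to [fit_activation()].
#' @param progress Print one line per recording.
#' @return List of class `activation_table`: `channel`, `roi` (tidy
#'   data.frames over all recordings), `quality` (per-recording data.frame
#'   with screening flag, SNR, Mayer amplitude, short-channel pass rate).
#' @export
activation_table <- function(study, ..., progress = FALSE) {
  recs <- if (inherits(study, "nirs_study")) study$recordings else study
  ch_l <- roi_l <- q_l <- list()
  for (key in names(recs)) {
    if (progress) message("fitting ", key)
    af <- fit_activation(recs[[key]], ...)
    ch_l[[key]] <- af$channel
    roi_l[[key]] <- af$roi
    m <- recs[[key]]$meta
    if (!is.null(af$quality)) {
      q_l[[key]] <- data.frame(
        subject = m$subject, session = m$session, run = m$run,
        mean_intensity = af$quality$signal$mean_intensity,
        snr_db = af$quality$signal$snr_db,
        screening_pass = af$quality$screening_pass,
        mayer_amplitude = af$quality$mayer_amplitude,
        short_pass_rate = mean(af$quality$short_channels$pass))
    }
  }
  out <- list(channel = do.call(rbind, ch_l),
              roi = do.call(rbind, roi_l),
              quality = do.call(rbind, q_l))
  rownames(out$channel) <- rownames(out$roi) <- rownames(out$quality) <- NULL
  class(out) <- "activation_table"
  out
}

#' Label a subject as strong or weak responder
#'
#' The maximal t-value over channels and conditions of each run is averaged
#' over the subject's four runs; the subject is a strong responder iff the
#' average strictly exceeds the threshold (default 30, the SCR baseline
#' threshold; a value exactly at the threshold is weak).
#'
#' @param tbl Channelwise activation data.frame (from [activation_table()]).
#' @param subject Subject id.
#' @param threshold Numeric threshold (default 30).
#' @param tag,chromophore Which slice of the table to use.
#' @return `"strong"` or `"weak"`.
#' @export
label_responder <- function(tbl, subject, threshold = 30, tag = "SCR",
                            chromophore = "o2hb") {
  sub <- tbl[tbl$subject == subject & tbl$tag == tag &
               tbl$chromophore == chromophore, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for subject ", subject)
  runs <- unique(sub[, c("session", "run")])
  expected <- expand.grid(session = 1:2, run = 1:2)
  missing <- !apply(expected, 1, function(e) {
    any(runs$session == e[1] & runs$run == e[2])
  })
  if (any(missing)) {
    stop("missing runs for subject ", subject, ": ",
         paste(sprintf("session %d run %d", expected$session[missing],
                       expected$run[missing]), collapse = ", "))
  }
  run_max <- stats::aggregate(t ~ session + run, data = sub, FUN = max)
  if (mean(run_max$t) > threshold) "strong" else "weak"
}
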