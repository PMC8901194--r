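#' Simulation configuration
#'
#' Defaults emulate the study protocol this package targets: 15 subjects,
#' 2 sessions x 2 runs, 30 trials (15 left / 15 right) of 16 s with 15-24 s
#' interstimulus intervals, 120 s leading and 60 s trailing rest, sampled at
#' 8.98 Hz. Physiology defaults (in micromolar at the scalp): Mayer-wave
#' oscillation 0.5 around 0.1 Hz with slowly varying amplitude, cardiac
#' pulsation 0.3 at 1-1.3 Hz, random linear drift, AR(1) background. The
#' superficial signal is shared per hemisphere and leaks into long channels
#' with a configurable share (default 0.4). Measurement noise is an additive
#' intensity noise floor of 0.6 mV, which makes a 0.06 V raw signal
#' correspond to a 40 dB SNR; short channels, sampling a much shallower and
#' brighter path, detect `short_intensity_gain` (default 10) times the
#' subject's long-channel light level.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; fixed seed implies identical output.
#' @param ... Overrides for any listed field.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 15, seed = 1, ...) {
  cfg <- list(
    n_subjects = n_subjects, sessions = 2L, runs_per_session = 2L,
    n_trials = 30L, trial_duration = 16, isi_range = c(15, 24),
    baseline_start = 120, baseline_end = 60, fs = 8.98,
    intensity_noise_sd = 6e-4, short_intensity_gain = 10,
    cardiac_freq = c(1.0, 1.3), cardiac_amp = 1.0,
    mayer_freq = c(0.095, 0.11), mayer_amp = 0.5,
    drift_amp = 0.3, background_sd = 0.1,
    superficial_share = 0.4, share_jitter = 0.1,
    short_gain = 1.0, gain_jitter = 0.1,
    hhb_ratio = -0.4, superficial_hhb_ratio = 0.25,
    amplitude_right_m1 = 0.26, amplitude_left_m1 = 0.21,
    seed = seed)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(cfg$trial_duration > 0, cfg$isi_range[1] <= cfg$isi_range[2],
            cfg$fs > 0)
  structure(cfg, class = "sim_config")
}

#' Spatial activation pattern over the 8 ROIs
#'
#' Relative oxyhemoglobin amplitude gain per ROI for one condition:
#' contralateral M1 full strength, adjacent contralateral premotor areas at
#' half, ipsilateral M1 at 0.2, remaining ROIs silent -- the canonical
#' lateralized pattern for unimanual grasping.
#'
#' @param condition `"left"` or `"right"`.
#' @return Numeric vector of length 8 (by ROI id).
#' @export
roi_activation_pattern <- function(condition) {
  g <- numeric(8)
  if (condition == "right") {
    g[1] <- 1; g[2:3] <- 0.5; g[5] <- 0.2
  } else {
    g[5] <- 1; g[6:7] <- 0.5; g[1] <- 0.2
  }
  g
}

#' Default subject profiles
#'
#' Nine strong responders (unit-scale hemodynamic amplitudes, adequate raw
#' intensity) and six weak responders: five with raw mean intensity below the
#' 0.06 V screening threshold (and correspondingly reduced response), one
#' with adequate optics but a near-absent response and high Mayer-wave
#' activity. Drawn from the current RNG state.
#'
#' @param cfg A [sim_config()].
#' @param n_strong,n_weak Group sizes (default 9 / 6).
#' @return List of profiles; each holds `subject_id`, `responder`,
#'   `hrf_scale`, `hrf_amplitude_o2hb` (8 ROIs x 2 conditions, micromolar),
#'   `hrf_amplitude_hhb`, `mw_amplitude`, `raw_mean_intensity` (V),
#'   `session_effect` (length 2).
#' @export
subject_profiles <- function(cfg, n_strong = 9, n_weak = 6) {
  n <- n_strong + n_weak
  base_amp <- cbind(left = cfg$amplitude_left_m1 * roi_activation_pattern("left"),
                    right = cfg$amplitude_right_m1 * roi_activation_pattern("right"))
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= n_strong) {
      responder <- "strong"
      hrf_scale <- exp(stats::rnorm(1, 0, 0.15))
      raw <- min(0.8, max(0.07, exp(stats::rnorm(1, log(0.15), 0.4))))
      mw <- stats::runif(1, 0.5, 1.5)
    } else if (i < n) {
      responder <- "weak"
      hrf_scale <- 0.3 * exp(stats::rnorm(1, 0, 0.2))
      raw <- stats::runif(1, 0.03, 0.055)
      mw <- stats::runif(1, 0.8, 2)
    } else {
      responder <- "weak"           # adequate optics, near-zero response
      hrf_scale <- 0.08
      raw <- 0.12
      mw <- stats::runif(1, 1.5, 2.5)
    }
    amp <- base_amp * hrf_scale
    profiles[[i]] <- list(
      subject_id = i, responder = responder, hrf_scale = hrf_scale,
      hrf_amplitude_o2hb = amp,
      hrf_amplitude_hhb = cfg$hhb_ratio * amp,
      mw_amplitude = mw, raw_mean_intensity = raw,
      session_effect = stats::rnorm(cfg$sessions, 1, 0.08))
  }
  profiles
}

#' Generate one run's block-design protocol
#'
#' 120 s leading rest, then 30 task blocks of 16 s (15 per condition in
#' seeded random order) separated by interstimulus intervals uniform on
#' 15-24 s; the recording extends 60 s past the last offset. Uses the
#' current RNG state.
#'
#' @param cfg A [sim_config()].
#' @return Event table (see [event_blocks()]).
#' @export
make_protocol <- function(cfg) {
  per_cond <- cfg$n_trials %/% 2
  conds <- sample(rep(c("left", "right"), per_cond))
  isi <- stats::runif(cfg$n_trials - 1, cfg$isi_range[1], cfg$isi_range[2])
  onsets <- cfg$baseline_start +
    cumsum(c(0, isi + cfg$trial_duration))
  event_blocks(conds, onsets, rep(cfg$trial_duration, cfg$n_trials))
}

# AR(1) background with ~5 s correlation time and given stationary sd
ar1_background <- function(n, fs, sd) {
  if (sd == 0) return(numeric(n))
  phi <- exp(-1 / (fs * 5))
  x <- numeric(n)
  inn <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + inn[i]
  x
}

# superficial (scalp) oxyhemoglobin trace for one hemisphere
superficial_trace <- function(n, fs, cfg, mw_amplitude) {
  t <- (seq_len(n) - 1) / fs
  f_mw <- stats::runif(1, cfg$mayer_freq[1], cfg$mayer_freq[2])
  ph_mw <- stats::runif(1, 0, 2 * pi)
  ph_mod <- stats::runif(1, 0, 2 * pi)
  mayer <- cfg$mayer_amp * mw_amplitude *
    (1 + 0.3 * sin(2 * pi * 0.013 * t + ph_mod)) * sin(2 * pi * f_mw * t + ph_mw)
  f_c <- stats::runif(1, cfg$cardiac_freq[1], cfg$cardiac_freq[2])
  cardiac <- cfg$cardiac_amp * sin(2 * pi * f_c * t + stats::runif(1, 0, 2 * pi))
  drift <- stats::rnorm(1, 0, cfg$drift_amp) * t / max(t[n], 1)
  mayer + cardiac + drift + ar1_background(n, fs, cfg$background_sd)
}

sim_core <- function(profile, cfg, events, n, session, run) {
  montage <- build_default_montage()
  fs <- cfg$fs
  sess_eff <- profile$session_effect[session]
  nroi <- length(montage$roi_map)
  cortical_o2hb <- matrix(0, n, nroi)
  if (nrow(events) > 0) {
    for (cond in c("left", "right")) {
      reg <- task_regressor(events, n, fs, cond, "canonical")
      for (r in seq_len(nroi)) {
        a <- profile$hrf_amplitude_o2hb[r, cond] * sess_eff
        if (a != 0) cortical_o2hb[, r] <- cortical_o2hb[, r] + a * reg
      }
    }
  }
  cortical_hhb <- cfg$hhb_ratio * cortical_o2hb
  sup_o2hb <- cbind(left = superficial_trace(n, fs, cfg, profile$mw_amplitude),
                    right = superficial_trace(n, fs, cfg, profile$mw_amplitude))
  sup_hhb <- cfg$superficial_hhb_ratio * sup_o2hb

  nch <- nrow(montage$channels)
  o2hb <- hhb <- matrix(0, n, nch)
  shares <- numeric(nch)
  for (c in seq_len(nch)) {
    h <- montage$channels$hemisphere[c]
    if (montage$channels$role[c] == "long") {
      shares[c] <- max(0.05, stats::rnorm(1, cfg$superficial_share,
                                          cfg$share_jitter))
      r <- montage$channels$roi_id[c]
      o2hb[, c] <- cortical_o2hb[, r] + shares[c] * sup_o2hb[, h]
      hhb[, c] <- cortical_hhb[, r] + shares[c] * sup_hhb[, h]
    } else {
      shares[c] <- max(0.1, stats::rnorm(1, cfg$short_gain, cfg$gain_jitter))
      o2hb[, c] <- shares[c] * sup_o2hb[, h]
      hhb[, c] <- shares[c] * sup_hhb[, h]
    }
  }

  params <- mbll_params_for(montage)
  od <- forward_mbll(o2hb, hhb, params)
  nwl <- length(montage$wavelengths)
  intens <- array(0, c(n, nch, nwl))
  for (c in seq_len(nch)) {
    # short channels sample a much shallower, brighter path
    bright <- if (montage$channels$role[c] == "short") {
      cfg$short_intensity_gain
    } else 1
    i0c <- bright * profile$raw_mean_intensity * exp(stats::rnorm(1, 0, 0.1))
    for (w in seq_len(nwl)) {
      i0 <- i0c * exp(stats::rnorm(1, 0, 0.05))
      noise <- if (cfg$intensity_noise_sd > 0) {
        stats::rnorm(n, 0, cfg$intensity_noise_sd)
      } else 0
      intens[, c, w] <- pmax(i0 * 10^(-od[, c, w]) + noise, 1e-6)
    }
  }
  rec <- nirs_recording(intens, fs, montage, events,
                        meta = list(subject = profile$subject_id,
                                    session = session, run = run))
  truth <- list(amplitudes_o2hb = profile$hrf_amplitude_o2hb * sess_eff,
                amplitudes_hhb = profile$hrf_amplitude_hhb * sess_eff,
                cortical_o2hb = cortical_o2hb,
                superficial_o2hb = sup_o2hb,
                shares = shares,
                responder = profile$responder,
                mw_amplitude = profile$mw_amplitude,
                raw_mean_intensity = profile$raw_mean_intensity)
  list(recording = rec, truth = truth)
}

#' Simulate one task run
#'
#' Builds lateralized cortical responses (task boxcar convolved with the
#' canonical HRF, O2Hb positive, HHb at the configured negative ratio), adds
#' the hemisphere-shared superficial physiology with channel-specific gains
#' (full strength into short channels, `superficial_share` into long
#' channels), converts hemoglobin to four-wavelength intensities through the
#' forward modified Beer-Lambert model at the subject's raw signal level, and
#' adds the sensor noise floor. Ground truth is returned alongside.
#'
#' @param profile One profile from [subject_profiles()].
#' @param cfg A [sim_config()].
#' @param session,run Indices stored in the metadata.
#' @param seed Optional seed for standalone use; inside [simulate_study()]
#'   the study RNG stream is used.
#' @return List with `recording` ([nirs_recording()]) and `truth`.
#' @export
simulate_recording <- function(profile, cfg, session = 1, run = 1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  events <- make_protocol(cfg)
  n <- ceiling((max(events$onset + events$duration) + cfg$baseline_end) *
                 cfg$fs)
  sim_core(profile, cfg, events, n, session, run)
}

#' Simulate a rest recording (no task)
#'
#' Same physiology and noise model as [simulate_recording()] but without any
#' task events; used to derive baseline activation thresholds.
#'
#' @inheritParams simulate_recording
#' @param duration Length in seconds.
#' @return List with `recording` and `truth`.
#' @export
simulate_rest_recording <- function(profile, cfg, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- event_blocks(character(0), numeric(0), numeric(0))
  sim_core(profile, cfg, ev, ceiling(duration * cfg$fs), 1, 1)
}

#' Simulate a full test-retest study
#'
#' `n_subjects x 2 sessions x 2 runs` recordings with per-session amplitude
#' effects, plus a manifest of the generating ground truth. Byte-identical
#' for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param profiles Optional list of profiles; defaults to
#'   [subject_profiles()] drawn from the study seed.
#' @return Object of class `nirs_study`: `recordings` (named list),
#'   `truth` (parallel list), `profiles`, `manifest` (data.frame), `config`.
#' @export
simulate_study <- function(cfg = sim_config(), profiles = NULL) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)
  if (is.null(profiles)) {
    n_weak <- round(cfg$n_subjects * 6 / 15)
    profiles <- subject_profiles(cfg, cfg$n_subjects - n_weak, n_weak)
  }
  recordings <- list()
  truth <- list()
  rows <- list()
  for (p in profiles) {
    for (s in seq_len(cfg$sessions)) {
      for (r in seq_len(cfg$runs_per_session)) {
        key <- sprintf("s%02d_sess%d_run%d", p$subject_id, s, r)
        sim <- simulate_recording(p, cfg, session = s, run = r)
        recordings[[key]] <- sim$recording
        truth[[key]] <- sim$truth
        rows[[key]] <- data.frame(
          subject = p$subject_id, session = s, run = r,
          responder = p$responder, hrf_scale = p$hrf_scale,
          raw_mean_intensity = p$raw_mean_intensity,
          mw_amplitude = p$mw_amplitude,
          session_effect = p$session_effect[s])
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(recordings = recordings, truth = truth,
                 profiles = profiles, manifest = manifest, config = cfg),
            class = "nirs_study")
}

#' @export
print.nirs_study <- function(x, ...) {
  cat(sprintf("fNIRS study: %d subjects x %d sessions x %d runs (%d recordings)\n",
              x$config$n_subjects, x$config$sessions,
              x$config$runs_per_session, length(x$recordings)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One recording file/bundle per run plus `manifest.csv` and
#' `ground_truth.json` (profiles and per-recording generating amplitudes).
#'
#' @param study A `nirs_study`.
#' @param dir Output directory.
#' @param dialect Passed to [write_recording()].
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, dialect = c("csv_bundle", "snirf")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (key in names(study$recordings)) {
    path <- file.path(dir, if (dialect == "snirf") paste0(key, ".snirf") else key)
    write_recording(study$recordings[[key]], path, dialect)
  }
  utils::write.csv(study$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- lapply(study$truth, function(tr) {
    tr[c("amplitudes_o2hb", "amplitudes_hhb", "shares", "responder",
         "mw_amplitude", "raw_mean_intensity")]
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
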