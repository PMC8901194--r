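#' Causal (forward-only) band-pass for pseudo-online processing
#'
#' High-pass Chebyshev type II of order 2 at 0.005 Hz (20 dB stop-band
#' attenuation) followed by a low-pass Butterworth of order 4 at 0.35 Hz,
#' both applied forward only, so the output at time t never uses future
#' samples.
#'
#' @param x Numeric vector/matrix, or a [hemo_series()].
#' @param fs Sampling rate (taken from the object if a `hemo_series`).
#' @param low,high Cutoffs in Hz.
#' @param stop_atten_db Chebyshev stop-band attenuation (dB).
#' @return Filtered object of the same shape/class.
#' @export
causal_filter <- function(x, fs = NULL, low = 0.005, high = 0.35,
                          stop_atten_db = 20) {
  if (inherits(x, "hemo_series")) {
    out <- x
    out$o2hb <- causal_filter(x$o2hb, x$fs, low, high, stop_atten_db)
    out$hhb <- causal_filter(x$hhb, x$fs, low, high, stop_atten_db)
    return(out)
  }
  stopifnot(!is.null(fs))
  if (high >= fs / 2 || low >= fs / 2) stop("cutoff at or above Nyquist")
  hp <- signal::cheby2(2, stop_atten_db, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  f1 <- function(v) {
    v <- signal::filter(hp, v)
    as.numeric(signal::filter(lp, v))
  }
  if (is.matrix(x)) apply(x, 2, f1) else f1(as.numeric(x))
}

#' Sample-wise adaptive non-negative short-channel regression
#'
#' Streaming regression of the short-channel signals out of one long channel:
#' at each sample the prediction `w' s_t` is subtracted from the long channel
#' and the weights are updated by normalized least-mean-squares, then
#' projected onto the non-negative orthant. Causal by construction.
#'
#' @param long Numeric vector (one long channel).
#' @param shorts Matrix `[n x n_short]` aligned with `long`.
#' @param step NLMS learning rate (> 0, default 0.01).
#' @return List with `regressed` (cleaned stream) and `weights`
#'   (`[n x n_short]` weight trace).
#' @export
adaptive_scr <- function(long, shorts, step = 0.01) {
  if (step <= 0) stop("step must be positive")
  shorts <- as.matrix(shorts)
  n <- length(long)
  stopifnot(nrow(shorts) == n)
  p <- ncol(shorts)
  w <- numeric(p)
  out <- numeric(n)
  trace <- matrix(0, n, p)
  # normalize by a smoothed power estimate: the instantaneous regressor power
  # vanishes at zero crossings and would blow the update up
  pw <- max(sum(shorts[1, ]^2), 1e-12)
  for (i in seq_len(n)) {
    s <- shorts[i, ]
    pw <- 0.99 * pw + 0.01 * sum(s * s)
    e <- long[i] - sum(w * s)
    out[i] <- e
    w <- pmax(0, w + step * e * s / (pw + 1e-12))
    trace[i, ] <- w
  }
  list(regressed = out, weights = trace)
}

#' Correlation-based signal improvement (CBSI) trace
#'
#' `x = (dO2Hb - sigma * dHHb) / 2` with `sigma = sd(dO2Hb)/sd(dHHb)`
#' computed over the same window, exploiting the anti-correlation of the two
#' chromophores during activation.
#'
#' @param o2hb,hhb Numeric vectors over one trial window.
#' @return Combined trace, same length.
#' @export
cbsi_trace <- function(o2hb, hhb) {
  s_h <- stats::sd(hhb)
  sigma <- if (s_h == 0) 0 else stats::sd(o2hb) / s_h
  (o2hb - sigma * hhb) / 2
}

#' Per-trial classification features
#'
#' For every channel of the supplied series and the 16 s trial window:
#' amplitude (window mean minus the value at onset) and slope (least-squares
#' line, per second) of each chromophore, plus the mean of the CBSI trace --
#' five features per channel.
#'
#' @param o2hb,hhb Matrices `[n x n_channels]`.
#' @param fs Sampling rate (Hz).
#' @param trial One event (list/row with `onset`, `duration`).
#' @return Named numeric feature vector.
#' @export
extract_features <- function(o2hb, hhb, fs, trial) {
  n <- nrow(o2hb)
  i0 <- floor(trial$onset * fs) + 1
  i1 <- floor((trial$onset + trial$duration) * fs)
  if (i1 > n) stop("trial window extends past the recording")
  idx <- i0:i1
  tt <- (idx - i0) / fs
  feats <- list()
  for (ch in seq_len(ncol(o2hb))) {
    o <- o2hb[idx, ch]; h <- hhb[idx, ch]
    sl <- function(y) sum((tt - mean(tt)) * (y - mean(y))) /
      sum((tt - mean(tt))^2)
    feats[[sprintf("ch%02d_o2hb_amplitude", ch)]] <- mean(o) - o[1]
    feats[[sprintf("ch%02d_hhb_amplitude", ch)]] <- mean(h) - h[1]
    feats[[sprintf("ch%02d_o2hb_slope", ch)]] <- sl(o)
    feats[[sprintf("ch%02d_hhb_slope", ch)]] <- sl(h)
    feats[[sprintf("ch%02d_cbsi", ch)]] <- mean(cbsi_trace(o, h))
  }
  unlist(feats)
}

#' Trial dataset for one run
#'
#' Runs the pseudo-online chain on an unfiltered hemoglobin series: causal
#' band-pass, then -- depending on the source -- adaptive non-negative
#' short-channel regression (`"SCR"`), plain long channels (`"LS_only"`) or
#' the short channels themselves (`"SS_only"`, a control that should carry no
#' task information), and extracts per-trial features.
#'
#' @param hemo_raw Unfiltered [hemo_series()] with task events.
#' @param source `"SCR"`, `"LS_only"` or `"SS_only"`.
#' @param step NLMS learning rate for the adaptive regression.
#' @return List of class `trial_dataset`: `features` (matrix trials x
#'   features), `labels` (factor left/right), `source`.
#' @export
bci_trial_dataset <- function(hemo_raw, source = c("SCR", "LS_only",
                                                   "SS_only"),
                              step = 0.01) {
  source <- match.arg(source)
  filt <- causal_filter(hemo_raw)
  li <- long_channels(hemo_raw$montage)
  si <- short_channels(hemo_raw$montage)
  pick <- function(mat) {
    if (source == "SS_only") return(mat[, si, drop = FALSE])
    if (source == "LS_only") return(mat[, li, drop = FALSE])
    ss <- mat[, si, drop = FALSE]
    vapply(li, function(ch) adaptive_scr(mat[, ch], ss, step)$regressed,
           numeric(nrow(mat)))
  }
  o2 <- pick(filt$o2hb)
  hh <- pick(filt$hhb)
  ev <- hemo_raw$events
  ev <- ev[ev$condition %in% c("left", "right"), , drop = FALSE]
  feats <- t(vapply(seq_len(nrow(ev)),
                    function(i) extract_features(o2, hh, hemo_raw$fs,
                                                 ev[i, ]),
                    extract_features(o2, hh, hemo_raw$fs, ev[1, ])))
  structure(list(features = feats,
                 labels = factor(ev$condition, levels = c("left", "right")),
                 source = source),
            class = "trial_dataset")
}

#' Train the sparse linear classifier
#'
#' L1-regularized linear model (lasso-penalized logistic regression via
#' glmnet) for joint training and feature selection, the features
#' standardized with training statistics and the penalty chosen by stratified
#' seeded 5-fold cross-validation over a 10-point log-spaced grid.
#'
#' @param train A `trial_dataset` (>= 10 trials, both classes present).
#' @param seed Seed for the CV fold assignment.
#' @param lambda_grid Penalty grid (default `10^seq(2, -3, length = 10)`).
#' @return List of class `bci_model`.
#' @export
train_classifier <- function(train, seed = 1,
                             lambda_grid = 10^seq(2, -3, length.out = 10)) {
  x <- train$features
  y <- train$labels
  if (nrow(x) < 10) stop("need at least 10 training trials")
  if (length(unique(y)) < 2) stop("both classes must be present")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  foldid <- integer(nrow(x))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(1:5, length(idx))
  }
  # 5-fold CV on 30 trials leaves 3 per class per fold; glmnet warns about
  # the small folds, which is inherent to the trial budget of a single run
  cv <- suppressWarnings(
    glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                      lambda = lambda_grid, foldid = foldid,
                      type.measure = "class", standardize = FALSE))
  coefs <- as.numeric(stats::coef(cv, s = cv$lambda.min))[-1]
  structure(list(cv = cv, lambda = cv$lambda.min, center = ctr, scale = scl,
                 feature_names = colnames(x),
                 n_selected = sum(abs(coefs) > 1e-8),
                 levels = levels(y)),
            class = "bci_model")
}

#' Predict trial labels
#'
#' @param object A `bci_model`.
#' @param newdata Feature matrix or `trial_dataset`.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.bci_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "trial_dataset")) newdata$features else newdata
  if (!identical(colnames(x), object$feature_names)) {
    stop("feature-name mismatch between training and test data")
  }
  xs <- scale(x, object$center, object$scale)
  pr <- stats::predict(object$cv, xs, s = object$lambda, type = "class")
  factor(as.character(pr), levels = object$levels)
}

#' Evaluate a classifier on the held-out run
#'
#' Accuracy over the test run's 30 trials (one decision per trial at window
#' end) and the significance flag against the configured accuracy line.
#'
#' @param model A `bci_model` trained on run 1.
#' @param test `trial_dataset` of run 2.
#' @param line Significance line in percent (default 70, the 1% level above
#'   chance for 30 trials as used in the study's display convention; see
#'   [significance_line()] for the exact binomial value).
#' @return List of class `classifier_result`: `predictions`, `accuracy`
#'   (percent), `n_selected`, `lambda`, `significant`.
#' @export
evaluate_session <- function(model, test, line = 70) {
  pred <- predict(model, test)
  acc <- 100 * mean(pred == test$labels)
  structure(list(predictions = pred, accuracy = acc,
                 n_selected = model$n_selected, lambda = model$lambda,
                 significant = acc >= line),
            class = "classifier_result")
}

#' Exact binomial significance line for a two-class accuracy
#'
#' Smallest accuracy k/n whose one-sided binomial tail probability under
#' chance (p = 0.5) does not exceed `alpha`, in percent.
#'
#' @param n_trials Number of test trials.
#' @param alpha Significance level.
#' @return Accuracy threshold in percent.
#' @export
significance_line <- function(n_trials, alpha = 0.01) {
  stopifnot(n_trials >= 1, alpha > 0, alpha < 1)
  k <- which(1 - stats::pbinom(0:n_trials - 1, n_trials, 0.5) <= alpha)[1] - 1
  100 * k / n_trials
}

#' Train-on-run-1, test-on-run-2 evaluation for one subject and session
#'
#' @param study A `nirs_study`.
#' @param subject,session Which recordings to use.
#' @param source Input signals for the classifier (see
#'   [bci_trial_dataset()]).
#' @param seed CV seed.
#' @param line Significance line (percent).
#' @return A `classifier_result`.
#' @export
bci_evaluate <- function(study, subject, session,
                         source = c("SCR", "LS_only", "SS_only"),
                         seed = 1, line = 70) {
  source <- match.arg(source)
  key <- function(run) sprintf("s%02d_sess%d_run%d", subject, session, run)
  mk <- function(run) {
    rec <- study$recordings[[key(run)]]
    if (is.null(rec)) stop("missing recording ", key(run))
    od <- intensity_to_od(rec)
    bci_trial_dataset(od_to_hemoglobin(od), source)
  }
  train <- mk(1)
  test <- mk(2)
  model <- train_classifier(train, seed = seed)
  evaluate_session(model, test, line = line)
}
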