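#' Peak-normalized task regressor
#'
#' Boxcar of one condition's blocks convolved with an HRF kernel. The
#' canonical regressor is scaled to unit peak so its GLM coefficient reads
#' directly in the data's concentration units (micromolar); derivative kernels
#' are scaled by the same factor. The simulator builds its cortical signals
#' with the identical function, so a noise-free round trip recovers the
#' generating amplitude exactly.
#'
#' @param events Event table.
#' @param n_samples,fs Series length and sampling rate.
#' @param condition Condition label.
#' @param kind HRF kernel kind, see [canonical_hrf()].
#' @return Numeric vector of length `n_samples`.
#' @export
task_regressor <- function(events, n_samples, fs, condition,
                           kind = "canonical") {
  box <- numeric(n_samples)
  sel <- events$condition == condition
  for (i in which(sel)) {
    i0 <- floor(events$onset[i] * fs) + 1
    i1 <- min(n_samples, ceiling((events$onset[i] + events$duration[i]) * fs))
    if (i0 <= n_samples) box[i0:i1] <- 1
  }
  tk <- seq(0, 32, by = 1 / fs)
  kern <- canonical_hrf(tk, kind)
  ref <- convolve_causal(box, canonical_hrf(tk, "canonical"))
  peak <- max(abs(ref))
  if (peak == 0) return(numeric(n_samples))
  convolve_causal(box, kern) / peak
}

convolve_causal <- function(x, kernel) {
  fast_conv(x, kernel)[seq_len(length(x))]
}

#' Build a GLM design matrix
#'
#' Per condition: canonical HRF regressor plus temporal and dispersion
#' derivative columns (orthogonalized against the canonical column so the
#' canonical coefficient keeps its amplitude meaning); then the optional
#' mean-centered short-channel nuisance series, flagged for the non-negativity
#' constraint; then a constant. With an empty event list the design degrades
#' to constant + nuisance (baseline mode).
#'
#' Short channels failing the quality threshold are dropped with a warning;
#' requesting short-channel regression with zero usable channels is an error.
#'
#' @param events Event table (may be empty).
#' @param n_samples,fs Length and sampling rate of the series to be fitted.
#' @param short_channels Optional matrix `[n_samples x n_short]` of short
#'   channel series of the matching chromophore (already filtered like the
#'   data).
#' @param short_quality_db Optional per-short-channel quality (dB) used to
#'   exclude bad channels.
#' @param quality_threshold Exclusion threshold (default 12 dB).
#' @param conditions Conditions to model.
#' @param filter_fn Optional function applied to each task column (use the
#'   same band-pass as applied to the data).
#' @param tag `"NR"` or `"SCR"`, recorded on the design.
#' @return List of class `glm_design` with `X`, `nonneg_mask`,
#'   `canonical_cols`, `fs`, `tag`.
#' @export
build_design <- function(events, n_samples, fs, short_channels = NULL,
                         short_quality_db = NULL, quality_threshold = 12,
                         conditions = c("left", "right"), filter_fn = NULL,
                         tag = if (is.null(short_channels)) "NR" else "SCR") {
  cols <- list()
  canonical_cols <- list()
  present <- intersect(conditions, unique(events$condition))
  for (cond in present) {
    block <- sapply(c("canonical", "temporal_derivative",
                      "dispersion_derivative"),
                    function(k) task_regressor(events, n_samples, fs, cond, k))
    if (!is.null(filter_fn)) block <- apply(block, 2, filter_fn)
    # orthogonalize derivatives against canonical (and each other), unit norm
    for (j in 2:3) {
      for (i in 1:(j - 1)) {
        block[, j] <- block[, j] -
          block[, i] * sum(block[, j] * block[, i]) / sum(block[, i]^2)
      }
      nrm <- sqrt(sum(block[, j]^2))
      if (nrm > 0) block[, j] <- block[, j] / nrm
    }
    colnames(block) <- paste(cond, c("canonical", "tderiv", "dderiv"),
                             sep = "_")
    canonical_cols[[cond]] <- paste0(cond, "_canonical")
    cols[[cond]] <- block
  }
  X <- do.call(cbind, cols)
  nonneg <- rep(FALSE, if (is.null(X)) 0 else ncol(X))
  if (!is.null(short_channels)) {
    ss <- as.matrix(short_channels)
    keep <- seq_len(ncol(ss))
    if (!is.null(short_quality_db)) {
      bad <- which(short_quality_db < quality_threshold)
      if (length(bad) > 0) {
        warning("excluding ", length(bad),
                " short channel(s) below the quality threshold")
        keep <- setdiff(keep, bad)
      }
    }
    if (length(keep) == 0) {
      stop("short-channel regression requested but no usable short channels")
    }
    ss <- ss[, keep, drop = FALSE]
    ss <- sweep(ss, 2, colMeans(ss))
    colnames(ss) <- paste0("ss", keep)
    X <- if (is.null(X)) ss else cbind(X, ss)
    nonneg <- c(nonneg, rep(TRUE, ncol(ss)))
  }
  X <- cbind(X, constant = 1)
  nonneg <- c(nonneg, FALSE)
  structure(list(X = X, nonneg_mask = nonneg,
                 canonical_cols = canonical_cols, fs = fs, tag = tag),
            class = "glm_design")
}

#' Baseline-derived activation threshold
#'
#' Fits the full task protocol at random temporal shifts within rest data
#' (no task events, hence no evoked response) and returns the 95th percentile
#' of the absolute null t-values -- the level below which a t-value is, with
#' 95% probability, explainable by rest physiology alone. With no rest data
#' supplied, the shipped defaults are returned: 30 for SCR and 22 for
#' unregressed data (levels derived from the original study's baseline
#' recordings).
#'
#' @param rest A filtered [hemo_series()] of rest data (no events), or NULL.
#' @param events_template Protocol to place (event table, onsets relative to
#'   protocol start).
#' @param n_draws Number of random placements (>= 100).
#' @param tag `"NR"` or `"SCR"`.
#' @param short_channels Matrix of filtered short-channel series matching
#'   `rest` (required for SCR).
#' @param chromophore `"o2hb"` or `"hhb"`.
#' @param probability Quantile of the absolute null distribution.
#' @param filter_fn Filter applied to task regressors (match the data).
#' @return List with `threshold` and the vector of null `t` values
#'   (`t_null`); with `rest = NULL`, the default threshold with empty
#'   `t_null`.
#' @export
baseline_threshold <- function(rest = NULL, events_template = NULL,
                               n_draws = 500, tag = c("SCR", "NR"),
                               short_channels = NULL,
                               chromophore = c("o2hb", "hhb"),
                               probability = 0.95, filter_fn = NULL) {
  tag <- match.arg(tag)
  chromophore <- match.arg(chromophore)
  if (is.null(rest)) {
    return(list(threshold = if (tag == "SCR") 30 else 22,
                t_null = numeric(0), tag = tag))
  }
  if (nrow(rest$events) > 0) stop("rest series must contain no task events")
  if (n_draws < 100) stop("n_draws must be at least 100")
  n <- nrow(rest$o2hb)
  fs <- rest$fs
  protocol_end <- max(events_template$onset + events_template$duration) + 60
  max_shift <- n - ceiling(protocol_end * fs)
  if (max_shift < 1) {
    stop("rest data too short for the protocol (need > ",
         round(protocol_end), " s)")
  }
  base <- build_design(events_template, n, fs,
                       short_channels = if (tag == "SCR") short_channels,
                       filter_fn = filter_fn, tag = tag)
  task_idx <- which(grepl("_(canonical|tderiv|dderiv)$", colnames(base$X)))
  conds <- names(base$canonical_cols)
  li <- long_channels(rest$montage)
  y_all <- rest[[chromophore]]
  t_null <- numeric(0)
  shifts <- sample.int(max_shift, n_draws, replace = TRUE)
  for (d in seq_len(n_draws)) {
    s <- shifts[d]
    des <- base
    des$X[, task_idx] <- rbind(
      matrix(0, s, length(task_idx)),
      base$X[seq_len(n - s), task_idx, drop = FALSE])
    y <- y_all[, li[(d - 1) %% length(li) + 1]]
    fit <- fit_glm_nnls(y, des)
    t_null <- c(t_null,
                vapply(conds, function(cc) t_value(fit, des, cc), numeric(1)))
  }
  list(threshold = as.numeric(stats::quantile(abs(t_null), probability)),
       t_null = t_null, tag = tag)
}
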