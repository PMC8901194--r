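#' Session-pair table for one analysis block
#'
#' Extracts, per subject, the session-1 and session-2 t-values of one ROI,
#' chromophore, condition and processing tag, averaging the two runs within
#' each session.
#'
#' @param roi_tbl ROI-level activation data.frame (from [activation_table()]).
#' @param roi ROI id.
#' @param chromophore,condition,tag Block selectors.
#' @return `data.frame` with columns `subject`, `session1`, `session2`.
#' @export
session_pair_table <- function(roi_tbl, roi, chromophore, condition, tag) {
  sub <- roi_tbl[roi_tbl$roi == roi & roi_tbl$chromophore == chromophore &
                   roi_tbl$condition == condition & roi_tbl$tag == tag, ]
  if (nrow(sub) == 0) stop("no rows for the requested block")
  agg <- stats::aggregate(t ~ subject + session, data = sub, FUN = mean)
  s1 <- agg[agg$session == 1, ]
  s2 <- agg[agg$session == 2, ]
  m <- merge(s1[, c("subject", "t")], s2[, c("subject", "t")],
             by = "subject", suffixes = c("_1", "_2"))
  data.frame(subject = m$subject, session1 = m$t_1, session2 = m$t_2)
}

#' Between-session Pearson correlation
#'
#' Pearson r between session-1 and session-2 values with the Fisher-z 95%
#' confidence interval and two-sided p-value.
#'
#' @param tbl A [session_pair_table()] (needs >= 3 subjects).
#' @return List with `r`, `ci` (length 2), `p`, `n`.
#' @export
session_correlation <- function(tbl) {
  stopifnot(nrow(tbl) >= 3)
  if (stats::sd(tbl$session1) == 0 || stats::sd(tbl$session2) == 0) {
    stop("zero variance in a session column")
  }
  ct <- stats::cor.test(tbl$session1, tbl$session2)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = nrow(tbl))
}

icc_bin <- function(icc) {
  if (icc < 0.40) "poor"
  else if (icc < 0.60) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Intraclass correlation, two-way random, absolute agreement
#'
#' ICC(2,1) (single measures) and ICC(2,k) (average measures) from the
#' two-way ANOVA decomposition of a subjects x sessions table:
#' `ICC(2,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k/n (MS_C - MS_E))`,
#' with the average-measures analog, and 95% confidence intervals from the
#' F-distribution (absolute-agreement formulas with Satterthwaite degrees of
#' freedom; the average-measure CI follows by the Spearman-Brown step-up).
#' Interpretation bins: poor (<0.40), fair (0.40-0.60), good (0.60-0.75),
#' excellent (0.75-1.00).
#'
#' @param tbl A [session_pair_table()], or a matrix `[n_subjects x k]`.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_result`: `icc_single`, `icc_average`,
#'   `ci_single`, `ci_average`, `n_subjects`, `k_sessions`,
#'   `interpretation` (of the single measure), and the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`).
#' @export
icc_two_way_random <- function(tbl, conf_level = 0.95) {
  x <- if (is.data.frame(tbl)) {
    as.matrix(tbl[, c("session1", "session2")])
  } else {
    as.matrix(tbl)
  }
  n <- nrow(x); k <- ncol(x)
  stopifnot(all(is.finite(x)))
  if (n < 3) stop("ICC needs at least 3 subjects")
  if (k != 2) warning("study design has k = 2 sessions; got k = ", k)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  alpha <- 1 - conf_level
  # Satterthwaite dof for the absolute-agreement single-measure CI
  fj <- msc / mse
  a <- (k * icc1) / (n * (1 - icc1))
  b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  res <- list(icc_single = icc1, icc_average = icck,
              ci_single = c(lo1, hi1), ci_average = c(sb(lo1), sb(hi1)),
              n_subjects = n, k_sessions = k,
              interpretation = icc_bin(icc1),
              ms_rows = msr, ms_cols = msc, ms_error = mse)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f [%.3f, %.3f] (%s); ICC(2,%d) = %.3f [%.3f, %.3f]\n",
              x$icc_single, x$ci_single[1], x$ci_single[2], x$interpretation,
              x$k_sessions, x$icc_average, x$ci_average[1], x$ci_average[2]))
  invisible(x)
}

#' Mean absolute scaled error between sessions
#'
#' `100 * mean(|session2 - session1|) / (max - min)` where the range is taken
#' over the pooled values of both sessions. Invariant to adding a constant;
#' scales correctly under multiplication.
#'
#' @param tbl A [session_pair_table()].
#' @return MAE in percent.
#' @export
mae_percent <- function(tbl) {
  pooled <- c(tbl$session1, tbl$session2)
  rng <- max(pooled) - min(pooled)
  if (rng == 0) stop("zero range of observed values")
  100 * mean(abs(tbl$session2 - tbl$session1)) / rng
}

#' Test-retest reproducibility report
#'
#' For each chromophore x condition x tag block, selects the contralateral
#' primary-motor ROI (ROI 1 for the right hand, ROI 5 for the left), averages
#' runs within session, and computes the between-session Pearson correlation,
#' ICC(2,1)/ICC(2,k) with confidence intervals, and MAE% -- eight rows for
#' the default two-tag analysis.
#'
#' @param roi_tbl ROI-level activation data.frame.
#' @param tags Processing tags to report.
#' @return `data.frame` of class `repro_report`, one row per block.
#' @export
reproducibility_report <- function(roi_tbl, tags = c("NR", "SCR")) {
  rows <- list()
  for (tag in tags) {
    for (chrom in c("o2hb", "hhb")) {
      for (cond in c("left", "right")) {
        roi <- contralateral_m1_roi(cond)
        tbl <- session_pair_table(roi_tbl, roi, chrom, cond, tag)
        sc <- session_correlation(tbl)
        icc <- icc_two_way_random(tbl)
        rows[[length(rows) + 1]] <- data.frame(
          tag = tag, chromophore = chrom, condition = cond, roi = roi,
          n = sc$n, r = sc$r, r_lo = sc$ci[1], r_hi = sc$ci[2], p = sc$p,
          icc_single = icc$icc_single,
          icc_single_lo = icc$ci_single[1], icc_single_hi = icc$ci_single[2],
          icc_average = icc$icc_average,
          icc_average_lo = icc$ci_average[1],
          icc_average_hi = icc$ci_average[2],
          interpretation = icc$interpretation,
          mae_percent = mae_percent(tbl))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("repro_report", class(out))
  out
}
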