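test_that("the causal filter never uses future samples and shapes the band", {
  fs <- 8.98
  set.seed(29)
  x <- rnorm(3000)
  y_full <- causal_filter(x, fs)
  y_trunc <- causal_filter(x[1:2000], fs)
  expect_equal(y_full[1:2000], y_trunc, tolerance = 1e-12)

  # step input decays back toward zero (high-pass)
  t <- seq(0, 900, by = 1 / fs)
  ys <- causal_filter(rep(1, length(t)), fs)
  expect_lt(abs(ys[length(ys)]), 0.15)
  expect_lt(abs(mean(tail(ys, 500))), abs(mean(ys[10:200])))

  # analytic order-4 Butterworth magnitude at 1 Hz
  gain <- function(f) {
    x1 <- sin(2 * pi * f * t)
    y1 <- causal_filter(x1, fs)
    sd(y1[3000:5000]) / sd(x1[3000:5000])
  }
  butter_mag <- function(f, fc) 1 / sqrt(1 + (f / fc)^(2 * 4))
  expect_lt(abs(20 * log10(gain(1)) - 20 * log10(butter_mag(1, 0.35))), 3)
  # 0.05 Hz passes within 3 dB
  expect_gt(20 * log10(gain(0.05)), -3)
  expect_error(causal_filter(x, fs, high = 5), "Nyquist")
})

test_that("adaptive non-negative regression converges to the batch solution", {
  fs <- 8.98
  n <- round(120 * fs)
  set.seed(30)
  s <- matrix(rnorm(n), ncol = 1)
  long <- 0.5 * s[, 1]
  res <- adaptive_scr(long, s, step = 0.05)
  w_end <- res$weights[n, 1]
  # batch non-negative LS oracle on the same window: w = 0.5 exactly
  batch <- max(0, sum(long * s) / sum(s^2))
  expect_equal(w_end, batch, tolerance = 0.02)
  expect_lt(sd(res$regressed[(n - 200):n]), 0.05)

  # uncorrelated shorts: weights stay near zero
  long2 <- rnorm(n)
  res2 <- adaptive_scr(long2, s, step = 0.01)
  expect_lt(abs(res2$weights[n, 1]), 0.05)

  # anti-correlated short is pinned at the constraint
  res3 <- adaptive_scr(-0.7 * s[, 1], s, step = 0.05)
  expect_equal(res3$weights[n, 1], 0)
  expect_error(adaptive_scr(long, s, step = 0), "positive")
})

test_that("trial features follow their closed forms", {
  fs <- 8.98
  n <- 400
  trial <- list(onset = 2, duration = 16)
  zero <- matrix(0, n, 2)
  f0 <- extract_features(zero, zero, fs, trial)
  expect_true(all(f0 == 0))

  # linear ramp a*t: slope a, amplitude a * duration/2
  a <- 0.3
  tt <- (seq_len(n) - 1) / fs
  ramp <- matrix(rep(a * tt, 2), ncol = 2)
  fr <- extract_features(ramp, zero, fs, trial)
  expect_equal(unname(fr["ch01_o2hb_slope"]), a, tolerance = 1e-6)
  expect_equal(unname(fr["ch01_o2hb_amplitude"]), a * 8, tolerance = 0.05)

  # perfectly anti-correlated chromophores: CBSI trace equals dO2Hb
  set.seed(31)
  o <- rnorm(200)
  h <- -4 * o
  expect_lt(max(abs(cbsi_trace(o, h) - o)), 1e-9)

  expect_error(extract_features(zero, zero, fs, list(onset = 50,
                                                     duration = 16)),
               "past the recording")
})

test_that("the sparse classifier separates, stays sparse, and rejects junk", {
  set.seed(32)
  n <- 30
  x <- cbind(f1 = c(rnorm(15, -2, 0.3), rnorm(15, 2, 0.3)),
             f2 = rnorm(n), f3 = rnorm(n), f4 = rnorm(n))
  labels <- factor(rep(c("left", "right"), each = 15),
                   levels = c("left", "right"))
  train <- structure(list(features = x, labels = labels, source = "SCR"),
                     class = "trial_dataset")
  model <- train_classifier(train, seed = 1)
  pred <- predict(model, x)
  expect_equal(mean(pred == labels), 1)
  expect_lte(model$n_selected, 2)

  # duplicated informative feature: L1 keeps at most one most of the time
  dup_kept <- 0
  for (s in 1:10) {
    set.seed(40 + s)
    x2 <- cbind(a = c(rnorm(15, -2, 0.5), rnorm(15, 2, 0.5)))
    x2 <- cbind(x2, b = x2[, "a"], c = rnorm(30), d = rnorm(30))
    tr2 <- structure(list(features = x2, labels = labels, source = "SCR"),
                     class = "trial_dataset")
    m2 <- train_classifier(tr2, seed = s)
    cf <- as.numeric(coef(m2$cv, s = m2$lambda))[-1]
    if (sum(abs(cf[1:2]) > 1e-8) <= 1) dup_kept <- dup_kept + 1
  }
  expect_gte(dup_kept, 8)

  expect_error(train_classifier(structure(
    list(features = x, labels = factor(rep("left", 30),
                                       levels = c("left", "right"))),
    class = "trial_dataset")), "both classes")

  # feature-name mismatch on evaluation
  test_ds <- structure(list(features = x[, c(2, 1, 3, 4)], labels = labels),
                       class = "trial_dataset")
  expect_error(predict(model, test_ds), "mismatch")
})

test_that("the significance line comes from exact binomial enumeration", {
  # oracle: exhaustive tail search
  oracle <- function(n, alpha) {
    for (k in 0:n) {
      if (sum(dbinom(k:n, n, 0.5)) <= alpha) return(100 * k / n)
    }
    100
  }
  for (n in c(10, 20, 30)) {
    for (a in c(0.5, 0.05, 0.01)) {
      expect_equal(significance_line(n, a), oracle(n, a))
    }
  }
  expect_equal(significance_line(30, 0.01), 100 * 22 / 30)
  expect_gte(significance_line(30, 1e-9), 97)
})

test_that("short-channel-only input classifies at chance, SCR far above", {
  study <- small_study()
  strong <- unique(study$manifest$subject[study$manifest$responder ==
                                            "strong"])
  acc_scr <- acc_ss <- c()
  for (s in strong) {
    acc_scr <- c(acc_scr, bci_evaluate(study, s, 1, "SCR", seed = 7)$accuracy)
    acc_ss <- c(acc_ss, bci_evaluate(study, s, 1, "SS_only",
                                     seed = 7)$accuracy)
  }
  expect_gte(mean(acc_scr), 90)
  expect_gte(mean(acc_ss), 30)
  expect_lte(mean(acc_ss), 70)
})
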