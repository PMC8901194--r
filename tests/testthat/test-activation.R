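proto_events <- function(n_trials = 10, seed = 18) {
  cfg <- quick_cfg(n_trials = n_trials)
  set.seed(seed)
  make_protocol(cfg)
}

test_that("design matrices have the documented column structure", {
  ev <- proto_events()
  n <- 5000; fs <- 8.98
  d0 <- build_design(ev, n, fs)
  expect_equal(ncol(d0$X), 7)           # 2 conditions x 3 + constant
  expect_false(any(d0$nonneg_mask))
  expect_equal(sum(colnames(d0$X) == "constant"), 1)

  set.seed(19)
  shorts <- matrix(rnorm(n * 8), n)
  d8 <- build_design(ev, n, fs, short_channels = shorts)
  expect_equal(ncol(d8$X), 15)
  expect_equal(sum(d8$nonneg_mask), 8)
  expect_false(d8$nonneg_mask[ncol(d8$X)])   # constant unconstrained
  # nuisance columns are mean-centered
  expect_lt(max(abs(colMeans(d8$X[, d8$nonneg_mask]))), 1e-12)

  # empty event list: baseline mode
  ev0 <- event_blocks(character(0), numeric(0), numeric(0))
  db <- build_design(ev0, n, fs, short_channels = shorts)
  expect_equal(ncol(db$X), 9)
  expect_warning(
    dq <- build_design(ev, n, fs, short_channels = shorts,
                       short_quality_db = c(20, 5, 20, 20, 20, 20, 20, 20)),
    "excluding 1")
  expect_equal(sum(dq$nonneg_mask), 7)
  expect_error(
    suppressWarnings(build_design(ev, n, fs, short_channels = shorts,
                                  short_quality_db = rep(0, 8))),
    "no usable short channels")
})

test_that("derivative regressors are orthogonal to their canonical column", {
  ev <- proto_events()
  d <- build_design(ev, 5000, 8.98)
  X <- d$X
  expect_lt(abs(sum(X[, "left_canonical"] * X[, "left_tderiv"])), 1e-8)
  expect_lt(abs(sum(X[, "left_canonical"] * X[, "left_dderiv"])), 1e-8)
})

test_that("noise-free task data gives a capped t with warning", {
  ev <- proto_events()
  d <- build_design(ev, 5000, 8.98)
  y <- 0.3 * d$X[, "right_canonical"]
  fit <- fit_glm_nnls(y, d)
  expect_warning(tv <- t_value(fit, d, "right"), "cap")
  expect_equal(tv, 1e6)
})

test_that("null t-values are centered and scale with amplitude", {
  ev <- proto_events()
  n <- 5000; fs <- 8.98
  d <- build_design(ev, n, fs)
  set.seed(20)
  tn <- replicate(300, {
    fit <- fit_glm_nnls(rnorm(n), d)
    t_value(fit, d, "left")
  })
  expect_lt(abs(mean(tn)), 0.2)    # Monte Carlo null

  # doubling the signal approximately doubles t at matched noise
  set.seed(21)
  noise <- rnorm(n)
  y1 <- 0.5 * d$X[, "right_canonical"] + noise
  y2 <- 1.0 * d$X[, "right_canonical"] + noise
  t1 <- t_value(fit_glm_nnls(y1, d), d, "right")
  t2 <- t_value(fit_glm_nnls(y2, d), d, "right")
  expect_equal(t2 / t1, 2, tolerance = 0.15)
})

test_that("baseline thresholds default to the shipped levels", {
  expect_equal(baseline_threshold(NULL, tag = "SCR")$threshold, 30)
  expect_equal(baseline_threshold(NULL, tag = "NR")$threshold, 22)
})

test_that("baseline threshold is scale-free on white-noise rest data", {
  m <- build_default_montage()
  fs <- 8.98
  cfg <- quick_cfg(n_trials = 4, seed = 22)
  set.seed(22)
  ev <- make_protocol(cfg)
  dur <- max(ev$onset + ev$duration) + 60
  n <- ceiling(2.2 * dur * fs)
  set.seed(23)
  o2 <- matrix(rnorm(n * 24), n)
  rest1 <- hemo_series(o2, -0.4 * o2, fs, m,
                       event_blocks(character(0), numeric(0), numeric(0)))
  rest2 <- rest1
  rest2$o2hb <- 2 * rest2$o2hb
  set.seed(24)
  th1 <- baseline_threshold(rest1, ev, n_draws = 150, tag = "NR")
  set.seed(24)
  th2 <- baseline_threshold(rest2, ev, n_draws = 150, tag = "NR")
  expect_equal(th2$threshold / th1$threshold, 1, tolerance = 0.1)
  expect_error(baseline_threshold(rest1, ev, n_draws = 50, tag = "NR"),
               "at least 100")
})

test_that("responder labeling averages run maxima with a strict threshold", {
  tbl <- expand.grid(session = 1:2, run = 1:2, channel = 1:2,
                     condition = c("left", "right"))
  tbl$subject <- 1
  tbl$tag <- "SCR"
  tbl$chromophore <- "o2hb"
  # run maxima 31, 35, 40, 44 -> mean 37.5 -> strong
  key <- interaction(tbl$session, tbl$run)
  tbl$t <- c(31, 35, 40, 44)[as.integer(key)] -
    ifelse(tbl$channel == 2, 5, 0)
  expect_identical(label_responder(tbl, 1), "strong")
  # run maxima 14, 20, 24, 22 -> mean 20 -> weak
  tbl$t <- c(14, 20, 24, 22)[as.integer(key)] -
    ifelse(tbl$channel == 2, 5, 0)
  expect_identical(label_responder(tbl, 1), "weak")
  # exactly at the threshold -> weak
  tbl$t <- 30
  expect_identical(label_responder(tbl, 1), "weak")
  expect_error(label_responder(tbl[tbl$session == 1, ], 1), "missing runs")
})

test_that("contralateral M1 carries the maximal t for strong responders", {
  act <- small_activation()
  study <- small_study()
  strong <- unique(study$manifest$subject[study$manifest$responder ==
                                            "strong"])
  roi <- act$roi[act$roi$tag == "SCR" & act$roi$chromophore == "o2hb", ]
  hits <- 0; total <- 0
  for (s in strong) {
    for (cond in c("left", "right")) {
      sub <- roi[roi$subject == s & roi$condition == cond, ]
      per_roi <- aggregate(t ~ roi, data = sub, FUN = mean)
      total <- total + 1
      if (per_roi$roi[which.max(per_roi$t)] == contralateral_m1_roi(cond)) {
        hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("the channelwise table has the full study bookkeeping", {
  act <- small_activation()
  ch <- act$channel
  # per chromophore and tag: subjects x 16 channels x 2 hands x 4 runs
  n_sub <- length(unique(ch$subject))
  expect_equal(nrow(ch[ch$chromophore == "o2hb" & ch$tag == "SCR", ]),
               n_sub * 16 * 2 * 4)
  expect_equal(nrow(ch), n_sub * 16 * 2 * 4 * 2 * 2)
})
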