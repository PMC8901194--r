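make_flat_recording <- function(value = 0.2, n = 500) {
  m <- build_default_montage()
  nirs_recording(array(value, c(n, 24, 4)), 8.98, m,
                 event_blocks(character(0), numeric(0), numeric(0)))
}

test_that("optical density follows the closed form", {
  rec <- make_flat_recording()
  od <- intensity_to_od(rec, c(0, 10))
  expect_true(all(od$od == 0))

  rec2 <- make_flat_recording()
  rec2$intensities[300, , ] <- 0.02       # reference / 10
  od2 <- intensity_to_od(rec2, c(0, 10))
  expect_equal(unname(od2$od[300, 1, 1]), 1, tolerance = 1e-12)

  # brute-force elementwise oracle on a random recording
  set.seed(6)
  rec3 <- make_flat_recording()
  rec3$intensities[] <- abs(rnorm(length(rec3$intensities), 0.2, 0.02)) + 0.01
  od3 <- intensity_to_od(rec3, c(0, 20))
  i1 <- ceiling(20 * rec3$fs)
  oracle <- -log10(rec3$intensities[17, 5, 2] /
                     mean(rec3$intensities[1:i1, 5, 2]))
  expect_equal(unname(od3$od[17, 5, 2]), oracle, tolerance = 1e-9)

  rec4 <- make_flat_recording()
  rec4$intensities[10, 2, 1] <- 0
  expect_error(intensity_to_od(rec4), "sample 10, channel 2")
})

test_that("MBLL inversion recovers known and random chromophore vectors", {
  m <- build_default_montage()
  params <- mbll_params(separations_mm = m$channels$separation_mm)
  # null case
  od0 <- structure(list(od = array(0, c(5, 24, 4)), fs = 8.98,
                        reference = NULL, montage = m,
                        events = event_blocks(character(0), numeric(0),
                                              numeric(0)),
                        meta = list()), class = "optical_density")
  h0 <- od_to_hemoglobin(od0, params)
  expect_true(all(h0$o2hb == 0) && all(h0$hhb == 0))

  # the study's reported response amplitudes
  o2 <- matrix(0.26, 3, 24); hh <- matrix(-0.12, 3, 24)
  od <- forward_mbll(o2, hh, params)
  odo <- od0; odo$od <- od
  back <- od_to_hemoglobin(odo, params)
  expect_lt(max(abs(back$o2hb - 0.26)), 1e-9)
  expect_lt(max(abs(back$hhb + 0.12)), 1e-9)

  # random round trips
  set.seed(7)
  o2r <- matrix(rnorm(200 * 24), 200, 24)
  hhr <- matrix(rnorm(200 * 24), 200, 24)
  odr <- od0; odr$od <- forward_mbll(o2r, hhr, params)
  backr <- od_to_hemoglobin(odr, params)
  expect_lt(max(abs(backr$o2hb - o2r), abs(backr$hhb - hhr)), 1e-8)
})

test_that("rank-deficient extinction tables are rejected", {
  e <- extinction_default()
  e[, 2] <- 2 * e[, 1]
  expect_error(mbll_params(extinction = e, separations_mm = rep(30, 4)),
               "rank")
})

test_that("band-pass magnitude and phase meet the design", {
  fs <- 8.98
  t <- seq(0, 700, by = 1 / fs)
  mid <- 2500:3500
  atten <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- bandpass_fir(x, fs = fs)
    20 * log10(sd(y[mid]) / sd(x[mid]))
  }
  expect_lt(atten(1), -40)            # cardiac rejected
  expect_lt(atten(0.5), -40)
  expect_gt(atten(0.1), -1)           # Mayer band passes
  expect_gt(atten(0.05), -1)
  expect_gt(atten(0.3), -1)
  # zero phase at 0.1 Hz
  x <- sin(2 * pi * 0.1 * t)
  y <- bandpass_fir(x, fs = fs)
  basis <- cbind(sin(2 * pi * 0.1 * t), cos(2 * pi * 0.1 * t))
  cf <- qr.solve(basis[mid, ], y[mid])
  expect_lt(abs(atan2(cf[2], cf[1]) * 180 / pi), 1)
  # DC removal
  yd <- bandpass_fir(rep(2, length(t)), fs = fs)
  expect_lt(abs(mean(yd[mid])), 1e-3 * 2)
  expect_error(bandpass_fir(rnorm(100), fs = fs), "order")
})

test_that("preprocessing is linear for artifact-free input", {
  cfg <- quick_cfg(seed = 8)
  set.seed(8)
  prof <- subject_profiles(cfg, 1, 0)[[1]]
  sim <- simulate_recording(prof, cfg, seed = 81)
  hemo <- od_to_hemoglobin(intensity_to_od(sim$recording))
  x <- hemo$o2hb[, 3]
  a <- 3.7
  y1 <- bandpass_fir(a * x, fs = hemo$fs)
  y2 <- a * bandpass_fir(x, fs = hemo$fs)
  expect_equal(y1, y2, tolerance = 1e-10)
})

test_that("spline motion correction removes steps, leaves clean data alone", {
  fs <- 8.98
  t <- seq(0, 300, by = 1 / fs)
  set.seed(9)
  # slow physiological background: level re-anchoring across an artifact is
  # only identifiable when the background varies slowly vs the anchor window
  clean <- 0.5 * sin(2 * pi * 0.01 * t) + rnorm(length(t), 0, 0.2)
  out <- remove_motion_spline(clean, fs)
  expect_identical(out$signal, clean)
  expect_false(any(out$mask))

  # constant signal: zero moving sd, unchanged
  cst <- rep(1.5, 200)
  outc <- remove_motion_spline(cst, fs)
  expect_identical(outc$signal, cst)
  expect_false(any(outc$mask))

  # injected step of 10x the noise sd
  step_at <- 1500
  step_size <- 10 * 0.2
  contaminated <- clean + c(rep(0, step_at), rep(step_size,
                                                 length(t) - step_at))
  outs <- remove_motion_spline(contaminated, fs)
  expect_true(any(outs$mask))
  # discontinuity at the step after correction, vs the uncontaminated signal
  w <- 20
  jump_before <- mean(outs$signal[(step_at - w):step_at]) -
    mean(clean[(step_at - w):step_at])
  jump_after <- mean(outs$signal[(step_at + 1):(step_at + w)]) -
    mean(clean[(step_at + 1):(step_at + w)])
  expect_lt(abs(jump_after - jump_before), 0.1 * step_size)
})

test_that("an all-artifact series is de-trended with a warning", {
  fs <- 8.98
  set.seed(10)
  # a vanishing threshold flags every sample
  x <- cumsum(rnorm(300, 0, 5)) + sin(seq(0, 10, length.out = 300))
  expect_warning(
    out <- remove_motion_spline(x, fs, threshold = 1e-6),
    "artifact")
  expect_true(all(out$mask))
})
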