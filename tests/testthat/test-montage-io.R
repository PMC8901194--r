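test_that("default montage matches the device geometry", {
  m <- build_default_montage()
  expect_equal(m$wavelengths, c(774, 817, 865, 892))
  expect_equal(sum(m$channels$role == "long"), 16)
  expect_equal(sum(m$channels$role == "short"), 8)
  expect_equal(length(m$roi_map), 8)
  for (rid in names(m$roi_map)) {
    idx <- m$roi_map[[rid]]
    expect_length(idx, 2)
    expect_true(all(m$channels$role[idx] == "long"))
  }
  expect_true(all(m$channels$separation_mm[m$channels$role == "short"] ==
                    7.5))
  expect_true(all(m$channels$separation_mm[m$channels$role == "long"] == 30))
})

test_that("channel role is a pure function of separation with a 10 mm cut", {
  set.seed(1)
  sep <- runif(500, 0.5, 60)
  role <- channel_role(sep)
  expect_identical(role, ifelse(sep <= 10, "short", "long"))
  expect_identical(channel_role(7.5), "short")
  expect_identical(channel_role(30), "long")
  expect_identical(channel_role(10), "short")
})

test_that("event tables reject overlap and negative onsets", {
  expect_error(event_blocks("left", -1, 10))
  expect_error(event_blocks(c("left", "right"), c(0, 5), c(10, 10)),
               "overlap")
  ev <- event_blocks(c("right", "left"), c(20, 0), c(5, 5))
  expect_equal(ev$onset, c(0, 20))   # sorted
})

make_test_recording <- function(n = 400, seed = 3) {
  m <- build_default_montage()
  set.seed(seed)
  intens <- array(abs(rnorm(n * 24 * 4, 0.2, 0.01)), c(n, 24, 4))
  ev <- event_blocks(c("left", "right"), c(5, 25), c(10, 10))
  nirs_recording(intens, 8.98, m, ev,
                 meta = list(subject = 4L, session = 2L, run = 1L))
}

test_that("csv bundle round-trips a recording losslessly", {
  rec <- make_test_recording()
  path <- file.path(tempdir(), "bundle_test")
  on.exit(unlink(path, recursive = TRUE))
  write_recording(rec, path, "csv_bundle")
  back <- read_recording(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$events, rec$events)
  expect_equal(back$montage$channels$separation_mm,
               rec$montage$channels$separation_mm)
  expect_identical(back$montage$channels$role, rec$montage$channels$role)
  expect_equal(back$meta$subject, rec$meta$subject)
  expect_lt(max(abs(back$intensities - rec$intensities)) /
              max(rec$intensities), 1e-12)
})

test_that("snirf round-trips a recording losslessly", {
  rec <- make_test_recording(seed = 8)
  path <- file.path(tempdir(), "test.snirf")
  on.exit(unlink(path))
  write_recording(rec, path, "snirf")
  back <- read_recording(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$events, rec$events)
  expect_identical(back$montage$channels$role, rec$montage$channels$role)
  expect_equal(back$montage$roi_map, rec$montage$roi_map)
  expect_lt(max(abs(back$intensities - rec$intensities)) /
              max(rec$intensities), 1e-12)
})

test_that("a recording with zero events writes a valid empty-stim file", {
  rec <- make_test_recording()
  rec$events <- event_blocks(character(0), numeric(0), numeric(0))
  for (dialect in c("csv_bundle", "snirf")) {
    path <- file.path(tempdir(), paste0("empty_", dialect))
    if (dialect == "snirf") path <- paste0(path, ".snirf")
    on.exit(unlink(path, recursive = TRUE), add = TRUE)
    write_recording(rec, path, dialect)
    back <- read_recording(path)
    expect_equal(nrow(back$events), 0)
  }
})

test_that("missing geometry and non-finite samples are rejected", {
  rec <- make_test_recording()
  path <- file.path(tempdir(), "broken_bundle")
  on.exit(unlink(path, recursive = TRUE))
  write_recording(rec, path, "csv_bundle")
  side <- jsonlite::read_json(file.path(path, "recording.json"),
                              simplifyVector = TRUE)
  side$montage$wavelengths <- NULL
  jsonlite::write_json(side, file.path(path, "recording.json"),
                       auto_unbox = TRUE)
  expect_error(read_recording(path), "wavelength")
  m <- build_default_montage()
  x <- array(0.1, c(10, 24, 4))
  x[3, 5, 1] <- NA
  expect_error(
    nirs_recording(x, 8.98, m, event_blocks(character(0), numeric(0),
                                            numeric(0))),
    "sample 3, channel 5")
})

test_that("recording validation enforces event bounds and montage match", {
  m <- build_default_montage()
  x <- array(0.1, c(10, 24, 4))
  ev <- event_blocks("left", 0.5, 10)   # ends after 10/8.98 s
  expect_error(nirs_recording(x, 8.98, m, ev), "ends after")
  expect_error(nirs_recording(array(0.1, c(10, 23, 4)), 8.98, m,
                              event_blocks(character(0), numeric(0),
                                           numeric(0))),
               "channel count")
})
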