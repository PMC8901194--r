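#' Write a recording to disk
#'
#' Two dialects are supported. `"snirf"` writes the community-standard SNIRF
#' HDF5 layout (groups `/nirs/data1`, `/nirs/probe`, `/nirs/stim*`) and, to
#' make write-then-read lossless, additionally stores the complete montage and
#' metadata as a JSON string under `/nirs/metaDataTags` (SNIRF permits extra
#' tags). `"csv_bundle"` writes a directory with one intensity CSV per
#' wavelength plus a JSON sidecar holding montage, events, sampling rate and
#' metadata -- convenient for eyeballing the numbers.
#'
#' @param rec A [nirs_recording()].
#' @param path Output file (`.snirf`) or directory (`csv_bundle`).
#' @param dialect `"snirf"` or `"csv_bundle"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("snirf", "csv_bundle")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "nirs_recording"))
  if (dialect == "csv_bundle") write_csv_bundle(rec, path)
  else write_snirf(rec, path)
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. Channel roles are re-derived from the
#' stored separations. Intensities round-trip to better than 1e-12 relative.
#'
#' @param path File or bundle directory.
#' @param dialect `"snirf"` or `"csv_bundle"`; guessed from `path` when
#'   missing (directory -> csv_bundle, file -> snirf).
#' @return A validated [nirs_recording()].
#' @export
read_recording <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (dir.exists(path)) "csv_bundle" else "snirf"
  }
  dialect <- match.arg(dialect, c("snirf", "csv_bundle"))
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dialect == "csv_bundle") read_csv_bundle(path) else read_snirf(path)
}

montage_to_list <- function(montage) {
  list(channels = montage$channels,
       wavelengths = montage$wavelengths,
       roi_map = montage$roi_map)
}

montage_from_list <- function(ml) {
  if (is.null(ml$wavelengths)) stop("format error: missing wavelength table")
  if (is.null(ml$channels)) stop("format error: missing channel geometry")
  ch <- as.data.frame(ml$channels)
  ch$roi_id <- as.integer(ch$roi_id)
  roi_map <- lapply(ml$roi_map, as.integer)
  nirs_montage(ch, as.numeric(ml$wavelengths), roi_map)
}

events_from_list <- function(el) {
  if (is.null(el) || length(el) == 0 ||
      (is.data.frame(el) && nrow(el) == 0)) {
    return(event_blocks(character(0), numeric(0), numeric(0)))
  }
  el <- as.data.frame(el)
  event_blocks(el$condition, el$onset, el$duration)
}

## --- csv_bundle ------------------------------------------------------------

write_csv_bundle <- function(rec, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create bundle directory: ", path)
  }
  side <- list(format = "nirscr_csv_bundle", version = 1L,
               fs = rec$fs, meta = rec$meta,
               montage = montage_to_list(rec$montage),
               events = rec$events)
  jsonlite::write_json(side, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (w in seq_along(rec$montage$wavelengths)) {
    f <- file.path(path, sprintf("intensity_%gnm.csv",
                                 rec$montage$wavelengths[w]))
    utils::write.table(format(rec$intensities[, , w], digits = 17,
                              scientific = TRUE, trim = TRUE),
                       f, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

read_csv_bundle <- function(path) {
  sidefile <- file.path(path, "recording.json")
  if (!file.exists(sidefile)) stop("format error: missing recording.json")
  side <- jsonlite::read_json(sidefile, simplifyVector = TRUE)
  montage <- montage_from_list(side$montage)
  events <- events_from_list(side$events)
  nwl <- length(montage$wavelengths)
  mats <- vector("list", nwl)
  for (w in seq_len(nwl)) {
    f <- file.path(path, sprintf("intensity_%gnm.csv", montage$wavelengths[w]))
    if (!file.exists(f)) stop("format error: missing intensity file ", f)
    mats[[w]] <- as.matrix(utils::read.table(f, sep = ","))
  }
  intens <- array(0, c(nrow(mats[[1]]), ncol(mats[[1]]), nwl))
  for (w in seq_len(nwl)) intens[, , w] <- mats[[w]]
  check_finite_intensities(intens)
  meta <- side$meta
  meta$session <- as.integer(meta$session)
  meta$run <- as.integer(meta$run)
  nirs_recording(intens, side$fs, montage, events, meta)
}

check_finite_intensities <- function(intens) {
  bad <- which(!is.finite(intens), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("validation error: non-finite sample %d on channel %d",
                 bad[1, 1], bad[1, 2]))
  }
}

## --- SNIRF -----------------------------------------------------------------

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the SNIRF dialect needs the 'rhdf5' package; ",
         "use dialect = \"csv_bundle\" otherwise")
  }
}

# nominal 2D optode coordinates (mm) for the probe block; the authoritative
# montage travels in metaDataTags
optode_positions <- function() {
  left <- cbind(x = c(-45, -45, -75, -75), y = c(0, 30, 0, 30))
  right <- cbind(x = -left[, "x"], y = left[, "y"])
  rbind(left, right)
}

write_snirf <- function(rec, path) {
  need_rhdf5()
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("I/O error: cannot create ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  h5w("1.0", "/formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  n <- dim(rec$intensities)[1]
  nch <- dim(rec$intensities)[2]
  nwl <- dim(rec$intensities)[3]
  # columns ordered wavelength-major within channel
  flat <- matrix(0, n, nch * nwl)
  k <- 0
  for (c in seq_len(nch)) {
    for (w in seq_len(nwl)) {
      k <- k + 1
      flat[, k] <- rec$intensities[, c, w]
    }
  }
  h5w(flat, "nirs/data1/dataTimeSeries")
  h5w(seq_len(n) / rec$fs - 1 / rec$fs, "nirs/data1/time")
  k <- 0
  for (c in seq_len(nch)) {
    for (w in seq_len(nwl)) {
      k <- k + 1
      g <- sprintf("nirs/data1/measurementList%d", k)
      rhdf5::h5createGroup(path, g)
      h5w(rec$montage$channels$source_id[c], paste0(g, "/sourceIndex"))
      h5w(rec$montage$channels$detector_id[c], paste0(g, "/detectorIndex"))
      h5w(w, paste0(g, "/wavelengthIndex"))
      h5w(1L, paste0(g, "/dataType"))
      h5w(1L, paste0(g, "/dataTypeIndex"))
    }
  }
  rhdf5::h5createGroup(path, "nirs/probe")
  h5w(rec$montage$wavelengths, "nirs/probe/wavelengths")
  pos <- optode_positions()
  h5w(cbind(pos, 0), "nirs/probe/sourcePos3D")
  h5w(cbind(pos + 7.5 / sqrt(2), 0), "nirs/probe/detectorPos3D")
  conds <- unique(rec$events$condition)
  for (i in seq_along(conds)) {
    g <- sprintf("nirs/stim%d", i)
    rhdf5::h5createGroup(path, g)
    h5w(conds[i], paste0(g, "/name"))
    sel <- rec$events$condition == conds[i]
    h5w(cbind(rec$events$onset[sel], rec$events$duration[sel], 1),
        paste0(g, "/data"))
  }
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  h5w("s", "nirs/metaDataTags/TimeUnit")
  h5w("V", "nirs/metaDataTags/LengthUnit")
  side <- list(fs = rec$fs, meta = rec$meta,
               montage = montage_to_list(rec$montage),
               events = rec$events)
  h5w(as.character(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                                    dataframe = "columns")),
      "nirs/metaDataTags/nirscrJSON")
  invisible(path)
}

read_snirf <- function(path) {
  need_rhdf5()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  if (!"nirscrJSON" %in% contents$name) {
    if (!"wavelengths" %in% contents$name) {
      stop("format error: missing wavelength table")
    }
    stop("format error: SNIRF file lacks the nirscr metadata tag")
  }
  side <- jsonlite::fromJSON(
    rhdf5::h5read(path, "nirs/metaDataTags/nirscrJSON"))
  montage <- montage_from_list(side$montage)
  events <- events_from_list(side$events)
  flat <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  nch <- nrow(montage$channels)
  nwl <- length(montage$wavelengths)
  n <- nrow(flat)
  intens <- array(0, c(n, nch, nwl))
  k <- 0
  for (c in seq_len(nch)) {
    for (w in seq_len(nwl)) {
      k <- k + 1
      intens[, c, w] <- flat[, k]
    }
  }
  check_finite_intensities(intens)
  meta <- side$meta
  meta$session <- as.integer(meta$session)
  meta$run <- as.integer(meta$run)
  nirs_recording(intens, side$fs, montage, events, meta)
}
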