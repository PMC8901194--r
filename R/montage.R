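#' Channel role from source-detector separation
#'
#' Channels at or below 10 mm separation are scalp-sensitive short-separation
#' (SS) channels; everything wider is a long-separation (LS) channel that
#' samples scalp plus cortex.
#'
#' @param separation_mm Numeric vector of source-detector separations in mm.
#' @return Character vector, `"short"` or `"long"`.
#' @export
channel_role <- function(separation_mm) {
  stopifnot(is.numeric(separation_mm), all(is.finite(separation_mm)),
            all(separation_mm > 0))
  ifelse(separation_mm <= 10, "short", "long")
}

#' Construct a montage
#'
#' A montage holds the ordered channel table, the source wavelengths and the
#' mapping from regions of interest (ROIs) to pairs of long channels.
#'
#' @param channels `data.frame` with columns `source_id`, `detector_id`,
#'   `separation_mm`, `roi_id` (NA for short channels) and `hemisphere`
#'   (`"left"`/`"right"`). The `role` column is derived from the separation.
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param roi_map Named list mapping ROI id (as character) to the integer
#'   indices of its long channels in `channels`.
#' @return An object of class `nirs_montage`.
#' @export
nirs_montage <- function(channels, wavelengths, roi_map) {
  stopifnot(is.data.frame(channels),
            all(c("source_id", "detector_id", "separation_mm", "roi_id",
                  "hemisphere") %in% names(channels)))
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  channels$role <- channel_role(channels$separation_mm)
  long_idx <- which(channels$role == "long")
  if (any(is.na(channels$roi_id[long_idx]))) {
    stop("every long channel must map to exactly one roi_id")
  }
  if (any(!is.na(channels$roi_id[channels$role == "short"]))) {
    stop("short channels must not carry a roi_id")
  }
  m <- structure(list(channels = channels,
                      wavelengths = as.numeric(wavelengths),
                      roi_map = roi_map),
                 class = "nirs_montage")
  for (rid in names(roi_map)) {
    idx <- roi_map[[rid]]
    if (any(channels$role[idx] != "long") ||
        any(channels$roi_id[idx] != as.integer(rid))) {
      stop("roi_map inconsistent with channel table for ROI ", rid)
    }
  }
  m
}

#' Default 8-optode bilateral motor-cortex montage
#'
#' Eight optode modules placed symmetrically over the two hemispheres (four
#' per side, covering M1 and premotor areas). Each module contributes one
#' 7.5 mm short-separation channel; modules within 30 mm of each other form
#' reciprocal long-channel pairs probing the same cortical location, giving
#' 16 long channels grouped into 8 ROIs of two channels each. ROI 1 is the
#' left M1 (contralateral to right-hand movement), ROI 5 the right M1.
#' Sources emit at 774, 817, 865 and 892 nm.
#'
#' Channel ordering is fixed (and arbitrary, since no device convention is
#' published): long channels 1-16 sorted by ROI (ROI r owns channels 2r-1 and
#' 2r), then short channels 17-24 sorted by optode.
#'
#' @return A `nirs_montage` with 24 channels.
#' @export
build_default_montage <- function() {
  # optodes 1:4 left hemisphere, 5:8 right; ROI r formed by the reciprocal
  # channel pair between two optodes
  roi_pairs <- list(`1` = c(1L, 2L), `2` = c(1L, 3L), `3` = c(2L, 4L),
                    `4` = c(3L, 4L),
                    `5` = c(5L, 6L), `6` = c(5L, 7L), `7` = c(6L, 8L),
                    `8` = c(7L, 8L))
  src <- det <- roi <- integer(0)
  for (rid in seq_along(roi_pairs)) {
    p <- roi_pairs[[rid]]
    src <- c(src, p[1], p[2])
    det <- c(det, p[2], p[1])
    roi <- c(roi, rid, rid)
  }
  channels <- data.frame(
    source_id = c(src, 1:8),
    detector_id = c(det, 1:8),
    separation_mm = c(rep(30, 16), rep(7.5, 8)),
    roi_id = c(roi, rep(NA_integer_, 8)),
    hemisphere = c(ifelse(src <= 4, "left", "right"),
                   ifelse(1:8 <= 4, "left", "right"))
  )
  roi_map <- lapply(1:8, function(r) which(channels$roi_id %in% r))
  names(roi_map) <- as.character(1:8)
  nirs_montage(channels, c(774, 817, 865, 892), roi_map)
}

#' @export
print.nirs_montage <- function(x, ...) {
  n_long <- sum(x$channels$role == "long")
  n_short <- sum(x$channels$role == "short")
  cat("fNIRS montage:", n_long, "long +", n_short, "short channels,",
      length(x$roi_map), "ROIs; wavelengths (nm):",
      paste(x$wavelengths, collapse = ", "), "\n")
  invisible(x)
}

#' Indices of long / short channels in a montage
#'
#' @param montage A [nirs_montage()].
#' @return Integer vector of channel indices.
#' @export
long_channels <- function(montage) which(montage$channels$role == "long")

#' @rdname long_channels
#' @export
short_channels <- function(montage) which(montage$channels$role == "short")

#' Contralateral primary-motor ROI for a task condition
#'
#' Right-hand grasping activates the left M1 (ROI 1) and vice versa (ROI 5).
#'
#' @param condition `"left"` or `"right"`.
#' @return Integer ROI id.
#' @export
contralateral_m1_roi <- function(condition) {
  switch(match.arg(condition, c("left", "right")), right = 1L, left = 5L)
}
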